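#' Branch-length optimization and BIC model choice
#'
#' Branch lengths are optimized one at a time by bracketed Brent search on
#' [bl_min, bl_max], cycling over branches until the total log-likelihood
#' improves by less than `tol` or `max_rounds` is reached. Model selection
#' replaces a full model-finder with a BIC sweep over a small candidate
#' family.
#'
#' @name likelihood-optimization
NULL

BL_MIN <- 1e-8
BL_MAX <- 10

#' Optimize branch lengths on a fixed topology
#'
#' @param tree unrooted `phylo` with starting branch lengths.
#' @param alignment a [dna_alignment].
#' @param model a [subst_model].
#' @param tol stop when a full cycle improves total lnL by less than this.
#' @param max_rounds maximum optimization cycles; a warning is issued if
#'   reached without convergence.
#' @param bl_min,bl_max clamps on branch lengths (substitutions/site).
#' @return The tree with optimized `edge.length` and attribute `loglik`
#'   (the final total log-likelihood, never below the starting one).
#' @export
optimize_branch_lengths <- function(tree, alignment, model, tol = 1e-6,
                                    max_rounds = 20L, bl_min = BL_MIN,
                                    bl_max = BL_MAX, warn = TRUE) {
  validate_phylo(tree, require_binary = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  tree$edge.length <- pmin(pmax(tree$edge.length, bl_min), bl_max)
  tipp <- tip_partials(alignment)[tree$tip.label]
  lnl_of <- function(el) {
    tr <- tree; tr$edge.length <- el
    sum(site_loglik_prepared(tr, tipp, model))
  }
  el <- tree$edge.length
  cur <- lnl_of(el)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    before <- cur
    for (e in seq_along(el)) {
      f <- function(x) { el2 <- el; el2[e] <- x; lnl_of(el2) }
      opt <- stats::optimize(f, c(bl_min, bl_max), maximum = TRUE,
                             tol = 1e-7)
      if (opt$objective > cur) {
        el[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tol) { converged <- TRUE; break }
  }
  if (!converged && warn)
    warning("branch-length optimization did not converge within max_rounds; ",
            "returning best lengths found")
  tree$edge.length <- el
  attr(tree, "loglik") <- cur
  tree
}

# Fit free model parameters (kappa / GTR exchangeabilities / gamma shape)
# and branch lengths for one candidate family, by alternating Brent
# branch-length passes with Nelder-Mead on log-transformed parameters.
fit_candidate <- function(alignment, tree, family, cycles = 1L) {
  gamma <- grepl("\\+G", family)
  base <- sub("\\+G\\d*$", "", family)
  freq <- if (base == "JC69") rep(0.25, 4) else base_frequencies(alignment)
  make <- function(par) {
    switch(base,
      JC69  = subst_model("JC69", gamma_shape = if (gamma) exp(par[1]) else 1,
                          gamma_k = if (gamma) 4L else 0L),
      HKY85 = subst_model("HKY85", freq = freq, kappa = exp(par[1]),
                          gamma_shape = if (gamma) exp(par[2]) else 1,
                          gamma_k = if (gamma) 4L else 0L),
      GTR   = subst_model("GTR", freq = freq,
                          rates = c(exp(par[1:5]), 1),
                          gamma_shape = if (gamma) exp(par[6]) else 1,
                          gamma_k = if (gamma) 4L else 0L))
  }
  npar_free <- switch(base, JC69 = 0L, HKY85 = 1L, GTR = 5L) + gamma
  par <- switch(base, JC69 = numeric(0), HKY85 = log(2),
                GTR = rep(0, 5))
  if (gamma) par <- c(par, log(1))
  model <- make(par)
  fit <- optimize_branch_lengths(tree, alignment, model, max_rounds = 5L,
                                 warn = FALSE)
  lnl <- attr(fit, "loglik")
  if (npar_free > 0L) {
    for (cy in seq_len(cycles)) {
      obj <- function(p) -total_log_likelihood(fit, alignment, make(p))
      o <- if (length(par) == 1L) {
        stats::optim(par, obj, method = "Brent", lower = -7, upper = 7)
      } else {
        stats::optim(par, obj, method = "Nelder-Mead",
                     control = list(maxit = 100L))
      }
      par <- o$par
      model <- make(par)
      fit <- optimize_branch_lengths(fit, alignment, model, max_rounds = 5L,
                                     warn = FALSE)
      lnl <- attr(fit, "loglik")
    }
  }
  # parameter count: branch lengths are shared across candidates and BIC is
  # used comparatively, so only substitution parameters are counted:
  # 3 free frequencies when empirical, exchangeabilities, and alpha.
  npar <- switch(base, JC69 = 0L, HKY85 = 4L, GTR = 8L) + gamma
  list(model = model, tree = fit, loglik = lnl, npar = npar)
}

#' Select a substitution model by BIC
#'
#' Fits each candidate on the given topology (branch lengths and free
#' model parameters optimized) and returns the candidate minimizing
#' BIC = -2 lnL + params * log(n); ties favour the model with fewer
#' parameters.
#'
#' @param alignment a [dna_alignment].
#' @param tree topology used for all candidate fits (e.g. [nj_tree()]).
#' @param candidates character vector of model names among "JC69",
#'   "HKY85", "GTR", optionally with "+G4".
#' @return The winning [subst_model], with attribute `selection` holding
#'   the comparison table (candidate, loglik, params, BIC).
#' @export
select_model <- function(alignment, tree,
                         candidates = c("JC69", "JC69+G4", "HKY85",
                                        "HKY85+G4", "GTR", "GTR+G4")) {
  if (!length(candidates)) stop("candidate list is empty")
  n <- ncol(alignment)
  fits <- lapply(candidates, function(fam)
    fit_candidate(alignment, tree, fam))
  tab <- data.frame(
    candidate = candidates,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    params = vapply(fits, `[[`, 0L, "npar"))
  tab$bic <- -2 * tab$loglik + tab$params * log(n)
  eligible <- which(tab$bic <= min(tab$bic) + 1e-9)
  best <- eligible[which.min(tab$params[eligible])]
  model <- fits[[best]]$model
  attr(model, "selection") <- tab
  model
}
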