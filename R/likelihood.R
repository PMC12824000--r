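#' Felsenstein pruning likelihood engine
#'
#' Site-wise log-likelihoods of an alignment on an unrooted tree under a
#' [subst_model], by post-order partial-likelihood propagation with
#' per-node rescaling (so alignments of thousands of sites at short branch
#' lengths do not underflow). Gap and IUPAC ambiguity characters contribute
#' partial likelihood 1 for every compatible state. Gamma rate
#' heterogeneity is an equal-weight discrete mixture; invariant-site
#' proportions mix a point mass at rate 0.
#'
#' @name likelihood-engine
NULL

IUPAC_STATES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"))

IUPAC_TABLE <- local({
  tab <- sapply(IUPAC_STATES, function(s)
    as.numeric(c("A", "C", "G", "T") %in% s))
  rownames(tab) <- c("A", "C", "G", "T")
  tab
})

# 4 x length(chars) indicator matrix of compatible states.
iupac_indicator <- function(chars) {
  m <- IUPAC_TABLE[, chars, drop = FALSE]
  dimnames(m) <- NULL
  m
}

# Per-taxon 4 x n tip partial likelihoods, as a named list.
tip_partials <- function(alignment) {
  m <- unclass(alignment)
  out <- lapply(seq_len(nrow(m)), function(i) iupac_indicator(m[i, ]))
  names(out) <- rownames(m)
  out
}

# Core pruning pass for one tree and one rate multiplier.
# edge/el come from a postorder-reordered tree; tipp is indexed by the
# tree's tip numbering. Returns list(loglik = per-site log-likelihood
# conditional on this rate).
prune_site_lik <- function(edge, el, tipp, ntip, nnode, model, rate) {
  n <- ncol(tipp[[1L]])
  partial <- vector("list", ntip + nnode)
  partial[seq_len(ntip)] <- tipp
  logsc <- numeric(n)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- transition_matrix(model, el[e] * rate)
    contrib <- P %*% partial[[ch]]
    acc <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
    mx <- pmax(acc[1L, ], acc[2L, ], acc[3L, ], acc[4L, ])
    scale_ok <- mx > 0
    mx[!scale_ok] <- 1
    partial[[p]] <- acc / rep(mx, each = 4L)
    logsc <- logsc + log(mx)
  }
  root <- edge[nrow(edge), 1L]
  log(colSums(model$freq * partial[[root]])) + logsc
}

# Likelihood of a column being an invariant realization of each state:
# sum_x pi_x * prod_taxa 1{taxon compatible with x}.
invariant_site_lik <- function(tipp, freq) {
  prod_ind <- Reduce(`*`, tipp)
  colSums(freq * prod_ind)
}

#' Site-wise log-likelihoods of an alignment on a tree
#'
#' @param tree an unrooted binary `phylo` whose tip labels match the
#'   alignment taxa exactly (no subsetting is performed).
#' @param alignment a [dna_alignment].
#' @param model a [subst_model].
#' @return Numeric vector of n site log-likelihoods.
#' @export
site_log_likelihoods <- function(tree, alignment, model) {
  stopifnot(inherits(alignment, "dna_alignment"),
            inherits(model, "subst_model"))
  validate_phylo(tree, require_binary = FALSE)
  if (!setequal(tree$tip.label, rownames(alignment)) ||
      length(tree$tip.label) != nrow(alignment))
    stop("tree taxa and alignment taxa must match exactly")
  tipp <- tip_partials(alignment)[tree$tip.label]
  site_loglik_prepared(tree, tipp, model)
}

# Same computation on pre-extracted tip partials ordered by tree$tip.label.
site_loglik_prepared <- function(tree, tipp, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  k <- max(model$gamma_k, 1L)
  rates <- model$cat_rates
  ll_cat <- lapply(rates, function(r)
    prune_site_lik(tree$edge, tree$edge.length, tipp, ntip, tree$Nnode,
                   model, r))
  if (length(ll_cat) == 1L) {
    mix <- ll_cat[[1L]]
  } else {
    # log of the equal-weight category mixture
    M <- do.call(rbind, ll_cat)
    mx <- apply(M, 2L, max)
    mix <- mx + log(colMeans(exp(M - rep(mx, each = k))))
  }
  out <- if (model$p_inv > 0) {
    iv <- invariant_site_lik(tipp, model$freq)
    mx <- pmax(mix, 0)
    mx + log((1 - model$p_inv) * exp(mix - mx) + model$p_inv * iv * exp(-mx))
  } else {
    mix
  }
  if (any(!is.finite(out)))
    stop("non-finite site log-likelihood")
  out
}

#' Total log-likelihood of an alignment on a tree
#'
#' Exactly the sum of [site_log_likelihoods()] (same code path), reflecting
#' the independence of alignment columns.
#'
#' @inheritParams site_log_likelihoods
#' @return Scalar log-likelihood.
#' @export
total_log_likelihood <- function(tree, alignment, model) {
  sum(site_log_likelihoods(tree, alignment, model))
}

#' Site log-likelihood matrix over a tree ensemble
#'
#' Computes the T x n matrix of site log-likelihoods (one row per random
#' tree) together with the per-tree totals: the features and the response
#' of the sparse informativeness regression.
#'
#' @param ensemble a `tree_ensemble` from [build_ensemble()].
#' @param alignment a [dna_alignment] over exactly the ensemble taxa.
#' @param model a [subst_model].
#' @param verbose log progress every 100 trees.
#' @return A `sitelh_matrix`: list with `loglik` (T x n), `totals`
#'   (length T), `n_taxa`.
#' @export
compute_sitelh_matrix <- function(ensemble, alignment, model,
                                  verbose = FALSE) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (!setequal(ensemble$taxa, rownames(alignment)))
    stop("ensemble taxa and alignment taxa must match exactly")
  tipp_all <- tip_partials(alignment)
  n <- ncol(alignment)
  Tn <- length(ensemble$trees)
  M <- matrix(NA_real_, Tn, n)
  for (t in seq_len(Tn)) {
    tr <- ensemble$trees[[t]]
    M[t, ] <- site_loglik_prepared(tr, tipp_all[tr$tip.label], model)
    if (verbose && t %% 100L == 0L)
      message(sprintf("  site likelihoods: %d / %d trees", t, Tn))
  }
  structure(list(loglik = M, totals = rowSums(M), n_taxa = nrow(alignment)),
            class = "sitelh_matrix")
}

#' @export
print.sitelh_matrix <- function(x, ...) {
  cat(sprintf("Site log-likelihood matrix: %d trees x %d sites\n",
              nrow(x$loglik), ncol(x$loglik)))
  invisible(x)
}

#' Write / read a site log-likelihood table as TSV
#'
#' Interchange format between the likelihood engine and the Lasso stage:
#' UTF-8, tab-separated, "." decimal; header
#' `tree_id  total_lnL  s1 ... sn`, one row per tree, 10 significant
#' digits.
#'
#' @param sitelh a `sitelh_matrix`.
#' @param path output (input) path.
#' @return `write_sitelh()`: `path` invisibly; `read_sitelh()`: a
#'   `sitelh_matrix`.
#' @export
write_sitelh <- function(sitelh, path) {
  stopifnot(inherits(sitelh, "sitelh_matrix"))
  M <- sitelh$loglik
  df <- data.frame(tree_id = seq_len(nrow(M)),
                   total_lnL = fmt10(sitelh$totals))
  cols <- as.data.frame(apply(M, 2L, fmt10))
  names(cols) <- paste0("s", seq_len(ncol(M)))
  utils::write.table(cbind(df, cols), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fmt10 <- function(x) formatC(x, digits = 10, format = "g")

#' @rdname write_sitelh
#' @export
read_sitelh <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  M <- as.matrix(df[, grep("^s\\d+$", names(df)), drop = FALSE])
  dimnames(M) <- NULL
  structure(list(loglik = M, totals = rowSums(M), n_taxa = NA_integer_),
            class = "sitelh_matrix")
}
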