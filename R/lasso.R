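#' Lasso-based site informativeness (PEGL)
#'
#' The core statistic: regress each random tree's total log-likelihood on
#' its site-wise log-likelihoods with an L1 penalty. Because the response
#' is exactly the row sum of the features, the regression asks which sites
#' are needed to predict the tree likelihood; the L1 penalty zeroes out
#' sites whose likelihood barely varies across trees. The number of sites
#' with non-zero coefficients at the cross-validated penalty lambda* is
#' the phylogenetically effective gene length, PEGL; PEGL/n is the
#' proportion of informative sites.
#'
#' @name lasso-informativeness
NULL

#' Build the regression design from a site log-likelihood matrix
#'
#' @param sitelh a `sitelh_matrix` from [compute_sitelh_matrix()].
#' @return List with `X` (T x n feature matrix of site log-likelihoods)
#'   and `y` (length-T response of per-tree totals). The structural
#'   identity `y = rowSums(X)` holds within 1e-8 by construction.
#' @export
build_design <- function(sitelh) {
  stopifnot(inherits(sitelh, "sitelh_matrix"))
  X <- sitelh$loglik
  y <- sitelh$totals
  if (length(y) != nrow(X))
    stop("shape mismatch between totals and site log-likelihood matrix")
  if (max(abs(y - rowSums(X))) > 1e-8)
    stop("totals do not equal the row sums of the site log-likelihoods")
  list(X = X, y = y)
}

#' Fit the cross-validated Lasso path
#'
#' Features are standardized internally (glmnet default; zero-variance
#' columns always receive coefficient 0), the intercept is unpenalized,
#' and the penalty path runs geometrically from lambda_max (smallest
#' penalty with an all-zero coefficient vector) down to
#' lambda_max * 1e-4. lambda* is chosen by seeded k-fold cross-validation,
#' either at the CV-error minimum (`"min"`, default) or by the
#' one-standard-error rule (`"1se"`). Coefficients are reported on the
#' original feature scale. Deterministic given `seed`.
#'
#' @param X T x n matrix of site log-likelihoods (features).
#' @param y length-T vector of per-tree total log-likelihoods (response).
#' @param n_lambda length of the penalty path (default 100).
#' @param folds number of CV folds (default 10); must satisfy
#'   2 <= folds < T.
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @return A `pegl_fit`: lambda path, CV curve (mean error and SE),
#'   `lambda_star`, intercept, dense coefficient vector `beta`, logical
#'   `mask` of informative sites, `pegl`, `proportion`, plus bookkeeping
#'   (`n`, `n_trees`, `folds`, `seed`, `lambda_rule`) and the underlying
#'   cv.glmnet object (`cv`).
#' @export
fit_lasso_cv <- function(X, y, n_lambda = 100L, folds = 10L, seed = NULL,
                         lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  Tn <- nrow(X); n <- ncol(X)
  if (n < 1L) stop("design has no sites")
  if (folds < 2L) stop("at least 2 CV folds are required")
  if (Tn <= folds) stop("more trees than folds are required (T > folds)")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (length(y) != Tn) stop("shape mismatch between X and y")
  if (stats::sd(y) == 0) stop("response is constant across trees")
  padded <- FALSE
  if (n == 1L) {
    # glmnet needs >= 2 columns; a zero-variance pad is always dropped to 0
    X <- cbind(X, 0)
    padded <- TRUE
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), Tn)))
  # explicit geometric path from lambda_max down to lambda_max * 1e-4:
  # glmnet's own path stops early once deviance saturates, which would
  # truncate the low-penalty end the CV rule must be able to reach
  lmax <- glmnet::glmnet(X, y, alpha = 1, nlambda = 3L,
                         standardize = TRUE)$lambda[1L]
  # a hair above lambda_max so the all-zero end of the path is exact
  # (at the borderline KKT point coordinate descent leaves O(1e-16) dust)
  lmax <- lmax * (1 + 1e-6)
  path <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, lambda = path,
                          standardize = TRUE, foldid = foldid)
  lambda_star <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(stats::coef(cv, s = lambda_star))
  intercept <- cf[1L]
  beta <- cf[-1L]
  if (padded) beta <- beta[1L]
  mask <- beta != 0
  structure(list(
    lambda = cv$lambda, cv_mean = cv$cvm, cv_se = cv$cvsd,
    lambda_star = lambda_star, lambda_rule = lambda_rule,
    intercept = intercept, beta = beta, mask = mask,
    pegl = sum(mask), proportion = sum(mask) / n,
    n = n, n_trees = Tn, folds = folds, seed = seed,
    cv = cv
  ), class = "pegl_fit")
}

#' @export
print.pegl_fit <- function(x, ...) {
  cat(sprintf(
    "Lasso informativeness fit: %d trees x %d sites\n", x$n_trees, x$n))
  cat(sprintf("  lambda* = %.6g (%s rule, %d-fold CV)\n",
              x$lambda_star, x$lambda_rule, x$folds))
  cat(sprintf("  PEGL = %d informative sites (%.1f%% of alignment)\n",
              x$pegl, 100 * x$proportion))
  invisible(x)
}

#' Phylogenetically effective gene length of a fit
#'
#' @param fit a `pegl_fit` (or the result of [informativeness_run()]).
#' @return List with `count` (number of sites with non-zero coefficient at
#'   lambda*) and `proportion` (count / n).
#' @export
pegl <- function(fit) {
  stopifnot(inherits(fit, "pegl_fit"))
  list(count = fit$pegl, proportion = fit$proportion)
}

# All-zero fit used when every feature column is constant (e.g. an
# alignment of only fully ambiguous columns): nothing can be informative.
trivial_pegl_fit <- function(n, Tn, folds, seed, lambda_rule) {
  structure(list(
    lambda = numeric(0), cv_mean = numeric(0), cv_se = numeric(0),
    lambda_star = NA_real_, lambda_rule = lambda_rule,
    intercept = NA_real_, beta = numeric(n), mask = logical(n),
    pegl = 0L, proportion = 0, n = n, n_trees = Tn, folds = folds,
    seed = seed, cv = NULL
  ), class = "pegl_fit")
}

#' End-to-end informativeness analysis of one alignment
#'
#' Composes the full per-gene procedure: random-tree ensemble, site
#' log-likelihood matrix, regression design, and cross-validated Lasso.
#' Two child seeds (ensemble, CV folds) are derived deterministically from
#' the master seed.
#'
#' @param alignment a [dna_alignment] with at least 4 taxa (with fewer
#'   taxa the topology cannot vary and the regression is meaningless).
#' @param n_trees ensemble size T (default 10000).
#' @param seed master integer seed.
#' @param model a [subst_model], a model name string ("JC69", "HKY85+G4",
#'   ...), or "auto" for BIC selection on a neighbor-joining tree.
#' @param bl_mean mean random-tree branch length (default 0.1).
#' @param n_lambda,folds,lambda_rule passed to [fit_lasso_cv()].
#' @param verbose log progress.
#' @return A `pegl_fit` with extra fields `model_family` and `sitelh`.
#' @export
informativeness_run <- function(alignment, n_trees = 10000L, seed = NULL,
                                model = "JC69", bl_mean = 0.1,
                                n_lambda = 100L, folds = 10L,
                                lambda_rule = c("min", "1se"),
                                verbose = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(alignment, "dna_alignment"))
  if (nrow(alignment) < 4L)
    stop("at least 4 taxa are required (topology must be able to vary)")
  seeds <- if (is.null(seed)) c(NA, NA) else
    with_seed(seed, sample.int(2147483647L, 2L))
  model <- resolve_model(model, alignment)
  if (verbose)
    message(sprintf("informativeness run: %d taxa, %d sites, T = %d trees",
                    nrow(alignment), ncol(alignment), n_trees))
  ens <- build_ensemble(rownames(alignment), n_trees,
                        seed = if (is.null(seed)) NULL else seeds[1L],
                        bl_mean = bl_mean)
  sitelh <- compute_sitelh_matrix(ens, alignment, model, verbose = verbose)
  d <- build_design(sitelh)
  # tolerance absorbs eigendecomposition round-off on fully ambiguous
  # columns, whose exact site likelihood is 1 on every tree
  col_var <- apply(d$X, 2L, stats::sd)
  fit <- if (all(col_var < 1e-10)) {
    trivial_pegl_fit(ncol(d$X), nrow(d$X), folds, seed, lambda_rule)
  } else {
    fit_lasso_cv(d$X, d$y, n_lambda = n_lambda, folds = folds,
                 seed = if (is.null(seed)) NULL else seeds[2L],
                 lambda_rule = lambda_rule)
  }
  fit$model_family <- model_label(model)
  fit$sitelh <- sitelh
  if (verbose)
    message(sprintf("  PEGL = %d / %d (%.1f%%)", fit$pegl, fit$n,
                    100 * fit$proportion))
  fit
}

resolve_model <- function(model, alignment, tree = NULL) {
  if (inherits(model, "subst_model")) return(model)
  if (identical(model, "auto")) {
    if (is.null(tree)) tree <- nj_tree(alignment)
    return(select_model(alignment, tree))
  }
  base <- sub("\\+G\\d*$", "", model)
  freq <- if (base == "JC69") NULL else base_frequencies(alignment)
  subst_model(model, freq = freq)
}

model_label <- function(model) {
  lbl <- model$family
  if (model$gamma_k > 0L) lbl <- sprintf("%s+G%d", lbl, model$gamma_k)
  lbl
}

#' Write per-site informativeness results as TSV
#'
#' Columns: `site` (1-based column index), `beta` (coefficient at
#' lambda*), `informative` (0/1).
#'
#' @param fit a `pegl_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(fit, path) {
  stopifnot(inherits(fit, "pegl_fit"))
  utils::write.table(
    data.frame(site = seq_len(fit$n), beta = fmt10(fit$beta),
               informative = as.integer(fit$mask)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
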