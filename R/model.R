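#' Nucleotide substitution models
#'
#' Time-reversible substitution models over states (A, C, G, T): JC69,
#' HKY85 and GTR, optionally with discrete-gamma rate heterogeneity
#' (k equal-weight categories, category means by the mean-of-quantiles
#' rule) and a proportion of invariant sites. The rate matrix Q is scaled
#' so the expected rate at stationarity is 1 substitution per site, i.e.
#' branch lengths are in substitutions/site.
#'
#' @param family one of "JC69", "HKY85", "GTR". A "+G4"-style suffix
#'   (e.g. "HKY85+G4") sets `gamma_k` from the suffix.
#' @param freq stationary base frequencies (A, C, G, T); must be positive
#'   and sum to 1. JC69 forces equal frequencies.
#' @param kappa transition/transversion rate ratio (HKY85 only).
#' @param rates six GTR exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT (GT conventionally 1).
#' @param gamma_shape gamma shape alpha (> 0); used when `gamma_k` > 0.
#' @param gamma_k number of discrete gamma categories (0 = rate
#'   homogeneity).
#' @param p_inv proportion of invariant sites, in [0, 1).
#' @return A `subst_model` object with the scaled rate matrix, its
#'   eigendecomposition and the discrete-gamma category rates.
#' @export
subst_model <- function(family = c("JC69", "HKY85", "GTR"),
                        freq = NULL, kappa = 2, rates = NULL,
                        gamma_shape = 1, gamma_k = 0L, p_inv = 0) {
  if (length(family) == 1L && grepl("\\+G\\d*$", family)) {
    k <- sub("^.*\\+G", "", family)
    gamma_k <- if (nzchar(k)) as.integer(k) else 4L
    family <- sub("\\+G\\d*$", "", family)
  }
  family <- match.arg(family)
  if (family == "JC69") {
    freq <- rep(0.25, 4)
  } else if (is.null(freq)) {
    freq <- rep(0.25, 4)
  }
  freq <- as.numeric(freq)
  if (length(freq) != 4L || any(freq <= 0) || abs(sum(freq) - 1) > 1e-8)
    stop("'freq' must be 4 positive values summing to 1")
  ex <- switch(family,
    JC69  = rep(1, 6),
    HKY85 = {
      if (!is.finite(kappa) || kappa <= 0) stop("'kappa' must be > 0")
      c(1, kappa, 1, 1, kappa, 1)
    },
    GTR   = {
      if (is.null(rates)) rates <- rep(1, 6)
      if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
        stop("'rates' must be 6 positive exchangeabilities (AC AG AT CG CT GT)")
      as.numeric(rates)
    })
  gamma_k <- as.integer(gamma_k)
  if (gamma_k > 0L && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("'gamma_shape' must be > 0 when gamma categories are used")
  if (!is.finite(p_inv) || p_inv < 0 || p_inv >= 1)
    stop("'p_inv' must be in [0, 1)")

  Q <- build_rate_matrix(ex, freq)
  # symmetrize with pi^(1/2) for a stable eigendecomposition
  sq <- sqrt(freq)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    family = family, freq = freq, kappa = if (family == "HKY85") kappa else NA,
    rates = ex, gamma_shape = if (gamma_k > 0L) gamma_shape else NA,
    gamma_k = gamma_k, p_inv = p_inv, Q = Q,
    eig = list(values = e$values,
               A = diag(1 / sq) %*% e$vectors,
               Ainv = t(e$vectors) %*% diag(sq)),
    cat_rates = if (gamma_k > 0L) discrete_gamma_rates(gamma_shape, gamma_k)
                else 1
  ), class = "subst_model")
}

# Q_ij = s_ij * pi_j for i != j, rows sum to zero, scaled to 1 expected
# substitution per site at stationarity.
build_rate_matrix <- function(ex, freq) {
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- ex[c(1, 2, 3, 4, 5, 6)]
  # fill in order (2,1)=AC (3,1)=AG (4,1)=AT (3,2)=CG (4,2)=CT (4,3)=GT
  S <- S + t(S)
  Q <- S * rep(freq, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q / mu
}

# Mean-of-quantiles discretization of Gamma(alpha, alpha): k equal-weight
# categories, each represented by its conditional mean; overall mean is 1.
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  b <- c(0, stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha), Inf)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

#' @export
print.subst_model <- function(x, ...) {
  lbl <- x$family
  if (x$gamma_k > 0L) lbl <- sprintf("%s+G%d (alpha = %g)", lbl, x$gamma_k,
                                     x$gamma_shape)
  if (x$p_inv > 0) lbl <- sprintf("%s+I (p_inv = %g)", lbl, x$p_inv)
  cat("Substitution model:", lbl, "\n")
  cat("  base frequencies:", paste(sprintf("%.4f", x$freq), collapse = " "),
      "\n")
  if (x$family == "HKY85") cat("  kappa:", format(x$kappa), "\n")
  if (x$family == "GTR")
    cat("  exchangeabilities (AC AG AT CG CT GT):",
        paste(sprintf("%.4g", x$rates), collapse = " "), "\n")
  invisible(x)
}

# P(t) = A exp(Lambda t) Ainv, clipped to [0, 1] against round-off.
transition_matrix <- function(model, t) {
  e <- model$eig
  P <- e$A %*% (exp(e$values * t) * e$Ainv)
  P[P < 0] <- 0
  P
}

#' Empirical base frequencies of an alignment
#'
#' Ambiguity-weighted counts: each character contributes weight 1 split
#' equally among its compatible states (gaps and `N`/`?` contribute 1/4 to
#' each base, so they do not bias composition).
#'
#' @param alignment a [dna_alignment].
#' @return Numeric 4-vector (A, C, G, T) summing to 1.
#' @export
base_frequencies <- function(alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  ind <- iupac_indicator(as.vector(unclass(alignment)))
  w <- ind / rep(colSums(ind), each = 4)
  f <- rowSums(w) / ncol(w)
  f / sum(f)
}
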