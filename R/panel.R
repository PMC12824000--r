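#' Gene-panel statistics and group comparisons
#'
#' Per-gene bookkeeping (PEGL, informative-site proportion, average aLRT,
#' codon-position counts) and the panel-level analyses: the
#' length-informativeness regression, positional profiles of informative
#' sites, descriptive summaries, and the percentile-bootstrap test for a
#' mean difference between two groups of genes.
#'
#' @name panel-statistics
NULL

#' One gene's panel record
#'
#' @param gene gene identifier.
#' @param level taxonomic level, `"within_species"` or `"among_species"`.
#' @param n alignment sites.
#' @param gapless_len count of completely gap-free columns (<= n).
#' @param pegl_count number of informative sites.
#' @param avg_alrt average parametric aLRT over internal branches (NA if
#'   not computed).
#' @param c1,c2,c3 informative-site counts by codon position; must sum to
#'   `pegl_count` when a reading frame is known (all NA otherwise).
#' @return One-row data frame with columns gene, level, n, gapless_len,
#'   pegl, proportion, avg_alrt, c1, c2, c3.
#' @export
panel_record <- function(gene, level = c("within_species", "among_species"),
                         n, gapless_len, pegl_count, avg_alrt = NA_real_,
                         c1 = NA_integer_, c2 = NA_integer_,
                         c3 = NA_integer_) {
  level <- match.arg(level)
  stopifnot(n >= 1, gapless_len >= 0, gapless_len <= n,
            pegl_count >= 0, pegl_count <= n)
  if (!is.na(c1) && c1 + c2 + c3 != pegl_count)
    stop("codon-position counts must sum to PEGL")
  data.frame(gene = gene, level = level, n = as.integer(n),
             gapless_len = as.integer(gapless_len),
             pegl = as.integer(pegl_count),
             proportion = pegl_count / n, avg_alrt = avg_alrt,
             c1 = as.integer(c1), c2 = as.integer(c2), c3 = as.integer(c3))
}

#' Length-informativeness regression across a panel
#'
#' Pearson correlation and ordinary least-squares fit of the number of
#' informative sites (PEGL) on gapless sequence length, the relationship
#' behind "longer genes carry more informative sites".
#'
#' @param records data frame with columns `gapless_len` and `pegl`
#'   (e.g. rbind-ed [panel_record()] rows), one row per gene.
#' @return List with `pearson_r`, `slope`, `intercept`, `p_value`
#'   (two-sided, from the t-distribution of r) and `r_squared`.
#' @export
length_informativeness_regression <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("gapless_len", "pegl") %in% names(records)))
  x <- records$gapless_len; y <- records$pegl
  if (length(x) < 3L) stop("at least 3 records are required")
  if (stats::sd(x) == 0) stop("zero variance in gapless length")
  if (stats::sd(y) == 0) {
    # flat informativeness: slope and r are exactly zero
    return(list(pearson_r = 0, slope = 0, intercept = mean(y), p_value = 1,
                r_squared = 0))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(pearson_r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = ct$p.value,
       r_squared = summary(fit)$r.squared)
}

#' Percentile-bootstrap test of a mean difference between two groups
#'
#' Each replicate resamples each group with replacement at its own size
#' and records mean(A*) - mean(B*); the 95% confidence interval is the
#' empirical 2.5/97.5 percentile of the replicates and the difference is
#' called significant when the interval excludes zero.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param n_reps bootstrap replicates R >= 100 (default 10000).
#' @param seed integer seed.
#' @param labels length-2 character vector naming the groups.
#' @return A `group_comparison`: observed mean difference, R, `ci`
#'   (lo, hi), `significant`, a two-sided bootstrap `p_value`, seed.
#' @export
bootstrap_mean_difference <- function(group_a, group_b, n_reps = 10000L,
                                      seed = NULL,
                                      labels = c("A", "B")) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (n_reps < 100L) stop("at least 100 bootstrap replicates are required")
  na <- length(group_a); nb <- length(group_b)
  diffs <- with_seed(seed, {
    ra <- matrix(sample(group_a, n_reps * na, replace = TRUE), n_reps)
    rb <- matrix(sample(group_b, n_reps * nb, replace = TRUE), n_reps)
    rowMeans(ra) - rowMeans(rb)
  })
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975)))
  obs <- mean(group_a) - mean(group_b)
  structure(list(
    labels = labels, observed = obs, n_reps = n_reps,
    ci = ci, significant = ci[1L] > 0 || ci[2L] < 0,
    p_value = 2 * min(mean(diffs <= 0), mean(diffs >= 0)),
    seed = seed
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Bootstrap mean difference (%s - %s): %.4g\n",
              x$labels[1L], x$labels[2L], x$observed))
  cat(sprintf("  95%% percentile CI [%.4g, %.4g] from %d replicates -> %s\n",
              x$ci[1L], x$ci[2L], x$n_reps,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Informative-site counts by codon position
#'
#' @param mask logical vector over alignment columns (informative yes/no).
#' @param frame codon phase (1, 2 or 3) of column 1.
#' @return Named integer vector `c(c1, c2, c3)`; the counts always sum to
#'   the number of TRUE entries in `mask`.
#' @export
codon_position_counts <- function(mask, frame = 1L) {
  stopifnot(is.logical(mask), frame %in% 1:3)
  pos <- ((seq_along(mask) - 1L + (frame - 1L)) %% 3L) + 1L
  counts <- vapply(1:3, function(p) sum(mask & pos == p), 0L)
  names(counts) <- c("c1", "c2", "c3")
  counts
}

#' Positional profile of informative sites
#'
#' Sliding-window counts of informative sites along the alignment. With
#' `step == window` (non-overlapping windows) the counts sum exactly to
#' PEGL.
#'
#' @param mask logical vector over alignment columns.
#' @param window window width in columns (>= 1).
#' @param step window step in columns (>= 1; default `window`).
#' @return Data frame with `start`, `end`, `count` and `density`
#'   (count / window width).
#' @export
positional_profile <- function(mask, window, step = window) {
  stopifnot(is.logical(mask), window >= 1L, step >= 1L)
  n <- length(mask)
  starts <- seq(1L, n, by = step)
  ends <- pmin(starts + window - 1L, n)
  counts <- vapply(seq_along(starts),
                   function(i) sum(mask[starts[i]:ends[i]]), 0L)
  data.frame(start = starts, end = ends, count = counts,
             density = counts / (ends - starts + 1L))
}

#' Panel manifest arithmetic
#'
#' Bookkeeping of how many alignments (and hence ML analyses) a panel
#' specification implies: one alignment per unit x gene.
#'
#' @param spec data frame with columns `dataset`, `units` (species or
#'   genera), `genes`.
#' @return A `panel_summary`: the spec with an `alignments` column
#'   (units x genes) plus attribute `total`.
#' @export
panel_manifest <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("dataset", "units", "genes") %in% names(spec)))
  if (any(spec$units < 1L) || any(spec$genes < 1L))
    stop("units and genes must be >= 1")
  spec$alignments <- as.integer(spec$units * spec$genes)
  structure(spec, total = sum(spec$alignments),
            class = c("panel_summary", "data.frame"))
}

#' @export
print.panel_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("total alignments:", attr(x, "total"), "\n")
  invisible(x)
}

#' Descriptive summaries of panel records per dataset
#'
#' Mean, sd (n - 1 denominator), min and max of the informative-site
#' proportion and the average aLRT, grouped by taxonomic level. With a
#' single record the sd is reported as NA.
#'
#' @param records data frame of [panel_record()] rows.
#' @param by grouping column (default `"level"`).
#' @return Data frame with one row per group and per metric.
#' @export
summarize_panels <- function(records, by = "level") {
  stopifnot(is.data.frame(records), by %in% names(records))
  groups <- split(records, records[[by]])
  do.call(rbind, lapply(names(groups), function(g) {
    r <- groups[[g]]
    do.call(rbind, lapply(c("proportion", "avg_alrt"), function(metric) {
      v <- r[[metric]]
      v <- v[!is.na(v)]
      if (!length(v))
        return(data.frame(group = g, metric = metric, n_records = 0L,
                          mean = NA_real_, sd = NA_real_, min = NA_real_,
                          max = NA_real_))
      data.frame(group = g, metric = metric, n_records = length(v),
                 mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 min = min(v), max = max(v))
    }))
  }))
}

#' Write panel records as TSV
#'
#' Columns: `gene level n gapless_len pegl proportion avg_alrt c1 c2 c3`.
#'
#' @param records data frame of [panel_record()] rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
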