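#' End-to-end analysis runs
#'
#' Orchestration wrappers that compose the package's stages on files or
#' in-memory objects and write their outputs (TSV / JSON / Newick /
#' FASTA) together with the fully resolved run configuration, so every
#' artifact records the parameters and seed that produced it. These
#' functions, plus the thin command-line wrapper shipped in
#' `inst/scripts/pegl-cli.R`, are the pipeline interface.
#'
#' @name pipeline
NULL

#' Resolved run configuration
#'
#' Collects the tunable parameters of a run with their defaults; every
#' `run_*` function serializes the resolved configuration into its JSON
#' summary (provenance contract).
#'
#' @param seed master seed.
#' @param n_trees random-tree ensemble size.
#' @param bl_mean mean random-tree branch length.
#' @param model model name or "auto".
#' @param n_lambda,folds,lambda_rule Lasso path/CV settings.
#' @param n_reps bootstrap replicates.
#' @param window positional-profile window width.
#' @param ... further command-specific entries.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_trees = 10000L, bl_mean = 0.1,
                       model = "JC69", n_lambda = 100L, folds = 10L,
                       lambda_rule = "min", n_reps = 10000L,
                       window = 60L, ...) {
  structure(list(seed = seed, n_trees = n_trees, bl_mean = bl_mean,
                 model = model, n_lambda = n_lambda, folds = folds,
                 lambda_rule = lambda_rule, n_reps = n_reps,
                 window = window, ...),
            class = "run_config")
}

write_json_summary <- function(x, path) {
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip) else v
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Writes aligned FASTA, the generating tree (Newick) and the planted
#' truth TSV for each simulated gene, plus a JSON file with the resolved
#' configuration.
#'
#' @param out_dir output directory (created if missing).
#' @param n_genes,level,gene_length_range,m,p_invariant,codon_rates,share_tree
#'   passed to [simulate_panel()].
#' @param seed master seed.
#' @return Invisibly, the list of simulated genes.
#' @export
run_simulate <- function(out_dir, n_genes = 10L, level = "within_species",
                         gene_length_range = c(700L, 2000L), m = NULL,
                         p_invariant = 0.45, codon_rates = c(1, 0.6, 4),
                         share_tree = FALSE, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(n_genes, level = level,
                          gene_length_range = gene_length_range, m = m,
                          p_invariant = p_invariant,
                          codon_rates = codon_rates,
                          share_tree = share_tree, seed = seed)
  for (g in panel) {
    write_fasta(g$alignment, file.path(out_dir, paste0(g$gene, ".fasta")))
    writeLines(write_newick(g$tree),
               file.path(out_dir, paste0(g$gene, ".nwk")))
    write_truth(g$truth, file.path(out_dir, paste0(g$gene, "_truth.tsv")))
  }
  cfg <- run_config(seed = seed, n_genes = n_genes, level = level,
                    gene_length_range = gene_length_range,
                    p_invariant = p_invariant, codon_rates = codon_rates,
                    share_tree = share_tree)
  write_json_summary(cfg, file.path(out_dir, "simulate_config.json"))
  invisible(panel)
}

#' Informativeness analysis of one alignment, with outputs on disk
#'
#' @param alignment a [dna_alignment] or path to an aligned FASTA file.
#' @param out_dir output directory.
#' @param n_trees,seed,model,bl_mean,n_lambda,folds,lambda_rule passed to
#'   [informativeness_run()].
#' @param write_sitelh_tsv also write the T x n site log-likelihood table
#'   (large; default FALSE).
#' @param verbose log progress.
#' @return Invisibly, the `pegl_fit`.
#' @export
run_informativeness <- function(alignment, out_dir, n_trees = 10000L,
                                seed = 1L, model = "JC69", bl_mean = 0.1,
                                n_lambda = 100L, folds = 10L,
                                lambda_rule = "min",
                                write_sitelh_tsv = FALSE,
                                verbose = FALSE) {
  if (!inherits(alignment, "dna_alignment"))
    alignment <- read_fasta(alignment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- informativeness_run(alignment, n_trees = n_trees, seed = seed,
                             model = model, bl_mean = bl_mean,
                             n_lambda = n_lambda, folds = folds,
                             lambda_rule = lambda_rule, verbose = verbose)
  write_site_report(fit, file.path(out_dir, "sites.tsv"))
  if (write_sitelh_tsv)
    write_sitelh(fit$sitelh, file.path(out_dir, "sitelh.tsv"))
  cfg <- run_config(seed = seed, n_trees = n_trees, bl_mean = bl_mean,
                    model = fit$model_family, n_lambda = n_lambda,
                    folds = folds, lambda_rule = lambda_rule)
  write_json_summary(list(
    config = cfg, n = fit$n, n_trees = fit$n_trees,
    lambda_star = fit$lambda_star, pegl = fit$pegl,
    proportion = fit$proportion),
    file.path(out_dir, "summary.json"))
  invisible(fit)
}

#' ML tree and aLRT supports, with outputs on disk
#'
#' @param alignment a [dna_alignment] or path to an aligned FASTA file.
#' @param out_dir output directory.
#' @param model model name or [subst_model] ("auto" for BIC selection).
#' @param seed seed (kept for provenance; the search is deterministic).
#' @return Invisibly, the `branch_support_tree`.
#' @export
run_support <- function(alignment, out_dir, model = "JC69", seed = 1L) {
  if (!inherits(alignment, "dna_alignment"))
    alignment <- read_fasta(alignment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mod <- resolve_model(model, alignment)
  ml <- ml_search(alignment, mod, seed = seed)
  bst <- alrt_annotate(ml, alignment, mod)
  write_support(bst, newick_path = file.path(out_dir, "ml_tree.nwk"),
                tsv_path = file.path(out_dir, "branches.tsv"))
  cfg <- run_config(seed = seed, model = model_label(mod))
  write_json_summary(list(config = cfg, loglik = attr(ml, "loglik"),
                          average_alrt = bst$average),
                     file.path(out_dir, "support_summary.json"))
  invisible(bst)
}

#' Compare two groups of per-gene values by percentile bootstrap
#'
#' @param group_a,group_b numeric vectors of per-gene metric values.
#' @param out_dir output directory (NULL to skip writing).
#' @param n_reps,seed,labels passed to [bootstrap_mean_difference()].
#' @return Invisibly, the `group_comparison`.
#' @export
run_compare <- function(group_a, group_b, out_dir = NULL,
                        n_reps = 10000L, seed = 1L,
                        labels = c("A", "B")) {
  cmp <- bootstrap_mean_difference(group_a, group_b, n_reps = n_reps,
                                   seed = seed, labels = labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_json_summary(list(
      config = run_config(seed = seed, n_reps = n_reps),
      labels = labels, observed = cmp$observed,
      ci_lo = cmp$ci[1L], ci_hi = cmp$ci[2L],
      significant = cmp$significant, p_value = cmp$p_value),
      file.path(out_dir, "comparison.json"))
  }
  invisible(cmp)
}

#' Full synthetic reproduction of the analysis shape
#'
#' Simulates a within-species and an among-species gene panel, runs the
#' informativeness analysis and the aLRT support analysis on every gene,
#' and assembles the panel-level products: the per-gene record table, the
#' length-informativeness regression (among-species), the codon-position
#' breakdown, a positional profile for the first gene, panel summaries,
#' and the percentile-bootstrap comparison of informative-site
#' proportions between the two levels.
#'
#' @param out_dir output directory (NULL for in-memory only).
#' @param n_genes genes per level.
#' @param n_trees ensemble size per gene.
#' @param m taxa per gene (NULL: drawn from 5:8).
#' @param gene_length_range gene length range in bp.
#' @param p_invariant,codon_rates generator settings (see
#'   [simulate_panel()]).
#' @param model model name used for likelihoods.
#' @param folds,lambda_rule Lasso CV settings.
#' @param n_reps bootstrap replicates for the group comparison.
#' @param window positional-profile window width.
#' @param seed master seed (child seeds per stage are derived from it).
#' @param verbose log progress.
#' @return List with `records`, `summary`, `regression`, `codon`,
#'   `profile`, `comparison`, `config`.
#' @export
run_reproduce_synthetic <- function(out_dir = NULL, n_genes = 8L,
                                    n_trees = 400L, m = NULL,
                                    gene_length_range = c(700L, 2000L),
                                    p_invariant = 0.45,
                                    codon_rates = c(1, 0.6, 4),
                                    model = "JC69", folds = 10L,
                                    lambda_rule = "min", n_reps = 10000L,
                                    window = 60L, seed = 1L,
                                    verbose = FALSE) {
  seeds <- with_seed(seed, sample.int(2147483647L, 4L))
  panels <- list(
    within_species = simulate_panel(n_genes, "within_species",
                                    gene_length_range, m = m,
                                    p_invariant = p_invariant,
                                    codon_rates = codon_rates,
                                    seed = seeds[1L]),
    among_species = simulate_panel(n_genes, "among_species",
                                   gene_length_range, m = m,
                                   p_invariant = p_invariant,
                                   codon_rates = codon_rates,
                                   seed = seeds[2L]))
  gene_seeds <- with_seed(seeds[3L],
                          sample.int(2147483647L, 2L * n_genes))
  records <- list(); fits <- list(); gi <- 0L
  for (lvl in names(panels)) {
    for (g in panels[[lvl]]) {
      gi <- gi + 1L
      if (verbose)
        message(sprintf("[%s] %s: %d taxa, %d sites", lvl, g$gene,
                        nrow(g$alignment), ncol(g$alignment)))
      fit <- informativeness_run(g$alignment, n_trees = n_trees,
                                 seed = gene_seeds[gi], model = model,
                                 folds = folds, lambda_rule = lambda_rule)
      mod <- resolve_model(model, g$alignment)
      bst <- alrt_annotate(ml_search(g$alignment, mod), g$alignment, mod)
      cc <- codon_position_counts(fit$mask,
                                  frame = attr(g$alignment, "frame"))
      records[[gi]] <- panel_record(
        paste(lvl, g$gene, sep = "_"), level = lvl,
        n = fit$n, gapless_len = gapless_length(g$alignment),
        pegl_count = fit$pegl, avg_alrt = bst$average,
        c1 = cc[1L], c2 = cc[2L], c3 = cc[3L])
      fits[[gi]] <- fit
    }
  }
  records <- do.call(rbind, records)
  among <- records[records$level == "among_species", ]
  within <- records[records$level == "within_species", ]
  regression <- length_informativeness_regression(among)
  codon <- colSums(records[, c("c1", "c2", "c3")])
  profile <- positional_profile(fits[[1L]]$mask, window)
  comparison <- bootstrap_mean_difference(
    within$proportion, among$proportion, n_reps = n_reps,
    seed = seeds[4L], labels = c("within_species", "among_species"))
  cfg <- run_config(seed = seed, n_trees = n_trees, model = model,
                    folds = folds, lambda_rule = lambda_rule,
                    n_reps = n_reps, window = window, n_genes = n_genes,
                    gene_length_range = gene_length_range,
                    p_invariant = p_invariant, codon_rates = codon_rates)
  out <- list(records = records, summary = summarize_panels(records),
              regression = regression, codon = codon, profile = profile,
              comparison = comparison, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel_records(records, file.path(out_dir, "panel_records.tsv"))
    utils::write.table(out$summary,
                       file.path(out_dir, "panel_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(profile, file.path(out_dir, "profile_gene1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_summary(list(
      config = cfg, regression = regression,
      codon = as.list(codon),
      comparison = list(observed = comparison$observed,
                        ci_lo = comparison$ci[1L],
                        ci_hi = comparison$ci[2L],
                        significant = comparison$significant)),
      file.path(out_dir, "report.json"))
  }
  out
}
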