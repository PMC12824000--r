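#' Synthetic alignments and panels with planted ground truth
#'
#' Generators for the two divergence regimes the analysis contrasts:
#' shallow within-species variation (short internal branches, relatively
#' long terminals, autapomorphy-dominated) and deeper among-species
#' divergence (Yule trees over congeners), with per-site rate classes,
#' codon-position rate heterogeneity, optional indel-rich regions, and a
#' truth label for every column. The truth object is the only oracle the
#' recovery tests have: invariant columns are expected-uninformative,
#' everything else expected-informative.
#'
#' @name synthetic-data
NULL

#' Simulate an among-species (Yule) tree
#'
#' Yule random-split topology; branch lengths are i.i.d. exponential and
#' then rescaled so the mean root-to-tip path of the rooted tree equals
#' `depth_scale` before unrooting.
#'
#' @param m number of leaves (>= 4).
#' @param depth_scale target mean root-to-tip depth in substitutions/site
#'   (default 0.05, congeneric-species scale).
#' @param seed integer seed.
#' @return An unrooted binary `phylo` with tips `t1..tm`.
#' @export
simulate_yule_tree <- function(m, depth_scale = 0.05, seed = NULL) {
  if (m < 4L) stop("at least 4 leaves are required")
  if (!is.finite(depth_scale) || depth_scale <= 0)
    stop("'depth_scale' must be > 0")
  with_seed(seed, {
    tree <- yule_split_topology(m)
    tree$edge.length <- stats::rexp(nrow(tree$edge))
    depths <- ape::node.depth.edgelength(tree)[seq_len(m)]
    tree$edge.length <- tree$edge.length * depth_scale / mean(depths)
    ape::unroot(tree)
  })
}

#' Simulate a shallow within-species tree
#'
#' Star-like coalescent-flavoured shape: Yule topology with short internal
#' branches (mean `internal_mean`) and comparatively long terminal
#' branches (mean `theta`), so most variable sites end up as
#' autapomorphies on terminal branches.
#'
#' @param m number of leaves (>= 4).
#' @param theta mean terminal branch length (default 0.005).
#' @param internal_mean mean internal branch length (default theta / 10).
#' @param seed integer seed.
#' @return An unrooted binary `phylo` with tips `t1..tm`.
#' @export
simulate_shallow_tree <- function(m, theta = 0.005,
                                  internal_mean = theta / 10, seed = NULL) {
  if (m < 4L) stop("at least 4 leaves are required")
  if (!is.finite(theta) || theta <= 0) stop("'theta' must be > 0")
  with_seed(seed, {
    tree <- ape::unroot(yule_split_topology(m))
    term <- tree$edge[, 2L] <= m
    tree$edge.length <- numeric(nrow(tree$edge))
    tree$edge.length[term] <- stats::rexp(sum(term), rate = 1 / theta)
    tree$edge.length[!term] <- stats::rexp(sum(!term),
                                           rate = 1 / internal_mean)
    tree
  })
}

#' Simulate an alignment along a tree
#'
#' Standard Markov-chain sequence simulation: the root state of each site
#' is drawn from the stationary frequencies and evolved along each branch
#' with transition probabilities exp(Q t r_i), where r_i is the per-site
#' rate multiplier. A fraction `p_invariant` of sites is invariant
#' (multiplier 0, identical across taxa); the remaining sites take the
#' codon-position multipliers `codon_rates` cycled along the alignment
#' from `frame`. Site classes: `invariant`, `fast` (multiplier > 1) and
#' `slow` (otherwise); planted labels: invariant columns are
#' expected-uninformative, all others expected-informative.
#'
#' @param tree a `phylo` (rooted or unrooted) with branch lengths.
#' @param model a [subst_model] (its gamma/p_inv fields are ignored here;
#'   rate variation is controlled by `p_invariant` and `codon_rates`).
#' @param n number of sites (>= 3).
#' @param p_invariant fraction of invariant sites, in [0, 1).
#' @param codon_rates positive rate multipliers of codon positions 1-3.
#' @param frame codon phase of column 1 (default 1).
#' @param seed integer seed.
#' @return List with `alignment` (a [dna_alignment]) and `truth` (a
#'   `synthetic_truth`: data frame `site`, `class`, `rate`,
#'   `expected_informative`, plus attributes `tree`, `frame`, `seed`).
#' @export
simulate_alignment <- function(tree, model, n, p_invariant = 0,
                               codon_rates = c(1, 1, 1), frame = 1L,
                               seed = NULL) {
  stopifnot(inherits(model, "subst_model"))
  if (n < 3L) stop("at least 3 sites are required")
  if (any(!is.finite(codon_rates)) || any(codon_rates <= 0) ||
      length(codon_rates) != 3L)
    stop("'codon_rates' must be 3 positive multipliers")
  if (!is.finite(p_invariant) || p_invariant < 0 || p_invariant >= 1)
    stop("'p_invariant' must be in [0, 1)")
  with_seed(seed, {
    pos <- ((seq_len(n) - 1L + (frame - 1L)) %% 3L) + 1L
    rate <- codon_rates[pos]
    invariant <- stats::runif(n) < p_invariant
    rate[invariant] <- 0
    states <- c("A", "C", "G", "T")
    m <- ape::Ntip(tree)
    tr <- ape::reorder.phylo(tree, "cladewise")
    nnode_all <- m + tr$Nnode
    root <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
    seq_at <- matrix(NA_integer_, nnode_all, n)
    seq_at[root, ] <- sample.int(4L, n, replace = TRUE, prob = model$freq)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      seq_at[ch, ] <- evolve_states(seq_at[p, ], tr$edge.length[e] * rate,
                                    model)
    }
    chars <- matrix(states[seq_at[seq_len(m), ]], m, n)
    rownames(chars) <- tr$tip.label
    truth <- data.frame(
      site = seq_len(n),
      class = ifelse(invariant, "invariant",
                     ifelse(rate > 1, "fast", "slow")),
      rate = rate,
      expected_informative = !invariant)
    attr(truth, "tree") <- tree
    attr(truth, "frame") <- as.integer(frame)
    attr(truth, "seed") <- seed
    class(truth) <- c("synthetic_truth", "data.frame")
    list(alignment = dna_alignment(chars, frame = frame), truth = truth)
  })
}

# Evolve integer states one branch; per-site durations t (length n) allow
# site-specific rate multipliers; sites are grouped by unique duration so
# each distinct rate costs one transition matrix.
evolve_states <- function(states, t, model) {
  out <- states
  for (d in unique(t)) {
    idx <- which(t == d)
    if (d == 0) { out[idx] <- states[idx]; next }
    P <- transition_matrix(model, d)
    Pc <- t(apply(P, 1L, cumsum))
    u <- stats::runif(length(idx))
    out[idx] <- vapply(seq_along(idx), function(i) {
      findInterval(u[i], Pc[states[idx[i]], ], left.open = TRUE) + 1L
    }, 0L)
  }
  out
}

#' Replace a region with gaps for a taxon subset
#'
#' Reproduces the indel-rich-region artifact: a contiguous block of
#' columns becomes all-gap for the chosen taxa, leaving n unchanged and
#' the truth labels aligned 1:1 with columns.
#'
#' @param alignment a [dna_alignment].
#' @param region integer vector of column indices (may be empty for the
#'   identity).
#' @param taxa taxon labels to gap out.
#' @return The modified [dna_alignment].
#' @export
inject_indels <- function(alignment, region, taxa) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (!length(region)) return(alignment)
  if (any(region < 1L) || any(region > ncol(alignment)))
    stop("'region' out of range")
  unknown <- setdiff(taxa, rownames(alignment))
  if (length(unknown)) stop("unknown taxon: ", unknown[1L])
  out <- unclass(alignment)
  out[taxa, region] <- "-"
  dna_alignment(out, frame = attr(alignment, "frame"))
}

#' Simulate a multi-gene panel
#'
#' Emulates a panel of protein-coding genes of varying length (uniform on
#' `gene_length_range`, rounded down to full codons): one tree per gene
#' (default) or a single shared tree, at the chosen divergence level.
#'
#' @param n_genes number of genes (>= 1).
#' @param level `"within_species"` (shallow trees) or `"among_species"`
#'   (Yule trees).
#' @param gene_length_range length range in bp (default c(700, 2000)).
#' @param m taxa per gene; default drawn uniformly from 5:8 per gene.
#' @param model a [subst_model] (default JC69).
#' @param p_invariant fraction of invariant sites (default 0.45).
#' @param codon_rates codon-position multipliers (default c(1, 0.6, 4),
#'   fast synonymous third positions).
#' @param share_tree use one tree for all genes (default FALSE).
#' @param seed master integer seed.
#' @return List of per-gene lists (`gene`, `alignment`, `truth`, `tree`).
#' @export
simulate_panel <- function(n_genes, level = c("within_species",
                                              "among_species"),
                           gene_length_range = c(700L, 2000L), m = NULL,
                           model = subst_model("JC69"), p_invariant = 0.45,
                           codon_rates = c(1, 0.6, 4), share_tree = FALSE,
                           seed = NULL) {
  level <- match.arg(level)
  if (n_genes < 1L) stop("at least one gene is required")
  stopifnot(length(gene_length_range) == 2L,
            gene_length_range[1L] <= gene_length_range[2L])
  with_seed(seed, {
    lens <- sample(gene_length_range[1L]:gene_length_range[2L], n_genes,
                   replace = TRUE)
    lens <- (lens %/% 3L) * 3L
    ms <- if (is.null(m)) sample(5:8, n_genes, replace = TRUE)
          else rep_len(m, n_genes)
    make_tree <- function(mm)
      if (level == "among_species") simulate_yule_tree(mm)
      else simulate_shallow_tree(mm)
    shared <- if (share_tree) make_tree(ms[1L]) else NULL
    lapply(seq_len(n_genes), function(g) {
      tree <- if (share_tree) shared else make_tree(ms[g])
      sim <- simulate_alignment(tree, model, lens[g],
                                p_invariant = p_invariant,
                                codon_rates = codon_rates, frame = 1L)
      list(gene = sprintf("gene%03d", g), alignment = sim$alignment,
           truth = sim$truth, tree = tree)
    })
  })
}

#' Write the planted truth table as TSV
#'
#' Columns: `site class rate expected_informative`.
#'
#' @param truth a `synthetic_truth` from [simulate_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- as.data.frame(truth)
  df$expected_informative <- as.integer(df$expected_informative)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
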