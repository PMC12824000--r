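#' ML tree search and aLRT branch support
#'
#' Small-scale maximum-likelihood tree estimation (neighbor-joining start
#' followed by NNI hill-climbing) and the parametric approximate
#' likelihood-ratio test: for each internal branch the statistic is
#' 2(l1 - l2), where l1 is the log-likelihood of the current arrangement
#' and l2 the better of the two NNI alternatives, and the parametric
#' support is 1 - p with p from the (chi2_0 + chi2_1)/2 mixture.
#'
#' @name branch-support
NULL

# Pairwise Jukes-Cantor ML distances; sites where either sequence is not
# a definite A/C/G/T are skipped. Saturated or undefined pairs are clamped
# to bl_max with a warning.
jc_distance_matrix <- function(alignment, bl_max = BL_MAX) {
  m <- unclass(alignment)
  acgt <- m %in% c("A", "C", "G", "T")
  dim(acgt) <- dim(m)
  ntax <- nrow(m)
  D <- matrix(0, ntax, ntax, dimnames = list(rownames(m), rownames(m)))
  clamped <- FALSE
  for (i in seq_len(ntax - 1L)) for (j in (i + 1L):ntax) {
    ok <- acgt[i, ] & acgt[j, ]
    nv <- sum(ok)
    if (nv == 0L) { D[i, j] <- D[j, i] <- bl_max; clamped <- TRUE; next }
    p <- sum(m[i, ok] != m[j, ok]) / nv
    if (p >= 0.75) { D[i, j] <- D[j, i] <- bl_max; clamped <- TRUE; next }
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  if (clamped)
    warning("saturated or undefined pairwise distance clamped to bl_max")
  D
}

#' Neighbor-joining starting tree
#'
#' NJ on pairwise Jukes-Cantor ML distances; negative NJ branch lengths
#' are clamped to zero and the tree is returned unrooted.
#'
#' @param alignment a [dna_alignment] with >= 3 taxa.
#' @param model unused placeholder for future distance models (JC closed
#'   form is always used).
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(alignment, model = NULL) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (nrow(alignment) < 3L) stop("at least 3 taxa are required")
  if (nrow(alignment) == 3L) {
    D <- jc_distance_matrix(alignment)
    # star-resolved 3-taxon tree from the three pairwise distances
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    tr <- parse_newick(sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                               rownames(D)[1], max(a, 0),
                               rownames(D)[2], max(b, 0),
                               rownames(D)[3], max(c, 0)))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(jc_distance_matrix(alignment)))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' The two NNI rearrangements around an internal branch
#'
#' Swaps the four subtrees around the given internal branch in the two
#' alternative ways; each swapped subtree keeps its own pendant branch
#' length.
#'
#' @param tree unrooted binary `phylo`.
#' @param internal_branch row index into `tree$edge` of an internal branch
#'   (both ends internal nodes).
#' @return List of the two neighbor `phylo` trees.
#' @export
nni_neighbors <- function(tree, internal_branch) {
  validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  p <- edge[internal_branch, 1L]; ch <- edge[internal_branch, 2L]
  if (p <= ntip || ch <= ntip)
    stop("NNI requires an internal branch (terminal branch given)")
  kid_edges <- which(edge[, 1L] == ch)
  side_edges <- which(edge[, 1L] == p & edge[, 2L] != ch)
  if (!length(side_edges)) stop("branch orientation not usable for NNI")
  s <- side_edges[1L]
  lapply(kid_edges[1:2], function(k) {
    tr <- tree
    tr$edge[k, 2L] <- edge[s, 2L]
    tr$edge[s, 2L] <- edge[k, 2L]
    tmp <- tr$edge.length[k]
    tr$edge.length[k] <- tr$edge.length[s]
    tr$edge.length[s] <- tmp
    # the stale order attribute would make reorder.phylo a no-op
    attr(tr, "order") <- NULL
    ape::reorder.phylo(tr, "postorder")
  })
}

#' NNI hill-climbing maximum-likelihood tree search
#'
#' Starts from the neighbor-joining tree, then alternates full
#' branch-length optimization with the best-improving NNI move until no
#' rearrangement improves the total log-likelihood by more than `tol`.
#'
#' @param alignment a [dna_alignment] with >= 4 taxa.
#' @param model a [subst_model].
#' @param seed unused (the search is deterministic); kept for interface
#'   symmetry with the stochastic stages.
#' @param tol minimum lnL improvement to accept an NNI move.
#' @param verbose log accepted moves.
#' @return The ML `phylo` with attributes `loglik` and `nni_moves`.
#' @export
ml_search <- function(alignment, model, seed = NULL, tol = 1e-4,
                      verbose = FALSE) {
  if (nrow(alignment) < 4L) stop("at least 4 taxa are required")
  cur <- optimize_branch_lengths(nj_tree(alignment), alignment, model)
  cur_lnl <- attr(cur, "loglik")
  moves <- 0L
  repeat {
    best_lnl <- cur_lnl; best_tree <- NULL
    for (e in internal_edges(cur)) {
      for (nb in nni_neighbors(cur, e)) {
        cand <- optimize_branch_lengths(nb, alignment, model,
                                        max_rounds = 4L, warn = FALSE)
        if (attr(cand, "loglik") > best_lnl) {
          best_lnl <- attr(cand, "loglik"); best_tree <- cand
        }
      }
    }
    if (is.null(best_tree) || best_lnl - cur_lnl <= tol) break
    cur <- optimize_branch_lengths(best_tree, alignment, model)
    cur_lnl <- attr(cur, "loglik")
    moves <- moves + 1L
    if (verbose) message(sprintf("  NNI move %d: lnL = %.4f", moves, cur_lnl))
  }
  attr(cur, "nni_moves") <- moves
  cur
}

# Re-optimize a single branch by Brent search, everything else fixed.
reopt_focal <- function(tree, tipp, model, e) {
  tree <- ape::reorder.phylo(tree, "postorder")
  f <- function(x) {
    tr <- tree; tr$edge.length[e] <- x
    sum(site_loglik_prepared(tr, tipp[tr$tip.label], model))
  }
  opt <- stats::optimize(f, c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-7)
  cur <- f(tree$edge.length[e])
  if (opt$objective > cur) opt$objective else cur
}

# Postorder edge index of the branch joining internal nodes p and ch.
find_edge <- function(tree, p, ch) {
  which((tree$edge[, 1L] == p & tree$edge[, 2L] == ch) |
        (tree$edge[, 1L] == ch & tree$edge[, 2L] == p))[1L]
}

#' Annotate a tree with parametric aLRT branch supports
#'
#' For each internal branch: l1 is the total lnL of the input arrangement
#' with the focal branch re-optimized, l2 the better of the two NNI
#' neighbors (each with the focal branch re-optimized). The statistic is
#' max(0, 2(l1 - l2)); a negative difference (possible when the input tree
#' is not locally optimal) is clamped to zero with a warning. Parametric
#' support is 1 - p with p = Pr(chi2_1 >= stat)/2 for stat > 0 and p = 1
#' at stat = 0 (the half-and-half chi-square mixture).
#'
#' @param tree the ML (or user-supplied) unrooted binary `phylo`.
#' @param alignment a [dna_alignment].
#' @param model a [subst_model].
#' @param optim_scope `"focal"` (default) re-optimizes only the tested
#'   branch; `"full"` also re-optimizes the four adjacent branches.
#' @return A `branch_support_tree`: list with `tree` (node labels carry
#'   supports), `branches` (data frame: edge, statistic, support) and
#'   `average` (mean support over internal branches).
#' @export
alrt_annotate <- function(tree, alignment, model,
                          optim_scope = c("focal", "full")) {
  optim_scope <- match.arg(optim_scope)
  validate_phylo(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ie <- internal_edges(tree)
  if (!length(ie)) stop("tree has no internal branches")
  tipp <- tip_partials(alignment)
  ntip <- ape::Ntip(tree)
  stats_out <- numeric(length(ie))
  clamped <- FALSE
  for (k in seq_along(ie)) {
    e <- ie[k]
    scope <- if (optim_scope == "focal") e else
      unique(c(e, which(tree$edge[, 1L] %in% tree$edge[e, ] |
                        tree$edge[, 2L] %in% tree$edge[e, ])))
    l1 <- reopt_scope(tree, tipp, model, scope)
    l2 <- max(vapply(nni_neighbors(tree, e), function(nb) {
      fe <- find_edge(nb, tree$edge[e, 1L], tree$edge[e, 2L])
      sc <- if (optim_scope == "focal") fe else
        unique(c(fe, which(nb$edge[, 1L] %in% nb$edge[fe, ] |
                           nb$edge[, 2L] %in% nb$edge[fe, ])))
      reopt_scope(nb, tipp, model, sc)
    }, 0))
    stat <- 2 * (l1 - l2)
    if (stat < 0) { clamped <- TRUE; stat <- 0 }
    stats_out[k] <- stat
  }
  if (clamped)
    warning("negative aLRT statistic clamped to 0; ",
            "the input tree is not locally optimal")
  support <- alrt_support(stats_out)
  tree$node.label <- rep("", tree$Nnode)
  tree$node.label[tree$edge[ie, 2L] - ntip] <- sprintf("%.4f", support)
  structure(list(
    tree = tree,
    branches = data.frame(edge = ie,
                          parent = tree$edge[ie, 1L],
                          child = tree$edge[ie, 2L],
                          statistic = stats_out, support = support),
    average = mean(support)
  ), class = "branch_support_tree")
}

# Parametric support from the aLRT statistic under the half-and-half
# (chi2_0 + chi2_1)/2 mixture: p = Pr(chi2_1 >= stat)/2 for stat > 0 and
# p = 1 at stat = 0, support = 1 - p.
alrt_support <- function(stat) {
  ifelse(stat > 0,
         1 - 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE),
         0)
}

# Cyclic Brent passes over a small set of branches (2 rounds).
reopt_scope <- function(tree, tipp, model, edges) {
  if (length(edges) == 1L) return(reopt_focal(tree, tipp, model, edges))
  tr <- ape::reorder.phylo(tree, "postorder")
  tp <- tipp[tr$tip.label]
  lnl_of <- function(el) {
    t2 <- tr; t2$edge.length <- el
    sum(site_loglik_prepared(t2, tp, model))
  }
  el <- tr$edge.length
  cur <- lnl_of(el)
  for (round in 1:2) for (e in edges) {
    f <- function(x) { el2 <- el; el2[e] <- x; lnl_of(el2) }
    opt <- stats::optimize(f, c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-7)
    if (opt$objective > cur) { el[e] <- opt$maximum; cur <- opt$objective }
  }
  cur
}

#' @export
print.branch_support_tree <- function(x, ...) {
  cat(sprintf("aLRT-annotated tree: %d internal branches, average support %.4f\n",
              nrow(x$branches), x$average))
  print(x$branches, row.names = FALSE)
  invisible(x)
}

#' Average parametric aLRT support over internal branches
#'
#' @param supported_tree a `branch_support_tree` from [alrt_annotate()].
#' @return Arithmetic mean of the internal-branch supports.
#' @export
average_alrt <- function(supported_tree) {
  stopifnot(inherits(supported_tree, "branch_support_tree"))
  if (!nrow(supported_tree$branches)) stop("no internal branches")
  mean(supported_tree$branches$support)
}

#' Write an aLRT-annotated tree and its branch table
#'
#' Newick output carries supports as internal node labels
#' (e.g. `)0.9500:0.012`); the TSV has columns
#' `branch_id  statistic  support`.
#'
#' @param supported_tree a `branch_support_tree`.
#' @param newick_path,tsv_path output paths (NULL to skip either).
#' @return Invisibly, the Newick string.
#' @export
write_support <- function(supported_tree, newick_path = NULL,
                          tsv_path = NULL) {
  stopifnot(inherits(supported_tree, "branch_support_tree"))
  nwk <- ape::write.tree(supported_tree$tree, digits = 12)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(tsv_path))
    utils::write.table(
      data.frame(branch_id = seq_len(nrow(supported_tree$branches)),
                 statistic = fmt10(supported_tree$branches$statistic),
                 support = fmt10(supported_tree$branches$support)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nwk)
}
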