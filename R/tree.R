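#' Tree I/O and random tree generation
#'
#' Trees are represented as unrooted binary `ape::phylo` objects with
#' non-negative branch lengths in expected substitutions per site and
#' taxon-labelled leaves. An unrooted binary tree over m leaves has
#' m - 2 internal nodes and m - 3 internal branches.
#'
#' @name pegl-trees
NULL

# Run code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

validate_phylo <- function(tree, require_binary = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L)
    stop("tree must be unrooted")
  if (require_binary && !ape::is.binary(tree))
    stop("tree must be binary (fully resolved)")
  invisible(tree)
}

#' Parse and write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Round-trips preserve topology, branch lengths (>= 10 significant digits)
#' and internal-node support labels.
#'
#' @param text a Newick string.
#' @return `parse_newick()`: an unrooted `phylo`; `write_newick()`: a
#'   Newick string.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick string")
  validate_phylo(tree, require_binary = FALSE)
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree) {
  validate_phylo(tree, require_binary = FALSE)
  ape::write.tree(tree, digits = 12)
}

#' Generate one random phylogenetic tree
#'
#' Topology is drawn by a Yule (random-split) growth process: starting from
#' two leaves, a uniformly chosen current leaf is repeatedly bifurcated
#' until m leaves exist; taxon labels are then assigned in random order and
#' the tree is unrooted. Every branch length is drawn i.i.d.
#' Exponential(mean = `bl_mean`). Deterministic given `seed`.
#'
#' @param taxa character vector of m >= 3 unique taxon labels.
#' @param seed integer seed (or NULL for the current RNG stream).
#' @param bl_mean mean branch length, substitutions/site (default 0.1).
#' @return An unrooted binary `phylo` over `taxa`.
#' @export
random_tree <- function(taxa, seed = NULL, bl_mean = 0.1) {
  m <- length(taxa)
  if (m < 3L) stop("at least 3 taxa are required")
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (!is.finite(bl_mean) || bl_mean <= 0) stop("'bl_mean' must be > 0")
  with_seed(seed, {
    tree <- yule_split_topology(m)
    tree$tip.label <- sample(taxa)
    # lengths are drawn on the unrooted edges so each of the 2m-3
    # branches is exactly Exponential(bl_mean)
    tree$edge.length <- rep(0, nrow(tree$edge))
    tree <- ape::unroot(tree)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / bl_mean)
    tree
  })
}

# Rooted Yule-split topology over m tips with placeholder labels t1..tm.
yule_split_topology <- function(m) {
  # ids: tips 1..m, internals m+1..2m-1, root = m+1
  parent <- integer(2L * m - 1L)
  kids <- vector("list", 2L * m - 1L)
  kids[[m + 1L]] <- c(1L, 2L)
  parent[1:2] <- m + 1L
  alive <- c(1L, 2L)
  next_int <- m + 2L
  for (k in seq_len(m)[-(1:2)]) {
    t <- alive[sample.int(length(alive), 1L)]
    u <- next_int; next_int <- next_int + 1L
    p <- parent[t]
    kids[[p]][kids[[p]] == t] <- u
    kids[[u]] <- c(t, k)
    parent[t] <- u; parent[k] <- u
    alive <- c(alive, k)
  }
  ints <- (m + 1L):(2L * m - 1L)
  edge <- do.call(rbind, lapply(ints, function(i) cbind(i, kids[[i]])))
  tree <- structure(list(edge = edge, Nnode = m - 1L,
                         tip.label = paste0("t", seq_len(m))),
                    class = "phylo", order = "cladewise")
  ape::reorder.phylo(tree)
}

#' Build an ensemble of random trees
#'
#' The ensemble of random trees (topologies and branch lengths) whose
#' site-wise log-likelihoods are the observations of the sparse regression.
#' The default size of 10,000 trees matches the scale the method was
#' designed for; child seeds are derived once from the master seed
#' (`sample.int(2^31 - 1, n_trees)` under `seed`), so ensembles are fully
#' reproducible.
#'
#' @param taxa character vector of m >= 3 unique taxon labels.
#' @param n_trees ensemble size T >= 2 (default 10000).
#' @param seed master integer seed.
#' @param bl_mean mean branch length passed to [random_tree()].
#' @return A `tree_ensemble`: list with `trees`, `taxa`, `seed`, `bl_mean`.
#' @export
build_ensemble <- function(taxa, n_trees = 10000L, seed = NULL, bl_mean = 0.1) {
  if (n_trees < 2L) stop("ensemble size must be at least 2")
  child_seeds <- if (is.null(seed)) {
    sample.int(2147483647L, n_trees)
  } else {
    with_seed(seed, sample.int(2147483647L, n_trees))
  }
  trees <- lapply(child_seeds, function(s) random_tree(taxa, s, bl_mean))
  structure(list(trees = trees, taxa = sort(taxa), seed = seed,
                 bl_mean = bl_mean, child_seeds = child_seeds),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("Random tree ensemble: %d trees over %d taxa (bl_mean = %g%s)\n",
              length(x$trees), length(x$taxa), x$bl_mean,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' @export
length.tree_ensemble <- function(x) length(x$trees)

# Internal-branch indices of an unrooted phylo: edges whose both ends are
# internal nodes.
internal_edges <- function(tree) {
  ntip <- ape::Ntip(tree)
  which(tree$edge[, 1] > ntip & tree$edge[, 2] > ntip)
}
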