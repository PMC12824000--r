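# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written without the package's own
# pruning/path machinery so the checks stay two-route.

# Jukes-Cantor transition matrix, closed form.
jc_prob <- function(t) {
  e <- exp(-4 * t / 3)
  matrix(0.25 - e / 4, 4, 4) + diag(rep(e, 4))
}

# Site likelihood by exhaustive enumeration of internal-node states
# (uniform 1/4 root prior, JC transition probabilities). Only feasible
# for small trees; the independent check for the pruning engine.
oracle_site_loglik <- function(tree, alignment, col) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nint <- tr$Nnode
  tipstate <- match(unclass(alignment)[tr$tip.label, col],
                    c("A", "C", "G", "T"))
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- c(tipstate, grid[g, ])
    p <- prod(vapply(seq_len(nrow(tr$edge)), function(e) {
      jc_prob(tr$edge.length[e])[st[tr$edge[e, 1L]], st[tr$edge[e, 2L]]]
    }, 0))
    total <- total + 0.25 * p
  }
  log(total)
}

# Canonical signature of an unrooted topology: the sorted set of
# bipartitions induced by internal edges, each written from its
# lexicographically canonical side.
topology_signature <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ie <- which(tr$edge[, 1L] > ntip & tr$edge[, 2L] > ntip)
  if (!length(ie)) return("star")
  sig <- vapply(ie, function(e) {
    side <- sort(below[[tr$edge[e, 2L]]])
    other <- sort(setdiff(tr$tip.label, side))
    if (length(side) > length(other) ||
        (length(side) == length(other) && side[1L] > other[1L]))
      side <- other
    paste(side, collapse = ",")
  }, "")
  paste(sort(sig), collapse = "|")
}

# 5-taxon fixture with an exact number of observed-variable and
# observed-constant columns, plus the planted labels; used by the
# recovery tests. Divergence follows the among-species generator default.
planted_alignment <- function(seed, n_variable = 200L, n_invariant = 200L,
                              depth_scale = 0.05) {
  mod <- subst_model("JC69")
  tree <- simulate_yule_tree(5, depth_scale = depth_scale, seed = seed)
  sv <- simulate_alignment(tree, mod, 20L * n_variable, p_invariant = 0,
                           seed = seed + 1000L)
  ch <- unclass(sv$alignment)
  varcols <- which(apply(ch, 2L, function(col) length(unique(col)) > 1L))
  stopifnot(length(varcols) >= n_variable)
  si <- simulate_alignment(tree, mod, 2L * n_invariant,
                           p_invariant = 0.999, seed = seed + 2000L)
  cc <- unclass(si$alignment)
  constcols <- which(apply(cc, 2L, function(col)
    length(unique(col)) == 1L))
  stopifnot(length(constcols) >= n_invariant)
  aln <- dna_alignment(cbind(ch[, varcols[seq_len(n_variable)]],
                             cc[, constcols[seq_len(n_invariant)]]))
  list(alignment = aln,
       variable = c(rep(TRUE, n_variable), rep(FALSE, n_invariant)),
       tree = tree)
}

# Tiny deterministic alignment used in many I/O and likelihood tests.
toy_alignment <- function() {
  dna_alignment(matrix(
    c("A", "C", "G", "T", "A", "-",
      "A", "C", "G", "T", "C", "-",
      "A", "C", "A", "T", "C", "T",
      "A", "C", "G", "C", "C", "T"),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("w", "x", "y", "z"), NULL)))
}
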