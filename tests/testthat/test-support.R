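test_that("NJ recovers the topology behind an additive distance matrix", {
  # data simulated on a known 4-taxon tree with a clear internal branch
  gen <- parse_newick("((a:0.04,b:0.05):0.08,c:0.04,d:0.06);")
  sim <- simulate_alignment(gen, subst_model("JC69"), 2000, seed = 12)
  nj <- nj_tree(sim$alignment)
  expect_identical(topology_signature(nj), topology_signature(gen))
  expect_true(all(nj$edge.length >= 0))
  # 3 taxa: the unique star-resolved tree
  aln3 <- dna_alignment(unclass(sim$alignment)[1:3, ])
  nj3 <- nj_tree(aln3)
  expect_identical(ape::Ntip(nj3), 3L)
  # identical sequences give zero lengths
  same <- dna_alignment(matrix("A", 4, 10,
                               dimnames = list(letters[1:4], NULL)))
  expect_true(all(nj_tree(same)$edge.length == 0))
})

test_that("NNI produces the two alternative 4-taxon arrangements", {
  tr <- parse_newick("((a:0.1,b:0.2):0.05,c:0.3,d:0.4);")
  ie <- which(tr$edge[, 1] > 4 & tr$edge[, 2] > 4)
  nbs <- nni_neighbors(tr, ie)
  sigs <- vapply(nbs, topology_signature, "")
  all3 <- c(topology_signature(tr), sigs)
  expect_identical(length(unique(all3)), 3L)  # the complete 4-taxon set
  # each neighbor differs from the input by exactly its one internal split
  expect_false(any(sigs == topology_signature(tr)))
  # double application returns to the original neighborhood
  back <- nni_neighbors(nbs[[1]],
                        which(nbs[[1]]$edge[, 1] > 4 &
                              nbs[[1]]$edge[, 2] > 4))
  expect_true(topology_signature(tr) %in%
                vapply(back, topology_signature, ""))
  term <- which(tr$edge[, 2] <= 4)[1]
  expect_error(nni_neighbors(tr, term), "terminal")
})

test_that("NNI preserves pendant branch lengths with their subtrees", {
  tr <- random_tree(letters[1:6], seed = 77)
  for (e in which(tr$edge[, 1] > 6 & tr$edge[, 2] > 6)) {
    for (nb in nni_neighbors(tr, e)) {
      expect_equal(sort(nb$edge.length), sort(tr$edge.length),
                   tolerance = 1e-12)
      expect_true(ape::is.binary(nb))
    }
  }
})

test_that("hill-climbing equals the exhaustive optimum on 4 taxa", {
  mod <- subst_model("JC69")
  gen <- parse_newick("((a:0.05,b:0.05):0.08,c:0.05,d:0.05);")
  sim <- simulate_alignment(gen, mod, 500, seed = 3)
  ml <- ml_search(sim$alignment, mod)
  topos <- c("((a:0.05,b:0.05):0.05,c:0.05,d:0.05);",
             "((a:0.05,c:0.05):0.05,b:0.05,d:0.05);",
             "((a:0.05,d:0.05):0.05,b:0.05,c:0.05);")
  ex <- vapply(topos, function(s)
    attr(optimize_branch_lengths(parse_newick(s), sim$alignment, mod,
                                 warn = FALSE), "loglik"), 0)
  expect_equal(attr(ml, "loglik"), max(ex), tolerance = 1e-3)
  expect_gte(attr(ml, "loglik") + 1e-9,
             attr(optimize_branch_lengths(nj_tree(sim$alignment),
                                          sim$alignment, mod,
                                          warn = FALSE), "loglik"))
})

test_that("search recovers a well-supported 5-taxon generating topology", {
  mod <- subst_model("JC69")
  hits <- 0L
  for (s in 1:10) {
    gen <- parse_newick(
      "(((a:0.04,b:0.04):0.1,c:0.04):0.1,d:0.04,e:0.04);")
    sim <- simulate_alignment(gen, mod, 1000, seed = s + 400)
    ml <- ml_search(sim$alignment, mod)
    hits <- hits + (topology_signature(ml) == topology_signature(gen))
  }
  expect_gte(hits, 9L)
})

test_that("the aLRT support mapping follows the chi-square mixture", {
  expect_identical(pegl:::alrt_support(0), 0)
  # Pr(chi2_1 >= 2.706) = 0.10, halved -> support 0.95
  expect_equal(pegl:::alrt_support(2.706), 0.95, tolerance = 1e-3)
  s <- c(0, 0.5, 1, 2, 4, 8)
  expect_true(all(diff(pegl:::alrt_support(s)) > 0))  # monotone
  expect_true(all(pegl:::alrt_support(s) >= 0 & pegl:::alrt_support(s) <= 1))
})

test_that("overwhelming signal yields near-unit support; star data yields none", {
  mod <- subst_model("JC69")
  gen <- parse_newick("((a:0.05,b:0.05):0.3,c:0.05,d:0.35);")
  sim <- simulate_alignment(gen, mod, 2000, seed = 4)
  bst <- alrt_annotate(ml_search(sim$alignment, mod), sim$alignment, mod)
  expect_gt(bst$branches$support[1], 0.99)
  expect_equal(average_alrt(bst), mean(bst$branches$support))
  # identical sequences: no internal signal at all
  flat <- dna_alignment(matrix(rep(c("A", "C", "G", "T"), 250), 4, 1000,
                               byrow = TRUE,
                               dimnames = list(letters[1:4], NULL)))
  ml <- optimize_branch_lengths(parse_newick(
    "((a:0.01,b:0.01):0.01,c:0.01,d:0.01);"), flat, mod, warn = FALSE)
  bst0 <- suppressWarnings(alrt_annotate(ml, flat, mod))
  expect_lt(bst0$branches$support[1], 0.1)
})

test_that("support annotation writes parseable Newick with node labels", {
  mod <- subst_model("JC69")
  gen <- parse_newick("((a:0.05,b:0.05):0.2,(c:0.05,d:0.05):0.1,e:0.05);")
  sim <- simulate_alignment(gen, mod, 600, seed = 21)
  bst <- alrt_annotate(ml_search(sim$alignment, mod), sim$alignment, mod)
  expect_identical(nrow(bst$branches), 2L)  # m - 3 internal branches
  nwk <- withr::local_tempfile(fileext = ".nwk")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_support(bst, newick_path = nwk, tsv_path = tsv)
  back <- ape::read.tree(nwk)
  expect_identical(topology_signature(back), topology_signature(bst$tree))
  expect_true(any(grepl("^[01]\\.", back$node.label)))
  tab <- read.delim(tsv)
  expect_identical(names(tab), c("branch_id", "statistic", "support"))
})
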