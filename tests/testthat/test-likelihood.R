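test_that("single-column closed forms match the pruning engine", {
  mod <- subst_model("JC69")
  pair <- function(x, y) dna_alignment(matrix(c(x, y), 2, 1,
                                              dimnames = list(c("p", "q"),
                                                              NULL)))
  t0 <- parse_newick("(p:0,q:0);")
  expect_equal(site_log_likelihoods(t0, pair("A", "A"), mod), log(0.25),
               tolerance = 1e-12)
  # fully ambiguous column has likelihood 1
  expect_equal(site_log_likelihoods(t0, pair("-", "-"), mod), 0,
               tolerance = 1e-12)
  # saturation limit: independent draws
  tfar <- parse_newick("(p:10,q:10);")
  expect_equal(site_log_likelihoods(tfar, pair("A", "C"), mod), log(1 / 16),
               tolerance = 1e-4)
  # partial ambiguity: R = {A,G} at t = 0 against A collapses to the
  # compatible state
  expect_equal(site_log_likelihoods(t0, pair("A", "R"), mod), log(0.25),
               tolerance = 1e-12)
})

test_that("pruning equals exhaustive internal-state enumeration (m = 4, 5)", {
  mod <- subst_model("JC69")
  for (m in 4:5) {
    for (s in 1:3) {
      tr <- random_tree(letters[1:m], seed = 100 * m + s)
      sim <- simulate_alignment(tr, mod, 10, seed = s)
      got <- site_log_likelihoods(tr, sim$alignment, mod)
      want <- vapply(1:10, function(j)
        oracle_site_loglik(tr, sim$alignment, j), 0)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("likelihood is invariant to the virtual root (pulley principle)", {
  mod <- subst_model("HKY85", freq = c(0.3, 0.2, 0.3, 0.2), kappa = 3)
  tr <- random_tree(letters[1:6], seed = 8)
  sim <- simulate_alignment(tr, subst_model("JC69"), 40, seed = 2)
  ref <- site_log_likelihoods(tr, sim$alignment, mod)
  for (og in c("a", "d", "f")) {
    re <- ape::unroot(ape::root(tr, outgroup = og, resolve.root = TRUE))
    expect_lt(max(abs(site_log_likelihoods(re, sim$alignment, mod) - ref)),
              1e-10)
  }
})

test_that("discrete-gamma mixture converges to homogeneity as alpha grows", {
  tr <- random_tree(letters[1:5], seed = 3)
  sim <- simulate_alignment(tr, subst_model("JC69"), 60, seed = 5)
  plain <- total_log_likelihood(tr, sim$alignment, subst_model("JC69"))
  with_g <- total_log_likelihood(tr, sim$alignment,
                                 subst_model("JC69", gamma_shape = 1e5,
                                             gamma_k = 4L))
  expect_lt(abs(with_g - plain), 1e-4)
  # the discretization itself has unit mean
  expect_equal(mean(pegl:::discrete_gamma_rates(0.5, 4L)), 1,
               tolerance = 1e-12)
})

test_that("totals are exact site sums and scale with column duplication", {
  mod <- subst_model("JC69", gamma_shape = 0.7, gamma_k = 4L)
  tr <- random_tree(letters[1:5], seed = 9)
  sim <- simulate_alignment(tr, subst_model("JC69"), 30, seed = 1)
  sl <- site_log_likelihoods(tr, sim$alignment, mod)
  expect_equal(total_log_likelihood(tr, sim$alignment, mod), sum(sl),
               tolerance = 1e-8)
  dup <- dna_alignment(cbind(unclass(sim$alignment),
                             unclass(sim$alignment)))
  expect_equal(total_log_likelihood(tr, dup, mod), 2 * sum(sl),
               tolerance = 1e-8)
  one <- dna_alignment(unclass(sim$alignment)[, 1, drop = FALSE])
  expect_equal(total_log_likelihood(tr, one, mod), sl[1], tolerance = 1e-12)
})

test_that("the site-likelihood matrix keeps rows independent and finite", {
  mod <- subst_model("JC69")
  tr <- random_tree(letters[1:5], seed = 30, bl_mean = 0.05)
  sim <- simulate_alignment(tr, mod, 100, p_invariant = 0.3, seed = 4)
  ens <- build_ensemble(letters[1:5], n_trees = 100, seed = 31)
  slh <- compute_sitelh_matrix(ens, sim$alignment, mod)
  expect_identical(dim(slh$loglik), c(100L, 100L))
  expect_true(all(is.finite(slh$loglik)))
  expect_true(all(slh$loglik < 0))
  expect_equal(slh$totals, rowSums(slh$loglik), tolerance = 1e-10)
  # permuting tree order permutes rows only
  perm <- ens
  perm$trees <- perm$trees[c(2:100, 1)]
  slh2 <- compute_sitelh_matrix(perm, sim$alignment, mod)
  expect_equal(slh2$loglik, slh$loglik[c(2:100, 1), ], tolerance = 1e-12)
  expect_error(compute_sitelh_matrix(ens, toy_alignment(), mod), "match")
})

test_that("the sitelh TSV interchange round-trips at 10 digits", {
  mod <- subst_model("JC69")
  tr <- random_tree(letters[1:4], seed = 2)
  sim <- simulate_alignment(tr, mod, 12, seed = 6)
  ens <- build_ensemble(letters[1:4], n_trees = 5, seed = 3)
  slh <- compute_sitelh_matrix(ens, sim$alignment, mod)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sitelh(slh, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(header[1:3], c("tree_id", "total_lnL", "s1"))
  back <- read_sitelh(f)
  expect_equal(back$loglik, slh$loglik, tolerance = 1e-9)
})

test_that("the engine agrees with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  tr <- random_tree(letters[1:6], seed = 5)
  sim <- simulate_alignment(tr, subst_model("JC69"), 80, seed = 2)
  pd <- phangorn::phyDat(unclass(sim$alignment))
  plain <- phangorn::pml(tr, pd, model = "JC")
  expect_equal(total_log_likelihood(tr, sim$alignment, subst_model("JC69")),
               as.numeric(plain$logLik), tolerance = 1e-10)
  gam <- phangorn::pml(tr, pd, model = "JC", k = 4, shape = 0.6)
  expect_equal(total_log_likelihood(tr, sim$alignment,
                                    subst_model("JC69", gamma_shape = 0.6,
                                                gamma_k = 4L)),
               as.numeric(gam$logLik), tolerance = 1e-10)
})

test_that("taxon-set mismatches are rejected rather than subset", {
  mod <- subst_model("JC69")
  tr <- random_tree(letters[1:5], seed = 1)
  aln <- toy_alignment()  # taxa w,x,y,z
  expect_error(site_log_likelihoods(tr, aln, mod), "match exactly")
})
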