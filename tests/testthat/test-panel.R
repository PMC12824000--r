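test_that("panel records enforce their bookkeeping invariants", {
  r <- panel_record("cytb", "among_species", n = 1141, gapless_len = 1100,
                    pegl_count = 342, avg_alrt = 0.7,
                    c1 = 80, c2 = 62, c3 = 200)
  expect_equal(r$proportion, 342 / 1141)
  expect_error(panel_record("g", "among_species", n = 100,
                            gapless_len = 120, pegl_count = 10),
               "gapless_len")
  expect_error(panel_record("g", "among_species", n = 100,
                            gapless_len = 90, pegl_count = 10,
                            c1 = 5, c2 = 5, c3 = 5), "sum to PEGL")
})

test_that("the length regression recovers a constructed linear truth", {
  lens <- seq(700, 2000, length.out = 30)
  rec <- data.frame(gapless_len = round(lens),
                    pegl = round(0.30 * lens))
  fit <- length_informativeness_regression(rec)
  expect_gt(fit$pearson_r, 0.999)
  expect_equal(fit$slope, 0.30, tolerance = 0.01)
  expect_lt(fit$p_value, 0.01)
  # constant response: flat line, zero correlation
  flat <- data.frame(gapless_len = round(lens), pegl = rep(100, 30))
  f0 <- length_informativeness_regression(flat)
  expect_identical(f0$slope, 0)
  expect_identical(f0$pearson_r, 0)
  expect_error(length_informativeness_regression(rec[1:2, ]),
               "at least 3")
  expect_error(length_informativeness_regression(
    data.frame(gapless_len = rep(1000, 5), pegl = 1:5)), "variance")
})

test_that("bootstrap comparison handles degenerate and identical groups", {
  a <- c(1, 2, 3, 4, 5)
  same <- bootstrap_mean_difference(a, a, n_reps = 500, seed = 1)
  expect_equal(same$observed, 0)
  expect_false(same$significant)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  # constant shift with zero within-group variance: point-mass CI
  shift <- bootstrap_mean_difference(rep(12, 6), rep(2, 6), n_reps = 500,
                                     seed = 2)
  expect_equal(shift$ci, c(10, 10))
  expect_true(shift$significant)
  expect_error(bootstrap_mean_difference(numeric(0), a), "empty")
  expect_error(bootstrap_mean_difference(a, a, n_reps = 10), "100")
  # determinism
  b <- stats::rnorm(20)
  r1 <- bootstrap_mean_difference(a, b, n_reps = 300, seed = 9)
  r2 <- bootstrap_mean_difference(a, b, n_reps = 300, seed = 9)
  expect_identical(r1$ci, r2$ci)
})

test_that("percentile intervals reach nominal coverage on Gaussian groups", {
  # 500 seeded runs, R = 1000, n = 50 per group, true difference 0
  covered <- vapply(1:500, function(s) {
    set.seed(s + 7000)
    a <- stats::rnorm(50); b <- stats::rnorm(50)
    ci <- bootstrap_mean_difference(a, b, n_reps = 1000, seed = s)$ci
    ci[1] <= 0 && ci[2] >= 0
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("codon-position counts map 1-based columns through the frame", {
  mask <- rep(FALSE, 9); mask[c(3, 6, 9)] <- TRUE
  expect_identical(unname(codon_position_counts(mask, frame = 1L)),
                   c(0L, 0L, 3L))
  # shifting the frame rotates the positions
  expect_identical(unname(codon_position_counts(mask, frame = 2L)),
                   c(3L, 0L, 0L))
  expect_identical(unname(codon_position_counts(logical(9), 1L)),
                   c(0L, 0L, 0L))
  cc <- codon_position_counts(as.logical(stats::rbinom(100, 1, 0.4)), 3L)
  expect_identical(sum(cc), sum(as.integer(cc)))
})

test_that("third-position rate excess surfaces in the codon breakdown", {
  mod <- subst_model("JC69")
  c3_exceeds <- vapply(1:8, function(s) {
    tr <- simulate_yule_tree(6, depth_scale = 0.05, seed = s)
    sim <- simulate_alignment(tr, mod, 600, p_invariant = 0.3,
                              codon_rates = c(1, 1, 5), seed = s + 90)
    ch <- unclass(sim$alignment)
    varmask <- apply(ch, 2, function(col) length(unique(col)) > 1)
    cc <- codon_position_counts(varmask, frame = 1L)
    cc[3] > (cc[1] + cc[2]) / 2
  }, TRUE)
  expect_gte(mean(c3_exceeds), 0.9)
})

test_that("positional profiles conserve the informative-site count", {
  mask <- c(rep(TRUE, 30), rep(FALSE, 30))
  prof <- positional_profile(mask, window = 30)
  expect_identical(prof$count, c(30L, 0L))
  expect_identical(sum(positional_profile(mask, window = 7)$count),
                   sum(mask))
  single <- positional_profile(mask, window = 60)
  expect_identical(nrow(single), 1L)
  expect_identical(single$count, sum(mask))
  # uniform density: non-overlapping windows within 1 of each other
  unif <- rep(c(TRUE, FALSE), 50)
  cu <- positional_profile(unif, window = 10)$count
  expect_lte(max(cu) - min(cu), 1L)
})

test_that("panel manifests reproduce unit-times-gene arithmetic", {
  spec <- data.frame(dataset = c("mito_within", "mito_among", "nuclear"),
                     units = c(122L, 100L, 8L),
                     genes = c(8L, 8L, 100L))
  man <- panel_manifest(spec)
  expect_identical(man$alignments, c(976L, 800L, 800L))
  expect_identical(attr(man, "total"), 2576L)
  expect_error(panel_manifest(data.frame(dataset = "x", units = 0L,
                                         genes = 5L)), ">= 1")
})

test_that("panel summaries report n-1 standard deviations per group", {
  rec <- rbind(
    panel_record("g1", "within_species", 100, 90, 20, avg_alrt = 0.5),
    panel_record("g2", "within_species", 100, 95, 40, avg_alrt = 0.7),
    panel_record("g3", "among_species", 100, 92, 30, avg_alrt = 0.9))
  s <- summarize_panels(rec)
  w <- s[s$group == "within_species" & s$metric == "proportion", ]
  expect_equal(w$mean, 0.3)
  expect_equal(w$sd, stats::sd(c(0.2, 0.4)))
  a <- s[s$group == "among_species" & s$metric == "proportion", ]
  expect_true(is.na(a$sd))  # single record: sd undefined
  const <- rbind(rec[1, ], rec[1, ])
  sc <- summarize_panels(const)
  expect_equal(sc$sd[sc$metric == "proportion"], 0)
})
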