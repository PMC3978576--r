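test_that("muscle contributions sum to 100 and are symmetric for equal volumes", {
  eq <- muscle_contributions(10, 10, 10, 10)
  expect_equal(unlist(eq), c(vm = 25, rf = 25, vi = 25, vl = 25))
  set.seed(1)
  for (i in 1:5) {
    v <- runif(4, 50, 300)
    ct <- muscle_contributions(v[1], v[2], v[3], v[4])
    expect_equal(sum(unlist(ct)), 100)
  }
  expect_error(muscle_contributions(0, 1, 1, 1), class = "enthesomorph_parameter_error")
})

test_that("VL/VM ratio is plain division with a guarded denominator", {
  expect_equal(vl_vm_ratio(247, 152), 247 / 152)
  expect_equal(vl_vm_ratio(100, 100), 1)
  expect_error(vl_vm_ratio(100, 0), class = "enthesomorph_parameter_error")
})

test_that("consensus grading: max over defects, agreement, majority, median", {
  expect_equal(consensus_icrs(c(1, 3), 3), 3)       # highest defect grade per grader
  expect_equal(consensus_icrs(2, 2), 2)             # agreement
  expect_equal(consensus_icrs(2, 3, grader3 = 3), 3)  # majority
  expect_equal(consensus_icrs(1, 3, grader3 = 2), 2)  # all differ -> median
  expect_equal(consensus_icrs(2, 3), 2.5)          # no adjudicator -> median of two
  expect_equal(consensus_icrs(c(0, 2), c(1, 2)), 2)
  expect_error(consensus_icrs(2, 5), class = "enthesomorph_parameter_error")
})

test_that("lateral/medial ratio flags non-positive medial values", {
  expect_equal(lateral_medial_ratio(0.41, 0.28), 0.41 / 0.28)
  expect_equal(lateral_medial_ratio(3, 3), 1)
  expect_warning(out <- lateral_medial_ratio(c(1, 2), c(2, 0)), "flagged")
  expect_true(is.na(out[2]) && out[1] == 0.5)
})

test_that("KS gate accepts normal samples and rejects bimodal ones", {
  accept <- vapply(1:20, function(s) {
    set.seed(s)
    ks_normality(rnorm(200))$is_normal
  }, logical(1))
  expect_gte(mean(accept), 0.85)   # nominal acceptance ~0.95
  set.seed(1)
  bimodal <- rep(0:1, 50) + rnorm(100, sd = 0.01)
  expect_false(ks_normality(bimodal)$is_normal)
  expect_error(ks_normality(c(1, 2, 3)), class = "enthesomorph_parameter_error")
  expect_true(ks_normality(rep(1, 10))$degenerate)
})

test_that("paired Wilcoxon exact p agrees with full sign enumeration", {
  set.seed(42)
  for (n in c(6, 8, 10)) {
    for (rep in 1:3) {
      x <- round(rnorm(n, 1, 2), 3)
      y <- round(rnorm(n, 0, 2), 3)
      if (any(duplicated(abs(x - y))) || any(x == y)) next
      got <- wilcoxon_paired(x, y)
      expect_equal(got$p, wilcoxon_enum_p(x, y), tolerance = 1e-12,
                   label = paste("n =", n))
    }
  }
})

test_that("degenerate and large-sample Wilcoxon paths behave", {
  x <- rnorm(10)
  expect_warning(res <- wilcoxon_paired(x, x), "zero")
  expect_equal(res$p, 1)
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40, 1)
  res <- wilcoxon_paired(a, b)
  expect_match(res$method, "normal approx")
  expect_lt(res$p, 0.01)
  res_u <- wilcoxon_unpaired(rnorm(15), rnorm(15, 2))
  expect_lt(res_u$p, 0.01)
})

test_that("region comparisons on calibrated cohorts are routinely significant", {
  # central vs medial calcified-fibrocartilage thickness, 12-donor cohorts
  p <- vapply(1:10, function(s) {
    coh <- gen_cohort(cohort_spec(n_donors = 12, seed = 500 + s))
    wilcoxon_paired(coh$cf_central, coh$cf_medial)$p
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.8)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- spearman_strength(x, y)$r
    expect_equal(spearman_strength(exp(x), y)$r, r0)
    expect_equal(spearman_strength(x, y^3)$r, r0)
    expect_equal(spearman_strength(rank(x), qnorm(rank(y) / 31))$r, r0)
  }
  expect_equal(spearman_strength(1:10, (1:10)^3)$r, 1)
})

test_that("strength labelling is total on [-1, 1] with half-open boundaries", {
  grid <- seq(-1, 1, by = 0.01)
  labels <- strength_label(grid)
  expect_true(all(labels %in% c("very strong", "moderate", "fair", "weak")))
  expect_identical(strength_label(c(0.8, 0.799, 0.6, 0.599, 0.3, 0.299, -0.81)),
                   c("very strong", "moderate", "moderate", "fair", "fair", "weak",
                     "very strong"))
  r <- spearman_strength(1:20, 20:1)
  expect_identical(r$strength, "very strong")
  expect_identical(r$direction, "inverse")
  expect_error(spearman_strength(rep(1, 10), 1:10), class = "enthesomorph_parameter_error")
})

test_that("ratio correlation table: co-monotone, independent and excluded records", {
  base <- seq(0.1, 2, length.out = 10)
  com <- data.frame(donor_id = 1:10, leg = "L", vl_vm = base, uf_ratio = base^2,
                    cf_ratio = exp(base), ba_ratio = base + 1, th_ratio = 2 * base,
                    icrs = rank(base))
  t2 <- build_table2(com)
  expect_true(all(abs(t2$r - 1) < 1e-12))
  set.seed(11)
  ind <- data.frame(donor_id = 1:500, leg = "L", vl_vm = rnorm(500),
                    uf_ratio = rnorm(500), cf_ratio = rnorm(500),
                    ba_ratio = rnorm(500), th_ratio = rnorm(500),
                    icrs = sample(0:4, 500, TRUE))
  t2i <- build_table2(ind)
  expect_lt(max(abs(t2i$r[upper.tri(t2i$r)])), 0.1)
  ind$ba_ratio[3] <- NA
  t2x <- build_table2(ind)
  expect_equal(t2x$n_excluded, 1L)
  expect_equal(t2x$n_used, 499L)
})

test_that("donor-level averaging halves the correlation sample size", {
  coh <- gen_cohort(cohort_spec(n_donors = 12, seed = 13))
  r <- knee_ratios(coh)
  expect_equal(build_table2(r, unit = "knee")$n_used, 24L)
  expect_equal(build_table2(r, unit = "donor")$n_used, 12L)
})
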