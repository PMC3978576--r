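test_that("compute_ba equals the pixel-count oracle exactly", {
  for (s in 1:5) {
    m <- random_mask(24, p = runif(1, 0.2, 0.8), seed = s)
    expect_identical(compute_ba(m), ba_oracle(m$bits))
  }
  all_bone <- binary_mask(matrix(TRUE, 8, 8), 0.05)
  expect_identical(compute_ba(all_bone), 1)
  out <- gen_trabecular_image(texture_spec("checkerboard", target_ba = 0.5, size_px = 64))
  expect_identical(compute_ba(out$mask), 0.5)
})

test_that("mean intercept length is analytic on periodic stripes", {
  # bone 8 px (0.2 mm), marrow 16 px (0.4 mm), horizontal scan normal to stripes
  px <- 0.025
  col_bone <- (0:(96 - 1)) %% 24 < 8
  bits <- matrix(rep(col_bone, each = 96), 96, 96)
  m <- binary_mask(bits, px)
  expect_equal(mean_intercept_length(m, phase = "marrow"), 16 * px)
  expect_equal(mean_intercept_length(m, phase = "bone"), 8 * px)
})

test_that("mean intercept length equals exhaustive run enumeration on random masks", {
  for (s in c(2, 7)) {
    m <- random_mask(20, p = 0.5, seed = s)
    for (phase in c("bone", "marrow")) {
      runs <- runs_oracle(m$bits, phase == "bone")
      expect_equal(mean_intercept_length(m, phase = phase),
                   mean(runs) * m$pixel_size_mm)
    }
  }
})

test_that("phase absent from the ROI errors; all-censored falls back with warning", {
  all_bone <- binary_mask(matrix(TRUE, 10, 10), 0.05)
  expect_error(mean_intercept_length(all_bone, phase = "marrow"),
               class = "enthesomorph_parameter_error")
  expect_warning(v <- mean_intercept_length(all_bone, phase = "bone"), "censored")
  expect_equal(v, 10 * 0.05)
})

test_that("thickness indices follow the printed formula and the plate model", {
  th <- compute_th(0.5, 2.0)
  expect_equal(th$TH_printed, 0.5)
  expect_equal(th$TH_plate_mm, 2.0)
  # monotone increasing in ba, vanishing as ba -> 0
  bas <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(bas, function(b) compute_th(b, 1.5)$TH_printed, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(vals[1], 0.1)
  expect_error(compute_th(0.5, 0), class = "enthesomorph_parameter_error")
  expect_error(compute_th(1, 1), class = "enthesomorph_parameter_error")
})

test_that("stripe construction ties BA, Tb.Sp and the thickness indices together", {
  # bone width = marrow width = 0.3 mm
  out <- gen_trabecular_image(texture_spec("stripes", target_ba = 0.5,
    strut_thickness_mm = 0.3, pixel_size_mm = 0.025, noise_sd = 0, size_px = 120))
  res <- morphometry(out$mask)
  w <- 0.3
  expect_equal(res$BA, 0.5)
  expect_equal(res$Tb_Sp, w)
  expect_equal(res$TH_intercept, w)          # mean bone intercept = strut width
  expect_equal(res$TH_plate, w)              # plate model equals strut width at BA 0.5
  expect_equal(res$TH, 2 * 0.5 / w)          # printed formula, units 1/mm
})

test_that("bone intercept recovers the strut width within one pixel spacing", {
  for (ba in c(0.4, 0.5)) {
    out <- gen_trabecular_image(texture_spec("stripes", target_ba = ba,
      strut_thickness_mm = 0.2, pixel_size_mm = 0.025, noise_sd = 0, size_px = 120))
    res <- morphometry(out$mask)
    expect_lt(abs(res$TH_intercept - 0.2), 0.025)
  }
})

test_that("region aggregation matches the two-pass reference and handles small groups", {
  rs <- list(
    structure(list(region = "lateral", BA = 0.4, Tb_Sp = 1, TH = 1, TH_plate = 1,
                   TH_intercept = 1, n_pixels_roi = 100L), class = "morphometry_result"),
    structure(list(region = "lateral", BA = 0.6, Tb_Sp = 1, TH = 1, TH_plate = 1,
                   TH_intercept = 1, n_pixels_roi = 100L), class = "morphometry_result"),
    structure(list(region = "central", BA = 0.5, Tb_Sp = 1, TH = 1, TH_plate = 1,
                   TH_intercept = 1, n_pixels_roi = 100L), class = "morphometry_result"))
  expect_warning(agg <- aggregate_regions(rs), "fewer than 2")
  expect_identical(agg$region, "lateral")
  expect_equal(agg$BA_mean, 0.5)
  expect_equal(agg$BA_sd, sd(c(0.4, 0.6)))   # n-1 denominator, ~0.1414
  # identical replicates -> SD 0
  rs2 <- rs[c(1, 1)]
  agg2 <- aggregate_regions(rs2)
  expect_equal(agg2$BA_sd, 0)
})

test_that("segmentation round-trip recovers the target bone fraction within 0.02", {
  for (target in c(0.28, 0.49)) {
    bas <- vapply(1:5, function(s) {
      sp <- texture_spec("gaussian_random_field", target_ba = target,
                         strut_thickness_mm = 0.3, pixel_size_mm = 0.025,
                         noise_sd = 15, seed = 100 + s, size_px = 160)
      g <- gen_trabecular_image(sp)
      compute_ba(segment_trabeculae(g$image))
    }, numeric(1))
    expect_lt(abs(mean(bas) - target), 0.02, label = paste("target", target))
  }
})
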