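test_that("LoG response of a constant image is exactly zero", {
  img <- section_image(matrix(120, 48, 48), pixel_size_mm = 0.05)
  expect_lt(max(abs(log_filter(img, sigma_mm = 0.15))), 1e-9)
})

test_that("separable LoG equals direct convolution with the sampled kernel", {
  set.seed(4)
  m <- matrix(runif(40 * 40, 0, 255), 40, 40)
  img <- section_image(m, pixel_size_mm = 0.05)
  got <- log_filter(img, sigma_mm = 0.1)  # sigma = 2 px
  want <- conv2d_brute(m, log_kernel_2d(2))
  # interior agrees exactly; edges differ only through the padding order of
  # the separable passes, so compare away from the border
  r <- 2 * ceiling(4 * 2)
  core <- (r + 1):(40 - r)
  expect_equal(got[core, core], want[core, core], tolerance = 1e-10)
})

test_that("a step edge gives an antisymmetric response crossing zero at the edge", {
  m <- cbind(matrix(50, 40, 20), matrix(200, 40, 20))
  img <- section_image(m, pixel_size_mm = 0.05)
  f <- log_filter(img, sigma_mm = 0.15)
  mid <- f[20, ]
  # zero crossing sits between the two columns flanking the edge
  expect_true(mid[20] > 0 && mid[21] < 0)
  # antisymmetry about the edge (columns 20+k vs 21-k)
  for (k in 0:5) expect_equal(mid[20 - k], -mid[21 + k], tolerance = 1e-6)
})

test_that("zero-crossing contour of a bright disk lies within 1 px of the circle", {
  out <- gen_trabecular_image(texture_spec("disk", target_ba = 0.2,
    noise_sd = 0, size_px = 96, pixel_size_mm = 0.05))
  mask <- segment_trabeculae(out$image, sigma_mm = 0.1)
  r_true <- sqrt(0.2 * 96^2 / pi)
  ctr <- (96 + 1) / 2
  d <- sqrt(outer((seq_len(96) - ctr)^2, (seq_len(96) - ctr)^2, "+"))
  wrong <- mask$bits != out$mask$bits
  expect_true(all(abs(d[wrong] - r_true) <= 1.5))
})

test_that("stripes are recovered up to a 1-px boundary band", {
  out <- gen_trabecular_image(texture_spec("stripes", target_ba = 0.5,
    strut_thickness_mm = 0.4, pixel_size_mm = 0.025, noise_sd = 0, size_px = 128))
  mask <- segment_trabeculae(out$image)
  wrong <- which(mask$bits != out$mask$bits, arr.ind = TRUE)
  if (nrow(wrong) > 0) {
    # disagreement only next to a stripe boundary (column changes phase)
    col_bone <- out$mask$bits[1, ]
    boundary_cols <- which(diff(col_bone) != 0)
    near <- vapply(wrong[, 2], function(j) min(abs(j - boundary_cols)) <= 1, logical(1))
    expect_true(all(near))
  }
  expect_lt(mean(mask$bits != out$mask$bits), 0.02)
})

test_that("dark-bone polarity returns the complement segmentation", {
  out <- gen_trabecular_image(texture_spec("stripes", target_ba = 0.5,
    strut_thickness_mm = 0.4, pixel_size_mm = 0.025, noise_sd = 0, size_px = 96))
  inverted <- section_image(250 - out$image$pixels, out$image$pixel_size_mm)
  m_bright <- segment_trabeculae(out$image)
  m_dark <- segment_trabeculae(inverted, polarity = "dark")
  expect_identical(m_bright$bits, m_dark$bits)
})

test_that("pure noise with a large sigma yields structureless BA near 0.5", {
  bas <- vapply(1:8, function(s) {
    set.seed(s)
    img <- section_image(matrix(rnorm(96 * 96, 125, 40), 96, 96), pixel_size_mm = 0.05)
    compute_ba(segment_trabeculae(img, sigma_mm = 0.3))
  }, numeric(1))
  expect_lt(abs(mean(bas) - 0.5), 0.05)
})

test_that("segmentation is deterministic", {
  sp <- texture_spec("gaussian_random_field", target_ba = 0.4, seed = 9,
                     noise_sd = 15, size_px = 96)
  img <- gen_trabecular_image(sp)$image
  expect_identical(segment_trabeculae(img)$bits, segment_trabeculae(img)$bits)
})

test_that("sigma below the pixel size is rejected", {
  img <- section_image(matrix(runif(64, 0, 255), 8, 8), pixel_size_mm = 0.05)
  expect_error(log_filter(img, sigma_mm = 0.01), class = "enthesomorph_parameter_error")
})

test_that("cortical rim is detected and excluded from the trabecular ROI", {
  set.seed(21)
  n <- 160
  bits <- matrix(runif(n * n) < 0.4, n, n)
  rim <- 20L
  bits[c(1:rim, (n - rim + 1):n), ] <- TRUE
  bits[, c(1:rim, (n - rim + 1):n)] <- TRUE
  mask <- binary_mask(bits, pixel_size_mm = 0.05)  # band 1 mm = 20 px
  cb <- detect_cortical_boundary(mask)
  expect_true(cb$shell_found)
  expect_true(min(cb$roi_rows) > rim && max(cb$roi_rows) <= n - rim)
  expect_lt(abs(compute_ba(mask, cb) - 0.4), 0.03)
})

test_that("absent or zero-thickness rim falls back to the full image with a warning", {
  set.seed(22)
  bits <- matrix(runif(80 * 80) < 0.4, 80, 80)
  mask <- binary_mask(bits, pixel_size_mm = 0.05)
  expect_warning(cb <- detect_cortical_boundary(mask), "no cortical shell")
  expect_false(cb$shell_found)
  expect_identical(length(cb$roi_rows), 80L)
  expect_equal(compute_ba(mask, cb), compute_ba(mask))
})
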