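test_that("wall thickness is the tissue span times section thickness", {
  ht <- rep(FALSE, 40); ht[4:34] <- TRUE          # first = 4, last = 34
  expect_equal(wall_thickness(ht), 210)
  ht2 <- rep(FALSE, 20); ht2[1:16] <- TRUE
  expect_equal(wall_thickness(ht2), 105)
  single <- c(FALSE, TRUE, FALSE)
  expect_warning(w <- wall_thickness(single), "degenerate")
  expect_equal(w, 0)
  expect_error(wall_thickness(rep(FALSE, 5)), "no tissue")
})

test_that("midwall selection keeps relative depths in [0.40, 0.60]", {
  # 10 tissue sections at depths k/9: only 4/9 and 5/9 fall in the band
  ht <- rep(TRUE, 10)
  expect_equal(select_midwall(ht), c(5, 6))
  # 5 sections at depths k/4: only the middle one (0.5)
  expect_equal(select_midwall(rep(TRUE, 5)), 3)
  expect_error(select_midwall(rep(FALSE, 10)), ">= 5")
})

test_that("channel subtraction isolates fibers and clamps at zero", {
  pol <- matrix(c(1, 0.05, 0.5, 0), 2)
  bf <- matrix(c(0, 0.95, 0.5, 1), 2)
  out <- subtract_images(list(polarized = pol, brightfield_blue = bf))
  expect_equal(out[1, 1], 1)      # fiber pixel
  expect_equal(out[2, 1], 0)      # background, clamped
  expect_true(all(out >= 0))
  same <- matrix(runif(16), 4)
  expect_equal(subtract_images(list(polarized = same, brightfield_blue = same)),
               matrix(0, 4, 4))
  expect_error(subtract_images(list(polarized = pol,
                                    brightfield_blue = matrix(0, 3, 3))),
               "shapes")
})

test_that("collagen area fraction recovers a painted mask fraction", {
  expect_equal(suppressWarnings(collagen_area_fraction(matrix(0, 32, 32))), 0)
  expect_equal(collagen_area_fraction(matrix(1, 32, 32),
                                      threshold_method = 0.5), 1)
  # known painted mask: 37% of pixels set to 1
  set.seed(61)
  img <- matrix(0, 100, 100)
  img[sample.int(1e4, 3700)] <- 1
  expect_equal(collagen_area_fraction(img), 0.37, tolerance = 0.02)
  expect_warning(collagen_area_fraction(matrix(0.5, 8, 8)), "constant")
})

test_that("structure tensor recovers stripe orientations (axial wrap included)", {
  f30 <- estimate_fiber_orientations(stripe_image(30), subwindow_px = 16)
  expect_true(any(f30$valid))
  expect_true(all(axial_dist(f30$theta[f30$valid], 30) < 3))
  f0 <- estimate_fiber_orientations(stripe_image(0), subwindow_px = 16)
  f90 <- estimate_fiber_orientations(stripe_image(90), subwindow_px = 16)
  d <- axial_dist(f0$theta[f0$valid][1], f90$theta[f90$valid][1])
  expect_equal(d, 90, tolerance = 3)
  blank <- estimate_fiber_orientations(matrix(0, 64, 64))
  expect_equal(sum(blank$valid), 0)
  expect_error(estimate_fiber_orientations(matrix(0, 8, 8), subwindow_px = 16),
               "smaller")
})

test_that("circular summary matches the complex-sum oracle to 1e-10", {
  set.seed(62)
  for (i in 1:25) {
    th <- runif(sample(3:40, 1), 0, 180)
    w <- runif(length(th), 0.1, 2)
    got <- circular_summary(th, weights = w)
    want <- complex_sum_summary(th, w)
    expect_equal(got$MVL, want$MVL, tolerance = 1e-10)
    expect_equal(axial_dist(got$theta_m, want$theta_m), 0, tolerance = 1e-10)
  }
})

test_that("circular summary honours the stated bounds and worked examples", {
  expect_equal(circular_summary(rep(73.2, 10))$MVL, 1)
  expect_equal(circular_summary(c(0, 45, 90, 135))$MVL, 0, tolerance = 1e-12)
  cs <- circular_summary(c(0, 30))
  expect_equal(cs$MVL, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(cs$theta_m, 15)
  expect_error(circular_summary(numeric(0)), "no valid")
})

test_that("MVL is rotation-invariant and theta_m shifts with the rotation", {
  set.seed(63)
  th <- runif(30, 0, 180)
  base <- circular_summary(th)
  for (rot in c(10, 45, 90, 170)) {
    r <- circular_summary((th + rot) %% 180)
    expect_equal(r$MVL, base$MVL, tolerance = 1e-12)
    expect_equal(axial_dist(r$theta_m, base$theta_m + rot), 0,
                 tolerance = 1e-9)
  }
})

test_that("estimated MVL increases monotonically with von Mises concentration", {
  kappas <- c(0, 1, 2, 4, 8)
  mean_mvl <- vapply(seq_along(kappas), function(i) {
    mvl <- vapply(1:20, function(rep) {
      tr <- fiber_truth(mu = 60, kappa = kappas[i], fiber_density = 8)
      pair <- simulate_scar_image_pair(tr, c(64, 64), noise_sd = 0,
                                       seed = 1000 * i + rep)
      circular_summary(pair$angles)$MVL
    }, numeric(1))
    mean(mvl)
  }, numeric(1))
  expect_true(all(diff(mean_mvl) > 0))
})

test_that("planted orientation is recovered from rendered images", {
  tr <- fiber_truth(mu = 35, kappa = 6, fiber_density = 4)
  pair <- simulate_scar_image_pair(tr, c(256, 256), noise_sd = 0.01, seed = 64)
  expect_gte(length(pair$angles), 200)
  res <- analyze_scar_pair(pair)
  expect_lt(axial_dist(res$summary$theta_m, 35), 3)
  # near-degenerate concentration: recovery within 2 degrees, strong alignment
  tr2 <- fiber_truth(mu = 120, kappa = 400, fiber_density = 4)
  pair2 <- simulate_scar_image_pair(tr2, c(256, 256), noise_sd = 0.01,
                                    seed = 65)
  res2 <- analyze_scar_pair(pair2)
  expect_lt(axial_dist(res2$summary$theta_m, 120), 2)
  expect_gt(res2$summary$MVL, 0.95)
})

test_that("group alignment test reproduces hand-derived statistics", {
  # all samples at the group orientation: v_i = MVL_i, t = mean/(sd/sqrt(n))
  samples <- data.frame(MVL = c(0.5, 0.6, 0.7), theta_m = c(40, 40, 40))
  at <- alignment_significance(samples)
  expect_equal(at$v, c(0.5, 0.6, 0.7), tolerance = 1e-12)
  expect_equal(at$t, 0.6 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(at$df, 2)
  # two equal-length vectors 90 degrees apart cancel: v sums to 0
  s2 <- data.frame(MVL = c(0.5, 0.5), theta_m = c(10, 100))
  at2 <- suppressWarnings(alignment_significance(s2))
  expect_equal(sum(at2$v), 0, tolerance = 1e-9)
  expect_error(alignment_significance(samples[1, , drop = FALSE]), ">= 2")
})

test_that("degenerate alignment input reports an undefined p-value", {
  s <- data.frame(MVL = c(0.4, 0.4), theta_m = c(25, 25))
  expect_warning(at <- alignment_significance(s), "zero variance")
  expect_true(is.na(at$p_value))
})

test_that("image pairs round-trip through 16-bit TIFF", {
  tr <- fiber_truth(mu = 10, kappa = 3, fiber_density = 2)
  pair <- simulate_scar_image_pair(tr, c(64, 64), seed = 66)
  pp <- tempfile(fileext = ".tif"); bp <- tempfile(fileext = ".tif")
  write_scar_pair_tiff(pair, pp, bp)
  back <- read_scar_pair(pp, bp, pixel_size = 2.21)
  expect_lt(max(abs(back$polarized - pair$polarized)), 2 / 65535)
  expect_lt(max(abs(back$brightfield_blue - pair$brightfield_blue)),
            2 / 65535)
  expect_equal(back$pixel_size, 2.21)
})
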