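# Spot images here are built by make_spot_image() (helper), an independent
# direct renderer, so detection is never validated against its own plumbing.

test_that("candidate finding isolates true maxima", {
  p <- detection_params()
  # all-zero image: empty result
  z <- pixel_grid(matrix(0, 64, 64), 107.5)
  expect_equal(nrow(find_candidates(z, p)), 0)

  # one noiseless spot well inside the field: exactly one seed at the mode
  ctr <- c(20, 25)
  img <- pixel_grid(make_spot_image(c(64, 64), matrix(ctr, 1)), 107.5)
  seeds <- find_candidates(img, p)
  expect_equal(nrow(seeds), 1)
  expect_equal(c(seeds$x_px, seeds$y_px), ctr)

  # two spots 6 sigma apart: exactly two seeds, matching a brute local-max scan
  sig <- 0.93
  ctrs <- matrix(c(20, 20, 20 + 6 * sig, 20), 2, 2, byrow = TRUE)
  img2 <- pixel_grid(make_spot_image(c(64, 48), ctrs), 107.5)
  seeds2 <- find_candidates(img2, p)
  expect_equal(nrow(seeds2), 2)
  # brute-force confirmation on the raw image: local maxima above half peak
  m <- img2$data
  brute <- 0
  for (r in 2:(nrow(m) - 1)) for (cc in 2:(ncol(m) - 1)) {
    nb <- m[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (m[r, cc] == max(nb) && sum(nb == max(nb)) == 1 && m[r, cc] > 500) {
      brute <- brute + 1
    }
  }
  expect_equal(brute, 2)

  # seeds inside the border margin are discarded
  img3 <- pixel_grid(make_spot_image(c(64, 64), matrix(c(3, 3), 1)), 107.5)
  expect_equal(nrow(find_candidates(img3, p)), 0)
})

test_that("subpixel refinement recovers the analytic centre", {
  p <- detection_params()
  # fractional centre, noiseless: centroid symmetry makes the
  # true centre exact; require 0.05 px agreement
  ctr <- c(10.30, 20.70)
  img <- pixel_grid(make_spot_image(c(40, 40), matrix(ctr, 1)), 107.5)
  r <- refine_subpixel(img, round(ctr), p)
  expect_lt(sqrt((r$x_px - ctr[1])^2 + (r$y_px - ctr[2])^2), 0.05)
  expect_equal(r$flag, "ok")
  expect_true(r$converged)

  # centred exactly on a pixel centre: recovered to within convergence_tol
  img0 <- pixel_grid(make_spot_image(c(33, 33), matrix(c(16, 16), 1)), 107.5)
  r0 <- refine_subpixel(img0, c(16, 16), p)
  expect_lt(abs(r0$x_px - 16), p$convergence_tol)
  expect_lt(abs(r0$y_px - 16), p$convergence_tol)

  # brightness is the background-subtracted integral over the fit window:
  # on a zero-background spot it approximates the full Gaussian integral
  expect_equal(r0$brightness, 1000 * 2 * pi * 0.93^2, tolerance = 0.05)
})

test_that("refinement agrees with the analytic centre at every subpixel phase", {
  p <- detection_params()
  worst <- 0
  for (fx in seq(0, 0.9, by = 0.1)) {
    for (fy in seq(0, 0.9, by = 0.1)) {
      ctr <- c(15 + fx, 17 + fy)
      img <- pixel_grid(make_spot_image(c(33, 35), matrix(ctr, 1)), 107.5)
      r <- refine_subpixel(img, round(ctr), p)
      worst <- max(worst, sqrt((r$x_px - ctr[1])^2 + (r$y_px - ctr[2])^2))
    }
  }
  expect_lt(worst, p$convergence_tol)
})

test_that("degenerate fits fall back to the weighted centroid and drift rejects", {
  p <- detection_params()
  # flat image: quadratic has no interior maximum anywhere
  flat <- pixel_grid(matrix(10, 33, 33), 107.5)
  r <- refine_subpixel(flat, c(16, 16), p)
  expect_equal(r$flag, "centroid")
  # seed far from any spot on a gradient pulls the estimate away: reject
  ramp <- pixel_grid(make_spot_image(c(64, 64), matrix(c(30, 30), 1)), 107.5)
  expect_null(refine_subpixel(ramp, c(26, 30), p))
})

test_that("detection is translation-equivariant away from borders", {
  set.seed(42)
  ctrs <- cbind(runif(6, 45, 80), runif(6, 45, 80))
  base <- make_spot_image(c(128, 128), ctrs)
  p <- detection_params()
  m0 <- detect_particles(pixel_grid(base, 107.5), p)
  shifted <- make_spot_image(c(128, 128), sweep(ctrs, 2, c(3, -2), "+"))
  m1 <- detect_particles(pixel_grid(shifted, 107.5), p)
  expect_equal(nrow(m1), nrow(m0))
  o0 <- order(m0$x_px); o1 <- order(m1$x_px)
  expect_equal(m1$x_px[o1], m0$x_px[o0] + 3, tolerance = 1e-6)
  expect_equal(m1$y_px[o1], m0$y_px[o0] - 2, tolerance = 1e-6)
})

test_that("detected positions are invariant to intensity scaling", {
  tr <- generate_scene(c(50, 1), field_px = c(256, 256), seed = 21)
  img <- render_channel(tr, 1, psf_model(), seed = 22)
  p <- detection_params()
  m1 <- detect_particles(img, p)
  m2 <- detect_particles(pixel_grid(img$data * 7.3, 107.5), p)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$x_px, m1$x_px, tolerance = 1e-9)
  expect_equal(m2$y_px, m1$y_px, tolerance = 1e-9)
})

test_that("full detection is exact on a well-separated high-SNR scene", {
  tr <- generate_scene(c(200, 1), field_px = c(512, 512), seed = 31)
  img <- render_channel(tr, 1, psf_model(), seed = 32)
  map <- detect_particles(img)
  ev <- evaluate_detection(tr, map, match_radius_px = 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # determinism: same image, same params, identical maps
  expect_identical(as.data.frame(map), as.data.frame(detect_particles(img)))
  # empty image gives an empty map
  empty <- detect_particles(pixel_grid(matrix(0, 64, 64), 107.5))
  expect_equal(nrow(empty), 0)
})

test_that("detection scoring follows the stated matching conventions", {
  tr <- generate_scene(c(30, 1), field_px = c(256, 256), seed = 41)
  p <- tr$particles[tr$particles$channel == "ch1", ]
  exact <- map_from_xy(p$x_px, p$y_px, field_px = c(256, 256))
  ev <- evaluate_detection(tr, exact)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$rms_error_nm, 0)
  # half the truth detected, nothing spurious
  half <- map_from_xy(p$x_px[1:15], p$y_px[1:15], field_px = c(256, 256))
  ev2 <- evaluate_detection(tr, half)
  expect_equal(ev2$recall, 0.5)
  expect_equal(ev2$precision, 1)
  # empty truth, empty detection: both ratios 1 by convention
  t0 <- generate_scene(c(0, 0), field_px = c(64, 64), seed = 1)
  ev3 <- evaluate_detection(t0, map_from_xy(numeric(0), numeric(0),
                                            field_px = c(64, 64)))
  expect_equal(ev3$precision, 1)
  expect_equal(ev3$recall, 1)
})

test_that("localisation error grows as the signal fades", {
  rms_at <- function(amp) {
    errs <- c()
    for (s in 1:3) {
      tr <- generate_scene(c(100, 1), field_px = c(512, 512),
                           amplitude = amp, seed = 50 + s)
      img <- render_channel(tr, 1, psf_model(), seed = 60 + s)
      ev <- evaluate_detection(tr, detect_particles(img))
      errs <- c(errs, ev$rms_error_nm)
    }
    mean(errs)
  }
  hi <- rms_at(2000)
  lo <- rms_at(250)
  expect_gt(lo, hi)
})
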