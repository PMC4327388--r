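test_that("matching a map against itself flags every particle at distance 0", {
  set.seed(1)
  m <- random_map(40)
  res <- match_directed(m, m, 215)
  expect_true(all(res$colocalised))
  expect_equal(res$nn_dist_nm, rep(0, 40))
  expect_equal(percent_colocalised(res), 100)
})

test_that("the threshold is a strict inequality", {
  # two particles exactly 2 px = 215 nm apart: NOT colocalised
  a <- map_from_xy(10, 10)
  b <- map_from_xy(12, 10, channel = "ch2")
  expect_false(match_directed(a, b, 215)$colocalised)
  # a hair inside the threshold is
  b2 <- map_from_xy(12 - 1e-9, 10, channel = "ch2")
  expect_true(match_directed(a, b2, 215)$colocalised)
})

test_that("empty targets yield infinite distances, empty sources an error", {
  a <- map_from_xy(c(1, 2), c(1, 2))
  none <- map_from_xy(numeric(0), numeric(0), channel = "ch2")
  res <- match_directed(a, none, 215)
  expect_equal(res$nn_dist_nm, c(Inf, Inf))
  expect_false(any(res$colocalised))
  expect_error(percent_colocalised(match_directed(none, a, 215)),
               "no particles")
})

test_that("percentages are plain flagged-over-total arithmetic", {
  a <- map_from_xy(c(0, 0, 0, 50), c(0, 10, 20, 50))
  b <- map_from_xy(c(0, 0, 0), c(0, 10, 20), channel = "ch2")
  expect_equal(percent_colocalised(match_directed(a, b, 215)), 75)
  expect_equal(percent_colocalised(match_directed(b, a, 215)), 100)
  far <- map_from_xy(400, 400, channel = "ch3")
  expect_equal(percent_colocalised(match_directed(a, far, 215)), 0)
})

test_that("vectorised matching equals the exhaustive double-loop scan", {
  set.seed(123)
  for (rep in 1:30) {
    ns <- sample(1:50, 1)
    nt <- sample(0:50, 1)
    src <- random_map(ns)
    tgt <- if (nt > 0) random_map(nt, channel = "ch2")
           else map_from_xy(numeric(0), numeric(0), channel = "ch2")
    got <- match_directed(src, tgt, 215)
    want <- brute_nn(cbind(src$x_px, src$y_px), cbind(tgt$x_px, tgt$y_px))
    expect_equal(got$nn_dist_nm, want$dist * 107.5, tolerance = 1e-9)
    expect_identical(got$colocalised, want$dist * 107.5 < 215)
  }
})

test_that("raw percentage is non-decreasing in the threshold", {
  set.seed(5)
  a <- random_map(80)
  b <- random_map(120, channel = "ch2")
  taus <- seq(20, 4000, length.out = 20)
  pct <- vapply(taus, function(t) {
    percent_colocalised(match_directed(a, b, t))
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("the two directions of an asymmetric fixture provably differ", {
  # three ch1 particles cluster around one ch2 particle: 100% of ch1 is
  # within reach of ch2, but ch2 also has isolated particles
  a <- map_from_xy(c(10, 10.5, 11), c(10, 10, 10))
  b <- map_from_xy(c(10.5, 200, 300), c(10, 200, 300), channel = "ch2")
  p_ab <- percent_colocalised(match_directed(a, b, 215))
  p_ba <- percent_colocalised(match_directed(b, a, 215))
  expect_equal(p_ab, 100)
  expect_equal(p_ba, 100 / 3)
})

test_that("scrambling preserves counts and brightness and is reproducible", {
  set.seed(9)
  m <- random_map(50)
  m$brightness <- runif(50, 100, 1000)
  s1 <- scramble_map(m, magnitude_px = 20, seed = 4)
  s2 <- scramble_map(m, magnitude_px = 20, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50)
  expect_equal(s1$brightness, m$brightness)
  expect_false(isTRUE(all.equal(s1$x_px, m$x_px)))
  # wrapped inside the field bounds
  expect_true(all(s1$x_px >= 0 & s1$x_px <= 511))
  expect_true(all(s1$y_px >= 0 & s1$y_px <= 511))
})

test_that("scrambling destroys short-range correlation down to chance level", {
  # scrambled self-colocalisation approaches the CSR law 1 - exp(-rho pi tau^2)
  set.seed(11)
  n <- 300; field <- 512; tau_px <- 2
  src <- random_map(100, field = field, margin = 25)
  tgt <- random_map(n, field = field, channel = "ch2")
  pct <- vapply(1:150, function(k) {
    percent_colocalised(match_directed(
      src, scramble_map(tgt, magnitude_px = 40, seed = 1000 + k),
      tau_px * 107.5))
  }, numeric(1))
  rho <- n / field^2
  expected <- 100 * (1 - exp(-rho * pi * tau_px^2))
  se <- sd(pct) / sqrt(length(pct))
  expect_lt(abs(mean(pct) - expected), 3 * se + 1e-6)
})

test_that("scrambling source or target is equivalent in expectation under CSR", {
  set.seed(13)
  a <- random_map(150, margin = 25)
  b <- random_map(150, margin = 25, channel = "ch2")
  p_t <- vapply(1:100, function(k) {
    percent_colocalised(match_directed(a, scramble_map(b, seed = k), 215))
  }, numeric(1))
  p_s <- vapply(1:100, function(k) {
    percent_colocalised(match_directed(scramble_map(a, seed = 5000 + k), b, 215))
  }, numeric(1))
  se <- sqrt(var(p_t) / 100 + var(p_s) / 100)
  expect_lt(abs(mean(p_t) - mean(p_s)), 3 * se + 1e-6)
})

test_that("net colocalisation is centred on zero for independent maps", {
  set.seed(17)
  maps <- list(random_map(120, channel = "ch1"),
               random_map(120, channel = "ch2"))
  cfg <- acquisition_config(107.5, threshold_px = 2)
  res <- net_colocalisation(maps, cfg, n_repeats = 100, seed = 19)
  # binomial noise on the raw percentage dominates: ~3 SE of p(1-p)/n
  p0 <- res$pairs$scrambled_mean / 100
  tol <- 3 * 100 * sqrt(max(p0 * (1 - p0)) / 120) + 0.5
  expect_true(all(abs(res$pairs$net_percent) < tol))
  expect_equal(res$pairs$net_percent,
               res$pairs$raw_percent - res$pairs$scrambled_mean)
})

test_that("identical maps give raw 100 and a positive net percentage", {
  set.seed(23)
  a <- random_map(80)
  b <- map_from_xy(a$x_px, a$y_px, channel = "ch2", field_px = c(512, 512))
  cfg <- acquisition_config(107.5, threshold_px = 2)
  res <- net_colocalisation(list(a, b), cfg, n_repeats = 50, seed = 29)
  expect_equal(res$pairs$raw_percent, c(100, 100))
  expect_true(all(res$pairs$net_percent > 90))
})

test_that("empty channels after ROI filtering warn and give NA pairs only there", {
  a <- map_from_xy(c(5, 6), c(5, 6), field_px = c(64, 64))
  b <- map_from_xy(c(50, 51), c(50, 51), channel = "ch2", field_px = c(64, 64))
  c3 <- map_from_xy(c(5.5, 6.5), c(5.5, 6.5), channel = "ch3",
                    field_px = c(64, 64))
  roi <- roi_polygon(c(0, 20, 20, 0), c(0, 0, 20, 20))
  cfg <- acquisition_config(107.5, threshold_px = 2,
                            channels = c("ch1", "ch2", "ch3"))
  expect_warning(
    res <- net_colocalisation(list(a, b, c3), cfg, n_repeats = 5, seed = 1,
                              roi = roi),
    "empty channel")
  pr <- res$pairs
  expect_true(all(is.na(pr$net_percent[pr$source == "ch2" | pr$target == "ch2"])))
  ok <- pr[pr$source == "ch1" & pr$target == "ch3", ]
  expect_false(is.na(ok$net_percent))
})

test_that("multi-channel flags equal per-pair brute force and conjunct correctly", {
  # deterministic triple fixture
  ref <- map_from_xy(c(10, 40, 70), c(10, 40, 70))
  ch2 <- map_from_xy(c(10.5, 70.5), c(10, 70), channel = "ch2")
  ch3 <- map_from_xy(10.2, 10.2, channel = "ch3")
  tab <- multi_colocalised(list(ref, ch2, ch3), 215)
  expect_equal(tab$in_ch2, c(TRUE, FALSE, TRUE))
  expect_equal(tab$in_ch3, c(TRUE, FALSE, FALSE))
  expect_equal(tab$all_channels, c(TRUE, FALSE, FALSE))

  # random instances against the double-loop oracle
  set.seed(31)
  for (rep in 1:10) {
    maps <- lapply(1:3, function(k) {
      random_map(sample(1:40, 1), channel = paste0("ch", k))
    })
    tab <- multi_colocalised(maps, 215)
    for (k in 2:3) {
      want <- brute_nn(cbind(maps[[1]]$x_px, maps[[1]]$y_px),
                       cbind(maps[[k]]$x_px, maps[[k]]$y_px))
      expect_identical(tab[[paste0("in_ch", k)]], want$dist * 107.5 < 215)
    }
  }
})

test_that("rigid motions applied to both maps leave percentages unchanged", {
  set.seed(37)
  a <- random_map(60, field = 512, margin = 100)
  b <- random_map(60, field = 512, margin = 100, channel = "ch2")
  p0 <- percent_colocalised(match_directed(a, b, 500))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(m) {
    xy <- cbind(m$x_px - 256, m$y_px - 256) %*% R
    map_from_xy(xy[, 1] + 260, xy[, 2] + 250,
                channel = attr(m, "channel"), field_px = c(512, 512))
  }
  expect_equal(percent_colocalised(match_directed(rot(a), rot(b), 500)), p0)
})

test_that("pooling across cells weights by particle counts", {
  mk <- function(raw, scr, n) {
    structure(list(
      pairs = data.frame(source = "ch1", target = "ch2", n_source = n,
                         n_target = n, raw_percent = raw,
                         scrambled_mean = scr, scrambled_sd = 0,
                         net_percent = raw - scr),
      threshold_nm = 215, threshold_px = 2, pixel_size_nm = 107.5,
      n_repeats = 1L, scramble_magnitude_px = 20, seed = 1L,
      roi_label = "cell"), class = "coloc_result")
  }
  pooled <- pool_coloc_results(list(mk(50, 2, 100), mk(80, 4, 300)))
  expect_equal(pooled$pairs$raw_percent, (50 * 100 + 80 * 300) / 400)
  expect_equal(pooled$pairs$scrambled_mean, (2 * 100 + 4 * 300) / 400)
  expect_equal(pooled$pairs$n_source, 400)
  averaged <- pool_coloc_results(list(mk(50, 2, 100), mk(80, 4, 300)),
                                 method = "mean")
  expect_equal(averaged$pairs$raw_percent, 65)
})
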