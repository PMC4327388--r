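# Independent oracles and fixture builders used across the suite.  These are
# deliberately naive reimplementations (double loops, direct formulas) kept
# separate from the package's vectorised code paths.

# Render Gaussian spots directly, independent of render_channel().
make_spot_image <- function(dims, centers, amp = 1000, sigma_px = 0.93,
                            bg = 0) {
  m <- matrix(bg, nrow = dims[2], ncol = dims[1])
  xs <- 0:(dims[1] - 1)
  ys <- 0:(dims[2] - 1)
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[i, 1])^2 / (2 * sigma_px^2))
    gy <- exp(-(ys - centers[i, 2])^2 / (2 * sigma_px^2))
    m <- m + amp * outer(gy, gx)
  }
  m
}

# Exhaustive O(ns * nt) nearest neighbour by explicit double loop.
brute_nn <- function(src, tgt) {
  ns <- nrow(src)
  idx <- rep(NA_integer_, ns)
  dst <- rep(Inf, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(nrow(tgt))) {
      d <- sqrt((src[i, 1] - tgt[j, 1])^2 + (src[i, 2] - tgt[j, 2])^2)
      if (d < dst[i]) {
        dst[i] <- d
        idx[i] <- j
      }
    }
  }
  list(index = idx, dist = dst)
}

# Build a particle_map straight from coordinates (no detection involved).
map_from_xy <- function(x, y, pixel_size_nm = 107.5, channel = "ch1",
                        field_px = NULL) {
  particle_map(data.frame(x_px = x, y_px = y),
               field_px = field_px, pixel_size_nm = pixel_size_nm,
               channel = channel)
}

# Uniform random map inside a margin of a square field.
random_map <- function(n, field = 512, margin = 0, pixel_size_nm = 107.5,
                      channel = "ch1") {
  map_from_xy(runif(n, margin, field - 1 - margin),
              runif(n, margin, field - 1 - margin),
              pixel_size_nm = pixel_size_nm, channel = channel,
              field_px = c(field, field))
}
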