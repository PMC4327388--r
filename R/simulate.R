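#' Point-spread-function and camera-noise model
#'
#' Punctae are sub-resolution emitters rendered as isotropic 2D Gaussians of
#' standard deviation `sigma_nm` on a constant background.  The noise model
#' is the standard camera model: Poisson noise on (signal + background),
#' optionally followed by additive Gaussian read noise.
#'
#' @param sigma_nm PSF standard deviation in nm (> 0).
#' @param background Mean background level in photons per pixel (>= 0).
#' @param noise `"poisson"` (default) or `"none"`.  With `"none"` the
#'   rendered image is the exact noiseless expectation (continuous values);
#'   with `"poisson"` the output is an integer-valued 16-bit grid.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise
#'   (photons; 0 disables it).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(sigma_nm = 100, background = 100,
                      noise = c("poisson", "none"), read_noise_sd = 0) {
  noise <- match.arg(noise)
  if (!is.numeric(sigma_nm) || sigma_nm <= 0) {
    stop("'sigma_nm' must be > 0", call. = FALSE)
  }
  if (!is.numeric(background) || background < 0) {
    stop("'background' must be >= 0", call. = FALSE)
  }
  if (read_noise_sd < 0) stop("'read_noise_sd' must be >= 0", call. = FALSE)
  structure(list(sigma_nm = sigma_nm, background = background,
                 noise = noise, read_noise_sd = read_noise_sd),
            class = "psf_model")
}

# Deterministic sub-seeds below 2^31, derived from one master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

place_csr <- function(n, existing, lo, hi, min_sep_px, max_attempts) {
  pts <- existing # matrix with columns x, y (may have 0 rows)
  placed <- 0L
  out <- matrix(NA_real_, n, 2)
  while (placed < n) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (nrow(pts) == 0L || min_sep_px <= 0 ||
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep_px^2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("infeasible packing: placed ", placed, " of ", n,
           " particles at min separation ", min_sep_px, " px", call. = FALSE)
    }
    placed <- placed + 1L
    out[placed, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

#' Generate a synthetic multi-channel scene with known ground truth
#'
#' Emulates a field of diffraction-limited punctae in two or more channels
#' with a controllable true colocalised fraction.  Channel 1 particles are
#' complete spatial randomness (uniform) inside the field margins, subject to
#' a minimum within-channel separation.  In every further channel, a fraction
#' `coloc_fraction` of its particles is paired to a random subset of channel-1
#' particles and placed at the partner position plus isotropic Gaussian jitter
#' of standard deviation `jitter_nm`; the remainder are independent CSR.
#'
#' @param n_per_channel Integer vector of particle counts, one per channel
#'   (length >= 1; colocalisation requires >= 2).
#' @param field_px Field dimensions `c(width, height)` in pixels.
#' @param coloc_fraction Fraction in `[0, 1]` of channel-1 particles given a
#'   partner in each later channel.  `round(coloc_fraction * n1)` pairs are
#'   recorded in the truth.
#' @param jitter_nm Pairing jitter: sd (nm) of the isotropic Gaussian
#'   displacement between partners; 0 (default) means perfect colocalisation.
#' @param min_separation_nm Minimum within-channel separation (nm) enforced
#'   by rejection sampling; the default, 400 nm, is four times the default
#'   PSF sigma and keeps scenes in the well-separated regime.
#' @param amplitude Peak amplitude in photons; scalar or one value per
#'   channel.
#' @param pixel_size_nm Pixel size in nm.
#' @param margin_px Particles are placed at least this far (pixels) from the
#'   field edge, so that PSF support stays inside the field.
#' @param channels Optional channel labels (default `ch1`, `ch2`, ...).
#' @param seed RNG seed; fixed seed gives a bit-reproducible scene.
#' @param max_attempts Rejection-sampling attempts per particle before an
#'   infeasible-packing error reports the achieved count.
#' @return An object of class `scene_truth`: list with `particles`
#'   (data.frame: channel, id, x_px, y_px, amplitude, pair_id), `pairs`
#'   (data.frame: pair_id, channel_a, channel_b, idx_a, idx_b, sep_px,
#'   sep_nm), `true_coloc_fraction` (named per directed channel pair),
#'   `field_px`, `pixel_size_nm`, `channels`, `seed` and the generation
#'   parameters.
#' @export
generate_scene <- function(n_per_channel = c(200L, 200L),
                           field_px = c(512L, 512L),
                           coloc_fraction = 0,
                           jitter_nm = 0,
                           min_separation_nm = 400,
                           amplitude = 1000,
                           pixel_size_nm = 107.5,
                           margin_px = 10,
                           channels = NULL,
                           seed = 1L,
                           max_attempts = 2000L) {
  if (any(n_per_channel < 0)) stop("'n_per_channel' must be >= 0", call. = FALSE)
  if (!is.numeric(coloc_fraction) || coloc_fraction < 0 || coloc_fraction > 1) {
    stop("'coloc_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (min_separation_nm < 0) stop("'min_separation_nm' must be >= 0", call. = FALSE)
  if (jitter_nm < 0) stop("'jitter_nm' must be >= 0", call. = FALSE)
  nch <- length(n_per_channel)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
  stopifnot(length(channels) == nch)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, nch)
  stopifnot(length(amplitude) == nch)
  W <- field_px[1]; H <- field_px[2]
  lo <- c(margin_px, margin_px)
  hi <- c(W - 1 - margin_px, H - 1 - margin_px)
  if (any(hi <= lo)) stop("field too small for the requested margin", call. = FALSE)
  min_sep_px <- min_separation_nm / pixel_size_nm
  jitter_px <- jitter_nm / pixel_size_nm

  set.seed(seed)
  xy <- vector("list", nch)
  pair_id_of <- vector("list", nch) # per channel, NA or pair id per particle
  pairs <- list()
  next_pair <- 1L

  xy[[1]] <- place_csr(n_per_channel[1], matrix(numeric(0), 0, 2),
                       lo, hi, min_sep_px, max_attempts)
  pair_id_of[[1]] <- rep(NA_integer_, n_per_channel[1])

  for (k in seq_len(nch)[-1]) {
    nk <- n_per_channel[k]
    n_pairs <- round(coloc_fraction * n_per_channel[1])
    n_pairs <- min(n_pairs, nk)
    idx_a <- if (n_pairs > 0) sort(sample.int(n_per_channel[1], n_pairs)) else integer(0)
    pts_k <- matrix(numeric(0), 0, 2)
    ids_k <- integer(0)
    for (j in seq_along(idx_a)) {
      base <- xy[[1]][idx_a[j], ]
      for (a in seq_len(max_attempts)) {
        cand <- base + stats::rnorm(2, 0, jitter_px)
        if (jitter_px == 0) cand <- base
        if (all(cand >= lo & cand <= hi)) break
        if (a == max_attempts) {
          stop("could not place paired particle inside the field margins",
               call. = FALSE)
        }
      }
      pts_k <- rbind(pts_k, cand)
      sep_px <- sqrt(sum((cand - base)^2))
      pairs[[length(pairs) + 1L]] <- data.frame(
        pair_id = next_pair, channel_a = channels[1], channel_b = channels[k],
        idx_a = idx_a[j], idx_b = j, sep_px = sep_px,
        sep_nm = sep_px * pixel_size_nm)
      ids_k <- c(ids_k, next_pair)
      if (k > 1) pair_id_of[[1]][idx_a[j]] <- next_pair
      next_pair <- next_pair + 1L
    }
    n_free <- nk - n_pairs
    if (n_free > 0) {
      free <- place_csr(n_free, pts_k, lo, hi, min_sep_px, max_attempts)
      pts_k <- rbind(pts_k, free)
      ids_k <- c(ids_k, rep(NA_integer_, n_free))
    }
    xy[[k]] <- pts_k
    pair_id_of[[k]] <- ids_k
  }

  particles <- do.call(rbind, lapply(seq_len(nch), function(k) {
    nk <- n_per_channel[k]
    data.frame(channel = rep(channels[k], nk),
               id = seq_len(nk),
               x_px = if (nk) xy[[k]][, 1] else numeric(0),
               y_px = if (nk) xy[[k]][, 2] else numeric(0),
               amplitude = rep(amplitude[k], nk),
               pair_id = pair_id_of[[k]])
  }))
  rownames(particles) <- NULL
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pair_id = integer(0), channel_a = character(0),
               channel_b = character(0), idx_a = integer(0),
               idx_b = integer(0), sep_px = numeric(0), sep_nm = numeric(0))
  rownames(pairs) <- NULL

  frac <- c()
  for (k in seq_len(nch)[-1]) {
    npk <- sum(pairs$channel_b == channels[k])
    frac[paste0(channels[1], "->", channels[k])] <-
      if (n_per_channel[1] > 0) npk / n_per_channel[1] else NA_real_
    frac[paste0(channels[k], "->", channels[1])] <-
      if (n_per_channel[k] > 0) npk / n_per_channel[k] else NA_real_
  }

  structure(
    list(particles = particles, pairs = pairs, true_coloc_fraction = frac,
         field_px = c(W, H), pixel_size_nm = pixel_size_nm,
         channels = channels, seed = seed,
         params = list(n_per_channel = n_per_channel,
                       coloc_fraction = coloc_fraction,
                       jitter_nm = jitter_nm,
                       min_separation_nm = min_separation_nm,
                       amplitude = amplitude, margin_px = margin_px,
                       max_attempts = max_attempts)),
    class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px, %g nm/px, seed %d\n",
              x$field_px[1], x$field_px[2], x$pixel_size_nm, x$seed))
  tab <- table(factor(x$particles$channel, levels = x$channels))
  for (ch in x$channels) cat(sprintf("  %s: %d particles\n", ch, tab[[ch]]))
  cat(sprintf("  %d colocalised pair(s)\n", nrow(x$pairs)))
  invisible(x)
}

#' Render one channel of a scene as a noisy image
#'
#' Sums an isotropic 2D Gaussian per particle (peak `amplitude`, sd
#' `psf$sigma_nm` converted to pixels), adds the background, and applies the
#' camera noise model.  Particles whose PSF support lies outside the field
#' are silently clipped.  With Poisson noise the result is an integer-valued
#' grid clipped to 16-bit range; with `noise = "none"` the exact continuous
#' expectation is returned.
#'
#' @param truth A [generate_scene()] result.
#' @param channel Channel label or index.
#' @param psf A [psf_model()].
#' @param seed RNG seed for the noise draw.
#' @return A [pixel_grid()].
#' @export
render_channel <- function(truth, channel, psf = psf_model(), seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"), inherits(psf, "psf_model"))
  if (is.numeric(channel)) channel <- truth$channels[channel]
  if (!channel %in% truth$channels) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  W <- truth$field_px[1]; H <- truth$field_px[2]
  sigma_px <- psf$sigma_nm / truth$pixel_size_nm
  img <- matrix(0, nrow = H, ncol = W)
  p <- truth$particles[truth$particles$channel == channel, ]
  r <- ceiling(5 * sigma_px) + 1L
  for (i in seq_len(nrow(p))) {
    x0 <- p$x_px[i]; y0 <- p$y_px[i]; a <- p$amplitude[i]
    cols <- max(0L, floor(x0) - r):min(W - 1L, ceiling(x0) + r)
    rows <- max(0L, floor(y0) - r):min(H - 1L, ceiling(y0) + r)
    if (x0 < -r || x0 > W - 1 + r || y0 < -r || y0 > H - 1 + r) next
    gx <- exp(-(cols - x0)^2 / (2 * sigma_px^2))
    gy <- exp(-(rows - y0)^2 / (2 * sigma_px^2))
    img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + a * outer(gy, gx)
  }
  expected <- img + psf$background
  if (psf$noise == "none" && psf$read_noise_sd == 0) {
    return(pixel_grid(expected, truth$pixel_size_nm, channel))
  }
  set.seed(seed)
  out <- if (psf$noise == "poisson") {
    matrix(stats::rpois(length(expected), lambda = expected), nrow = H)
  } else expected
  if (psf$read_noise_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, psf$read_noise_sd)
  }
  out <- round(pmin(pmax(out, 0), 65535))
  pixel_grid(out, truth$pixel_size_nm, channel)
}

#' Write a simulated scene to disk
#'
#' Writes one 16-bit TIFF per channel, a ground-truth CSV
#' (`channel, x_px, y_px, amplitude, pair_id`) and a JSON scene manifest
#' recording all parameters and derived per-channel noise seeds.  With a
#' fixed seed the truth CSV and TIFFs are byte-identical across runs.
#'
#' @param truth A [generate_scene()] result.
#' @param dir Output directory (created if missing).
#' @param psf A [psf_model()] used for every channel.
#' @param seed Master seed for the per-channel noise draws.
#' @return Invisibly, a named list of written paths (`images`, `truth`,
#'   `manifest`).
#' @export
write_scene <- function(truth, dir, psf = psf_model(), seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch_seeds <- derive_seeds(seed, length(truth$channels))
  img_paths <- character(0)
  for (k in seq_along(truth$channels)) {
    ch <- truth$channels[k]
    g <- render_channel(truth, ch, psf, seed = ch_seeds[k])
    path <- file.path(dir, paste0(ch, ".tif"))
    write_image_tiff(g, path)
    img_paths[ch] <- path
  }
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth$particles[, c("channel", "x_px", "y_px",
                                       "amplitude", "pair_id")],
                   truth_path, row.names = FALSE)
  manifest <- list(
    tool = "objcoloc",
    version = as.character(utils::packageVersion("objcoloc")),
    kind = "scene",
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    scene_seed = truth$seed,
    noise_seed = seed,
    channel_noise_seeds = as.list(stats::setNames(ch_seeds, truth$channels)),
    field_px = truth$field_px,
    pixel_size_nm = truth$pixel_size_nm,
    psf = unclass(psf),
    params = truth$params,
    files = as.list(c(img_paths, truth = truth_path)),
    md5 = as.list(tools::md5sum(c(unname(img_paths), truth_path))))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(images = img_paths, truth = truth_path,
                 manifest = manifest_path))
}
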