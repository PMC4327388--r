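#' @title Object-based colocalisation
#' @description Core matching stage: per source particle, the nearest target
#'   particle and a strict distance-threshold flag; scrambled-coordinate
#'   null; chance-corrected net percentages.
#' @name coloc
NULL

# Exact nearest neighbour from each src row to the tgt set, vectorised and
# chunked so the distance block never exceeds ~chunk x n_target doubles.
nn_search <- function(src, tgt, chunk = 1024L) {
  ns <- nrow(src); nt <- nrow(tgt)
  if (ns == 0L) return(list(index = integer(0), dist_px = numeric(0)))
  if (nt == 0L) {
    return(list(index = rep(NA_integer_, ns), dist_px = rep(Inf, ns)))
  }
  t2 <- tgt[, 1]^2 + tgt[, 2]^2
  idx <- integer(ns); dpx <- numeric(ns)
  for (s in seq(1L, ns, by = chunk)) {
    e <- min(s + chunk - 1L, ns)
    sc <- src[s:e, , drop = FALSE]
    d2 <- outer(sc[, 1]^2 + sc[, 2]^2, t2, "+") - 2 * tcrossprod(sc, tgt)
    d2 <- pmax(d2, 0)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    # recompute the winning distance directly: the expansion above loses
    # precision by cancellation (a self-match must come out exactly 0)
    dpx[s:e] <- sqrt((sc[, 1] - tgt[j, 1])^2 + (sc[, 2] - tgt[j, 2])^2)
  }
  list(index = idx, dist_px = dpx)
}

#' Match one channel's particles against another
#'
#' Each source particle is considered in turn; its nearest target particle
#' (Euclidean distance, in nm) is identified and the particle is flagged
#' colocalised when that distance is strictly less than `threshold_nm`.
#' There is no one-to-one constraint: several source particles may share a
#' target.  With an empty target set every flag is `FALSE` and distances are
#' reported as `Inf`.
#'
#' @param source,target [particle_map()]s sharing the same pixel size.
#' @param threshold_nm Distance threshold in nm (> 0).
#' @return An object of class `match_result`: a data frame with one row per
#'   source particle (`source_index`, `nn_index`, `nn_dist_nm`,
#'   `colocalised`) plus attributes `source_channel`, `target_channel`,
#'   `threshold_nm`, `n_source`, `n_target`.
#' @export
match_directed <- function(source, target, threshold_nm) {
  stopifnot(inherits(source, "particle_map"), inherits(target, "particle_map"))
  if (!isTRUE(all.equal(attr(source, "pixel_size_nm"),
                        attr(target, "pixel_size_nm")))) {
    stop("source and target maps have different pixel sizes", call. = FALSE)
  }
  if (!is.numeric(threshold_nm) || threshold_nm <= 0) {
    stop("'threshold_nm' must be > 0", call. = FALSE)
  }
  ps <- attr(source, "pixel_size_nm")
  nn <- nn_search(cbind(source$x_px, source$y_px),
                  cbind(target$x_px, target$y_px))
  d_nm <- nn$dist_px * ps
  structure(
    data.frame(source_index = seq_len(nrow(source)),
               nn_index = nn$index,
               nn_dist_nm = d_nm,
               colocalised = d_nm < threshold_nm),
    source_channel = attr(source, "channel"),
    target_channel = attr(target, "channel"),
    threshold_nm = threshold_nm,
    n_source = nrow(source), n_target = nrow(target),
    class = c("match_result", "data.frame"))
}

#' Percentage of source particles colocalised
#'
#' @param match A [match_directed()] result with at least one source
#'   particle.
#' @return `100 * flagged / n_source`.
#' @export
percent_colocalised <- function(match) {
  stopifnot(inherits(match, "match_result"))
  n <- attr(match, "n_source")
  if (n == 0L) {
    stop("percentage undefined: the source map has no particles",
         call. = FALSE)
  }
  100 * sum(match$colocalised) / n
}

#' Scramble particle coordinates
#'
#' The chance control: each particle is displaced by independent uniform
#' offsets in `[-magnitude_px, +magnitude_px]` on x and y, wrapped
#' toroidally inside the analysis bounds so the global density is preserved.
#' Brightness values and the particle count are unchanged.
#'
#' @param map A [particle_map()].
#' @param magnitude_px Half-width of the uniform offset (pixels, > 0).
#' @param seed RNG seed; fixed seed gives a bit-reproducible result.
#' @param bounds Analysis bounds `c(xmin, xmax, ymin, ymax)`.  Defaults to
#'   the ROI bounding box if the map was ROI-filtered, else the image
#'   extent, else the map's own bounding box.
#' @return A scrambled [particle_map()].
#' @export
scramble_map <- function(map, magnitude_px = 20, seed = 1L, bounds = NULL) {
  stopifnot(inherits(map, "particle_map"))
  if (magnitude_px <= 0) stop("'magnitude_px' must be > 0", call. = FALSE)
  if (is.null(bounds)) {
    bb <- attr(map, "roi_bbox")
    fp <- attr(map, "field_px")
    bounds <- if (!is.null(bb)) unname(bb[c("xmin", "xmax", "ymin", "ymax")])
      else if (!is.null(fp)) c(0, fp[1] - 1, 0, fp[2] - 1)
      else c(min(map$x_px), max(map$x_px), min(map$y_px), max(map$y_px))
  }
  wrap <- function(v, lo, hi, off) {
    span <- hi - lo
    if (span <= 0) return(v)
    lo + (v - lo + off) %% span
  }
  n <- nrow(map)
  set.seed(seed)
  ox <- stats::runif(n, -magnitude_px, magnitude_px)
  oy <- stats::runif(n, -magnitude_px, magnitude_px)
  df <- as.data.frame(map)
  df$x_px <- wrap(df$x_px, bounds[1], bounds[2], ox)
  df$y_px <- wrap(df$y_px, bounds[3], bounds[4], oy)
  out <- particle_map(df, field_px = attr(map, "field_px"),
                      pixel_size_nm = attr(map, "pixel_size_nm"),
                      channel = attr(map, "channel"),
                      params = attr(map, "params"))
  attr(out, "roi_bbox") <- attr(map, "roi_bbox")
  attr(out, "roi_label") <- attr(map, "roi_label")
  out
}

#' Net (chance-corrected) colocalisation between channels
#'
#' For every ordered channel pair: the raw colocalised percentage on the
#' observed maps, the mean (and sd) percentage over `n_repeats` independent
#' scrambles of the target map, and the net percentage
#' `raw - mean(scrambled)`.  Negative net values are reported as-is.  If an
#' ROI is given the maps are first restricted to it (and the scramble wraps
#' within the ROI bounding box).  A channel left empty after ROI filtering
#' makes its pairs undefined (NA) with a warning; other pairs are
#' unaffected.
#'
#' @param maps List of [particle_map()]s (>= 2), named by channel or using
#'   each map's channel attribute.
#' @param cfg An [acquisition_config()]; supplies the threshold.
#' @param n_repeats Number of scramble repeats (default 100; a single run,
#'   `n_repeats = 1`, reproduces the one-shot scramble control).
#' @param scramble_magnitude_px Offset half-width for [scramble_map()].
#' @param seed Master RNG seed; per-pair, per-repeat sub-seeds are derived
#'   from it and recorded in the result.
#' @param roi Optional [roi_polygon()].
#' @return An object of class `coloc_result`: list with a `pairs` data frame
#'   (`source`, `target`, `n_source`, `n_target`, `raw_percent`,
#'   `scrambled_mean`, `scrambled_sd`, `net_percent`) plus the threshold,
#'   scramble parameters, seed and ROI label.
#' @export
net_colocalisation <- function(maps, cfg, n_repeats = 100L,
                               scramble_magnitude_px = 20, seed = 1L,
                               roi = NULL) {
  stopifnot(is.list(maps), length(maps) >= 2,
            inherits(cfg, "acquisition_config"))
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- vapply(maps, function(m) attr(m, "channel"), "")
  }
  if (anyDuplicated(names(maps))) {
    stop("channel labels must be distinct", call. = FALSE)
  }
  if (!is.null(roi)) maps <- lapply(maps, filter_roi, roi = roi)
  tau <- threshold_nm(cfg)
  nch <- length(maps)
  combos <- expand.grid(tgt = seq_len(nch), src = seq_len(nch))
  combos <- combos[combos$src != combos$tgt, c("src", "tgt")]
  combos <- combos[order(combos$src, combos$tgt), ]
  seeds <- matrix(derive_seeds(seed, nrow(combos) * n_repeats),
                  nrow = n_repeats)
  rows <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    i <- combos$src[r]; j <- combos$tgt[r]
    ns <- nrow(maps[[i]]); nt <- nrow(maps[[j]])
    if (ns == 0L || nt == 0L) {
      warning(sprintf("pair %s->%s undefined: empty channel after filtering",
                      names(maps)[i], names(maps)[j]), call. = FALSE)
      rows[[r]] <- data.frame(source = names(maps)[i], target = names(maps)[j],
                              n_source = ns, n_target = nt,
                              raw_percent = NA_real_, scrambled_mean = NA_real_,
                              scrambled_sd = NA_real_, net_percent = NA_real_)
      next
    }
    raw <- percent_colocalised(match_directed(maps[[i]], maps[[j]], tau))
    scr <- vapply(seq_len(n_repeats), function(q) {
      tgt_s <- scramble_map(maps[[j]], magnitude_px = scramble_magnitude_px,
                            seed = seeds[q, r])
      percent_colocalised(match_directed(maps[[i]], tgt_s, tau))
    }, numeric(1))
    rows[[r]] <- data.frame(source = names(maps)[i], target = names(maps)[j],
                            n_source = ns, n_target = nt,
                            raw_percent = raw,
                            scrambled_mean = mean(scr),
                            scrambled_sd = if (n_repeats > 1) stats::sd(scr) else NA_real_,
                            net_percent = raw - mean(scr))
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs,
         threshold_nm = tau, threshold_px = cfg$threshold_px,
         pixel_size_nm = cfg$pixel_size_nm,
         n_repeats = as.integer(n_repeats),
         scramble_magnitude_px = scramble_magnitude_px,
         seed = seed,
         roi_label = if (is.null(roi)) NA_character_ else roi$label),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Net colocalisation (threshold %g nm, %d scramble repeat(s), seed %s)\n",
              x$threshold_nm, x$n_repeats, format(x$seed)))
  if (!is.na(x$roi_label)) cat(sprintf("  ROI: %s\n", x$roi_label))
  df <- x$pairs
  df$raw_percent <- round(df$raw_percent, 2)
  df$scrambled_mean <- round(df$scrambled_mean, 2)
  df$scrambled_sd <- round(df$scrambled_sd, 2)
  df$net_percent <- round(df$net_percent, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Pool colocalisation results across cells
#'
#' Combines per-ROI (per-cell) results for the same channel pairs.  The
#' default pools by total particle counts (each cell's percentage weighted
#' by its `n_source`, equivalent to merging all particles before dividing);
#' `method = "mean"` instead averages the per-cell percentages unweighted.
#'
#' @param results List of [net_colocalisation()] results with identical pair
#'   structure.
#' @param method `"pooled"` (count-weighted, default) or `"mean"`.
#' @return A `coloc_result` whose `pairs` table holds the combined values
#'   (scrambled sd is dropped: it is a within-cell quantity).
#' @export
pool_coloc_results <- function(results, method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "coloc_result")))
  key <- function(res) paste(res$pairs$source, res$pairs$target)
  k0 <- key(results[[1]])
  if (!all(vapply(results, function(r) identical(key(r), k0), TRUE))) {
    stop("results have different channel-pair structure", call. = FALSE)
  }
  pairs <- results[[1]]$pairs
  for (r in seq_len(nrow(pairs))) {
    raws <- vapply(results, function(x) x$pairs$raw_percent[r], numeric(1))
    scrs <- vapply(results, function(x) x$pairs$scrambled_mean[r], numeric(1))
    ns <- vapply(results, function(x) x$pairs$n_source[r], numeric(1))
    nt <- vapply(results, function(x) x$pairs$n_target[r], numeric(1))
    ok <- !is.na(raws) & ns > 0
    w <- if (method == "pooled") ns[ok] / sum(ns[ok]) else
      rep(1 / sum(ok), sum(ok))
    pairs$raw_percent[r] <- sum(w * raws[ok])
    pairs$scrambled_mean[r] <- sum(w * scrs[ok])
    pairs$scrambled_sd[r] <- NA_real_
    pairs$net_percent[r] <- pairs$raw_percent[r] - pairs$scrambled_mean[r]
    pairs$n_source[r] <- sum(ns[ok])
    pairs$n_target[r] <- sum(nt[ok])
  }
  out <- results[[1]]
  out$pairs <- pairs
  out$roi_label <- paste0("pooled[", method, "]:",
                          paste(vapply(results, function(x) x$roi_label, ""),
                                collapse = "+"))
  out
}

#' Multi-channel colocalisation flags
#'
#' For three or more channels: every particle of the reference channel is
#' scored, per other channel, for whether a particle of that channel lies
#' within the threshold (strict nearest-neighbour test, as in
#' [match_directed()]).  The conjunction column flags particles colocalised
#' with all other channels simultaneously (triple-positive scoring).
#'
#' @param maps List of >= 3 [particle_map()]s.
#' @param threshold_nm Distance threshold in nm.
#' @param reference Index or name of the reference channel (default first).
#' @return Data frame: `source_index`, one logical `in_<channel>` column per
#'   other channel, and `all_channels`.
#' @export
multi_colocalised <- function(maps, threshold_nm, reference = 1L) {
  stopifnot(is.list(maps), length(maps) >= 3)
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- vapply(maps, function(m) attr(m, "channel"), "")
  }
  if (is.character(reference)) reference <- match(reference, names(maps))
  ref <- maps[[reference]]
  others <- setdiff(seq_along(maps), reference)
  out <- data.frame(source_index = seq_len(nrow(ref)))
  for (j in others) {
    m <- match_directed(ref, maps[[j]], threshold_nm)
    out[[paste0("in_", names(maps)[j])]] <- m$colocalised
  }
  flags <- out[, -1, drop = FALSE]
  out$all_channels <- if (nrow(out)) Reduce(`&`, flags) else logical(0)
  out
}
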