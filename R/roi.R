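#' Region-of-interest polygon
#'
#' A closed polygon in pixel coordinates restricting analysis to a cell or
#' subcellular region (e.g. a cell outline or a peripheral zone).  The
#' vertex list is stored open (last vertex != first); closure is implicit.
#' Degenerate (< 3 distinct vertices, zero area) and self-intersecting
#' polygons are rejected.
#'
#' @param x,y Numeric vertex coordinates (>= 3 vertices).
#' @param label Region label.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y, label = "roi") {
  stopifnot(length(x) == length(y))
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (length(x) < 3 || anyNA(x) || anyNA(y) ||
      any(!is.finite(x)) || any(!is.finite(y))) {
    stop("degenerate polygon: need >= 3 finite vertices", call. = FALSE)
  }
  if (polygon_self_intersects(x, y)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  # shoelace area; zero means collinear/degenerate (a bow-tie is caught
  # above, before its cancelling signed area can mask it)
  n <- length(x)
  j <- c(2:n, 1)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  if (area <= 0) stop("degenerate polygon: zero area", call. = FALSE)
  structure(list(x = x, y = y, label = label), class = "roi_polygon")
}

# Any two non-adjacent edges properly or improperly crossing?
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  seg <- cbind(x, y, x[j], y[j])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (they share a vertex by construction)
      if (b == a + 1 || (a == 1 && b == n)) next
      d1 <- cross(seg[a, 1], seg[a, 2], seg[a, 3], seg[a, 4], seg[b, 1], seg[b, 2])
      d2 <- cross(seg[a, 1], seg[a, 2], seg[a, 3], seg[a, 4], seg[b, 3], seg[b, 4])
      d3 <- cross(seg[b, 1], seg[b, 2], seg[b, 3], seg[b, 4], seg[a, 1], seg[a, 2])
      d4 <- cross(seg[b, 1], seg[b, 2], seg[b, 3], seg[b, 4], seg[a, 3], seg[a, 4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("ROI '%s': %d vertices, bbox x [%g, %g], y [%g, %g]\n",
              x$label, length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Test points against a polygon (even-odd rule, strict interior)
#'
#' Even-odd (ray-casting) point-in-polygon test.  Points exactly on a
#' polygon edge or vertex are classified as outside: the filter keeps only
#' the strict interior.
#'
#' @param px,py Numeric point coordinates.
#' @param roi A [roi_polygon()].
#' @return Logical vector: `TRUE` for points strictly inside.
#' @export
point_in_polygon <- function(px, py, roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  x <- roi$x; y <- roi$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  out <- logical(length(px))
  tol <- 1e-12 * max(1, max(abs(x)), max(abs(y)))
  for (k in seq_along(px)) {
    X <- px[k]; Y <- py[k]
    on_edge <- FALSE
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- x[j[i]]; y1 <- y[j[i]]; x2 <- x[i]; y2 <- y[i]
      # boundary check: collinear and within the segment's bounding box
      cr <- (x2 - x1) * (Y - y1) - (y2 - y1) * (X - x1)
      if (abs(cr) <= tol &&
          X >= min(x1, x2) - tol && X <= max(x1, x2) + tol &&
          Y >= min(y1, y2) - tol && Y <= max(y1, y2) + tol) {
        on_edge <- TRUE
        break
      }
      if ((y1 > Y) != (y2 > Y)) {
        xi <- (x2 - x1) * (Y - y1) / (y2 - y1) + x1
        if (X < xi) inside <- !inside
      }
    }
    out[k] <- inside && !on_edge
  }
  out
}

#' Restrict a particle map to a region of interest
#'
#' Keeps particles strictly inside the polygon (even-odd rule; boundary
#' points are excluded).  The ROI bounding box is attached to the result and
#' later used as the scramble bounds.
#'
#' @param map A [particle_map()].
#' @param roi A [roi_polygon()].
#' @return A filtered [particle_map()].
#' @export
filter_roi <- function(map, roi) {
  stopifnot(inherits(map, "particle_map"), inherits(roi, "roi_polygon"))
  keep <- point_in_polygon(map$x_px, map$y_px, roi)
  out <- particle_map(as.data.frame(map)[keep, , drop = FALSE],
                      field_px = attr(map, "field_px"),
                      pixel_size_nm = attr(map, "pixel_size_nm"),
                      channel = attr(map, "channel"),
                      params = attr(map, "params"))
  attr(out, "roi_label") <- roi$label
  attr(out, "roi_bbox") <- c(xmin = min(roi$x), xmax = max(roi$x),
                             ymin = min(roi$y), ymax = max(roi$y))
  out
}

#' Read an ROI polygon from CSV
#'
#' Expects one vertex per line with columns `x_px, y_px` (header required).
#'
#' @param path CSV path.
#' @param label Region label; defaults to the file name.
#' @return A [roi_polygon()].
#' @export
read_roi_csv <- function(path, label = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_px", "y_px") %in% names(df)))
  roi_polygon(df$x_px, df$y_px, label = label)
}

#' @rdname read_roi_csv
#' @param roi A [roi_polygon()] to write.
#' @export
write_roi_csv <- function(roi, path) {
  utils::write.csv(data.frame(x_px = roi$x, y_px = roi$y), path,
                   row.names = FALSE)
  invisible(path)
}
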