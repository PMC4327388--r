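#' Single-channel intensity raster
#'
#' A `pixel_grid` is one channel's 2D intensity image together with its
#' physical pixel size.  Intensities must be finite and non-negative.  The
#' underlying matrix is indexed `[row, col]`; user-facing coordinates are
#' 0-based with `x = col - 1`, `y = row - 1` and the origin at the centre of
#' the top-left pixel.
#'
#' @param data Numeric matrix of non-negative intensities.
#' @param pixel_size_nm Pixel size in nm (> 0).
#' @param channel Channel label.
#' @return An object of class `pixel_grid`.
#' @export
pixel_grid <- function(data, pixel_size_nm, channel = "ch1") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    stop("image intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("'pixel_size_nm' must be > 0", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size_nm = as.numeric(pixel_size_nm),
         channel = as.character(channel)),
    class = "pixel_grid")
}

#' @export
dim.pixel_grid <- function(x) dim(x$data)

#' @export
print.pixel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Pixel grid '%s': %d x %d px (%g nm/px), range [%g, %g]\n",
              x$channel, d[2], d[1], x$pixel_size_nm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read one channel of a TIFF image
#'
#' Accepts single-plane TIFFs or multi-page stacks where each page is one
#' channel.  Interleaved RGB(A) images are refused: per-channel planes are
#' the only unambiguous convention for quantitative data.  Pixel values are
#' read as stored (no rescaling).
#'
#' @param path Path to a TIFF file (8- or 16-bit greyscale).
#' @param channel 1-based page index to read.
#' @param pixel_size_nm Pixel size in nm (TIFF metadata is not parsed; the
#'   pixel size is always explicit).
#' @param label Channel label; defaults to `"ch<channel>"`.
#' @return A [pixel_grid()].
#' @export
read_image_tiff <- function(path, channel = 1L, pixel_size_nm,
                            label = paste0("ch", channel)) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (channel < 1L || channel > length(planes)) {
    stop("channel ", channel, " requested but file has ", length(planes),
         " plane(s)", call. = FALSE)
  }
  m <- planes[[channel]]
  if (length(dim(m)) == 3L) {
    stop("interleaved multi-sample (RGB/RGBA) TIFF refused; supply one ",
         "greyscale plane per channel", call. = FALSE)
  }
  pixel_grid(m * 1.0, pixel_size_nm = pixel_size_nm, channel = label)
}

#' Write a pixel grid to a 16-bit TIFF
#'
#' Values are stored as integers; the round-trip through
#' [read_image_tiff()] is exact for integer grids in `[0, 65535]`.
#'
#' @param grid A [pixel_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  m <- round(grid$data)
  if (any(m > 65535)) {
    warning("intensities above 65535 clipped on write")
    m <- pmin(m, 65535)
  }
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
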