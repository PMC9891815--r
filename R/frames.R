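#' Frames and frame pairs
#'
#' A *frame* is a single grayscale image stored as a plain numeric matrix
#' (rows = image height, columns = width, values in detector counts or any
#' affinely related unit). All statistics in this package are invariant to
#' affine intensity maps, so no internal renormalisation is performed.
#'
#' @name frames
NULL

#' Validate a frame
#'
#' Checks that `x` is a finite numeric matrix with at least 2x2 pixels
#' (the smallest frame on which sample statistics and block reduction are
#' defined).
#'
#' @param x object to check.
#' @param min_dim minimum number of rows and columns (default 2).
#' @return `x`, invisibly, if valid; otherwise an error is signalled.
#' @export
check_frame <- function(x, min_dim = 2L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a frame must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop(sprintf("frame must be at least %dx%d pixels, got %dx%d",
                 min_dim, min_dim, nrow(x), ncol(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("frame contains non-finite pixel values", call. = FALSE)
  }
  invisible(x)
}

check_pair <- function(t1, t2) {
  check_frame(t1)
  check_frame(t2)
  if (!identical(dim(t1), dim(t2))) {
    stop(sprintf("frame pair dimensions differ: %dx%d vs %dx%d",
                 nrow(t1), ncol(t1), nrow(t2), ncol(t2)), call. = FALSE)
  }
  invisible(NULL)
}

#' Read a grayscale frame from a TIFF or PNG file
#'
#' RGB(A) inputs are converted to grayscale with the Rec. 709 luminance rule
#' (0.2126 R + 0.7152 G + 0.0722 B); the conversion is reported via a message
#' so runs remain auditable. Multi-page TIFFs are read with [read_frame_stack()].
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @return numeric matrix (rows = height).
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  as_gray(img)
}

as_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    message("converting RGB input to grayscale (Rec. 709 luminance)")
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  storage.mode(img) <- "double"
  img
}

#' Read a multi-page TIFF stack as a list of frames
#'
#' @param path multi-page TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_frame_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, as_gray)
}

#' Write a list of frames as a multi-page 16-bit TIFF
#'
#' Pixel values are affinely rescaled to \[0, 1\] over the whole stack before
#' writing (a single global map, so relative contrast between frames is
#' preserved). Because the SNR estimator is invariant to affine intensity
#' maps, the rescaling does not affect any downstream metric.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  rng <- range(unlist(lapply(frames, range)))
  span <- diff(rng)
  if (span <= 0) span <- 1
  scaled <- lapply(frames, function(f) (f - rng[1]) / span)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}
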