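#' @title Image containers
#' @name images
#' @description
#' Two lightweight containers carry all pixel data in fusegan:
#' \describe{
#'   \item{`gray_image`}{an H x W numeric matrix of intensities in \[0, 1\].
#'     MRI, CT, the luminance (Y) channel and fused outputs all live here.}
#'   \item{`color_image`}{an H x W x 3 numeric array in \[0, 1\] with a
#'     `space` attribute, either `"RGB"` or `"YCbCr"`. PET/SPECT pseudo-color
#'     inputs and recombined fused outputs live here.}
#' }
#' Both are plain base-R structures with a class attribute, so every numeric
#' operation in the package works on them directly.
NULL

#' Create a grayscale image
#'
#' @param data numeric matrix, H x W, values in \[0, 1\].
#' @return a `gray_image` (numeric matrix with class attribute).
#' @export
gray_image <- function(data) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("gray_image: `data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("gray_image: empty matrix", call. = FALSE)
  if (!all(is.finite(data)))
    stop("gray_image: non-finite pixel values", call. = FALSE)
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9)
    stop("gray_image: intensities must lie in [0, 1]", call. = FALSE)
  data <- pmin(pmax(data, 0), 1)
  structure(data, class = c("gray_image", class(matrix())))
}

#' Create a color image
#'
#' @param data numeric array, H x W x 3, values in \[0, 1\].
#' @param space `"RGB"` or `"YCbCr"`. Chroma planes of YCbCr images are stored
#'   with a +0.5 offset so all planes live in \[0, 1\].
#' @return a `color_image`.
#' @export
color_image <- function(data, space = c("RGB", "YCbCr")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("color_image: `data` must be an H x W x 3 array", call. = FALSE)
  if (dim(data)[1] < 8L || dim(data)[2] < 8L)
    stop("color_image: images must be at least 8 x 8", call. = FALSE)
  if (!all(is.finite(data)))
    stop("color_image: non-finite pixel values", call. = FALSE)
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9)
    stop("color_image: values must lie in [0, 1]", call. = FALSE)
  data <- pmin(pmax(data, 0), 1)
  structure(data, space = space, class = "color_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image %d x %d x 3 (%s)>\n", d[1], d[2], attr(x, "space")))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image") ||
  (is.matrix(x) && is.numeric(x))

same_size <- function(a, b) {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  identical(as.integer(da), as.integer(db))
}

stop_size_mismatch <- function(what) {
  stop(sprintf("%s: inputs must share the same height and width", what),
       call. = FALSE)
}

#' Load an image from PNG or TIFF
#'
#' Intensities are normalized to \[0, 1\] on load (the png and tiff readers
#' already do this for 8- and 16-bit data). Grayscale files return a
#' [gray_image()], 3-channel files a [color_image()] in RGB. An alpha channel,
#' if present, is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return `gray_image` or `color_image`, with a `bit_depth` attribute
#'   recording the source depth for round-trip saving.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("load_image: file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth %||% 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path)
    depth <- 8L
  } else {
    stop(sprintf("load_image: unsupported format '%s' (PNG/TIFF only)", ext),
         call. = FALSE)
  }
  attr(raw, "info") <- NULL
  if (length(dim(raw)) == 2L) {
    out <- gray_image(pmin(pmax(raw, 0), 1))
  } else if (dim(raw)[3] >= 3L) {
    out <- color_image(pmin(pmax(raw[, , 1:3, drop = FALSE], 0), 1), "RGB")
  } else if (dim(raw)[3] == 1L) {
    out <- gray_image(pmin(pmax(raw[, , 1], 0), 1))
  } else {
    stop("load_image: unsupported channel count", call. = FALSE)
  }
  attr(out, "bit_depth") <- as.integer(depth)
  out
}

#' Save an image as 8-bit PNG
#'
#' @param img `gray_image` or `color_image` (RGB).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  if (inherits(img, "color_image") &&
      !identical(attr(img, "space"), "RGB"))
    stop("save_image: convert YCbCr images to RGB before saving",
         call. = FALSE)
  x <- unclass(img)
  attributes(x) <- list(dim = dim(x))
  png::writePNG(pmin(pmax(x, 0), 1), target = path)
  invisible(path)
}

#' Save a gradient map as 32-bit float TIFF
#'
#' Gradient maps are signed and unbounded while TIFF storage expects
#' \[0, 1\], so the map is min-max normalized before writing; the dump
#' exists for visual inspection. The original range is returned so exact
#' values can be recovered as `lo + (hi - lo) * pixel`.
#'
#' @param gmap a `gradient_map` (or plain numeric matrix).
#' @param path output path ending in .tif/.tiff.
#' @return invisibly, `c(lo = min, hi = max)` of the original map.
#' @export
save_gradient_tiff <- function(gmap, path) {
  x <- unclass(gmap)
  attributes(x) <- list(dim = dim(x))
  lo <- min(x); hi <- max(x)
  xn <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
  tiff::writeTIFF(xn, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(c(lo = lo, hi = hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
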