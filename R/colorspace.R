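#' @title YCbCr color pipeline
#' @name colorspace
#' @description
#' PET and SPECT images carry functional information as pseudo-color. To fuse
#' them with a grayscale MRI without disturbing that color, the RGB image is
#' decomposed into luminance (Y) and chroma (Cb, Cr); only Y takes part in
#' fusion, and the fused Y is recombined with the untouched chroma planes.
#' Single-channel CT inputs bypass this module and are fused directly.
#'
#' The transform is full-range BT.601: Y = 0.299 R + 0.587 G + 0.114 B, with
#' chroma zero-centered and offset by +0.5 so every plane lives in \[0, 1\].
NULL

# full-range BT.601 forward matrix (rows: Y, Cb, Cr)
.ycbcr_fwd <- matrix(c(
   0.299,     0.587,     0.114,
  -0.168736, -0.331264,  0.5,
   0.5,      -0.418688, -0.081312
), nrow = 3, byrow = TRUE)

.ycbcr_inv <- solve(.ycbcr_fwd)

#' Decompose an RGB image into YCbCr planes
#'
#' @param img a [color_image()] in RGB space.
#' @return a list of class `ycbcr_planes` with `gray_image` elements
#'   `y`, `cb`, `cr` (chroma stored with +0.5 offset).
#' @export
rgb_to_ycbcr <- function(img) {
  if (!inherits(img, "color_image"))
    stop("rgb_to_ycbcr: input must be a color_image", call. = FALSE)
  if (!identical(attr(img, "space"), "RGB"))
    stop("rgb_to_ycbcr: input must be in RGB space", call. = FALSE)
  d <- dim(img)
  px <- matrix(unclass(img), ncol = 3L)      # (H*W) x 3, columns R,G,B
  yc <- px %*% t(.ycbcr_fwd)
  yc[, 2:3] <- yc[, 2:3] + 0.5
  mk <- function(k) gray_image(pmin(pmax(matrix(yc[, k], d[1], d[2]), 0), 1))
  structure(list(y = mk(1), cb = mk(2), cr = mk(3)), class = "ycbcr_planes")
}

#' Recompose YCbCr planes into an RGB image
#'
#' Exact inverse of [rgb_to_ycbcr()] up to clipping: out-of-gamut values after
#' the inverse transform are clipped to \[0, 1\], never rescaled, so in-gamut
#' pixels survive bit-for-bit.
#'
#' @param planes a `ycbcr_planes` list, or the `y` plane if `cb`/`cr` given.
#' @param cb,cr optional chroma planes overriding those in `planes`.
#' @return a [color_image()] in RGB space.
#' @export
ycbcr_to_rgb <- function(planes, cb = NULL, cr = NULL) {
  if (inherits(planes, "ycbcr_planes")) {
    y <- planes$y; cb <- cb %||% planes$cb; cr <- cr %||% planes$cr
  } else {
    y <- planes
    if (is.null(cb) || is.null(cr))
      stop("ycbcr_to_rgb: need cb and cr when not given ycbcr_planes",
           call. = FALSE)
  }
  if (!same_size(y, cb) || !same_size(y, cr))
    stop_size_mismatch("ycbcr_to_rgb")
  d <- dim(y)
  yc <- cbind(as.vector(unclass(y)),
              as.vector(unclass(cb)) - 0.5,
              as.vector(unclass(cr)) - 0.5)
  px <- yc %*% t(.ycbcr_inv)
  px <- pmin(pmax(px, 0), 1)
  color_image(array(px, c(d[1], d[2], 3L)), "RGB")
}

#' Recombine a fused luminance plane with source chroma
#'
#' The fusion core outputs a single fused Y plane; this puts the original
#' Cb/Cr planes back so the functional color is preserved exactly.
#'
#' @param fused_y `gray_image`, the fused luminance.
#' @param source `ycbcr_planes` of the original functional image.
#' @return a [color_image()] in RGB space.
#' @export
recombine <- function(fused_y, source) {
  if (!inherits(source, "ycbcr_planes"))
    stop("recombine: `source` must be ycbcr_planes", call. = FALSE)
  if (!same_size(fused_y, source$y))
    stop_size_mismatch("recombine")
  ycbcr_to_rgb(fused_y, cb = source$cb, cr = source$cr)
}
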