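#' @title Laplacian gradient maps
#' @name gradients
#' @description
#' The adversarial mechanism operates on gradient maps, not images. The
#' "false data" is the absolute Laplacian of the fused image; the "real data"
#' is the joint gradient map, the pixelwise maximum of the absolute Laplacians
#' of the two inputs. The discriminator sees these maps unnormalized.
#'
#' The Laplace operator is the 3x3 4-neighbor kernel by default (an
#' 8-neighbor variant is available); borders use edge-mirroring padding so
#' the image frame is not itself a spurious edge — important when functional
#' inputs have large exactly-black backgrounds.
NULL

laplacian_kernel <- function(neighbors = 4L) {
  if (neighbors == 4L)
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  else if (neighbors == 8L)
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
  else stop("laplacian_kernel: neighbors must be 4 or 8", call. = FALSE)
}

# Edge-mirroring pad by p pixels on each side.
pad_mirror <- function(x, p = 1L) {
  H <- nrow(x); W <- ncol(x)
  ri <- c(rev(seq_len(p)), seq_len(H), H + 1L - seq_len(p))
  ci <- c(rev(seq_len(p)), seq_len(W), W + 1L - seq_len(p))
  x[ri, ci, drop = FALSE]
}

# Same-size 2-D convolution of a matrix with a (2p+1)^2 kernel under
# edge-mirroring padding. Implemented as a sum of shifted copies; for the
# small fixed kernels used here this is faster than FFT and exact.
conv2_same <- function(x, kern) {
  k <- nrow(kern)
  stopifnot(k == ncol(kern), k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  if (H < k || W < k)
    stop("conv2_same: image smaller than kernel", call. = FALSE)
  xp <- pad_mirror(x, p)
  out <- matrix(0, H, W)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    w <- kern[a, b]
    if (w != 0)
      out <- out + w * xp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W)]
  }
  out
}

new_gradient_map <- function(data, source) {
  structure(data, source = source,
            class = c("gradient_map", class(matrix())))
}

#' Laplacian of an image
#'
#' Signed Laplacian response, same size as the input.
#'
#' @param img `gray_image` or numeric matrix.
#' @param neighbors 4 (default) or 8; selects the discrete Laplace kernel.
#' @return a `gradient_map` with `source = "single"`.
#' @export
laplacian <- function(img, neighbors = 4L) {
  x <- unclass(img); attributes(x) <- list(dim = dim(x))
  if (!all(is.finite(x)))
    stop("laplacian: non-finite input", call. = FALSE)
  new_gradient_map(conv2_same(x, laplacian_kernel(neighbors)), "single")
}

#' Gradient map of a fused image (adversarial "false data")
#'
#' Elementwise absolute Laplacian of the fused image.
#'
#' @inheritParams laplacian
#' @param fused the fused `gray_image`.
#' @return a non-negative `gradient_map` with `source = "fused"`.
#' @export
fused_gradient <- function(fused, neighbors = 4L) {
  g <- laplacian(fused, neighbors)
  new_gradient_map(abs(unclass(g)), "fused")
}

#' Joint gradient map of an input pair (adversarial "real data")
#'
#' Pixelwise maximum of the absolute Laplacians of the two inputs. This is
#' the target texture the generator is pushed toward: at every pixel, the
#' stronger edge of the two modalities.
#'
#' @param m structural `gray_image` (MRI).
#' @param i companion `gray_image` (CT, or the Y channel of PET/SPECT).
#' @param neighbors 4 or 8.
#' @return a non-negative `gradient_map` with `source = "joint"`.
#' @export
joint_gradient <- function(m, i, neighbors = 4L) {
  if (!same_size(m, i)) stop_size_mismatch("joint_gradient")
  gm <- abs(unclass(laplacian(m, neighbors)))
  gi <- abs(unclass(laplacian(i, neighbors)))
  new_gradient_map(pmax(gm, gi), "joint")
}
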