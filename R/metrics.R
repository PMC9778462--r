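#' @title Fusion quality metrics
#' @name metrics
#' @description
#' Four reference-free fusion metrics, evaluated on the fused image and the
#' two sources:
#' \describe{
#'   \item{AG}{average gradient — mean magnitude of forward differences on
#'     the (H-1) x (W-1) grid, with the factor 1/4 inside the square root as
#'     the defining formula prints it (`quarter = FALSE` selects the more
#'     common 1/2 convention); a sharpness proxy, higher is better.}
#'   \item{EI}{edge intensity — mean 3x3 Sobel gradient magnitude under
#'     edge-mirroring padding; higher is better.}
#'   \item{q_abf}{windowed quality index — in each window the universal
#'     image quality index Q0 of each source against the fused image,
#'     blended by relative source saliency (windowed variance); in
#'     \[-1, 1\], 1 at perfect self-fusion; higher is better.}
#'   \item{q_cv}{visual-error index — saliency-weighted regional
#'     mean-squared error of Gaussian band-filtered difference images;
#'     0 at perfect self-fusion; lower is better.}
#' }
#' Metric functions accept plain numeric matrices as well as
#' [gray_image()]s, and do not require \[0, 1\] intensities.
NULL

#' Window specification for the windowed metrics
#'
#' Windows tile the image domain; final partial windows are included.
#'
#' @param size odd-or-even window side, >= 1.
#' @param stride window step, >= 1; `stride == size` tiles without overlap.
#' @return a `win_spec` list.
#' @export
win_spec <- function(size = 8L, stride = size) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 1L || stride < 1L)
    stop("win_spec: size and stride must be >= 1", call. = FALSE)
  structure(list(size = size, stride = stride), class = "win_spec")
}

window_starts <- function(n, size, stride) {
  s <- seq.int(1L, n, by = stride)
  s[s <= n]
}

#' Average gradient (AG)
#'
#' @param img image (matrix or `gray_image`), at least 2 x 2.
#' @param quarter keep the printed 1/4 factor inside the square root
#'   (default); `FALSE` uses the 1/2 convention common elsewhere.
#' @return non-negative scalar; 0 only for images without intensity
#'   variation.
#' @export
average_gradient <- function(img, quarter = TRUE) {
  x <- as_plain_matrix(img)
  H <- nrow(x); W <- ncol(x)
  if (H < 2L || W < 2L)
    stop("average_gradient: image must be at least 2 x 2", call. = FALSE)
  dh <- x[2:H, 1:(W - 1L), drop = FALSE] - x[1:(H - 1L), 1:(W - 1L), drop = FALSE]
  dw <- x[1:(H - 1L), 2:W, drop = FALSE] - x[1:(H - 1L), 1:(W - 1L), drop = FALSE]
  fac <- if (quarter) 0.25 else 0.5
  mean(sqrt(fac * (dh^2 + dw^2)))
}

sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
sobel_y <- t(sobel_x)                                     # d/dy (rows)

sobel_magnitude <- function(x) {
  sx <- conv2_same(x, sobel_x)
  sy <- conv2_same(x, sobel_y)
  sqrt(sx^2 + sy^2)
}

#' Edge intensity (EI)
#'
#' @param img image (matrix or `gray_image`), at least 3 x 3.
#' @return non-negative scalar mean Sobel magnitude.
#' @export
edge_intensity <- function(img) {
  x <- as_plain_matrix(img)
  if (nrow(x) < 3L || ncol(x) < 3L)
    stop("edge_intensity: image must be at least 3 x 3", call. = FALSE)
  mean(sobel_magnitude(x))
}

# Universal image quality index of two equal-size windows, population
# moments. Degenerate windows fall back to the surviving factor; two
# identically-zero windows score 1 (they are identical). The two factors
# are divided separately: the product d1 * d2 can underflow to zero for
# near-constant windows (deeply saturated network outputs produce
# variances around 1e-230) even though each factor is well defined.
uqi_window <- function(a, f) {
  mu_a <- mean(a); mu_f <- mean(f)
  va <- mean((a - mu_a)^2); vf <- mean((f - mu_f)^2)
  caf <- mean((a - mu_a) * (f - mu_f))
  d1 <- va + vf; d2 <- mu_a^2 + mu_f^2
  if (d1 > 0 && d2 > 0) (2 * caf / d1) * (2 * mu_a * mu_f / d2)
  else if (d1 == 0 && d2 > 0) 2 * mu_a * mu_f / d2
  else if (d1 > 0) 2 * caf / d1
  else 1
}

#' Windowed fusion quality index (q_abf)
#'
#' In every window the universal image quality index Q0 is computed for each
#' source against the fused image; the two are blended by the relative
#' windowed-variance saliency `lambda = s(A)/(s(A)+s(B))` (0.5 when both
#' saliencies vanish), and the blend is averaged over windows.
#'
#' @param a,b source images.
#' @param f fused image, same size.
#' @param win a [win_spec()]; default 8 x 8 windows, stride 8.
#' @return scalar in \[-1, 1\]; 1 when `f == a == b`.
#' @export
q_abf <- function(a, b, f, win = win_spec(8L)) {
  a <- as_plain_matrix(a); b <- as_plain_matrix(b); f <- as_plain_matrix(f)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(f)))
    stop_size_mismatch("q_abf")
  H <- nrow(a); W <- ncol(a)
  hs <- window_starts(H, win$size, win$stride)
  ws <- window_starts(W, win$size, win$stride)
  total <- 0; nwin <- 0L
  for (h0 in hs) for (w0 in ws) {
    ri <- h0:min(h0 + win$size - 1L, H)
    ci <- w0:min(w0 + win$size - 1L, W)
    aw <- a[ri, ci]; bw <- b[ri, ci]; fw <- f[ri, ci]
    sa <- mean((aw - mean(aw))^2); sb <- mean((bw - mean(bw))^2)
    lam <- if (sa + sb > 0) sa / (sa + sb) else 0.5
    total <- total + lam * uqi_window(aw, fw) + (1 - lam) * uqi_window(bw, fw)
    nwin <- nwin + 1L
  }
  total / nwin
}

gauss_kernel_2d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

#' Visual-error fusion index (q_cv)
#'
#' Difference images between each source and the fused image are band
#' filtered with a Gaussian (a smooth stand-in for the contrast sensitivity
#' of the visual system), then the windowed mean-squared error of each
#' filtered difference is weighted by the source's windowed edge saliency
#' (mean Sobel magnitude raised to `p`) and normalized by the total
#' saliency. Lower is better; 0 at perfect self-fusion.
#'
#' @inheritParams q_abf
#' @param win a [win_spec()]; default 16 x 16 windows, stride 16.
#' @param sigma Gaussian band-filter width in pixels.
#' @param p saliency exponent.
#' @return non-negative scalar.
#' @export
q_cv <- function(a, b, f, win = win_spec(16L), sigma = 1.5, p = 1) {
  a <- as_plain_matrix(a); b <- as_plain_matrix(b); f <- as_plain_matrix(f)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(f)))
    stop_size_mismatch("q_cv")
  H <- nrow(a); W <- ncol(a)
  gk <- gauss_kernel_2d(sigma)
  da <- conv2_same(a - f, gk)
  db <- conv2_same(b - f, gk)
  ga <- sobel_magnitude(a)
  gb <- sobel_magnitude(b)
  hs <- window_starts(H, win$size, win$stride)
  ws <- window_starts(W, win$size, win$stride)
  num <- 0; den <- 0
  for (h0 in hs) for (w0 in ws) {
    ri <- h0:min(h0 + win$size - 1L, H)
    ci <- w0:min(w0 + win$size - 1L, W)
    la <- mean(ga[ri, ci])^p
    lb <- mean(gb[ri, ci])^p
    num <- num + la * mean(da[ri, ci]^2) + lb * mean(db[ri, ci]^2)
    den <- den + la + lb
  }
  if (den > 0) num / den else 0
}

#' Full metric report for a fusion triple
#'
#' @inheritParams q_abf
#' @param win_abf,win_cv window specs for the two windowed metrics.
#' @return a one-row data frame with columns `ag`, `ei`, `q_abf`, `q_cv`
#'   (AG and EI are computed on the fused image).
#' @export
metric_report <- function(a, b, f, win_abf = win_spec(8L),
                          win_cv = win_spec(16L)) {
  data.frame(ag = average_gradient(f),
             ei = edge_intensity(f),
             q_abf = q_abf(a, b, f, win_abf),
             q_cv = q_cv(a, b, f, win_cv))
}
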