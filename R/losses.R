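#' @title Fusion loss suite
#' @name losses
#' @description
#' The generator minimizes `L = L_Gan + lambda1 * L_pixel + lambda2 * L_grad`:
#' a squared adversarial term pushing the fused image's gradient map toward
#' the "real" label, a screened pixel-intensity term, and a screened
#' Laplacian-gradient (texture) term. The discriminator minimizes a squared
#' two-label loss on fused-gradient ("false", label a = 0) versus
#' joint-gradient ("true", label b = 1) maps.
#'
#' The screening maps decide, pixel by pixel, which source the fused image
#' should resemble: `map1 = 1` where the structural image's local saliency
#' (windowed variance) strictly exceeds the companion's, `0` where it is
#' strictly lower, and `0.5` on ties, with `map2 = 1 - map1`.
NULL

#' Adversarial labels
#'
#' @param a label of "false" data (fused gradient maps), default 0.
#' @param b label of "true" data (joint gradient maps), default 1.
#' @param c generator target: the value the generator wants the
#'   discriminator to emit for its fused gradients, default 1.
#' @return an `adversarial_labels` list.
#' @export
adversarial_labels <- function(a = 0, b = 1, c = 1) {
  if (!(a < b)) stop("adversarial_labels: need a < b", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "adversarial_labels")
}

#' Loss weights
#'
#' @param lambda1 weight of the pixel-distance loss.
#' @param lambda2 weight of the gradient (texture) loss.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1) {
  if (!all(is.finite(c(lambda1, lambda2))) || lambda1 < 0 || lambda2 < 0)
    stop("loss_weights: weights must be finite and non-negative",
         call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "loss_weights")
}

box_mean <- function(x, window) {
  conv2_same(x, matrix(1 / (window * window), window, window))
}

windowed_variance <- function(x, window) {
  mu <- box_mean(x, window)
  pmax(box_mean(x * x, window) - mu * mu, 0)
}

#' Screening maps from local saliency
#'
#' @param m structural image (`gray_image` or matrix).
#' @param i companion image, same size.
#' @param window odd window (>= 3) for the local variance, default 7.
#' @param constant set `TRUE` for the fallback mode in which both maps are
#'   0.5 everywhere (no screening).
#' @return list of class `screening_maps` with matrices `map1`, `map2`
#'   satisfying `map1 + map2 == 1`.
#' @export
screening_maps <- function(m, i, window = 7L, constant = FALSE) {
  m <- as_plain_matrix(m); i <- as_plain_matrix(i)
  if (!identical(dim(m), dim(i))) stop_size_mismatch("screening_maps")
  if (window %% 2L != 1L || window < 3L)
    stop("screening_maps: window must be odd and >= 3", call. = FALSE)
  if (constant) {
    map1 <- matrix(0.5, nrow(m), ncol(m))
  } else {
    vm <- windowed_variance(m, window)
    vi <- windowed_variance(i, window)
    map1 <- matrix(0.5, nrow(m), ncol(m))
    map1[vm > vi] <- 1
    map1[vm < vi] <- 0
  }
  structure(list(map1 = map1, map2 = 1 - map1), class = "screening_maps")
}

as_plain_matrix <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

#' Adversarial loss of the generator
#'
#' Mean squared distance between discriminator scores on fused gradient maps
#' and the generator target label `c`.
#'
#' @param d_scores numeric vector of discriminator probabilities in \[0, 1\].
#' @param labels an [adversarial_labels()].
#' @return non-negative scalar.
#' @export
adversarial_loss <- function(d_scores, labels = adversarial_labels()) {
  if (length(d_scores) == 0L)
    stop("adversarial_loss: empty batch", call. = FALSE)
  mean((d_scores - labels$c)^2)
}

#' Screened pixel-distance loss
#'
#' @param fused fused image.
#' @param m,i source images, same size.
#' @param maps a [screening_maps()] of the sources.
#' @return non-negative scalar.
#' @export
pixel_loss <- function(fused, m, i, maps) {
  f <- as_plain_matrix(fused); m <- as_plain_matrix(m)
  i <- as_plain_matrix(i)
  if (!identical(dim(f), dim(m)) || !identical(dim(f), dim(i)) ||
      !identical(dim(f), dim(maps$map1)))
    stop_size_mismatch("pixel_loss")
  mean(maps$map1 * (f - m)^2 + maps$map2 * (f - i)^2)
}

#' Screened gradient (texture) loss
#'
#' Compares the Laplacian of the fused image against the Laplacians of the
#' sources under the screening maps.
#'
#' @inheritParams pixel_loss
#' @param y companion image (CT, or Y channel of PET/SPECT).
#' @param neighbors Laplacian kernel variant, see [laplacian()].
#' @return non-negative scalar.
#' @export
gradient_loss <- function(fused, m, y, maps, neighbors = 4L) {
  f <- as_plain_matrix(fused); m <- as_plain_matrix(m)
  y <- as_plain_matrix(y)
  if (!identical(dim(f), dim(m)) || !identical(dim(f), dim(y)) ||
      !identical(dim(f), dim(maps$map1)))
    stop_size_mismatch("gradient_loss")
  lf <- unclass(laplacian(f, neighbors))
  lm <- unclass(laplacian(m, neighbors))
  ly <- unclass(laplacian(y, neighbors))
  mean(maps$map1 * (lf - lm)^2 + maps$map2 * (lf - ly)^2)
}

#' Total generator loss
#'
#' @param lgan,lpix,lgrad loss components.
#' @param w a [loss_weights()].
#' @return `lgan + lambda1 * lpix + lambda2 * lgrad`.
#' @export
generator_total <- function(lgan, lpix, lgrad, w = loss_weights()) {
  stopifnot(is.finite(lgan), is.finite(lpix), is.finite(lgrad))
  lgan + w$lambda1 * lpix + w$lambda2 * lgrad
}

#' Discriminator loss
#'
#' @param scores_false discriminator scores on fused-gradient maps.
#' @param scores_true discriminator scores on joint-gradient maps; same
#'   length as `scores_false`.
#' @param labels an [adversarial_labels()].
#' @return non-negative scalar.
#' @export
discriminator_loss <- function(scores_false, scores_true,
                               labels = adversarial_labels()) {
  if (length(scores_false) != length(scores_true))
    stop("discriminator_loss: score vectors must have equal length",
         call. = FALSE)
  if (length(scores_false) == 0L)
    stop("discriminator_loss: empty batch", call. = FALSE)
  mean((scores_false - labels$a)^2 + (scores_true - labels$b)^2)
}

#' Calibrate loss weights to equalize component magnitudes
#'
#' The three generator loss terms are meant to carry equal importance.
#' Given the components measured on a first training batch, this returns
#' weights that rescale the pixel and gradient terms to the magnitude of
#' the adversarial term.
#'
#' @param lgan,lpix,lgrad component values measured on one batch.
#' @param floor smallest component magnitude considered non-degenerate.
#' @return a [loss_weights()].
#' @export
calibrate_loss_weights <- function(lgan, lpix, lgrad, floor = 1e-8) {
  lgan <- as.numeric(lgan); lpix <- as.numeric(lpix)
  lgrad <- as.numeric(lgrad)
  l1 <- if (abs(lpix) > floor) abs(lgan) / abs(lpix) else 1
  l2 <- if (abs(lgrad) > floor) abs(lgan) / abs(lgrad) else 1
  loss_weights(l1, l2)
}
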