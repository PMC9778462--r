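#' @title Generator and discriminator architectures
#' @name networks
#' @description
#' The generator fuses two grayscale inputs (MRI and the CT image or the
#' Y channel of a PET/SPECT image) through two weight-independent branches:
#' two 3x3 conv-ELU extraction layers, a back-project dense block (BPDB),
#' and a convolutional block attention module (CBAM). The branch outputs are
#' concatenated and pass through a composite BPDB + CBAM stage at doubled
#' width, then a reconstruction head (conv-ELU, conv, sigmoid) emits the
#' fused image in \[0, 1\]. All convolutions are stride-1 and padded, so
#' spatial size is preserved end to end.
#'
#' The BPDB suppresses the influence of large black backgrounds through
#' three stages of back-projection arithmetic:
#' \itemize{
#'   \item enhancement: encode `F_enc`, take the difference between its
#'     conv-activation and itself, add back, decode to `F_add`;
#'   \item residual: absolute difference between the conv-activation of
#'     `F_add` and `F_add`, decoded to `F_res`;
#'   \item reconstruction: encode `F_res`, add `F_add`, decode.
#' }
#'
#' The discriminator never sees images — only Laplacian gradient maps. It is
#' a stack of stride-2 conv-ELU layers followed by global average pooling
#' and a single sigmoid unit emitting the probability that a gradient map is
#' a joint gradient map ("real") rather than a fused-image gradient map.
NULL

#' Generator configuration
#'
#' @param base_channels branch width (channels); the composite stage runs at
#'   twice this. Must be at least 4.
#' @param conv_kernel odd convolution kernel size (default 3).
#' @param activation hidden activation; `"ELU"`.
#' @param attention_gate activation gating the CBAM attention weights.
#'   `"ELU"` follows the architecture as published; `"sigmoid"` is the
#'   conventional bounded alternative.
#' @param attention_ratio channel-attention bottleneck reduction ratio.
#' @return a `generator_config` list.
#' @export
generator_config <- function(base_channels = 32L, conv_kernel = 3L,
                             activation = "ELU",
                             attention_gate = c("ELU", "sigmoid"),
                             attention_ratio = 8L) {
  attention_gate <- match.arg(attention_gate)
  base_channels <- as.integer(base_channels)
  conv_kernel <- as.integer(conv_kernel)
  if (base_channels < 4L)
    stop("generator_config: base_channels must be >= 4", call. = FALSE)
  if (conv_kernel %% 2L != 1L)
    stop("generator_config: conv_kernel must be odd", call. = FALSE)
  structure(list(base_channels = base_channels, conv_kernel = conv_kernel,
                 activation = activation, attention_gate = attention_gate,
                 attention_ratio = as.integer(attention_ratio)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' @param channel_schedule widths of the stride-2 downsampling conv layers.
#' @param use_spectral_norm scale each layer's weights by the reciprocal of
#'   their estimated spectral norm before discriminator updates (power
#'   iteration; the scale is treated as constant in the backward pass).
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(channel_schedule = c(16L, 32L, 64L, 64L),
                                 use_spectral_norm = FALSE) {
  if (length(channel_schedule) < 1L)
    stop("discriminator_config: empty channel schedule", call. = FALSE)
  structure(list(channel_schedule = as.integer(channel_schedule),
                 use_spectral_norm = isTRUE(use_spectral_norm)),
            class = "discriminator_config")
}

## ---- BPDB ------------------------------------------------------------------

bpdb_new <- function(channels, k = 3L) {
  list(
    enc0 = conv_layer(channels, channels, k),
    enh  = conv_layer(channels, channels, k),
    dec1 = conv_layer(channels, channels, k),
    res  = conv_layer(channels, channels, k),
    dec2 = conv_layer(channels, channels, k),
    enc3 = conv_layer(channels, channels, k),
    dec3 = conv_layer(channels, channels, k)
  )
}

bpdb_graph <- function(bp, xn) {
  f_enc <- ag_elu(ag_conv(xn, bp$enc0))
  d <- ag_sub(ag_elu(ag_conv(f_enc, bp$enh)), f_enc)
  f_add <- ag_elu(ag_conv(ag_add(f_enc, d), bp$dec1))
  f_res <- ag_elu(ag_conv(ag_abs(ag_sub(ag_elu(ag_conv(f_add, bp$res)),
                                        f_add)), bp$dec2))
  f_res_en <- ag_elu(ag_conv(f_res, bp$enc3))
  ag_elu(ag_conv(ag_add(f_res_en, f_add), bp$dec3))
}

#' Run a back-project dense block on a feature volume
#'
#' Mostly useful for inspection and testing; inside the generator the block
#' is part of the recorded graph.
#'
#' @param bp a BPDB created internally (see [generator_new()]'s `$branch_m$bpdb`).
#' @param x numeric array (C, H, W) matching the block's width.
#' @return numeric array of the same shape.
#' @export
bpdb_forward <- function(bp, x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("bpdb_forward: input must be a (C,H,W) array", call. = FALSE)
  if (dim(x)[1] != bp$enc0$c_in)
    stop(sprintf("bpdb_forward: input has %d channels, block expects %d",
                 dim(x)[1], bp$enc0$c_in), call. = FALSE)
  ag_tape_reset(record = FALSE)
  bpdb_graph(bp, ag_const(x))$value
}

## ---- CBAM ------------------------------------------------------------------

cbam_new <- function(channels, ratio = 8L, gate = "ELU") {
  if (channels < 2L)
    stop("cbam_new: channel attention needs at least 2 channels",
         call. = FALSE)
  hidden <- max(1L, channels %/% ratio)
  list(
    fc1 = fc_layer(channels, hidden),
    fc2 = fc_layer(hidden, channels),
    sp  = conv_layer(2L, 1L, k = 1L, pad = 0L),
    gate = gate
  )
}

cbam_gate <- function(n, gate) {
  if (identical(gate, "sigmoid")) ag_sigmoid(n) else ag_elu(n)
}

cbam_graph <- function(cb, xn) {
  mlp <- function(v) ag_fc(ag_elu(ag_fc(v, cb$fc1)), cb$fc2)
  cw <- cbam_gate(ag_axpy(mlp(ag_gmp(xn)), mlp(ag_gap(xn))), cb$gate)
  x1 <- ag_scale_channels(xn, cw)
  sp_in <- ag_stack2(ag_chan_max(x1), ag_chan_mean(x1))
  sg <- cbam_gate(ag_drop_channel(ag_conv(sp_in, cb$sp)), cb$gate)
  ag_scale_spatial(x1, sg)
}

#' Run a convolutional block attention module on a feature volume
#'
#' Channel attention (shared max/avg-pooled MLP bottleneck) followed by
#' spatial attention (1x1 convolution over channelwise max and mean maps),
#' each applied multiplicatively.
#'
#' @param cb a CBAM created internally (see [generator_new()]).
#' @param x numeric array (C, H, W) with C >= 2.
#' @return numeric array of the same shape.
#' @export
cbam_forward <- function(cb, x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[1] < 2L)
    stop("cbam_forward: input must be a (C,H,W) array with C >= 2",
         call. = FALSE)
  ag_tape_reset(record = FALSE)
  cbam_graph(cb, ag_const(x))$value
}

## ---- generator -------------------------------------------------------------

branch_new <- function(cfg) {
  bc <- cfg$base_channels; k <- cfg$conv_kernel
  list(
    ext1 = conv_layer(1L, bc, k),
    ext2 = conv_layer(bc, bc, k),
    bpdb = bpdb_new(bc, k),
    cbam = cbam_new(bc, cfg$attention_ratio, cfg$attention_gate)
  )
}

#' Create a fusion generator
#'
#' Weights are drawn from the current RNG state (Kaiming fan-in); seed the
#' RNG before calling for reproducible initialization.
#'
#' @param cfg a [generator_config()].
#' @param ablation list of flags `use_bpdb`, `use_cbam`; a disabled block is
#'   skipped (identity), leaving all shapes unchanged.
#' @return a `fg_generator` object.
#' @export
generator_new <- function(cfg = generator_config(),
                          ablation = list(use_bpdb = TRUE, use_cbam = TRUE)) {
  bc <- cfg$base_channels; k <- cfg$conv_kernel
  g <- list(
    cfg = cfg,
    ablation = list(use_bpdb = !isFALSE(ablation$use_bpdb),
                    use_cbam = !isFALSE(ablation$use_cbam)),
    branch_m = branch_new(cfg),
    branch_y = branch_new(cfg),
    comp_bpdb = bpdb_new(2L * bc, k),
    comp_cbam = cbam_new(2L * bc, cfg$attention_ratio, cfg$attention_gate),
    head1 = conv_layer(2L * bc, bc, k),
    head2 = conv_layer(bc, 1L, k)
  )
  # small-scale output head: the initial fused image starts near the
  # sigmoid midpoint instead of deep in saturation, where the pixel and
  # gradient losses would see vanishing gradients
  g$head2$W <- g$head2$W * 0.1
  class(g) <- "fg_generator"
  g
}

branch_layers <- function(br) c(list(br$ext1, br$ext2), unname(br$bpdb),
                                list(br$cbam$fc1, br$cbam$fc2, br$cbam$sp))

generator_layers <- function(g) {
  c(branch_layers(g$branch_m), branch_layers(g$branch_y),
    unname(g$comp_bpdb),
    list(g$comp_cbam$fc1, g$comp_cbam$fc2, g$comp_cbam$sp,
         g$head1, g$head2))
}

branch_graph <- function(br, xn, ablation) {
  f1 <- ag_elu(ag_conv(ag_elu(ag_conv(xn, br$ext1)), br$ext2))
  f2 <- if (ablation$use_bpdb) bpdb_graph(br$bpdb, f1) else f1
  if (ablation$use_cbam) cbam_graph(br$cbam, f2) else f2
}

generator_graph <- function(g, m, y) {
  mn <- ag_const(array(m, c(1L, nrow(m), ncol(m))))
  yn <- ag_const(array(y, c(1L, nrow(y), ncol(y))))
  fm <- branch_graph(g$branch_m, mn, g$ablation)
  fy <- branch_graph(g$branch_y, yn, g$ablation)
  ff <- ag_concat(fm, fy)
  fe <- if (g$ablation$use_bpdb) bpdb_graph(g$comp_bpdb, ff) else ff
  fe <- if (g$ablation$use_cbam) cbam_graph(g$comp_cbam, fe) else fe
  out <- ag_conv(ag_elu(ag_conv(fe, g$head1)), g$head2)
  ag_drop_channel(ag_sigmoid(out))
}

#' Fuse two grayscale images with a generator
#'
#' @param g an `fg_generator`.
#' @param m structural image (`gray_image` or numeric matrix).
#' @param y companion luminance image, same size.
#' @return fused `gray_image` with values in \[0, 1\].
#' @export
generator_forward <- function(g, m, y) {
  m <- unclass(m); attributes(m) <- list(dim = dim(m))
  y <- unclass(y); attributes(y) <- list(dim = dim(y))
  if (!identical(dim(m), dim(y)))
    stop_size_mismatch("generator_forward")
  ag_tape_reset(record = FALSE)
  gray_image(generator_graph(g, m, y)$value)
}

## ---- discriminator ---------------------------------------------------------

#' Create a gradient-map discriminator
#'
#' @inheritParams generator_new
#' @param cfg a [discriminator_config()].
#' @return an `fg_discriminator` object.
#' @export
discriminator_new <- function(cfg = discriminator_config()) {
  sch <- cfg$channel_schedule
  convs <- vector("list", length(sch))
  c_in <- 1L
  for (i in seq_along(sch)) {
    convs[[i]] <- conv_layer(c_in, sch[i], k = 3L, stride = 2L, pad = 1L)
    c_in <- sch[i]
  }
  d <- list(cfg = cfg, convs = convs, fc = fc_layer(c_in, 1L))
  class(d) <- "fg_discriminator"
  d
}

discriminator_layers <- function(d) c(d$convs, list(d$fc))

discriminator_graph <- function(d, gn) {
  x <- ag_add_channel(gn)
  for (l in d$convs) x <- ag_elu(ag_conv(x, l))
  ag_sigmoid(ag_fc(ag_gap(x), d$fc))
}

#' Score a gradient map
#'
#' @param d an `fg_discriminator`.
#' @param gmap a `gradient_map` or numeric matrix.
#' @return scalar probability in \[0, 1\] that the map is a joint gradient
#'   map of real inputs.
#' @export
discriminator_forward <- function(d, gmap) {
  x <- unclass(gmap); attributes(x) <- list(dim = dim(x))
  if (!all(is.finite(x)))
    stop("discriminator_forward: non-finite input", call. = FALSE)
  ag_tape_reset(record = FALSE)
  as.numeric(discriminator_graph(d, ag_const(x))$value)
}

# Power-iteration spectral normalization: refresh each layer's weight scale.
spectral_rescale <- function(d, iters = 1L) {
  if (!d$cfg$use_spectral_norm) return(invisible(NULL))
  for (l in discriminator_layers(d)) {
    if (is.null(l$u)) l$u <- stats::rnorm(nrow(l$W))
    for (i in seq_len(iters)) {
      v <- drop(crossprod(l$W, l$u)); v <- v / max(sqrt(sum(v^2)), 1e-12)
      u <- drop(l$W %*% v); nu <- max(sqrt(sum(u^2)), 1e-12)
      l$u <- u / nu
    }
    l$wscale <- 1 / max(nu, 1e-12)
  }
  invisible(NULL)
}

#' Count trainable parameters
#'
#' @param net an `fg_generator` or `fg_discriminator`.
#' @return integer parameter count (weights plus biases).
#' @export
n_params <- function(net) {
  layers <- if (inherits(net, "fg_generator")) generator_layers(net)
            else discriminator_layers(net)
  as.integer(n_layer_params(layers))
}
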