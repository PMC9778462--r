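#' @title Run configuration
#' @name config
#' @description
#' One nested configuration tree with documented defaults for every tunable
#' in the package. YAML files override defaults; unknown keys are rejected
#' by name so typos never silently fall back to a default.
NULL

#' Default run configuration
#'
#' @return nested list with sections `generator`, `discriminator`, `train`,
#'   `window`, `phantom`, `paths`, `verbosity`.
#' @export
run_config_defaults <- function() {
  list(
    generator = list(base_channels = 8L, conv_kernel = 3L,
                     activation = "ELU", attention_gate = "ELU",
                     attention_ratio = 8L),
    discriminator = list(channel_schedule = c(16L, 32L, 64L, 64L),
                         use_spectral_norm = FALSE),
    train = list(batch_size = 4L, disc_steps = 2L, epochs = 5L, lr = 1e-4,
                 betas = c(0.9, 0.999), seed = 1L,
                 split = c(0.7, 0.2, 0.1), lambda1 = 1, lambda2 = 1,
                 calibrate_weights = FALSE, screen_window = 7L,
                 laplacian_neighbors = 4L,
                 use_bpdb = TRUE, use_cbam = TRUE,
                 use_pixel_loss = TRUE, use_grad_loss = TRUE),
    window = list(abf_size = 8L, abf_stride = 8L, cv_size = 16L,
                  cv_stride = 16L, cv_sigma = 1.5, cv_p = 1),
    phantom = list(height = 64L, width = 64L, n_structures = 4L,
                   texture_freq = 8, n_blobs = 3L, blob_sigma = NA,
                   background_fraction = 0.6, noise_sd = 0.02, seed = 1L),
    paths = list(data_dir = ".", out = "."),
    verbosity = 1L
  )
}

merge_config <- function(defaults, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("load_config: unknown key '%s'", full), call. = FALSE)
    dv <- defaults[[key]]
    ov <- override[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(ov))
        stop(sprintf("load_config: key '%s' must be a section", full),
             call. = FALSE)
      defaults[[key]] <- merge_config(dv, ov, full)
    } else {
      if (is.list(ov)) ov <- unlist(ov)
      if (is.numeric(dv) && !is.numeric(ov))
        stop(sprintf("load_config: key '%s' must be numeric", full),
             call. = FALSE)
      if (is.logical(dv) && !is.logical(ov))
        stop(sprintf("load_config: key '%s' must be logical", full),
             call. = FALSE)
      if (is.numeric(dv) && is.integer(dv)) ov <- as.integer(ov)
      defaults[[key]] <- ov
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' An empty (or missing-section) file yields all defaults; unknown or
#' type-mismatched keys raise a configuration error naming the key.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("load_config: no such file: %s", path), call. = FALSE)
    override <- yaml::read_yaml(path)
    if (!is.null(override)) cfg <- merge_config(cfg, override)
  }
  cfg
}

config_to_train <- function(cfg) {
  tr <- cfg$train
  train_config(
    batch_size = tr$batch_size, disc_steps = tr$disc_steps,
    epochs = tr$epochs, lr = tr$lr, betas = tr$betas, seed = tr$seed,
    split = tr$split, weights = loss_weights(tr$lambda1, tr$lambda2),
    calibrate_weights = tr$calibrate_weights,
    screen_window = tr$screen_window,
    laplacian_neighbors = tr$laplacian_neighbors,
    gen = generator_config(cfg$generator$base_channels,
                           cfg$generator$conv_kernel,
                           cfg$generator$activation,
                           cfg$generator$attention_gate,
                           cfg$generator$attention_ratio),
    disc = discriminator_config(cfg$discriminator$channel_schedule,
                                cfg$discriminator$use_spectral_norm),
    ablation = list(use_bpdb = tr$use_bpdb, use_cbam = tr$use_cbam,
                    use_pixel_loss = tr$use_pixel_loss,
                    use_grad_loss = tr$use_grad_loss))
}

config_to_phantom <- function(cfg, seed = NULL) {
  ph <- cfg$phantom
  phantom_spec(size = c(ph$height, ph$width),
               n_structures = ph$n_structures,
               texture_freq = ph$texture_freq, n_blobs = ph$n_blobs,
               blob_sigma = if (is.na(ph$blob_sigma)) NULL else ph$blob_sigma,
               background_fraction = ph$background_fraction,
               noise_sd = ph$noise_sd,
               seed = seed %||% ph$seed)
}
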