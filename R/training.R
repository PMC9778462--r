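#' @title Adversarial training loop
#' @name training
#' @description
#' Alternating optimization on (structural, functional-or-CT) pairs. Per
#' optimization cycle the discriminator receives exactly `disc_steps`
#' updates (on the squared two-label loss over fused-gradient vs
#' joint-gradient maps) per single generator update (on the total loss
#' `L_Gan + lambda1 L_pixel + lambda2 L_grad`). Screening maps, source
#' Laplacians and joint gradients depend only on the inputs and are cached
#' per record before the loop. One seed controls weight initialization and
#' batch shuffling, making runs bit-reproducible on one machine.
NULL

#' One training example
#'
#' @param structural `gray_image` (MRI/CT).
#' @param companion `gray_image` (CT) or `color_image` (PET/SPECT); same
#'   height and width as `structural`.
#' @return a `fusion_record`.
#' @export
fusion_record <- function(structural, companion) {
  if (!same_size(structural, companion))
    stop_size_mismatch("fusion_record")
  structure(list(structural = structural, companion = companion),
            class = "fusion_record")
}

#' Training configuration
#'
#' Defaults are the desk-scale testing profile (64 x 64 phantoms, narrow
#' generator); `inst/config/paper_scale.yaml` carries the full-scale
#' settings (batch 32, 300 epochs, 256 x 256).
#'
#' @param batch_size mini-batch size `b`.
#' @param disc_steps discriminator updates per generator update `p`.
#' @param epochs passes over the training set `M`; each epoch runs
#'   `K = floor(n / b)` optimization cycles.
#' @param lr,betas Adam learning rate and moment decays.
#' @param seed master seed for init and shuffling.
#' @param split (train, validation, test) fractions summing to 1.
#' @param weights a [loss_weights()].
#' @param calibrate_weights recalibrate `weights` on the first batch so the
#'   three generator loss components have equal magnitude
#'   (see [calibrate_loss_weights()]).
#' @param labels an [adversarial_labels()].
#' @param screen_window window of the screening-map saliency; `NA` uses the
#'   constant-0.5 fallback maps.
#' @param laplacian_neighbors 4 or 8, Laplacian kernel of the gradient
#'   machinery.
#' @param gen a [generator_config()].
#' @param disc a [discriminator_config()].
#' @param ablation flags `use_bpdb`, `use_cbam`, `use_pixel_loss`,
#'   `use_grad_loss`.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 4L, disc_steps = 2L, epochs = 5L,
                         lr = 1e-4, betas = c(0.9, 0.999), seed = 1L,
                         split = c(0.7, 0.2, 0.1),
                         weights = loss_weights(),
                         calibrate_weights = FALSE,
                         labels = adversarial_labels(),
                         screen_window = 7L,
                         laplacian_neighbors = 4L,
                         gen = generator_config(base_channels = 8L),
                         disc = discriminator_config(),
                         ablation = list(use_bpdb = TRUE, use_cbam = TRUE,
                                         use_pixel_loss = TRUE,
                                         use_grad_loss = TRUE)) {
  if (batch_size < 1L || disc_steps < 1L || epochs < 1L)
    stop("train_config: batch_size, disc_steps and epochs must be >= 1",
         call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8)
    stop("train_config: split fractions must sum to 1", call. = FALSE)
  ab <- list(use_bpdb = !isFALSE(ablation$use_bpdb),
             use_cbam = !isFALSE(ablation$use_cbam),
             use_pixel_loss = !isFALSE(ablation$use_pixel_loss),
             use_grad_loss = !isFALSE(ablation$use_grad_loss))
  structure(list(batch_size = as.integer(batch_size),
                 disc_steps = as.integer(disc_steps),
                 epochs = as.integer(epochs), lr = lr, betas = betas,
                 seed = as.integer(seed), split = split, weights = weights,
                 calibrate_weights = isTRUE(calibrate_weights),
                 labels = labels, screen_window = screen_window,
                 laplacian_neighbors = as.integer(laplacian_neighbors),
                 gen = gen, disc = disc, ablation = ab),
            class = "train_config")
}

#' Split records into train/validation/test
#'
#' Floor-and-largest-remainder allocation, shuffled reproducibly: 10 records
#' at 7:2:1 give sizes (7, 2, 1).
#'
#' @param records list of records.
#' @param fractions non-negative fractions summing to 1.
#' @param seed shuffle seed.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  n <- length(records)
  k <- length(fractions)
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop("split_dataset: fractions must be non-negative and sum to 1",
         call. = FALSE)
  if (n < k)
    stop("split_dataset: fewer records than partitions", call. = FALSE)
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  idx <- with_seed(seed, sample.int(n))
  ends <- cumsum(cnt)
  starts <- c(1, utils::head(ends, -1) + 1)
  parts <- lapply(seq_len(k), function(j)
    if (cnt[j] > 0) records[idx[starts[j]:ends[j]]] else list())
  names(parts) <- c("train", "val", "test")[seq_len(k)]
  parts
}

record_luminance <- function(rec) {
  if (inherits(rec$companion, "color_image")) {
    as_plain_matrix(rgb_to_ycbcr(rec$companion)$y)
  } else {
    as_plain_matrix(rec$companion)
  }
}

# Cache everything that depends only on the inputs.
prepare_records <- function(records, cfg) {
  lapply(records, function(rec) {
    m <- as_plain_matrix(rec$structural)
    y <- record_luminance(rec)
    maps <- if (is.na(cfg$screen_window))
      screening_maps(m, y, constant = TRUE)
    else screening_maps(m, y, window = cfg$screen_window)
    list(m = m, y = y, maps = maps,
         lap_m = unclass(laplacian(m, cfg$laplacian_neighbors)),
         lap_y = unclass(laplacian(y, cfg$laplacian_neighbors)),
         grad2 = unclass(joint_gradient(m, y, cfg$laplacian_neighbors)))
  })
}

# Generator-side per-sample loss graph. Returns scalar nodes and values.
gen_sample_graph <- function(gen, disc, pr, cfg, kern) {
  fused <- generator_graph(gen, pr$m, pr$y)
  lapf <- ag_laplacian(fused, kern)
  score <- discriminator_graph(disc, ag_abs(lapf))
  lgan <- ag_sq_err(score, cfg$labels$c)
  lpix <- ag_wmse(fused, pr$m, pr$maps$map1)
  lpix <- ag_axpy(lpix, ag_wmse(fused, pr$y, pr$maps$map2))
  lgrad <- ag_wmse(lapf, pr$lap_m, pr$maps$map1)
  lgrad <- ag_axpy(lgrad, ag_wmse(lapf, pr$lap_y, pr$maps$map2))
  w1 <- if (cfg$ablation$use_pixel_loss) cfg$weights$lambda1 else 0
  w2 <- if (cfg$ablation$use_grad_loss) cfg$weights$lambda2 else 0
  total <- ag_axpy(lgan, ag_axpy(lpix, lgrad, w1, w2))
  list(total = total, lgan = lgan$value, lpix = lpix$value,
       lgrad = lgrad$value)
}

#' Train the fusion GAN
#'
#' @param cfg a [train_config()].
#' @param train_set list of [fusion_record()]s (non-empty).
#' @param val_set optional validation records; mean metric report logged
#'   per epoch.
#' @param log_path optional CSV path for the per-step loss log.
#' @param verbose print per-epoch progress.
#' @return an `fg_checkpoint`: generator, discriminator, config, seed,
#'   per-step loss log (`data.frame`), update counters and per-epoch
#'   validation metrics.
#' @export
train <- function(cfg, train_set, val_set = NULL, log_path = NULL,
                  verbose = FALSE) {
  if (length(train_set) == 0L)
    stop("train: empty training set", call. = FALSE)
  set.seed(cfg$seed)
  gen <- generator_new(cfg$gen, cfg$ablation)
  disc <- discriminator_new(cfg$disc)
  gl <- generator_layers(gen)
  dl <- discriminator_layers(disc)
  opt_g <- adam_new(gl, lr = cfg$lr, beta1 = cfg$betas[1],
                    beta2 = cfg$betas[2])
  opt_d <- adam_new(dl, lr = cfg$lr, beta1 = cfg$betas[1],
                    beta2 = cfg$betas[2])
  prep <- prepare_records(train_set, cfg)
  kern <- laplacian_kernel(cfg$laplacian_neighbors)
  n <- length(prep)
  b <- min(cfg$batch_size, n)
  K <- max(1L, n %/% b)
  gen_updates <- 0L
  disc_updates <- 0L
  log <- vector("list", cfg$epochs * K)
  val_log <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (kstep in seq_len(K)) {
      batch <- prep[ord[((kstep - 1L) * b + 1L):(kstep * b)]]

      # fused images under the current generator (no gradient recording);
      # the p discriminator updates of this cycle all use these maps
      grad1 <- lapply(batch, function(pr) {
        ag_tape_reset(record = FALSE)
        abs(conv2_same(generator_graph(gen, pr$m, pr$y)$value, kern))
      })

      ld <- NA_real_
      for (pstep in seq_len(cfg$disc_steps)) {
        spectral_rescale(disc)
        zero_grads(dl)
        ld_batch <- 0
        for (j in seq_along(batch)) {
          ag_tape_reset(record = TRUE)
          sf <- discriminator_graph(disc, ag_const(grad1[[j]]))
          st <- discriminator_graph(disc, ag_const(batch[[j]]$grad2))
          ls <- ag_axpy(ag_sq_err(sf, cfg$labels$a),
                        ag_sq_err(st, cfg$labels$b))
          ag_backward(ls, seed = 1 / length(batch))
          ld_batch <- ld_batch + ls$value / length(batch)
        }
        adam_step(opt_d)
        disc_updates <- disc_updates + 1L
        ld <- ld_batch
      }

      zero_grads(gl); zero_grads(dl)
      comp <- c(lgan = 0, lpix = 0, lgrad = 0)
      for (pr in batch) {
        ag_tape_reset(record = TRUE)
        gs <- gen_sample_graph(gen, disc, pr, cfg, kern)
        ag_backward(gs$total, seed = 1 / length(batch))
        comp <- comp + c(gs$lgan, gs$lpix, gs$lgrad) / length(batch)
      }
      if (cfg$calibrate_weights && gen_updates == 0L) {
        cfg$weights <- calibrate_loss_weights(comp["lgan"], comp["lpix"],
                                              comp["lgrad"])
      }
      adam_step(opt_g)
      gen_updates <- gen_updates + 1L
      ltot <- generator_total(comp["lgan"], comp["lpix"], comp["lgrad"],
                              cfg$weights)
      if (!is.finite(ltot) || !is.finite(ld))
        stop(sprintf(
          "train: non-finite loss at epoch %d step %d (L=%g, L_D=%g)",
          epoch, kstep, ltot, ld), call. = FALSE)
      log[[gen_updates]] <- data.frame(
        step = gen_updates, epoch = epoch,
        l_gan = unname(comp["lgan"]), l_pixel = unname(comp["lpix"]),
        l_grad = unname(comp["lgrad"]), l_total = unname(ltot), l_d = ld)
    }
    if (!is.null(val_set) && length(val_set)) {
      val_log[[epoch]] <- cbind(epoch = epoch,
                                evaluate_records(gen, val_set, cfg))
    }
    if (verbose)
      message(sprintf("epoch %d/%d  L=%.5f  L_D=%.5f", epoch, cfg$epochs,
                      log[[gen_updates]]$l_total, ld))
  }
  log <- do.call(rbind, log)
  if (!is.null(log_path))
    utils::write.csv(log, log_path, row.names = FALSE)
  ckpt <- list(generator = gen, discriminator = disc, cfg = cfg,
               seed = cfg$seed, log = log,
               counters = c(gen_updates = gen_updates,
                            disc_updates = disc_updates),
               val_metrics = if (is.null(val_set)) NULL
                             else do.call(rbind, val_log))
  class(ckpt) <- "fg_checkpoint"
  ckpt
}

# Mean metric report of a generator over records.
evaluate_records <- function(gen, records, cfg) {
  reps <- lapply(records, function(rec) {
    m <- as_plain_matrix(rec$structural)
    y <- record_luminance(rec)
    f <- unclass(generator_forward(gen, m, y))
    metric_report(m, y, f)
  })
  as.data.frame(t(colMeans(do.call(rbind, reps))))
}

#' Fuse a pair with a trained checkpoint
#'
#' A 3-channel companion goes through the YCbCr route: its luminance is
#' fused with the structural image and the original chroma is recombined,
#' so output chroma equals input chroma. A single-channel companion (CT) is
#' fused directly into a grayscale output.
#'
#' @param ckpt an `fg_checkpoint` (or bare `fg_generator`).
#' @param structural `gray_image`.
#' @param companion `gray_image` or `color_image`, same size.
#' @return `color_image` (RGB) for color companions, `gray_image` for
#'   grayscale ones.
#' @export
fuse_pair <- function(ckpt, structural, companion) {
  gen <- if (inherits(ckpt, "fg_checkpoint")) ckpt$generator else ckpt
  if (!same_size(structural, companion))
    stop_size_mismatch("fuse_pair")
  if (inherits(companion, "color_image")) {
    planes <- rgb_to_ycbcr(companion)
    fused_y <- generator_forward(gen, structural, planes$y)
    recombine(fused_y, planes)
  } else {
    generator_forward(gen, structural, companion)
  }
}

#' Run the module / loss ablation harness
#'
#' Trains one model per grid row under a shared config and reports the mean
#' metric report on held-out records. `grid = "modules"` covers backbone,
#' +BPDB, +CBAM and both; `grid = "losses"` covers adversarial+gradient,
#' adversarial+pixel and all three. A custom data frame of flag columns is
#' also accepted.
#'
#' @param cfg a [train_config()] shared by every row.
#' @param train_set,test_set record lists.
#' @param grid `"modules"`, `"losses"`, or a data frame whose columns are a
#'   subset of `use_bpdb`, `use_cbam`, `use_pixel_loss`, `use_grad_loss`
#'   plus an optional `label`.
#' @param verbose print progress per row.
#' @return data frame: one row per configuration with flag columns and the
#'   metric report (`ag`, `ei`, `q_abf`, `q_cv`).
#' @export
run_ablation <- function(cfg, train_set, test_set, grid = "modules",
                         verbose = FALSE) {
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("modules", "losses")),
      modules = data.frame(
        label = c("backbone", "backbone+bpdb", "backbone+cbam",
                  "backbone+bpdb+cbam"),
        use_bpdb = c(FALSE, TRUE, FALSE, TRUE),
        use_cbam = c(FALSE, FALSE, TRUE, TRUE)),
      losses = data.frame(
        label = c("gan+grad", "gan+pixel", "gan+pixel+grad"),
        use_pixel_loss = c(FALSE, TRUE, TRUE),
        use_grad_loss = c(TRUE, FALSE, TRUE)))
  }
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg_r <- cfg
    for (fl in intersect(names(grid),
                         c("use_bpdb", "use_cbam", "use_pixel_loss",
                           "use_grad_loss")))
      cfg_r$ablation[[fl]] <- isTRUE(grid[[fl]][r])
    if (verbose)
      message(sprintf("ablation row %d/%d", r, nrow(grid)))
    ck <- train(cfg_r, train_set)
    rows[[r]] <- cbind(grid[r, , drop = FALSE],
                       evaluate_records(ck$generator, test_set, cfg_r))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- checkpoint serialization ---------------------------------------------

layer_export <- function(l) list(W = l$W, b = l$b, k = l$k %||% NULL,
                                 stride = l$stride %||% NULL,
                                 pad = l$pad %||% NULL)

net_export <- function(layers) lapply(layers, layer_export)

net_import <- function(layers, saved) {
  for (j in seq_along(layers)) {
    layers[[j]]$W <- saved[[j]]$W
    layers[[j]]$b <- saved[[j]]$b
  }
  invisible(NULL)
}

#' Save / load a checkpoint archive
#'
#' The archive holds weights, full config, seed and the loss log in one
#' RDS file.
#'
#' @param ckpt an `fg_checkpoint`.
#' @param path file path.
#' @return `path` (save) or the restored `fg_checkpoint` (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  payload <- list(
    gen_weights = net_export(generator_layers(ckpt$generator)),
    disc_weights = net_export(discriminator_layers(ckpt$discriminator)),
    cfg = ckpt$cfg, seed = ckpt$seed, log = ckpt$log,
    counters = ckpt$counters, val_metrics = ckpt$val_metrics)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  cfg <- payload$cfg
  set.seed(cfg$seed)
  gen <- generator_new(cfg$gen, cfg$ablation)
  disc <- discriminator_new(cfg$disc)
  net_import(generator_layers(gen), payload$gen_weights)
  net_import(discriminator_layers(disc), payload$disc_weights)
  ckpt <- list(generator = gen, discriminator = disc, cfg = cfg,
               seed = payload$seed, log = payload$log,
               counters = payload$counters,
               val_metrics = payload$val_metrics)
  class(ckpt) <- "fg_checkpoint"
  ckpt
}
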