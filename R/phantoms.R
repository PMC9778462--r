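#' @title Synthetic co-registered phantom pairs
#' @name phantoms
#' @description
#' Training and testing need co-registered pairs with the statistical
#' contrast the fusion model assumes: a sharp, textured structural image
#' (MRI/CT surrogate) and a smooth pseudo-color functional image (PET/SPECT
#' surrogate) whose activity blobs sit inside the anatomy on an exactly
#' black background. Co-registration comes from shared geometry: both
#' members of a pair are derived from the same seeded ellipse layout, so no
#' warping or registration step is involved.
NULL

#' Phantom specification
#'
#' @param size integer (H, W), both >= 16; default 256 x 256, the slice size
#'   typical of whole-brain atlas data.
#' @param n_structures number of ellipse/ring structures in the structural
#'   image.
#' @param texture_freq spatial frequency (cycles across the image) of the
#'   sinusoidal texture; 0 disables texture.
#' @param n_blobs number of functional activity blobs.
#' @param blob_sigma Gaussian blob width in pixels; `NULL` defaults to 8% of
#'   the smaller image side.
#' @param background_fraction minimum fraction of exactly-zero pixels in the
#'   functional image, in \[0, 1).
#' @param noise_sd additive Gaussian noise s.d. on the structural image.
#' @param seed integer seed; one seed defines one co-registered pair.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(256L, 256L), n_structures = 4L,
                         texture_freq = 8, n_blobs = 3L, blob_sigma = NULL,
                         background_fraction = 0.6, noise_sd = 0.02,
                         seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L))
    stop("phantom_spec: size must be (H, W) with both >= 16", call. = FALSE)
  if (background_fraction < 0 || background_fraction >= 1)
    stop("phantom_spec: background_fraction must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0 || n_structures < 0L || n_blobs < 0L || texture_freq < 0)
    stop("phantom_spec: negative parameter", call. = FALSE)
  if (is.null(blob_sigma)) blob_sigma <- 0.08 * min(size)
  structure(list(size = size, n_structures = as.integer(n_structures),
                 texture_freq = texture_freq, n_blobs = as.integer(n_blobs),
                 blob_sigma = blob_sigma,
                 background_fraction = background_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shared seeded geometry: both modalities of one pair derive from this.
phantom_geometry <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  with_seed(spec$seed, {
    n <- spec$n_structures
    list(
      cy = stats::runif(n, 0.25 * H, 0.75 * H),
      cx = stats::runif(n, 0.25 * W, 0.75 * W),
      ry = stats::runif(n, 0.12 * H, 0.3 * H),
      rx = stats::runif(n, 0.12 * W, 0.3 * W),
      ang = stats::runif(n, 0, pi),
      ring = stats::runif(n) < 0.4,
      val = stats::runif(n, 0.35, 0.9),
      tex_phase = stats::runif(1, 0, 2 * pi),
      tex_dir = stats::runif(1, 0, pi)
    )
  })
}

ellipse_r2 <- function(H, W, cy, cx, ry, rx, ang) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(ang) * xx + sin(ang) * yy
  v <- -sin(ang) * xx + cos(ang) * yy
  (u / rx)^2 + (v / ry)^2
}

#' Generate a structural phantom (MRI/CT surrogate)
#'
#' Overlapping ellipses and rings with sharp boundaries, plus sinusoidal
#' texture and additive Gaussian noise, clipped to \[0, 1\]. Deterministic
#' per seed.
#'
#' @param spec a [phantom_spec()].
#' @return a [gray_image()].
#' @export
make_structural <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  geo <- phantom_geometry(spec)
  img <- matrix(0, H, W)
  for (s in seq_len(spec$n_structures)) {
    r2 <- ellipse_r2(H, W, geo$cy[s], geo$cx[s], geo$ry[s], geo$rx[s],
                     geo$ang[s])
    mask <- if (geo$ring[s]) r2 <= 1 & r2 >= 0.55 else r2 <= 1
    img[mask] <- geo$val[s]
  }
  if (spec$texture_freq > 0) {
    yy <- matrix(seq_len(H), H, W) / H
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) / W
    u <- cos(geo$tex_dir) * xx + sin(geo$tex_dir) * yy
    img <- img + 0.08 * sin(2 * pi * spec$texture_freq * u + geo$tex_phase)
  }
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed + 1000003L,
                           matrix(stats::rnorm(H * W, sd = spec$noise_sd),
                                  H, W))
  }
  gray_image(pmin(pmax(img, 0), 1))
}

# black -> blue -> green -> yellow -> red, piecewise linear; 0 maps to
# exactly (0,0,0) so thresholded background stays exactly black.
pseudo_color_ramp <- function(a) {
  stops <- c(0, 0.25, 0.5, 0.75, 1)
  rch <- c(0, 0, 0, 1, 1)
  gch <- c(0, 0, 1, 1, 0)
  bch <- c(0, 1, 0, 0, 0)
  v <- as.vector(a)
  cbind(stats::approx(stops, rch, v, rule = 2)$y,
        stats::approx(stops, gch, v, rule = 2)$y,
        stats::approx(stops, bch, v, rule = 2)$y)
}

#' Generate a functional phantom (PET/SPECT surrogate)
#'
#' Smooth Gaussian activity blobs, centered inside the structural anatomy of
#' the same seed, colored with a black-blue-green-yellow-red ramp on an
#' exactly-zero background. At least `background_fraction` of the pixels are
#' exactly (0, 0, 0).
#'
#' @param spec a [phantom_spec()].
#' @return a [color_image()] in RGB space, co-registered with
#'   `make_structural(spec)`.
#' @export
make_functional <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  geo <- phantom_geometry(spec)
  act <- matrix(0, H, W)
  if (spec$n_blobs > 0L) {
    blobs <- with_seed(spec$seed + 2000003L, {
      k <- spec$n_blobs
      if (spec$n_structures > 0L) {
        host <- sample.int(spec$n_structures, k, replace = TRUE)
        th <- stats::runif(k, 0, 2 * pi)
        rr <- sqrt(stats::runif(k)) * 0.7
        list(cy = geo$cy[host] + rr * sin(th) * geo$ry[host],
             cx = geo$cx[host] + rr * cos(th) * geo$rx[host],
             amp = stats::runif(k, 0.6, 1))
      } else {
        list(cy = stats::runif(k, 0.3 * H, 0.7 * H),
             cx = stats::runif(k, 0.3 * W, 0.7 * W),
             amp = stats::runif(k, 0.6, 1))
      }
    })
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (b in seq_len(spec$n_blobs)) {
      d2 <- (yy - blobs$cy[b])^2 + (xx - blobs$cx[b])^2
      act <- act + blobs$amp[b] * exp(-d2 / (2 * spec$blob_sigma^2))
    }
    # enforce the exact-zero background: the background_fraction quantile
    # becomes the zero level, and activity decays smoothly above it
    nz <- ceiling(spec$background_fraction * H * W)
    if (nz >= 1L) {
      thr <- sort(as.vector(act), partial = nz)[nz]
      act <- pmax(act - thr, 0)
    }
    if (max(act) > 0) act <- act / max(act)
  }
  rgb <- pseudo_color_ramp(act)
  color_image(array(pmin(pmax(rgb, 0), 1), c(H, W, 3L)), "RGB")
}

#' Generate a co-registered phantom pair
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `structural` ([gray_image()]) and
#'   `functional` ([color_image()]).
#' @export
make_pair <- function(spec) {
  list(structural = make_structural(spec), functional = make_functional(spec))
}

#' Write a phantom dataset to disk
#'
#' Writes `n` co-registered pairs (seeds `spec$seed + 0:(n-1)`) as 8-bit
#' PNGs plus a tab-separated manifest and the spec as YAML. Byte-identical
#' on regeneration with the same spec.
#'
#' @param spec a [phantom_spec()].
#' @param n number of pairs, >= 1.
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
make_dataset <- function(spec, n, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("make_dataset: cannot create directory %s", out_dir),
         call. = FALSE)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    sj <- spec; sj$seed <- spec$seed + j - 1L
    pair <- make_pair(sj)
    fs <- sprintf("s_%04d.png", j)
    ff <- sprintf("f_%04d.png", j)
    save_image(pair$structural, file.path(out_dir, fs))
    save_image(pair$functional, file.path(out_dir, ff))
    rows[[j]] <- data.frame(pair = j, structural = fs, functional = ff,
                            seed = sj$seed)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(out_dir, "spec.yaml"))
  invisible(manifest)
}

#' Load a phantom dataset written by [make_dataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return list of `fusion_record`s.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf))
    stop(sprintf("load_dataset: no manifest.tsv in %s", dir), call. = FALSE)
  manifest <- utils::read.delim(mf)
  lapply(seq_len(nrow(manifest)), function(j) {
    fusion_record(load_image(file.path(dir, manifest$structural[j])),
                  load_image(file.path(dir, manifest$functional[j])))
  })
}
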