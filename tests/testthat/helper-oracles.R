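# Independent brute-force oracles: everything here is written from the
# defining formulas with explicit per-pixel / per-window loops and its own
# boundary handling, never by calling package internals.

rand_img <- function(H, W = H) matrix(runif(H * W), H, W)

# edge-inclusive mirror index
mirror_idx <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

# correlation of x with an odd square kernel under mirrored borders
oracle_filter <- function(x, kern) {
  H <- nrow(x); W <- ncol(x)
  k <- nrow(kern); p <- (k - 1L) %/% 2L
  out <- matrix(0, H, W)
  off <- seq_len(k) - 1L - p
  for (i in seq_len(H)) {
    ri <- mirror_idx(i + off, H)
    for (j in seq_len(W)) {
      ci <- mirror_idx(j + off, W)
      out[i, j] <- sum(kern * x[ri, ci])
    }
  }
  out
}

oracle_lap_kernel_4 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

oracle_laplacian <- function(x) oracle_filter(x, oracle_lap_kernel_4)

oracle_joint_gradient <- function(m, i) {
  gm <- abs(oracle_laplacian(m))
  gi <- abs(oracle_laplacian(i))
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m)))
    out[r, c] <- max(gm[r, c], gi[r, c])
  out
}

oracle_ag <- function(x) {
  H <- nrow(x); W <- ncol(x)
  total <- 0
  for (h in seq_len(H - 1L)) for (w in seq_len(W - 1L)) {
    dh <- x[h + 1L, w] - x[h, w]
    dw <- x[h, w + 1L] - x[h, w]
    total <- total + sqrt((dh^2 + dw^2) / 4)
  }
  total / ((H - 1L) * (W - 1L))
}

oracle_sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)

oracle_ei <- function(x) {
  sx <- oracle_filter(x, oracle_sobel_x)
  sy <- oracle_filter(x, t(oracle_sobel_x))
  mean(sqrt(sx^2 + sy^2))
}

# universal image quality index of one window pair (population moments)
oracle_q0 <- function(a, f) {
  n <- length(a)
  mu_a <- sum(a) / n; mu_f <- sum(f) / n
  va <- sum((a - mu_a)^2) / n; vf <- sum((f - mu_f)^2) / n
  caf <- sum((a - mu_a) * (f - mu_f)) / n
  d1 <- va + vf; d2 <- mu_a^2 + mu_f^2
  if (d1 > 0 && d2 > 0) 4 * caf * mu_a * mu_f / (d1 * d2)
  else if (d1 == 0 && d2 > 0) 2 * mu_a * mu_f / d2
  else if (d1 > 0) 2 * caf / d1
  else 1
}

oracle_windows <- function(n, size, stride) {
  starts <- seq(1L, n, by = stride)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

oracle_qabf <- function(a, b, f, size = 8L, stride = size) {
  rws <- oracle_windows(nrow(a), size, stride)
  cws <- oracle_windows(ncol(a), size, stride)
  vals <- c()
  for (ri in rws) for (ci in cws) {
    aw <- a[ri, ci]; bw <- b[ri, ci]; fw <- f[ri, ci]
    sa <- sum((aw - mean(aw))^2) / length(aw)
    sb <- sum((bw - mean(bw))^2) / length(bw)
    lam <- if (sa + sb > 0) sa / (sa + sb) else 0.5
    vals <- c(vals, lam * oracle_q0(aw, fw) + (1 - lam) * oracle_q0(bw, fw))
  }
  mean(vals)
}

oracle_gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  outer(g1, g1)
}

oracle_qcv <- function(a, b, f, size = 16L, stride = size, sigma = 1.5,
                       p = 1) {
  gk <- oracle_gauss_kernel(sigma)
  da <- oracle_filter(a - f, gk)
  db <- oracle_filter(b - f, gk)
  ga <- sqrt(oracle_filter(a, oracle_sobel_x)^2 +
             oracle_filter(a, t(oracle_sobel_x))^2)
  gb <- sqrt(oracle_filter(b, oracle_sobel_x)^2 +
             oracle_filter(b, t(oracle_sobel_x))^2)
  rws <- oracle_windows(nrow(a), size, stride)
  cws <- oracle_windows(ncol(a), size, stride)
  num <- 0; den <- 0
  for (ri in rws) for (ci in cws) {
    la <- mean(ga[ri, ci])^p
    lb <- mean(gb[ri, ci])^p
    num <- num + la * mean(da[ri, ci]^2) + lb * mean(db[ri, ci]^2)
    den <- den + la + lb
  }
  if (den > 0) num / den else 0
}

# windowed variance at one pixel under mirrored borders
oracle_window_variance <- function(x, i, j, window) {
  p <- (window - 1L) %/% 2L
  ri <- mirror_idx(i + (-p):p, nrow(x))
  ci <- mirror_idx(j + (-p):p, ncol(x))
  v <- as.vector(x[ri, ci])
  mean(v^2) - mean(v)^2
}

rel_err <- function(x, ref) abs(x - ref) / pmax(1e-12, abs(ref))

# small co-registered phantom record lists for training tests
make_records <- function(n, size = 32L, seed0 = 1L, color = TRUE) {
  lapply(seq_len(n), function(j) {
    sp <- fusegan::phantom_spec(size = c(size, size), seed = seed0 + j - 1L)
    comp <- if (color) fusegan::make_functional(sp)
            else fusegan::rgb_to_ycbcr(fusegan::make_functional(sp))$y
    fusegan::fusion_record(fusegan::make_structural(sp), comp)
  })
}
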