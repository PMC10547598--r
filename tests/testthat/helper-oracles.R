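# Independent reference implementations used as oracles. Deliberately naive
# (loops, enumeration) and kept separate from the package code paths.

# --- colour-space inverses (test-only) ---------------------------------------

hsv_to_rgb_ref <- function(hsv) {
  h <- hsv[1]; s <- hsv[2]; v <- hsv[3]
  c_ <- v * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- v - c_
  rgb1 <- if (h < 60) c(c_, x, 0) else if (h < 120) c(x, c_, 0) else
    if (h < 180) c(0, c_, x) else if (h < 240) c(0, x, c_) else
    if (h < 300) c(x, 0, c_) else c(c_, 0, x)
  (rgb1 + m) * 255
}

lab_to_rgb_ref <- function(lab) {
  white <- c(0.950470, 1.000000, 1.088830)
  fy <- (lab[1] + 16) / 116
  fx <- fy + lab[2] / 500
  fz <- fy - lab[3] / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- c(finv(fx), finv(fy), finv(fz)) * white
  M <- solve(matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE))
  lin <- as.numeric(M %*% xyz)
  u <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  pmin(255, pmax(0, u * 255))
}

# --- metrics by definitional arithmetic --------------------------------------

regression_metrics_ref <- function(y, yhat) {
  e <- yhat - y
  list(mae = sum(abs(e)) / length(e), mse = sum(e^2) / length(e),
       r2 = 1 - sum(e^2) / sum((y - sum(y) / length(y))^2))
}

# --- brute-force K-means (many plain Lloyd restarts) -------------------------

kmeans_bruteforce <- function(X, k, restarts = 60, iters = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  for (r in seq_len(restarts)) {
    C <- X[sample.int(n, k), , drop = FALSE]
    for (it in seq_len(iters)) {
      d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
      lab <- max.col(-d, ties.method = "first")
      newC <- C
      for (j in seq_len(k)) if (any(lab == j)) {
        newC[j, ] <- colMeans(X[lab == j, , drop = FALSE])
      }
      if (max(abs(newC - C)) < 1e-12) { C <- newC; break }
      C <- newC
    }
    d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
    lab <- max.col(-d, ties.method = "first")
    inertia <- sum(pmax(0, d[cbind(seq_len(n), lab)]))
    best <- min(best, inertia)
  }
  best
}

# --- all-point AP by direct PR-curve enumeration -----------------------------

ap_bruteforce <- function(is_tp_sorted, n_gt) {
  n <- length(is_tp_sorted)
  prec <- rec <- numeric(n)
  for (i in seq_len(n)) {
    tp <- sum(is_tp_sorted[1:i])
    prec[i] <- tp / i
    rec[i] <- tp / n_gt
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_len(n)) {
    p_int <- max(prec[i:n])
    ap <- ap + (rec[i] - prev_r) * p_int
    prev_r <- rec[i]
  }
  ap
}

# --- naive Canny reference (loops over pixels) -------------------------------

canny_reference <- function(gray, sigma, low, high, mask) {
  H <- nrow(gray); W <- ncol(gray)
  r <- ceiling(3 * sigma)
  # replicate-padded Gaussian blur, separable, naive loops
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  clampr <- function(i) min(max(i, 1), H)
  clampc <- function(j) min(max(j, 1), W)
  tmp <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (t in -r:r) s <- s + k[t + r + 1] * gray[clampr(i + t), j]
    tmp[i, j] <- s
  }
  sm <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (t in -r:r) s <- s + k[t + r + 1] * tmp[i, clampc(j + t)]
    sm[i, j] <- s
  }
  gx <- gy <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gx[i, j] <- (sm[i, clampc(j + 1)] - sm[i, clampc(j - 1)]) / 2
    gy[i, j] <- (sm[clampr(i + 1), j] - sm[clampr(i - 1), j]) / 2
  }
  mag <- sqrt(gx^2 + gy^2)
  keep <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    a <- (atan2(gy[i, j], gx[i, j]) * 180 / pi) %% 180
    if (a < 22.5 || a >= 157.5) { d1 <- c(0, 1); d2 <- c(0, -1) }
    else if (a < 67.5) { d1 <- c(1, 1); d2 <- c(-1, -1) }
    else if (a < 112.5) { d1 <- c(1, 0); d2 <- c(-1, 0) }
    else { d1 <- c(1, -1); d2 <- c(-1, 1) }
    n1 <- mag[clampr(i + d1[1]), clampc(j + d1[2])]
    n2 <- mag[clampr(i + d2[1]), clampc(j + d2[2])]
    keep[i, j] <- mag[i, j] > n1 && mag[i, j] >= n2
  }
  strong <- keep & mag > high
  weak <- keep & mag > low
  edges <- strong
  repeat {
    changed <- FALSE
    for (i in 1:H) for (j in 1:W) {
      if (weak[i, j] && !edges[i, j]) {
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && edges[ii, jj]) {
            edges[i, j] <- TRUE; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  # 2-px mask boundary exclusion, naive erosion
  interior <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    ok <- TRUE
    for (di in -2:2) for (dj in -2:2) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W || !mask[ii, jj]) ok <- FALSE
    }
    interior[i, j] <- ok
  }
  edges & interior
}

# --- shared fixture builders -------------------------------------------------

empty_det <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), confidence = numeric(0))
}

# seeded random 8-bit RGB array
with_seed_arr <- function(seed, hw) {
  set.seed(seed)
  array(as.double(sample(0:255, prod(hw) * 3, replace = TRUE)),
        dim = c(hw, 3))
}

tiny_scene <- function(colour = 8, mealiness = 0, noise = 0, seed = 1,
                       size = c(96L, 96L), n_roots = 1L,
                       background = c(12, 12, 12)) {
  render_scene(synthetic_spec(image_size = size, n_roots = n_roots,
                              colour_score = colour,
                              mealiness_score = mealiness,
                              background_rgb = background,
                              pixel_noise_sd = noise, seed = seed))
}
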