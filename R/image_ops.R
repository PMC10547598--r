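# Low-level image operators shared by detection, segmentation and texture
# modules. Matrices are H x W with pixel (row, col); all loops are over the
# (small) kernel, never over pixels.

# shift a matrix by (dr, dc), replicating edges
shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian blur, kernel radius ceil(3 sigma), replicate padding
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(m, i - r - 1L, 0L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_replicate(out, 0L, i - r - 1L)
  out2
}

# central-difference gradients (3x3 stencil, replicate edges)
gradient_xy <- function(m) {
  gx <- (shift_replicate(m, 0L, -1L) - shift_replicate(m, 0L, 1L)) / 2
  gy <- (shift_replicate(m, -1L, 0L) - shift_replicate(m, 1L, 0L)) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# binary dilation / erosion with a (2r+1)^2 square structuring element
dilate <- function(bin, r = 1L) {
  out <- matrix(FALSE, nrow(bin), ncol(bin))
  for (dr in -r:r) for (dc in -r:r) {
    out <- out | shift_zero(bin, dr, dc)
  }
  out
}

# erosion treats out-of-bounds pixels as background, so a mask touching the
# image frame is still eroded at the frame
erode <- function(bin, r = 1L) {
  out <- matrix(TRUE, nrow(bin), ncol(bin))
  for (dr in -r:r) for (dc in -r:r) {
    out <- out & shift_zero(bin, dr, dc)
  }
  out
}

# shift with FALSE/0 padding
shift_zero <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(if (is.logical(m)) FALSE else 0, H, W)
  rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[which(rok), which(cok)] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

morph_open <- function(bin, r = 1L) dilate(erode(bin, r), r)
morph_close <- function(bin, r = 1L) erode(dilate(bin, r), r)

#' Label connected components of a binary matrix
#'
#' Breadth-first label propagation; 4- or 8-connectivity.
#'
#' @param bin logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background); attribute
#'   `n_components` carries the component count.
#' @export
label_components <- function(bin, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  todo <- which(bin)
  cur <- 0L
  offs <- if (connectivity == 8L) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  while (length(todo) > 0) {
    seedpix <- todo[1]
    cur <- cur + 1L
    frontier <- seedpix
    lab[seedpix] <- cur
    while (length(frontier) > 0) {
      r0 <- (frontier - 1L) %% H + 1L
      c0 <- (frontier - 1L) %/% H + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r0 + offs$dr[k]; cc <- c0 + offs$dc[k]
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        idx <- (cc[ok] - 1L) * H + rr[ok]
        idx <- idx[bin[idx] & lab[idx] == 0L]
        if (length(idx) > 0) {
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- todo[lab[todo] == 0L]
  }
  attr(lab, "n_components") <- cur
  lab
}

# Otsu threshold on a numeric matrix (256-bin histogram over its range)
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(nb, floor((v - rng[1]) / diff(rng) * nb) + 1L), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# mean over a (2r+1)^2 box, replicate padding
box_mean <- function(m, r = 2L) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -r:r) for (dc in -r:r) out <- out + shift_replicate(m, dr, dc)
  out / (2 * r + 1)^2
}
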