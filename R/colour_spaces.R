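#' RGB to HSV (hexcone model)
#'
#' Hue in degrees \[0, 360); saturation and value in \[0, 1\]. Hue is defined
#' as 0 when saturation is 0 (achromatic input).
#'
#' @param rgb numeric triple with components in \[0, 255\], or an n x 3 matrix.
#' @return numeric triple `(H, S, V)` or an n x 3 matrix.
#' @export
rgb_to_hsv <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  if (ncol(m) != 3 || anyNA(m) || min(m) < 0 || max(m) > 255) {
    abort_rs("rgb components must lie in [0, 255]", "rootsense_input_error")
  }
  x <- m / 255
  v <- pmax(x[, 1], x[, 2], x[, 3])
  mn <- pmin(x[, 1], x[, 2], x[, 3])
  c_ <- v - mn
  s <- ifelse(v > 0, c_ / v, 0)
  h <- numeric(nrow(m))
  nz <- c_ > 0
  r <- x[, 1]; g <- x[, 2]; b <- x[, 3]
  hmax <- max.col(x, ties.method = "first")
  h[nz & hmax == 1] <- 60 * (((g - b) / c_)[nz & hmax == 1] %% 6)
  h[nz & hmax == 2] <- 60 * (((b - r) / c_)[nz & hmax == 2] + 2)
  h[nz & hmax == 3] <- 60 * (((r - g) / c_)[nz & hmax == 3] + 4)
  out <- cbind(H = h %% 360, S = s, V = v)
  if (is.matrix(rgb)) out else drop(out)
}

# sRGB transfer function (IEC 61966-2-1) and its D65 XYZ matrix
srgb_to_linear <- function(u) ifelse(u <= 0.04045, u / 12.92,
                                     ((u + 0.055) / 1.055)^2.4)

.xyz_d65 <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   nrow = 3, byrow = TRUE)
.white_d65 <- c(0.950470, 1.000000, 1.088830)

#' RGB to CIE L*a*b* (sRGB input, D65 illuminant, 2 degree observer)
#'
#' sRGB components are linearised with the IEC 61966-2-1 transfer function,
#' mapped to XYZ under D65, then to L*a*b* against the D65 white point. The
#' DigiEye cabinet that motivates this pipeline uses 6500 K illumination, so
#' D65 is the faithful reference white.
#'
#' @inheritParams rgb_to_hsv
#' @return numeric triple `(L, a, b)` with L in \[0, 100\], or an n x 3 matrix.
#' @export
rgb_to_lab <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  if (ncol(m) != 3 || anyNA(m) || min(m) < 0 || max(m) > 255) {
    abort_rs("rgb components must lie in [0, 255]", "rootsense_input_error")
  }
  lin <- srgb_to_linear(m / 255)
  xyz <- lin %*% t(.xyz_d65)
  xr <- sweep(xyz, 2, .white_d65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xr > eps, xr^(1 / 3), xr / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  out <- cbind(L = L, a = a, b = b)
  if (is.matrix(rgb)) out else drop(out)
}
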