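#' Per-channel RGB histograms of masked pixels
#'
#' Equal-width bins over \[0, 255\]; with the default 256 bins each intensity
#' level gets its own bin. Counts per channel sum to the number of pixels.
#'
#' @param pixels n x 3 matrix of RGB values (0-255).
#' @param bins number of bins.
#' @return 3 x `bins` integer matrix (rows R, G, B).
#' @export
rgb_histogram <- function(pixels, bins = 256L) {
  px <- as.matrix(pixels)
  if (nrow(px) == 0) abort_rs("no pixels to histogram", "rootsense_empty_error")
  w <- 256 / bins
  out <- matrix(0L, 3, bins, dimnames = list(c("R", "G", "B"), NULL))
  for (ch in 1:3) {
    idx <- pmin(bins, floor(px[, ch] / w) + 1L)
    out[ch, ] <- tabulate(idx, nbins = bins)
  }
  out
}

#' Mean RGB of masked pixels
#'
#' @param pixels n x 3 matrix (0-255).
#' @return numeric RGB triple (reals, not rounded).
#' @export
mean_rgb <- function(pixels) {
  px <- as.matrix(pixels)
  if (nrow(px) == 0) abort_rs("no pixels to average", "rootsense_empty_error")
  c(R = mean(px[, 1]), G = mean(px[, 2]), B = mean(px[, 3]))
}

#' Dominant colours by K-means
#'
#' Clusters the masked pixels with the same engine as segmentation and
#' returns centroids with their cluster shares, sorted by descending share.
#'
#' @param pixels n x 3 matrix (0-255).
#' @param k number of colours.
#' @param seed integer seed.
#' @return list with `centroids` (k x 3, ordered) and `proportions`
#'   (descending, summing to 1).
#' @export
dominant_colours <- function(pixels, k = 2L, seed = 1L) {
  px <- as.matrix(pixels)
  if (k == 1L) {
    return(list(centroids = matrix(mean_rgb(px), 1, 3,
                                   dimnames = list(NULL, c("R", "G", "B"))),
                proportions = 1))
  }
  res <- kmeans_pixels(px, k = k, seed = seed)
  prop <- tabulate(res$labels, nbins = k) / nrow(px)
  ord <- order(-prop)
  list(centroids = res$centroids[ord, , drop = FALSE],
       proportions = prop[ord])
}

#' Assemble the colour feature vector of one image
#'
#' Pools all masked pixels of the image (every root in the frame; the panel
#' scores one sample per image) and computes: mean RGB, mean HSV, mean
#' CIELAB, per-channel histograms and the dominant colours. The default model
#' feature row is the 9 colour-space means, in the fixed order
#' `mean_r, mean_g, mean_b, mean_h, mean_s, mean_v, mean_L, mean_a, mean_b_lab`
#' (feature schema `colour-v1`); histograms and dominant colours are carried
#' alongside for exploration.
#'
#' @param image H x W x 3 array (0-255).
#' @param mask logical H x W mask (root pixels TRUE).
#' @param hist_bins histogram bins.
#' @param dominant_k dominant-colour clusters.
#' @param seed seed for the dominant-colour K-means.
#' @return object of class `colour_features` with fields `mean_rgb`,
#'   `mean_hsv`, `mean_lab`, `hist_rgb`, `dominant`, `n_pixels` and
#'   `feature_row` (named numeric vector of length 9).
#' @export
assemble_colour_features <- function(image, mask, hist_bins = 16L,
                                     dominant_k = 2L, seed = 1L) {
  px <- masked_pixels(image, mask)
  if (nrow(px) == 0) abort_rs("mask is empty", "rootsense_empty_error")
  mrgb <- mean_rgb(px)
  mhsv <- colMeans(rgb_to_hsv(px))
  mlab <- colMeans(rgb_to_lab(px))
  # a (near-)uniform root can have fewer distinct colours than dominant_k
  k_eff <- min(dominant_k, nrow(unique(px)))
  dom <- dominant_colours(px, k = k_eff, seed = seed)
  row <- c(mean_r = unname(mrgb[1]), mean_g = unname(mrgb[2]),
           mean_b = unname(mrgb[3]),
           mean_h = unname(mhsv[1]), mean_s = unname(mhsv[2]),
           mean_v = unname(mhsv[3]),
           mean_L = unname(mlab[1]), mean_a = unname(mlab[2]),
           mean_b_lab = unname(mlab[3]))
  structure(list(mean_rgb = mrgb, mean_hsv = mhsv, mean_lab = mlab,
                 hist_rgb = rgb_histogram(px, hist_bins), dominant = dom,
                 n_pixels = nrow(px), feature_row = row,
                 schema = "colour-v1"),
            class = "colour_features")
}
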