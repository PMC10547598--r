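#' Segmentation parameters
#'
#' @param k clusters for the background/root split (the method assumes 2).
#' @param seed integer seed for the K-means restarts.
#' @param n_init restarts.
#' @param max_iter,tol Lloyd controls.
#' @param colour_space `"rgb"` (default, as the capture pipeline implies) or
#'   `"lab"` for clustering in CIELAB.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(k = 2L, seed = 1L, n_init = 5L,
                                max_iter = 100L, tol = 1e-8,
                                colour_space = c("rgb", "lab")) {
  if (k < 2) abort_rs("k must be >= 2", "rootsense_input_error")
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 n_init = as.integer(n_init), max_iter = as.integer(max_iter),
                 tol = tol, colour_space = match.arg(colour_space)),
            class = "segmentation_params")
}

#' Pick the root cluster of a 2-way ROI clustering
#'
#' Inside a correct ROI the background surrounds the root, so the cluster
#' holding the majority of the ROI's border pixels is declared background and
#' the other cluster is the root. An exact border tie is broken toward the
#' higher-saturation centroid (boiled flesh is more saturated than the
#' imaging board).
#'
#' @param labels integer vector of cluster labels for the ROI pixels, in
#'   column-major ROI order.
#' @param centroids k x 3 RGB centroid matrix.
#' @param roi_dim `(height, width)` of the ROI.
#' @return the root cluster index.
#' @export
select_root_cluster <- function(labels, centroids, roi_dim) {
  h <- roi_dim[1]; w <- roi_dim[2]
  lm <- matrix(labels, h, w)
  border <- c(lm[1, ], lm[h, ], lm[, 1], lm[, w])
  counts <- tabulate(border, nbins = nrow(centroids))
  bg <- which(counts == max(counts))
  if (length(bg) > 1) {
    # tie: the background is the *less* saturated of the tied centroids
    sat <- rgb_to_hsv(centroids)[, "S"]
    bg <- bg[which.min(sat[bg])]
  }
  cand <- setdiff(seq_len(nrow(centroids)), bg)
  if (length(cand) == 1) return(cand)
  # k > 2: among non-background clusters return the most saturated
  sat <- rgb_to_hsv(centroids)[, "S"]
  cand[which.max(sat[cand])]
}

#' Eliminate the background inside detected ROIs
#'
#' For each bounding box, clusters the ROI pixels into `k = 2` groups
#' ([kmeans_pixels()]), selects the root cluster by the border-majority rule
#' ([select_root_cluster()]), and unions the per-box root masks. Every pixel
#' outside the final mask (including pixels outside every box) is set to
#' black, mirroring the deployed preprocessing convention.
#'
#' @param image H x W x 3 array (0-255).
#' @param boxes n x 4 matrix of pixel boxes (`x_min, y_min, x_max, y_max`,
#'   0-based half-open).
#' @param params a [segmentation_params()].
#' @return list with `image` (masked copy, background black) and `mask`
#'   (logical H x W).
#' @export
segment_image <- function(image, boxes, params = segmentation_params()) {
  check_image(image)
  boxes <- as.matrix(boxes)
  if (nrow(boxes) == 0) {
    abort_rs("segment_image needs at least one bounding box",
             "rootsense_input_error")
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, 1:4]
    rows <- (b[2] + 1):b[4]
    cols <- (b[1] + 1):b[3]
    roi <- image[rows, cols, , drop = FALSE]
    px <- cbind(as.numeric(roi[, , 1]), as.numeric(roi[, , 2]),
                as.numeric(roi[, , 3]))
    feat <- if (params$colour_space == "lab") rgb_to_lab(px) else px
    res <- tryCatch(
      kmeans_pixels(feat, k = params$k, seed = params$seed,
                    n_init = params$n_init, max_iter = params$max_iter,
                    tol = params$tol),
      rootsense_degenerate_error = function(e) {
        warning(sprintf("box %d skipped: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    cent_rgb <- if (params$colour_space == "lab") {
      # centroid RGB = mean RGB of members (for the saturation tie-break)
      t(vapply(seq_len(params$k), function(j) {
        if (any(res$labels == j)) colMeans(px[res$labels == j, , drop = FALSE])
        else c(0, 0, 0)
      }, numeric(3)))
    } else res$centroids
    root <- select_root_cluster(res$labels, cent_rgb,
                                c(length(rows), length(cols)))
    roi_mask <- matrix(res$labels == root, length(rows), length(cols))
    mask[rows, cols] <- mask[rows, cols] | roi_mask
  }
  out <- image
  for (ch in 1:3) {
    pl <- out[, , ch]; pl[!mask] <- 0; out[, , ch] <- pl
  }
  list(image = out, mask = mask)
}

#' Mask overlap metrics
#'
#' Dice coefficient `2|A∩B| / (|A|+|B|)` and mask IoU `|A∩B| / |A∪B|`.
#' Both are 1 for identical non-empty masks and 0 for disjoint masks;
#' comparing two empty masks is undefined and raises an error.
#'
#' @param a,b logical matrices of equal shape.
#' @return numeric scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_mask(a); check_mask(b)
  if (!identical(dim(a), dim(b))) {
    abort_rs("masks must have equal shapes", "rootsense_input_error")
  }
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) abort_rs("both masks are empty", "rootsense_undefined_error")
  2 * sum(a & b) / (sa + sb)
}

#' @rdname dice
#' @export
iou_mask <- function(a, b) {
  check_mask(a); check_mask(b)
  if (!identical(dim(a), dim(b))) {
    abort_rs("masks must have equal shapes", "rootsense_input_error")
  }
  u <- sum(a | b)
  if (u == 0) abort_rs("both masks are empty", "rootsense_undefined_error")
  sum(a & b) / u
}
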