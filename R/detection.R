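#' Intersection over union of two pixel boxes
#'
#' Boxes are 0-based half-open `(x_min, y_min, x_max, y_max)`, so a box's
#' area is `(x_max - x_min) * (y_max - y_min)` with no off-by-one. Returns 0
#' for disjoint boxes.
#'
#' @param a,b numeric length-4 vectors.
#' @return numeric scalar in \[0, 1\].
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (area <= 0) return(0)
  unname(inter / area)
}

#' Training-free root detector
#'
#' A deterministic classical stand-in for a learned detector, matched to the
#' capture regime (roots brighter and more saturated than a dark uniform
#' board): each pixel's Euclidean RGB distance from the border-estimated
#' background colour is thresholded with Otsu's method, the binary map is
#' cleaned by morphological opening then closing, and connected components
#' become detections. Confidence is each component's mean contrast normalized
#' by the largest component contrast in the image, so it lies in (0, 1\].
#'
#' @param image H x W x 3 array (0-255).
#' @param min_area_frac components smaller than this fraction of the image
#'   area are dropped (speckle guard).
#' @param morph_radius radius of the square structuring element.
#' @return data.frame with columns `x_min, y_min, x_max, y_max, confidence`
#'   (0 rows when nothing is found).
#' @export
detect_roots <- function(image, min_area_frac = 0.001, morph_radius = 1L) {
  check_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < 2 * morph_radius + 1 || W < 2 * morph_radius + 1) {
    abort_rs("image smaller than the morphology kernel", "rootsense_input_error")
  }
  border_idx <- unique(c(seq_len(W) * H, (seq_len(W) - 1) * H + 1,
                         seq_len(H), (W - 1) * H + seq_len(H)))
  bg <- vapply(1:3, function(ch) stats::median(image[, , ch][border_idx]),
               numeric(1))
  contrast <- sqrt((image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 +
                   (image[, , 3] - bg[3])^2)
  if (diff(range(contrast)) < 1e-9) {
    return(empty_detections())
  }
  thr <- otsu_threshold(contrast)
  bin <- contrast > thr
  # a near-uniform image can still produce a "foreground" of pure noise;
  # require the foreground to be meaningfully brighter than the background
  if (mean(contrast[bin]) - mean(contrast[!bin]) < 10) {
    return(empty_detections())
  }
  bin <- morph_close(morph_open(bin, morph_radius), morph_radius)
  lab <- label_components(bin, 8L)
  n <- attr(lab, "n_components")
  if (n == 0) return(empty_detections())
  out <- vector("list", n)
  for (j in seq_len(n)) {
    hit <- lab == j
    area <- sum(hit)
    if (area < min_area_frac * H * W) next
    rows <- range(which(rowSums(hit) > 0))
    cols <- range(which(colSums(hit) > 0))
    out[[j]] <- c(cols[1] - 1, rows[1] - 1, cols[2], rows[2],
                  mean(contrast[hit]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_detections())
  m <- do.call(rbind, out)
  m[, 5] <- m[, 5] / max(m[, 5])
  df <- as.data.frame(m)
  names(df) <- c("x_min", "y_min", "x_max", "y_max", "confidence")
  df[order(-df$confidence), , drop = FALSE]
}

empty_detections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), confidence = numeric(0))
}

#' Evaluate detections against ground truth (single-class mAP)
#'
#' Detections from all images are ranked by confidence (ties broken by larger
#' best-IoU, then input order) and greedily matched one-to-one to ground
#' truth boxes of the same image at `IoU >= iou_threshold`. AP is the area
#' under the precision-recall curve with all-point interpolation; with a
#' single class, mAP = AP.
#'
#' @param detections list (one element per image) of data.frames/matrices
#'   with columns `x_min, y_min, x_max, y_max, confidence`.
#' @param truths list (same length) of ground-truth box matrices.
#' @param iou_threshold match threshold (default 0.5).
#' @return list of class `detection_eval` with `map_at_iou`,
#'   `iou_threshold`, and `per_image` (data.frame of TP/FP/FN counts).
#' @export
evaluate_map <- function(detections, truths, iou_threshold = 0.5) {
  stopifnot(length(detections) == length(truths))
  n_gt <- sum(vapply(truths, function(t) nrow(as.matrix(t)), integer(1)))
  if (n_gt == 0) {
    abort_rs("no ground-truth boxes: recall undefined", "rootsense_undefined_error")
  }
  recs <- list()
  for (i in seq_along(detections)) {
    d <- as.matrix(as.data.frame(detections[[i]]))
    if (nrow(d) == 0) next
    g <- as.matrix(truths[[i]])
    best_iou <- apply(d, 1, function(row) {
      if (nrow(g) == 0) 0 else max(apply(g[, 1:4, drop = FALSE], 1, iou,
                                         a = row[1:4]))
    })
    recs[[length(recs) + 1]] <- data.frame(
      img = i, conf = d[, 5], best_iou = best_iou,
      x_min = d[, 1], y_min = d[, 2], x_max = d[, 3], y_max = d[, 4])
  }
  per_image <- data.frame(image = seq_along(truths), tp = 0L, fp = 0L, fn = 0L)
  if (length(recs) == 0) {
    per_image$fn <- vapply(truths, function(t) nrow(as.matrix(t)), integer(1))
    return(structure(list(map_at_iou = 0, iou_threshold = iou_threshold,
                          per_image = per_image), class = "detection_eval"))
  }
  all <- do.call(rbind, recs)
  ord <- order(-all$conf, -all$best_iou)
  all <- all[ord, , drop = FALSE]
  used <- lapply(truths, function(t) rep(FALSE, nrow(as.matrix(t))))
  tp <- logical(nrow(all))
  for (r in seq_len(nrow(all))) {
    i <- all$img[r]
    g <- as.matrix(truths[[i]])
    if (nrow(g) == 0) next
    ious <- apply(g[, 1:4, drop = FALSE], 1, iou,
                  a = as.numeric(all[r, c("x_min", "y_min", "x_max", "y_max")]))
    ious[used[[i]]] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[r] <- TRUE
      used[[i]][j] <- TRUE
      per_image$tp[i] <- per_image$tp[i] + 1L
    } else {
      per_image$fp[i] <- per_image$fp[i] + 1L
    }
  }
  per_image$fn <- vapply(seq_along(truths), function(i) {
    nrow(as.matrix(truths[[i]])) - per_image$tp[i]
  }, integer(1))
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_gt
  # all-point interpolation: AP = sum over recall steps of interpolated p
  p_interp <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * p_interp)
  structure(list(map_at_iou = ap, iou_threshold = iou_threshold,
                 per_image = per_image), class = "detection_eval")
}
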