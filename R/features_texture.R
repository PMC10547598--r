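#' Luminance grayscale
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B` (ITU-R BT.601 weights), not rounded.
#'
#' @param image H x W x 3 array (0-255).
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(image) {
  check_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Edge-detection parameters
#'
#' These are the hyperparameters that make fixed-threshold edge detection
#' fragile on real roots (edge expression shifts with flesh colour), which is
#' why the default model feature set prefers the smoother graininess
#' statistics; they are exposed so any configuration can be reproduced.
#'
#' @param gaussian_sigma smoothing sigma (px).
#' @param low_threshold,high_threshold hysteresis thresholds on gradient
#'   magnitude (intensity levels per px); low < high required.
#' @param connectivity component connectivity for counting (4 or 8).
#' @return list of class `edge_params`.
#' @export
edge_params <- function(gaussian_sigma = 1.0, low_threshold = 8,
                        high_threshold = 20, connectivity = 8L) {
  if (!is.finite(gaussian_sigma) || gaussian_sigma < 0) {
    abort_rs("gaussian_sigma must be finite and >= 0", "rootsense_input_error")
  }
  if (low_threshold >= high_threshold) {
    abort_rs("low_threshold must be < high_threshold", "rootsense_input_error")
  }
  structure(list(gaussian_sigma = gaussian_sigma,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 connectivity = as.integer(connectivity)),
            class = "edge_params")
}

# non-maximum suppression with gradient direction quantized to 0/45/90/135
nms_quantized <- function(mag, gx, gy) {
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  bin <- integer(length(ang))
  bin[(ang < 22.5) | (ang >= 157.5)] <- 0L   # horizontal gradient -> compare E/W
  bin[ang >= 22.5 & ang < 67.5] <- 1L        # diagonal \
  bin[ang >= 67.5 & ang < 112.5] <- 2L       # vertical gradient -> compare N/S
  bin[ang >= 112.5 & ang < 157.5] <- 3L      # diagonal /
  dim(bin) <- dim(mag)
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  nb <- list(`0` = list(c(0L, 1L), c(0L, -1L)),
             `1` = list(c(1L, 1L), c(-1L, -1L)),
             `2` = list(c(1L, 0L), c(-1L, 0L)),
             `3` = list(c(1L, -1L), c(-1L, 1L)))
  # strict comparison against the forward neighbour resolves exact plateau
  # ties to a single 1-px edge
  for (b in 0:3) {
    o <- nb[[as.character(b)]]
    n1 <- shift_replicate(mag, -o[[1]][1], -o[[1]][2])
    n2 <- shift_replicate(mag, -o[[2]][1], -o[[2]][2])
    keep <- keep | (bin == b & mag > n1 & mag >= n2)
  }
  keep
}

#' Canny edge detection restricted to a mask interior
#'
#' Gaussian smoothing, 3x3 central-difference gradients, non-maximum
#' suppression with the gradient direction quantized to four bins, then
#' double-threshold hysteresis (weak edges kept only when 8-connected to a
#' strong edge). Edges outside the mask or within 2 px of the mask boundary
#' are removed so the root outline never counts as grain.
#'
#' @param gray H x W numeric matrix.
#' @param params an [edge_params()].
#' @param mask logical H x W matrix; `NULL` means the full frame.
#' @return logical H x W edge map, a subset of the 2-px-eroded mask.
#' @export
canny_edges <- function(gray, params = edge_params(), mask = NULL) {
  stopifnot(is.matrix(gray))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  check_mask(mask)
  if (sum(mask) == 0) abort_rs("mask is empty", "rootsense_empty_error")
  r <- ceiling(3 * params$gaussian_sigma)
  if (nrow(gray) < 2 * r + 1 || ncol(gray) < 2 * r + 1) {
    abort_rs("mask/image too small for the smoothing window",
             "rootsense_input_error")
  }
  sm <- gaussian_blur(gray, params$gaussian_sigma)
  g <- gradient_xy(sm)
  thin <- nms_quantized(g$mag, g$gx, g$gy)
  strong <- thin & g$mag > params$high_threshold
  weak <- thin & g$mag > params$low_threshold
  # hysteresis: grow strong edges through weak ones (8-connectivity)
  edges <- strong
  repeat {
    grown <- weak & dilate(edges, 1L)
    if (all(grown == edges)) break
    edges <- grown | strong
  }
  interior <- erode(mask, 2L)
  edges & interior
}

#' Trace closed contours of a binary map
#'
#' Moore-neighbour border following on every 8-connected foreground region;
#' holes (background regions fully enclosed by foreground) are traced as
#' separate contours. Each contour is an m x 2 matrix of (row, col) pixel
#' coordinates forming a closed path (the first pixel is not repeated).
#'
#' @param bin logical matrix.
#' @return list of contour matrices (empty list for an empty map).
#' @export
find_contours <- function(bin) {
  check_mask(bin)
  out <- list()
  lab <- label_components(bin, 8L)
  for (j in seq_len(attr(lab, "n_components"))) {
    out[[length(out) + 1]] <- trace_boundary(lab == j)
  }
  # holes: 4-connected background components that never touch the border
  bg <- label_components(!bin, 4L)
  nb <- attr(bg, "n_components")
  if (nb > 0) {
    H <- nrow(bin); W <- ncol(bin)
    border_labs <- unique(c(bg[1, ], bg[H, ], bg[, 1], bg[, W]))
    for (j in setdiff(seq_len(nb), border_labs)) {
      out[[length(out) + 1]] <- trace_boundary(bg == j)
    }
  }
  out
}

# Moore-neighbour tracing of one connected region's outer boundary
trace_boundary <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  idx <- which(comp)
  rs <- (idx - 1L) %% H + 1L
  cs <- (idx - 1L) %/% H + 1L
  # raster-scan start: smallest row, then smallest col
  o <- order(rs, cs)[1]
  start <- c(rs[o], cs[o])
  # clockwise Moore neighbourhood starting W
  dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(p) p[1] >= 1 && p[1] <= H && p[2] >= 1 && p[2] <= W
  fg <- function(p) inside(p) && comp[p[1], p[2]]
  path <- matrix(start, 1, 2)
  cur <- start
  back_dir <- 1L  # came "from the west"
  max_steps <- 4L * (length(idx) + 4L)
  first_move <- NULL
  for (step in seq_len(max_steps)) {
    found <- FALSE
    for (t in 0:7) {
      d <- ((back_dir - 1L + t) %% 8L) + 1L
      cand <- cur + dirs[d, ]
      if (fg(cand)) {
        # next backtrack direction: one step counter-clockwise of where we
        # found the pixel, relative to the new pixel
        back_dir <- ((d - 1L + 4L + 1L) %% 8L) + 1L
        cur <- cand
        found <- TRUE
        if (is.null(first_move)) first_move <- d
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start)) break
    path <- rbind(path, cur)
  }
  dimnames(path) <- list(NULL, c("row", "col"))
  path
}

#' Graininess statistics of a masked root
#'
#' The image-texture surrogate for mealiness: within the 2-px-eroded mask
#' interior it computes the Canny edge density (edge pixels / interior
#' pixels), the count of 8-connected edge components, the mean gradient
#' magnitude of the smoothed luminance, and the mean 5x5 local variance.
#' All four are non-decreasing in the generator's mealiness when
#' seed-averaged. The default model feature row (`texture-v1`) is the three
#' smooth statistics; the raw component count is reported but excluded by
#' default because it is the least stable under threshold choice.
#'
#' @param image H x W x 3 array.
#' @param mask logical root mask.
#' @param params an [edge_params()].
#' @return object of class `texture_features` with fields `edge_density`,
#'   `component_count`, `mean_gradient_magnitude`, `local_variance_mean` and
#'   `feature_row` (length 3, named).
#' @export
graininess_features <- function(image, mask, params = edge_params()) {
  check_image(image); check_mask(mask, image)
  if (sum(mask) == 0) abort_rs("mask is empty", "rootsense_empty_error")
  gray <- to_grayscale(image)
  # neutralize everything outside the mask so the statistics depend only on
  # root pixels (background is replaced by the mean masked luminance, which
  # also keeps the root outline from leaking gradient into the interior)
  gray[!mask] <- mean(gray[mask])
  interior <- erode(mask, 2L)
  edges <- canny_edges(gray, params, mask)
  n_int <- max(1L, sum(interior))
  density <- sum(edges) / n_int
  lab <- label_components(edges, params$connectivity)
  sm <- gaussian_blur(gray, params$gaussian_sigma)
  g <- gradient_xy(sm)
  mg <- if (sum(interior) > 0) mean(g$mag[interior]) else 0
  mu <- box_mean(gray, 2L)
  mu2 <- box_mean(gray^2, 2L)
  lv <- pmax(0, mu2 - mu^2)
  lvm <- if (sum(interior) > 0) mean(lv[interior]) else 0
  structure(list(edge_density = density,
                 component_count = attr(lab, "n_components"),
                 mean_gradient_magnitude = mg,
                 local_variance_mean = lvm,
                 feature_row = c(edge_density = density,
                                 mean_gradient_magnitude = mg,
                                 local_variance_mean = lvm),
                 schema = "texture-v1"),
            class = "texture_features")
}

# ---- embedding provider registry ------------------------------------------

.embedding_registry <- new.env(parent = emptyenv())

#' Pluggable image-embedding providers
#'
#' Stand-in for pretrained-CNN feature extraction: a provider is a function
#' `(image, mask) -> numeric vector` of fixed length. The built-in
#' `"handcrafted"` provider needs no network or weights: it concatenates the
#' 9 colour-space means, the 3 smooth graininess statistics and a 16-bin
#' grey-level histogram (proportions over the mask), length 28. Adapters for
#' real backbones can be registered at run time.
#'
#' @param name provider name.
#' @param fn function `(image, mask)` returning a fixed-length numeric vector.
#' @export
register_embedding_provider <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .embedding_registry)
  invisible(name)
}

#' @rdname register_embedding_provider
#' @param image,mask the masked root image.
#' @param provider registered provider name.
#' @return numeric vector with attributes `provider` and `length`.
#' @export
extract_embedding <- function(image, mask, provider = "handcrafted") {
  if (!exists(provider, envir = .embedding_registry, inherits = FALSE)) {
    abort_rs(paste0("unregistered embedding provider: ", provider),
             "rootsense_config_error")
  }
  fn <- get(provider, envir = .embedding_registry)
  v <- fn(image, mask)
  attr(v, "provider") <- provider
  attr(v, "length") <- length(v)
  v
}

handcrafted_embedding <- function(image, mask) {
  cf <- assemble_colour_features(image, mask)
  tf <- graininess_features(image, mask)
  gray <- to_grayscale(image)
  gh <- tabulate(pmin(16L, floor(gray[mask] / 16) + 1L), nbins = 16L)
  unname(c(cf$feature_row, tf$feature_row, gh / sum(gh)))
}

.onLoad <- function(libname, pkgname) {
  register_embedding_provider("handcrafted", handcrafted_embedding)
}
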