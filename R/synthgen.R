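#' Specification of a synthetic boiled-root scene
#'
#' The generator emulates what a calibrated imaging cabinet sees after a root
#' cross-section is photographed on a dark board: one or more smooth convex
#' root blobs whose fill colour encodes a flesh-colour score on the 0-10
#' anchor scale, a speckle texture whose density and contrast encode a
#' mealiness score, a uniform near-black background, and i.i.d. Gaussian
#' pixel noise. Every render carries exact ground truth (mask, boxes,
#' scores), which is what makes the downstream stages testable offline.
#'
#' @param image_size integer `(height, width)` in pixels.
#' @param n_roots number of roots to place (>= 1); roots never overlap.
#' @param colour_score flesh-colour score in \[0, 10\].
#' @param mealiness_score mealiness score in \[0, 10\].
#' @param background_rgb background colour; default near-black, matching the
#'   post-segmentation convention of converting background to black.
#' @param pixel_noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity levels, applied per channel then clipped to \[0, 255\]).
#' @param include_label_patch add a small bright distractor rectangle (a
#'   stand-in for a sample label card) that is *not* part of the ground truth.
#' @param seed integer RNG seed; renders are bit-identical for a fixed spec.
#' @param scale the [colour_scale()] used to paint the root.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(128L, 128L), n_roots = 1L,
                           colour_score = 5, mealiness_score = 5,
                           background_rgb = c(12, 12, 12),
                           pixel_noise_sd = 5, include_label_patch = FALSE,
                           seed = 1L, scale = colour_scale()) {
  if (colour_score < 0 || colour_score > 10 ||
      mealiness_score < 0 || mealiness_score > 10) {
    abort_rs("scores must lie in [0, 10]", "rootsense_domain_error")
  }
  if (n_roots < 1) abort_rs("n_roots must be >= 1", "rootsense_domain_error")
  if (pixel_noise_sd < 0) {
    abort_rs("pixel_noise_sd must be >= 0", "rootsense_domain_error")
  }
  structure(list(image_size = as.integer(image_size), n_roots = as.integer(n_roots),
                 colour_score = colour_score, mealiness_score = mealiness_score,
                 background_rgb = background_rgb, pixel_noise_sd = pixel_noise_sd,
                 include_label_patch = isTRUE(include_label_patch),
                 seed = as.integer(seed), scale = scale),
            class = "synthetic_spec")
}

#' Map a mealiness score to speckle-grain parameters
#'
#' Mealiness is scored by hand (how readily the boiled flesh crumbles when
#' rubbed) and correlates visually with surface graininess. The generator
#' encodes it with two affine maps:
#' \deqn{density(m) = 0.004 \, m \ \mathrm{px}^{-2}, \qquad
#'       contrast(m) = 6 \, m \ \mathrm{levels}.}
#' Both are non-decreasing in mealiness and zero speckle density at
#' mealiness 0 gives a perfectly smooth root. The slopes are a generator
#' convention (a controllable monotone signal), not a biological claim.
#'
#' @param mealiness numeric scalar in \[0, 10\].
#' @return list with `density` (speckles per px^2) and `contrast`
#'   (intensity levels).
#' @export
mealiness_to_grain <- function(mealiness) {
  if (!is.numeric(mealiness) || length(mealiness) != 1 ||
      !is.finite(mealiness) || mealiness < 0 || mealiness > 10) {
    abort_rs("mealiness must be a single value in [0, 10]",
             "rootsense_domain_error")
  }
  list(density = 0.004 * mealiness, contrast = 6 * mealiness)
}

# radial multiplier of a perturbed ellipse: 1 + sum_k amp_k cos(k theta + ph_k)
blob_radial <- function(theta, amps, phases, ks) {
  s <- rep(1, length(theta))
  for (j in seq_along(ks)) s <- s + amps[j] * cos(ks[j] * theta + phases[j])
  s
}

# sample non-overlapping blob geometries; error after bounded retries
place_blobs <- function(H, W, n_roots) {
  # multi-root scenes use smaller blobs so non-overlapping placement stays
  # feasible; whole-scene placement restarts up to 25 times
  for (restart in 1:25) {
    res <- tryCatch(place_blobs_once(H, W, n_roots),
                    rootsense_placement_error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  abort_rs("could not place roots without overlap after 200 retries",
           "rootsense_placement_error")
}

place_blobs_once <- function(H, W, n_roots) {
  blobs <- list()
  boxes <- matrix(numeric(0), ncol = 4)
  base <- 0.30 * min(H, W) / sqrt(n_roots)
  if (n_roots > 1) base <- base * 0.85
  for (i in seq_len(n_roots)) {
    ok <- FALSE
    for (try in 1:200) {
      a <- base * runif(1, 0.8, 1.1)
      b <- a * runif(1, 0.75, 1.0)
      phi <- runif(1, 0, pi)
      amps <- runif(3, 0.01, 0.05)
      phases <- runif(3, 0, 2 * pi)
      rmax <- max(a, b) * (1 + sum(amps))
      cx <- runif(1, rmax + 2, W - rmax - 2)
      cy <- runif(1, rmax + 2, H - rmax - 2)
      cand <- c(cx - rmax, cy - rmax, cx + rmax, cy + rmax)
      clash <- FALSE
      if (nrow(boxes) > 0) {
        for (r in seq_len(nrow(boxes))) {
          if (cand[1] < boxes[r, 3] + 3 && cand[3] > boxes[r, 1] - 3 &&
              cand[2] < boxes[r, 4] + 3 && cand[4] > boxes[r, 2] - 3) {
            clash <- TRUE; break
          }
        }
      }
      if (!clash) {
        boxes <- rbind(boxes, cand)
        blobs[[i]] <- list(cx = cx, cy = cy, a = a, b = b, phi = phi,
                           amps = amps, phases = phases, ks = c(2L, 3L, 4L))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort_rs("could not place roots without overlap after 200 retries",
               "rootsense_placement_error")
    }
  }
  blobs
}

# logical mask of one blob on an H x W grid (pixel centres at integer coords)
blob_mask <- function(blob, H, W) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - blob$cx
  ys <- matrix(rep(seq_len(H), W), H, W) - blob$cy
  u <- cos(blob$phi) * xs + sin(blob$phi) * ys
  v <- -sin(blob$phi) * xs + cos(blob$phi) * ys
  rho <- sqrt((u / blob$a)^2 + (v / blob$b)^2)
  theta <- atan2(v / blob$b, u / blob$a)
  rho <= blob_radial(theta, blob$amps, blob$phases, blob$ks)
}

# analytic area of a perturbed ellipse: pi a b (1 + sum amp^2 / 2)
blob_area <- function(blob) {
  pi * blob$a * blob$b * (1 + sum(blob$amps^2) / 2)
}

#' Render a synthetic scene with exact ground truth
#'
#' Deterministic for a fixed spec (the spec's `seed` drives all randomness;
#' the caller's RNG state is untouched). Roots are filled with
#' `round(colour_score_to_rgb(colour_score))`, speckled according to
#' [mealiness_to_grain()] with balanced bright/dark speckles (so the mean
#' colour over the mask is approximately score-faithful even for mealy
#' roots), then Gaussian noise is added and the result clipped to \[0, 255\]
#' and rounded.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `image` (H x W x 3 integer-valued array) and `truth`,
#'   itself a list: `boxes` (n x 4 matrix of 0-based half-open
#'   `x_min,y_min,x_max,y_max`), `mask` (logical H x W), `colour_score`,
#'   `mealiness_score`, `fill_rgb` (the rounded fill colour) and
#'   `analytic_area` (per-root blob areas in px^2).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(spec$seed, {
    blobs <- place_blobs(H, W, spec$n_roots)
    fill <- round(colour_score_to_rgb(spec$colour_score, spec$scale))
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch]
    mask <- matrix(FALSE, H, W)
    boxes <- matrix(0L, spec$n_roots, 4,
                    dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
    for (i in seq_along(blobs)) {
      m <- blob_mask(blobs[[i]], H, W)
      mask <- mask | m
      rows <- range(which(rowSums(m) > 0))
      cols <- range(which(colSums(m) > 0))
      boxes[i, ] <- c(cols[1] - 1L, rows[1] - 1L, cols[2], rows[2])
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[m] <- fill[ch]; img[, , ch] <- pl
      }
    }
    # speckle grain: balanced +/- contrast discs at random mask positions
    grain <- mealiness_to_grain(spec$mealiness_score)
    n_speck <- round(grain$density * sum(mask))
    if (n_speck > 0) {
      centres <- sample(which(mask), n_speck, replace = n_speck > sum(mask))
      signs <- rep_len(c(1, -1), n_speck)[sample.int(n_speck)]
      radii <- sample(c(1, 1.5), n_speck, replace = TRUE)
      rs <- (centres - 1L) %% H + 1L
      cs <- (centres - 1L) %/% H + 1L
      bump <- matrix(0, H, W)
      for (j in seq_len(n_speck)) {
        rr <- max(1, rs[j] - 1):min(H, rs[j] + 1)
        cc <- max(1, cs[j] - 1):min(W, cs[j] + 1)
        dd <- outer((rr - rs[j])^2, (cc - cs[j])^2, "+")
        hit <- dd <= radii[j]^2
        bump[rr, cc][hit] <- bump[rr, cc][hit] + signs[j] * grain$contrast
      }
      bump[!mask] <- 0
      for (ch in 1:3) img[, , ch] <- img[, , ch] + bump
    }
    if (spec$include_label_patch) {
      ph <- max(6L, round(0.1 * H)); pw <- max(10L, round(0.16 * W))
      # top-left corner, kept clear of roots by construction margin
      img[2:(1 + ph), 2:(1 + pw), 1] <- 245
      img[2:(1 + ph), 2:(1 + pw), 2] <- 245
      img[2:(1 + ph), 2:(1 + pw), 3] <- 245
    }
    if (spec$pixel_noise_sd > 0) {
      img <- img + array(rnorm(H * W * 3, 0, spec$pixel_noise_sd),
                         dim = c(H, W, 3))
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img,
         truth = list(boxes = boxes, mask = mask,
                      colour_score = spec$colour_score,
                      mealiness_score = spec$mealiness_score,
                      fill_rgb = fill,
                      analytic_area = vapply(blobs, blob_area, numeric(1))))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG scenes plus, per image, a ground-truth mask PNG and a
#' normalized centre-format annotation file, and two CSVs: the ground-truth
#' table (`image, variety, colour_score, mealiness_score`) and a manifest
#' listing every path. Fully reproducible for a fixed seed.
#'
#' @param n_images number of images (>= 1).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @param score_distribution list of two samplers `colour(n)` and
#'   `mealiness(n)`; defaults draw both uniformly on \[0, 10\].
#' @param image_size,n_roots,pixel_noise_sd,include_label_patch passed to
#'   [synthetic_spec()].
#' @param scale the [colour_scale()].
#' @return the manifest as a data.frame (also written to
#'   `out_dir/manifest.csv`), invisibly.
#' @export
generate_dataset <- function(n_images, out_dir, seed = 1L,
                             score_distribution = list(
                               colour = function(n) stats::runif(n, 0, 10),
                               mealiness = function(n) stats::runif(n, 0, 10)),
                             image_size = c(128L, 128L), n_roots = 1L,
                             pixel_noise_sd = 5, include_label_patch = FALSE,
                             scale = colour_scale()) {
  if (n_images < 1) abort_rs("n_images must be >= 1", "rootsense_domain_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort_rs(paste0("cannot create output directory: ", out_dir),
             "rootsense_io_error")
  }
  scores <- with_seed(seed, {
    list(colour = score_distribution$colour(n_images),
         mealiness = score_distribution$mealiness(n_images))
  })
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- synthetic_spec(image_size = image_size, n_roots = n_roots,
                         colour_score = scores$colour[i],
                         mealiness_score = scores$mealiness[i],
                         pixel_noise_sd = pixel_noise_sd,
                         include_label_patch = include_label_patch,
                         seed = seed + i, scale = scale)
    sc <- render_scene(sp)
    img_path <- file.path(out_dir, sprintf("synth_%04d.png", i))
    mask_path <- file.path(out_dir, sprintf("synth_%04d_mask.png", i))
    ann_path <- file.path(out_dir, sprintf("synth_%04d.txt", i))
    write_image(sc$image, img_path)
    write_mask(sc$truth$mask, mask_path)
    write_annotations(sc$truth$boxes, image_size, ann_path)
    rows[[i]] <- data.frame(
      image = img_path, mask = mask_path, annotation = ann_path,
      variety = sprintf("SYNTH-%04d", i),
      colour_score = scores$colour[i],
      mealiness_score = scores$mealiness[i],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  gt <- data.frame(image = basename(manifest$image),
                   variety = manifest$variety,
                   colour_score = manifest$colour_score,
                   mealiness_score = manifest$mealiness_score)
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
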