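#' The 0-10 flesh-colour anchor scale
#'
#' Trained sensory panels score boiled sweetpotato flesh-colour intensity on a
#' discrete 0-10 scale with six named anchors: 0 = white, 1 = cream,
#' 3 = yellow, 5 = yellow-orange, 8 = orange and 10 = deep orange. The panel
#' protocol defines the anchors verbally, not colorimetrically, so the RGB
#' triple attached to each anchor here is a package default chosen to be
#' plausible for boiled root flesh; only the ordering of the anchors carries
#' meaning and the palette is fully configurable.
#'
#' @param anchors named list or 6 x 3 matrix mapping the class codes
#'   `0,1,3,5,8,10` to RGB triples (0-255). Default palette documented below.
#' @return an object of class `colour_scale` with components `codes`
#'   (integer vector), `names` (anchor names) and `rgb` (6 x 3 matrix).
#' @examples
#' sc <- colour_scale()
#' colour_score_to_rgb(8, sc)   # the orange anchor
#' @export
colour_scale <- function(anchors = NULL) {
  codes <- c(0L, 1L, 3L, 5L, 8L, 10L)
  nm <- c("white", "cream", "yellow", "yellow-orange", "orange", "deep orange")
  default <- rbind(
    c(235, 231, 222),  # white
    c(238, 222, 180),  # cream
    c(240, 205,  90),  # yellow
    c(238, 170,  60),  # yellow-orange
    c(230, 125,  35),  # orange
    c(200,  85,  20)   # deep orange
  )
  rgbm <- if (is.null(anchors)) default else {
    m <- if (is.list(anchors)) do.call(rbind, anchors) else as.matrix(anchors)
    if (!identical(dim(m), c(6L, 3L))) {
      abort_rs("anchors must provide exactly six RGB triples",
               "rootsense_input_error")
    }
    m
  }
  storage.mode(rgbm) <- "double"
  if (min(rgbm) < 0 || max(rgbm) > 255) {
    abort_rs("anchor RGB components must lie in [0, 255]",
             "rootsense_input_error")
  }
  dimnames(rgbm) <- list(nm, c("R", "G", "B"))
  structure(list(codes = codes, names = nm, rgb = rgbm),
            class = "colour_scale")
}

#' Map a continuous flesh-colour score to an RGB triple
#'
#' Returns the anchor colour exactly when `score` equals an anchor code and
#' interpolates linearly (per channel) between the two bracketing anchors
#' otherwise. Used by the synthetic generator to paint roots of known score.
#'
#' @param score numeric scalar in \[0, 10\].
#' @param scale a [colour_scale()].
#' @return numeric RGB triple (not rounded).
#' @export
colour_score_to_rgb <- function(score, scale = colour_scale()) {
  if (!is.numeric(score) || length(score) != 1 || !is.finite(score) ||
      score < 0 || score > 10) {
    abort_rs("score must be a single value in [0, 10]", "rootsense_domain_error")
  }
  codes <- scale$codes
  if (score %in% codes) {
    return(unname(scale$rgb[match(score, codes), ]))
  }
  hi <- which(codes > score)[1]
  lo <- hi - 1L
  t <- (score - codes[lo]) / (codes[hi] - codes[lo])
  unname(scale$rgb[lo, ] + t * (scale$rgb[hi, ] - scale$rgb[lo, ]))
}

#' Snap a continuous score to the nearest anchor class code
#'
#' Classification targets use the discrete class codes `{0,1,3,5,8,10}`.
#' Exact midpoints between two codes round toward the lower (paler) code.
#'
#' @param score finite numeric scalar (or vector).
#' @inheritParams colour_score_to_rgb
#' @return integer class code(s).
#' @export
nearest_scale_class <- function(score, scale = colour_scale()) {
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score))) {
    abort_rs("score must be finite", "rootsense_domain_error")
  }
  codes <- scale$codes
  vapply(score, function(s) {
    d <- abs(codes - s)
    # which.min takes the first minimum: codes are ascending, so exact ties
    # already resolve toward the lower code
    codes[which.min(d)]
  }, integer(1))
}
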