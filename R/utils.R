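#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_rs <- function(msg, class) {
  stop(structure(class = c(class, "rootsense_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate an RGB image array
#'
#' @param image object to check: numeric H x W x 3 array, values in 0..255.
#' @return the image, invisibly
#' @noRd
check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort_rs("image must be an H x W x 3 array", "rootsense_input_error")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    abort_rs("image values must be finite and within [0, 255]",
             "rootsense_input_error")
  }
  invisible(image)
}

check_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_rs("mask must be a logical matrix", "rootsense_input_error")
  }
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2])) {
    abort_rs("mask and image dimensions differ", "rootsense_input_error")
  }
  invisible(mask)
}

#' Pixels of an image under a mask as an n x 3 matrix
#' @noRd
masked_pixels <- function(image, mask) {
  check_image(image); check_mask(mask, image)
  cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
}
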