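#' Read an 8-bit RGB image
#'
#' Supports PNG, JPEG and plain uncompressed TIFF. Returns an H x W x 3
#' numeric array of integers in \[0, 255\], channel order R, G, B. Greyscale
#' inputs are replicated to three channels; an alpha channel is dropped.
#'
#' @param path image path; format chosen by extension.
#' @return H x W x 3 array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort_rs(paste0("image file not found: ", path), "rootsense_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw01 <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) abort_rs(
                     paste0("cannot decode PNG ", path, ": ", conditionMessage(e)),
                     "rootsense_io_error")),
    jpg = ,
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) abort_rs(
                      paste0("cannot decode JPEG ", path, ": ", conditionMessage(e)),
                      "rootsense_io_error")),
    tif = ,
    tiff = return(read_tiff_minimal(path)),
    abort_rs(paste0("unsupported image format: .", ext), "rootsense_io_error")
  )
  if (length(dim(raw01)) == 2) {
    img <- array(0, c(dim(raw01), 3))
    for (ch in 1:3) img[, , ch] <- raw01
  } else {
    img <- raw01[, , 1:3, drop = FALSE]
  }
  round(img * 255)
}

#' Write an 8-bit RGB image (PNG, JPEG or plain TIFF)
#'
#' @param image H x W x 3 array with values in \[0, 255\].
#' @param path destination; format chosen by extension. JPEG is lossy
#'   (quality 0.95); PNG and TIFF round-trip bit-exactly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  ext <- tolower(tools::file_ext(path))
  x <- round(image) / 255
  switch(ext,
    png = png::writePNG(x, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(x, path, quality = 0.95),
    tif = ,
    tiff = write_tiff_minimal(image, path),
    abort_rs(paste0("unsupported image format: .", ext), "rootsense_io_error")
  )
  invisible(path)
}

#' Write / read a binary mask as a single-channel PNG (0/255)
#' @param mask logical matrix.
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

# canonical sensory columns and accepted aliases (normalized form)
.sensory_aliases <- list(
  variety_name = c("variety_name", "variety", "genotype", "name"),
  flesh_colour_mean = c("flesh_colour_mean", "flesh_colour", "flesh_color",
                        "flesh_colour_intensity", "colour", "color"),
  mealiness_by_hand_mean = c("mealiness_by_hand_mean", "mealiness_by_hand",
                             "mealiness"),
  positive_force_1r = c("positive_force_1r", "positive_force", "force_1r",
                        "positive_peak_force")
)

normalize_colname <- function(x) {
  x <- tolower(trimws(x))
  gsub("_+", "_", gsub("[^a-z0-9]+", "_", x))
}

#' Read a sensory ground-truth table
#'
#' Expects a CSV with one row per variety and columns for the variety name,
#' mean flesh-colour score, mean mealiness-by-hand score and positive force
#' 1R. Column names are matched case-insensitively against documented
#' aliases (e.g. "Mealiness by hand" -> `mealiness_by_hand_mean`). Scores
#' must lie in \[0, 10\] and force must be non-negative; violations raise a
#' row-level error naming the offending rows.
#'
#' @param path CSV path.
#' @return data.frame with columns `variety_name`, `flesh_colour_mean`,
#'   `mealiness_by_hand_mean`, `positive_force_1r`.
#' @export
read_sensory_table <- function(path) {
  if (!file.exists(path)) {
    abort_rs(paste0("sensory table not found: ", path), "rootsense_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nn <- normalize_colname(names(df))
  out <- list()
  for (canon in names(.sensory_aliases)) {
    hit <- which(nn %in% .sensory_aliases[[canon]])
    if (length(hit) == 0) {
      abort_rs(paste0("missing required column: ", canon,
                      " (aliases: ", paste(.sensory_aliases[[canon]], collapse = ", "), ")"),
               "rootsense_schema_error")
    }
    out[[canon]] <- df[[hit[1]]]
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(out)
  for (col in names(.sensory_aliases)[-1]) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & out[[col]] != "")
    if (length(bad) > 0) {
      abort_rs(paste0("unparsable numeric in column ", col, ", row(s): ",
                      paste(bad, collapse = ", ")), "rootsense_parse_error")
    }
    out[[col]] <- v
  }
  bad <- which(out$flesh_colour_mean < 0 | out$flesh_colour_mean > 10 |
               out$mealiness_by_hand_mean < 0 | out$mealiness_by_hand_mean > 10 |
               out$positive_force_1r < 0)
  if (length(bad) > 0) {
    abort_rs(paste0("out-of-range sensory values in row(s): ",
                    paste(bad, collapse = ", ")), "rootsense_parse_error")
  }
  out
}

#' Read / write bounding-box annotations (normalized centre format)
#'
#' One object per line: `class_id cx cy w h`, all four geometry values
#' normalized to \[0, 1\] by image width (x) and height (y). Pixel boxes use
#' 0-based half-open coordinates `(x_min, y_min, x_max, y_max)`; the round
#' trip through a file preserves normalized values to 6 decimals, which for
#' any image under ~100k pixels per side recovers integer pixel boxes
#' exactly.
#'
#' @param path annotation file path.
#' @param image_size integer `(height, width)`.
#' @param boxes n x 4 matrix of pixel boxes (columns
#'   `x_min, y_min, x_max, y_max`); an optional 5th column `confidence` is
#'   written as a 6th field and read back when present.
#' @param class_id integer class written on each line (single class: 0).
#' @return `read_annotations`: n x 4 (or n x 5 with confidence) matrix of
#'   pixel boxes; `write_annotations`: the path, invisibly.
#' @export
read_annotations <- function(path, image_size) {
  if (!file.exists(path)) {
    abort_rs(paste0("annotation file not found: ", path), "rootsense_io_error")
  }
  H <- image_size[1]; W <- image_size[2]
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max"))))
  }
  parse_line <- function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) < 5 || anyNA(f)) {
      abort_rs(paste0("malformed annotation line ", i, ": ", lines[i]),
               "rootsense_parse_error")
    }
    g <- f[2:5]
    lo <- c(f[2] - f[4] / 2, f[3] - f[5] / 2)
    hi <- c(f[2] + f[4] / 2, f[3] + f[5] / 2)
    if (any(g < 0 | g > 1) || any(lo < -1e-6) || any(hi > 1 + 1e-6)) {
      abort_rs(paste0("annotation values outside [0,1] at line ", i),
               "rootsense_validation_error")
    }
    box <- c(round((f[2] - f[4] / 2) * W), round((f[3] - f[5] / 2) * H),
             round((f[2] + f[4] / 2) * W), round((f[3] + f[5] / 2) * H))
    if (length(f) >= 6) c(box, f[6]) else box
  }
  rows <- lapply(seq_along(lines), parse_line)
  ncol_out <- max(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r) c(r, rep(NA, ncol_out - length(r)))))
  colnames(m) <- c("x_min", "y_min", "x_max", "y_max",
                   if (ncol_out == 5) "confidence")
  m
}

#' @rdname read_annotations
#' @export
write_annotations <- function(boxes, image_size, path, class_id = 0L) {
  H <- image_size[1]; W <- image_size[2]
  boxes <- as.matrix(boxes)
  lines <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    cx <- (b[1] + b[3]) / 2 / W; cy <- (b[2] + b[4]) / 2 / H
    w <- (b[3] - b[1]) / W; h <- (b[4] - b[2]) / H
    base <- sprintf("%d %.6f %.6f %.6f %.6f", class_id, cx, cy, w, h)
    lines[i] <- if (ncol(boxes) >= 5 && !is.na(b[5])) {
      paste0(base, sprintf(" %.6f", b[5]))
    } else base
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write batch prediction results as CSV
#'
#' One row per image: image name, the extracted mean RGB (three integer
#' columns), the predicted score, image height and width, and the attribute
#' predicted — the download format of the deployed prediction tool.
#'
#' @param records data.frame with columns `image_name`, `mean_r`, `mean_g`,
#'   `mean_b`, `predicted_score`, `height`, `width`, `attribute`.
#' @param path output CSV path.
#' @export
write_predictions_csv <- function(records, path) {
  needed <- c("image_name", "mean_r", "mean_g", "mean_b",
              "predicted_score", "height", "width", "attribute")
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_rs("records must be a non-empty data.frame", "rootsense_input_error")
  }
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort_rs(paste0("prediction records missing column(s): ",
                    paste(missing, collapse = ", ")), "rootsense_schema_error")
  }
  out <- records[needed]
  out$mean_r <- as.integer(round(out$mean_r))
  out$mean_g <- as.integer(round(out$mean_g))
  out$mean_b <- as.integer(round(out$mean_b))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
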