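# Minimal baseline TIFF codec (uncompressed 8-bit grey/RGB, single plane).
# The environment ships no TIFF package; this covers the plain uncompressed
# files the pipeline needs and rejects anything fancier with a clear error.

read_tiff_minimal <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 4)
  little <- identical(hdr[1:2], as.raw(c(0x49, 0x49)))
  if (!little && !identical(hdr[1:2], as.raw(c(0x4d, 0x4d)))) {
    abort_rs(paste0("not a TIFF file: ", path), "rootsense_io_error")
  }
  endian <- if (little) "little" else "big"
  rd <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  signed = size >= 4, endian = endian)
  ifd_off <- readBin(con, "integer", 1, 4, endian = endian)
  seek(con, ifd_off)
  n_entries <- rd(1, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- rd(1, 2); type <- rd(1, 2); count <- readBin(con, "integer", 1, 4, endian = endian)
    val_raw <- readBin(con, "raw", 4)
    tags[[as.character(tag)]] <- list(type = type, count = count, raw = val_raw)
  }
  getv <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(default)
    sz <- c(`1` = 1L, `3` = 2L, `4` = 4L)[[as.character(e$type)]]
    if (is.null(sz)) abort_rs("unsupported TIFF tag type", "rootsense_io_error")
    total <- sz * e$count
    if (total <= 4) {
      vals <- readBin(e$raw, "integer", n = e$count, size = sz,
                      signed = sz >= 4, endian = endian)
    } else {
      off <- readBin(e$raw, "integer", 1, 4, endian = endian)
      seek(con, off)
      vals <- rd(e$count, sz)
    }
    vals
  }
  W <- getv(256); H <- getv(257)
  bits <- getv(258, 8L); comp <- getv(259, 1L)
  spp <- getv(277, 1L)
  offsets <- getv(273); counts <- getv(279)
  rows_per_strip <- getv(278, H)
  if (comp != 1L) abort_rs("only uncompressed TIFF supported", "rootsense_io_error")
  if (any(bits != 8L)) abort_rs("only 8-bit TIFF supported", "rootsense_io_error")
  if (!spp %in% c(1L, 3L)) abort_rs("only grey/RGB TIFF supported", "rootsense_io_error")
  buf <- raw(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    buf <- c(buf, readBin(con, "raw", counts[s]))
  }
  vals <- as.integer(buf)[seq_len(H * W * spp)]
  if (spp == 1L) {
    g <- matrix(vals, nrow = W, ncol = H)  # row-major in file
    g <- t(g)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- g
  } else {
    arr <- array(vals, dim = c(3, W, H))   # interleaved RGB, row-major
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- t(arr[ch, , ])
  }
  img
}

write_tiff_minimal <- function(image, path) {
  check_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  px <- array(0L, dim = c(3, W, H))
  for (ch in 1:3) px[ch, , ] <- t(round(image[, , ch]))
  data <- as.raw(as.integer(px))
  con <- file(path, "wb"); on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wb4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)  # II, magic 42
  n_tags <- 9L
  # layout: header(8) + data + bits-per-sample array(6) + IFD
  data_off <- 8L
  bps_off <- data_off + length(data)
  ifd_off <- bps_off + 6L
  wb4(ifd_off)
  writeBin(data, con)
  wb2(c(8L, 8L, 8L))                                 # BitsPerSample values
  wb2(n_tags)
  entry <- function(tag, type, count, value) {
    wb2(tag); wb2(type); wb4(count)
    if (type == 3 && count == 1) { wb2(value); wb2(0L) } else wb4(value)
  }
  entry(256, 4, 1, W)            # ImageWidth
  entry(257, 4, 1, H)            # ImageLength
  entry(258, 3, 3, bps_off)      # BitsPerSample -> offset
  entry(259, 3, 1, 1)            # Compression = none
  entry(262, 3, 1, 2)            # Photometric = RGB
  entry(273, 4, 1, data_off)     # StripOffsets
  entry(277, 3, 1, 3)            # SamplesPerPixel
  entry(278, 4, 1, H)            # RowsPerStrip
  entry(279, 4, 1, length(data)) # StripByteCounts
  wb4(0L)                        # next IFD
  invisible(path)
}
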