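# Minimal baseline-TIFF I/O for single-channel uncompressed rasters.
# No TIFF reader/writer package ships with the supported stack, and the only
# features needed are grayscale 8/16-bit uncompressed strips, so a small
# purpose-built codec is used. Writer emits little-endian, one strip.

TIFF_TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
              photometric = 262L, strip_offsets = 273L, samples = 277L,
              rows_per_strip = 278L, strip_counts = 279L,
              planar_config = 284L)

uint16_le <- function(x) {
  x <- as.integer(x)
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

uint32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# One 12-byte IFD entry: tag, type (3 = SHORT, 4 = LONG), count 1, value.
ifd_entry <- function(tag, type, value) {
  val <- if (type == 3L) c(uint16_le(value), as.raw(c(0, 0))) else uint32_le(value)
  c(uint16_le(tag), uint16_le(type), uint32_le(1), val)
}

# Write an integer matrix of raw counts in [0, 65535] as 16-bit grayscale.
write_tiff_gray16 <- function(counts, path) {
  if (!is.matrix(counts)) stop_lum("'counts' must be a matrix")
  v <- as.integer(round(counts))
  if (anyNA(v) || any(v < 0L) || any(v > 65535L))
    stop_lum("raw counts must be integers in [0, 65535]")
  h <- nrow(counts); w <- ncol(counts)
  pixel_bytes <- uint16_le(as.integer(t(matrix(v, h, w))))  # row-major
  n_bytes <- length(pixel_bytes)
  ifd_offset <- 8 + n_bytes
  entries <- c(
    ifd_entry(TIFF_TAG[["width"]], 4L, w),
    ifd_entry(TIFF_TAG[["length"]], 4L, h),
    ifd_entry(TIFF_TAG[["bits"]], 3L, 16L),
    ifd_entry(TIFF_TAG[["compression"]], 3L, 1L),
    ifd_entry(TIFF_TAG[["photometric"]], 3L, 1L),
    ifd_entry(TIFF_TAG[["strip_offsets"]], 4L, 8L),
    ifd_entry(TIFF_TAG[["samples"]], 3L, 1L),
    ifd_entry(TIFF_TAG[["rows_per_strip"]], 4L, h),
    ifd_entry(TIFF_TAG[["strip_counts"]], 4L, n_bytes),
    ifd_entry(TIFF_TAG[["planar_config"]], 3L, 1L)
  )
  n_entries <- length(entries) / 12L
  out <- c(charToRaw("II"), uint16_le(42L), uint32_le(ifd_offset),
           pixel_bytes,
           uint16_le(n_entries), entries, uint32_le(0))
  writeBin(out, path)
  invisible(path)
}

rd_uint <- function(bytes, endian) {
  b <- as.numeric(bytes)
  if (endian == "little") b <- rev(b)
  Reduce(function(acc, x) acc * 256 + x, b, accumulate = FALSE, 0)
}

# Read a single-channel uncompressed grayscale TIFF (8 or 16 bits/sample).
# For multi-sample (e.g. RGB) chunky files, `channel` selects one plane;
# without it multi-channel input is refused.
read_tiff_gray <- function(path, channel = NULL) {
  data <- readBin(path, "raw", n = file.size(path))
  if (length(data) < 8L) stop_lum("not a TIFF file: ", path)
  order_mark <- rawToChar(data[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop_lum("not a TIFF file (bad byte-order mark): ", path))
  if (rd_uint(data[3:4], endian) != 42)
    stop_lum("not a TIFF file (bad magic): ", path)
  ifd_at <- rd_uint(data[5:8], endian)
  n_entries <- rd_uint(data[ifd_at + 1:2], endian)
  tags <- list()
  type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  for (i in seq_len(n_entries)) {
    at <- ifd_at + 2 + (i - 1) * 12
    tag <- rd_uint(data[at + 1:2], endian)
    typ <- rd_uint(data[at + 3:4], endian)
    cnt <- rd_uint(data[at + 5:8], endian)
    if (!as.character(typ) %in% names(type_size)) next
    sz <- type_size[[as.character(typ)]]
    total <- sz * cnt
    val_bytes <- if (total <= 4) data[at + 9:(8 + total)]
                 else data[rd_uint(data[at + 9:12], endian) + seq_len(total)]
    vals <- vapply(seq_len(cnt), function(j)
      rd_uint(val_bytes[(j - 1) * sz + seq_len(sz)], endian), numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_lum("TIFF missing required tag ", tag)
      default
    } else v
  }
  w <- need(TIFF_TAG[["width"]]); h <- need(TIFF_TAG[["length"]])
  compression <- need(TIFF_TAG[["compression"]], 1)
  if (compression != 1)
    stop_lum("only uncompressed TIFF is supported (compression tag ",
             compression, ")")
  samples <- need(TIFF_TAG[["samples"]], 1)
  bits <- unique(need(TIFF_TAG[["bits"]], 1))
  if (length(bits) != 1L || !bits %in% c(8, 16))
    stop_lum("only 8- or 16-bit samples are supported")
  if (samples > 1 && is.null(channel))
    stop_lum("multi-channel image (", samples,
             " samples/pixel): pass an explicit 'channel' to select one")
  offsets <- need(TIFF_TAG[["strip_offsets"]])
  counts <- need(TIFF_TAG[["strip_counts"]])
  if (length(offsets) != length(counts))
    stop_lum("malformed TIFF strip tables")
  payload <- unlist(lapply(seq_along(offsets), function(i)
    data[offsets[i] + seq_len(counts[i])]), use.names = FALSE)
  px <- if (bits == 8) {
    as.integer(payload)
  } else {
    b <- matrix(as.integer(payload), nrow = 2)
    if (endian == "little") b[1, ] + 256L * b[2, ] else b[2, ] + 256L * b[1, ]
  }
  if (samples > 1) {
    channel <- as.integer(channel)
    if (channel < 1L || channel > samples)
      stop_lum("'channel' must be in 1..", samples)
    px <- px[seq(channel, length(px), by = samples)]
  }
  if (length(px) < w * h) stop_lum("TIFF pixel data truncated")
  matrix(px[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
}
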