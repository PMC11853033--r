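# Minimal PNG writer for 8-bit RGB images (used for pseudo-colour renders).
# memCompress(type = "gzip") emits a zlib stream, which is exactly the IDAT
# payload format, so only chunk framing and CRC-32 are implemented here.

.png_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(.png_env$tab)) {
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L))
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))
        else bitwShiftR(bitwAnd(c, -2L), 1)
      }
      tab[n + 1] <- c
    }
    .png_env$tab <- tab
  }
  .png_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    c <- bitwXor(bitwShiftR(bitwAnd(c, -256L), 8),
                 tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L])
  bitwXor(c, -1L)
}

uint32_be <- function(x) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 4294967296  # two's-complement CRC values
  as.raw(c((x %/% 16777216) %% 256, (x %/% 65536) %% 256,
           (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32(body)))
}

# rgb: h x w x 3 array of integers in [0, 255]
write_png_rgb <- function(rgb, path) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop_lum("'rgb' must be a height x width x 3 array")
  v <- as.integer(round(rgb))
  if (anyNA(v) || any(v < 0L) || any(v > 255L))
    stop_lum("RGB values must be integers in [0, 255]")
  h <- d[1]; w <- d[2]
  dim(v) <- d
  # interleave channels row-major, filter byte 0 per scanline
  scan <- vapply(seq_len(h), function(r) {
    row <- rbind(v[r, , 1], v[r, , 2], v[r, , 3])
    c(as.raw(0), as.raw(row))
  }, raw(1 + 3 * w))
  idat <- memCompress(as.vector(scan), type = "gzip")  # zlib stream
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(8, 2, 0, 0, 0)))  # 8-bit, truecolour RGB
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}
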