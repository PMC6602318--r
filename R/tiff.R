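## Minimal uncompressed multi-page TIFF codec (baseline, strip-based).
## Writer: little-endian, 8-bit grayscale, one strip per page.
## Reader: either byte order; 8-bit gray (photometric 0/1) or 8-bit RGB
## (photometric 2, chunky); compression 1 only. TIFF carries no frame rate,
## so read_frames() requires an explicit fps for stacks.

tiff_write <- function(seq, path) {
  w <- seq$width; h <- seq$height
  n <- length(seq$frames)
  con <- file(path, "wb")
  on.exit(close(con))
  npix <- w * h
  ifd_len <- 2L + 9L * 12L + 4L
  data_off <- 8L                              # image data directly after header
  ifd0_off <- 8L + n * npix
  writeBin(c(charToRaw("II"), u16(42L), u32(ifd0_off)), con)
  for (i in seq_len(n))
    writeBin(as.raw(t(seq$frames[[i]])), con)  # row-major top-down
  entry <- function(tag, type, count, value)
    c(u16(tag), u16(type), u32(count),
      if (type == 3L) c(u16(value), u16(0L)) else u32(value))
  for (i in seq_len(n)) {
    nxt <- if (i < n) ifd0_off + i * ifd_len else 0L
    ifd <- c(u16(9L),
             entry(256L, 4L, 1L, w),           # ImageWidth
             entry(257L, 4L, 1L, h),           # ImageLength
             entry(258L, 3L, 1L, 8L),          # BitsPerSample
             entry(259L, 3L, 1L, 1L),          # Compression: none
             entry(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
             entry(273L, 4L, 1L, data_off + (i - 1L) * npix),  # StripOffsets
             entry(277L, 3L, 1L, 1L),          # SamplesPerPixel
             entry(278L, 4L, 1L, h),           # RowsPerStrip
             entry(279L, 4L, 1L, npix),        # StripByteCounts
             u32(nxt))
    writeBin(ifd, con)
  }
  invisible(path)
}

tiff_read <- function(path, as_grayscale = TRUE, fps = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop2("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop2("not a TIFF file: ", path)
  rd <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  if (rd(2L, 2L, signed = FALSE) != 42L) stop2("not a TIFF file: ", path)

  type_size <- c(1L, 1L, 2L, 4L, 8L)          # BYTE ASCII SHORT LONG RATIONAL
  read_values <- function(off) {              # one IFD entry -> tag + values
    tag <- rd(off, 2L, signed = FALSE)
    type <- rd(off + 2L, 2L, signed = FALSE)
    count <- rd(off + 4L, 4L)
    ts <- if (type <= 5L) type_size[type] else 1L
    total <- ts * count
    voff <- if (total <= 4L) off + 8L else rd(off + 8L, 4L)
    vals <- switch(as.character(type),
                   "3" = rd(voff, 2L, count, signed = FALSE),
                   "4" = rd(voff, 4L, count),
                   "1" = as.integer(raw[(voff + 1L):(voff + count)]),
                   NULL)
    list(tag = tag, values = vals)
  }

  frames <- list()
  ifd_off <- rd(4L, 4L)
  while (ifd_off > 0L) {
    nent <- rd(ifd_off, 2L, signed = FALSE)
    tags <- list()
    for (k in seq_len(nent)) {
      e <- read_values(ifd_off + 2L + (k - 1L) * 12L)
      tags[[as.character(e$tag)]] <- e$values
    }
    w <- tags[["256"]][1L]; h <- tags[["257"]][1L]
    comp <- (tags[["259"]] %||% 1L)[1L]
    if (comp != 1L)
      stop2("compressed TIFF (compression=", comp, ") is not supported: ",
            path)
    photo <- (tags[["262"]] %||% 1L)[1L]
    spp <- (tags[["277"]] %||% 1L)[1L]
    bits <- tags[["258"]] %||% 8L
    if (any(bits != 8L)) stop2("only 8-bit TIFF samples are supported: ", path)
    if (!is.null(tags[["284"]]) && tags[["284"]][1L] != 1L)
      stop2("planar TIFF layout is not supported: ", path)
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    buf <- raw[unlist(lapply(seq_along(offs), function(i)
      (offs[i] + 1L):(offs[i] + cnts[i])))]
    v <- as.integer(buf)
    if (spp == 1L) {
      m <- matrix(v, nrow = w)[, seq_len(h), drop = FALSE]
      m <- t(m)
      if (photo == 0L) m <- 255L - m          # WhiteIsZero
      storage.mode(m) <- "integer"
    } else if (spp == 3L) {
      r <- t(matrix(v[seq(1L, length(v), 3L)], nrow = w))
      g <- t(matrix(v[seq(2L, length(v), 3L)], nrow = w))
      b <- t(matrix(v[seq(3L, length(v), 3L)], nrow = w))
      m <- rgb_to_gray(array(c(r, g, b), c(h, w, 3L)))
    } else stop2("unsupported TIFF samples-per-pixel: ", spp)
    frames[[length(frames) + 1L]] <- m
    nxt_off <- ifd_off + 2L + nent * 12L
    ifd_off <- rd(nxt_off, 4L)
  }
  if (length(frames) == 0L) stop2("TIFF contains zero frames: ", path)
  if (is.null(fps))
    stop2("TIFF stacks carry no frame rate; pass fps= explicitly")
  frame_sequence(frames, fps = fps)
}
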