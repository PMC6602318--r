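## Minimal uncompressed-AVI (RIFF) codec.
##
## Writer emits a single 'vids' stream of 8-bit palettised DIB frames
## (biCompression = BI_RGB) with a 256-level gray palette, plus an idx1 index
## so ordinary players accept the file. Reader accepts 8-bit palettised and
## 24-bit BGR DIB frames; anything with a compressed fourcc/biCompression is
## rejected — the same constraint the ImageJ frame-differencing workflow has,
## which is why recordings are transcoded to uncompressed AVI upstream.

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                            endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                            endian = "little")
fourcc <- function(s) charToRaw(s)

avi_stride <- function(width) ((width + 3L) %/% 4L) * 4L

## one frame -> bottom-up padded DIB pixel raw vector
dib_pack <- function(m) {
  h <- nrow(m); w <- ncol(m)
  stride <- avi_stride(w)
  flip <- m[h:1L, , drop = FALSE]
  if (stride > w) {
    out <- matrix(0L, nrow = stride, ncol = h)
    out[1:w, ] <- t(flip)
  } else out <- t(flip)
  as.raw(out)
}

write_avi <- function(seq, path) {
  w <- seq$width; h <- seq$height
  nfr <- length(seq$frames)
  stride <- avi_stride(w)
  fbytes <- stride * h
  scale <- 1000L
  rate <- as.integer(round(seq$fps * 1000))

  avih <- c(u32(round(1e6 / seq$fps)), u32(fbytes * ceiling(seq$fps)),
            u32(0L), u32(0x10L),            # AVIF_HASINDEX
            u32(nfr), u32(0L), u32(1L), u32(fbytes + 8L),
            u32(w), u32(h), u32(rep(0L, 4L)))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0L), u16(0L), u16(0L),
            u32(0L), u32(scale), u32(rate), u32(0L), u32(nfr),
            u32(fbytes + 8L), u32(0L), u32(0L),
            u16(c(0L, 0L, w, h)))
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256L)))  # BGR0 gray ramp
  strf <- c(u32(40L), u32(w), u32(h), u16(1L), u16(8L), u32(0L),
            u32(fbytes), u32(0L), u32(0L), u32(256L), u32(0L), pal)
  strl <- c(fourcc("LIST"), u32(4L + 8L + length(strh) + 8L + length(strf)),
            fourcc("strl"),
            fourcc("strh"), u32(length(strh)), strh,
            fourcc("strf"), u32(length(strf)), strf)
  hdrl <- c(fourcc("LIST"), u32(4L + 8L + length(avih) + length(strl)),
            fourcc("hdrl"),
            fourcc("avih"), u32(length(avih)), avih,
            strl)

  movi_size <- 4L + nfr * (8L + fbytes)
  idx_size <- nfr * 16L
  riff_size <- 4L + length(hdrl) + 8L + movi_size + 8L + idx_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(riff_size), fourcc("AVI ")), con)
  writeBin(hdrl, con)
  writeBin(c(fourcc("LIST"), u32(movi_size), fourcc("movi")), con)
  offsets <- integer(nfr)
  off <- 4L
  for (i in seq_len(nfr)) {
    writeBin(c(fourcc("00db"), u32(fbytes)), con)
    writeBin(dib_pack(seq$frames[[i]]), con)
    offsets[i] <- off
    off <- off + 8L + fbytes
  }
  writeBin(c(fourcc("idx1"), u32(idx_size)), con)
  for (i in seq_len(nfr))
    writeBin(c(fourcc("00db"), u32(0x10L), u32(offsets[i]), u32(fbytes)), con)
  invisible(path)
}

r_u32 <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L,
          endian = "little")
}
r_u16 <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
r_tag <- function(raw, off) rawToChar(raw[(off + 1L):(off + 4L)])

read_avi <- function(path, as_grayscale = TRUE) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 12L || r_tag(raw, 0L) != "RIFF" ||
      r_tag(raw, 8L) != "AVI ")
    stop2("not an AVI file: ", path)

  fps <- NULL; width <- NULL; height <- NULL; bitcount <- NULL
  palette_gray <- NULL
  frames_raw <- list()

  walk <- function(off, end) {
    while (off + 8L <= end) {
      tag <- r_tag(raw, off)
      size <- r_u32(raw, off + 4L)
      body <- off + 8L
      if (tag == "LIST") {
        ltype <- r_tag(raw, body)
        if (ltype %in% c("hdrl", "strl", "movi"))
          walk(body + 4L, body + size)
      } else if (tag == "strh") {
        if (r_tag(raw, body) == "vids") {
          hraw <- raw[(body + 5L):(body + 8L)]
          handler <- rawToChar(hraw[hraw != as.raw(0L)])
          if (!handler %in% c("DIB ", "", "    "))
            stop2("compressed AVI stream ('", handler,
                  "') is not supported: ", path)
          sc <- r_u32(raw, body + 20L)
          rt <- r_u32(raw, body + 24L)
          if (sc > 0L && rt > 0L) fps <<- rt / sc
        }
      } else if (tag == "strf" && is.null(width)) {
        width <<- r_u32(raw, body + 4L)
        height <<- r_u32(raw, body + 8L)
        bitcount <<- r_u16(raw, body + 14L)
        if (r_u32(raw, body + 16L) != 0L)
          stop2("compressed AVI (biCompression != 0) is not supported: ",
                path)
        if (bitcount == 8L) {
          nclr <- r_u32(raw, body + 32L)
          if (nclr == 0L) nclr <- 256L
          pal <- as.integer(raw[(body + 41L):(body + 40L + 4L * nclr)])
          pm <- matrix(pal, nrow = 4L)          # B, G, R, 0
          lum <- round(0.299 * pm[3L, ] + 0.587 * pm[2L, ] +
                         0.114 * pm[1L, ])
          palette_gray <<- as.integer(c(lum, rep(lum[length(lum)],
                                                 256L - nclr)))
        }
      } else if (grepl("^..(db|dc)$", tag) && size > 0L) {
        frames_raw[[length(frames_raw) + 1L]] <<- raw[(body + 1L):
                                                        (body + size)]
      }
      off <- body + size + (size %% 2L)       # chunks are word-aligned
    }
  }
  walk(12L, length(raw))

  if (is.null(width)) stop2("no video stream header found in ", path)
  if (length(frames_raw) == 0L) stop2("AVI contains zero frames: ", path)
  if (is.null(fps)) stop2("AVI lacks frame-rate metadata: ", path)

  decode <- function(buf) {
    if (bitcount == 8L) {
      stride <- avi_stride(width)
      px <- matrix(as.integer(buf[seq_len(stride * height)]),
                   nrow = stride)[seq_len(width), , drop = FALSE]
      m <- t(px)[height:1L, , drop = FALSE]
      if (!is.null(palette_gray)) m[] <- palette_gray[m + 1L]
      storage.mode(m) <- "integer"
      m
    } else if (bitcount == 24L) {
      stride <- ((3L * width + 3L) %/% 4L) * 4L
      v <- as.integer(buf[seq_len(stride * height)])
      px <- matrix(v, nrow = stride)[seq_len(3L * width), , drop = FALSE]
      b <- t(px[seq(1L, 3L * width, 3L), , drop = FALSE])[height:1L, ,
                                                          drop = FALSE]
      g <- t(px[seq(2L, 3L * width, 3L), , drop = FALSE])[height:1L, ,
                                                          drop = FALSE]
      r <- t(px[seq(3L, 3L * width, 3L), , drop = FALSE])[height:1L, ,
                                                          drop = FALSE]
      if (as_grayscale) rgb_to_gray(array(c(r, g, b), c(height, width, 3L)))
      else rgb_to_gray(array(c(r, g, b), c(height, width, 3L)))
    } else stop2("unsupported AVI bit depth: ", bitcount)
  }
  frame_sequence(lapply(frames_raw, decode), fps = fps)
}
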