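#' Read a video into a frame sequence
#'
#' Supports uncompressed AVI (8-bit palettised or 24-bit DIB frames) and
#' uncompressed multi-page TIFF. Compressed codecs are rejected with an error
#' naming the file — recordings must be transcoded to uncompressed AVI
#' upstream, exactly as the ImageJ frame-differencing workflow requires.
#' RGB input is converted to grayscale with ITU-R BT.601 luma weights.
#'
#' @param path Path to an `.avi` or `.tif`/`.tiff` file.
#' @param as_grayscale Convert RGB content to grayscale (always done; kept as
#'   an explicit flag for interface clarity).
#' @param fps Frame rate override. Required for TIFF stacks (the container
#'   has no rate metadata); optional for AVI, where it overrides the header.
#' @return A [frame_sequence].
#' @seealso [write_frames()]
#' @export
read_frames <- function(path, as_grayscale = TRUE, fps = NULL) {
  if (!file.exists(path)) stop2("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  seq <- switch(ext,
                avi = read_avi(path, as_grayscale),
                tif = ,
                tiff = tiff_read(path, as_grayscale, fps = fps),
                stop2("unsupported video format '.", ext, "': ", path))
  if (!is.null(fps)) seq$fps <- as.numeric(fps)
  if (seq$fps <= 0) stop2("fps must be > 0")
  seq
}

#' Write a frame sequence to disk, losslessly
#'
#' The container is chosen from the file extension: `.avi` gives an
#' uncompressed 8-bit palettised DIB AVI (frame rate stored in the stream
#' header), `.tif`/`.tiff` an uncompressed multi-page grayscale TIFF.
#' `read_frames(write_frames(x))` returns pixel-identical frames.
#'
#' @param seq A [frame_sequence].
#' @param path Output path ending in `.avi`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(seq, path) {
  if (!inherits(seq, "frame_sequence")) stop2("seq must be a frame_sequence")
  if (length(seq$frames) == 0L) stop2("cannot write an empty frame sequence")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         avi = write_avi(seq, path),
         tif = ,
         tiff = tiff_write(seq, path),
         stop2("unsupported output format '.", ext, "': ", path))
  invisible(path)
}
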