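#' Frame sequence container
#'
#' An ordered stack of 8-bit grayscale frames with a frame rate. Frames are
#' stored as integer matrices with `height` rows and `width` columns; pixel
#' `(x, y)` (x rightward, y downward, 0-based, origin top-left) lives at
#' `frame[y + 1, x + 1]`.
#'
#' @param frames List of numeric/integer matrices, all of identical
#'   dimensions, values in `[0, 255]`.
#' @param fps Frames per second; must be positive.
#' @return An object of class `frame_sequence` with fields `frames`, `fps`,
#'   `width`, `height`.
#' @examples
#' fs <- frame_sequence(list(matrix(0L, 4, 6), matrix(255L, 4, 6)), fps = 30)
#' fs$width  # 6
#' @export
frame_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0L)
    stop2("frames must be a non-empty list of matrices")
  assert_scalar_num(fps, "fps", positive = TRUE)
  d <- dim(frames[[1L]])
  if (is.null(d)) stop2("frames must be matrices")
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (!identical(dim(f), d))
      stop2("frame ", i, " has dimensions ", paste(dim(f), collapse = "x"),
            ", expected ", paste(d, collapse = "x"))
    if (anyNA(f) || min(f) < 0 || max(f) > 255)
      stop2("frame ", i, " has intensities outside [0, 255]")
    storage.mode(f) <- "integer"
    f
  })
  structure(
    list(frames = frames, fps = as.numeric(fps),
         width = d[2L], height = d[1L]),
    class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps\n",
              length(x$frames), x$width, x$height, x$fps))
  invisible(x)
}

#' Convert an RGB frame to 8-bit grayscale (ITU-R BT.601 luma)
#'
#' @param arr Either a `height x width x 3` array (R, G, B planes) or a
#'   grayscale matrix (returned unchanged after rounding).
#' @return Integer matrix of luma values in `[0, 255]`.
#' @export
rgb_to_gray <- function(arr) {
  if (is.matrix(arr)) {
    g <- round(arr)
  } else {
    if (length(dim(arr)) != 3L || dim(arr)[3L] != 3L)
      stop2("expected a height x width x 3 array")
    g <- round(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
  }
  storage.mode(g) <- "integer"
  g
}
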