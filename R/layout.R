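#' Tank layout: rectangular ROIs plus pixel calibration
#'
#' Describes where each tank sits in the camera frame. ROIs are axis-aligned
#' rectangles in pixel coordinates (0-based, x rightward, y downward) and are
#' half-open: a pixel with integer coordinates `(x, y)` belongs to a tank iff
#' `x_min <= x < x_max` and `y_min <= y < y_max`. ROIs must be pairwise
#' disjoint.
#'
#' @param tanks data.frame with columns `tank_id`, `x_min`, `y_min`, `x_max`,
#'   `y_max` (pixels).
#' @param expected_fish_per_tank Positive integer, recycled across tanks.
#' @param px_per_cm Positive calibration factor (pixels per centimetre).
#' @return Object of class `tank_layout`.
#' @export
tank_layout <- function(tanks, expected_fish_per_tank = 1L, px_per_cm) {
  need <- c("tank_id", "x_min", "y_min", "x_max", "y_max")
  if (!is.data.frame(tanks) || !all(need %in% names(tanks)))
    stop2("tanks must be a data.frame with columns ",
          paste(need, collapse = ", "))
  if (nrow(tanks) == 0L) stop2("layout has no tanks")
  assert_scalar_num(px_per_cm, "px_per_cm", positive = TRUE)
  if (any(tanks$x_max <= tanks$x_min) || any(tanks$y_max <= tanks$y_min))
    stop2("every ROI needs x_min < x_max and y_min < y_max")
  n <- nrow(tanks)
  ef <- as.integer(rep_len(expected_fish_per_tank, n))
  if (any(ef < 1L)) stop2("expected_fish_per_tank must be >= 1")
  ## pairwise disjointness of half-open rectangles
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (tanks$x_min[i] < tanks$x_max[j] && tanks$x_min[j] < tanks$x_max[i] &&
        tanks$y_min[i] < tanks$y_max[j] && tanks$y_min[j] < tanks$y_max[i])
      stop2("ROIs of tanks ", tanks$tank_id[i], " and ", tanks$tank_id[j],
            " overlap")
  }
  tanks$expected_fish <- ef
  structure(list(tanks = tanks, px_per_cm = as.numeric(px_per_cm)),
            class = "tank_layout")
}

#' Build the standard grid layout of identical tanks
#'
#' Arranges `n_tanks` rectangular tanks (default 20 x 10 cm, the common
#' small-aquarium footprint) in a grid with a fixed pixel margin, mirroring a
#' camera looking down on a bank of tanks sitting on a light box.
#'
#' @param n_tanks Number of tanks.
#' @param fish_per_tank Expected fish per tank.
#' @param px_per_cm Pixels per centimetre of the camera view.
#' @param tank_cm Tank width and height in cm, `c(w, h)`.
#' @param ncol Number of grid columns.
#' @param margin_px Margin between/around tanks, pixels.
#' @return A `tank_layout`; attribute `frame_dim` holds `c(width, height)` of
#'   the minimal enclosing frame.
#' @export
default_tank_layout <- function(n_tanks = 6L, fish_per_tank = 3L,
                                px_per_cm = 4, tank_cm = c(20, 10),
                                ncol = 3L, margin_px = 4L) {
  tw <- round(tank_cm[1L] * px_per_cm)
  th <- round(tank_cm[2L] * px_per_cm)
  idx <- seq_len(n_tanks) - 1L
  col <- idx %% ncol
  row <- idx %/% ncol
  x0 <- margin_px + col * (tw + margin_px)
  y0 <- margin_px + row * (th + margin_px)
  tanks <- data.frame(tank_id = seq_len(n_tanks),
                      x_min = x0, y_min = y0,
                      x_max = x0 + tw, y_max = y0 + th)
  lay <- tank_layout(tanks, fish_per_tank, px_per_cm)
  attr(lay, "frame_dim") <- c(width = max(tanks$x_max) + margin_px,
                              height = max(tanks$y_max) + margin_px)
  lay
}

#' @export
print.tank_layout <- function(x, ...) {
  cat(sprintf("<tank_layout> %d tanks, %.3g px/cm\n",
              nrow(x$tanks), x$px_per_cm))
  print(x$tanks, row.names = FALSE)
  invisible(x)
}

## check every ROI fits inside a width x height frame
check_layout_in_frame <- function(layout, width, height) {
  t <- layout$tanks
  if (any(t$x_min < 0) || any(t$y_min < 0) ||
      any(t$x_max > width) || any(t$y_max > height))
    stop2("tank ROIs extend outside the ", width, "x", height, " frame")
  invisible(TRUE)
}

## ROI pixel area (half-open)
roi_area <- function(roi) (roi$x_max - roi$x_min) * (roi$y_max - roi$y_min)

## extract the ROI submatrix of a frame (half-open pixel rectangle)
roi_sub <- function(frame, roi) {
  frame[(roi$y_min + 1L):roi$y_max, (roi$x_min + 1L):roi$x_max, drop = FALSE]
}

## tank size in cm, c(w, h)
tank_cm_dims <- function(layout, k) {
  r <- layout$tanks[k, ]
  c((r$x_max - r$x_min) / layout$px_per_cm,
    (r$y_max - r$y_min) / layout$px_per_cm)
}
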