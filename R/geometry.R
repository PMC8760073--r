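# Arena and screen geometry shared by the generator and the analyses.

#' Target grid in arena coordinates
#'
#' The task presents nine targets arranged in a 3 x 3 grid, spaced
#' `spacing` arena units apart and centered on the origin. Columns are
#' indexed left to right, rows near to far; location ids run row-major from
#' the near-left corner.
#'
#' @param spacing Distance between adjacent targets in arena units.
#' @return A tibble with one row per location: `location`, `col`, `row`,
#'   `x`, `y`, `target_column` (left/center/right) and `target_side`
#'   (identical to `target_column`; kept separate for binary analyses that
#'   drop the center column).
#' @export
#' @examples
#' target_grid()
target_grid <- function(spacing = 290) {
  grid <- tidyr::expand_grid(row = 1:3, col = 1:3)
  grid |>
    mutate(
      location = (row - 1L) * 3L + col,
      x = (col - 2L) * spacing,
      y = (row - 2L) * spacing,
      target_column = c("left", "center", "right")[col],
      target_side = target_column
    ) |>
    select(location, col, row, x, y, target_column, target_side) |>
    arrange(location)
}

#' Screen geometry of the display
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_cm,height_cm Physical display size.
#' @param distance_cm Viewing distance.
#' @return A list of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            width_cm = 45, height_cm = 33.5,
                            distance_cm = 80) {
  structure(
    list(width_px = width_px, height_px = height_px,
         width_cm = width_cm, height_cm = height_cm,
         distance_cm = distance_cm,
         # small-angle-free conversion at screen center
         deg_per_px_x = 2 * atan(width_cm / 2 / distance_cm) * 180 / pi / width_px,
         deg_per_px_y = 2 * atan(height_cm / 2 / distance_cm) * 180 / pi / height_px),
    class = "screen_geometry"
  )
}

#' Screen projection of the nine target locations
#'
#' Maps the 3 x 3 arena grid onto display pixels: columns at 25/50/75% of
#' screen width, rows stacked vertically with far targets higher on screen
#' (smaller y; the pixel origin is the top-left corner).
#'
#' @param screen A [screen_geometry()].
#' @return Tibble with `location`, `sx`, `sy` (pixels).
#' @export
target_screen_xy <- function(screen = screen_geometry()) {
  g <- target_grid()
  g |>
    mutate(
      sx = screen$width_px * c(0.25, 0.5, 0.75)[col],
      sy = screen$height_px * c(0.70, 0.50, 0.30)[row]
    ) |>
    select(location, sx, sy)
}

#' Regular grid over the screen
#'
#' Used for the 16-cell fixation-count decoder and for the on-target
#' fixation window (one cell of this grid).
#'
#' @param nx,ny Number of cells along each axis.
#' @param screen A [screen_geometry()].
#' @return List with cell edges and dimensions.
#' @export
screen_grid <- function(nx = 4, ny = 4, screen = screen_geometry()) {
  list(
    nx = nx, ny = ny,
    x_edges = seq(0, screen$width_px, length.out = nx + 1),
    y_edges = seq(0, screen$height_px, length.out = ny + 1),
    cell_w = screen$width_px / nx,
    cell_h = screen$height_px / ny
  )
}

#' 5 x 5 occupancy grid over the task arena
#'
#' Sized so the cells tightly enclose the nine target locations: the grid
#' spans the bounding box of the targets padded by half the target spacing.
#'
#' @param spacing Target spacing in arena units.
#' @param n Cells per side.
#' @return List with `x_edges`, `y_edges`, `n`.
#' @export
trajectory_grid <- function(spacing = 290, n = 5) {
  half <- spacing + spacing / 2
  list(
    x_edges = seq(-half, half, length.out = n + 1),
    y_edges = seq(-half, half, length.out = n + 1),
    n = n
  )
}

# Index of the grid cell containing each point; NA outside the grid.
# Half-open cells [edge_i, edge_{i+1}) except the last, which is closed.
grid_cell_index <- function(x, y, x_edges, y_edges) {
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  bad <- ix < 1L | ix > nx | iy < 1L | iy > ny
  out <- (iy - 1L) * nx + ix
  out[bad] <- NA_integer_
  out
}
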