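#' Build a velocity-field frame from grid vectors
#'
#' A velocity-field frame is the package's tabular equivalent of one PIV
#' output: velocity components sampled on a regular grid. It is stored as a
#' tibble with columns `frame`, `t_h`, `x_um`, `y_um`, `u_umph`, `v_umph`;
#' grid nodes that are invalid (e.g. outside the imaged domain) are simply
#' absent. Axes follow the mathematical convention: x to the right, y up,
#' so positive vorticity and +1 winding are counterclockwise.
#'
#' @param x,y Node coordinates in micrometers (same length as `u`, `v`).
#' @param u,v Velocity components in micrometers per hour.
#' @param frame Integer frame index (default 1).
#' @param t_h Time stamp in hours (default 0).
#' @return A tibble with one row per valid grid node.
#' @export
velocity_field <- function(x, y, u, v, frame = 1L, t_h = 0) {
  stopifnot(length(x) == length(y), length(u) == length(x), length(v) == length(x))
  bad <- !is.finite(u) | !is.finite(v)
  tibble::tibble(
    frame = as.integer(frame), t_h = as.double(t_h),
    x_um = as.double(x), y_um = as.double(y),
    u_umph = as.double(u), v_umph = as.double(v)
  )[!bad, ]
}

#' Describe a regular analysis grid
#'
#' @param nx,ny Number of nodes along x and y (>= 3).
#' @param spacing Node spacing in micrometers.
#' @param origin Coordinates of the lower-left node, micrometers.
#' @return A list with class `field_grid`.
#' @export
field_grid <- function(nx, ny, spacing, origin = c(0, 0)) {
  stopifnot(nx >= 3, ny >= 3, spacing > 0, length(origin) == 2)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         spacing = as.double(spacing), origin = as.double(origin),
         xs = origin[1] + spacing * (seq_len(nx) - 1),
         ys = origin[2] + spacing * (seq_len(ny) - 1)),
    class = "field_grid"
  )
}

# Recover grid geometry from a field-frame tibble. Nodes may be missing
# (masked); spacing is inferred as the minimal positive coordinate step.
field_grid_of <- function(field) {
  xs <- sort(unique(field$x_um))
  ys <- sort(unique(field$y_um))
  if (length(xs) < 2 || length(ys) < 2) {
    abort("field frame does not span a grid (need >= 2 distinct x and y values)")
  }
  step <- min(diff(xs), diff(ys))
  # expand to the full implied lattice so masked nodes keep their index
  nx <- round((max(xs) - min(xs)) / step) + 1L
  ny <- round((max(ys) - min(ys)) / step) + 1L
  field_grid(max(nx, 3L), max(ny, 3L), step, origin = c(min(xs), min(ys)))
}

# Field frame -> u, v, valid matrices indexed [ix, iy] on the full grid.
field_matrices <- function(field, grid = field_grid_of(field)) {
  ix <- round((field$x_um - grid$origin[1]) / grid$spacing) + 1L
  iy <- round((field$y_um - grid$origin[2]) / grid$spacing) + 1L
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  u <- matrix(NA_real_, grid$nx, grid$ny)
  v <- matrix(NA_real_, grid$nx, grid$ny)
  u[cbind(ix[ok], iy[ok])] <- field$u_umph[ok]
  v[cbind(ix[ok], iy[ok])] <- field$v_umph[ok]
  list(u = u, v = v, valid = !is.na(u) & !is.na(v), grid = grid)
}

# Split a multi-frame field series into per-frame tibbles, ordered by frame.
split_frames <- function(fields) {
  stopifnot(is.data.frame(fields), all(c("frame", "x_um", "y_um") %in% names(fields)))
  fr <- sort(unique(fields$frame))
  lapply(fr, function(f) fields[fields$frame == f, , drop = FALSE])
}
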