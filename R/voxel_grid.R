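VALID_UNITS <- c("HU", "g/cm3", "Gy", "1")

#' Create a voxel grid
#'
#' A `voxel_grid` is a 3-D scalar volume with physical geometry: voxel values,
#' voxel spacing in mm, origin (physical position of the center of voxel
#' `[1,1,1]`) in mm, and a semantic unit tag.  Geometry is axis-aligned LPS
#' (+x patient left, +y posterior, +z superior); oblique acquisitions are not
#' supported.
#'
#' @param values numeric 3-D array (dims: x, y, z).
#' @param spacing numeric length-3, voxel spacing in mm, strictly positive.
#' @param origin numeric length-3, position of the first voxel center in mm.
#' @param unit one of `"HU"`, `"g/cm3"`, `"Gy"`, `"1"` (dimensionless).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       unit = "1") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  unit <- match.arg(unit, VALID_UNITS)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d [%s]\n", d[1], d[2], d[3], x$unit))
  cat(sprintf("  spacing: %s mm  origin: %s mm\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

grid_dim <- function(g) dim(g$values)

#' Voxel volume in cm^3
#' @param grid a `voxel_grid` or `mask`.
#' @return scalar voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

## physical coordinates of voxel centers along one axis (1 = x, 2 = y, 3 = z)
axis_coords <- function(g, axis) {
  g$origin[axis] + (seq_len(dim(g$values)[axis]) - 1) * g$spacing[axis]
}

## n x 3 matrix of all voxel center coordinates, in array order
grid_points <- function(g) {
  d <- dim(g$values)
  cbind(rep(axis_coords(g, 1), times = d[2] * d[3]),
        rep(rep(axis_coords(g, 2), each = d[1]), times = d[3]),
        rep(axis_coords(g, 3), each = d[1] * d[2]))
}

geometry_of <- function(g) list(dim = dim(g$values), spacing = g$spacing,
                                origin = g$origin)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("dosemass_geometry_error", "error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("dosemass_format_error", "error")))
}
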