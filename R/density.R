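#' Create an HU to mass-density conversion table
#'
#' Piecewise-linear calibration between CT numbers (HU) and mass density in
#' g/cm^3, as used by treatment planning systems to assign density to CT
#' voxels.  HU breakpoints must be strictly increasing and densities
#' non-negative.
#'
#' @param hu numeric vector of HU breakpoints, strictly increasing.
#' @param density matching mass densities in g/cm^3.
#' @return an object of class `density_table`.
#' @export
density_table <- function(hu, density) {
  hu <- as.numeric(hu); density <- as.numeric(density)
  if (length(hu) != length(density) || length(hu) < 2L)
    stop_parse("density table needs at least 2 (hu, density) breakpoints")
  if (any(diff(hu) <= 0)) stop_parse("HU breakpoints must be strictly increasing")
  if (any(!is.finite(density)) || any(density < 0))
    stop_parse("densities must be finite and >= 0")
  structure(list(hu = hu, density = density), class = "density_table")
}

#' Default HU to mass-density table
#'
#' Four-point air / water / soft-bone / dense-bone calibration: `-1000 HU`
#' maps to air (0.00121 g/cm^3), `0 HU` to water (1.0), `1000 HU` to 1.6 and
#' `3000 HU` to 2.5 g/cm^3.  Strictly increasing, hence invertible, which the
#' phantom generator uses to derive HU values from construction densities.
#'
#' @return a [density_table].
#' @export
default_density_table <- function() {
  density_table(c(-1000, 0, 1000, 3000), c(0.00121, 1.0, 1.6, 2.5))
}

#' Read a density table from CSV
#'
#' Expects a header with columns `hu` and `density_g_cm3`.
#'
#' @param path CSV path.
#' @return a [density_table].
#' @export
read_density_table <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- read.csv(path)
  if (!all(c("hu", "density_g_cm3") %in% names(df)))
    stop_format("density CSV must have columns hu, density_g_cm3")
  density_table(df$hu, df$density_g_cm3)
}

#' Write a density table to CSV
#' @param table a [density_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(table, path) {
  write.csv(data.frame(hu = table$hu, density_g_cm3 = table$density),
            path, row.names = FALSE)
  invisible(path)
}

#' Convert a CT volume from HU to mass density
#'
#' Per-voxel piecewise-linear interpolation between the table breakpoints;
#' values outside the table range are clamped to the end densities.
#'
#' @param ct a [voxel_grid] in HU.
#' @param table a [density_table]; defaults to [default_density_table()].
#' @return a [voxel_grid] in g/cm^3.
#' @export
hu_to_density <- function(ct, table = default_density_table()) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(table, "density_table"))
  if (ct$unit != "HU") stop(paste("expected an HU grid, got", ct$unit))
  v <- approx(table$hu, table$density, xout = as.numeric(ct$values),
              rule = 2)$y
  voxel_grid(array(v, dim = dim(ct$values)), ct$spacing, ct$origin,
             unit = "g/cm3")
}

#' Invert the density table: mass density to HU
#'
#' Requires strictly increasing densities.  Used by the phantom generator so
#' that [hu_to_density()] recovers construction densities exactly.
#'
#' @param density numeric vector in g/cm^3.
#' @param table a [density_table].
#' @return numeric vector of HU values.
#' @export
density_to_hu <- function(density, table = default_density_table()) {
  if (any(diff(table$density) <= 0))
    stop_parse("density table not invertible (densities not strictly increasing)")
  approx(table$density, table$hu, xout = as.numeric(density), rule = 2)$y
}
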