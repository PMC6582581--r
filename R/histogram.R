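stop_empty <- function(msg) {
  stop(errorCondition(msg, class = c("dosemass_empty_structure_error", "error")))
}

## Extract per-voxel dose and weight samples for a masked structure.
masked_samples <- function(dose, mask, density = NULL) {
  stopifnot(inherits(dose, "voxel_grid"), inherits(mask, "mask"))
  if (!same_geometry(dose, mask))
    stop_geometry("dose grid not aligned to mask (resample first)")
  idx <- which(mask$values)
  if (length(idx) == 0L) stop_empty("mask selects no voxels")
  vv <- voxel_volume_cm3(mask)
  if (is.null(density)) {
    weight <- rep(vv, length(idx))
    unit <- "cm3"
  } else {
    stopifnot(inherits(density, "voxel_grid"))
    if (!same_geometry(density, mask))
      stop_geometry("density grid not aligned to mask")
    rho <- density$values[idx]
    if (any(rho < 0)) stop("negative density values in masked region")
    weight <- rho * vv
    unit <- "g"
  }
  list(dose = as.numeric(dose$values[idx]), weight = weight, unit = unit)
}

make_cumulative <- function(samples, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  edges <- seq(0, max(samples$dose) + bin_width, by = bin_width)
  ## bin m holds weight of voxels with dose in [edge_m, edge_{m+1});
  ## cumulative at edge k = weight of all bins >= k
  idx <- findInterval(samples$dose, edges)
  binw <- numeric(length(edges))
  agg <- rowsum(samples$weight, idx)
  binw[as.integer(rownames(agg))] <- agg[, 1]
  cumulative <- rev(cumsum(rev(binw)))
  structure(list(bin_edges = edges, cumulative = cumulative,
                 total = sum(samples$weight), unit = samples$unit,
                 samples = samples),
            class = "cumulative_histogram")
}

#' Cumulative dose-volume histogram
#'
#' `cumulative[k]` is the structure volume (cm^3) receiving at least
#' `bin_edges[k]` Gy; `total` is the structure volume.  The per-voxel dose
#' samples are retained on the object so that [dose_metrics()] can evaluate
#' Dmean and Vx by exact recount rather than from the binned curve.
#'
#' @param dose a [voxel_grid] in Gy, aligned to `mask`.
#' @param mask a [mask_grid] of the structure.
#' @param bin_width histogram bin width in Gy (default 0.1).
#' @return a `cumulative_histogram` with unit cm^3.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  make_cumulative(masked_samples(dose, mask), bin_width)
}

#' Cumulative dose-mass histogram
#'
#' Like [compute_dvh()] but each voxel contributes its mass
#' (density x voxel volume, g), so the curve tracks irradiated structure
#' mass and accounts for density changes between breathing states.
#'
#' @inheritParams compute_dvh
#' @param density a [voxel_grid] in g/cm^3 aligned to `mask`.
#' @return a `cumulative_histogram` with unit g.
#' @export
compute_dmh <- function(dose, mask, density, bin_width = 0.1) {
  make_cumulative(masked_samples(dose, mask, density), bin_width)
}

#' @export
print.cumulative_histogram <- function(x, ...) {
  cat(sprintf("<cumulative_histogram> %s, total %.2f %s, %d edges (0..%.1f Gy)\n",
              if (x$unit == "g") "DMH" else "DVH", x$total, x$unit,
              length(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
as.data.frame.cumulative_histogram <- function(x, ...) {
  df <- data.frame(dose_gy = x$bin_edges, cumulative = x$cumulative,
                   relative_pct = 100 * x$cumulative / x$total)
  names(df)[2] <- paste0("cumulative_", if (x$unit == "g") "g" else "cm3")
  df
}

#' Export a cumulative histogram as CSV
#' @param x a `cumulative_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Scalar DVH/DMH metrics for a structure
#'
#' Computes the volume-weighted and mass-weighted mean dose and, per queried
#' dose level x, the volume Vx and mass Mx receiving at least x Gy, as
#' absolute (cm^3, g) and relative (% of structure) values.  All metrics are
#' evaluated from the raw per-voxel samples carried by the histograms (exact
#' recount with the ">= x" convention), not by interpolating the binned
#' curves.
#'
#' @param dvh a `cumulative_histogram` from [compute_dvh()].
#' @param dmh a `cumulative_histogram` from [compute_dmh()], or `NULL` for
#'   volume-only metrics.
#' @param dose_levels numeric vector of dose levels in Gy (>= 0).
#' @return an object of class `dose_metrics`: fields `dmean_volume`,
#'   `dmean_mass`, `volume`, `mass`, `mean_density` and a data frame
#'   `levels` with columns `level`, `vx_rel`, `vx_abs`, `mx_rel`, `mx_abs`.
#' @export
dose_metrics <- function(dvh, dmh = NULL, dose_levels = numeric(0)) {
  stopifnot(inherits(dvh, "cumulative_histogram"))
  if (any(dose_levels < 0)) stop("dose levels must be >= 0")
  if (dvh$total <= 0) stop_empty("structure has zero volume")
  sv <- dvh$samples
  dmean_volume <- sum(sv$dose * sv$weight) / dvh$total
  vx_abs <- vapply(dose_levels, function(x) sum(sv$weight[sv$dose >= x]),
                   numeric(1))
  res <- list(dmean_volume = dmean_volume,
              volume = dvh$total,
              dmean_mass = NA_real_, mass = NA_real_,
              mean_density = NA_real_)
  lev <- data.frame(level = dose_levels, vx_abs = vx_abs,
                    vx_rel = 100 * vx_abs / dvh$total,
                    mx_abs = rep(NA_real_, length(dose_levels)),
                    mx_rel = rep(NA_real_, length(dose_levels)))
  if (!is.null(dmh)) {
    stopifnot(inherits(dmh, "cumulative_histogram"))
    if (dmh$total <= 0) stop_empty("structure has zero mass")
    sm <- dmh$samples
    res$dmean_mass <- sum(sm$dose * sm$weight) / dmh$total
    res$mass <- dmh$total
    res$mean_density <- dmh$total / dvh$total
    lev$mx_abs <- vapply(dose_levels, function(x) sum(sm$weight[sm$dose >= x]),
                         numeric(1))
    lev$mx_rel <- 100 * lev$mx_abs / dmh$total
  }
  res$levels <- lev[, c("level", "vx_rel", "vx_abs", "mx_rel", "mx_abs")]
  class(res) <- "dose_metrics"
  res
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("<dose_metrics> Dmean(DVH) %.3f Gy", x$dmean_volume))
  if (!is.na(x$dmean_mass)) cat(sprintf("  Dmean(DMH) %.3f Gy", x$dmean_mass))
  cat(sprintf("\n  volume %.1f cm^3", x$volume))
  if (!is.na(x$mass))
    cat(sprintf("  mass %.1f g  mean density %.3f g/cm^3", x$mass,
                x$mean_density))
  cat("\n")
  if (nrow(x$levels)) print(x$levels, row.names = FALSE)
  invisible(x)
}
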