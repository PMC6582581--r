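#' Resample a volume onto another grid geometry
#'
#' Trilinear interpolation at the target voxel centers.  Target voxels whose
#' centers fall outside the source extent receive 0; their count is attached
#' as attribute `n_outside` and reported with a warning-level message.
#' Typical use: bringing a 2.5 mm dose grid onto the CT grid before
#' voxel-wise combination with density and masks.
#'
#' @param source a [voxel_grid].
#' @param target_geometry a [voxel_grid] (or `mask`) whose geometry to adopt,
#'   or a list with elements `dim`, `spacing`, `origin`.
#' @param quiet suppress the out-of-extent message.
#' @return a [voxel_grid] on the target geometry, same unit as `source`.
#' @export
resample_to_grid <- function(source, target_geometry, quiet = FALSE) {
  stopifnot(inherits(source, "voxel_grid"))
  tg <- if (inherits(target_geometry, c("voxel_grid", "mask")))
    geometry_of(target_geometry) else target_geometry
  d <- as.integer(tg$dim)
  ## physical extents (outer voxel faces) must overlap
  s_lo <- source$origin - source$spacing / 2
  s_hi <- source$origin + (grid_dim(source) - 0.5) * source$spacing
  t_lo <- tg$origin - tg$spacing / 2
  t_hi <- tg$origin + (d - 0.5) * tg$spacing
  if (any(s_hi < t_lo) || any(t_hi < s_lo))
    stop_geometry("source and target extents are disjoint")
  pts <- cbind(
    rep(tg$origin[1] + (seq_len(d[1]) - 1) * tg$spacing[1], times = d[2] * d[3]),
    rep(rep(tg$origin[2] + (seq_len(d[2]) - 1) * tg$spacing[2], each = d[1]),
        times = d[3]),
    rep(tg$origin[3] + (seq_len(d[3]) - 1) * tg$spacing[3], each = d[1] * d[2]))
  r <- c_trilinear(as.numeric(source$values), grid_dim(source),
                   source$origin, source$spacing, pts, 0)
  if (r$n_outside > 0 && !quiet)
    message(sprintf("resample_to_grid: %d target voxels outside source extent set to 0",
                    r$n_outside))
  out <- voxel_grid(array(r$values, dim = d), tg$spacing, tg$origin,
                    unit = source$unit)
  attr(out, "n_outside") <- r$n_outside
  out
}
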