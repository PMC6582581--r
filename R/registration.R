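#' Create a deformation vector field
#'
#' Per-voxel displacement in mm on a reference geometry.  Component order is
#' (left, posterior, superior) = (+x, +y, +z); the field maps positions in
#' the fixed (FB) anatomy to the corresponding positions in the moving
#' (DIBH) anatomy.
#'
#' @param displacements numeric matrix, one row per voxel in array order,
#'   columns (dx, dy, dz) mm.
#' @param dim,spacing,origin reference grid geometry.
#' @return an object of class `deformation_field`.
#' @export
deformation_field <- function(displacements, dim, spacing, origin) {
  displacements <- as.matrix(displacements)
  dim <- as.integer(dim)
  if (nrow(displacements) != prod(dim) || ncol(displacements) != 3L)
    stop_geometry("displacement matrix does not match reference grid")
  if (any(!is.finite(displacements)))
    stop("deformation field contains non-finite displacements")
  structure(list(displacements = displacements, dim = dim,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf("<deformation_field> %s, |d| mean %.2f mm, max %.2f mm\n",
              paste(x$dim, collapse = " x "), mean(mag), max(mag)))
  invisible(x)
}

field_geometry <- function(f) list(dim = f$dim, spacing = f$spacing,
                                   origin = f$origin)

#' Split a CT into lung and non-lung images
#'
#' Replaces voxels outside (inside) the lung mask with a constant fill HU so
#' the two tissue classes can be registered independently, avoiding
#' cross-tissue gradients at the lung border.
#'
#' @param ct a [voxel_grid] in HU.
#' @param lung_mask a [mask_grid] aligned to `ct`.
#' @param fill fill HU (default -1000, air).
#' @return list with `lung` and `nonlung` [voxel_grid]s; the fill value is
#'   recorded as attribute `fill` on each.
#' @export
split_tissue <- function(ct, lung_mask, fill = -1000) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(lung_mask, "mask"))
  if (!same_geometry(ct, lung_mask)) stop_geometry("mask not aligned to CT")
  if (!any(lung_mask$values)) stop_empty("lung mask is empty")
  lungv <- ct$values; lungv[!lung_mask$values] <- fill
  nonv <- ct$values; nonv[lung_mask$values] <- fill
  lung <- voxel_grid(lungv, ct$spacing, ct$origin, unit = ct$unit)
  nonlung <- voxel_grid(nonv, ct$spacing, ct$origin, unit = ct$unit)
  attr(lung, "fill") <- fill; attr(nonlung, "fill") <- fill
  list(lung = lung, nonlung = nonlung)
}

## Linearly map the moving image's foreground intensities onto the fixed
## image's (mean/SD match).  Foreground = values above the fill/background
## level (the `fill` attribute when present, else the volume minimum).
match_foreground <- function(moving, fixed) {
  fill_m <- attr(moving, "fill"); fill_f <- attr(fixed, "fill")
  if (is.null(fill_m)) fill_m <- min(moving$values)
  if (is.null(fill_f)) fill_f <- min(fixed$values)
  fg_m <- moving$values > fill_m + 1e-6
  fg_f <- fixed$values > fill_f + 1e-6
  if (sum(fg_m) < 10 || sum(fg_f) < 10) return(moving)
  mu_m <- mean(moving$values[fg_m]); sd_m <- sd(moving$values[fg_m])
  mu_f <- mean(fixed$values[fg_f]); sd_f <- sd(fixed$values[fg_f])
  if (!is.finite(sd_m) || sd_m < 1e-9) return(moving)
  v <- moving$values
  v[fg_m] <- (v[fg_m] - mu_m) * (sd_f / sd_m) + mu_f
  out <- voxel_grid(v, moving$spacing, moving$origin, unit = moving$unit)
  attr(out, "fill") <- fill_m
  out
}

## Downsample a grid by integer factor 2 along every axis (block average).
downsample2 <- function(g) {
  d <- grid_dim(g)
  avg_axis <- function(a, axis) {
    n <- dim(a)[axis]
    if (n < 2L) return(a)
    n2 <- n %/% 2L
    i1 <- seq.int(1L, 2L * n2, by = 2L)
    ix <- function(idx) switch(axis, a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE],
                               a[, , idx, drop = FALSE])
    (ix(i1) + ix(i1 + 1L)) / 2
  }
  out <- avg_axis(avg_axis(avg_axis(g$values, 1L), 2L), 3L)
  sp <- ifelse(d >= 2L, g$spacing * 2, g$spacing)
  or <- ifelse(d >= 2L, g$origin + g$spacing / 2, g$origin)
  voxel_grid(out, sp, or, unit = g$unit)
}

downsample_by <- function(g, factor) {
  while (factor >= 2) { g <- downsample2(g); factor <- factor / 2 }
  g
}

## Central-difference spatial gradient volumes (value per mm).
gradient_volumes <- function(g) {
  d <- grid_dim(g)
  grad1 <- function(a, axis, h) {
    n <- dim(a)[axis]
    ix <- function(idx) switch(axis, a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE],
                               a[, , idx, drop = FALSE])
    if (n < 2L) return(array(0, dim(a)))
    up <- c(2:n, n); lo <- c(1, 1:(n - 1))
    den <- rep(2 * h, n); den[1] <- h; den[n] <- h
    out <- (ix(up) - ix(lo))
    scl <- array(1, dim(a))
    if (axis == 1L) scl[] <- rep(den, times = dim(a)[2] * dim(a)[3])
    if (axis == 2L) scl[] <- rep(rep(den, each = dim(a)[1]), times = dim(a)[3])
    if (axis == 3L) scl[] <- rep(den, each = dim(a)[1] * dim(a)[2])
    out / scl
  }
  list(gx = grad1(g$values, 1L, g$spacing[1]),
       gy = grad1(g$values, 2L, g$spacing[2]),
       gz = grad1(g$values, 3L, g$spacing[3]))
}

control_grid_for <- function(geom, cspacing) {
  extent <- (geom$dim - 1) * geom$spacing
  nc <- pmax(4L, as.integer(floor((extent + cspacing) / cspacing)) + 4L)
  corigin <- geom$origin - cspacing
  list(dim = nc, spacing = rep(cspacing, 3), origin = corigin)
}

eval_coef_field <- function(coef, cg, geom) {
  c_bspline_field(coef, cg$dim, cg$origin, cg$spacing,
                  as.integer(geom$dim), geom$origin, geom$spacing)
}

#' Multi-resolution B-spline deformable registration
#'
#' Free-form deformation parameterized by cubic B-spline control points,
#' optimized over coarse-to-fine stages by minimizing the mean squared
#' intensity error (L-BFGS-B with analytic gradient).  The control-point
#' spacing halves at every stage down to `finest_spacing`; images are block-
#' averaged to a matching pyramid level at the coarse stages.  The fixed
#' image defines the output geometry, so with fixed = FB and moving = DIBH
#' the returned field expresses FB-to-DIBH motion.
#'
#' Non-convergence is not an error: the field is returned together with
#' per-stage MSE diagnostics (attribute `diagnostics`), and the final MSE is
#' checked against the identity-transform MSE.
#'
#' @param fixed,moving [voxel_grid]s sharing a physical frame overlap.
#' Between breathing states the mean lung density drops, so the same tissue
#' is systematically darker in the DIBH scan; with `normalize = TRUE`
#' (default) the moving-image foreground intensities are linearly matched
#' to the fixed-image foreground (mean/SD, excluding the fill background)
#' before optimization, which makes the squared-error metric well posed.
#'
#' @param stages number of multi-resolution stages (default 6).
#' @param finest_spacing control-point spacing at the last stage, mm.
#' @param max_iter L-BFGS-B iterations per stage.
#' @param normalize match moving foreground intensities to fixed before
#'   registering.
#' @param verbose print per-stage MSE.
#' @return a [deformation_field] on the fixed geometry.
#' @export
register_deformable <- function(fixed, moving, stages = 6L,
                                finest_spacing = 10, max_iter = 40L,
                                normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(fixed, "voxel_grid"), inherits(moving, "voxel_grid"))
  if (stages < 1L) stop("stages must be >= 1")
  if (normalize) moving <- match_foreground(moving, fixed)
  s_lo <- fixed$origin; s_hi <- fixed$origin + (grid_dim(fixed) - 1) * fixed$spacing
  m_lo <- moving$origin; m_hi <- moving$origin + (grid_dim(moving) - 1) * moving$spacing
  if (any(m_hi < s_lo) || any(s_hi < m_lo))
    stop_geometry("fixed and moving frames are disjoint")
  diagnostics <- list()
  prev <- NULL   # list(coef, cg)
  for (s in seq_len(stages)) {
    cspacing <- finest_spacing * 2^(stages - s)
    shrink <- max(1, min(4, 2^(stages - s - 1)))
    fs <- downsample_by(fixed, shrink)
    ms <- downsample_by(moving, shrink)
    gr <- gradient_volumes(ms)
    geom_f <- geometry_of(fs)
    cg <- control_grid_for(geom_f, cspacing)
    coef <- if (is.null(prev)) {
      numeric(prod(cg$dim) * 3)
    } else {
      ## initialize from the previous stage's field sampled at the new
      ## control points (B-spline quasi-interpolation)
      as.numeric(eval_coef_field(prev$coef, prev$cg,
                                 list(dim = cg$dim, spacing = cg$spacing,
                                      origin = cg$origin)))
    }
    cache <- new.env(parent = emptyenv())
    evalc <- function(par, want_grad) {
      r <- c_reg_cost_grad(as.numeric(fs$values), grid_dim(fs), fs$origin,
                           fs$spacing, as.numeric(ms$values),
                           as.numeric(gr$gx), as.numeric(gr$gy),
                           as.numeric(gr$gz), grid_dim(ms), ms$origin,
                           ms$spacing, par, cg$dim, cg$origin, cg$spacing,
                           want_grad)
      r
    }
    fn <- function(par) {
      r <- evalc(par, TRUE)
      cache$par <- par; cache$grad <- r$grad
      r$cost
    }
    grf <- function(par) {
      if (!is.null(cache$par) && identical(cache$par, par)) return(cache$grad)
      evalc(par, TRUE)$grad
    }
    mse0 <- evalc(coef, FALSE)$cost
    opt <- stats::optim(coef, fn, grf, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1e7))
    coef <- opt$par
    mse1 <- opt$value
    diagnostics[[s]] <- list(stage = s, control_spacing = cspacing,
                             shrink = shrink, mse_initial = mse0,
                             mse_final = mse1)
    if (verbose)
      message(sprintf("stage %d: spacing %.0f mm, shrink %d, MSE %.4g -> %.4g",
                      s, cspacing, shrink, mse0, mse1))
    prev <- list(coef = coef, cg = cg)
  }
  geom <- geometry_of(fixed)
  disp <- eval_coef_field(prev$coef, prev$cg, geom)
  out <- deformation_field(disp, geom$dim, geom$spacing, geom$origin)
  ## contract: registered MSE should not exceed the identity MSE
  fsl <- downsample_by(fixed, diagnostics[[stages]]$shrink)
  id_mse <- {
    msl <- downsample_by(moving, diagnostics[[stages]]$shrink)
    grl <- gradient_volumes(msl)
    c_reg_cost_grad(as.numeric(fsl$values), grid_dim(fsl), fsl$origin,
                    fsl$spacing, as.numeric(msl$values), as.numeric(grl$gx),
                    as.numeric(grl$gy), as.numeric(grl$gz), grid_dim(msl),
                    msl$origin, msl$spacing,
                    numeric(prod(prev$cg$dim) * 3), prev$cg$dim,
                    prev$cg$origin, prev$cg$spacing, FALSE)$cost
  }
  final_mse <- diagnostics[[stages]]$mse_final
  if (final_mse > id_mse + 1e-9)
    warning("registration did not improve on the identity transform")
  attr(out, "diagnostics") <- list(stages = diagnostics,
                                   identity_mse = id_mse,
                                   final_mse = final_mse)
  out
}

## morphological helpers on logical arrays (6-neighborhood)
shift_logical <- function(a, axis, by, fill) {
  n <- dim(a)[axis]
  out <- array(fill, dim(a))
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  if (axis == 2L) out[, dst, ] <- a[, src, ]
  if (axis == 3L) out[, , dst] <- a[, , src]
  out
}

dilate1 <- function(a) {
  a | shift_logical(a, 1L, 1L, FALSE) | shift_logical(a, 1L, -1L, FALSE) |
    shift_logical(a, 2L, 1L, FALSE) | shift_logical(a, 2L, -1L, FALSE) |
    shift_logical(a, 3L, 1L, FALSE) | shift_logical(a, 3L, -1L, FALSE)
}

erode1 <- function(a) {
  a & shift_logical(a, 1L, 1L, TRUE) & shift_logical(a, 1L, -1L, TRUE) &
    shift_logical(a, 2L, 1L, TRUE) & shift_logical(a, 2L, -1L, TRUE) &
    shift_logical(a, 3L, 1L, TRUE) & shift_logical(a, 3L, -1L, TRUE)
}

#' Merge lung and non-lung deformation fields
#'
#' Takes the lung field inside the lung mask and the non-lung field outside,
#' with a linear cross-fade over a morphological boundary band of `band`
#' voxels on each side to avoid a discontinuity at the lung surface.  With
#' `band = 0` the merge is exactly piecewise.
#'
#' @param lung_dvf,nonlung_dvf [deformation_field]s on the same geometry.
#' @param lung_mask a [mask_grid] on the same geometry.
#' @param band cross-fade half-width in voxels (default 3).
#' @return a merged [deformation_field].
#' @export
merge_dvf <- function(lung_dvf, nonlung_dvf, lung_mask, band = 3L) {
  if (!identical(lung_dvf$dim, nonlung_dvf$dim) ||
      max(abs(lung_dvf$origin - nonlung_dvf$origin)) > 1e-6 ||
      !identical(lung_dvf$dim, dim(lung_mask$values)))
    stop_geometry("fields and mask must share one geometry")
  m <- lung_mask$values
  if (band <= 0) {
    w <- as.numeric(m)
  } else {
    acc <- array(as.numeric(m), dim(m))
    d <- m; e <- m
    for (i in seq_len(band)) {
      d <- dilate1(d); e <- erode1(e)
      acc <- acc + d + e
    }
    w <- as.numeric(acc) / (2 * band + 1)
  }
  disp <- lung_dvf$displacements * w + nonlung_dvf$displacements * (1 - w)
  out <- deformation_field(disp, lung_dvf$dim, lung_dvf$spacing,
                           lung_dvf$origin)
  attr(out, "blend_band") <- band
  out
}

#' Warp a mask through a deformation field
#'
#' Pull-back warp with nearest-neighbor sampling: the output voxel at
#' position x takes the input mask value at x + u(x).  With the FB-to-DIBH
#' field this maps a DIBH-frame structure onto the FB anatomy (the direction
#' used to compare the deformed DIBH V20 region with the FB V20 region).
#' Positions mapping outside the mask extent are empty.  The relative volume
#' change is recorded as attribute `volume_change`.
#'
#' @param mask a [mask_grid].
#' @param dvf a [deformation_field] on the mask geometry.
#' @return the warped [mask_grid].
#' @export
warp_mask <- function(mask, dvf) {
  stopifnot(inherits(mask, "mask"), inherits(dvf, "deformation_field"))
  if (!identical(dim(mask$values), dvf$dim))
    stop_geometry("field not on mask geometry")
  d <- dvf$dim
  pts <- cbind(
    rep(mask$origin[1] + (seq_len(d[1]) - 1) * mask$spacing[1], times = d[2] * d[3]),
    rep(rep(mask$origin[2] + (seq_len(d[2]) - 1) * mask$spacing[2], each = d[1]),
        times = d[3]),
    rep(mask$origin[3] + (seq_len(d[3]) - 1) * mask$spacing[3], each = d[1] * d[2]))
  p <- pts + dvf$displacements
  ijk <- round(sweep(sweep(p, 2, mask$origin), 2, mask$spacing, "/")) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- logical(prod(d))
  lin <- ijk[ok, 1] + d[1] * (ijk[ok, 2] - 1) + d[1] * d[2] * (ijk[ok, 3] - 1)
  out[ok] <- mask$values[lin]
  res <- mask_grid(array(out, d), mask$spacing, mask$origin)
  v0 <- sum(mask$values)
  attr(res, "volume_change") <- if (v0 > 0) (sum(out) - v0) / v0 else NA_real_
  res
}

#' Dice overlap of two masks
#' @param a,b [mask_grid]s on the same geometry.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a$values), dim(b$values)))
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

#' Directional lung-expansion metrics from a deformation field
#'
#' Means of the displacement components over the masked (FB-frame) voxels,
#' reported in the anatomical directions of interest: left (+x), anterior
#' (-y) and caudal (-z).  `expansion_3d` is the Euclidean norm of the mean
#' component vector (the voxel-wise mean displacement magnitude is also
#' reported as `expansion_3d_voxelwise`).  The breathing-pattern index is
#' the caudal-minus-anterior difference normalized to the anterior
#' expansion, in percent: negative means chest-dominant (anterior) breathing,
#' positive abdominal-dominant.  With near-zero anterior expansion the index
#' is undefined and returned as `NA` with `breathing_index_defined = FALSE`.
#'
#' @param dvf a [deformation_field].
#' @param mask a [mask_grid] on the field geometry selecting the structure.
#' @return an object of class `expansion_metrics` with fields `mean_left`,
#'   `mean_anterior`, `mean_caudal`, `expansion_3d`,
#'   `expansion_3d_voxelwise`, `breathing_index`, `breathing_index_defined`.
#' @export
expansion_metrics <- function(dvf, mask) {
  stopifnot(inherits(dvf, "deformation_field"), inherits(mask, "mask"))
  if (!identical(dvf$dim, dim(mask$values)))
    stop_geometry("field and mask not aligned")
  idx <- which(mask$values)
  if (!length(idx)) stop_empty("mask selects no voxels")
  u <- dvf$displacements[idx, , drop = FALSE]
  mean_left <- mean(u[, 1])
  mean_anterior <- -mean(u[, 2])
  mean_caudal <- -mean(u[, 3])
  e3d <- sqrt(mean_left^2 + mean_anterior^2 + mean_caudal^2)
  e3dv <- mean(sqrt(rowSums(u^2)))
  defined <- abs(mean_anterior) > 1e-9
  bi <- if (defined) (mean_caudal - mean_anterior) * 100 / mean_anterior
        else NA_real_
  structure(list(mean_left = mean_left, mean_anterior = mean_anterior,
                 mean_caudal = mean_caudal, expansion_3d = e3d,
                 expansion_3d_voxelwise = e3dv, breathing_index = bi,
                 breathing_index_defined = defined),
            class = "expansion_metrics")
}

#' @export
print.expansion_metrics <- function(x, ...) {
  cat(sprintf("<expansion_metrics> left %.2f, anterior %.2f, caudal %.2f mm\n",
              x$mean_left, x$mean_anterior, x$mean_caudal))
  cat(sprintf("  3D expansion %.2f mm, breathing index %s\n", x$expansion_3d,
              if (x$breathing_index_defined)
                sprintf("%.1f%%", x$breathing_index) else "undefined"))
  invisible(x)
}
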