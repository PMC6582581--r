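## Paired FB/DIBH thorax phantom generator.  The phantom is a stated world:
## an elliptic-cylinder body, a left lung ellipsoid that expands
## anisotropically between breathing states under an affine map with known
## volume factor (mass-conserving density change), a spherical heart that is
## displaced posterior-inferior in DIBH, a breast-like PTV, and an opposed-
## tangential-field dose model anchored to the anterior lung surface.

stop_param <- function(msg) {
  stop(errorCondition(msg, class = c("dosemass_parameter_error", "error")))
}

## run code with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## truncated normal via inverse-CDF (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Phantom construction parameters
#'
#' Defaults describe the cohort the generator emulates: a 1432 cm^3 free-
#' breathing left lung of density 0.31 g/cm^3 that expands by a factor 1.8
#' in DIBH with conserved mass; mean lung displacements of 1.5 mm (left),
#' 16.0 mm (anterior) and 12.2 mm (caudal); a heart displaced 18 mm
#' posterior and 12 mm inferior out of the tangential fields; and opposed
#' tangential beams normalized to a 50 Gy median PTV dose.  Voxels default
#' to 2.5 x 2.5 x 3 mm.
#'
#' @param spacing voxel spacing in mm (x, y, z).
#' @param body_half_axes body half-axes (x, y) and half-length (z), mm.
#' @param lung_volume_cm3 FB left-lung volume target.
#' @param lung_density_fb FB lung mass density, g/cm^3.
#' @param expansion_factor DIBH/FB lung volume ratio (> 1); the DIBH
#'   density is derived from it by mass conservation.
#' @param mean_expansion_mm named (left, anterior, caudal) mean lung
#'   displacements in mm.
#' @param scale_exponents partition of the volume factor over (x, y, z)
#'   axis scalings (must sum to 1); anterior-dominant by default.
#' @param lung_center_fb,lung_axes_base FB lung ellipsoid center and
#'   half-axis proportions (rescaled to the volume target), mm.
#' @param heart_center_fb,heart_radius heart sphere geometry, mm.
#' @param heart_displacement named (posterior, inferior) DIBH heart shift, mm.
#' @param ptv_volume_cm3,ptv_center,ptv_axes_base PTV ellipsoid; the DIBH
#'   PTV follows the chest wall anteriorly by
#'   `ptv_tracking * anterior expansion`.
#' @param ptv_tracking fraction of the anterior lung expansion applied to
#'   the PTV position in DIBH (the PTV is moved further anteriorly when
#'   needed to keep the tangential field covering it, see
#'   `ptv_field_margin_mm`).
#' @param ptv_field_margin_mm minimum margin between the field border and
#'   the PTV center projection, mm.
#' @param field_angle_deg angle of the tangential field border normal from
#'   +x towards -y (left-anterior wedge).
#' @param field_depth_mm central lung distance: depth of the field border
#'   posterior to the anterior lung surface, identical in both phases.
#' @param penumbra_sigma_mm Gaussian penumbra width.
#' @param scatter_frac,scatter_range_mm out-of-field exponential scatter
#'   floor (fraction of prescription, decay length mm).
#' @param field_z_margin_mm field length margin beyond the PTV.
#' @param prescription_gy prescription dose (median PTV dose after
#'   normalization).
#' @param noise_hu CT noise SD in HU.
#' @param density_noise lung density noise SD, g/cm^3.
#' @param texture_amp,texture_wavelength_mm smooth intra-lung density
#'   texture (relative amplitude; per-axis wavelengths) that deforms with
#'   the ground-truth map, giving the registration interior structure.
#' @param adverse logical: construct an adverse-anatomy patient in which
#'   the anterior in-field lung stays poorly aerated in DIBH (relatively
#'   dense, mass redistributed from the rest of the lung) so the irradiated
#'   lung mass increases despite the volumetric benefit.
#' @param adverse_density_boost relative density excess of the in-field
#'   lung band for adverse patients.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(spacing = c(2.5, 2.5, 3),
                           body_half_axes = c(175, 135, 160),
                           lung_volume_cm3 = 1432,
                           lung_density_fb = 0.31,
                           expansion_factor = 1.8,
                           mean_expansion_mm = c(left = 1.5, anterior = 16,
                                                 caudal = 12.2),
                           scale_exponents = c(0.08, 0.55, 0.37),
                           lung_center_fb = c(85, 20, 20),
                           lung_axes_base = c(55, 60, 95),
                           heart_center_fb = c(5, -50, -95),
                           heart_radius = 40,
                           heart_displacement = c(posterior = 18,
                                                  inferior = 12),
                           ptv_volume_cm3 = 965,
                           ptv_center = c(80, -62, 0),
                           ptv_axes_base = c(64, 45, 80),
                           ptv_tracking = 0.8,
                           ptv_field_margin_mm = 15,
                           field_angle_deg = 35,
                           field_depth_mm = 30,
                           penumbra_sigma_mm = 5,
                           scatter_frac = 0.05,
                           scatter_range_mm = 50,
                           field_z_margin_mm = 5,
                           prescription_gy = 50,
                           noise_hu = 10,
                           density_noise = 0.02,
                           texture_amp = 0.25,
                           texture_wavelength_mm = c(48, 42, 56),
                           adverse = FALSE,
                           adverse_density_boost = 0.8) {
  p <- as.list(environment())
  if (p$expansion_factor <= 1) stop_param("expansion factor must be > 1")
  if (p$lung_density_fb <= 0 || p$lung_density_fb >= 2)
    stop_param("lung density must be in (0, 2) g/cm^3")
  if (any(p$spacing <= 0) || any(p$body_half_axes <= 0) ||
      p$lung_volume_cm3 <= 0 || p$heart_radius <= 0 || p$ptv_volume_cm3 <= 0)
    stop_param("all sizes must be positive")
  if (abs(sum(p$scale_exponents) - 1) > 1e-9)
    stop_param("scale_exponents must sum to 1")
  class(p) <- "phantom_params"
  p
}

## analytic per-phase geometry derived from parameters
phantom_geometry <- function(p) {
  s <- (p$lung_volume_cm3 * 1000 /
          (4 / 3 * pi * prod(p$lung_axes_base)))^(1 / 3)
  half_fb <- p$lung_axes_base * s
  scl <- p$expansion_factor^p$scale_exponents
  dc <- c(p$mean_expansion_mm[["left"]], -p$mean_expansion_mm[["anterior"]],
          -p$mean_expansion_mm[["caudal"]])
  lung_fb <- list(center = p$lung_center_fb, half = half_fb)
  lung_dibh <- list(center = p$lung_center_fb + dc, half = half_fb * scl)
  heart_fb <- list(center = p$heart_center_fb, r = p$heart_radius)
  heart_dibh <- list(center = p$heart_center_fb +
                       c(0, p$heart_displacement[["posterior"]],
                         -p$heart_displacement[["inferior"]]),
                     r = p$heart_radius)
  sp <- (p$ptv_volume_cm3 * 1000 /
           (4 / 3 * pi * prod(p$ptv_axes_base)))^(1 / 3)
  ptv_fb <- list(center = p$ptv_center, half = p$ptv_axes_base * sp)
  a <- p$field_angle_deg * pi / 180
  nrm <- c(sin(a), -cos(a), 0)
  surf <- function(l) sum(l$center * nrm) +
    sqrt(sum((l$half * nrm)^2))
  ## the breast sits on the chest wall: in DIBH the PTV follows the anterior
  ## expansion, and at least far enough that the field border (anchored to
  ## the anterior lung surface) keeps covering it with a penumbra margin
  ptv_proj_fb <- sum(ptv_fb$center * nrm)
  needed <- surf(lung_dibh) - p$field_depth_mm + p$ptv_field_margin_mm
  shift_ant <- max(p$ptv_tracking * p$mean_expansion_mm[["anterior"]],
                   (needed - ptv_proj_fb) / abs(nrm[2]))
  ptv_dibh <- list(center = p$ptv_center + c(0, -shift_ant, 0),
                   half = ptv_fb$half)
  zwin <- c(p$ptv_center[3] - ptv_fb$half[3] - p$field_z_margin_mm,
            p$ptv_center[3] + ptv_fb$half[3] + p$field_z_margin_mm)
  list(s = s, scl = scl, dc = dc,
       lung = list(fb = lung_fb, dibh = lung_dibh),
       heart = list(fb = heart_fb, dibh = heart_dibh),
       ptv = list(fb = ptv_fb, dibh = ptv_dibh),
       normal = nrm,
       threshold = list(fb = surf(lung_fb) - p$field_depth_mm,
                        dibh = surf(lung_dibh) - p$field_depth_mm),
       zwin = zwin)
}

phantom_grid_geom <- function(p) {
  ext <- c(p$body_half_axes[1] + 15, p$body_half_axes[2] + 15,
           p$body_half_axes[3] + 10)
  d <- as.integer(floor(2 * ext / p$spacing)) + 1L
  list(dim = d, spacing = p$spacing, origin = -(d - 1) / 2 * p$spacing)
}

## squared-ellipsoid level array over a grid geometry (1 on the surface)
level_array <- function(geom, center, half) {
  lx <- ((geom$origin[1] + (seq_len(geom$dim[1]) - 1) * geom$spacing[1] -
            center[1]) / half[1])^2
  ly <- ((geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2] -
            center[2]) / half[2])^2
  lz <- ((geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3] -
            center[3]) / half[3])^2
  array(rep(lx, times = geom$dim[2] * geom$dim[3]) +
          rep(rep(ly, each = geom$dim[1]), times = geom$dim[3]) +
          rep(lz, each = geom$dim[1] * geom$dim[2]), dim = geom$dim)
}

body_array <- function(geom, p) {
  lx <- ((geom$origin[1] + (seq_len(geom$dim[1]) - 1) * geom$spacing[1]) /
           p$body_half_axes[1])^2
  ly <- ((geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2]) /
           p$body_half_axes[2])^2
  zz <- abs(geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3]) <=
    p$body_half_axes[3]
  inplane <- rep(lx, times = geom$dim[2]) + rep(ly, each = geom$dim[1]) <= 1
  array(rep(inplane, times = geom$dim[3]) &
          rep(zz, each = geom$dim[1] * geom$dim[2]), dim = geom$dim)
}

## closed N-gon approximating an ellipse cross-section
ellipse_polygon <- function(cx, cy, ax, ay, z, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + ax * cos(th), cy + ay * sin(th), z)
}

ellipsoid_contours <- function(center, half, zs, n = 64L) {
  out <- list()
  for (z in zs) {
    rr <- 1 - ((z - center[3]) / half[3])^2
    if (rr <= 1e-4) next
    out[[length(out) + 1L]] <-
      ellipse_polygon(center[1], center[2], half[1] * sqrt(rr),
                      half[2] * sqrt(rr), z, n)
  }
  if (!length(out)) stop_param("structure intersects no slice")
  out
}

body_contours <- function(p, zs, n = 64L) {
  out <- list()
  for (z in zs) {
    if (abs(z) > p$body_half_axes[3]) next
    out[[length(out) + 1L]] <-
      ellipse_polygon(0, 0, p$body_half_axes[1], p$body_half_axes[2], z, n)
  }
  out
}

## smooth non-periodic texture in FB material coordinates: a sum of
## random-direction sinusoids (seeded per patient), giving the registration
## interior landmarks without the phase ambiguity of a periodic pattern
texture_basis <- function(p, n_waves = 6L) {
  dirs <- matrix(rnorm(3 * n_waves), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  wl <- runif(n_waves, min(p$texture_wavelength_mm),
              max(p$texture_wavelength_mm))
  list(k = dirs / wl, phase = runif(n_waves, 0, 2 * pi),
       amp = rep(1 / sqrt(n_waves / 2), n_waves))
}

lung_texture <- function(x, y, z, basis) {
  out <- 0
  for (j in seq_along(basis$phase))
    out <- out + basis$amp[j] *
      sin(2 * pi * (x * basis$k[j, 1] + y * basis$k[j, 2] +
                      z * basis$k[j, 3]) + basis$phase[j])
  out
}

## coordinate component arrays for a grid geometry
coord_arrays <- function(geom) {
  list(x = rep(geom$origin[1] + (seq_len(geom$dim[1]) - 1) * geom$spacing[1],
               times = geom$dim[2] * geom$dim[3]),
       y = rep(rep(geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2],
                   each = geom$dim[1]), times = geom$dim[3]),
       z = rep(geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3],
               each = geom$dim[1] * geom$dim[2]))
}

#' Opposed-tangential-field dose model
#'
#' Geometric two-tangent dose: prescription dose anterior-left of a field
#' border plane anchored `field_depth_mm` posterior to the anterior lung
#' surface of the phase, within the PTV's longitudinal window, smoothed with
#' a Gaussian penumbra and an exponential scatter floor outside, zero
#' outside the body, and renormalized so the median PTV dose equals the
#' prescription.  This is a field-shape model, not a transport calculation.
#'
#' @param ct the phase's CT [voxel_grid] (supplies the geometry).
#' @param structures the phase's [structure_set] (needs `left_lung`, `ptv`,
#'   `body`).
#' @param params a [phantom_params].
#' @return a [voxel_grid] in Gy.
#' @export
generate_tangential_dose <- function(ct, structures, params) {
  geom <- geometry_of(ct)
  nrm <- c(sin(params$field_angle_deg * pi / 180),
           -cos(params$field_angle_deg * pi / 180))
  lung_pts <- do.call(rbind, structures$structures$left_lung)
  ptv_pts <- do.call(rbind, structures$structures$ptv)
  thr <- max(lung_pts[, 1] * nrm[1] + lung_pts[, 2] * nrm[2]) -
    params$field_depth_mm
  zwin <- range(ptv_pts[, 3]) + c(-1, 1) * params$field_z_margin_mm
  xs <- geom$origin[1] + (seq_len(geom$dim[1]) - 1) * geom$spacing[1]
  ys <- geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2]
  zs <- geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3]
  proj <- rep(xs * nrm[1], times = geom$dim[2]) +
    rep(ys * nrm[2], each = geom$dim[1])
  dn <- proj - thr
  pr_xy <- pmax(pnorm(dn / params$penumbra_sigma_mm),
                params$scatter_frac * exp(pmin(dn, 0) / params$scatter_range_mm))
  dz_out <- pmax(zwin[1] - zs, zs - zwin[2], 0)
  pr_z <- pmax(pnorm((zs - zwin[1]) / params$penumbra_sigma_mm) *
                 pnorm((zwin[2] - zs) / params$penumbra_sigma_mm),
               params$scatter_frac * exp(-dz_out / params$scatter_range_mm))
  dose <- array(rep(pr_xy, times = geom$dim[3]) *
                  rep(pr_z, each = geom$dim[1] * geom$dim[2]),
                dim = geom$dim) * params$prescription_gy
  dose_grid <- voxel_grid(dose, geom$spacing, geom$origin, unit = "Gy")
  body <- rasterize(structures, dose_grid, name = "body")
  dose[!body$values] <- 0
  ptv <- rasterize(structures, dose_grid, name = "ptv")
  med <- median(dose[ptv$values])
  if (!is.finite(med) || med <= 0) {
    warning("PTV receives no dose; normalization skipped")
  } else {
    dose <- dose * params$prescription_gy / med
  }
  voxel_grid(dose, geom$spacing, geom$origin, unit = "Gy")
}

#' Generate a paired FB/DIBH phantom
#'
#' Builds the FB and DIBH CT volumes, structure sets (left_lung, heart, ptv,
#' body), tangential-field dose grids and the analytic ground-truth
#' deformation field (FB to DIBH).  The DIBH lung is the affine image of the
#' FB lung: center shifted by the requested mean expansions, half-axes
#' scaled so the volume grows by `expansion_factor`; the DIBH density is the
#' material-mapped FB density divided by the local volume factor, so lung
#' mass is conserved by construction.  CT values are obtained by inverting
#' the default density table, closing the loop with [hu_to_density()].
#'
#' @param params a [phantom_params].
#' @param seed integer seed; the pair is bit-reproducible given (params,
#'   seed).
#' @return an object of class `patient_pair`: `fb` and `dibh` (each with
#'   `ct`, `structures`, `dose`), `ground_truth_dvf`, `params`.
#' @export
generate_pair <- function(params = phantom_params(), seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  with_local_seed(seed, {
    g <- phantom_geometry(params)
    geom <- phantom_grid_geom(params)
    zs <- geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3]
    body <- body_array(geom, params)
    lev_lung_fb <- level_array(geom, g$lung$fb$center, g$lung$fb$half)
    lev_lung_dibh <- level_array(geom, g$lung$dibh$center, g$lung$dibh$half)
    lev_heart_fb <- level_array(geom, g$heart$fb$center, rep(g$heart$fb$r, 3))
    lev_heart_dibh <- level_array(geom, g$heart$dibh$center,
                                  rep(g$heart$dibh$r, 3))
    ## parameter validity: organs inside body and mutually disjoint
    if (any(lev_lung_fb <= 1 & !body) || any(lev_lung_dibh <= 1 & !body) ||
        any(lev_heart_fb <= 1 & !body) || any(lev_heart_dibh <= 1 & !body))
      stop_param("lung or heart exceeds the body outline")
    if (any(lev_lung_fb <= 1 & lev_heart_fb <= 1) ||
        any(lev_lung_dibh <= 1 & lev_heart_dibh <= 1))
      stop_param("lung and heart overlap")
    co <- coord_arrays(geom)
    basis <- texture_basis(params)
    f <- params$expansion_factor

    rho_lung_fb <- function(x, y, z) {
      pmax(params$lung_density_fb *
             (1 + params$texture_amp * lung_texture(x, y, z, basis)),
           0.03)
    }
    ## FB density volume
    rho_fb <- array(0.00121, geom$dim)
    rho_fb[body] <- 1.04
    sel <- lev_lung_fb <= 1
    rho_fb[sel] <- rho_lung_fb(co$x[sel], co$y[sel], co$z[sel]) +
      rnorm(sum(sel), 0, params$density_noise)
    rho_fb[lev_heart_fb <= 1] <- 1.06

    ## DIBH density: material-mapped FB density / volume factor
    rho_dibh <- array(0.00121, geom$dim)
    rho_dibh[body] <- 1.04
    sel_d <- lev_lung_dibh <= 1
    xb <- g$lung$fb$center[1] + (co$x[sel_d] - g$lung$dibh$center[1]) / g$scl[1]
    yb <- g$lung$fb$center[2] + (co$y[sel_d] - g$lung$dibh$center[2]) / g$scl[2]
    zb <- g$lung$fb$center[3] + (co$z[sel_d] - g$lung$dibh$center[3]) / g$scl[3]
    rho_d <- rho_lung_fb(xb, yb, zb) / f
    if (isTRUE(params$adverse)) {
      ## adverse anatomy: the anterior in-field lung band stays poorly
      ## aerated in DIBH (denser); mass is redistributed, not created
      nrm <- g$normal[1:2]
      proj <- co$x[sel_d] * nrm[1] + co$y[sel_d] * nrm[2]
      infield <- proj >= g$threshold$dibh & co$z[sel_d] >= g$zwin[1] &
        co$z[sel_d] <= g$zwin[2]
      if (any(infield) && any(!infield)) {
        m_in <- sum(rho_d[infield]); m_out <- sum(rho_d[!infield])
        boost <- params$adverse_density_boost
        rho_d[infield] <- rho_d[infield] * (1 + boost)
        rho_d[!infield] <- rho_d[!infield] * (1 - boost * m_in / m_out)
      }
    }
    rho_dibh[sel_d] <- pmax(rho_d + rnorm(sum(sel_d), 0, params$density_noise),
                            0.02)
    rho_dibh[lev_heart_dibh <= 1] <- 1.06

    tab <- default_density_table()
    hu_fb <- density_to_hu(rho_fb, tab) + rnorm(length(rho_fb), 0, params$noise_hu)
    hu_dibh <- density_to_hu(rho_dibh, tab) +
      rnorm(length(rho_dibh), 0, params$noise_hu)
    ct_fb <- voxel_grid(array(hu_fb, geom$dim), geom$spacing, geom$origin, "HU")
    ct_dibh <- voxel_grid(array(hu_dibh, geom$dim), geom$spacing, geom$origin,
                          "HU")

    ss_fb <- structure_set(list(
      left_lung = ellipsoid_contours(g$lung$fb$center, g$lung$fb$half, zs),
      heart = ellipsoid_contours(g$heart$fb$center, rep(g$heart$fb$r, 3), zs),
      ptv = ellipsoid_contours(g$ptv$fb$center, g$ptv$fb$half, zs),
      body = body_contours(params, zs)))
    ss_dibh <- structure_set(list(
      left_lung = ellipsoid_contours(g$lung$dibh$center, g$lung$dibh$half, zs),
      heart = ellipsoid_contours(g$heart$dibh$center, rep(g$heart$dibh$r, 3), zs),
      ptv = ellipsoid_contours(g$ptv$dibh$center, g$ptv$dibh$half, zs),
      body = body_contours(params, zs)))

    dose_fb <- generate_tangential_dose(ct_fb, ss_fb, params)
    dose_dibh <- generate_tangential_dose(ct_dibh, ss_dibh, params)

    ## analytic ground-truth field: affine inside the lung, smooth falloff
    w <- ifelse(lev_lung_fb <= 1.05, 1,
                exp(-((sqrt(pmax(lev_lung_fb, 0)) - 1.05) / 0.45)^2))
    ux <- g$dc[1] + (g$scl[1] - 1) * (co$x - g$lung$fb$center[1])
    uy <- g$dc[2] + (g$scl[2] - 1) * (co$y - g$lung$fb$center[2])
    uz <- g$dc[3] + (g$scl[3] - 1) * (co$z - g$lung$fb$center[3])
    dvf <- deformation_field(cbind(ux * as.numeric(w), uy * as.numeric(w),
                                   uz * as.numeric(w)),
                             geom$dim, geom$spacing, geom$origin)
    structure(list(
      fb = list(ct = ct_fb, structures = ss_fb, dose = dose_fb),
      dibh = list(ct = ct_dibh, structures = ss_dibh, dose = dose_dibh),
      ground_truth_dvf = dvf,
      params = params, seed = seed), class = "patient_pair")
  })
}

#' @export
print.patient_pair <- function(x, ...) {
  cat(sprintf("<patient_pair> grid %s, seed %s%s\n",
              paste(dim(x$fb$ct$values), collapse = " x "), x$seed,
              if (isTRUE(x$params$adverse)) " (adverse anatomy)" else ""))
  invisible(x)
}

#' Cohort sampling distributions
#'
#' Means and SDs (with truncation ranges) for the per-patient parameters of
#' [generate_cohort()], defaulting to the emulated cohort: lung volume
#' 1432 +/- 290 cm^3, density 0.31 +/- 0.05 g/cm^3, volume change
#' 84 +/- 26 %, expansions 1.5 +/- 2.4 / 16 +/- 4 / 12.2 +/- 4.6 mm and PTV
#' volume 969 +/- 377 cm^3.
#'
#' @return a named list of `c(mean, sd, lo, hi)` vectors.
#' @export
cohort_distributions <- function() {
  list(lung_volume_cm3 = c(1432, 290, 900, 1950),
       lung_density_fb = c(0.31, 0.05, 0.20, 0.45),
       dvolume_pct = c(84, 26, 40, 115),
       expansion_left = c(1.5, 2.4, -4, 7),
       expansion_anterior = c(16, 4, 8, 26),
       expansion_caudal = c(12.2, 4.6, 2, 22),
       ptv_volume_cm3 = c(969, 377, 450, 1800),
       heart_posterior = c(18, 3, 10, 26),
       heart_inferior = c(12, 3, 5, 20),
       adverse_dvolume_pct = c(35, 5, 25, 45),
       adverse_caudal = c(24, 2, 20, 28))
}

sample_patient_params <- function(base, dist, adverse) {
  draw <- function(nm) {
    d <- dist[[nm]]
    rtnorm(1, d[1], d[2], d[3], d[4])
  }
  f <- if (adverse) 1 + draw("adverse_dvolume_pct") / 100
       else 1 + draw("dvolume_pct") / 100
  caudal <- if (adverse) draw("adverse_caudal") else draw("expansion_caudal")
  pp <- base
  pp$lung_volume_cm3 <- draw("lung_volume_cm3")
  pp$lung_density_fb <- draw("lung_density_fb")
  pp$expansion_factor <- f
  pp$mean_expansion_mm <- c(left = draw("expansion_left"),
                            anterior = draw("expansion_anterior"),
                            caudal = caudal)
  pp$ptv_volume_cm3 <- draw("ptv_volume_cm3")
  pp$heart_displacement <- c(posterior = draw("heart_posterior"),
                             inferior = draw("heart_inferior"))
  pp$adverse <- adverse
  pp
}

#' Generate a synthetic FB/DIBH cohort
#'
#' Samples per-patient parameters from [cohort_distributions()] (truncated
#' normals) and builds one [generate_pair()] phantom per patient.  A
#' configurable fraction of patients is constructed with adverse anatomy
#' (see [phantom_params()]); the adverse patient indices are sampled from
#' the same seed and recorded.
#'
#' @param n number of patients (>= 2).
#' @param params base [phantom_params] shared by all patients.
#' @param seed cohort seed; patient i uses a sub-seed derived from it.
#' @param adverse_fraction fraction of adverse-anatomy patients (default
#'   4/31).
#' @param distributions sampling distributions, see [cohort_distributions()].
#' @param materialize if `FALSE`, return the per-patient parameters and
#'   seeds without building the (memory-heavy) pairs; [cohort_pair()] then
#'   builds a single pair on demand.
#' @return if materialized, a list of [generate_pair()] objects with
#'   attributes `adverse_index` and `manifest`; otherwise a
#'   `phantom_cohort` manifest object.
#' @export
generate_cohort <- function(n, params = phantom_params(), seed = 1L,
                            adverse_fraction = 4 / 31,
                            distributions = cohort_distributions(),
                            materialize = TRUE) {
  if (n < 2) stop_param("cohort needs n >= 2")
  manifest <- with_local_seed(seed, {
    n_adv <- round(adverse_fraction * n)
    adverse_index <- sort(sample.int(n, n_adv))
    lapply(seq_len(n), function(i) {
      pp <- sample_patient_params(params, distributions, i %in% adverse_index)
      list(patient = i, params = pp, seed = (seed * 1000L + i) %% .Machine$integer.max,
           adverse = i %in% adverse_index)
    })
  })
  adverse_index <- which(vapply(manifest, `[[`, logical(1), "adverse"))
  cohort <- structure(list(manifest = manifest, adverse_index = adverse_index,
                           seed = seed),
                      class = "phantom_cohort")
  if (!materialize) return(cohort)
  pairs <- lapply(manifest, function(m) generate_pair(m$params, m$seed))
  attr(pairs, "adverse_index") <- adverse_index
  attr(pairs, "manifest") <- manifest
  pairs
}

#' Build one patient pair from a cohort manifest
#' @param cohort a `phantom_cohort` from `generate_cohort(materialize = FALSE)`.
#' @param i patient index.
#' @return a `patient_pair`.
#' @export
cohort_pair <- function(cohort, i) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  m <- cohort$manifest[[i]]
  generate_pair(m$params, m$seed)
}

#' Write a patient pair to research formats
#'
#' Layout: `<dir>/{fb,dibh}_ct.mha`, `_dose.mha`, `_structures.json`,
#' `ground_truth_dvf.mha`, `params.json`, `density_table.csv`.
#'
#' @param pair a `patient_pair`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_patient_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in c("fb", "dibh")) {
    write_volume(pair[[ph]]$ct, file.path(dir, paste0(ph, "_ct.mha")))
    write_volume(pair[[ph]]$dose, file.path(dir, paste0(ph, "_dose.mha")))
    write_structures(pair[[ph]]$structures,
                     file.path(dir, paste0(ph, "_structures.json")))
  }
  write_dvf_mha(pair$ground_truth_dvf, file.path(dir, "ground_truth_dvf.mha"))
  write_density_table(default_density_table(),
                      file.path(dir, "density_table.csv"))
  pj <- pair$params
  class(pj) <- NULL
  jsonlite::write_json(list(seed = pair$seed, params = pj),
                       file.path(dir, "params.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a patient pair written by [write_patient_pair()]
#' @param dir directory.
#' @return a `patient_pair`.
#' @export
read_patient_pair <- function(dir) {
  if (!file.exists(file.path(dir, "params.json")))
    stop_format(paste("not a patient pair directory:", dir))
  read_phase <- function(ph) {
    list(ct = read_volume(file.path(dir, paste0(ph, "_ct.mha"))),
         dose = read_dose(file.path(dir, paste0(ph, "_dose.mha"))),
         structures = read_structures(file.path(dir,
                                                paste0(ph, "_structures.json"))))
  }
  pj <- jsonlite::read_json(file.path(dir, "params.json"),
                            simplifyVector = TRUE)
  dvf_path <- file.path(dir, "ground_truth_dvf.mha")
  structure(list(fb = read_phase("fb"), dibh = read_phase("dibh"),
                 ground_truth_dvf = if (file.exists(dvf_path))
                   read_dvf_mha(dvf_path) else NULL,
                 params = pj$params, seed = pj$seed),
            class = "patient_pair")
}
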