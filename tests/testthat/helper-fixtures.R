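## Small builders and independent oracles shared across the suite.

## random dose grid + mask + density on a tiny geometry
random_case <- function(seed, max_dim = 10L) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  sp <- runif(3, 0.8, 4)
  dose <- voxel_grid(array(runif(prod(d), 0, 60), d), sp, c(0, 0, 0), "Gy")
  mask <- mask_grid(array(runif(prod(d)) < 0.6, d), sp, c(0, 0, 0))
  if (!any(mask$values)) mask$values[1] <- TRUE
  density <- voxel_grid(array(runif(prod(d), 0.05, 1.2), d), sp, c(0, 0, 0),
                        "g/cm3")
  list(dose = dose, mask = mask, density = density)
}

## brute-force per-voxel dosimetry oracle (independent of the histogram path)
brute_metrics <- function(dose, mask, density, levels) {
  vv <- prod(dose$spacing) / 1000
  d <- dose$values[mask$values]
  rho <- density$values[mask$values]
  vol <- length(d) * vv
  mass <- sum(rho * vv)
  out <- list(volume = vol, mass = mass,
              dmean_volume = sum(d * vv) / vol,
              dmean_mass = sum(d * rho * vv) / mass,
              mean_density = mass / vol)
  out$vx_abs <- vapply(levels, function(x) sum(d >= x) * vv, numeric(1))
  out$mx_abs <- vapply(levels, function(x) sum(rho[d >= x] * vv), numeric(1))
  out$vx_rel <- 100 * out$vx_abs / vol
  out$mx_rel <- 100 * out$mx_abs / mass
  out
}

## full sign-assignment enumeration oracle for the Wilcoxon exact p-value
wilcoxon_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 0L
  cnt_le <- 0L; cnt_ge <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    w <- sum(r[signs])
    cnt_le <- cnt_le + (w <= w_obs + 1e-9)
    cnt_ge <- cnt_ge + (w >= w_obs - 1e-9)
    total <- total + 1L
  }
  min(1, 2 * min(cnt_le / total, cnt_ge / total))
}

## coarse phantom parameters for fast tests
coarse_params <- function(...) phantom_params(spacing = c(10, 10, 12), ...)
medium_params <- function(...) phantom_params(spacing = c(6, 6, 7.5), ...)

lung_mask_of <- function(pair, phase = "fb") {
  rasterize(pair[[phase]]$structures, pair[[phase]]$ct, name = "left_lung")
}

lung_mass_of <- function(pair, phase) {
  m <- lung_mask_of(pair, phase)
  den <- hu_to_density(pair[[phase]]$ct)
  sum(den$values[m$values]) * voxel_volume_cm3(m)
}

## ---- minimal explicit-VR-LE DICOM writer (fixture only) ----

dcm_raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                       endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, as.raw(if (vr %in% c("OB")) 0 else 0x20))
  head <- c(dcm_raw_uint16(group), dcm_raw_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, dcm_raw_uint16(length(value_raw)), value_raw)
  }
}

dcm_ds <- function(group, elem, values)
  dcm_element(group, elem, "DS", charToRaw(paste(format(values, scientific = FALSE,
                                                        trim = TRUE),
                                                 collapse = "\\")))
dcm_is <- function(group, elem, values)
  dcm_element(group, elem, "IS", charToRaw(paste(as.integer(values),
                                                 collapse = "\\")))
dcm_us <- function(group, elem, value)
  dcm_element(group, elem, "US", dcm_raw_uint16(value))

dcm_file <- function(path, elements) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 128)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(unlist(elements), con)
  invisible(path)
}

## write an axial CT slice (signed 16-bit, HU = stored * slope + intercept)
write_ct_slice <- function(path, vals_xy, dx, dy, ipp, thickness = NULL,
                           slope = 1, intercept = 0) {
  ## array order (x fastest) equals DICOM raster order (columns within rows)
  stored <- round((vals_xy - intercept) / slope)
  px <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  els <- list()
  if (!is.null(thickness)) els <- c(els, list(dcm_ds(0x0018, 0x0050, thickness)))
  els <- c(els, list(
    dcm_ds(0x0020, 0x0032, ipp),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0010, ncol(vals_xy)),   # Rows (y)
    dcm_us(0x0028, 0x0011, nrow(vals_xy)),   # Columns (x)
    dcm_ds(0x0028, 0x0030, c(dy, dx)),       # row spacing, col spacing
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0103, 1L),
    dcm_ds(0x0028, 0x1052, intercept),
    dcm_ds(0x0028, 0x1053, slope),
    dcm_element(0x7FE0, 0x0010, "OW", px)))
  dcm_file(path, els)
}

write_rtdose_file <- function(path, vals, spacing, origin, scaling) {
  d <- dim(vals)
  stored <- as.integer(round(vals / scaling))
  px <- writeBin(stored, raw(), size = 2, endian = "little")
  dcm_file(path, list(
    dcm_ds(0x0020, 0x0032, origin),
    dcm_is(0x0028, 0x0008, d[3]),
    dcm_us(0x0028, 0x0010, d[2]),
    dcm_us(0x0028, 0x0011, d[1]),
    dcm_ds(0x0028, 0x0030, c(spacing[2], spacing[1])),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_ds(0x3004, 0x000C, (seq_len(d[3]) - 1) * spacing[3]),
    dcm_ds(0x3004, 0x000E, scaling),
    dcm_element(0x7FE0, 0x0010, "OW", px)))
}
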