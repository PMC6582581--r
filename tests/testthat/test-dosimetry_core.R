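micro_case <- function() {
  sp <- c(10, 10, 10)                         # 1 cm^3 voxels
  dose <- voxel_grid(array(c(10, 20, 30), c(3, 1, 1)), sp, unit = "Gy")
  density <- voxel_grid(array(c(0.1, 0.2, 0.3), c(3, 1, 1)), sp,
                        unit = "g/cm3")
  mask <- mask_grid(array(TRUE, c(3, 1, 1)), sp, c(0, 0, 0))
  list(dose = dose, density = density, mask = mask)
}

test_that("the 3-voxel worked example matches the hand-derived oracle", {
  mc <- micro_case()
  dvh <- compute_dvh(mc$dose, mc$mask, bin_width = 1)
  dmh <- compute_dmh(mc$dose, mc$mask, mc$density, bin_width = 1)
  expect_equal(dvh$total, 3)                       # cm^3
  expect_equal(dmh$total, 0.6)                     # g
  expect_equal(dvh$cumulative[dvh$bin_edges == 20], 2)
  expect_equal(dmh$cumulative[dmh$bin_edges == 20], 0.5)
  m <- dose_metrics(dvh, dmh, dose_levels = c(20))
  expect_equal(m$dmean_volume, 20)
  expect_equal(m$dmean_mass, (0.1 * 10 + 0.2 * 20 + 0.3 * 30) / 0.6)
  expect_equal(m$levels$vx_rel, 100 * 2 / 3)
  expect_equal(m$levels$mx_rel, 100 * 0.5 / 0.6)
  expect_equal(m$levels$vx_abs, 2)
  expect_equal(m$levels$mx_abs, 0.5)
  expect_equal(m$mean_density * m$volume, m$mass)
})

test_that("histogram metrics equal the brute-force voxel loop on random grids", {
  levels <- c(0, 5, 10, 20, 40, 55)
  for (seed in 1:20) {
    cs <- random_case(seed)
    dvh <- compute_dvh(cs$dose, cs$mask)
    dmh <- compute_dmh(cs$dose, cs$mask, cs$density)
    m <- dose_metrics(dvh, dmh, levels)
    o <- brute_metrics(cs$dose, cs$mask, cs$density, levels)
    expect_equal(m$dmean_volume, o$dmean_volume, tolerance = 1e-12)
    expect_equal(m$dmean_mass, o$dmean_mass, tolerance = 1e-12)
    expect_equal(m$levels$vx_abs, o$vx_abs, tolerance = 1e-12)
    expect_equal(m$levels$mx_abs, o$mx_abs, tolerance = 1e-12)
    expect_equal(m$levels$vx_rel, o$vx_rel, tolerance = 1e-12)
    expect_equal(m$levels$mx_rel, o$mx_rel, tolerance = 1e-12)
    ## histogram curve consistency at its own edges
    expect_true(all(diff(dvh$cumulative) <= 1e-12))
    expect_true(all(diff(dmh$cumulative) <= 1e-12))
    expect_equal(dvh$cumulative[1], dvh$total)
  }
})

test_that("uniform density collapses DMH onto DVH", {
  for (seed in 21:30) {
    cs <- random_case(seed)
    rho <- runif(1, 0.1, 1.5)
    unif <- voxel_grid(array(rho, dim(cs$density$values)), cs$density$spacing,
                       cs$density$origin, "g/cm3")
    dvh <- compute_dvh(cs$dose, cs$mask)
    dmh <- compute_dmh(cs$dose, cs$mask, unif)
    expect_equal(dmh$cumulative, rho * dvh$cumulative, tolerance = 1e-12)
    m <- dose_metrics(dvh, dmh, c(10, 30))
    expect_equal(m$dmean_mass, m$dmean_volume, tolerance = 1e-9)
    expect_equal(m$levels$mx_rel, m$levels$vx_rel, tolerance = 1e-9)
  }
})

test_that("degenerate dosimetry inputs raise the contracted errors", {
  mc <- micro_case()
  empty <- mc$mask; empty$values[] <- FALSE
  expect_error(compute_dvh(mc$dose, empty),
               class = "dosemass_empty_structure_error")
  neg <- mc$density; neg$values[1] <- -0.2
  expect_error(compute_dmh(mc$dose, mc$mask, neg), "negative density")
  dvh <- compute_dvh(mc$dose, mc$mask)
  expect_error(dose_metrics(dvh, NULL, dose_levels = -5), ">= 0")
  expect_error(compute_dvh(mc$dose, mc$mask, bin_width = 0), "bin_width")
  ## zero-mass structure errors on metric extraction
  zero <- mc$density; zero$values[] <- 0
  dmh0 <- compute_dmh(mc$dose, mc$mask, zero)
  expect_equal(dmh0$total, 0)
  expect_error(dose_metrics(dvh, dmh0, 20),
               class = "dosemass_empty_structure_error")
  ## misaligned grids are a geometry error
  shifted <- mc$dose; shifted$origin <- shifted$origin + 1
  expect_error(compute_dvh(shifted, mc$mask),
               class = "dosemass_geometry_error")
})

test_that("Vx and Mx are non-increasing in the dose level", {
  cs <- random_case(99)
  m <- dose_metrics(compute_dvh(cs$dose, cs$mask),
                    compute_dmh(cs$dose, cs$mask, cs$density),
                    seq(0, 60, by = 2.5))
  expect_true(all(diff(m$levels$vx_rel) <= 1e-12))
  expect_true(all(diff(m$levels$mx_rel) <= 1e-12))
  expect_true(all(m$levels$vx_rel >= 0 & m$levels$vx_rel <= 100))
})

test_that("histogram CSV export carries dose, cumulative and relative columns", {
  mc <- micro_case()
  dvh <- compute_dvh(mc$dose, mc$mask, bin_width = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(dvh, p)
  df <- read.csv(p)
  expect_named(df, c("dose_gy", "cumulative_cm3", "relative_pct"))
  expect_equal(df$cumulative_cm3[1], 3)
  expect_equal(df$relative_pct[1], 100)
})

test_that("trilinear resampling is exact on constants and linear ramps", {
  src <- voxel_grid(array(50, c(8, 8, 8)), spacing = c(4, 4, 4))
  fine <- list(dim = c(12, 12, 12), spacing = c(2, 2, 2), origin = c(2, 2, 2))
  out <- resample_to_grid(src, fine)
  expect_equal(unique(as.numeric(out$values)), 50)

  ## d(x) = x Gy/mm is reproduced exactly inside the source extent
  xs <- (0:7) * 4
  ramp <- voxel_grid(array(rep(xs, times = 64), c(8, 8, 8)),
                     spacing = c(4, 4, 4), unit = "Gy")
  outr <- resample_to_grid(ramp, fine)
  expect_equal(outr$values[, 1, 1], 2 + (0:11) * 2, tolerance = 1e-12)

  ## targets outside the source extent get 0 and are counted
  far <- list(dim = c(4, 4, 4), spacing = c(4, 4, 4), origin = c(20, 20, 20))
  expect_message(outf <- resample_to_grid(ramp, far), "outside")
  expect_gt(attr(outf, "n_outside"), 0)
  expect_equal(outf$values[4, 4, 4], 0)

  disjoint <- list(dim = c(4, 4, 4), spacing = c(2, 2, 2),
                   origin = c(100, 100, 100))
  expect_error(resample_to_grid(ramp, disjoint),
               class = "dosemass_geometry_error")
})
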