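## small sphere image with a radial intensity gradient (well-posed for MSE)
sphere_image <- function(center_y = 0, dim = c(32, 32, 32), sp = 5) {
  geom <- list(dim = dim, spacing = rep(sp, 3),
               origin = -(dim - 1) / 2 * sp)
  lev <- dosemass:::level_array(geom, c(0, center_y, 0), c(32, 32, 32))
  v <- array(-1000, dim)
  sel <- lev <= 1
  v[sel] <- -1000 + 800 * (1 - sqrt(lev[sel]))
  voxel_grid(v, geom$spacing, geom$origin, "HU")
}

test_that("split_tissue partitions the CT with a configurable fill", {
  ct <- voxel_grid(array(0, c(6, 6, 6)), spacing = c(5, 5, 5))
  mvals <- array(FALSE, c(6, 6, 6)); mvals[2:4, 2:4, 2:4] <- TRUE
  m <- mask_grid(mvals, ct$spacing, ct$origin)
  sp <- split_tissue(ct, m)
  expect_equal(unique(as.numeric(sp$lung$values[mvals])), 0)
  expect_equal(unique(as.numeric(sp$lung$values[!mvals])), -1000)
  expect_equal(unique(as.numeric(sp$nonlung$values[mvals])), -1000)
  expect_identical(attr(sp$lung, "fill"), -1000)
  ## custom fill is echoed
  sp2 <- split_tissue(ct, m, fill = -500)
  expect_identical(attr(sp2$nonlung, "fill"), -500)
  ## no voxel keeps CT values in both images
  both <- sp$lung$values != -1000 & sp$nonlung$values != -1000
  expect_false(any(both))
  empty <- m; empty$values[] <- FALSE
  expect_error(split_tissue(ct, empty),
               class = "dosemass_empty_structure_error")
})

test_that("identity registration returns a (near) zero field", {
  fx <- sphere_image()
  dvf <- register_deformable(fx, fx, stages = 3, finest_spacing = 40,
                             max_iter = 15)
  expect_lt(mean(sqrt(rowSums(dvf$displacements^2))), 0.1)
  d <- attr(dvf, "diagnostics")
  expect_lte(d$final_mse, d$identity_mse + 1e-9)
})

test_that("a 10 mm anterior translation is recovered within 1 mm", {
  fx <- sphere_image(0)
  mv <- sphere_image(-10)                      # anterior = -y
  dvf <- register_deformable(fx, mv, stages = 4, finest_spacing = 20,
                             max_iter = 25)
  geom <- list(dim = dim(fx$values), spacing = fx$spacing, origin = fx$origin)
  msk <- mask_grid(dosemass:::level_array(geom, c(0, 0, 0),
                                          c(32, 32, 32)) <= 1,
                   fx$spacing, fx$origin)
  em <- expansion_metrics(dvf, msk)
  expect_lt(abs(em$mean_anterior - 10), 1)
  expect_lt(abs(em$mean_left), 1)
  expect_lt(abs(em$mean_caudal), 1)
})

test_that("merge_dvf blends fields linearly across the boundary band", {
  d <- c(12, 6, 6)
  geom <- list(dim = d, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  n <- prod(d)
  A <- deformation_field(matrix(rep(c(2, 0, 0), each = n), ncol = 3),
                         d, geom$spacing, geom$origin)
  B <- deformation_field(matrix(rep(c(10, 0, 0), each = n), ncol = 3),
                         d, geom$spacing, geom$origin)
  mvals <- array(FALSE, d); mvals[1:6, , ] <- TRUE
  m <- mask_grid(mvals, geom$spacing, geom$origin)

  ## identical fields merge to themselves
  same <- merge_dvf(A, A, m, band = 3)
  expect_equal(same$displacements, A$displacements)

  ## band 0: exact piecewise field
  pw <- merge_dvf(A, B, m, band = 0)
  expect_equal(unique(pw$displacements[as.logical(mvals), 1]), 2)
  expect_equal(unique(pw$displacements[!as.logical(mvals), 1]), 10)

  ## band 3: convex combination, averaging to (A+B)/2 across the boundary
  bl <- merge_dvf(A, B, m, band = 3)
  ux <- array(bl$displacements[, 1], d)
  expect_true(all(ux >= 2 - 1e-9 & ux <= 10 + 1e-9))
  expect_true(all(diff(ux[, 3, 3]) >= -1e-9))          # monotone fade
  expect_equal(mean(ux[6:7, 3, 3]), 6)                 # (A + B) / 2
  expect_equal(ux[1, 3, 3], 2)                         # beyond the band
  expect_equal(ux[12, 3, 3], 10)

  bad <- deformation_field(matrix(0, 10, 3), c(10, 1, 1), c(1, 1, 1), c(0, 0, 0))
  expect_error(merge_dvf(A, bad, m), class = "dosemass_geometry_error")
})

test_that("warp_mask is identity for a zero field and shifts centroids", {
  d <- c(20, 20, 20)
  mvals <- array(FALSE, d); mvals[8:12, 8:12, 8:12] <- TRUE
  m <- mask_grid(mvals, c(2, 2, 2), c(0, 0, 0))
  zero <- deformation_field(matrix(0, prod(d), 3), d, c(2, 2, 2), c(0, 0, 0))
  expect_identical(warp_mask(m, zero)$values, m$values)

  tr <- deformation_field(matrix(rep(c(0, 10, 0), each = prod(d)), ncol = 3),
                          d, c(2, 2, 2), c(0, 0, 0))
  w <- warp_mask(m, tr)
  shift <- mask_centroid(w) - mask_centroid(m)
  expect_lt(abs(abs(shift[2]) - 10), 2)               # within one voxel
  expect_lt(abs(shift[1]), 1e-9)
})

test_that("expansion metrics reproduce the hand-computed norm and index", {
  d <- c(5, 5, 5)
  ## (left, anterior, caudal) = (1.5, 16.0, 12.2) => displacement
  ## components (+1.5, -16.0, -12.2) in LPS
  u <- matrix(rep(c(1.5, -16, -12.2), each = prod(d)), ncol = 3)
  dvf <- deformation_field(u, d, c(1, 1, 1), c(0, 0, 0))
  m <- mask_grid(array(TRUE, d), c(1, 1, 1), c(0, 0, 0))
  em <- expansion_metrics(dvf, m)
  expect_equal(em$mean_left, 1.5)
  expect_equal(em$mean_anterior, 16)
  expect_equal(em$mean_caudal, 12.2)
  expect_equal(em$expansion_3d, sqrt(1.5^2 + 16^2 + 12.2^2))
  expect_equal(round(em$expansion_3d, 2), 20.18)
  expect_equal(em$breathing_index, (12.2 - 16) / 16 * 100)
  expect_equal(round(em$breathing_index, 2), -23.75)

  ## zero field: all metrics 0, index undefined but not an error
  z <- expansion_metrics(deformation_field(matrix(0, prod(d), 3), d,
                                           c(1, 1, 1), c(0, 0, 0)), m)
  expect_equal(z$expansion_3d, 0)
  expect_false(z$breathing_index_defined)
  expect_true(is.na(z$breathing_index))

  ## anterior == caudal: index 0 (chest/abdominal boundary)
  eq <- deformation_field(matrix(rep(c(0, -8, -8), each = prod(d)), ncol = 3),
                          d, c(1, 1, 1), c(0, 0, 0))
  expect_equal(expansion_metrics(eq, m)$breathing_index, 0)
})

test_that("phantom sign conventions: chest breathing and cranial V20 shift", {
  pair <- generate_pair(coarse_params(), seed = 5)
  lung_fb <- lung_mask_of(pair, "fb")
  em <- expansion_metrics(pair$ground_truth_dvf, lung_fb)
  expect_lt(em$breathing_index, 0)         # anterior-dominant expansion

  ## warped DIBH V20 sits more cranial than FB V20
  v20 <- function(ph) {
    m <- lung_mask_of(pair, ph)
    m$values <- m$values & pair[[ph]]$dose$values >= 20
    m
  }
  w <- warp_mask(v20("dibh"), pair$ground_truth_dvf)
  expect_gt(mask_centroid(w)[3], mask_centroid(v20("fb"))[3])

  ## ground-truth warp maps the DIBH lung onto the FB lung (Dice > 0.95)
  wl <- warp_mask(lung_mask_of(pair, "dibh"), pair$ground_truth_dvf)
  expect_gt(dice_coefficient(wl, lung_fb), 0.95)
})
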