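test_that("phantom generation is deterministic given the seed", {
  a <- generate_pair(coarse_params(), seed = 11)
  b <- generate_pair(coarse_params(), seed = 11)
  expect_identical(a$fb$ct$values, b$fb$ct$values)
  expect_identical(a$dibh$dose$values, b$dibh$dose$values)
  expect_identical(a$ground_truth_dvf$displacements,
                   b$ground_truth_dvf$displacements)
  c <- generate_pair(coarse_params(), seed = 12)
  expect_false(identical(a$fb$ct$values, c$fb$ct$values))
})

test_that("lung volume expands by the requested factor with conserved mass", {
  for (seed in 1:3) {
    pair <- generate_pair(medium_params(), seed = seed)
    vf <- mask_volume_cm3(lung_mask_of(pair, "fb"))
    vd <- mask_volume_cm3(lung_mask_of(pair, "dibh"))
    expect_lt(abs(vd / vf - 1.8), 0.05)
    expect_lt(abs(vf - 1432) / 1432, 0.05)
    mf <- lung_mass_of(pair, "fb"); md <- lung_mass_of(pair, "dibh")
    expect_lt(abs(md - mf) / mf, 0.02)
  }
})

test_that("ground-truth field means equal the requested expansions", {
  pair <- generate_pair(medium_params(), seed = 2)
  em <- expansion_metrics(pair$ground_truth_dvf, lung_mask_of(pair, "fb"))
  expect_lt(abs(em$mean_left - 1.5), 0.5)
  expect_lt(abs(em$mean_anterior - 16), 0.5)
  expect_lt(abs(em$mean_caudal - 12.2), 0.5)
})

test_that("dose is normalized to the prescription at the PTV median", {
  pair <- generate_pair(coarse_params(), seed = 3)
  for (ph in c("fb", "dibh")) {
    ptv <- rasterize(pair[[ph]]$structures, pair[[ph]]$ct, name = "ptv")
    med <- median(pair[[ph]]$dose$values[ptv$values])
    expect_lt(abs(med - 50), 0.01)
    body <- rasterize(pair[[ph]]$structures, pair[[ph]]$ct, name = "body")
    expect_equal(sum(pair[[ph]]$dose$values[!body$values]), 0)
  }
})

test_that("heart displacement monotonically decreases the heart dose", {
  dmean_heart <- function(disp) {
    pp <- coarse_params(heart_displacement = c(posterior = disp,
                                               inferior = 12),
                        noise_hu = 0, density_noise = 0)
    pair <- generate_pair(pp, seed = 4)
    h <- rasterize(pair$dibh$structures, pair$dibh$ct, name = "heart")
    dvh <- compute_dvh(pair$dibh$dose, h)
    dose_metrics(dvh)$dmean_volume
  }
  vals <- vapply(c(5, 15, 25), dmean_heart, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(expansion_factor = 0.9),
               class = "dosemass_parameter_error")
  expect_error(phantom_params(lung_density_fb = 2.5),
               class = "dosemass_parameter_error")
  expect_error(phantom_params(heart_radius = -1),
               class = "dosemass_parameter_error")
  ## structures exceeding the body are a parameter error at generation
  expect_error(generate_pair(coarse_params(lung_volume_cm3 = 6000), seed = 1),
               class = "dosemass_parameter_error")
})

test_that("cohorts are reproducible, distinct, and flag adverse patients", {
  co <- generate_cohort(31, coarse_params(), seed = 7, materialize = FALSE)
  co2 <- generate_cohort(31, coarse_params(), seed = 7, materialize = FALSE)
  expect_equal(length(co$manifest), 31)
  expect_identical(lapply(co$manifest, `[[`, "params"),
                   lapply(co2$manifest, `[[`, "params"))
  expect_equal(length(co$adverse_index), 4)     # round(4/31 * 31)
  vols <- vapply(co$manifest, function(m) m$params$lung_volume_cm3, numeric(1))
  expect_equal(length(unique(vols)), 31)
  ## materialized pairs reproduce the manifest pairs
  p1 <- cohort_pair(co, 1)
  pairs <- generate_cohort(3, coarse_params(), seed = 7,
                           adverse_fraction = 0, materialize = TRUE)
  expect_length(pairs, 3)
  expect_s3_class(pairs[[2]], "patient_pair")
  expect_error(generate_cohort(1, coarse_params()),
               class = "dosemass_parameter_error")
  expect_identical(p1$seed, co$manifest[[1]]$seed)
})

test_that("phantom pairs round-trip through the research file formats", {
  pair <- generate_pair(coarse_params(), seed = 9)
  dir <- withr::local_tempdir()
  write_patient_pair(pair, dir)
  back <- read_patient_pair(dir)
  expect_identical(back$fb$ct$values, pair$fb$ct$values)
  expect_identical(back$dibh$dose$values, pair$dibh$dose$values)
  expect_equal(back$fb$structures$structures, pair$fb$structures$structures)
  expect_equal(back$ground_truth_dvf$displacements,
               pair$ground_truth_dvf$displacements)
})
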