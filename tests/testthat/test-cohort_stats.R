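test_that("paired deltas follow the DIBH-minus-FB convention", {
  pd <- paired_delta(18.9, 14.4)
  expect_equal(pd$delta, -4.5)
  expect_equal(pd$delta_relative_pct, -4.5 * 100 / 18.9)
  expect_equal(round(pd$delta_relative_pct, 2), -23.81)
  expect_equal(paired_delta(10, 8.1)$delta, -1.9)
  expect_equal(paired_delta(7, 7), list(delta = 0, delta_relative_pct = 0,
                                        relative_defined = TRUE))
  z <- paired_delta(0, 3)
  expect_true(is.na(z$delta_relative_pct))
  expect_false(z$relative_defined)
  ## antisymmetry property
  set.seed(1)
  a <- rnorm(20, 10); b <- rnorm(20, 8)
  expect_equal(paired_delta(a, b)$delta, -paired_delta(b, a)$delta)
})

test_that("Wilcoxon exact p matches hand cases and full enumeration", {
  ## all six pairs increase: two-sided p = 2/2^6
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
  expect_equal(w$p_value, 2 / 64)
  expect_identical(w$method, "exact")

  ## balanced antisymmetric differences: p = 1
  w2 <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_equal(w2$p_value, 1)

  ## zero differences are dropped
  w3 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5, 6),
                             c(0, 0, 2, 4, 6, 8, 10, 12))
  expect_equal(w3$n_effective, 6)
  expect_equal(w3$p_value, 2 / 64)

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)),
               class = "dosemass_stat_error")

  ## oracle: full sign-assignment enumeration for n <= 10, with ties
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), if (rep %% 2) 2 else 0)  # integers force ties
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enumeration(d),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon normal approximation agrees with stats::wilcox.test", {
  set.seed(3)
  d <- rnorm(40, 0.4)
  mine <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_identical(mine$method, "normal_approximation")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("regression zero-crossing matches closed forms and recovers truth", {
  x <- c(-20, -10, 0, 5, 12)
  fit <- regression_zero_crossing(x, 2 * x + 4)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 4)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$x_at_y0, -2)

  flat <- regression_zero_crossing(x, rep(0, 5))
  expect_false(flat$crossing_defined)
  expect_true(is.na(flat$x_at_y0))
  expect_error(regression_zero_crossing(rep(1, 5), x), "constant")

  ## generative recovery: y = 1.1 x + 9.24 (zero crossing -8.4) + noise
  set.seed(3)
  xg <- rnorm(31, -19, 9)
  yg <- 1.1 * xg + 9.24 + rnorm(31, 0, 1)
  rec <- regression_zero_crossing(xg, yg)
  expect_lt(abs(rec$x_at_y0 - (-8.4)), 1)
})

test_that("Spearman correlations match the rank formula and flag constants", {
  expect_equal(dosemass:::spearman_one(1:8, (1:8)^3)[["r"]], 1)
  expect_equal(dosemass:::spearman_one(1:8, -(1:8))[["r"]], -1)
  ## hand case: ranks (1..5) vs (2,1,4,3,5) -> 1 - 6*4/120 = 0.8
  expect_equal(dosemass:::spearman_one(1:5, c(2, 1, 4, 3, 5))[["r"]], 0.8)

  ## invariance under strictly monotone transforms
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- dosemass:::spearman_one(a, b)[["r"]]
  expect_equal(dosemass:::spearman_one(exp(a), b)[["r"]], r0)
  expect_equal(dosemass:::spearman_one(a, qnorm(pnorm(b)))[["r"]], r0,
               tolerance = 1e-9)

  tab <- spearman_correlations(data.frame(f1 = 1:6, f2 = rep(1, 6)),
                               data.frame(d1 = c(2, 1, 4, 3, 6, 5)))
  expect_true(is.na(tab$r[tab$factor == "f2"]))
  expect_false(is.na(tab$r[tab$factor == "f1"]))
  expect_true(all(tab$stars %in% c("", "*", "**")))
})

test_that("build_summary aggregates patients and degenerates sanely", {
  row <- c(ptv_volume_cm3_fb = 900, ptv_volume_cm3_dibh = 890,
           lung_volume_cm3_fb = 1400, lung_volume_cm3_dibh = 2500,
           lung_dmean_dvh_gy_fb = 10, lung_dmean_dvh_gy_dibh = 8,
           lung_dmean_dmh_gy_fb = 8.3, lung_dmean_dmh_gy_dibh = 7.3,
           lung_v20_pct_fb = 19, lung_v20_pct_dibh = 14,
           lung_m20_pct_fb = 15, lung_m20_pct_dibh = 12.6,
           heart_dmean_gy_fb = 4, heart_dmean_gy_dibh = 1.7)
  df <- as.data.frame(rbind(row, row))
  res <- build_summary(df)
  expect_s3_class(res, "cohort_result")
  expect_true(all(res$summary$fb_sd == 0))       # identical patients
  expect_true(all(res$summary$delta_sd == 0))
  expect_equal(res$summary$delta_mean[res$summary$key == "lung_v20_pct"], -5)
  expect_error(build_summary(df[1, , drop = FALSE]),
               class = "dosemass_parameter_error")
})
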