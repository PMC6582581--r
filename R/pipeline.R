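#' Analysis run configuration
#'
#' A single configuration drives phantom generation or file loading,
#' per-patient dosimetry and expansion analysis, and cohort statistics.
#'
#' @param mode `"synthetic"` (generate phantoms) or `"files"` (read pairs
#'   written by [write_patient_pair()] from `data_dir`).
#' @param n cohort size for synthetic mode.
#' @param seed master seed; all randomness derives from it.
#' @param phantom a [phantom_params] for synthetic mode.
#' @param adverse_fraction fraction of adverse-anatomy patients.
#' @param data_dir directory of per-patient subdirectories (files mode).
#' @param density_table a [density_table].
#' @param dose_levels lung Vx/Mx levels in Gy (default 5..45 by 5).
#' @param heart_levels heart Vx levels in Gy (default 20, 40).
#' @param bin_width histogram bin width, Gy.
#' @param expansion_source `"ground_truth"` (use the phantom's analytic
#'   field; exact and fast), `"registration"` (run the 3-step deformable
#'   workflow) or `"none"`.
#' @param registration list of [register_deformable()] settings (`stages`,
#'   `finest_spacing`, `max_iter`) plus `blend_band` for [merge_dvf()].
#' @param output_dir optional directory for report files.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), n = 31L, seed = 1L,
                       phantom = phantom_params(),
                       adverse_fraction = 4 / 31,
                       data_dir = NULL,
                       density_table = default_density_table(),
                       dose_levels = seq(5, 45, by = 5),
                       heart_levels = c(20, 40),
                       bin_width = 0.1,
                       expansion_source = c("ground_truth", "registration",
                                            "none"),
                       registration = list(stages = 6L, finest_spacing = 10,
                                           max_iter = 40L, blend_band = 3L),
                       output_dir = NULL) {
  mode <- match.arg(mode)
  expansion_source <- match.arg(expansion_source)
  if (is.unsorted(dose_levels) || any(dose_levels <= 0))
    stop_param("dose levels must be positive and sorted")
  if (mode == "files" && is.null(data_dir))
    stop_param("files mode needs data_dir")
  structure(list(mode = mode, n = as.integer(n), seed = as.integer(seed),
                 phantom = phantom, adverse_fraction = adverse_fraction,
                 data_dir = data_dir, density_table = density_table,
                 dose_levels = dose_levels, heart_levels = heart_levels,
                 bin_width = bin_width, expansion_source = expansion_source,
                 registration = registration, output_dir = output_dir),
            class = "run_config")
}

## 3-step registration workflow: tissue split, per-tissue B-spline
## registration, field merge
register_pair_workflow <- function(pair, config) {
  reg <- config$registration
  lung_fb <- rasterize(pair$fb$structures, pair$fb$ct, name = "left_lung")
  split_fb <- split_tissue(pair$fb$ct, lung_fb)
  lung_dibh <- rasterize(pair$dibh$structures, pair$dibh$ct, name = "left_lung")
  split_dibh <- split_tissue(pair$dibh$ct, lung_dibh)
  dvf_lung <- register_deformable(split_fb$lung, split_dibh$lung,
                                  stages = reg$stages,
                                  finest_spacing = reg$finest_spacing,
                                  max_iter = reg$max_iter)
  dvf_non <- register_deformable(split_fb$nonlung, split_dibh$nonlung,
                                 stages = reg$stages,
                                 finest_spacing = reg$finest_spacing,
                                 max_iter = reg$max_iter)
  merge_dvf(dvf_lung, dvf_non, lung_fb, band = reg$blend_band)
}

phase_metrics <- function(phase, config, levels, with_mass = TRUE) {
  ct <- phase$ct
  dose <- phase$dose
  if (!same_geometry(dose, ct)) dose <- resample_to_grid(dose, ct, quiet = TRUE)
  density <- hu_to_density(ct, config$density_table)
  list(ct = ct, dose = dose, density = density)
}

structure_dose_metrics <- function(vols, structures, name, levels, config,
                                   with_mass = TRUE) {
  m <- rasterize(structures, vols$ct, name = name)
  dvh <- compute_dvh(vols$dose, m, bin_width = config$bin_width)
  dmh <- if (with_mass)
    compute_dmh(vols$dose, m, vols$density, bin_width = config$bin_width)
  else NULL
  list(mask = m, metrics = dose_metrics(dvh, dmh, levels))
}

#' Analyze one FB/DIBH patient pair
#'
#' Computes DVH and DMH metrics of the left lung, heart DVH metrics,
#' anatomical factors, and lung / V20-region expansion metrics from the
#' deformation field (ground truth or registration, per the configuration).
#'
#' @param pair a `patient_pair`.
#' @param config a [run_config].
#' @return an object of class `patient_metrics`: a named numeric vector
#'   `row` of all scalar metrics plus the `expansion` objects.
#' @export
run_patient <- function(pair, config = run_config()) {
  stopifnot(inherits(pair, "patient_pair"))
  for (ph in c("fb", "dibh"))
    for (nm in c("left_lung", "heart", "ptv", "body"))
      if (!nm %in% names(pair[[ph]]$structures$structures))
        stop(sprintf("missing structure '%s' in phase %s", nm, ph))
  row <- c()
  lung_masks <- list(); v20_masks <- list()
  for (ph in c("fb", "dibh")) {
    vols <- phase_metrics(pair[[ph]], config)
    lung <- structure_dose_metrics(vols, pair[[ph]]$structures, "left_lung",
                                   config$dose_levels, config)
    heart <- structure_dose_metrics(vols, pair[[ph]]$structures, "heart",
                                    config$heart_levels, config,
                                    with_mass = FALSE)
    ptv <- rasterize(pair[[ph]]$structures, vols$ct, name = "ptv")
    lm <- lung$metrics
    lev <- lm$levels
    g20 <- which(lev$level == 20)
    suffix <- paste0("_", ph)
    add <- c(ptv_volume_cm3 = mask_volume_cm3(ptv),
             lung_volume_cm3 = lm$volume,
             lung_mass_g = lm$mass,
             lung_density_g_cm3 = lm$mean_density,
             lung_dmean_dvh_gy = lm$dmean_volume,
             lung_dmean_dmh_gy = lm$dmean_mass,
             heart_dmean_gy = heart$metrics$dmean_volume)
    if (length(g20)) {
      add <- c(add,
               lung_v20_pct = lev$vx_rel[g20], lung_v20_cm3 = lev$vx_abs[g20],
               lung_m20_pct = lev$mx_rel[g20], lung_m20_g = lev$mx_abs[g20])
    }
    for (i in seq_len(nrow(lev))) {
      add[paste0("lung_v", lev$level[i], "_pct")] <- lev$vx_rel[i]
      add[paste0("lung_m", lev$level[i], "_pct")] <- lev$mx_rel[i]
    }
    hl <- heart$metrics$levels
    for (i in seq_len(nrow(hl)))
      add[paste0("heart_v", hl$level[i], "_pct")] <- hl$vx_rel[i]
    names(add) <- paste0(names(add), suffix)
    row <- c(row, add)
    lung_masks[[ph]] <- lung$mask
    v20 <- lung$mask
    v20$values <- v20$values & vols$dose$values >= 20
    v20_masks[[ph]] <- v20
  }
  row["dlung_volume_pct"] <-
    paired_delta(row[["lung_volume_cm3_fb"]],
                 row[["lung_volume_cm3_dibh"]])$delta_relative_pct
  expansion <- NULL; v20_expansion <- NULL
  dvf <- switch(config$expansion_source,
                ground_truth = pair$ground_truth_dvf,
                registration = register_pair_workflow(pair, config),
                none = NULL)
  if (!is.null(dvf)) {
    expansion <- expansion_metrics(dvf, lung_masks$fb)
    v20_expansion <- if (any(v20_masks$fb$values))
      expansion_metrics(dvf, v20_masks$fb) else NULL
    row <- c(row,
             exp_left_mm = expansion$mean_left,
             exp_anterior_mm = expansion$mean_anterior,
             exp_caudal_mm = expansion$mean_caudal,
             exp_3d_mm = expansion$expansion_3d,
             breathing_index_pct = expansion$breathing_index)
    if (!is.null(v20_expansion))
      row <- c(row,
               v20_exp_left_mm = v20_expansion$mean_left,
               v20_exp_anterior_mm = v20_expansion$mean_anterior,
               v20_exp_caudal_mm = v20_expansion$mean_caudal,
               v20_exp_3d_mm = v20_expansion$expansion_3d)
  }
  row["adverse"] <- as.numeric(isTRUE(pair$params$adverse))
  structure(list(row = row, expansion = expansion,
                 v20_expansion = v20_expansion),
            class = "patient_metrics")
}

summary_metric_map <- function() {
  c(ptv_volume_cm3 = "PTV volume [cm3]",
    lung_volume_cm3 = "left lung volume [cm3]",
    lung_mass_g = "left lung mass [g]",
    lung_density_g_cm3 = "left lung density [g/cm3]",
    lung_dmean_dvh_gy = "lung Dmean (DVH) [Gy]",
    lung_dmean_dmh_gy = "lung Dmean (DMH) [Gy]",
    lung_v20_pct = "lung V20 [%]",
    lung_v20_cm3 = "lung V20 [cm3]",
    lung_m20_pct = "lung M20 [%]",
    lung_m20_g = "lung M20 [g]",
    heart_dmean_gy = "heart Dmean (DVH) [Gy]",
    heart_v20_pct = "heart V20 [%]",
    heart_v40_pct = "heart V40 [%]")
}

## per-patient relative deltas used by regression and correlations
delta_frame <- function(df) {
  rel <- function(key) {
    paired_delta(df[[paste0(key, "_fb")]],
                 df[[paste0(key, "_dibh")]])$delta_relative_pct
  }
  data.frame(ddmean_lung_dvh_pct = rel("lung_dmean_dvh_gy"),
             ddmean_lung_dmh_pct = rel("lung_dmean_dmh_gy"),
             dv20_rel_pct = rel("lung_v20_pct"),
             dm20_rel_pct = rel("lung_m20_pct"),
             dheart_dmean_pct = rel("heart_dmean_gy"))
}

#' Aggregate per-patient metrics into cohort-level results
#'
#' Produces the cohort summary table (mean +/- sample SD of FB, DIBH,
#' delta and per-patient relative delta, with a Wilcoxon signed-rank p per
#' metric), the DVH-DMH regressions with zero crossings (Dmean pair and
#' V20/M20 pair), and the Spearman correlation table between anatomical
#' factors / expansions and relative dose deltas.
#'
#' @param cohort_metrics list of `patient_metrics` or a data frame of their
#'   rows.
#' @return an object of class `cohort_result` with elements `patients`,
#'   `summary`, `regression`, `correlations`, `n`.
#' @export
build_summary <- function(cohort_metrics) {
  df <- if (is.data.frame(cohort_metrics)) cohort_metrics
  else as.data.frame(do.call(rbind, lapply(cohort_metrics, `[[`, "row")))
  if (nrow(df) < 2L) stop_param("cohort summary needs n >= 2")
  map <- summary_metric_map()
  rows <- list()
  for (key in names(map)) {
    fb <- df[[paste0(key, "_fb")]]; dibh <- df[[paste0(key, "_dibh")]]
    if (is.null(fb) || is.null(dibh)) next
    pd <- paired_delta(fb, dibh)
    p <- tryCatch(wilcoxon_signed_rank(fb, dibh)$p_value,
                  error = function(e) NA_real_)
    rows[[key]] <- data.frame(
      metric = map[[key]], key = key,
      fb_mean = mean(fb), fb_sd = sd(fb),
      dibh_mean = mean(dibh), dibh_sd = sd(dibh),
      delta_mean = mean(pd$delta), delta_sd = sd(pd$delta),
      delta_rel_mean = mean(pd$delta_relative_pct, na.rm = TRUE),
      delta_rel_sd = sd(pd$delta_relative_pct, na.rm = TRUE),
      delta_of_means_rel = 100 * (mean(dibh) - mean(fb)) / mean(fb),
      p_wilcoxon = p)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  deltas <- delta_frame(df)
  safe_reg <- function(x, y) tryCatch(regression_zero_crossing(x, y),
                                      error = function(e)
                                        list(slope = NA_real_,
                                             intercept = NA_real_,
                                             r_squared = NA_real_,
                                             x_at_y0 = NA_real_,
                                             crossing_defined = FALSE,
                                             error = conditionMessage(e)))
  regression <- list(
    dmean = safe_reg(deltas$ddmean_lung_dvh_pct, deltas$ddmean_lung_dmh_pct),
    v20 = safe_reg(deltas$dv20_rel_pct, deltas$dm20_rel_pct))
  factor_cols <- c(ptv_volume_cm3_fb = "PTV volume FB [cm3]",
                   lung_volume_cm3_fb = "lung volume FB [cm3]",
                   dlung_volume_pct = "dlung volume [%]",
                   exp_left_mm = "left expansion [mm]",
                   exp_anterior_mm = "anterior expansion [mm]",
                   exp_caudal_mm = "caudal expansion [mm]",
                   exp_3d_mm = "3D expansion [mm]")
  have <- names(factor_cols)[names(factor_cols) %in% names(df)]
  correlations <- if (length(have) && nrow(df) >= 5L)
    spearman_correlations(df[have], deltas) else NULL
  structure(list(patients = df, deltas = deltas, summary = summary,
                 regression = regression, correlations = correlations,
                 n = nrow(df)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> n = %d patients\n", x$n))
  s <- x$summary
  cat(sprintf("  %-26s %9s %9s %9s %9s %8s\n", "metric", "FB", "DIBH",
              "delta", "delta%", "p"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-26s %9.2f %9.2f %9.2f %8.1f%% %8.2g\n", s$metric[i],
                s$fb_mean[i], s$dibh_mean[i], s$delta_mean[i],
                s$delta_rel_mean[i], s$p_wilcoxon[i]))
  r <- x$regression
  cat(sprintf("  Dmean regression: slope %.2f, R2 %.2f, zero-crossing %.1f%%\n",
              r$dmean$slope, r$dmean$r_squared, r$dmean$x_at_y0))
  cat(sprintf("  V20 regression:   slope %.2f, R2 %.2f, zero-crossing %.1f%%\n",
              r$v20$slope, r$v20$r_squared, r$v20$x_at_y0))
  invisible(x)
}

#' Run the full cohort analysis
#'
#' Generates (or loads) every patient pair, analyzes it with
#' [run_patient()], and aggregates with [build_summary()].  Patient
#' failures are recorded and skipped as long as at least 2 patients
#' succeed.  With `output_dir` set, writes per-patient metric JSON files,
#' the summary and correlation tables as CSV, the regression results and a
#' run log (seed, package version, failures) as JSON.
#'
#' @param config a [run_config].
#' @return a `cohort_result`, with `failures` attribute.
#' @export
run_cohort <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    if (config$n < 2) stop_param("cohort needs n >= 2")
    cohort <- generate_cohort(config$n, config$phantom, config$seed,
                              adverse_fraction = config$adverse_fraction,
                              materialize = FALSE)
    loaders <- lapply(seq_len(config$n), function(i)
      function() cohort_pair(cohort, i))
    ids <- sprintf("patient_%02d", seq_len(config$n))
  } else {
    dirs <- sort(list.dirs(config$data_dir, recursive = FALSE))
    if (length(dirs) < 2) stop_param("files mode needs >= 2 patient directories")
    loaders <- lapply(dirs, function(d) function() read_patient_pair(d))
    ids <- basename(dirs)
  }
  metrics <- list(); failures <- list()
  out <- config$output_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(loaders)) {
    m <- tryCatch(run_patient(loaders[[i]](), config), error = function(e) e)
    if (inherits(m, "error")) {
      failures[[ids[i]]] <- conditionMessage(m)
      warning(sprintf("%s failed: %s", ids[i], conditionMessage(m)))
    } else {
      metrics[[ids[i]]] <- m
      if (!is.null(out))
        jsonlite::write_json(as.list(m$row),
                             file.path(out, paste0(ids[i], "_metrics.json")),
                             digits = NA, auto_unbox = TRUE)
    }
    rm(m); gc(verbose = FALSE)
  }
  if (length(metrics) < 2L)
    stop_param(sprintf("only %d patients analyzable; need >= 2",
                       length(metrics)))
  result <- build_summary(metrics)
  result$failures <- failures
  if (!is.null(out)) {
    write.csv(result$summary, file.path(out, "cohort_summary.csv"),
              row.names = FALSE)
    if (!is.null(result$correlations))
      write.csv(result$correlations, file.path(out, "correlations.csv"),
                row.names = FALSE)
    write.csv(cbind(patient = rownames(result$patients), result$patients,
                    result$deltas),
              file.path(out, "patient_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(regression = result$regression,
           seed = config$seed, n = result$n,
           failures = failures,
           package_version = as.character(utils::packageVersion("dosemass")),
           r_version = R.version.string),
      file.path(out, "run_log.json"), digits = NA, auto_unbox = TRUE)
  }
  result
}
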