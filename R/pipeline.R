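#' Default run configuration
#'
#' A single document collecting every numeric constant of the pipeline:
#' classification thresholds, genomic composition, fiber-model constants,
#' rescale percentiles, fit settings, variance-filter radius, and the seed.
#' Unknown keys are rejected, so typos cannot silently fall back to
#' defaults.
#'
#' @param ... Overrides, as nested lists mirroring the default structure
#'   (e.g. `condensation = list(genome = list(white = 0.05, ...))`).
#' @param seed Integer seed governing every stochastic stage.
#' @param stages Character vector of stages to run, in any order; they are
#'   executed in dependency order.
#' @return A validated `run_config` list.
#' @export
run_config <- function(..., seed = 1L,
                       stages = c("fixtures", "frap", "flip",
                                  "condensation", "coloc")) {
  defaults <- list(
    seed = as.integer(seed),
    stages = stages,
    frap = list(n_starts = 5),
    condensation = list(
      thresholds = list(background_max = 82, white_max = 148, gray_max = 224),
      genome = list(white = 0.05, gray = 0.25, black = 0.70),
      rescale = list(p_low = 0.0035, p_high = 0.9965)),
    fiber = list(nm_per_bp = 0.34, packing_ratio = 6.8),
    fragments = list(
      I = list(dna_bp = 360000, lengths = 0.72)),
    variance = list(radius = 2),
    coloc = list(threshold = "otsu"))
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "config")
  cfg$seed <- as.integer(seed)
  cfg$stages <- stages
  unknown <- setdiff(cfg$stages,
                     c("fixtures", "frap", "flip", "condensation", "coloc"))
  check_that(length(unknown) == 0, "stages",
             paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  structure(cfg, class = "run_config")
}

# Recursive override merge that rejects keys absent from the defaults.
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  check_that(length(bad) == 0, path,
             paste("unknown key(s):", paste(bad, collapse = ", ")))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste(path, nm, sep = "$"))
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}

#' Generate the canonical synthetic fixture bundle
#'
#' Six seeded fixtures spanning the kinetic regimes of the study system:
#' a fast remodeler-like FRAP curve (half-time 0.7 s on a 70 ms protocol),
#' a twofold-slower ATPase-mutant-like curve (1.7 s), a transcription-factor
#' -like gland-protocol curve with a 0.14 immobile fraction (half-time
#' 3.0 s), a histone-like slow recovery reaching ~20 percent in 40 min, a
#' banded-nucleus phantom at 52/43/5 percent white/gray/black, and a
#' half-nucleus FLIP-FRAP pair.  Different seeds change only the noise
#' realization, never the ground-truth parameters.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, curves are written as CSV,
#'   the phantom as TIFF + JSON sidecar, and a `manifest.json` with all
#'   ground truth.
#' @param noise_sd Curve-level noise SD (normalized units).
#' @return Named list of fixtures, each carrying the simulated data and its
#'   `ground_truth`, invisibly when `dir` is given.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL, noise_sd = 0.02) {
  seed <- as.integer(seed)
  acq_s2 <- function(s) acquisition_spec(n_pre = 20, n_post = 200,
                                         interval = 0.070, bleach_depth = 0.8,
                                         noise_sd = noise_sd, seed = s)
  acq_gland <- function(s) acquisition_spec(n_pre = 10, n_post = 250,
                                            interval = 0.648,
                                            bleach_depth = 0.8,
                                            noise_sd = noise_sd, seed = s)
  # long time base for histone turnover: ~47 min at 12 s per frame
  acq_slow <- function(s) acquisition_spec(n_pre = 5, n_post = 235,
                                           interval = 12, bleach_depth = 0.8,
                                           noise_sd = noise_sd, seed = s)
  fx <- list()

  p_fast <- kinetic_params_for_t_half(0.7)
  fx$brm_fast <- list(curve = simulate_frap_curve(p_fast, acq_s2(seed + 101L)),
                      ground_truth = c(p_fast, list(t_half = 0.7, mobile = 1)))

  p_slow <- kinetic_params_for_t_half(1.7)
  fx$k804r_slow <- list(curve = simulate_frap_curve(p_slow, acq_s2(seed + 202L)),
                        ground_truth = c(p_slow, list(t_half = 1.7, mobile = 1)))

  p_ecr <- kinetic_params_for_t_half(3.0, mobile = 0.86)
  fx$ecr_immobile <- list(
    curve = simulate_frap_curve(p_ecr, acq_gland(seed + 303L)),
    ground_truth = c(p_ecr, list(t_half = 3.0, mobile = 0.86,
                                 immobile = 0.14)))

  k_h2b <- -log(0.1) / 2400   # 90 percent of plateau reached at 40 min
  fx$h2b_slow <- list(
    curve = simulate_slow_recovery(0.2, k_h2b, acq_slow(seed + 404L)),
    ground_truth = list(plateau = 0.2, k = k_h2b,
                        recovery_at_40min = 0.2 * 0.9))

  ph_spec <- phantom_spec(seed = seed + 505L)
  fx$phantom <- c(render_nucleus_phantom(ph_spec), list())

  flip_spec <- two_compartment_spec(k_ex = log(2) / 30 / 2)  # t_half ~30 s
  fx$flip_pair <- c(
    simulate_flip_frap(flip_spec,
                       acquisition_spec(n_pre = 10, n_post = 250,
                                        interval = 0.648, bleach_depth = 1,
                                        noise_sd = noise_sd,
                                        seed = seed + 606L)),
    list(spec = flip_spec))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("brm_fast", "k804r_slow", "ecr_immobile", "h2b_slow"))
      write_curve_csv(fx[[nm]]$curve, file.path(dir, paste0(nm, ".csv")))
    write_phantom_tiff(fx$phantom, file.path(dir, "phantom.tif"))
    write_curve_csv(fx$flip_pair$bleached, file.path(dir, "flip_bleached.csv"))
    write_curve_csv(fx$flip_pair$unbleached,
                    file.path(dir, "flip_unbleached.csv"))
    manifest <- list(
      seed = seed,
      fixtures = list(
        brm_fast = fx$brm_fast$ground_truth,
        k804r_slow = fx$k804r_slow$ground_truth,
        ecr_immobile = fx$ecr_immobile$ground_truth,
        h2b_slow = fx$h2b_slow$ground_truth,
        phantom = list(fractions = as.list(fx$phantom$ground_truth)),
        flip_pair = list(k_ex = flip_spec$k_ex,
                         t_half_exchange = fx$flip_pair$t_half_exchange)))
    jsonlite::write_json(lapply(manifest, strip_classes),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(fx)
}

strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  unclass(x)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the synthetic
#' fixture bundle: fixture generation, FRAP normalization and fitting,
#' FLIP-FRAP exchange analysis, condensation quantification (volume
#' fractions, density ratios, fragment compaction) and
#' clustering/colocalization statistics.  The report is a pure function of
#' the configuration: identical config and seed give an identical report.
#' A resolved copy of the configuration is written alongside the outputs
#' and its MD5 hash is recorded in the report.
#'
#' @param config A [run_config()].
#' @param output_dir Directory for the report, resolved config and fixture
#'   files.
#' @return A `run_report` list with one entry per executed stage, plus
#'   `version`, `config_hash` and collected `warnings`.  Stage failure
#'   aborts with the failing stage named; outputs of completed stages are
#'   retained on disk.
#' @export
run_pipeline <- function(config = run_config(), output_dir = tempfile("run")) {
  check_that(inherits(config, "run_config"), "config", "must be a run_config")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(strip_classes(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config_hash <- unname(tools::md5sum(cfg_path))

  warnings_log <- character(0)
  report <- list()
  order <- c("fixtures", "frap", "flip", "condensation", "coloc")
  stages <- order[order %in% config$stages]

  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  fx <- run_stage("fixtures",
                  make_fixtures(config$seed,
                                dir = file.path(output_dir, "fixtures")))
  if ("fixtures" %in% stages)
    report$fixtures <- list(n_fixtures = length(fx),
                            manifest = file.path("fixtures", "manifest.json"))

  if ("frap" %in% stages) {
    report$frap <- run_stage("frap", {
      fits <- lapply(c("brm_fast", "k804r_slow", "ecr_immobile"),
                     function(nm) {
        fit <- fit_double_exponential(
          full_scale_normalize(background_correct(fx[[nm]]$curve)),
          n_starts = config$frap$n_starts)
        list(fixture = nm, a = fit$a, b = fit$b, k1 = fit$k1, k2 = fit$k2,
             mobile_fraction = fit$mobile_fraction, t_half_s = fit$t_half,
             sse = fit$sse, converged = fit$converged, model = fit$model)
      })
      nc_h2b <- full_scale_normalize(background_correct(fx$h2b_slow$curve))
      fits[[4]] <- list(fixture = "h2b_slow",
                        recovery_at_40min =
                          percent_recovery_at(nc_h2b, 2400, window = 120))
      ratio <- fits[[2]]$t_half_s / fits[[1]]$t_half_s
      list(fits = fits, t_half_ratio_slow_fast = ratio)
    })
  }

  if ("flip" %in% stages) {
    report$flip <- run_stage("flip", {
      res <- analyze_flip_frap(fx$flip_pair$bleached, fx$flip_pair$unbleached)
      list(equilibration_t_half_s = res$equilibration_t_half,
           gain_loss_balance = res$gain_loss_balance,
           bleached_recovery_pct = res$bleached_recovery_pct,
           unbleached_loss_pct = res$unbleached_loss_pct)
    })
  }

  if ("condensation" %in% stages) {
    report$condensation <- run_stage("condensation", {
      th <- config$condensation$thresholds
      scheme <- class_scheme(th$background_max, th$white_max, th$gray_max)
      labels <- classify_voxels(fx$phantom$image, scheme)
      vols <- volume_fractions(labels)
      genome <- do.call(genomic_composition, config$condensation$genome)
      cond <- relative_condensation(genome, vols)
      fm <- fiber_model(config$fiber$nm_per_bp, config$fiber$packing_ratio)
      compaction <- lapply(names(config$fragments), function(nm) {
        fr <- config$fragments[[nm]]
        meas <- fragment_measurement(fr$lengths, dna_bp = fr$dna_bp)
        fc <- fold_compaction_linear(measurement = meas, model = fm)
        list(fragment = nm, extended_um = fc$extended_length,
             observed_um = fc$observed_mean, fold = fc$fold)
      })
      list(volume_fractions = as.list(vols$fractions),
           ground_truth_fractions = as.list(fx$phantom$ground_truth),
           density = as.list(cond$density),
           ratios = as.list(cond$ratios),
           compaction = compaction)
    })
  }

  if ("coloc" %in% stages) {
    report$coloc <- run_stage("coloc", {
      mid <- ceiling(dim(fx$phantom$image)[3] / 2)
      h2b <- fx$phantom$image[, , mid]
      # remodeler-like channel: bright where chromatin is open
      brm <- 255 - h2b
      nucleus <- fx$phantom$labels[, , mid] > 1L
      vm <- local_variance_map(h2b, radius = config$variance$radius,
                               mask = nucleus)
      mc <- manders_coefficients(brm, h2b,
                                 threshold = config$coloc$threshold,
                                 mask = nucleus)
      list(mean_nuclear_variance = vm$mean_nuclear_variance,
           manders_M1 = mc$M1, manders_M2 = mc$M2)
    })
  }

  report$version <- as.character(utils::packageVersion("chromodyn"))
  report$config_hash <- config_hash
  report$warnings <- warnings_log
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(report, class = "run_report")
}
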