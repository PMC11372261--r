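#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic cohort, the phantom
#' grid, tracer-specific AIF fit forms and uptake-time-correction
#' parameters, segmentation margin, and the seed. By default the late
#' window is analyzed with the extrapolated early AIF fit (the scanner
#' workflow when late blood is unmeasurable); `use_true_aif = TRUE`
#' substitutes the ground-truth input function to isolate
#' extrapolation-induced Ki bias.
#'
#' @param cohort A [cohort_config()].
#' @param grid A [grid_spec()].
#' @param corrections Named list of [correction_params()] per tracer.
#' @param aif_fit_form Named character: fit form per tracer.
#' @param use_true_aif Use the ground-truth AIF instead of the fit.
#' @param blood_noise_scale Noise scale for the sampled blood curve. The
#'   image-derived blood value averages the whole aortic VOI, so its noise
#'   is far below voxel level: the default is a tenth of the cohort's voxel
#'   noise scale.
#' @param mask_dilate Ground-truth lesion mask dilation, voxels.
#' @param seed Default seed for [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            grid = grid_spec(),
                            corrections = correction_defaults(),
                            aif_fit_form = c(FDG = "exponential_tail",
                                             DOTATATE = "linear_piecewise"),
                            use_true_aif = FALSE,
                            blood_noise_scale = NULL,
                            mask_dilate = 1,
                            seed = 1L) {
  if (is.null(blood_noise_scale)) blood_noise_scale <- cohort$noise_scale / 10
  structure(
    list(cohort = cohort, grid = grid, corrections = corrections,
         aif_fit_form = aif_fit_form, use_true_aif = use_true_aif,
         blood_noise_scale = blood_noise_scale, mask_dilate = mask_dilate,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read and validate a pipeline configuration from YAML or JSON
#'
#' Unknown keys (at the top level, or inside `cohort`/`grid`) are rejected
#' by name before any stage runs.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config_keys(raw)
  args <- raw
  if (!is.null(raw$cohort)) {
    ck <- raw$cohort
    for (nm in c("tracer_mix")) {
      if (!is.null(ck[[nm]])) ck[[nm]] <- unlist(ck[[nm]])
    }
    args$cohort <- do.call(cohort_config, ck)
  }
  if (!is.null(raw$grid)) args$grid <- do.call(grid_spec, raw$grid)
  if (!is.null(raw$corrections)) {
    args$corrections <- purrr::map(raw$corrections,
                                   ~ do.call(correction_params, .x))
  }
  if (!is.null(raw$aif_fit_form)) args$aif_fit_form <- unlist(raw$aif_fit_form)
  do.call(pipeline_config, args)
}

validate_config_keys <- function(raw) {
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$cohort)) {
    unknown <- setdiff(names(raw$cohort), names(formals(cohort_config)))
    if (length(unknown)) {
      stop("unknown cohort key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(raw$grid)) {
    unknown <- setdiff(names(raw$grid), names(formals(grid_spec)))
    if (length(unknown)) {
      stop("unknown grid key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate a cohort: blood samples and dynamic phantoms
#'
#' Deterministic given `seed`. With `out_dir` set, writes
#' `cohort.json`, per-subject blood TAC CSVs, 4D phantom NIfTI images with
#' frame-time sidecars and lesion-placement JSONs, and a run manifest.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param out_dir Optional output directory.
#' @return A `pet_simulation` list: `cohort`, `blood` (named TAC list),
#'   `phantoms` (named [render_dynamic_phantom()] list), `seed`, `config`.
#' @export
run_simulate <- function(config, seed = config$seed, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  cohort <- generate_cohort(config$cohort, seed)
  blood <- list()
  phantoms <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    blood[[sid]] <- simulate_blood_samples(
      cohort$aif[[i]], t_end = config$cohort$t_measured_end,
      noise_scale = config$blood_noise_scale, seed = seed + 1000L + i
    )
    phantoms[[sid]] <- render_dynamic_phantom(
      cohort[i, ], grid = config$grid, seed = seed + 2000L + i,
      noise_scale = config$cohort$noise_scale
    )
  }
  sim <- structure(
    list(cohort = cohort, blood = blood, phantoms = phantoms,
         seed = as.integer(seed), config = config),
    class = "pet_simulation"
  )
  if (!is.null(out_dir)) write_simulation(sim, out_dir, elapsed(t0))
  sim
}

elapsed <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

write_simulation <- function(sim, out_dir, timing = NA_real_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- file.path(out_dir, "cohort.json")
  write_cohort(sim$cohort, p)
  files <- c(files, p)
  for (sid in names(sim$blood)) {
    p <- file.path(out_dir, paste0("blood_", sid, ".csv"))
    write_tac(sim$blood[[sid]], p)
    files <- c(files, p)
    ph <- sim$phantoms[[sid]]
    img_path <- file.path(out_dir, paste0("phantom_", sid, ".nii.gz"))
    write_pet_image(ph$image, img_path)
    files <- c(files, img_path, paste0(img_path, ".json"))
    les_path <- file.path(out_dir, paste0("lesions_", sid, ".json"))
    les <- ph$lesions
    jsonlite::write_json(
      list(
        lesion_id = les$lesion_id, diameter_mm = les$diameter_mm,
        center = lapply(seq_len(nrow(les)), function(j) {
          c(les$center_x[j], les$center_y[j], les$center_z[j])
        }),
        frame_centers = les$frame_centers,
        aorta_tube = unclass(ph$aorta_tube),
        aorta_voi = unclass(ph$aorta_voi)
      ),
      les_path, digits = NA, auto_unbox = TRUE
    )
    files <- c(files, les_path)
  }
  manifest <- list(
    stage = "simulate", seed = sim$seed,
    config_hash = rlang::hash(sim$config),
    files = basename(files), warnings = character(0),
    timing_s = timing
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest_simulate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Restore a simulation from serialized stage outputs
#'
#' @param dir Directory written by [run_simulate()].
#' @param config The [pipeline_config()] used (for downstream stages).
#' @return A `pet_simulation` list.
#' @export
read_simulation <- function(dir, config) {
  cohort <- read_cohort(file.path(dir, "cohort.json"))
  blood <- list()
  phantoms <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    blood[[sid]] <- read_tac(file.path(dir, paste0("blood_", sid, ".csv")))
    img <- read_pet_image(file.path(dir, paste0("phantom_", sid, ".nii.gz")))
    lj <- jsonlite::read_json(file.path(dir, paste0("lesions_", sid,
                                                    ".json")),
                              simplifyVector = FALSE)
    les <- cohort$lesions[[i]]
    ctr <- t(vapply(lj$center, function(cc) as.numeric(unlist(cc)),
                    numeric(3)))
    les$center_x <- ctr[, 1]
    les$center_y <- ctr[, 2]
    les$center_z <- ctr[, 3]
    les$frame_centers <- lapply(lj$frame_centers, function(m) {
      matrix(as.numeric(unlist(m)), ncol = 3, byrow = TRUE)
    })
    phantoms[[sid]] <- structure(
      list(image = img, lesions = les,
           aorta_tube = voi_cylinder(as.numeric(unlist(lj$aorta_tube$center)),
                                     lj$aorta_tube$diameter,
                                     lj$aorta_tube$length,
                                     as.numeric(unlist(lj$aorta_tube$axis))),
           aorta_voi = voi_cylinder(as.numeric(unlist(lj$aorta_voi$center)),
                                    lj$aorta_voi$diameter,
                                    lj$aorta_voi$length,
                                    as.numeric(unlist(lj$aorta_voi$axis))),
           subject = cohort[i, ]),
      class = "pet_phantom"
    )
  }
  structure(list(cohort = cohort, blood = blood, phantoms = phantoms,
                 seed = NA_integer_, config = config),
            class = "pet_simulation")
}

#' Quantify lesions: SUV, SUR, Ki, and corrected metrics
#'
#' For every lesion and timepoint: builds the window SUV map (mean of the
#' three pass frames) and the voxelwise Patlak Ki map, extracts maximum and
#' 1-mL-sphere peak values over the (dilated) ground-truth lesion mask,
#' measures the aortic blood-pool SUVmean for SUR, applies hematocrit
#' correction to DOTATATE Ki, and appends uptake-time-corrected cSUV/cSUR
#' columns.
#'
#' @param sim A `pet_simulation` (from [run_simulate()]) or a directory of
#'   serialized stage outputs.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for `metrics.csv` and a manifest.
#' @return Tibble, one row per lesion x timepoint.
#' @export
run_analyze <- function(sim, config, out_dir = NULL) {
  if (is.character(sim)) sim <- read_simulation(sim, config)
  stopifnot(inherits(sim, "pet_simulation"))
  t0 <- Sys.time()
  warnings_log <- character(0)
  rows <- list()
  for (i in seq_len(nrow(sim$cohort))) {
    subj <- sim$cohort[i, ]
    sid <- subj$subject_id
    tracer <- subj$tracer
    ph <- sim$phantoms[[sid]]
    aif_used <- if (config$use_true_aif) {
      subj$aif[[1]]
    } else {
      fit_aif(sim$blood[[sid]], form = config$aif_fit_form[[tracer]])
    }
    sched <- ph$image$frame_times
    masks <- lapply(ph$lesions$lesion_id, function(lid) {
      lesion_mask(ph, lid, dilate = config$mask_dilate)
    })
    for (win in c("early", "late")) {
      wi <- sched[sched$window == win, ]
      t0w <- effective_uptake_time(c(min(wi$frame_start),
                                     max(wi$frame_end)))
      suv_img <- window_suv_image(ph$image, win, subj$injected_dose_MBq,
                                  subj$body_weight_kg)
      ki_img <- voxelwise_ki(ph$image, aif_used, win)
      if (attr(ki_img, "n_failed") > 0) {
        warnings_log <- c(warnings_log,
                          sprintf("%s %s: %d voxelwise fits failed",
                                  sid, win, attr(ki_img, "n_failed")))
      }
      suv_peak_map <- sphere_mean_map(suv_img$data, suv_img$voxel_size)
      ki_peak_map <- sphere_mean_map(ki_img$data, ki_img$voxel_size)
      blood_suv <- blood_pool_mean(suv_img, ph$aorta_voi)
      for (j in seq_len(nrow(ph$lesions))) {
        m <- masks[[j]]
        suv_max <- extract_max(suv_img, m)
        suv_peak <- max(suv_peak_map[m], na.rm = TRUE)
        ki_max <- hematocrit_correct(extract_max(ki_img, m),
                                     subj$hematocrit, tracer)
        ki_peak <- hematocrit_correct(max(ki_peak_map[m], na.rm = TRUE),
                                      subj$hematocrit, tracer)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sid, tracer = tracer,
          lesion_id = ph$lesions$lesion_id[j], timepoint = win,
          effective_uptake_time = t0w,
          suv_max = suv_max, suv_peak = suv_peak,
          blood_suv_mean = blood_suv,
          sur_max = compute_sur(suv_max, blood_suv),
          sur_peak = compute_sur(suv_peak, blood_suv),
          ki_max = ki_max, ki_peak = ki_peak
        )
      }
    }
  }
  metrics <- apply_corrections(dplyr::bind_rows(rows), config$corrections)
  metrics <- dplyr::arrange(metrics, .data$subject_id, .data$lesion_id,
                            .data$timepoint)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    manifest <- list(stage = "analyze", config_hash = rlang::hash(config),
                     files = "metrics.csv", warnings = warnings_log,
                     timing_s = elapsed(t0))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest_analyze.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  metrics
}

#' Repeatability report: per-tracer summary and plot-ready tables
#'
#' Tracers are analyzed separately. Produces the per-metric repeatability
#' summary (medians with quartiles, Wilcoxon p, R-squared, ICC, limits of
#' repeatability), plus long-format Bland--Altman and box-plot data tables.
#'
#' @param metrics Lesion metrics table from [run_analyze()] (or a directory
#'   containing `metrics.csv`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for `summary.csv`, `summary.json`,
#'   `bland_altman.csv`, `boxplot_data.csv`, and a manifest.
#' @return List with `summary`, `bland_altman`, `boxplot_data` tibbles.
#' @export
run_report <- function(metrics, config, out_dir = NULL) {
  if (is.character(metrics)) {
    metrics <- tibble::as_tibble(
      utils::read.csv(file.path(metrics, "metrics.csv"),
                      stringsAsFactors = FALSE)
    )
  }
  t0 <- Sys.time()
  summary <- summarize_repeatability(metrics)
  metric_cols <- unique(summary$metric)
  long <- tidyr::pivot_longer(
    metrics[, c("tracer", "lesion_id", "timepoint", metric_cols)],
    dplyr::all_of(metric_cols), names_to = "metric", values_to = "value"
  )
  wide <- tidyr::pivot_wider(long, names_from = "timepoint",
                             values_from = "value")
  ba <- dplyr::transmute(
    wide, tracer = .data$tracer, metric = .data$metric,
    lesion_id = .data$lesion_id,
    pair_mean = (.data$early + .data$late) / 2,
    delta = .data$late - .data$early,
    pct_delta = 100 * (.data$late - .data$early) /
      ((.data$early + .data$late) / 2)
  )
  box <- dplyr::mutate(ba, abs_pct_delta = abs(.data$pct_delta))
  box <- box[, c("tracer", "metric", "lesion_id", "pct_delta",
                 "abs_pct_delta")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(ba, file.path(out_dir, "bland_altman.csv"),
                     row.names = FALSE)
    utils::write.csv(box, file.path(out_dir, "boxplot_data.csv"),
                     row.names = FALSE)
    manifest <- list(stage = "report", config_hash = rlang::hash(config),
                     files = c("summary.csv", "summary.json",
                               "bland_altman.csv", "boxplot_data.csv"),
                     warnings = character(0), timing_s = elapsed(t0))
    jsonlite::write_json(manifest, file.path(out_dir,
                                             "manifest_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, bland_altman = ba, boxplot_data = box)
}

#' Run the full pipeline: simulate, analyze, report
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param out_dir Optional directory; each stage serializes its outputs
#'   there, so stages can later be re-run independently.
#' @return List with `simulation`, `metrics`, and the [run_report()] tables.
#' @export
run_pipeline <- function(config, seed = config$seed, out_dir = NULL) {
  sim <- run_simulate(config, seed = seed, out_dir = out_dir)
  metrics <- run_analyze(sim, config, out_dir = out_dir)
  report <- run_report(metrics, config, out_dir = out_dir)
  c(list(simulation = sim, metrics = metrics), report)
}
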