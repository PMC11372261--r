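#' Synthetic cohort configuration
#'
#' Defaults define an oncologic whole-body dynamic PET study: FDG-like
#' subjects carry irreversibly trapping lesions (`k4 = 0`), DOTATATE-like
#' subjects partially reversible ones (`k4 > 0`) plus a hematocrit used for
#' plasma correction of Ki. Each subject has 1--5 spherical lesions, an
#' aortic blood input function measurable to 50 min (forcing extrapolation
#' for the late window), and early/late windows of three 5-min passes with
#' per-subject uptake-time jitter.
#'
#' Kinetic ranges give true Ki of roughly 1--4 mL/min/100 mL for FDG (the
#' clinical lesion scale) with lesion SUV growth between the windows
#' consistent with the published FDG power-law exponent; blood clearance is
#' set so the blood pool falls about 20% between the window midpoints.
#'
#' @param n_subjects Number of subjects (must be >= 1 at generation time).
#' @param tracer_mix Named proportions for `FDG` and `DOTATATE`.
#' @param min_lesions,max_lesions Lesions per subject (1--5).
#' @param lesion_diameter_mm Range of lesion diameters (mm).
#' @param motion_amplitude_mm Range of per-lesion inter-frame motion (mm).
#'   The default is 0: the emulated workflow reviews passes for motion and
#'   segments lesions frame by frame, and a voxel phantom without
#'   point-spread-function smoothing over-expresses motion artifacts, so
#'   the default represents the post-mitigation condition. Set a positive
#'   range to study motion-induced Ki errors.
#' @param early_window,late_window Nominal acquisition windows (min).
#' @param window_jitter_min Uniform jitter applied to each window start
#'   (min), per subject per timepoint.
#' @param dose_MBq,weight_kg,hematocrit Subject metadata ranges.
#' @param blood_suv60 Range of blood-pool SUV at 60 min, setting the
#'   per-subject AIF scale.
#' @param noise_scale TAC/phantom noise scale (see [add_tac_noise()]).
#' @param kinetics Per-tracer lists of 2TC rate ranges (`K1`, `k2`, `k3`,
#'   `k4`, `vb`, each a length-2 range).
#' @param background Per-tracer [kinetic_params()] for non-lesion tissue.
#' @param t_measured_end Last blood-sampling time (min).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 10,
                          tracer_mix = c(FDG = 1, DOTATATE = 0),
                          min_lesions = 1, max_lesions = 5,
                          lesion_diameter_mm = c(10, 25),
                          motion_amplitude_mm = c(0, 0),
                          early_window = c(35, 50),
                          late_window = c(75, 90),
                          window_jitter_min = 5,
                          dose_MBq = c(300, 450),
                          weight_kg = c(55, 100),
                          hematocrit = c(0.35, 0.48),
                          blood_suv60 = c(1.4, 2.2),
                          noise_scale = 0.2,
                          kinetics = NULL,
                          background = NULL,
                          t_measured_end = 50) {
  if (is.null(kinetics)) {
    kinetics <- list(
      FDG = list(K1 = c(0.06, 0.14), k2 = c(0.25, 0.45),
                 k3 = c(0.10, 0.30), k4 = c(0, 0), vb = c(0.02, 0.06)),
      DOTATATE = list(K1 = c(0.10, 0.30), k2 = c(0.20, 0.50),
                      k3 = c(0.05, 0.20), k4 = c(0.005, 0.02),
                      vb = c(0.02, 0.06))
    )
  }
  if (is.null(background)) {
    background <- list(
      FDG = kinetic_params(K1 = 0.05, k2 = 0.40, k3 = 0.004, vb = 0.03),
      DOTATATE = kinetic_params(K1 = 0.05, k2 = 0.40, k3 = 0.002,
                                k4 = 0.005, vb = 0.03)
    )
  }
  if (max_lesions > 5 || min_lesions < 1 || min_lesions > max_lesions) {
    stop("lesion count bounds must satisfy 1 <= min <= max <= 5",
         call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, tracer_mix = tracer_mix,
         min_lesions = min_lesions, max_lesions = max_lesions,
         lesion_diameter_mm = lesion_diameter_mm,
         motion_amplitude_mm = motion_amplitude_mm,
         early_window = early_window, late_window = late_window,
         window_jitter_min = window_jitter_min,
         dose_MBq = dose_MBq, weight_kg = weight_kg,
         hematocrit = hematocrit, blood_suv60 = blood_suv60,
         noise_scale = noise_scale, kinetics = kinetics,
         background = background, t_measured_end = t_measured_end),
    class = "cohort_config"
  )
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a synthetic subject cohort
#'
#' Deterministic given `seed`: subject metadata, per-subject AIF scale and
#' jittered acquisition windows, and 1--5 lesions with 2TC parameters drawn
#' from the configured ranges.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `pet_cohort` tibble, one row per subject, with list-columns
#'   `aif` ([make_aif()] objects), `schedule` ([make_schedule()] tibbles),
#'   `lesions` (tibbles of lesion geometry and `params`), and `background`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 1) {
    stop("cohort must contain at least one subject", call. = FALSE)
  }
  with_preserved_seed(seed, {
    tracers <- assign_tracers(config$tracer_mix, config$n_subjects)
    rows <- purrr::map(seq_len(config$n_subjects), function(i) {
      tracer <- tracers[i]
      dose <- runif1(config$dose_MBq)
      weight <- runif1(config$weight_kg)
      hct <- if (tracer == "DOTATATE") runif1(config$hematocrit) else NA_real_
      half_life <- if (tracer == "FDG") 109.77 else 67.71
      # scale AIF so blood-pool SUV at 60 min lands in the configured range
      base <- make_aif("feng_exponential_sum",
                       t_measured_end = config$t_measured_end)
      target_suv <- runif1(config$blood_suv60)
      scale <- target_suv * dose / weight / aif_value(base, 60)
      aif <- make_aif("feng_exponential_sum", scale = scale,
                      t_measured_end = config$t_measured_end)
      jit <- function(w) w + stats::runif(1, -config$window_jitter_min,
                                          config$window_jitter_min)
      sched <- make_schedule(jit(config$early_window),
                             jit(config$late_window))
      n_les <- sample(seq(config$min_lesions, config$max_lesions), 1)
      kr <- config$kinetics[[tracer]]
      lesions <- purrr::map(seq_len(n_les), function(j) {
        tibble::tibble(
          lesion_id = sprintf("S%02d_L%d", i, j),
          diameter_mm = runif1(config$lesion_diameter_mm),
          motion_amplitude_mm = runif1(config$motion_amplitude_mm),
          params = list(kinetic_params(
            K1 = runif1(kr$K1), k2 = runif1(kr$k2), k3 = runif1(kr$k3),
            k4 = runif1(kr$k4), vb = runif1(kr$vb)
          ))
        )
      })
      tibble::tibble(
        subject_id = sprintf("S%02d", i), tracer = tracer,
        injected_dose_MBq = dose, body_weight_kg = weight,
        hematocrit = hct, half_life_min = half_life,
        aif = list(aif), schedule = list(sched),
        lesions = list(dplyr::bind_rows(lesions)),
        background = list(config$background[[tracer]])
      )
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("pet_cohort", class(out))
    out
  })
}

assign_tracers <- function(mix, n) {
  mix <- mix[mix > 0]
  if (length(mix) == 0) stop("tracer_mix must be non-empty", call. = FALSE)
  if (!all(names(mix) %in% c("FDG", "DOTATATE"))) {
    stop("tracers must be FDG and/or DOTATATE", call. = FALSE)
  }
  counts <- round(mix / sum(mix) * n)
  # fix rounding so counts sum to n
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  while (sum(counts) < n) counts[which.min(counts)] <- counts[which.min(counts)] + 1
  rep(names(counts), counts)
}

#' Simulate densely framed blood samples from a subject's AIF
#'
#' Emulates image-derived aortic blood measurements: short frames over the
#' first pass, coarsening to 5-min frames, ending at the last measurable
#' time (default 50 min; the subject leaves the scanner afterwards, so late
#' blood values must be extrapolated).
#'
#' @param aif A [make_aif()] object.
#' @param t_end Last sampling time (min).
#' @param noise_scale,seed Optional frame noise (see [add_tac_noise()]).
#' @return A TAC tibble of frame-averaged blood concentrations.
#' @export
simulate_blood_samples <- function(aif, t_end = 50, noise_scale = 0,
                                   seed = 1L) {
  edges <- unique(c(seq(0, 2, by = 1 / 6), seq(2, 10, by = 0.5),
                    seq(10, 20, by = 2), seq(20, t_end, by = 5), t_end))
  edges <- sort(edges)
  start <- utils::head(edges, -1)
  end <- utils::tail(edges, -1)
  # frame average = difference of the closed-form running integral
  vals <- (aif_integral(aif, end) - aif_integral(aif, start)) / (end - start)
  tac <- new_tac(start, end, vals)
  if (noise_scale > 0) tac <- add_tac_noise(tac, noise_scale, seed) else tac
}

#' Simulate lesion SUV pairs following a power-law uptake trajectory
#'
#' Generates early/late SUV pairs from \eqn{SUV(t) = S_{60} (t/60)^{1-b}},
#' the growth model underlying uptake-time correction; used to validate the
#' empirical derivation of the exponent `b` (see [derive_b()]).
#'
#' @param n_subjects,lesions_per_subject Cohort shape.
#' @param b True exponent (scalar, or per-lesion values recycled).
#' @param t_early_range,t_late_range Uniform ranges of actual uptake times.
#' @param suv60_range Range of SUV at the 60-min reference time.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   measurement noise on each SUV (0 = noiseless).
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `lesion_id`, `suv_early`, `t_early`,
#'   `suv_late`, `t_late`.
#' @export
simulate_power_law_pairs <- function(n_subjects, lesions_per_subject = 3,
                                     b = 0.313,
                                     t_early_range = c(37, 48),
                                     t_late_range = c(75, 88),
                                     suv60_range = c(3, 12),
                                     noise_cv = 0, seed = 1L) {
  with_preserved_seed(seed, {
    grid <- tidyr::expand_grid(si = seq_len(n_subjects),
                               li = seq_len(lesions_per_subject))
    n <- nrow(grid)
    bs <- rep_len(b, n)
    te <- stats::runif(n, t_early_range[1], t_early_range[2])
    tl <- stats::runif(n, t_late_range[1], t_late_range[2])
    s60 <- stats::runif(n, suv60_range[1], suv60_range[2])
    se <- s60 * (te / 60)^(1 - bs)
    sl <- s60 * (tl / 60)^(1 - bs)
    if (noise_cv > 0) {
      se <- pmax(se * (1 + stats::rnorm(n, sd = noise_cv)), 1e-6)
      sl <- pmax(sl * (1 + stats::rnorm(n, sd = noise_cv)), 1e-6)
    }
    tibble::tibble(
      subject_id = sprintf("S%02d", grid$si),
      lesion_id = sprintf("S%02d_L%d", grid$si, grid$li),
      suv_early = se, t_early = te, suv_late = sl, t_late = tl
    )
  })
}

#' Serialize / restore a cohort as JSON
#'
#' @param cohort A `pet_cohort` tibble.
#' @param path JSON file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   restored `pet_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  subjects <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    les <- row$lesions[[1]]
    list(
      subject_id = row$subject_id, tracer = row$tracer,
      injected_dose_MBq = row$injected_dose_MBq,
      body_weight_kg = row$body_weight_kg,
      hematocrit = row$hematocrit, half_life_min = row$half_life_min,
      aif = unclass(row$aif[[1]]),
      schedule = as.list(row$schedule[[1]][c("frame_start", "frame_end",
                                             "window")]),
      lesions = purrr::map(seq_len(nrow(les)), function(j) {
        list(lesion_id = les$lesion_id[j],
             diameter_mm = les$diameter_mm[j],
             motion_amplitude_mm = les$motion_amplitude_mm[j],
             params = unclass(les$params[[j]]))
      }),
      background = unclass(row$background[[1]])
    )
  })
  jsonlite::write_json(subjects, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  subjects <- jsonlite::read_json(path)
  rows <- purrr::map(subjects, function(s) {
    aif <- make_aif(s$aif$form,
                    params = if (length(s$aif$params)) {
                      purrr::map(s$aif$params, ~ unlist(.x, use.names = FALSE))
                    } else NULL,
                    onset = s$aif$onset, scale = s$aif$scale,
                    t_measured_end = s$aif$t_measured_end)
    sched <- tibble::tibble(
      frame_start = unlist(s$schedule$frame_start),
      frame_end = unlist(s$schedule$frame_end),
      window = unlist(s$schedule$window)
    )
    les <- dplyr::bind_rows(purrr::map(s$lesions, function(l) {
      tibble::tibble(lesion_id = l$lesion_id, diameter_mm = l$diameter_mm,
                     motion_amplitude_mm = l$motion_amplitude_mm,
                     params = list(do.call(kinetic_params, l$params)))
    }))
    tibble::tibble(
      subject_id = s$subject_id, tracer = s$tracer,
      injected_dose_MBq = s$injected_dose_MBq,
      body_weight_kg = s$body_weight_kg,
      hematocrit = if (is.null(s$hematocrit)) NA_real_ else s$hematocrit,
      half_life_min = s$half_life_min,
      aif = list(aif), schedule = list(sched), lesions = list(les),
      background = list(do.call(kinetic_params, s$background))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pet_cohort", class(out))
  out
}
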