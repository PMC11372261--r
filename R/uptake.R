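#' Uptake-time correction parameters
#'
#' `Tc` is the reference uptake time every measurement is corrected to
#' (60 min, the commonly targeted clinical uptake time); `b` is the
#' tracer-specific power-law exponent of SUV growth, \eqn{SUV(t) \propto
#' t^{1-b}}: 0.313 for FDG (published value) and 0.63 for DOTATATE
#' (empirically derived).
#'
#' @param b Exponent in `[0, 1.5]`.
#' @param Tc Reference uptake time, min (> 0).
#' @return A `correction_params` list.
#' @export
correction_params <- function(b, Tc = 60) {
  if (Tc <= 0) stop("`Tc` must be > 0", call. = FALSE)
  if (b < 0 || b > 1.5) {
    stop("`b` must lie in [0, 1.5]", call. = FALSE)
  }
  structure(list(b = b, Tc = Tc), class = "correction_params")
}

#' @rdname correction_params
#' @export
correction_defaults <- function() {
  list(FDG = correction_params(b = 0.313, Tc = 60),
       DOTATATE = correction_params(b = 0.63, Tc = 60))
}

#' Effective uptake time of an acquisition window
#'
#' The midpoint of the actual acquisition window, e.g. 44.5 min for a
#' 37--52 min window.
#'
#' @param window Length-2 numeric `(t_start, t_end)`, min, `t_end > t_start
#'   >= 0`.
#' @return Midpoint in minutes.
#' @examples
#' effective_uptake_time(c(37, 52)) # 44.5
#' @export
effective_uptake_time <- function(window) {
  if (length(window) != 2 || window[2] <= window[1] || window[1] < 0) {
    stop("window must be (t_start, t_end) with t_end > t_start >= 0",
         call. = FALSE)
  }
  (window[1] + window[2]) / 2
}

#' Tumor-to-blood standardized uptake ratio
#'
#' SUR = tumor SUV / blood-pool mean SUV. SURmax and SURpeak are built from
#' SUVmax and SUVpeak with the same blood SUVmean.
#'
#' @param tumor_suv Tumor SUV (vectorized).
#' @param blood_suv_mean Blood-pool mean SUV (> 0).
#' @return Unitless SUR.
#' @export
compute_sur <- function(tumor_suv, blood_suv_mean) {
  if (any(blood_suv_mean <= 0)) {
    stop("blood SUVmean must be > 0", call. = FALSE)
  }
  tumor_suv / blood_suv_mean
}

#' Uptake-time-corrected SUV and SUR
#'
#' \eqn{cSUV = SUV (T_c/T_0)^{1-b}} rescales an SUV measured at actual
#' uptake time \eqn{T_0} to the reference time \eqn{T_c};
#' \eqn{cSUR = SUR \cdot T_c/T_0} does the same for SUR, exact when SUR
#' grows linearly with time (the Patlak-like regime).
#'
#' @param suv,sur Measured value(s).
#' @param T0 Actual (effective) uptake time, min (> 0).
#' @param params A [correction_params()] (for `correct_suv`).
#' @param Tc Reference time, min (for `correct_sur`).
#' @return Corrected value(s).
#' @examples
#' correct_suv(6, 44.5, correction_params(0.313)) # 6 * (60/44.5)^0.687
#' correct_sur(3, 90, Tc = 60) # 2
#' @export
correct_suv <- function(suv, T0, params) {
  stopifnot(inherits(params, "correction_params"))
  if (any(T0 <= 0)) stop("`T0` must be > 0", call. = FALSE)
  suv * (params$Tc / T0)^(1 - params$b)
}

#' @rdname correct_suv
#' @export
correct_sur <- function(sur, T0, Tc = 60) {
  if (any(T0 <= 0)) stop("`T0` must be > 0", call. = FALSE)
  sur * Tc / T0
}

#' Empirically derive the uptake-time exponent b
#'
#' For each lesion with an early and a late SUV measurement, the two-point
#' power-law equation \eqn{SUV_{late} = SUV_{early} (T_{late}/T_{early})^{1-b}}
#' is solved exactly:
#' \deqn{b = 1 - \ln(SUV_{late}/SUV_{early}) / \ln(T_{late}/T_{early}).}
#' Per-lesion values are averaged within subject and then across subjects
#' (default), so lesion-rich subjects do not dominate; `aggregate =
#' "lesion"` pools all lesions instead.
#'
#' @param pairs Tibble with columns `subject_id`, `suv_early`, `t_early`,
#'   `suv_late`, `t_late` (all SUVs > 0, `t_late > t_early > 0`).
#' @param aggregate `"subject"` (default) or `"lesion"`.
#' @return The cross-subject (or pooled) mean `b`. A warning is issued if
#'   the result lies outside `[0, 1.5]`.
#' @export
derive_b <- function(pairs, aggregate = c("subject", "lesion")) {
  aggregate <- match.arg(aggregate)
  needed <- c("subject_id", "suv_early", "t_early", "suv_late", "t_late")
  if (!all(needed %in% names(pairs))) {
    stop("`pairs` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  with(pairs, {
    if (any(suv_early <= 0) || any(suv_late <= 0)) {
      stop("SUVs must be positive", call. = FALSE)
    }
    if (any(t_early <= 0) || any(t_late <= t_early)) {
      stop("times must satisfy t_late > t_early > 0", call. = FALSE)
    }
  })
  per_lesion <- dplyr::mutate(
    pairs,
    b = 1 - log(.data$suv_late / .data$suv_early) /
      log(.data$t_late / .data$t_early)
  )
  b <- if (aggregate == "subject") {
    per_subject <- dplyr::summarise(
      dplyr::group_by(per_lesion, .data$subject_id),
      b = mean(.data$b), .groups = "drop"
    )
    mean(per_subject$b)
  } else {
    mean(per_lesion$b)
  }
  if (b < 0 || b > 1.5) {
    warning("derived b = ", format(b, digits = 4),
            " lies outside [0, 1.5]; values > 1 imply washout")
  }
  b
}

#' Apply uptake-time corrections to a lesion metrics table
#'
#' Fills `csuv_max`/`csuv_peak` via [correct_suv()] and
#' `csur_max`/`csur_peak` via [correct_sur()], using the tracer-specific
#' correction parameters (FDG b = 0.313, DOTATATE b = 0.63, Tc = 60 min by
#' default) and each row's effective uptake time.
#'
#' @param metrics Tibble with `tracer`, `effective_uptake_time`, `suv_max`,
#'   `suv_peak`, `sur_max`, `sur_peak`.
#' @param params Named list of [correction_params()] per tracer.
#' @return `metrics` with the four corrected columns added (or replaced).
#' @export
apply_corrections <- function(metrics, params = correction_defaults()) {
  needed <- c("tracer", "effective_uptake_time", "suv_max", "suv_peak",
              "sur_max", "sur_peak")
  if (!all(needed %in% names(metrics))) {
    stop("`metrics` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(metrics$effective_uptake_time))) {
    stop("effective uptake time missing for some rows", call. = FALSE)
  }
  rows <- dplyr::group_split(metrics, .data$tracer)
  out <- purrr::map(rows, function(g) {
    p <- params[[g$tracer[1]]]
    if (is.null(p)) {
      stop("no correction parameters for tracer ", g$tracer[1],
           call. = FALSE)
    }
    T0 <- g$effective_uptake_time
    dplyr::mutate(
      g,
      csuv_max = correct_suv(.data$suv_max, T0, p),
      csuv_peak = correct_suv(.data$suv_peak, T0, p),
      csur_max = correct_sur(.data$sur_max, T0, p$Tc),
      csur_peak = correct_sur(.data$sur_peak, T0, p$Tc)
    )
  })
  dplyr::bind_rows(out)
}
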