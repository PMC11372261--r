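#' Fit an arterial input function to sampled blood data
#'
#' Fits the measured blood TAC with one of the forms used by scanner
#' software: a sum of two decaying exponentials on post-peak samples
#' (FDG-style, `exponential_tail`) or an interpolating polyline through all
#' sample midpoints (DOTATATE-style, `linear_piecewise`). Values beyond the
#' fitted window are produced by the declared extrapolation rule (see
#' [evaluate_aif()]): continued exponentials, or continuation of the final
#' segment's slope clamped at 0.
#'
#' The bi-exponential models the settled clearance tail, not the first-pass
#' transit, so samples within `settle_min` minutes after the peak are
#' excluded from its support, and the least squares is weighted by frame
#' duration (the discrete analogue of a continuous-time fit, so densely
#' framed early samples are not over-counted).
#'
#' @param samples Blood TAC tibble (e.g. [simulate_blood_samples()]).
#' @param form `"exponential_tail"` or `"linear_piecewise"`.
#' @param settle_min Post-peak settle interval (min) excluded from the
#'   exponential fit.
#' @return An `aif_fit` object with `form`, `params`, `fit_window` (min)
#'   and `residual_rms` (kBq/mL).
#' @export
fit_aif <- function(samples, form = c("exponential_tail",
                                      "linear_piecewise"),
                    settle_min = 3) {
  form <- match.arg(form)
  t <- tac_midpoints(samples)
  v <- samples$value
  if (form == "linear_piecewise") {
    if (length(t) < 2) {
      stop("linear_piecewise requires at least 2 samples", call. = FALSE)
    }
    fit <- structure(
      list(form = form, params = list(t = t, value = v),
           fit_window = range(t), residual_rms = 0),
      class = "aif_fit"
    )
    return(fit)
  }
  peak <- which.max(v)
  keep <- which(t >= t[peak] + settle_min)
  if (length(keep) < 4) keep <- seq(peak, length(t)) # short curves: all post-peak
  tp <- t[keep]
  vp <- v[keep]
  wp <- (samples$frame_end - samples$frame_start)[keep]
  if (length(tp) < 4) {
    stop("exponential_tail requires >= 4 post-peak samples", call. = FALSE)
  }
  # starting values: slow component from the last third (log-linear), fast
  # component from the residual of the first post-peak points
  n <- length(tp)
  tail_idx <- seq(max(1, floor(2 * n / 3)), n)
  vt <- pmax(vp[tail_idx], 1e-9)
  cf_slow <- stats::coef(stats::lm(log(vt) ~ tp[tail_idx]))
  l2_0 <- max(-cf_slow[2], 1e-4)
  A2_0 <- exp(cf_slow[1])
  resid0 <- pmax(vp - A2_0 * exp(-l2_0 * tp), 1e-9)
  head_idx <- seq_len(max(2, floor(n / 3)))
  cf_fast <- stats::coef(stats::lm(log(resid0[head_idx]) ~ tp[head_idx]))
  l1_0 <- max(-cf_fast[2], l2_0 * 2)
  A1_0 <- exp(cf_fast[1])
  df <- data.frame(t = tp, v = vp, w = wp)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t), data = df,
      start = list(A1 = A1_0, l1 = l1_0, A2 = A2_0, l2 = l2_0),
      lower = c(0, 1e-6, 0, 1e-6), weights = df$w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop("AIF exponential fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  p <- as.list(stats::coef(fit))
  # order components fast-to-slow
  if (p$l1 < p$l2) p <- list(A1 = p$A2, l1 = p$l2, A2 = p$A1, l2 = p$l1)
  structure(
    list(form = form,
         params = list(A = c(p$A1, p$A2), lambda = c(p$l1, p$l2)),
         fit_window = range(tp),
         residual_rms = sqrt(mean(stats::resid(fit)^2))),
    class = "aif_fit"
  )
}

#' @export
print.aif_fit <- function(x, ...) {
  cat("<aif_fit>", x$form, " window:",
      paste(round(x$fit_window, 2), collapse = "-"),
      "min  rms:", format(x$residual_rms, digits = 3), "\n")
  invisible(x)
}

#' @export
aif_value.aif_fit <- function(x, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("times must be >= 0", call. = FALSE)
  if (x$form == "exponential_tail") {
    exp_sum_value(t, x$params$A, x$params$lambda)
  } else {
    piecewise_value(t, x$params$t, x$params$value)
  }
}

#' @export
aif_integral.aif_fit <- function(x, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("times must be >= 0", call. = FALSE)
  if (x$form == "exponential_tail") {
    exp_sum_integral(t, x$params$A, x$params$lambda)
  } else {
    piecewise_integral(t, x$params$t, x$params$value)
  }
}

#' @export
aif_extrapolated.aif_fit <- function(x, t) t > x$fit_window[2]

#' Evaluate a fitted input function, flagging extrapolated times
#'
#' @param fit An [fit_aif()] object (a [make_aif()] truth also works).
#' @param times Numeric times (min), all `>= 0`.
#' @return Tibble with `time`, `value` and logical `extrapolated`.
#' @export
evaluate_aif <- function(fit, times) {
  tibble::tibble(time = times, value = aif_value(fit, times),
                 extrapolated = aif_extrapolated(fit, times))
}

#' Cumulative integral of an input function
#'
#' \eqn{\int_0^t C_p\,d\tau}: closed form for exponential-family objects,
#' exact trapezoidal integration for polylines and for sampled TACs (with a
#' linear rise from 0 at t = 0 to the first sample midpoint).
#'
#' @param x An AIF object (`pet_aif`, `aif_fit`) or a TAC tibble.
#' @param t Times (min).
#' @return Numeric vector, kBq.min/mL.
#' @export
aif_cumulative_integral <- function(x, t) {
  if (any(t < 0)) stop("times must be >= 0", call. = FALSE)
  if (inherits(x, "pet_aif") || inherits(x, "aif_fit")) {
    return(aif_integral(x, t))
  }
  if (is.data.frame(x) && all(c("frame_start", "frame_end", "value") %in%
                              names(x))) {
    return(piecewise_integral(t, tac_midpoints(x), x$value))
  }
  stop("`x` must be an AIF object or a TAC tibble", call. = FALSE)
}

#' Patlak transform of a tissue TAC
#'
#' Computes the graphical-analysis coordinates at each frame midpoint:
#' \eqn{x = \int_0^t C_p d\tau / C_p(t)} (min, "stretched time") and
#' \eqn{y = C_t(t) / C_p(t)} (unitless). Under irreversible trapping the
#' points approach a line with slope \eqn{K_i} and intercept the apparent
#' distribution volume.
#'
#' @param tissue Tissue TAC tibble.
#' @param aif An AIF object (`aif_fit` or `pet_aif` ground truth); the same
#'   object supplies both the denominator and the cumulative integral.
#' @return Tibble with `t`, `x`, `y` (one row per frame).
#' @export
patlak_points <- function(tissue, aif) {
  t <- tac_midpoints(tissue)
  cp <- aif_value(aif, t)
  bad <- which(cp <= 0)
  if (length(bad)) {
    stop("non-positive blood concentration at frame midpoint(s) ",
         paste(round(t[bad], 2), collapse = ", "), " min", call. = FALSE)
  }
  tibble::tibble(t = t, x = aif_integral(aif, t) / cp, y = tissue$value / cp)
}

#' Fit the Patlak regression
#'
#' Unweighted ordinary least squares of `y` on `x`, optionally restricted to
#' frames whose midpoint time lies in `window`. The slope is reported as
#' \eqn{K_i} in mL/min/100 mL (slope x 100); the intercept is the apparent
#' distribution volume.
#'
#' @param points A [patlak_points()] tibble (needs `x`, `y`; `t` used for
#'   windowing when present).
#' @param window Optional `(t0, t1)` time window (min).
#' @return A `patlak_fit` object; see [tidy.patlak_fit()].
#' @export
fit_patlak <- function(points, window = NULL) {
  pts <- points
  if (!is.null(window)) {
    if (!"t" %in% names(pts)) {
      stop("windowing requires a `t` column in `points`", call. = FALSE)
    }
    pts <- pts[pts$t >= window[1] & pts$t <= window[2], , drop = FALSE]
  }
  if (nrow(pts) < 2) {
    stop("Patlak fit requires at least 2 points in the window",
         call. = FALSE)
  }
  if (is.unsorted(pts$x, strictly = TRUE)) {
    stop("Patlak x values must be strictly increasing", call. = FALSE)
  }
  xc <- pts$x - mean(pts$x)
  yc <- pts$y - mean(pts$y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  intercept <- mean(pts$y) - slope * mean(pts$x)
  sst <- sum(yc^2)
  r2 <- if (sst > 0) 1 - sum((pts$y - intercept - slope * pts$x)^2) / sst
        else NA_real_
  structure(
    list(Ki = 100 * slope, intercept = intercept, r_squared_fit = r2,
         points_used = pts, window = window),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat("<patlak_fit> Ki:", format(x$Ki, digits = 4),
      "mL/min/100 mL  V0:", format(x$intercept, digits = 3),
      " R2:", format(x$r_squared_fit, digits = 3),
      " n:", nrow(x$points_used), "\n")
  invisible(x)
}

#' Tidy methods for Patlak fits
#'
#' @param x A `patlak_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per model term; `glance()`: a one-row model
#'   summary with `ki` (mL/min/100 mL), `intercept`, `r_squared`,
#'   `n_points`.
#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("ki", "intercept"),
                 estimate = c(x$Ki, x$intercept),
                 unit = c("mL/min/100 mL", "unitless"))
}

#' @rdname tidy.patlak_fit
#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(ki = x$Ki, intercept = x$intercept,
                 r_squared = x$r_squared_fit, n_points = nrow(x$points_used))
}

#' Voxelwise Patlak Ki map
#'
#' Applies [patlak_points()] + [fit_patlak()] independently to every voxel
#' of a dynamic image over the frames of one acquisition window. Voxels
#' whose transform is undefined are set to `NA`; their count is attached as
#' attribute `n_failed`.
#'
#' @param image 4D activity [pet_image()] with a `window` column in its
#'   frame times.
#' @param aif An AIF object used for both \eqn{C_p} and its integral.
#' @param window `"early"` or `"late"`.
#' @return 3D [pet_image()] of kind `"ki"` (mL/min/100 mL).
#' @export
voxelwise_ki <- function(image, aif, window) {
  idx <- which(image$frame_times$window == window)
  if (length(idx) < 2) {
    stop("window must contain at least 2 frames", call. = FALSE)
  }
  ft <- image$frame_times[idx, ]
  mids <- (ft$frame_start + ft$frame_end) / 2
  cp <- aif_value(aif, mids)
  if (any(cp <= 0)) {
    stop("non-positive blood concentration on the analysis window",
         call. = FALSE)
  }
  x <- aif_integral(aif, mids) / cp
  d <- dim(image$data)
  mat <- matrix(image$data[, , , idx], ncol = length(idx))
  y <- sweep(mat, 2, cp, "/")
  xc <- x - mean(x)
  slope <- as.numeric(y %*% xc) / sum(xc^2)
  bad <- !is.finite(slope)
  slope[bad] <- NA_real_
  ki <- array(100 * slope, dim = d[1:3])
  out <- structure(
    list(data = ki, voxel_size = image$voxel_size, kind = "ki",
         frame_times = NULL),
    class = "pet_image"
  )
  attr(out, "n_failed") <- sum(bad)
  out
}

#' Hematocrit correction of Ki
#'
#' Intravascular DOTATATE stays in plasma (it does not enter red blood
#' cells), so a Ki measured against whole-blood concentration is corrected
#' to the plasma scale: `Ki / (1 - hematocrit)`. FDG values are returned
#' unchanged.
#'
#' @param ki Numeric Ki value(s).
#' @param hematocrit Fraction in `[0, 1)`.
#' @param tracer `"FDG"` or `"DOTATATE"`.
#' @return Corrected Ki, same shape as `ki`.
#' @examples
#' hematocrit_correct(1.2, 0.40, "DOTATATE") # 2.0
#' @export
hematocrit_correct <- function(ki, hematocrit, tracer) {
  tracer <- match.arg(tracer, c("FDG", "DOTATATE"))
  if (tracer == "FDG") return(ki)
  if (is.na(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("`hematocrit` must be in [0, 1)", call. = FALSE)
  }
  ki / (1 - hematocrit)
}
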