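#' Two-tissue-compartment rate constants
#'
#' The two-tissue compartment (2TC) model exchanges tracer between blood and
#' a free tissue pool (rates `K1`, `k2`) and between the free and a bound
#' pool (rates `k3`, `k4`). With `k4 = 0` the bound pool traps tracer
#' irreversibly (FDG-like behavior, the Patlak model assumption); `k4 > 0`
#' allows late washout from the bound pool (DOTATATE-like partial
#' reversibility). `vb` is the fractional blood volume seen by the voxel.
#'
#' @param K1 Influx rate, mL/min/mL tissue.
#' @param k2,k3,k4 First-order rates, 1/min. All must be `>= 0`.
#' @param vb Fractional blood volume in `[0, 1)`.
#' @return A `kinetic_params` list.
#' @examples
#' kp <- kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.15)
#' ki_true(kp) # K1*k3/(k2+k3) = 0.0333...
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, vb = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic rates must be finite and >= 0", call. = FALSE)
  }
  if (vb < 0 || vb >= 1) stop("`vb` must be in [0, 1)", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb),
            class = "kinetic_params")
}

#' True net influx rate of a 2TC parameter set
#'
#' For irreversible kinetics the Patlak slope converges to
#' \eqn{K_i = K_1 k_3 / (k_2 + k_3)} (units 1/min; multiply by 100 for
#' mL/min/100 mL).
#'
#' @param params A [kinetic_params()] object.
#' @return `Ki` in 1/min (mL/min/mL).
#' @export
ki_true <- function(params) {
  if (params$k2 + params$k3 == 0) return(params$K1 * 0)
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Acquisition schedule with early and late multi-pass windows
#'
#' Each analysis window spans three contiguous 5-min whole-body passes;
#' defaults are 35--50 min (early) and 75--90 min (late) post-injection.
#'
#' @param early_window,late_window Length-2 numeric `(t0, t1)` in minutes.
#' @param n_passes Number of contiguous passes per window.
#' @return Tibble with `frame_start`, `frame_end` (min) and `window`
#'   (`"early"`/`"late"`), class `pet_schedule`.
#' @export
make_schedule <- function(early_window = c(35, 50), late_window = c(75, 90),
                          n_passes = 3) {
  check_window <- function(w, nm) {
    if (length(w) != 2 || w[2] <= w[1] || w[1] < 0) {
      stop("`", nm, "` must be (t0, t1) with t1 > t0 >= 0", call. = FALSE)
    }
  }
  check_window(early_window, "early_window")
  check_window(late_window, "late_window")
  if (late_window[1] < early_window[2]) {
    stop("windows must not overlap and early must precede late", call. = FALSE)
  }
  cuts <- function(w) seq(w[1], w[2], length.out = n_passes + 1)
  ce <- cuts(early_window)
  cl <- cuts(late_window)
  out <- tibble::tibble(
    frame_start = c(utils::head(ce, -1), utils::head(cl, -1)),
    frame_end = c(utils::tail(ce, -1), utils::tail(cl, -1)),
    window = rep(c("early", "late"), each = n_passes)
  )
  class(out) <- c("pet_schedule", class(out))
  out
}

#' Build a time--activity curve tibble
#'
#' A time--activity curve (TAC) is the framed record of activity
#' concentration: one row per frame with `frame_start`, `frame_end` (min)
#' and `value` (kBq/mL, frame average). All simulated concentrations are
#' decay-corrected to injection time.
#'
#' @param frame_start,frame_end Frame boundaries, minutes post-injection.
#' @param value Frame-average activity concentration, kBq/mL.
#' @return A tibble with attribute `decay_corrected = TRUE`.
#' @export
new_tac <- function(frame_start, frame_end, value) {
  if (length(frame_start) != length(frame_end) ||
      length(value) != length(frame_start)) {
    stop("frame vectors must have equal length", call. = FALSE)
  }
  if (any(frame_end <= frame_start)) {
    stop("each frame must have frame_end > frame_start", call. = FALSE)
  }
  mid <- (frame_start + frame_end) / 2
  if (is.unsorted(mid, strictly = TRUE)) {
    stop("frame midpoints must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(value))) stop("TAC values must be finite", call. = FALSE)
  out <- tibble::tibble(frame_start = frame_start, frame_end = frame_end,
                        value = value)
  attr(out, "decay_corrected") <- TRUE
  out
}

tac_midpoints <- function(tac) (tac$frame_start + tac$frame_end) / 2

#' Simulate a framed tissue time--activity curve
#'
#' Solves the 2TC response to an input function and averages it over the
#' acquisition frames. The continuous solution is the sum-of-exponentials
#' convolution
#' \deqn{C_t(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
#'   e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right] \otimes
#'   C_p(t) + v_b C_p(t)}
#' with \eqn{\alpha_{1,2}} the compartment eigenvalues; for `k4 = 0` this
#' reduces to \eqn{K_i \int_0^t C_p + \frac{K_1 k_2}{k_2+k_3}
#' (e^{-(k_2+k_3)t} \otimes C_p) + v_b C_p}. The convolution is computed by
#' an exact exponential-step recursion on a fine grid (`fine_dt` minutes,
#' piecewise-linear input), and frame values are means of the continuous
#' curve sampled at 0.1-min midpoints within each frame.
#'
#' @param params [kinetic_params()].
#' @param aif [make_aif()] input function (or an [fit_aif()] object).
#' @param schedule A [make_schedule()] tibble, or any tibble with
#'   `frame_start`/`frame_end` columns.
#' @param fine_dt Fine-grid step (min) for the continuous solution.
#' @return A [new_tac()] tibble (with the schedule's `window` column kept,
#'   if present).
#' @export
simulate_tissue_tac <- function(params, aif, schedule, fine_dt = 0.01) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!all(c("frame_start", "frame_end") %in% names(schedule))) {
    stop("`schedule` needs frame_start and frame_end columns", call. = FALSE)
  }
  t_end <- max(schedule$frame_end)
  tg <- seq(0, t_end, by = fine_dt)
  ct <- tissue_curve_on_grid(params, aif, tg)
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    mids <- seq(schedule$frame_start[i] + 0.05, schedule$frame_end[i] - 0.05,
                by = 0.1)
    mean(stats::approx(tg, ct, xout = mids)$y)
  }, numeric(1))
  out <- new_tac(schedule$frame_start, schedule$frame_end, vals)
  if ("window" %in% names(schedule)) out$window <- schedule$window
  out
}

# Continuous 2TC solution sampled on a time grid.
tissue_curve_on_grid <- function(params, aif, tg) {
  cp <- aif_value(aif, tg)
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  s <- k2 + k3 + k4
  if (s == 0) {
    return(K1 * aif_integral(aif, tg) + params$vb * cp)
  }
  disc <- s^2 - 4 * k2 * k4
  if (disc < 1e-18) k4 <- k4 * (1 + 1e-9) # split a (measure-zero) double root
  disc <- max((k2 + k3 + k4)^2 - 4 * k2 * k4, 0)
  d <- sqrt(disc)
  a1 <- ((k2 + k3 + k4) - d) / 2
  a2 <- ((k2 + k3 + k4) + d) / 2
  w1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  w2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  w1 * exp_convolve(cp, tg, a1) + w2 * exp_convolve(cp, tg, a2) +
    params$vb * cp
}

# y(t) = int_0^t e^{-a (t-s)} Cp(s) ds for Cp piecewise linear on grid tg.
# Exact per-step update, accumulated with a linear recursive filter.
exp_convolve <- function(cp, tg, a) {
  n <- length(tg)
  if (n < 2) return(numeric(n))
  h <- tg[2] - tg[1]
  c0 <- cp[-n]
  c1 <- (cp[-1] - cp[-n]) / h
  if (a <= 0) {
    inc <- c0 * h + c1 * h^2 / 2
    return(c(0, cumsum(inc)))
  }
  e <- exp(-a * h)
  inc <- c0 * (1 - e) / a + c1 * (h / a - (1 - e) / a^2)
  y <- stats::filter(inc, filter = e, method = "recursive")
  c(0, as.numeric(y))
}

#' Add PET-like measurement noise to a TAC
#'
#' Adds zero-mean Gaussian noise with per-frame standard deviation
#' `noise_scale * sqrt(value / frame_duration)` -- a first-order model of
#' reconstructed-PET count noise (variance proportional to activity, inverse
#' to frame duration). Values are clamped at 0.
#'
#' @param tac A TAC tibble.
#' @param noise_scale Non-negative scale; 0 returns the TAC unchanged.
#' @param seed Integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return A TAC tibble of the same shape.
#' @export
add_tac_noise <- function(tac, noise_scale, seed) {
  if (noise_scale < 0) stop("`noise_scale` must be >= 0", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (noise_scale == 0) return(tac)
  dur <- tac$frame_end - tac$frame_start
  sd <- noise_scale * sqrt(pmax(tac$value, 0) / dur)
  eps <- with_preserved_seed(seed, stats::rnorm(nrow(tac), sd = sd))
  out <- tac
  out$value <- pmax(tac$value + eps, 0)
  out
}

# Run code under a fixed seed, restoring the global RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Read / write time--activity curves as CSV
#'
#' The CSV dialect has columns `frame_start_min`, `frame_end_min`,
#' `value_kBq_per_mL` (plus any extra columns, preserved).
#'
#' @param tac A TAC tibble.
#' @param path File path.
#' @return `write_tac()` returns `path` invisibly; `read_tac()` a TAC tibble.
#' @export
write_tac <- function(tac, path) {
  out <- tac
  names(out)[match(c("frame_start", "frame_end", "value"), names(out))] <-
    c("frame_start_min", "frame_end_min", "value_kBq_per_mL")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame_start_min", "frame_end_min", "value_kBq_per_mL")
  if (!all(needed %in% names(raw))) {
    stop("TAC CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tac <- new_tac(raw$frame_start_min, raw$frame_end_min, raw$value_kBq_per_mL)
  extra <- setdiff(names(raw), needed)
  for (nm in extra) tac[[nm]] <- raw[[nm]]
  tac
}
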