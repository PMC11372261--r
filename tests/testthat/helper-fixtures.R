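# Shared fixtures: a population-scale input function, the standard two-window
# schedule, and a small phantom grid that keeps voxel tests fast.

fix_aif <- function(scale = 0.5) {
  make_aif("feng_exponential_sum", scale = scale)
}

fix_schedule <- function() make_schedule()

fix_grid <- function() grid_spec(shape = c(32, 32, 32), voxel_size = 4)

# constant input function as a degenerate polyline (exactly representable)
fix_constant_aif <- function(value, t_end = 1000) {
  make_aif("linear_piecewise", list(t = c(1e-9, t_end), value = c(value, value)),
           t_measured_end = t_end)
}

fix_small_config <- function(n_subjects = 2, max_lesions = 2, ...) {
  cohort_config(n_subjects = n_subjects, max_lesions = max_lesions, ...)
}

# fine-grid trapezoid, the numerical integration oracle
trapz_oracle <- function(f, t_max, dt = 0.001) {
  tg <- seq(0, t_max, by = dt)
  v <- f(tg)
  sum(diff(tg) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}
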