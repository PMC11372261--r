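test_that("bi-exponential AIF parameters are recovered from exact samples", {
  a <- make_aif("exponential_tail", list(A = c(50, 20),
                                         lambda = c(0.1, 0.01)))
  starts <- seq(0, 46, 2)
  ends <- seq(2, 48, 2)
  vals <- (aif_integral(a, ends) - aif_integral(a, starts)) / 2
  fit <- fit_aif(new_tac(starts, ends, vals), "exponential_tail")
  expect_equal(sort(fit$params$A), c(20, 50), tolerance = 0.01)
  expect_equal(sort(fit$params$lambda), c(0.01, 0.1), tolerance = 0.01)
  expect_lt(fit$residual_rms, 0.05)
})

test_that("underdetermined exponential fits are rejected", {
  tac <- new_tac(c(0, 5), c(5, 10), c(10, 8))
  expect_error(fit_aif(tac, "exponential_tail"), ">= 4")
  expect_error(fit_aif(tac[1, ], "linear_piecewise"), "at least 2")
})

test_that("piecewise fit reproduces collinear samples exactly", {
  starts <- seq(0, 40, 5)
  vals <- 100 - 1.5 * (starts + 2.5)
  fit <- fit_aif(new_tac(starts, starts + 5, vals), "linear_piecewise")
  expect_equal(aif_value(fit, 17.3), 100 - 1.5 * 17.3)
  expect_equal(fit$residual_rms, 0)
})

test_that("evaluation inside the window matches the closed form; beyond is flagged", {
  a <- make_aif("exponential_tail", list(A = c(50, 20),
                                         lambda = c(0.1, 0.01)))
  starts <- seq(0, 46, 2)
  vals <- (aif_integral(a, starts + 2) - aif_integral(a, starts)) / 2
  fit <- fit_aif(new_tac(starts, starts + 2, vals), "exponential_tail")
  ev <- evaluate_aif(fit, c(10, 30, 60, 90))
  expect_equal(ev$extrapolated, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ev$value,
               fit$params$A[1] * exp(-fit$params$lambda[1] * ev$time) +
                 fit$params$A[2] * exp(-fit$params$lambda[2] * ev$time),
               tolerance = 1e-12)
  # extrapolation of decaying exponentials is strictly decreasing
  late <- evaluate_aif(fit, seq(50, 120, 5))$value
  expect_true(all(diff(late) < 0))
  expect_error(evaluate_aif(fit, -1), ">= 0")
})

test_that("cumulative integrals are exact for constants and lines", {
  const <- new_tac(seq(0, 45, 5), seq(5, 50, 5), rep(7, 10))
  # linear rise from 0 to the first midpoint, constant thereafter
  expect_equal(aif_cumulative_integral(const, 40), 7 * 2.5 / 2 + 7 * 37.5)
  lin <- new_tac(seq(0, 45, 5), seq(5, 50, 5), 2 * (seq(0, 45, 5) + 2.5))
  mids <- seq(2.5, 47.5, 5)
  expect_equal(aif_cumulative_integral(lin, 47.5),
               5 / 2 * 5 / 2 + (2 * 2.5 + 2 * 47.5) / 2 * 45)
})

test_that("closed-form exponential integral agrees with a fine trapezoid", {
  a <- make_aif("exponential_tail", list(A = c(30, 10),
                                         lambda = c(0.2, 0.008)))
  starts <- seq(0, 46, 2)
  vals <- (aif_integral(a, starts + 2) - aif_integral(a, starts)) / 2
  fit <- fit_aif(new_tac(starts, starts + 2, vals), "exponential_tail")
  ref <- trapz_oracle(function(t) aif_value(fit, t), 90, dt = 0.001)
  expect_lt(abs(aif_cumulative_integral(fit, 90) - ref) / ref, 1e-4)
})

test_that("Patlak points behave for constant and pure-trapping cases", {
  cp0 <- 8
  aif <- fix_constant_aif(cp0)
  sched <- fix_schedule()
  const_tissue <- new_tac(sched$frame_start, sched$frame_end, rep(4, 6))
  pts <- patlak_points(const_tissue, aif)
  expect_equal(pts$y, rep(0.5, 6))
  expect_equal(pts$x, tac_mid <- (sched$frame_start + sched$frame_end) / 2,
               tolerance = 1e-9)

  # pure trapping: Ct = alpha * int Cp  =>  y = alpha * x exactly
  alpha <- 0.03
  feng <- fix_aif()
  mids <- (sched$frame_start + sched$frame_end) / 2
  trap_tissue <- new_tac(sched$frame_start, sched$frame_end,
                         alpha * aif_integral(feng, mids))
  pts2 <- patlak_points(trap_tissue, feng)
  expect_equal(pts2$y, alpha * pts2$x, tolerance = 1e-12)

  zero_cp <- make_aif("linear_piecewise",
                      list(t = c(1, 30), value = c(5, 0)))
  expect_error(patlak_points(const_tissue, zero_cp), "non-positive")
})

test_that("late-window Patlak slope recovers the true net influx rate", {
  kp <- kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.15, vb = 0.04)
  aif <- fix_aif()
  tac <- simulate_tissue_tac(kp, aif, fix_schedule())
  pts <- patlak_points(tac, aif)
  fit <- fit_patlak(pts, window = c(75, 90))
  expect_equal(fit$Ki, 100 * ki_true(kp), tolerance = 0.01)
})

test_that("the Patlak regression is exact on lines and matches an OLS oracle", {
  x <- c(10, 20, 30, 40)
  pts <- tibble::tibble(t = x, x = x, y = 0.02 * x + 0.5)
  fit <- fit_patlak(pts)
  expect_equal(fit$Ki, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)

  flat <- tibble::tibble(t = x, x = x, y = rep(1.3, 4))
  expect_equal(fit_patlak(flat)$Ki, 0)

  set.seed(12)
  xr <- sort(stats::runif(8, 1, 60))
  yr <- stats::rnorm(8)
  fr <- fit_patlak(tibble::tibble(t = xr, x = xr, y = yr))
  X <- cbind(1, xr)
  beta <- solve(t(X) %*% X, t(X) %*% yr) # normal-equations oracle
  expect_equal(fr$Ki, 100 * beta[2], tolerance = 1e-10)
  expect_equal(fr$intercept, beta[1], tolerance = 1e-10)

  expect_error(fit_patlak(pts[1, ]), "at least 2")
})

test_that("Patlak quantities are invariant to joint input/tissue scaling", {
  kp <- kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.15, vb = 0.04)
  sched <- fix_schedule()
  a1 <- fix_aif(scale = 0.5)
  a2 <- fix_aif(scale = 2.0)
  t1 <- simulate_tissue_tac(kp, a1, sched)
  t2 <- simulate_tissue_tac(kp, a2, sched)
  p1 <- patlak_points(t1, a1)
  p2 <- patlak_points(t2, a2)
  expect_equal(p1$x, p2$x, tolerance = 1e-9)
  expect_equal(p1$y, p2$y, tolerance = 1e-9)
})

test_that("voxelwise Ki equals the lesion-level fit on a uniform field", {
  kp <- kinetic_params(K1 = 0.08, k2 = 0.25, k3 = 0.12, vb = 0.03)
  aif <- fix_aif()
  sched <- fix_schedule()
  tac <- simulate_tissue_tac(kp, aif, sched)
  dat <- array(rep(tac$value, each = 6^3), dim = c(6, 6, 6, 6))
  img <- pet_image(dat, 4, "activity", frame_times = sched)
  ki_map <- voxelwise_ki(img, aif, "late")
  ref <- fit_patlak(patlak_points(tac, aif), c(75, 90))$Ki
  expect_equal(unique(round(as.numeric(ki_map$data), 10)), round(ref, 10))
  expect_equal(attr(ki_map, "n_failed"), 0)
})

test_that("a non-trapping background yields a near-zero Ki map", {
  kp <- kinetic_params(K1 = 0.05, k2 = 0.4, k3 = 0, vb = 0)
  aif <- fix_aif()
  sched <- fix_schedule()
  tac <- simulate_tissue_tac(kp, aif, sched)
  dat <- array(rep(tac$value, each = 4^3), dim = c(4, 4, 4, 6))
  img <- pet_image(dat, 4, "activity", frame_times = sched)
  ki_map <- voxelwise_ki(img, aif, "late")
  expect_lt(max(abs(ki_map$data)), 1e-2)
})

test_that("noiseless phantom Ki_max lands within 2% of truth", {
  co <- generate_cohort(fix_small_config(n_subjects = 1, noise_scale = 0,
                                         max_lesions = 1), 41)
  subj <- co[1, ]
  ph <- render_dynamic_phantom(subj, fix_grid(), seed = 2)
  ki_map <- voxelwise_ki(ph$image, subj$aif[[1]], "late")
  m <- lesion_mask(ph, ph$lesions$lesion_id[1], dilate = 1)
  truth <- 100 * ki_true(ph$lesions$params[[1]])
  expect_equal(extract_max(ki_map, m), truth, tolerance = 0.02)
})

test_that("hematocrit correction applies to DOTATATE only", {
  expect_equal(hematocrit_correct(1.2, 0.40, "DOTATATE"), 2.0)
  expect_equal(hematocrit_correct(1.2, 0.40, "FDG"), 1.2)
  expect_equal(hematocrit_correct(1.2, 0, "DOTATATE"), 1.2)
  expect_error(hematocrit_correct(1.2, 1, "DOTATATE"), "hematocrit")
})

test_that("an AIF extrapolated below truth inflates the late Ki", {
  aif <- fix_aif()
  sched <- fix_schedule()
  kp <- kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.15, vb = 0.04)
  tac <- simulate_tissue_tac(kp, aif, sched)
  # linear continuation of a convex decaying tail lies below the true curve
  low_fit <- fit_aif(simulate_blood_samples(aif), "linear_piecewise")
  late_mids <- c(77.5, 82.5, 87.5)
  expect_true(all(aif_value(low_fit, late_mids) < aif_value(aif, late_mids)))
  ki_early_true <- fit_patlak(patlak_points(tac, aif), c(35, 50))$Ki
  ki_late_low <- fit_patlak(patlak_points(tac, low_fit), c(75, 90))$Ki
  expect_gt(ki_late_low, ki_early_true)
})

test_that("reversible binding lowers the late-window slope", {
  aif <- fix_aif()
  kp <- kinetic_params(K1 = 0.15, k2 = 0.3, k3 = 0.1, k4 = 0.015,
                       vb = 0.04)
  pts <- patlak_points(simulate_tissue_tac(kp, aif, fix_schedule()), aif)
  expect_lt(fit_patlak(pts, c(75, 90))$Ki, fit_patlak(pts, c(35, 50))$Ki)
})

test_that("tidy and glance summarize a Patlak fit", {
  x <- c(10, 20, 30)
  fit <- fit_patlak(tibble::tibble(t = x, x = x, y = 0.01 * x + 0.2))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "ki"], 1.0, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$n_points, 3)
  expect_equal(gl$r_squared, 1, tolerance = 1e-12)
})
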