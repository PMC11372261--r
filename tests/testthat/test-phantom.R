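make_uniform_image <- function(value = 1, shape = c(20, 20, 20),
                               voxel_size = 2) {
  pet_image(array(value, dim = shape), voxel_size, "suv")
}

test_that("digitized sphere and cylinder volumes match their geometry", {
  img <- make_uniform_image(shape = c(24, 24, 24), voxel_size = 2)
  m <- voi_mask(voi_sphere(c(23, 23, 23), 20), img) # on a voxel center
  vol <- sum(m) * 2^3
  expect_lt(abs(vol - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)

  img2 <- pet_image(array(1, dim = c(24, 24, 36)), 2, "suv")
  m2 <- voi_mask(voi_cylinder(c(23, 23, 34), 10, 60), img2)
  vol2 <- sum(m2) * 2^3
  expect_lt(abs(vol2 - pi * 25 * 60) / (pi * 25 * 60), 0.10)
})

test_that("a sphere smaller than a voxel selects exactly its voxel", {
  img <- make_uniform_image()
  center <- c(9.5 * 2, 9.5 * 2, 9.5 * 2) # center of voxel (10,10,10)
  m <- voi_mask(voi_sphere(center, 1.5), img)
  expect_equal(sum(m), 1)
  expect_true(m[10, 10, 10])
})

test_that("VOIs outside the image are rejected", {
  img <- make_uniform_image()
  expect_error(voi_mask(voi_sphere(c(500, 500, 500), 10), img),
               "does not intersect")
})

test_that("extract_max equals an exhaustive scan on a random field", {
  set.seed(7)
  a <- array(stats::rnorm(20^3), dim = c(20, 20, 20))
  img <- pet_image(a, 2, "suv")
  mask <- voi_mask(voi_sphere(c(20, 20, 20), 24), img)
  brute <- -Inf
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (mask[i, j, k]) brute <- max(brute, a[i, j, k])
  }
  expect_equal(extract_max(img, mask), brute)
})

test_that("extract_peak matches a brute-force sphere-placement search", {
  set.seed(8)
  vs <- 4
  a <- array(stats::rexp(12^3), dim = c(12, 12, 12))
  img <- pet_image(a, vs, "suv")
  mask <- voi_mask(voi_sphere(c(24, 24, 24), 30), img)
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  centers <- which(mask, arr.ind = TRUE)
  brute <- -Inf
  for (row in seq_len(nrow(centers))) {
    c0 <- centers[row, ]
    vals <- c()
    for (i in 1:12) for (j in 1:12) for (k in 1:12) {
      if (sum(((c(i, j, k) - c0) * vs)^2) <= r^2) vals <- c(vals, a[i, j, k])
    }
    brute <- max(brute, mean(vals))
  }
  expect_equal(extract_peak(img, mask), brute)
})

test_that("peak respects its averaging bound and uniform-field identity", {
  img <- make_uniform_image(value = 3.7)
  mask <- voi_mask(voi_sphere(c(20, 20, 20), 16), img)
  expect_equal(extract_peak(img, mask), 3.7)
  expect_equal(extract_max(img, mask), 3.7)
  set.seed(9)
  noisy <- pet_image(array(stats::rexp(20^3), dim = c(20, 20, 20)), 2, "suv")
  expect_lte(extract_peak(noisy, mask), extract_max(noisy, mask))
})

test_that("peak is invariant to whole-voxel translation", {
  set.seed(10)
  a <- array(0, dim = c(16, 16, 16))
  a[4:8, 4:8, 4:8] <- stats::rexp(125)
  img1 <- pet_image(a, 4, "suv")
  img2 <- pet_image(patlakr:::shift_array(a, c(3, 2, 1)), 4, "suv")
  m1 <- array(FALSE, dim = dim(a)); m1[4:8, 4:8, 4:8] <- TRUE
  m2 <- patlakr:::shift_array(m1, c(3, 2, 1), fill = FALSE)
  expect_equal(extract_peak(img1, m1), extract_peak(img2, m2))
})

test_that("blood_pool_mean equals the mask-sum oracle", {
  set.seed(11)
  a <- array(stats::runif(20^3, 1, 3), dim = c(20, 20, 20))
  img <- pet_image(a, 2, "suv")
  spec <- voi_cylinder(c(20, 20, 20), 10, 30)
  m <- voi_mask(spec, img)
  expect_equal(blood_pool_mean(img, spec), sum(a[m]) / sum(m),
               tolerance = 1e-12)
})

test_that("SUV conversion follows its definitional unit case and scaling", {
  expect_equal(activity_to_suv(5, 370, 74), 1)
  expect_equal(activity_to_suv(0, 370, 74), 0)
  expect_equal(activity_to_suv(5, 740, 74), 0.5)
  expect_error(activity_to_suv(5, 0, 74), "positive")
})

test_that("phantom renders background, aorta tube, and lesions", {
  co <- generate_cohort(fix_small_config(n_subjects = 1), 31)
  subj <- co[1, ]
  ph <- render_dynamic_phantom(subj, fix_grid(), seed = 3)
  img <- ph$image
  expect_equal(dim(img$data)[4], 6)
  # aorta tube voxels carry the frame-averaged blood value
  tube <- voi_mask(ph$aorta_tube, pet_image(img$data[, , , 1],
                                            img$voxel_size, "activity"))
  sched <- img$frame_times
  blood1 <- (aif_integral(subj$aif[[1]], sched$frame_end[1]) -
               aif_integral(subj$aif[[1]], sched$frame_start[1])) /
    (sched$frame_end[1] - sched$frame_start[1])
  expect_equal(unique(img$data[, , , 1][tube]), blood1, tolerance = 1e-10)
  # lesion core voxels carry the lesion TAC value
  lm <- lesion_mask(ph, ph$lesions$lesion_id[1], dilate = 0)
  les_tac <- simulate_tissue_tac(ph$lesions$params[[1]], subj$aif[[1]],
                                 sched)
  core <- max(img$data[, , , 6][lm])
  expect_equal(core, les_tac$value[6], tolerance = 1e-6)
})

test_that("a zero-lesion phantom is background outside the aorta", {
  co <- generate_cohort(fix_small_config(n_subjects = 1), 32)
  subj <- co[1, ]
  subj$lesions[[1]] <- subj$lesions[[1]][0, ]
  ph <- render_dynamic_phantom(subj, fix_grid(), seed = 4)
  vol <- ph$image$data[, , , 2]
  tube <- voi_mask(ph$aorta_tube, pet_image(vol, 4, "activity"))
  expect_equal(length(unique(vol[!tube])), 1)
})

test_that("without motion the lesion mask is identical in all frames", {
  co <- generate_cohort(fix_small_config(n_subjects = 1,
                                         motion_amplitude_mm = c(0, 0)), 33)
  ph <- render_dynamic_phantom(co[1, ], fix_grid(), seed = 5)
  fc <- ph$lesions$frame_centers[[1]]
  expect_true(all(apply(fc, 2, function(col) length(unique(col)) == 1)))
})

test_that("volume-fraction rendering conserves sphere volume", {
  frac <- patlakr:::sphere_fraction(c(24, 24, 24), 2, c(24, 24, 24), 20)
  vol <- sum(frac) * 8
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("NIfTI images round-trip with their sidecar metadata", {
  co <- generate_cohort(fix_small_config(n_subjects = 1), 34)
  ph <- render_dynamic_phantom(co[1, ], fix_grid(), seed = 6)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_pet_image(ph$image, p)
  img2 <- read_pet_image(p)
  expect_equal(img2$voxel_size, 4)
  expect_equal(img2$kind, "activity")
  expect_equal(img2$frame_times$frame_start, ph$image$frame_times$frame_start)
  expect_equal(as.numeric(img2$data), as.numeric(ph$image$data),
               tolerance = 1e-6)
})
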