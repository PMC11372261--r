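#' PET image containers and voxel geometry
#'
#' A `pet_image` wraps a 3D (parametric) or 4D (dynamic) array on an
#' isotropic voxel grid. Coordinates are image-space millimeters with the
#' origin at the corner of voxel `(1,1,1)`; the center of voxel `(i,j,k)`
#' is at `(i-0.5, j-0.5, k-0.5) * voxel_size`.
#'
#' @param data 3D or 4D numeric array. For dynamic images the 4th dimension
#'   indexes frames.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param kind `"activity"` (kBq/mL), `"suv"` (g/mL) or `"ki"`
#'   (mL/min/100 mL).
#' @param frame_times Tibble with `frame_start`, `frame_end` (min) for
#'   dynamic images (and optionally `window`).
#' @return A `pet_image` object.
#' @export
pet_image <- function(data, voxel_size, kind = c("activity", "suv", "ki"),
                      frame_times = NULL) {
  kind <- match.arg(kind)
  nd <- length(dim(data))
  if (!nd %in% c(3, 4)) stop("`data` must be a 3D or 4D array", call. = FALSE)
  if (any(!is.finite(data))) stop("image values must be finite", call. = FALSE)
  if (nd == 4) {
    if (is.null(frame_times) || nrow(frame_times) != dim(data)[4]) {
      stop("dynamic images need one frame_times row per frame", call. = FALSE)
    }
  }
  structure(list(data = data, voxel_size = voxel_size, kind = kind,
                 frame_times = frame_times),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<pet_image>", x$kind, paste(d, collapse = "x"),
      "@", x$voxel_size, "mm\n")
  invisible(x)
}

#' @describeIn pet_image Phantom grid specification (spatial shape and
#'   voxel size).
#' @param shape Integer length-3 vector of voxel counts.
#' @export
grid_spec <- function(shape = c(32, 32, 32), voxel_size = 4) {
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_size > 0)
  list(shape = as.integer(shape), voxel_size = voxel_size)
}

# n x 3 matrix of voxel-center coordinates (mm)
voxel_centers <- function(shape, voxel_size) {
  cx <- (seq_len(shape[1]) - 0.5) * voxel_size
  cy <- (seq_len(shape[2]) - 0.5) * voxel_size
  cz <- (seq_len(shape[3]) - 0.5) * voxel_size
  cbind(rep(cx, times = shape[2] * shape[3]),
        rep(rep(cy, each = shape[1]), times = shape[3]),
        rep(cz, each = shape[1] * shape[2]))
}

#' Volume-of-interest specifications
#'
#' VOIs select voxels whose centers fall inside a geometric shape.
#'
#' @param center Length-3 center, mm.
#' @param diameter Sphere/cylinder diameter, mm (> 0).
#' @param length Cylinder length, mm (> 0).
#' @param axis Cylinder axis (unit-normalized internally).
#' @param mask Logical 3D array for an explicit-mask VOI.
#' @return A `voi_spec` object.
#' @export
voi_sphere <- function(center, diameter) {
  stopifnot(length(center) == 3, diameter > 0)
  structure(list(shape = "sphere", center = center, diameter = diameter),
            class = "voi_spec")
}

#' @rdname voi_sphere
#' @export
voi_cylinder <- function(center, diameter, length, axis = c(0, 0, 1)) {
  stopifnot(length(center) == 3, diameter > 0, length > 0)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(shape = "cylinder", center = center, diameter = diameter,
                 length = length, axis = axis),
            class = "voi_spec")
}

#' @rdname voi_sphere
#' @export
voi_explicit <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3 || !any(mask)) {
    stop("explicit mask must be a non-empty logical 3D array", call. = FALSE)
  }
  structure(list(shape = "explicit_mask", mask = mask), class = "voi_spec")
}

#' Rasterize a VOI on an image grid
#'
#' @param spec A [voi_sphere()], [voi_cylinder()] or [voi_explicit()] spec.
#' @param image A [pet_image()] (only its grid is used).
#' @return Logical 3D array; errors if the VOI selects no voxel.
#' @export
voi_mask <- function(spec, image) {
  stopifnot(inherits(spec, "voi_spec"), inherits(image, "pet_image"))
  shape <- dim(image$data)[1:3]
  if (spec$shape == "explicit_mask") {
    if (!all(dim(spec$mask) == shape)) {
      stop("explicit mask shape does not match image", call. = FALSE)
    }
    return(spec$mask)
  }
  ctr <- voxel_centers(shape, image$voxel_size)
  d <- sweep(ctr, 2, spec$center)
  inside <- if (spec$shape == "sphere") {
    rowSums(d^2) <= (spec$diameter / 2)^2
  } else {
    along <- d %*% spec$axis
    rad2 <- rowSums(d^2) - along^2
    abs(along) <= spec$length / 2 & rad2 <= (spec$diameter / 2)^2
  }
  if (!any(inside)) {
    stop("VOI does not intersect the image grid", call. = FALSE)
  }
  array(inside, dim = shape)
}

#' Dilate a voxel mask
#'
#' Morphological dilation with a 26-connected (box) structuring element,
#' applied `voxels` times. Used to pad ground-truth lesion masks, standing
#' in for manual segmentation margins.
#'
#' @param mask Logical 3D array.
#' @param voxels Number of dilation passes.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, voxels = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  for (rep in seq_len(voxels)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      out <- out | shift_array(mask, c(dx, dy, dz), fill = FALSE)
    }
    mask <- out
  }
  mask
}

# Shift a 3D array by integer voxel offsets, filling exposed borders.
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (off[k] >= 0) {
      src[[k]] <- seq_len(d[k] - off[k])
      dst[[k]] <- src[[k]] + off[k]
    } else {
      src[[k]] <- seq(1 - off[k], d[k])
      dst[[k]] <- src[[k]] + off[k]
    }
    if (length(src[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Render a 4D dynamic voxel phantom for one subject
#'
#' Background voxels carry the background-tissue TAC, each lesion is a
#' sphere carrying its lesion TAC (optionally shifted between frames by its
#' motion amplitude), and an aorta tube running along z carries the
#' frame-averaged blood input function. Optional voxel-level Gaussian noise
#' follows the [add_tac_noise()] model.
#'
#' @param subject One row of a [generate_cohort()] tibble.
#' @param grid A [grid_spec()].
#' @param seed Integer seed (placement, motion, noise).
#' @param noise_scale Voxel noise scale; 0 for noiseless.
#' @return A `pet_phantom` list: `image` (4D activity [pet_image()]),
#'   `lesions` (placement tibble with per-frame centers), `aorta_tube` and
#'   `aorta_voi` ([voi_cylinder()] specs), and the subject row.
#' @export
render_dynamic_phantom <- function(subject, grid = grid_spec(), seed = 1L,
                                   noise_scale = 0) {
  stopifnot(nrow(subject) == 1)
  vs <- grid$voxel_size
  ext <- grid$shape * vs
  sched <- subject$schedule[[1]]
  aif <- subject$aif[[1]]
  les <- subject$lesions[[1]]
  n_frames <- nrow(sched)

  tube_diam <- 20
  tube_center <- c(0.25 * ext[1], 0.5 * ext[2], 0.5 * ext[3])
  aorta_tube <- voi_cylinder(tube_center, tube_diam, ext[3])
  aorta_voi <- voi_cylinder(tube_center, 10, 60)
  if (ext[3] < 60) {
    stop("grid too small to hold the 6-cm aorta measurement cylinder",
         call. = FALSE)
  }

  with_preserved_seed(seed, {
    centers <- place_lesions(les$diameter_mm, ext, tube_center,
                             tube_diam / 2)
    # per-frame lesion centers: random sub-amplitude shift per frame
    frame_centers <- purrr::map(seq_len(nrow(les)), function(j) {
      amp <- les$motion_amplitude_mm[j]
      t(vapply(seq_len(n_frames), function(f) {
        if (amp <= 0) return(centers[j, ])
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        centers[j, ] + dir * stats::runif(1, 0, amp)
      }, numeric(3)))
    })

    bg_tac <- simulate_tissue_tac(subject$background[[1]], aif, sched)
    les_tacs <- purrr::map(les$params, simulate_tissue_tac, aif = aif,
                           schedule = sched)
    blood <- (aif_integral(aif, sched$frame_end) -
                aif_integral(aif, sched$frame_start)) /
      (sched$frame_end - sched$frame_start)

    dat <- array(0, dim = c(grid$shape, n_frames))
    proto <- pet_image(array(0, dim = grid$shape), vs, "activity")
    tube_mask <- voi_mask(aorta_tube, proto)
    for (f in seq_len(n_frames)) {
      vol <- array(bg_tac$value[f], dim = grid$shape)
      vol[tube_mask] <- blood[f]
      for (j in seq_len(nrow(les))) {
        # a PET voxel reports the volume average of the activity inside it:
        # blend lesion and background by the voxel's inside-sphere fraction
        frac <- sphere_fraction(grid$shape, vs, frame_centers[[j]][f, ],
                                les$diameter_mm[j])
        vol <- vol * (1 - frac) + frac * les_tacs[[j]]$value[f]
      }
      if (noise_scale > 0) {
        dur <- sched$frame_end[f] - sched$frame_start[f]
        sd <- noise_scale * sqrt(pmax(vol, 0) / dur)
        vol <- pmax(vol + array(stats::rnorm(length(vol), sd = sd),
                                dim = dim(vol)), 0)
      }
      dat[, , , f] <- vol
    }

    lesions <- les
    lesions$center_x <- centers[, 1]
    lesions$center_y <- centers[, 2]
    lesions$center_z <- centers[, 3]
    lesions$frame_centers <- frame_centers
    structure(
      list(image = pet_image(dat, vs, "activity", frame_times = sched),
           lesions = lesions, aorta_tube = aorta_tube,
           aorta_voi = aorta_voi, subject = subject),
      class = "pet_phantom"
    )
  })
}

# Per-voxel inside-sphere volume fraction (slab approximation: linear ramp
# across one voxel width around the surface; exact 0/1 away from it).
sphere_fraction <- function(shape, voxel_size, center, diameter) {
  ctr <- voxel_centers(shape, voxel_size)
  d <- sqrt(rowSums(sweep(ctr, 2, center)^2))
  frac <- pmin(pmax((diameter / 2 - d) / voxel_size + 0.5, 0), 1)
  array(frac, dim = shape)
}

# Rejection-sample non-overlapping lesion centers away from the aorta tube.
place_lesions <- function(diameters, ext, tube_center, tube_radius,
                          clearance = 4, max_tries = 500) {
  n <- length(diameters)
  centers <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    r <- diameters[j] / 2
    lo <- rep(r + clearance, 3)
    hi <- ext - r - clearance
    if (any(hi <= lo)) {
      stop("grid too small for lesion of diameter ", diameters[j],
           call. = FALSE)
    }
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]),
                stats::runif(1, lo[3], hi[3]))
      d_tube <- sqrt(sum((cand[1:2] - tube_center[1:2])^2))
      if (d_tube < tube_radius + r + clearance) next
      clash <- FALSE
      if (j > 1) {
        for (i in seq_len(j - 1)) {
          if (sqrt(sum((cand - centers[i, ])^2)) <
              r + diameters[i] / 2 + clearance) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash) {
        centers[j, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place lesions without overlap; enlarge the grid",
           call. = FALSE)
    }
  }
  centers
}

#' Ground-truth lesion mask from a phantom
#'
#' Union of the lesion sphere over all frames (capturing motion), optionally
#' dilated; the stand-in for manual segmentation.
#'
#' @param phantom A [render_dynamic_phantom()] result.
#' @param lesion_id Lesion identifier.
#' @param dilate Dilation passes (voxels).
#' @return Logical 3D array.
#' @export
lesion_mask <- function(phantom, lesion_id, dilate = 1) {
  j <- match(lesion_id, phantom$lesions$lesion_id)
  if (is.na(j)) stop("unknown lesion_id", call. = FALSE)
  proto <- pet_image(array(0, dim = dim(phantom$image$data)[1:3]),
                     phantom$image$voxel_size, "activity")
  fc <- phantom$lesions$frame_centers[[j]]
  m <- array(FALSE, dim = dim(proto$data))
  for (f in seq_len(nrow(fc))) {
    m <- m | voi_mask(voi_sphere(fc[f, ], phantom$lesions$diameter_mm[j]),
                      proto)
  }
  if (dilate > 0) m <- dilate_mask(m, dilate)
  m
}

#' Convert activity concentration to SUV
#'
#' SUV = concentration (kBq/mL) / (injected dose (kBq) / body weight (g)),
#' i.e. SUV 1 when the tracer is uniformly distributed over body mass at
#' 1 g/mL density. Input must be decay-corrected to injection time.
#'
#' @param x Numeric vector/array or an activity [pet_image()].
#' @param injected_dose_MBq Injected dose, MBq (> 0).
#' @param body_weight_kg Body weight, kg (> 0).
#' @return Same shape as `x`, in SUV units (g/mL).
#' @examples
#' activity_to_suv(5, 370, 74) # 1.0
#' @export
activity_to_suv <- function(x, injected_dose_MBq, body_weight_kg) {
  if (injected_dose_MBq <= 0 || body_weight_kg <= 0) {
    stop("dose and weight must be positive", call. = FALSE)
  }
  f <- body_weight_kg / injected_dose_MBq # (kBq/mL) -> SUV
  if (inherits(x, "pet_image")) {
    if (x$kind != "activity") stop("image is not an activity image",
                                   call. = FALSE)
    return(pet_image(x$data * f, x$voxel_size, "suv",
                     frame_times = x$frame_times))
  }
  x * f
}

#' Static SUV image for an acquisition window
#'
#' The per-timepoint SUV map is the voxelwise mean of the three frame SUV
#' images inside the window, mirroring a multi-pass static reconstruction.
#'
#' @param image 4D activity [pet_image()] with a `window` column in its
#'   frame times.
#' @param window `"early"` or `"late"`.
#' @param injected_dose_MBq,body_weight_kg Subject dose and weight.
#' @return A 3D `pet_image` of kind `"suv"`.
#' @export
window_suv_image <- function(image, window, injected_dose_MBq,
                             body_weight_kg) {
  idx <- which(image$frame_times$window == window)
  if (length(idx) == 0) stop("window not present in image", call. = FALSE)
  m <- apply(image$data[, , , idx, drop = FALSE], 1:3, mean)
  activity_to_suv(pet_image(m, image$voxel_size, "activity"),
                  injected_dose_MBq, body_weight_kg)
}

#' Maximum, peak, and blood-pool statistics
#'
#' `extract_max()` is the maximum voxel value within a mask. `extract_peak()`
#' is the highest mean over a 1-mL sphere whose center voxel lies within the
#' mask (the PERCIST-style peak); the sphere may extend beyond the mask and
#' is clipped at image borders. `blood_pool_mean()` averages a (typically
#' aortic cylinder) VOI.
#'
#' @param image A 3D parametric [pet_image()].
#' @param mask Logical 3D array (non-empty).
#' @param sphere_volume_mL Peak sphere volume (default 1 mL, diameter
#'   about 12.4 mm).
#' @return A single numeric value.
#' @export
extract_max <- function(image, mask) {
  check_mask(image, mask)
  max(image$data[mask], na.rm = TRUE)
}

#' @rdname extract_max
#' @export
extract_peak <- function(image, mask, sphere_volume_mL = 1) {
  check_mask(image, mask)
  mean_map <- sphere_mean_map(image$data, image$voxel_size, sphere_volume_mL)
  max(mean_map[mask])
}

#' @rdname extract_max
#' @param spec A [voi_cylinder()] (or other VOI) spec for the blood pool.
#' @export
blood_pool_mean <- function(image, spec) {
  m <- voi_mask(spec, image)
  mean(image$data[m])
}

check_mask <- function(image, mask) {
  if (!is.logical(mask) || !all(dim(mask) == dim(image$data)[1:3])) {
    stop("mask must be a logical array matching the image grid",
         call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

# Voxelwise mean over a sphere of given volume, border-clipped.
sphere_mean_map <- function(a, voxel_size, volume_mL = 1) {
  r <- (3 * volume_mL * 1000 / (4 * pi))^(1 / 3) # mm
  k <- floor(r / voxel_size)
  acc <- array(0, dim = dim(a))
  cnt <- array(0, dim = dim(a))
  ones <- array(1, dim = dim(a))
  for (dx in -k:k) for (dy in -k:k) for (dz in -k:k) {
    if ((dx^2 + dy^2 + dz^2) * voxel_size^2 > r^2) next
    acc <- acc + shift_array(a, c(dx, dy, dz), fill = 0)
    cnt <- cnt + shift_array(ones, c(dx, dy, dz), fill = 0)
  }
  acc / cnt
}

#' Read / write PET images as NIfTI-1
#'
#' Writes the array with its voxel size in the NIfTI header and, for dynamic
#' or parametric images, a JSON sidecar (`<path>.json`) carrying frame times
#' and the image kind.
#'
#' @param image A [pet_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_pet_image()` returns `path` invisibly; `read_pet_image()`
#'   a `pet_image`.
#' @export
write_pet_image <- function(image, path) {
  nii <- RNifti::asNifti(image$data,
                         pixdim = rep(image$voxel_size, 3))
  RNifti::writeNifti(nii, path)
  sidecar <- list(kind = image$kind, voxel_size = image$voxel_size)
  if (!is.null(image$frame_times)) {
    sidecar$frame_start <- image$frame_times$frame_start
    sidecar$frame_end <- image$frame_times$frame_end
    if ("window" %in% names(image$frame_times)) {
      sidecar$window <- image$frame_times$window
    }
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pet_image
#' @export
read_pet_image <- function(path) {
  nii <- RNifti::readNifti(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing image sidecar JSON: ", side_path, call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ft <- NULL
  if (!is.null(side$frame_start)) {
    ft <- tibble::tibble(frame_start = side$frame_start,
                         frame_end = side$frame_end)
    if (!is.null(side$window)) ft$window <- side$window
  }
  pet_image(array(as.numeric(nii), dim = dim(nii)),
            voxel_size = side$voxel_size, kind = side$kind,
            frame_times = ft)
}
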