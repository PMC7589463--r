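#' Phantom and outcome specifications for synthetic cohorts
#'
#' The phantom generator emulates the data the pipeline expects when no
#' clinical images are at hand: ellipsoidal tumours on a CT-like background,
#' with a homogeneous core and a textured rim whose voxelwise noise standard
#' deviation carries a latent per-patient prognostic signal `z`, and
#' right-censored time-to-event outcomes whose hazard depends on `z`.
#'
#' `rim_texture_sd` is the rim noise SD at `z = 0`; the per-patient SD is
#' `max(0, rim_texture_sd * (1 + rim_texture_gain * z))`, a linear map with a
#' floor at zero so that texture (not volume) is what carries prognosis.
#' Tumour intensities are clamped to the soft-tissue window \[-150, 180\] HU
#' so that re-segmentation is non-destructive on clean phantoms.
#'
#' @param tumour_axes_mm ellipsoid semi-axes (mm), length 3.
#' @param grid_shape voxels per axis; `NULL` grows a grid holding the tumour
#'   plus a 10 mm margin on every side.
#' @param voxel_spacing_mm isotropic voxel spacing (mm).
#' @param core_mean_hu,rim_mean_hu,background_mean_hu mean intensities (HU).
#' @param rim_texture_sd baseline rim noise SD (HU) at `z = 0`.
#' @param rim_texture_gain slope of the latent-to-SD linear map.
#' @param core_radius_frac normalised ellipsoid radius below which a voxel
#'   belongs to the homogeneous core region (texture boundary of the phantom,
#'   distinct from the geometric rim/core split applied downstream).
#' @param noise_sd_hu global additive Gaussian noise SD (HU).
#' @param seed integer seed for voxel noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(tumour_axes_mm = c(15, 15, 15),
                         grid_shape = NULL,
                         voxel_spacing_mm = 1,
                         core_mean_hu = 40,
                         rim_mean_hu = 60,
                         background_mean_hu = -50,
                         rim_texture_sd = 20,
                         rim_texture_gain = 0.5,
                         core_radius_frac = 0.85,
                         noise_sd_hu = 5,
                         seed = 1L) {
  tumour_axes_mm <- rep_len(as.numeric(tumour_axes_mm), 3L)
  if (any(tumour_axes_mm <= 0)) stop("semi-axes must be > 0", call. = FALSE)
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0", call. = FALSE)
  if (voxel_spacing_mm <= 0) stop("voxel spacing must be > 0", call. = FALSE)
  if (is.null(grid_shape)) {
    grid_shape <- 2L * ceiling((tumour_axes_mm + 10) / voxel_spacing_mm) + 1L
  }
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  half_extent <- (grid_shape - 1) / 2 * voxel_spacing_mm
  if (any(half_extent < tumour_axes_mm + 10)) {
    stop("tumour plus 10 mm margin does not fit in the grid", call. = FALSE)
  }
  structure(
    list(
      tumour_axes_mm = tumour_axes_mm, grid_shape = grid_shape,
      voxel_spacing_mm = voxel_spacing_mm, core_mean_hu = core_mean_hu,
      rim_mean_hu = rim_mean_hu, background_mean_hu = background_mean_hu,
      rim_texture_sd = rim_texture_sd, rim_texture_gain = rim_texture_gain,
      core_radius_frac = core_radius_frac, noise_sd_hu = noise_sd_hu,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @param beta log-hazard coefficient on the standardised latent signal.
#' @param weibull_shape,weibull_scale baseline Weibull event-time
#'   distribution (months).
#' @param censor_time_max administrative censoring horizon (months); events
#'   compete with a Uniform(0, `censor_time_max`) censoring time.
#' @rdname phantom_spec
#' @export
outcome_spec <- function(beta = 1.5, weibull_shape = 1.2, weibull_scale = 50,
                         censor_time_max = 60, seed = 1L) {
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stop("Weibull shape and scale must be > 0", call. = FALSE)
  }
  if (censor_time_max <= 0) stop("censor_time_max must be > 0", call. = FALSE)
  structure(
    list(
      beta = beta, weibull_shape = weibull_shape,
      weibull_scale = weibull_scale, censor_time_max = censor_time_max,
      seed = as.integer(seed)
    ),
    class = "outcome_spec"
  )
}

# run expr under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate one phantom image/mask pair
#'
#' Builds an ellipsoidal tumour on a noisy background. Voxels with normalised
#' ellipsoid radius below `core_radius_frac` form a homogeneous core at
#' `core_mean_hu`; the remaining in-mask shell is the textured rim at
#' `rim_mean_hu` with Gaussian voxel noise whose SD increases linearly with
#' the latent signal `z` (floored at zero).
#'
#' @param spec a [phantom_spec()].
#' @param z latent scalar driving rim texture heterogeneity.
#' @return A list with elements `image` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_phantom <- function(spec, z = 0) {
  stopifnot(inherits(spec, "phantom_spec"), is.finite(z))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  centre <- (d - 1) / 2 * sp
  ax <- spec$tumour_axes_mm
  cx <- (seq_len(d[1]) - 1) * sp - centre[1]
  cy <- (seq_len(d[2]) - 1) * sp - centre[2]
  cz <- (seq_len(d[3]) - 1) * sp - centre[3]
  rn2 <- outer(outer((cx / ax[1])^2, (cy / ax[2])^2, `+`), (cz / ax[3])^2, `+`)
  mask <- rn2 <= 1
  core <- rn2 <= spec$core_radius_frac^2
  rim <- mask & !core

  rim_sd <- max(0, spec$rim_texture_sd * (1 + spec$rim_texture_gain * z))
  img <- with_local_seed(spec$seed, {
    vals <- array(spec$background_mean_hu, dim = d)
    vals[core] <- spec$core_mean_hu
    vals[rim] <- spec$rim_mean_hu +
      if (rim_sd > 0) stats::rnorm(sum(rim), 0, rim_sd) else 0
    if (spec$noise_sd_hu > 0) {
      vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd_hu)
    }
    # keep tumour voxels inside the soft-tissue window by construction
    vals[mask] <- pmin(pmax(vals[mask], -150), 180)
    vals
  })
  list(
    image = image_volume(img, sp),
    mask = roi_mask(array(as.integer(mask), dim = d), sp, role = "entire")
  )
}

#' Simulate right-censored survival outcomes from a latent signal
#'
#' Event times follow a proportional-hazards Weibull model on the
#' standardised latent signal: `T ~ Weibull(shape, scale *
#' exp(-beta * z_std / shape))`, so the hazard is multiplied by
#' `exp(beta * z_std)`. Censoring is administrative-uniform on
#' `(0, censor_time_max)`; the record keeps `min(T, C)` and the event
#' indicator `T <= C`.
#'
#' @param z_values numeric vector of latent signals, one per patient.
#' @param spec an [outcome_spec()].
#' @return A tibble with columns `patient_id`, `time_months`, `event`.
#' @export
generate_outcomes <- function(z_values, spec) {
  stopifnot(inherits(spec, "outcome_spec"))
  if (length(z_values) == 0) stop("`z_values` is empty", call. = FALSE)
  if (any(!is.finite(z_values))) stop("`z_values` must be finite", call. = FALSE)
  n <- length(z_values)
  z_std <- if (stats::sd(z_values) > 0) {
    (z_values - mean(z_values)) / stats::sd(z_values)
  } else {
    rep(0, n)
  }
  with_local_seed(spec$seed, {
    scale_i <- spec$weibull_scale * exp(-spec$beta * z_std / spec$weibull_shape)
    t_event <- stats::rweibull(n, shape = spec$weibull_shape, scale = scale_i)
    t_event <- pmax(t_event, 1e-6)
    t_cens <- if (is.finite(spec$censor_time_max)) {
      stats::runif(n, 0, spec$censor_time_max)
    } else {
      rep(Inf, n)
    }
    t_cens <- pmax(t_cens, 1e-6)
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-patient latent signals `z` from a standard normal, tumour
#' volumes log-uniform over `volume_range_cm3` (mildly anisotropic ellipsoid
#' axes at fixed volume), splits patients into exploratory and validation
#' cohorts at `split_ratio`:1, and simulates outcomes with
#' [generate_outcomes()]. Images are not materialised here; regenerate any
#' patient's phantom on demand with [cohort_phantom()] — every per-patient
#' seed is derived deterministically from `seed`.
#'
#' @param n number of patients (>= 10).
#' @param split_ratio exploratory:validation ratio (2 gives a 2:1 split).
#' @param phantom a [phantom_spec()] template (per-patient axes/seed override
#'   its `tumour_axes_mm` and `seed`).
#' @param outcomes an [outcome_spec()].
#' @param volume_range_cm3 tumour volume range spanned log-uniformly.
#' @param seed master seed.
#' @return A `rimcore_cohort` tibble: `patient_id`, `cohort`, `z`,
#'   `time_months`, `event`, `volume_cm3`, per-axis semi-axes and the
#'   per-patient seed, with the phantom template in attribute
#'   `phantom_spec`.
#' @export
generate_cohort <- function(n, split_ratio = 2, phantom = phantom_spec(),
                            outcomes = outcome_spec(),
                            volume_range_cm3 = c(5, 150), seed = 1L) {
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  frac <- split_ratio / (split_ratio + 1)
  if (!is.finite(frac) || frac <= 0 || frac >= 1) {
    stop("invalid split ratio", call. = FALSE)
  }
  info <- with_local_seed(seed, {
    z <- stats::rnorm(n)
    vol <- exp(stats::runif(n, log(volume_range_cm3[1]),
                            log(volume_range_cm3[2])))
    r <- (3 * vol * 1000 / (4 * pi))^(1 / 3) # cm3 -> mm3 -> radius mm
    aniso <- matrix(exp(stats::rnorm(3 * n, 0, 0.08)), ncol = 3)
    aniso <- aniso / exp(rowMeans(log(aniso))) # volume-preserving
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    n_exp <- round(n * frac)
    cohort <- rep("validation", n)
    cohort[sample.int(n, n_exp)] <- "exploratory"
    list(z = z, r = r, aniso = aniso, seeds = seeds, cohort = cohort)
  })
  out <- generate_outcomes(info$z, outcomes)
  ax <- info$aniso * info$r
  res <- tibble::tibble(
    patient_id = out$patient_id,
    cohort = info$cohort,
    z = info$z,
    time_months = out$time_months,
    event = out$event,
    volume_cm3 = 4 / 3 * pi * ax[, 1] * ax[, 2] * ax[, 3] / 1000,
    axis_a_mm = ax[, 1], axis_b_mm = ax[, 2], axis_c_mm = ax[, 3],
    phantom_seed = info$seeds
  )
  attr(res, "phantom_spec") <- phantom
  class(res) <- c("rimcore_cohort", class(res))
  res
}

#' Rebuild the phantom image and mask for one cohort patient
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param patient row index or patient id.
#' @return As [generate_phantom()].
#' @export
cohort_phantom <- function(cohort, patient) {
  stopifnot(inherits(cohort, "rimcore_cohort"))
  i <- if (is.character(patient)) {
    match(patient, cohort$patient_id)
  } else {
    as.integer(patient)
  }
  if (is.na(i) || i < 1 || i > nrow(cohort)) {
    stop("unknown patient", call. = FALSE)
  }
  template <- attr(cohort, "phantom_spec")
  spec <- phantom_spec(
    tumour_axes_mm = c(
      cohort$axis_a_mm[i], cohort$axis_b_mm[i], cohort$axis_c_mm[i]
    ),
    voxel_spacing_mm = template$voxel_spacing_mm,
    core_mean_hu = template$core_mean_hu,
    rim_mean_hu = template$rim_mean_hu,
    background_mean_hu = template$background_mean_hu,
    rim_texture_sd = template$rim_texture_sd,
    rim_texture_gain = template$rim_texture_gain,
    core_radius_frac = template$core_radius_frac,
    noise_sd_hu = template$noise_sd_hu,
    seed = cohort$phantom_seed[i]
  )
  generate_phantom(spec, z = cohort$z[i])
}
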