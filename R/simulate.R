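#' Cohort simulation configuration
#'
#' Describes a synthetic multi-phase CT cohort: per-subject latent true
#' non-contrast liver attenuation drawn from a two-component
#' (steatotic / non-steatotic) Gaussian mixture, post-contrast liver values
#' obtained by inverting the phase's correction model at the latent value,
#' paired observed non-contrast values carrying phase-specific Gaussian
#' residual noise on the non-contrast side, and per-phase spleen attenuation.
#'
#' Defaults emulate a derivation-like screening cohort: 7.6 percent
#' moderate-to-severe steatosis prevalence, component means 28.8 HU
#' (steatotic) and 57.9 HU (non-steatotic) with 7 HU within-component SD,
#' spleen means (38.2, 86.0, 99.3, 73.1 HU) across the four phases with 6 HU
#' SD, and residual SDs (4.7, 7.4, 4.9 HU) for arterial/venous/delayed.
#'
#' @param n_subjects number of subjects
#' @param prevalence_moderate fraction in [0, 1] assigned to the steatotic
#'   component
#' @param mean_L_normal,sd_L_normal non-steatotic latent component (HU)
#' @param mean_L_steatotic,sd_L_steatotic steatotic latent component (HU)
#' @param spleen_mean_by_phase named numeric, spleen mean per phase (HU)
#' @param spleen_sd spleen SD (HU)
#' @param residual_sd_by_phase named numeric, non-contrast residual SD paired
#'   with each post-contrast phase (HU); may include `"non-contrast"` for
#'   measurement noise on the non-contrast scan itself (default 0)
#' @param phases phases to simulate
#' @param seed integer RNG seed
#' @return object of class `cohort_sim_config`
#' @export
cohort_sim_config <- function(n_subjects,
                              prevalence_moderate = 0.076,
                              mean_L_normal = 57.9, sd_L_normal = 7,
                              mean_L_steatotic = 28.8, sd_L_steatotic = 7,
                              spleen_mean_by_phase = c(
                                "non-contrast" = 38.2, arterial = 86.0,
                                venous = 99.3, delayed = 73.1
                              ),
                              spleen_sd = 6,
                              residual_sd_by_phase = c(
                                arterial = 4.7, venous = 7.4, delayed = 4.9
                              ),
                              phases = c("non-contrast", "arterial",
                                         "venous", "delayed"),
                              seed = 1L) {
  all_phases <- c("non-contrast", "arterial", "venous", "delayed")
  stopifnot(
    n_subjects >= 1,
    prevalence_moderate >= 0, prevalence_moderate <= 1,
    sd_L_normal > 0, sd_L_steatotic > 0, spleen_sd > 0,
    all(phases %in% all_phases), length(phases) >= 1
  )
  post <- setdiff(phases, "non-contrast")
  missing_sd <- setdiff(post, names(residual_sd_by_phase))
  if (length(missing_sd)) {
    stop("missing residual SD for phase(s): ", paste(missing_sd, collapse = ", "))
  }
  stopifnot(all(residual_sd_by_phase >= 0))
  missing_spleen <- setdiff(phases, names(spleen_mean_by_phase))
  if (length(missing_spleen)) {
    stop("missing spleen mean for phase(s): ", paste(missing_spleen, collapse = ", "))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      prevalence_moderate = prevalence_moderate,
      mean_L_normal = mean_L_normal, sd_L_normal = sd_L_normal,
      mean_L_steatotic = mean_L_steatotic, sd_L_steatotic = sd_L_steatotic,
      spleen_mean_by_phase = spleen_mean_by_phase, spleen_sd = spleen_sd,
      residual_sd_by_phase = residual_sd_by_phase,
      phases = phases, seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

# Draw latent non-contrast attenuations restricted to (lower, upper) by
# resampling; errors out if a component cannot produce in-range draws.
draw_truncated <- function(n, mean, sd, lower, upper, max_attempts = 1000L) {
  if (n == 0) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  attempts <- 0L
  while (length(bad) > 0) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not draw latent attenuation inside (%.2f, %.2f) after %d attempts",
        lower, upper, max_attempts
      ))
    }
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

#' Simulate a multi-phase attenuation cohort
#'
#' Generates one row per subject per requested phase. Each subject receives a
#' latent true non-contrast liver attenuation from the two-component mixture;
#' post-contrast liver values are the exact model inverse at the latent value,
#' and the observed non-contrast value paired with each post-contrast phase is
#' the model forward-evaluated at that post-contrast value plus Gaussian noise
#' with the phase's residual SD (i.e. noise sits on the non-contrast response,
#' mirroring the regression setup the correction equations come from). The
#' latent value is restricted to 5 HU above the floor and 5 HU below the
#' lowest saturation level (alpha + beta) among the requested post-contrast
#' phases, so every inversion is defined; out-of-range draws are resampled.
#' Ground-truth moderate-to-severe steatosis is latent L < 40 HU.
#'
#' @param config a [cohort_sim_config()]
#' @param models registry of correction models (default [published_models()])
#' @return data.frame with columns `subject_id`, `phase`, `liver_hu`,
#'   `spleen_hu`, `liver_nc_paired_hu` (NA for the non-contrast rows),
#'   `latent_liver_nc_hu`, `steatosis_truth`
#' @export
simulate_cohort <- function(config, models = published_models()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  post <- setdiff(config$phases, "non-contrast")
  missing_model <- setdiff(post, names(models))
  if (length(missing_model)) {
    stop("no correction model registered for phase(s): ",
         paste(missing_model, collapse = ", "))
  }
  set.seed(config$seed)
  n <- config$n_subjects

  # latent restricted to (5, min(alpha+beta) - 5) over requested post phases
  lower <- 5
  upper <- if (length(post)) {
    min(vapply(post, function(p) models[[p]]$alpha + models[[p]]$beta,
               numeric(1))) - 5
  } else Inf

  steatotic <- stats::runif(n) < config$prevalence_moderate
  latent <- numeric(n)
  latent[steatotic] <- draw_truncated(
    sum(steatotic), config$mean_L_steatotic, config$sd_L_steatotic, lower, upper
  )
  latent[!steatotic] <- draw_truncated(
    sum(!steatotic), config$mean_L_normal, config$sd_L_normal, lower, upper
  )

  nc_sd <- if ("non-contrast" %in% names(config$residual_sd_by_phase)) {
    config$residual_sd_by_phase[["non-contrast"]]
  } else 0

  rows <- lapply(config$phases, function(ph) {
    spleen <- stats::rnorm(n, config$spleen_mean_by_phase[[ph]], config$spleen_sd)
    if (ph == "non-contrast") {
      liver <- latent + if (nc_sd > 0) stats::rnorm(n, 0, nc_sd) else 0
      paired <- rep(NA_real_, n)
    } else {
      m <- models[[ph]]
      liver <- invert_correction(latent, m)
      sd_ph <- config$residual_sd_by_phase[[ph]]
      noise <- if (sd_ph > 0) stats::rnorm(n, 0, sd_ph) else 0
      paired <- correct_attenuation(liver, m) + noise
    }
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      phase = ph,
      liver_hu = liver,
      spleen_hu = spleen,
      liver_nc_paired_hu = paired,
      latent_liver_nc_hu = latent,
      steatosis_truth = latent < 40
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate paired post/non-contrast attenuations from a correction model
#'
#' The refit protocol used for parameter-recovery studies: latent non-contrast
#' values are drawn uniformly over `latent_range`, inverted through the model
#' to post-contrast values, and the observed non-contrast responses are the
#' model forward evaluation plus Gaussian noise of SD `noise_sd` (noise on the
#' non-contrast side).
#'
#' @param model a [correction_model()]
#' @param n number of pairs
#' @param noise_sd residual SD on the non-contrast side (HU)
#' @param latent_range length-2 range for the uniform latent draw (HU); must
#'   lie inside the model's invertible interval
#' @param seed integer RNG seed
#' @return data.frame with `l_post`, `l_nc`, `latent`
#' @export
simulate_correction_pairs <- function(model, n, noise_sd,
                                      latent_range = c(10, 70), seed = 1L) {
  stopifnot(inherits(model, "correction_model"), n >= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  latent <- stats::runif(n, latent_range[1], latent_range[2])
  l_post <- invert_correction(latent, model)
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  data.frame(
    l_post = l_post,
    l_nc = correct_attenuation(l_post, model) + noise,
    latent = latent
  )
}

#' Phantom volume configuration
#'
#' An axis-aligned ellipsoid "liver" and "spleen" embedded in an air
#' background (-1000 HU) on a regular grid, with optional Gaussian texture
#' and optional axial cropping emulating scans whose field of view truncates
#' the organs (partial organ volume).
#'
#' @param grid_shape integer length-3 grid dimensions (voxels)
#' @param voxel_spacing numeric length-3, mm per axis
#' @param liver_ellipsoid,spleen_ellipsoid lists with `center` and `semiaxes`
#'   (voxel units)
#' @param liver_hu,spleen_hu organ mean attenuations (HU)
#' @param texture_sd voxelwise Gaussian texture SD (HU, >= 0)
#' @param crop_fraction fraction in [0, 1) of the axial (z) extent removed
#'   from the superior end
#' @param seed integer RNG seed
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(grid_shape, voxel_spacing = c(1, 1, 1),
                           liver_ellipsoid, spleen_ellipsoid,
                           liver_hu = 55, spleen_hu = 45,
                           texture_sd = 0, crop_fraction = 0, seed = 1L) {
  stopifnot(
    length(grid_shape) == 3, all(grid_shape >= 1),
    length(voxel_spacing) == 3, all(voxel_spacing > 0),
    texture_sd >= 0, crop_fraction >= 0, crop_fraction < 1
  )
  check_ellipsoid <- function(e, nm) {
    if (!all(c("center", "semiaxes") %in% names(e))) {
      stop(nm, " must have 'center' and 'semiaxes'")
    }
    stopifnot(length(e$center) == 3, length(e$semiaxes) == 3,
              all(e$semiaxes > 0))
    if (any(e$center - e$semiaxes < 1) || any(e$center + e$semiaxes > grid_shape)) {
      stop(nm, " does not lie within the grid")
    }
  }
  check_ellipsoid(liver_ellipsoid, "liver_ellipsoid")
  check_ellipsoid(spleen_ellipsoid, "spleen_ellipsoid")
  structure(
    list(
      grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
      liver_ellipsoid = liver_ellipsoid, spleen_ellipsoid = spleen_ellipsoid,
      liver_hu = liver_hu, spleen_hu = spleen_hu,
      texture_sd = texture_sd, crop_fraction = crop_fraction,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

ellipsoid_mask <- function(grid_shape, center, semiaxes) {
  dx <- ((seq_len(grid_shape[1]) - center[1]) / semiaxes[1])^2
  dy <- ((seq_len(grid_shape[2]) - center[2]) / semiaxes[2])^2
  dz <- ((seq_len(grid_shape[3]) - center[3]) / semiaxes[3])^2
  d <- outer(outer(dx, dy, `+`), dz, `+`)
  d <= 1
}

#' Simulate a labeled CT phantom
#'
#' Voxels inside the liver ellipsoid are N(liver_hu, texture_sd), spleen
#' likewise; background is -1000 HU (air). The mask labels liver 1 and
#' spleen 2. With `crop_fraction > 0`, that fraction of axial slices is
#' removed from the superior end of both image and mask.
#'
#' @param config a [phantom_config()]
#' @return a [phantom_volume()]
#' @export
simulate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  gs <- config$grid_shape
  liver <- ellipsoid_mask(gs, config$liver_ellipsoid$center,
                          config$liver_ellipsoid$semiaxes)
  spleen <- ellipsoid_mask(gs, config$spleen_ellipsoid$center,
                           config$spleen_ellipsoid$semiaxes)
  if (any(liver & spleen)) stop("liver and spleen ellipsoids overlap")

  image <- array(-1000, gs)
  draw_organ <- function(sel, hu) {
    n <- sum(sel)
    image[sel] <<- if (config$texture_sd > 0) {
      stats::rnorm(n, hu, config$texture_sd)
    } else rep(hu, n)
  }
  draw_organ(liver, config$liver_hu)
  draw_organ(spleen, config$spleen_hu)
  mask <- array(0L, gs)
  mask[liver] <- 1L
  mask[spleen] <- 2L

  if (config$crop_fraction > 0) {
    keep <- seq_len(gs[3] - floor(config$crop_fraction * gs[3]))
    image <- image[, , keep, drop = FALSE]
    mask <- mask[, , keep, drop = FALSE]
  }
  phantom_volume(image, mask, spacing = config$voxel_spacing)
}

#' Simulate per-slice contrast-phase predictions
#'
#' Emulates a slice-level phase classifier applied along the spine: each
#' slice's label equals the true phase with probability `accuracy`, otherwise
#' a uniformly chosen other phase. Confidences are Gaussian draws (clamped to
#' [0, 1]) whose mean may differ between correctly and incorrectly labeled
#' slices.
#'
#' @param true_phase the scan's true phase
#' @param n_slices number of sampled slices (>= 1)
#' @param accuracy per-slice label accuracy in [0, 1]
#' @param confidence_params list with `mean_correct`, `mean_incorrect`, `sd`
#' @param seed integer RNG seed
#' @return data.frame with `slice_index`, `label`, `confidence`
#' @export
simulate_slice_predictions <- function(true_phase, n_slices, accuracy,
                                       confidence_params = list(
                                         mean_correct = 0.85,
                                         mean_incorrect = 0.55,
                                         sd = 0.1
                                       ),
                                       seed = 1L) {
  phases <- c("non-contrast", "arterial", "venous", "delayed")
  true_phase <- match.arg(true_phase, phases)
  stopifnot(n_slices >= 1, accuracy >= 0, accuracy <= 1)
  set.seed(as.integer(seed))
  correct <- stats::runif(n_slices) < accuracy
  others <- setdiff(phases, true_phase)
  label <- ifelse(correct, true_phase,
                  others[sample.int(3, n_slices, replace = TRUE)])
  mu <- ifelse(correct, confidence_params$mean_correct,
               confidence_params$mean_incorrect)
  confidence <- pmin(1, pmax(0, stats::rnorm(n_slices, mu, confidence_params$sd)))
  data.frame(slice_index = seq_len(n_slices), label = label,
             confidence = confidence)
}
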