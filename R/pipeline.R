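#' Pipeline run configuration
#'
#' Describes an end-to-end synthetic run: which stages to execute, where to
#' write artifacts, the master seed, and the cohort / phantom / evaluation
#' settings. Stage order is fixed; a subset may be requested but consumers
#' must follow their producers.
#'
#' @param out_dir output directory (created if absent)
#' @param seed master integer seed; per-stage child seeds are
#'   `seed + 100 * stage_index` (documented, reproducible fan-out)
#' @param stages subset of
#'   `c("simulate_cohort", "extract_phantom", "phase_vote",
#'      "fit_correction", "fat_fraction", "evaluate")`
#' @param n_subjects cohort size
#' @param phases phases to simulate and analyse
#' @param threshold_grid_hu candidate liver-attenuation thresholds (HU)
#' @param threshold_grid_ff candidate fat-fraction thresholds (percent)
#' @param models correction-model registry
#' @return object of class `run_config`
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate_cohort", "extract_phantom",
                                  "phase_vote", "fit_correction",
                                  "fat_fraction", "evaluate"),
                       n_subjects = 1000L,
                       phases = c("non-contrast", "arterial", "venous", "delayed"),
                       threshold_grid_hu = seq(40, 100, by = 5),
                       threshold_grid_ff = seq(5, 20, by = 5),
                       models = published_models()) {
  known <- c("simulate_cohort", "extract_phantom", "phase_vote",
             "fit_correction", "fat_fraction", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]     # enforce canonical order
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         n_subjects = as.integer(n_subjects), phases = phases,
         threshold_grid_hu = threshold_grid_hu,
         threshold_grid_ff = threshold_grid_ff, models = models),
    class = "run_config"
  )
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the synthetic steatosis pipeline end to end
#'
#' Executes the configured stages in order (simulate cohort, phantom
#' attenuation extraction, phase voting, correction refitting, fat-fraction
#' conversion, threshold/ROC evaluation), writing each stage's tabular
#' artifacts as CSV plus a JSON manifest recording the seed fan-out and an
#' md5 checksum per artifact. Identical config and seed reproduce identical
#' artifacts. A stage failure aborts the run with the failing stage named and
#' leaves a `FAILED` marker file in the output directory.
#'
#' @param config a [run_config()]
#' @return the manifest (invisibly), a list also written to `manifest.json`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  child_seed <- function(k) config$seed + 100L * k
  all_stages <- c("simulate_cohort", "extract_phantom", "phase_vote",
                  "fit_correction", "fat_fraction", "evaluate")
  artifacts <- character(0)
  stage_log <- list()
  cohort <- NULL

  run_stage <- function(name, fun) {
    message(sprintf("[%s] running", name))
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  for (stage in config$stages) {
    k <- match(stage, all_stages)
    seed_k <- child_seed(k)
    out <- switch(
      stage,
      simulate_cohort = run_stage(stage, function() {
        cfg <- cohort_sim_config(config$n_subjects, phases = config$phases,
                                 seed = seed_k)
        cohort <<- simulate_cohort(cfg, config$models)
        write_csv_plain(cohort, file.path(config$out_dir, "cohort.csv"))
      }),
      extract_phantom = run_stage(stage, function() {
        cfg <- phantom_config(
          grid_shape = c(64, 64, 48),
          liver_ellipsoid = list(center = c(24, 32, 24), semiaxes = c(14, 18, 16)),
          spleen_ellipsoid = list(center = c(50, 32, 24), semiaxes = c(8, 10, 12)),
          liver_hu = 55, spleen_hu = 45, texture_sd = 8,
          crop_fraction = 0.25, seed = seed_k
        )
        vol <- simulate_phantom(cfg)
        liver <- masked_mean(vol, 1L)
        spleen <- masked_mean(vol, 2L)
        df <- data.frame(
          organ = c("liver", "spleen"),
          mean_hu = c(liver$mean_hu, spleen$mean_hu),
          n_voxels = c(liver$n_voxels, spleen$n_voxels)
        )
        write_csv_plain(df, file.path(config$out_dir, "phantom_attenuation.csv"))
      }),
      phase_vote = run_stage(stage, function() {
        votes <- lapply(config$phases, function(ph) {
          preds <- simulate_slice_predictions(ph, n_slices = 12,
                                              accuracy = 0.8,
                                              seed = seed_k + match(ph, config$phases))
          v <- vote_phase(preds)
          data.frame(true_phase = ph, voted_phase = v$phase, tied = v$tied)
        })
        write_csv_plain(do.call(rbind, votes),
                        file.path(config$out_dir, "phase_votes.csv"))
      }),
      fit_correction = run_stage(stage, function() {
        if (is.null(cohort)) {
          cohort <<- utils::read.csv(file.path(config$out_dir, "cohort.csv"))
        }
        post <- setdiff(config$phases, "non-contrast")
        fits <- lapply(post, function(ph) {
          sub <- cohort[cohort$phase == ph, ]
          fit <- fit_correction(sub$liver_hu, sub$liver_nc_paired_hu, phase = ph)
          data.frame(phase = ph, alpha = fit$model$alpha, beta = fit$model$beta,
                     kappa = fit$model$kappa, rmse = fit$rmse, n = fit$n,
                     converged = fit$converged)
        })
        write_csv_plain(do.call(rbind, fits),
                        file.path(config$out_dir, "correction_fits.csv"))
      }),
      fat_fraction = run_stage(stage, function() {
        if (is.null(cohort)) {
          cohort <<- utils::read.csv(file.path(config$out_dir, "cohort.csv"))
        }
        ffs <- lapply(split(cohort, cohort$phase), function(sub) {
          res <- ff_from_scan(sub$liver_hu, sub$phase[1], config$models)
          cbind(subject_id = sub$subject_id, res,
                steatosis_truth = sub$steatosis_truth)
        })
        out <- do.call(rbind, ffs)
        rownames(out) <- NULL
        write_csv_plain(out, file.path(config$out_dir, "fat_fraction.csv"))
      }),
      evaluate = run_stage(stage, function() {
        ff <- utils::read.csv(file.path(config$out_dir, "fat_fraction.csv"))
        sweeps <- lapply(split(ff, ff$phase), function(sub) {
          rows <- threshold_sweep(sub$ff_percent, sub$steatosis_truth,
                                  config$threshold_grid_ff, "greater_than")
          cbind(phase = sub$phase[1], rows)
        })
        write_csv_plain(do.call(rbind, sweeps),
                        file.path(config$out_dir, "ff_thresholds.csv"))
        aucs <- lapply(split(ff, ff$phase), function(sub) {
          data.frame(phase = sub$phase[1],
                     auroc = roc_auc(sub$ff_percent, sub$steatosis_truth,
                                     "greater")$auroc)
        })
        write_csv_plain(do.call(rbind, aucs),
                        file.path(config$out_dir, "ff_auroc.csv"))
      })
    )
    files <- if (stage == "evaluate") {
      file.path(config$out_dir, c("ff_thresholds.csv", "ff_auroc.csv"))
    } else out
    artifacts <- c(artifacts, files)
    stage_log[[stage]] <- list(seed = seed_k, outputs = basename(files))
  }

  checksums <- as.list(tools::md5sum(artifacts))
  names(checksums) <- basename(artifacts)
  manifest <- list(
    package = "steatoCT",
    version = as.character(utils::packageVersion("steatoCT")),
    seed = config$seed,
    stages = stage_log,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
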