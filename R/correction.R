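#' Phase-specific attenuation correction model
#'
#' A correction model converts post-contrast mean liver attenuation L' (HU)
#' into a non-contrast-equivalent value via the increasing exponential-decay
#' form
#' \deqn{L = \alpha + \beta (1 - e^{-L' \kappa})}
#' which is strictly increasing in L' and saturates at \eqn{\alpha + \beta}.
#'
#' @param phase one of `"arterial"`, `"venous"`, `"delayed"`
#' @param alpha intercept-like coefficient (HU); the corrected value at L' = 0
#' @param beta amplitude (HU); must be positive
#' @param kappa rate constant (per HU); must be positive
#' @return an object of class `correction_model`
#' @seealso [published_models()], [correct_attenuation()], [invert_correction()]
#' @export
correction_model <- function(phase, alpha, beta, kappa) {
  phase <- match.arg(phase, c("arterial", "venous", "delayed"))
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(kappa))
  if (beta <= 0) stop("beta must be > 0 (increasing, saturating form)")
  if (kappa <= 0) stop("kappa must be > 0 (increasing, saturating form)")
  structure(
    list(phase = phase, alpha = alpha, beta = beta, kappa = kappa),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "Correction model [%s]: corrected L = %.3f + %.3f * (1 - exp(-L' * %.4f))\n",
    x$phase, x$alpha, x$beta, x$kappa
  ))
  cat(sprintf("  saturation (alpha + beta): %.3f HU\n", x$alpha + x$beta))
  invisible(x)
}

#' Published correction model registry
#'
#' The three phase-specific correction equations estimated on a multi-phase
#' derivation cohort by nonlinear least squares:
#' arterial (-31.478, 114.8, 0.022), venous (-33.488, 109.094, 0.015),
#' delayed (-25.431, 96.961, 0.02).
#'
#' @param phase optional; if given, return the single model for that phase
#' @return a named list of `correction_model` objects, or one model
#' @export
published_models <- function(phase = NULL) {
  registry <- list(
    arterial = correction_model("arterial", -31.478, 114.8,   0.022),
    venous   = correction_model("venous",   -33.488, 109.094, 0.015),
    delayed  = correction_model("delayed",  -25.431, 96.961,  0.02)
  )
  if (is.null(phase)) return(registry)
  phase <- match.arg(phase, names(registry))
  registry[[phase]]
}

#' Convert post-contrast liver attenuation to a non-contrast equivalent
#'
#' Evaluates the correction equation `alpha + beta * (1 - exp(-l_post * kappa))`.
#' Defined for all real inputs; negative post-contrast attenuations are
#' physically implausible for liver and trigger a warning but are not refused.
#'
#' @param l_post post-contrast mean liver attenuation L' (HU); vectorised
#' @param model a [correction_model()]
#' @return non-contrast-equivalent attenuation (HU)
#' @export
correct_attenuation <- function(l_post, model) {
  stopifnot(inherits(model, "correction_model"), all(is.finite(l_post)))
  if (any(l_post < 0)) {
    warning("negative post-contrast attenuation is implausible for liver; correcting anyway")
  }
  model$alpha + model$beta * (1 - exp(-l_post * model$kappa))
}

#' Invert a correction model
#'
#' Algebraic inverse of the correction equation: given a non-contrast
#' attenuation in the open interval (alpha, alpha + beta), returns the
#' post-contrast value L' that the model maps onto it,
#' `L' = -log(1 - (l_nc - alpha) / beta) / kappa`.
#'
#' @param l_nc non-contrast attenuation (HU); must satisfy
#'   `alpha < l_nc < alpha + beta`
#' @param model a [correction_model()]
#' @return post-contrast attenuation L' (HU)
#' @export
invert_correction <- function(l_nc, model) {
  stopifnot(inherits(model, "correction_model"), all(is.finite(l_nc)))
  lo <- model$alpha
  hi <- model$alpha + model$beta
  if (any(l_nc <= lo | l_nc >= hi)) {
    stop(sprintf(
      "inversion defined only on the open interval (%.3f, %.3f) HU for the %s model",
      lo, hi, model$phase
    ))
  }
  -log(1 - (l_nc - model$alpha) / model$beta) / model$kappa
}

#' Root mean squared error of a correction model on paired data
#'
#' RMSE of the non-contrast residuals `l_nc - correct(l_post)`, with divisor
#' n (not n - 3).
#'
#' @param l_post,l_nc paired post-contrast and non-contrast attenuations (HU)
#' @param model a [correction_model()]
#' @return RMSE in HU
#' @export
correction_rmse <- function(l_post, l_nc, model) {
  stopifnot(length(l_post) == length(l_nc), length(l_post) >= 1)
  r <- l_nc - correct_attenuation(l_post, model)
  sqrt(mean(r^2))
}

#' Read or write a correction-model registry as JSON
#'
#' Serialises models as an array of `{phase, alpha, beta, kappa}` records.
#'
#' @param models named list of [correction_model()] objects
#' @param path file path
#' @return `read_model_registry` returns a named list of models
#' @export
write_model_registry <- function(models, path) {
  recs <- lapply(models, function(m) {
    list(phase = m$phase, alpha = m$alpha, beta = m$beta, kappa = m$kappa)
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_registry
#' @export
read_model_registry <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(recs, function(r) {
    correction_model(r$phase, r$alpha, r$beta, r$kappa)
  })
  names(models) <- vapply(models, `[[`, "", "phase")
  models
}
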