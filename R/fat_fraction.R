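#' MR-PDFF-equivalent fat fraction from non-contrast liver attenuation
#'
#' Linear conversion FF = -0.58 * L + 38.2 (percent), mapping non-contrast
#' (or corrected non-contrast-equivalent) mean liver attenuation to an
#' MR-PDFF-equivalent fat fraction. The conversion is exactly coherent with
#' the standard steatosis thresholds: L = 40 HU maps to FF = 15 percent, so
#' classifying FF > 15 is algebraically identical to classifying L < 40.
#' Negative fat fractions (attenuation above ~65.9 HU) are reported as-is and
#' flagged, never clamped.
#'
#' @param l_nc non-contrast(-equivalent) mean liver attenuation (HU); vectorised
#' @return data.frame with columns `l_nc`, `ff_percent`, `negative_ff`
#' @export
ff_from_attenuation <- function(l_nc) {
  stopifnot(all(is.finite(l_nc)))
  ff <- -0.58 * l_nc + 38.2
  data.frame(l_nc = l_nc, ff_percent = ff, negative_ff = ff < 0)
}

#' Binary threshold classification with strict inequality
#'
#' Applies a strict `<` or `>` comparison, matching how clinical thresholds
#' are printed ("< 40 HU", "> 15 percent"): a value exactly at the threshold
#' is negative.
#'
#' @param value numeric vector
#' @param threshold scalar threshold
#' @param direction `"less_than"` or `"greater_than"`
#' @return logical vector
#' @export
classify_threshold <- function(value, threshold,
                               direction = c("less_than", "greater_than")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(value)), is.finite(threshold))
  if (direction == "less_than") value < threshold else value > threshold
}

#' Fat fraction from a (possibly post-contrast) attenuation measurement
#'
#' Composes correction and conversion: post-contrast attenuation is first
#' mapped to a non-contrast equivalent with the phase's correction model,
#' then converted to fat fraction. `phase = "non-contrast"` bypasses
#' correction. Both the intermediate corrected attenuation and the final fat
#' fraction are returned; implausible (negative) post-contrast inputs are
#' flagged.
#'
#' @param liver_hu measured mean liver attenuation (HU); vectorised
#' @param phase `"non-contrast"`, `"arterial"`, `"venous"` or `"delayed"`
#' @param models registry of correction models (default [published_models()])
#' @return data.frame with `phase`, `liver_hu`, `corrected_l`, `ff_percent`,
#'   `negative_ff`, `implausible_input`
#' @export
ff_from_scan <- function(liver_hu, phase, models = published_models()) {
  stopifnot(all(is.finite(liver_hu)))
  phase <- match.arg(phase, c("non-contrast", "arterial", "venous", "delayed"))
  if (phase == "non-contrast") {
    corrected <- liver_hu
    implausible <- liver_hu < 0
  } else {
    if (is.null(models[[phase]])) {
      stop(sprintf("no correction model registered for phase '%s'", phase))
    }
    implausible <- liver_hu < 0
    corrected <- suppressWarnings(correct_attenuation(liver_hu, models[[phase]]))
    if (any(implausible)) {
      warning("negative post-contrast attenuation corrected; flagged implausible_input")
    }
  }
  ff <- ff_from_attenuation(corrected)
  data.frame(
    phase = phase,
    liver_hu = liver_hu,
    corrected_l = corrected,
    ff_percent = ff$ff_percent,
    negative_ff = ff$negative_ff,
    implausible_input = implausible
  )
}
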