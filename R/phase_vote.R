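#' Scan-level contrast-phase call by confidence-weighted majority vote
#'
#' A per-slice phase classifier emits one (label, confidence) prediction per
#' sampled slice; the scan-level phase is the label with the largest total
#' confidence. Weights are the raw confidences (no thresholding or
#' exponentiation). If every confidence is zero the vote falls back to the
#' unweighted slice majority with a warning. Exact ties are broken by the
#' fixed order non-contrast > delayed > venous > arterial and flagged.
#'
#' @param predictions data.frame with columns `slice_index`, `label`
#'   (one of the four phases) and `confidence` in [0, 1]
#' @return list with `phase` (winning label), `weights` (named numeric total
#'   per label, all four phases), and `tied` (logical)
#' @export
vote_phase <- function(predictions) {
  phases <- c("non-contrast", "delayed", "venous", "arterial")  # tie-break order
  stopifnot(is.data.frame(predictions),
            all(c("label", "confidence") %in% names(predictions)))
  if (nrow(predictions) == 0) stop("no slice predictions to vote on")
  if (!all(predictions$label %in% phases)) {
    stop("unknown phase label in predictions")
  }
  conf <- predictions$confidence
  stopifnot(all(is.finite(conf)), all(conf >= 0), all(conf <= 1))

  if (all(conf == 0)) {
    warning("all confidences are zero; falling back to unweighted majority")
    conf <- rep(1, length(conf))
  }
  weights <- vapply(
    phases,
    function(p) sum(conf[predictions$label == p]),
    numeric(1)
  )
  top <- max(weights)
  winners <- names(weights)[weights == top]
  list(
    phase = winners[1],                  # phases ordered by tie-break priority
    weights = weights[c("non-contrast", "arterial", "venous", "delayed")],
    tied = length(winners) > 1
  )
}
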