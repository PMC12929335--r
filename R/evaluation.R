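#' Confusion counts for a binary steatosis call
#'
#' @param tp,fp,fn,tn non-negative integer counts; total must be positive
#' @return object of class `confusion_counts`
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)), sum(counts) > 0)
  structure(as.list(counts), class = "confusion_counts")
}

#' Round half up (decimal reporting convention)
#'
#' Printed tables round .x5 upward; base `round()` rounds half to even, so
#' reported percents use this helper.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn) and balanced accuracy (mean of sensitivity and specificity),
#' all as percents at full precision. A metric whose denominator is zero is
#' undefined and reported as NA, never as 0. Use [round_half_up()] for
#' 1-decimal table reporting.
#'
#' @param counts a [confusion_counts()]
#' @return named list: `sensitivity`, `specificity`, `ba`, `ppv`, `npv`
#'   (percents), plus the counts
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- frac(counts$tp, counts$tp + counts$fn)
  spec <- frac(counts$tn, counts$tn + counts$fp)
  list(
    sensitivity = sens,
    specificity = spec,
    ba = (sens + spec) / 2,
    ppv = frac(counts$tp, counts$tp + counts$fp),
    npv = frac(counts$tn, counts$tn + counts$fn),
    counts = counts
  )
}

#' Threshold sweep with balanced-accuracy optimum
#'
#' Applies each candidate threshold to the scores with a strict inequality
#' (`"less_than"` for attenuation-like markers where low values indicate
#' steatosis, `"greater_than"` for fat fraction), computes the confusion
#' metrics against the reference labels, and marks the threshold with
#' maximal balanced accuracy. Balanced-accuracy ties are broken toward the
#' more specific threshold (highest specificity; if still tied, the earlier
#' threshold in the grid).
#'
#' @param scores numeric marker values
#' @param truth logical (or 0/1) reference labels; both classes required
#' @param thresholds numeric candidate thresholds
#' @param direction `"less_than"` or `"greater_than"`
#' @return data.frame with one row per threshold (threshold, ba, sensitivity,
#'   specificity, ppv, npv, tp, fp, fn, tn, optimal)
#' @export
threshold_sweep <- function(scores, truth, thresholds,
                            direction = c("less_than", "greater_than")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), length(thresholds) >= 1)
  if (length(unique(truth)) < 2) {
    stop("reference labels contain a single class; sweep undefined")
  }
  rows <- lapply(thresholds, function(thr) {
    call <- classify_threshold(scores, thr, direction)
    cts <- confusion_counts(
      tp = sum(call & truth), fp = sum(call & !truth),
      fn = sum(!call & truth), tn = sum(!call & !truth)
    )
    m <- confusion_metrics(cts)
    data.frame(
      threshold = thr, ba = m$ba,
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, npv = m$npv,
      tp = cts$tp, fp = cts$fp, fn = cts$fn, tn = cts$tn
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$ba, -out$specificity)   # BA ties -> more specific threshold
  out$optimal <- FALSE
  out$optimal[ord[1]] <- TRUE
  out
}

#' Trapezoidal AUROC
#'
#' Builds the ROC curve over all distinct score cutoffs and integrates with
#' the trapezoidal rule. With ties this equals the concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie). For markers where LOW values
#' indicate the positive class (attenuation), pass `direction = "less"` and
#' the scores are negated internally so an informative marker yields
#' AUROC > 0.5.
#'
#' @param scores numeric marker values
#' @param truth logical (or 0/1) reference labels; both classes required
#' @param direction `"greater"` if high scores indicate positives, `"less"`
#'   if low scores do
#' @return list with `points` (data.frame fpr, tpr) and `auroc`
#' @export
roc_auc <- function(scores, truth, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for a ROC curve")
  s <- if (direction == "less") -scores else scores

  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; t <- truth[ord]
  # one ROC vertex per distinct cutoff (call positive when score >= cutoff)
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(t)[last] / n_pos)
  fpr <- c(0, cumsum(!t)[last] / n_neg)
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auroc = auroc)
}

# Placement values (midrank form) underlying DeLong's estimator:
# v10[i] = P-hat(score of positive i exceeds a random negative), v01 likewise.
delong_placements <- function(s, truth) {
  x <- s[truth]; y <- s[!truth]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n))
}

#' Paired DeLong comparison of two ROC curves
#'
#' Nonparametric comparison of the AUROCs of two markers measured on the same
#' subjects, using the placement-value (midrank) form of DeLong's variance
#' and covariance estimator. Returns the two AUROCs, the z statistic for the
#' AUROC difference and a two-sided normal p-value. Identical score vectors
#' give z = 0, p = 1; a zero-variance difference with unequal AUROCs yields
#' an undefined (NA) p with an explanatory warning.
#'
#' @param scores_a,scores_b paired marker values on identical subjects
#' @param truth logical (or 0/1) reference labels; both classes required
#' @param direction as in [roc_auc()], applied to both markers
#' @return list: `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`
#' @export
delong_compare <- function(scores_a, scores_b, truth,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  if (sum(truth) == 0 || sum(!truth) == 0) {
    stop("both classes required for a ROC comparison")
  }
  if (direction == "less") {
    scores_a <- -scores_a; scores_b <- -scores_b
  }
  pa <- delong_placements(scores_a, truth)
  pb <- delong_placements(scores_b, truth)
  m <- sum(truth); n <- sum(!truth)

  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff_auc <- pa$auc - pb$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    if (diff_auc == 0) {
      z <- 0; p <- 1
    } else {
      warning("zero variance of the AUROC difference (degenerate scores); p undefined")
      z <- NA_real_; p <- NA_real_
    }
  } else {
    z <- diff_auc / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p_value = p, var_diff = var_diff)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using midranks for ties; the two-sided p-value uses the
#' t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3)
#' @return list with `r` and `p_value`
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  n <- length(x)
  r <- stats::cor(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p)
}
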