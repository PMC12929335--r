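test_that("confusion metrics reproduce printed-table rows and guard zero denominators", {
  # venous "< 85" row of the liver-attenuation table
  m <- confusion_metrics(confusion_counts(tp = 71, fp = 13, fn = 4, tn = 109))
  expect_equal(round_half_up(m$sensitivity), 94.7)
  expect_equal(round_half_up(m$specificity), 89.3)
  expect_equal(round_half_up(m$ba), 92.0)
  expect_equal(round_half_up(m$ppv), 84.5)
  expect_equal(round_half_up(m$npv), 96.5)

  # delayed "< 60" row
  m2 <- confusion_metrics(confusion_counts(tp = 76, fp = 5, fn = 2, tn = 128))
  expect_equal(round_half_up(m2$sensitivity), 97.4)
  expect_equal(round_half_up(m2$specificity), 96.2)

  # no positives: sensitivity is undefined, not zero
  m3 <- confusion_metrics(confusion_counts(tp = 0, fp = 3, fn = 0, tn = 7))
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$ba))
  expect_false(is.na(m3$specificity))
})

test_that("threshold sweep finds the balanced-accuracy optimum", {
  # perfectly separated scores: some threshold reaches BA = 100
  scores <- c(rnorm(50, 20), rnorm(50, 80))
  truth <- rep(c(TRUE, FALSE), each = 50)
  rows <- threshold_sweep(scores, truth, seq(30, 70, by = 5), "less_than")
  expect_equal(rows$ba[rows$optimal], 100)

  # constant scores: every call is all-positive or all-negative
  rows2 <- threshold_sweep(rep(5, 20), rep(c(TRUE, FALSE), 10),
                           c(0, 5, 10), "less_than")
  expect_equal(rows2$sensitivity + rows2$specificity, rep(100, 3))

  expect_error(threshold_sweep(1:5, rep(TRUE, 5), c(2, 3)), "single class")
})

test_that("optimal venous attenuation threshold is stable across simulation seeds", {
  optima <- vapply(c(101, 202, 303), function(seed) {
    cfg <- cohort_sim_config(10000, phases = c("non-contrast", "venous"),
                             seed = seed)
    cohort <- simulate_cohort(cfg)
    ven <- cohort[cohort$phase == "venous", ]
    rows <- threshold_sweep(ven$liver_hu, ven$steatosis_truth,
                            seq(40, 100, by = 5), "less_than")
    rows$threshold[rows$optimal]
  }, numeric(1))
  expect_lte(max(optima) - min(optima), 5)   # within one 5-HU grid step
})

test_that("trapezoidal AUROC equals pairwise concordance, including ties", {
  expect_equal(roc_auc(rep(3, 10), rep(c(TRUE, FALSE), 5))$auroc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auroc,
               0.75)
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c(F, F, F, T, T))$auroc, 1)

  for (s in 1:100) {
    set.seed(s)
    n <- sample(8:25, 1)
    scores <- sample(1:6, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    truth <- runif(n) < 0.5
    if (sum(truth) == 0 || sum(!truth) == 0) next
    expect_equal(roc_auc(scores, truth)$auroc, oracle_concordance(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms and direction-aware", {
  set.seed(31)
  scores <- rnorm(60)
  truth <- runif(60) < 0.4
  base <- roc_auc(scores, truth)$auroc
  expect_equal(roc_auc(exp(scores), truth)$auroc, base)
  expect_equal(roc_auc(qnorm(pnorm(scores))^3 + scores, truth)$auroc, base)
  # attenuation-like orientation: negation and direction = "less" agree
  expect_equal(roc_auc(-scores, truth, direction = "less")$auroc, base)
})

test_that("DeLong comparison is exact for identical scores and matches resampling", {
  set.seed(8)
  n <- 150
  z <- rnorm(n)
  truth <- runif(n) < plogis(1.5 * z)
  scores_a <- z + rnorm(n, 0, 0.8)
  scores_b <- 0.6 * z + rnorm(n, 0, 1)

  same <- delong_compare(scores_a, scores_a, truth)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  res <- delong_compare(scores_a, scores_b, truth)
  boot <- bootstrap_var_auc_diff(scores_a, scores_b, truth, B = 2000, seed = 99)
  expect_lt(abs(res$var_diff - boot) / boot, 0.10)
})

test_that("DeLong z and p agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  n <- 200
  z <- rnorm(n)
  truth <- runif(n) < plogis(z)
  scores_a <- z + rnorm(n)
  scores_b <- 0.5 * z + rnorm(n)
  res <- delong_compare(scores_a, scores_b, truth)
  ref <- pROC::roc.test(
    pROC::roc(truth, scores_a, direction = "<", quiet = TRUE),
    pROC::roc(truth, scores_b, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE
  )
  expect_equal(abs(res$z), abs(unname(ref$statistic)), tolerance = 1e-9)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong test rejects reliably for a strong-vs-weak marker at n = 2000", {
  rejections <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 2000
    truth <- runif(n) < 0.3
    strong <- ifelse(truth, rnorm(n, 1.0), rnorm(n, 0))
    weak <- ifelse(truth, rnorm(n, 0.45), rnorm(n, 0))
    delong_compare(strong, weak, truth)$p_value < 0.01
  }, logical(1))
  expect_gt(mean(rejections), 0.9)
})

test_that("Spearman correlation handles exact ranks, ties and guards", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$r, 0.8)
  expect_error(spearman_cor(rep(2, 5), 1:5), "constant")

  # midranks: agreement with cor() on ranked data under ties
  set.seed(3)
  x <- sample(1:5, 30, replace = TRUE)
  y <- x + sample(0:2, 30, replace = TRUE)
  expect_equal(spearman_cor(x, y)$r,
               cor(x, y, method = "spearman"))
})

test_that("ROI and volumetric means correlate strongly across a phantom batch", {
  # shared per-subject signal, independent measurement noise for each method
  n_subj <- 200
  roi_vals <- numeric(n_subj)
  vol_vals <- numeric(n_subj)
  for (i in seq_len(n_subj)) {
    true_hu <- 55 - (i %% 20) * 1.5            # spread of subject liver values
    cfg <- phantom_config(
      grid_shape = c(24, 24, 16),
      liver_ellipsoid = list(center = c(9, 12, 8), semiaxes = c(6, 8, 6)),
      spleen_ellipsoid = list(center = c(19, 12, 8), semiaxes = c(3, 4, 5)),
      liver_hu = true_hu, spleen_hu = 45, texture_sd = 8, seed = 1000 + i
    )
    vol <- simulate_phantom(cfg)
    vol_vals[i] <- masked_mean(vol, 1L)$mean_hu
    roi_vals[i] <- roi_mean(vol, list(roi_spec(c(9, 12, 8), 2.5)))$mean_hu
  }
  res <- spearman_cor(roi_vals, vol_vals)
  expect_gt(res$r, 0.9)
  expect_lt(res$p_value, 1e-6)
})
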