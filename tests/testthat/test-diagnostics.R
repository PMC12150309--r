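test_that("STP curation keeps one suspected sample per subject with the right priority", {
  md <- data.frame(
    sample_id = sprintf("S%02d", 1:9),
    subject_id = c("A", "A", "B", "B", "C", "C", "D", "E", "E"),
    group = c("sepsis", "sepsis", "SINS", "sepsis", "control", "SINS",
              "control", "SINS", "SINS"),
    is_followup = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    episode_index = c(1, 1, 1, 2, 0, 1, 0, 1, 1),
    postnatal_age = c(10, 11, 5, 20, 8, 9, 12, 3, 4),
    stringsAsFactors = FALSE)
  expect_warning(sel <- curate_stp(md), "'E'")
  # A: suspected sepsis sample only (follow-up dropped)
  expect_true("S01" %in% sel); expect_false("S02" %in% sel)
  # B: sepsis episode outranks the earlier SINS episode
  expect_true("S04" %in% sel); expect_false("S03" %in% sel)
  # C had a SINS episode, so is not control-eligible
  expect_false("S05" %in% sel)
  # D is a clean control
  expect_true("S07" %in% sel)
  # E has only follow-ups -> excluded with a warning
  expect_false(any(c("S08", "S09") %in% sel))
})

test_that("univariate logistic regression is calibrated, symmetric and powered", {
  y <- rep(c(0, 1), each = 30)
  x0 <- rep(1:30, 2)                       # identical distribution in both arms
  r0 <- univariate_logistic(x0, y)
  expect_lt(abs(r0$estimate), 1e-8)
  expect_gt(r0$p, 0.99)
  x <- withr::with_seed(5, stats::rnorm(60) + y)
  r1 <- univariate_logistic(x, y)
  r2 <- univariate_logistic(x, 1 - y)
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  hits <- vapply(1:10, function(s) {
    xs <- withr::with_seed(s, stats::rnorm(200) + rep(c(0, 1), each = 100))
    univariate_logistic(xs, rep(c(0, 1), each = 100))$p < 0.001
  }, logical(1))
  expect_gte(sum(hits), 9)
  sep <- univariate_logistic(c(stats::rnorm(20), stats::rnorm(20) + 50),
                             rep(c(0, 1), each = 20))
  expect_equal(sep$flag, "separation")
})

test_that("bootstrap LASSO is seeded, calibrated on noise, and finds planted signal", {
  y <- rep(c(0, 1), each = 30)
  X0 <- withr::with_seed(1, matrix(stats::rnorm(60 * 30), 60, 30,
                                   dimnames = list(NULL, sprintf("F%02d", 1:30))))
  b1 <- bootstrap_lasso(X0, y, B = 60, seed = 42)
  b2 <- bootstrap_lasso(X0, y, B = 60, seed = 42)
  expect_identical(b1, b2)
  # null calibration in expectation over data sets (a single finite data set
  # carries chance associations that OOB evaluation inherits)
  null_aucs <- vapply(1:6, function(s) {
    Xn <- withr::with_seed(200 + s, matrix(stats::rnorm(60 * 30), 60, 30,
                                           dimnames = list(NULL, sprintf("F%02d", 1:30))))
    bootstrap_lasso(Xn, y, B = 30, seed = s)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)
  Xs <- X0; Xs[, 1] <- Xs[, 1] + 1.5 * y
  bs <- bootstrap_lasso(Xs, y, B = 60, seed = 43)
  expect_gt(bs$selection_freq[["F01"]], 0.9)
  expect_gt(bs$mean_auc, 0.7)
  expect_error(bootstrap_lasso(X0[1:8, ], y[c(1:4, 31:34)], B = 10), ">= 5")
})

test_that("panel selection is strictly greater-than the threshold", {
  freqs <- c(a = 0.46, b = 0.45, c = 0.44)
  expect_identical(select_panel(freqs, 0.45), "a")
  expect_warning(empty <- select_panel(c(a = 0, b = 0), 0.45), "empty")
  expect_length(empty, 0)
  expect_setequal(select_panel(c(a = 0.1, b = 0, c = 0.9), 0), c("a", "c"))
})

test_that("LOOCV evaluation is exact on separable data and null on permuted labels", {
  y <- rep(c(0, 1), each = 20)
  x <- c(stats::rnorm(20), stats::rnorm(20) + 10)
  pm <- loocv_evaluate(cbind(marker = x), y)
  expect_equal(pm$auc, 1)
  expect_equal(pm$sensitivity, 1)
  expect_equal(pm$specificity, 1)
  withr::with_seed(9, {
    Xn <- matrix(stats::rnorm(200 * 3), 200, 3)
    yn <- sample(rep(c(0, 1), each = 100))
  })
  null <- loocv_evaluate(Xn, yn)
  expect_lt(abs(null$auc - 0.5), 0.1)
  expect_true(all(null$predictions >= 0 & null$predictions <= 1))
})

test_that("McNemar comparisons use the exact branch symmetrically", {
  # b = 1, c = 9: two-sided exact binomial, 2 * P(X <= 1 | n = 10)
  y <- rep(1, 10)
  pa <- c(1, rep(0, 9)); pb <- c(0, rep(1, 9))
  res <- compare_models_mcnemar(pa, pb, y)
  expect_equal(res$method, "exact")
  expect_equal(res$b, 1); expect_equal(res$c, 9)
  expect_equal(res$p, 0.021484375)
  swapped <- compare_models_mcnemar(pb, pa, y)
  expect_equal(swapped$p, res$p)
  tie <- compare_models_mcnemar(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(tie$p, 1)
  same <- compare_models_mcnemar(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(same$p, 1)
})

test_that("the diagnostic framework reports all nine model variants deterministically", {
  sim <- simulate_dataset(
    cspec = cohort_spec(n_subjects = 120, group_probs = c(0.2, 0.35, 0.45), seed = 33),
    espec = effect_spec(n_features = 40, n_measured = 40,
                        class_counts = c(sepsis_specific = 5),
                        effect_range = 1.2, effect_sign = "up",
                        censor_quantile = 0.05, seed = 34),
    mspec = marker_spec(seed = 35), seed = 33)
  ds <- preprocess(sim$features, sim$qc, sim$blanks, sim$metadata, seed = 36)
  md <- sim$metadata
  stp <- curate_stp(md)
  sub <- list(scaled = ds$scaled[ds$scaled$sample_id %in% stp, ],
              imputed = ds$imputed[ds$imputed$sample_id %in% stp, ])
  md_stp <- md[md$sample_id %in% stp, ]
  rep1 <- run_diagnostics(sub, md_stp, B = 40, seed = 7)
  expect_setequal(names(rep1$models),
                  c("panel", "IL6", "CRP", "PCT", "all_markers",
                    "panel_IL6", "panel_CRP", "panel_PCT", "panel_all_markers"))
  rep2 <- run_diagnostics(sub, md_stp, B = 40, seed = 7)
  expect_identical(rep1$summary, rep2$summary)
  expect_true(all(rep1$comparisons$model_a == "panel"))
  expect_equal(nrow(rep1$comparisons), 8)
  expect_true(all(rep1$univariate$q >= rep1$univariate$p, na.rm = TRUE))
  # label shuffling destroys every model's discrimination
  md_perm <- md_stp
  md_perm$group <- withr::with_seed(11, sample(md_perm$group))
  if (min(table(md_perm$group[md_perm$group != "control"])) >= 5) {
    rep_perm <- suppressWarnings(run_diagnostics(sub, md_perm, B = 40, seed = 7))
    expect_true(all(rep_perm$summary$auc <= 0.75))
  }
})
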