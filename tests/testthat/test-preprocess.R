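test_that("QC metrics match direct arithmetic", {
  samples <- mat_ft(matrix(c(1, 2, NA, 4), 4, 1))
  qc <- mat_ft(matrix(c(1, 1, 1, 2), 4, 1), ids = sprintf("QC%d", 1:4))
  blanks <- mat_ft(matrix(c(0.5, 0.5), 2, 1), ids = c("BL1", "BL2"))
  rep <- compute_feature_qc(samples, qc, blanks)
  expect_equal(rep$rsd_pct, 100 * 0.5 / 1.25)      # mean 1.25, sd 0.5 -> 40%
  expect_equal(rep$blank_pct, 100 * 0.5 / 1.25)
  expect_equal(rep$missing_pct, 25)
})

test_that("feature filtering uses strict inequalities at the thresholds", {
  rep <- data.frame(feature = c("a", "b", "c", "d"),
                    rsd_pct = c(29.99, 30, 10, 10),
                    blank_pct = c(39.99, 10, 40, 10),
                    missing_pct = c(19.99, 10, 10, 20),
                    zero_qc_mean = FALSE, pass_rsd = NA, pass_blank = NA,
                    pass_missing = NA, pass = NA, stringsAsFactors = FALSE)
  out <- filter_features(rep, qc_thresholds())
  expect_identical(attr(out, "retained"), "a")
  expect_identical(out$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(out, "n_retained") + attr(out, "n_removed"), 4)
})

test_that("planted QC violators are exactly the features removed", {
  sim <- simulate_dataset(
    cspec = cohort_spec(n_subjects = 80, seed = 3),
    espec = effect_spec(n_features = 60, n_measured = 60,
                        class_counts = c(null = 0), censor_quantile = 0.05,
                        qc_violators = c(high_cv = 10, high_blank = 10,
                                         high_missing = 10), seed = 4),
    mspec = marker_spec(), n_qc = 20, seed = 3)
  rep <- filter_features(compute_feature_qc(sim$features, sim$qc, sim$blanks))
  removed <- rep$feature[!rep$pass]
  planted <- sim$truth$feature_info$feature[sim$truth$feature_info$viol_kind != "none"]
  expect_setequal(removed, planted)
})

test_that("the Rosner test flags a gross outlier and respects its level", {
  # reference generalized-ESD arithmetic for x = (1, 2, 3, 100), k = 1
  x <- c(1, 2, 3, 100)
  R1 <- max(abs(x - mean(x))) / stats::sd(x)
  t1 <- stats::qt(1 - 0.05 / (2 * 4), 2)
  lam1 <- 3 * t1 / sqrt((2 + t1^2) * 4)
  expect_true(R1 > lam1)                           # the oracle itself detects it
  rt <- rosner_test(x, alpha = 0.05, kmax = 1)
  expect_equal(rt$n_outliers, 1L)
  expect_equal(rt$outlier_index, 4L)
  expect_equal(rt$stats$R[1], R1)
  expect_equal(rt$stats$lambda[1], lam1)
  # null level: clean standard-normal samples rarely yield any outlier
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, rosner_test(stats::rnorm(200), kmax = 5)$n_outliers > 0)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
  expect_warning(out <- rosner_test(rep(5, 30)), "constant")
  expect_equal(out$n_outliers, 0L)
})

test_that("planted internal-standard outliers are recovered end to end", {
  sim <- tiny_sim(seed = 77, n_subjects = 120, n_is_outliers = 4,
                  is_outlier_shift = 1)
  flagged <- detect_outlier_samples(
    stats::setNames(sim$metadata$is_log_mean, sim$metadata$sample_id))
  expect_setequal(flagged, sim$metadata$sample_id[sim$metadata$is_outlier_true])
})

test_that("derived features follow ratio/sum/mean semantics on the linear scale", {
  M <- cbind(A = c(2, 3, NA, 4), B = c(2, 3, 1, 0), C = c(4, 3, 1, 2))
  raw <- mat_ft(M)
  rec <- list(feature_recipe("A_over_B", "ratio", c("A", "B")),
              feature_recipe("BplusC", "sum", c("B", "C")),
              feature_recipe("BC_mean", "mean", c("B", "C")))
  drv <- derive_features(raw, rec)
  D <- ft_matrix(drv)
  expect_equal(unname(D[1:2, "A_over_B"]), c(1, 1))
  expect_true(is.na(D[3, "A_over_B"]))             # missing operand
  expect_true(is.na(D[4, "A_over_B"]))             # zero denominator
  expect_equal(unname(D[, "BplusC"]), c(6, 6, 2, 2))
  expect_equal(unname(D[, "BC_mean"]), c(3, 3, 1, 1))
  expect_error(derive_features(raw, list(feature_recipe("bad", "sum", c("A", "Z")))),
               "bad")
  expect_error(feature_recipe("r", "ratio", c("A", "B", "C")), "exactly 2")
})

test_that("log2 transform handles missing values and rejects nonpositives", {
  raw <- mat_ft(cbind(x = c(8, 1, NA)))
  out <- ft_matrix(log2_transform(raw))
  expect_equal(unname(out[1:2, 1]), c(3, 0))
  expect_true(is.na(out[3, 1]))
  expect_error(log2_transform(mat_ft(cbind(x = c(1, 0)))), "nonpositive")
})

test_that("QRILC recovers the censored-normal parameters and respects truncation", {
  mu_err <- sd_err <- numeric(20)
  for (s in 1:20) {
    y <- withr::with_seed(s, stats::rnorm(300, 10, 2))
    thr <- stats::quantile(y, 0.2)
    yc <- ifelse(y < thr, NA, y)
    tab <- mat_ft(matrix(yc, nrow = 1), ids = "S1")   # one sample, 300 features
    imp <- qrilc_impute(tab, seed = s)
    mu_err[s] <- imp$params$mu[1] - 10
    sd_err[s] <- imp$params$sigma[1] - 2
    # imputed values stay below the fitted truncation limit
    lim <- imp$params$mu[1] + imp$params$sigma[1] * stats::qnorm(imp$params$missing_frac[1])
    expect_true(all(ft_matrix(imp$table)[1, is.na(yc)] <= lim + 1e-12))
    # observed values preserved bitwise
    expect_identical(ft_matrix(imp$table)[1, !is.na(yc)], ft_matrix(tab)[1, !is.na(yc)])
  }
  expect_lt(abs(mean(mu_err)), 0.15)
  expect_lt(abs(mean(sd_err)), 0.3)
})

test_that("QRILC leaves complete tables untouched and beats minimum imputation on average", {
  full <- mat_ft(matrix(stats::rnorm(200, 5), 4, 50))
  expect_identical(qrilc_impute(full, seed = 1)$table, full)
  mae_qrilc <- mae_min <- numeric(50)
  for (s in 1:50) {
    y <- withr::with_seed(100 + s, stats::rnorm(200, 10, 2))
    thr <- stats::quantile(y, 0.2)
    yc <- ifelse(y < thr, NA, y)
    tab <- mat_ft(matrix(yc, nrow = 1), ids = "S1")
    imp <- ft_matrix(qrilc_impute(tab, seed = s)$table)[1, ]
    m <- is.na(yc)
    mae_qrilc[s] <- mean(abs(imp[m] - y[m]))
    mae_min[s] <- mean(abs(min(yc, na.rm = TRUE) - y[m]))
  }
  expect_lt(mean(mae_qrilc), mean(mae_min))
})

test_that("autoscaling centres and scales exactly, and is idempotent", {
  M <- matrix(stats::rnorm(600, 7, 3), 30, 20)
  sc <- autoscale(mat_ft(M))
  Z <- ft_matrix(sc$table)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, stats::sd) - 1) < 1e-9))
  again <- ft_matrix(autoscale(sc$table)$table)
  expect_true(all(abs(again - Z) < 1e-9))
  two <- autoscale(mat_ft(matrix(c(0, 2), 2, 1)))
  expect_equal(unname(ft_matrix(two$table)[, 1]), c(-1, 1) / sqrt(2))
  expect_error(autoscale(mat_ft(matrix(1, 5, 1))), "constant")
})

test_that("the preprocessing pipeline chains stages with consistent accounting", {
  sim <- tiny_sim(seed = 19, n_subjects = 80, n_is_outliers = 3,
                  is_outlier_shift = 1)
  rec <- list(feature_recipe("M1_over_M2", "ratio", c("M001", "M002")))
  ds <- preprocess(sim$features, sim$qc, sim$blanks, sim$metadata,
                   recipes = rec, seed = 2)
  expect_s3_class(ds, "processed_dataset")
  acc <- ds$accounting
  expect_equal(acc$n_features[1], ncol(sim$features) - 1L)
  expect_equal(acc$n_features[2], attr(ds$qc_report, "n_retained"))
  expect_equal(acc$n_samples[3], acc$n_samples[1] - length(ds$outlier_samples))
  # imputation preserved all observed log2 values bitwise
  L <- ft_matrix(ds$log2); I <- ft_matrix(ds$imputed)
  obs <- !is.na(L)
  expect_identical(I[obs], L[obs])
  # scaled table is complete with unit variance
  Z <- ft_matrix(ds$scaled)
  expect_false(anyNA(Z))
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  # derived ratio equals difference of log2 values
  expect_equal(unname(L[, "M1_over_M2"]),
               unname(L[, "M001"] - L[, "M002"]))
})
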