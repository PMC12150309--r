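# Helper: processed-dataset stand-in from an abundance matrix (already log2).
ds_from_log2 <- function(tab) {
  list(scaled = autoscale(tab)$table, imputed = tab)
}

test_that("contrast specifications encode the five models", {
  inf <- contrast_spec("Inflamed")
  expect_setequal(inf$coded1, c("SINS", "sepsis"))
  expect_setequal(inf$groups, c("control", "SINS", "sepsis"))
  expect_equal(contrast_spec("SINS_S")$coded1, "sepsis")
  expect_setequal(contrast_spec("C_SINS")$groups, c("control", "SINS"))
  expect_error(contrast_spec("bogus"))
})

test_that("confounder identification finds planted associations and skips noise", {
  md <- generate_cohort(cohort_spec(n_subjects = 200, seed = 5))
  load <- matrix(0, 60, 5, dimnames = list(NULL, NULL))
  load[1:50, 1] <- 0.5                      # gestational age drives 50 features
  es <- effect_spec(n_features = 60, n_measured = 60, class_counts = c(null = 0),
                    confounder_loadings = load, censor_quantile = 0, seed = 6)
  ab <- generate_abundances(md, es)
  sc <- autoscale(ab$features)$table
  md$noise_cov <- withr::with_seed(1, stats::rnorm(nrow(md)))
  covs <- c(gestational_age = "continuous", noise_cov = "continuous",
            mechanical_ventilation = "categorical")
  cs <- identify_confounders(md, sc, covariates = covs)
  expect_true("gestational_age" %in% cs$covariates)
  d <- cs$detail
  expect_true(d$metabolome_associated[d$covariate == "gestational_age"])
  # mechanical ventilation is generated with a sepsis-dependent prevalence
  expect_true(d$outcome_associated[d$covariate == "mechanical_ventilation"])
  # a pure-noise covariate stays out in most seeded replicates
  hits <- vapply(1:10, function(s) {
    md$noise_cov <- withr::with_seed(100 + s, stats::rnorm(nrow(md)))
    cs2 <- identify_confounders(md, sc,
                                covariates = c(noise_cov = "continuous"))
    "noise_cov" %in% cs2$covariates
  }, logical(1))
  expect_gte(mean(!hits), 0.6)              # 6 tests per covariate at alpha 0.05
})

test_that("a single-feature screen returns q = p", {
  md <- generate_cohort(cohort_spec(n_subjects = 50, seed = 7))
  es <- effect_spec(n_features = 1, n_measured = 1, class_counts = c(null = 0),
                    censor_quantile = 0, seed = 8)
  tab <- generate_abundances(md, es)$features
  res <- run_screen(ds_from_log2(tab), md, "Sepsis")
  expect_equal(nrow(res), 1)
  expect_equal(res$q, res$p)
  expect_equal(res$directed_p, -log10(res$p) * sign(res$estimate))
})

test_that("planted effects are recovered at q < 0.1 and nulls are controlled", {
  md <- generate_cohort(cohort_spec(n_subjects = 150, seed = 9))
  es <- effect_spec(n_features = 100, n_measured = 100,
                    class_counts = c(sepsis_specific = 10),
                    effect_range = 0.8, effect_sign = "up",
                    censor_quantile = 0, seed = 10)
  ab <- generate_abundances(md, es)
  res <- run_screen(ds_from_log2(ab$features), md, "Sepsis")
  planted <- ab$truth$feature_info$class == "sepsis_specific"
  expect_gte(sum(res$q[planted] < 0.1), 8)
  expect_lte(sum(res$q[!planted] < 0.1), 3)
  # directional consistency between Sepsis, C_S and SINS_S for planted features
  for (cn in c("C_S", "SINS_S")) {
    r2 <- run_screen(ds_from_log2(ab$features), md, cn)
    expect_gte(mean(sign(r2$estimate[planted]) == sign(res$estimate[planted])), 0.95)
  }
})

test_that("confounder adjustment restores the nominal level", {
  withr::with_seed(14, {
    n <- 400
    grp <- rep(c("control", "sepsis"), each = n / 2)
    md <- toy_metadata(grp)
    # a confounder strongly tied to group membership drives all features
    md$oxygen_pct <- 30 + 10 * (grp == "sepsis") + stats::rnorm(n, 0, 5)
    Y <- matrix(stats::rnorm(n * 60), n, 60) + 0.1 * md$oxygen_pct
    tab <- mat_ft(Y, ids = md$sample_id)
    ds <- ds_from_log2(tab)
    raw <- run_screen(ds, md, "C_S")
    adj <- run_screen(ds, md, "C_S", confounders = "oxygen_pct")
    expect_gt(mean(raw$p < 0.05), 0.5)       # omitted confounder inflates hits
    expect_lt(mean(adj$p < 0.05), 0.15)      # adjustment restores the level
  })
})

test_that("stratified screens isolate sex-specific effects and drop the stratum", {
  md <- generate_cohort(cohort_spec(n_subjects = 250, seed = 15))
  es <- effect_spec(n_features = 40, n_measured = 40,
                    class_counts = c(sex_specific = 6),
                    effect_range = 1.0, effect_sign = "up",
                    censor_quantile = 0, seed = 16)
  ab <- generate_abundances(md, es)
  ds <- ds_from_log2(ab$features)
  male <- stratified_screen(ds, md, "sex", "male",
                            confounders = c("sex", "gestational_age"))
  female <- stratified_screen(ds, md, "sex", "female",
                              confounders = c("sex", "gestational_age"))
  expect_false("sex" %in% attr(male, "confounders"))
  planted <- ab$truth$feature_info$class == "sex_specific"
  expect_gte(sum(male$q[planted] < 0.1), 4)
  expect_lte(sum(female$q[planted] < 0.1), 2)
  expect_error(stratified_screen(ds, md, "pathogen_type", "viral"), "viral")
})

test_that("trend classification follows the compact-letter rules", {
  row <- function(est, p) data.frame(estimate = est, p = p)
  means_up <- c(control = 0, SINS = 0.5, sepsis = 1)
  expect_equal(classify_trend(row(0.5, 0.01), row(0.9, 0.001), row(0.4, 0.5),
                              means_up), "shared_inflammation")
  expect_equal(classify_trend(row(0.5, 0.01), row(1, 0.001), row(0.5, 0.01),
                              means_up), "progressive_up")
  expect_equal(classify_trend(row(-0.5, 0.01), row(-1, 0.001), row(-0.5, 0.01),
                              c(control = 1, SINS = 0.5, sepsis = 0)),
               "progressive_down")
  expect_equal(classify_trend(row(0.1, 0.8), row(0.9, 0.001), row(0.8, 0.01),
                              c(control = 0, SINS = 0, sepsis = 1)),
               "sepsis_specific")
  expect_equal(classify_trend(row(0.8, 0.01), row(0.1, 0.9), row(-0.7, 0.02),
                              c(control = 0, SINS = 0.8, sepsis = 0.1)),
               "sins_specific")
  expect_equal(classify_trend(row(0.8, 0.01), row(0.1, 0.9), row(0.1, 1),
                              c(control = 0, SINS = 0.8, sepsis = 0.6)),
               "sins_specific")
  expect_equal(classify_trend(row(0, 1), row(0, 1), row(0, 1), means_up),
               "unclassified")
  expect_equal(classify_trend(row(NA, NA), row(0, 0.01), row(0, 1), means_up),
               "unclassified")
})
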