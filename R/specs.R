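#' Cohort specification for the synthetic-data generator
#'
#' Describes a preterm-neonate study cohort: how many subjects, how they split
#' into control / SINS (systemic inflammation, no sepsis) / sepsis, how often a
#' suspected episode contributes a follow-up sample 6-48 h later, and the
#' distributions of the ten clinical confounders carried by every sample.
#' Defaults emulate the comprehensive data set of a single-centre cohort of
#' 94 preterm neonates (gestational age 24-32 weeks): roughly 86 control, 56
#' SINS and 85 sepsis samples, with sepsis blood cultures split
#' culture-negative / gram-positive / gram-negative at 42:29:14.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param group_probs Probabilities over \code{c(control, SINS, sepsis)}.
#' @param followup_prob Probability that a SINS/sepsis subject contributes one
#'   follow-up sample carrying the same group label.
#' @param male_prob Probability a subject is male.
#' @param sepsis_culture_probs Probabilities over
#'   \code{c(culture_negative, gram_positive, gram_negative)} for sepsis cases.
#' @param confounder_dists Named list of distribution parameters; see defaults.
#'   Continuous covariates are \code{c(mean, sd)}; binary covariates a single
#'   Bernoulli probability. \code{mechanical_ventilation} and \code{ivh} take
#'   \code{c(base, logit_shift)}: prevalence among controls and the logit shift
#'   applied to sepsis subjects (half of it to SINS), reflecting their
#'   association with sepsis outcome.
#' @param n_is_outliers Number of samples given a shifted internal-standard
#'   summary (to exercise Rosner outlier detection).
#' @param is_outlier_shift Size of that shift (log units).
#' @param is_noise_sd SD of the per-sample internal-standard summary.
#' @param seed RNG seed used by [generate_cohort()].
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 180,
                        group_probs = c(control = 0.48, SINS = 0.21, sepsis = 0.31),
                        followup_prob = 0.5,
                        male_prob = 0.5991,
                        sepsis_culture_probs = c(culture_negative = 42, gram_positive = 29,
                                                 gram_negative = 14) / 85,
                        confounder_dists = list(
                          gestational_age = c(mean = 26.67, sd = 2.07),
                          birthweight = c(mean = 891.9, sd = 279.45),
                          postnatal_age = c(mean = 21.19, sd = 18.45),
                          tpn_proportion = c(mean = 0.38, sd = 0.38),
                          oxygen_pct = c(mean = 30.13, sd = 14.33),
                          sample_source_artery = 0.2247,
                          mechanical_ventilation = c(base = 0.33, logit_shift = 1.3),
                          ivh = c(base = 0.17, logit_shift = 1.25),
                          antibiotics_24h = 0.30),
                        n_is_outliers = 0,
                        is_outlier_shift = 0.6,
                        is_noise_sd = 0.05,
                        seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 3)
    config_error("n_subjects", "must be a single count >= 3")
  check_prob_vector(group_probs, "group_probs", 3L)
  check_prob_scalar(followup_prob, "followup_prob")
  check_prob_scalar(male_prob, "male_prob")
  check_prob_vector(sepsis_culture_probs, "sepsis_culture_probs", 3L)
  for (nm in c("gestational_age", "birthweight", "postnatal_age",
               "tpn_proportion", "oxygen_pct")) {
    d <- confounder_dists[[nm]]
    if (is.null(d) || length(d) != 2L || !is.finite(d[2]) || d[2] <= 0)
      config_error(paste0("confounder_dists$", nm), "must be c(mean, sd) with sd > 0")
  }
  check_prob_scalar(confounder_dists$sample_source_artery, "confounder_dists$sample_source_artery")
  check_prob_scalar(confounder_dists$antibiotics_24h, "confounder_dists$antibiotics_24h")
  for (nm in c("mechanical_ventilation", "ivh")) {
    d <- confounder_dists[[nm]]
    if (is.null(d) || length(d) != 2L)
      config_error(paste0("confounder_dists$", nm), "must be c(base, logit_shift)")
    check_prob_scalar(d[[1]], paste0("confounder_dists$", nm, "[base]"))
  }
  if (is_noise_sd <= 0) config_error("is_noise_sd", "must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 group_probs = unname(group_probs),
                 followup_prob = followup_prob, male_prob = male_prob,
                 sepsis_culture_probs = unname(sepsis_culture_probs),
                 confounder_dists = confounder_dists,
                 n_is_outliers = as.integer(n_is_outliers),
                 is_outlier_shift = is_outlier_shift,
                 is_noise_sd = is_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Effect specification for synthetic abundance generation
#'
#' Defines how many metabolic features to simulate, which differential-effect
#' class each belongs to, and the variance structure of the underlying linear
#' mixed model: a subject random intercept with intraclass correlation
#' \code{subject_icc}, residual SD \code{residual_sd} on the log2 scale, and
#' group effects expressed in residual-SD units (drawn from
#' \code{effect_range}, matching the 0.3-1.0 magnitude of typical model
#' estimates on autoscaled data).
#'
#' @param n_features Number of analysis features (measured + derived slots).
#' @param n_measured Number of those flagged as directly measured.
#' @param class_counts Named counts per differential class (see
#'   \code{FEATURE_CLASSES}); features not covered are null. Alternatively pass
#'   \code{feature_classes}, a full per-feature character vector.
#' @param feature_classes Optional explicit class per feature.
#' @param effect_range Range (residual-SD units) for effect magnitudes; a
#'   single value fixes all magnitudes.
#' @param effect_sign \code{"random"}, \code{"up"} or \code{"down"}.
#' @param confounder_loadings Optional matrix (features x continuous
#'   confounders) of per-SD loadings; default all zero.
#' @param subject_icc Intraclass correlation of the subject intercept.
#' @param residual_sd Within-subject residual SD (log2 scale).
#' @param technical_cv Relative SD of pooled-QC replicates (linear scale).
#' @param blank_fraction Method-blank signal as a fraction of the QC mean.
#' @param censor_quantile Left-censoring quantile per feature (scalar or
#'   vector, each in [0, 0.5]).
#' @param qc_violators Named counts \code{c(high_cv, high_blank, high_missing)}
#'   of extra planted features violating each QC rule (appended to the table,
#'   expected to be removed by filtering).
#' @param violator_values Parameter values given to planted violators.
#' @param seed RNG seed used by [generate_abundances()].
#' @return An object of class \code{effect_spec}.
#' @export
effect_spec <- function(n_features = 296,
                        n_measured = 254,
                        class_counts = c(shared_inflammation = 30, progressive = 20,
                                         sepsis_specific = 20, sins_specific = 6,
                                         sex_specific = 10, pathogen_specific = 10),
                        feature_classes = NULL,
                        effect_range = c(0.3, 1.0),
                        effect_sign = c("random", "up", "down"),
                        confounder_loadings = NULL,
                        subject_icc = 0.4,
                        residual_sd = 1,
                        technical_cv = 0.1,
                        blank_fraction = 0.05,
                        censor_quantile = 0.1,
                        qc_violators = c(high_cv = 0, high_blank = 0, high_missing = 0),
                        violator_values = c(cv = 0.5, blank = 0.8, missing = 0.4),
                        seed = 1L) {
  effect_sign <- match.arg(effect_sign)
  if (n_features < 1) config_error("n_features", "must be >= 1")
  if (n_measured > n_features) config_error("n_measured", "cannot exceed n_features")
  if (subject_icc < 0 || subject_icc >= 1)
    config_error("subject_icc", "must satisfy 0 <= icc < 1")
  if (residual_sd <= 0) config_error("residual_sd", "must be > 0")
  if (any(censor_quantile < 0) || any(censor_quantile > 0.5))
    config_error("censor_quantile", "must lie in [0, 0.5]")
  if (length(effect_range) == 1L) effect_range <- rep(effect_range, 2L)
  if (any(!is.finite(effect_range)) || any(effect_range < 0))
    config_error("effect_range", "must be finite and nonnegative")
  if (is.null(feature_classes)) {
    if (is.null(names(class_counts)) ||
        !all(names(class_counts) %in% FEATURE_CLASSES))
      config_error("class_counts", "has unknown class names")
    if (sum(class_counts) > n_features)
      config_error("class_counts", "sums to more than n_features")
    feature_classes <- rep("null", n_features)
    idx <- 1L
    for (cl in names(class_counts)) {
      k <- class_counts[[cl]]
      if (k > 0) {
        feature_classes[idx:(idx + k - 1L)] <- cl
        idx <- idx + k
      }
    }
  } else {
    if (length(feature_classes) != n_features)
      config_error("feature_classes", "must have length n_features")
    if (!all(feature_classes %in% FEATURE_CLASSES))
      config_error("feature_classes", "has unknown class names")
  }
  qv <- c(high_cv = 0, high_blank = 0, high_missing = 0)
  qv[names(qc_violators)] <- qc_violators
  structure(list(n_features = as.integer(n_features),
                 n_measured = as.integer(n_measured),
                 feature_classes = feature_classes,
                 effect_range = effect_range, effect_sign = effect_sign,
                 confounder_loadings = confounder_loadings,
                 subject_icc = subject_icc, residual_sd = residual_sd,
                 technical_cv = technical_cv, blank_fraction = blank_fraction,
                 censor_quantile = censor_quantile,
                 qc_violators = qv, violator_values = violator_values,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Inflammatory-marker specification
#'
#' IL-6, CRP and PCT are simulated on a log scale as weakly discriminative
#' markers: a clear shift between non-inflamed and inflamed samples and a small
#' SINS-to-sepsis shift (in noise-SD units). Default sepsis shifts give
#' binormal SINS-vs-sepsis AUCs of about 0.53-0.59, the limited diagnostic
#' range typical of routine markers at the moment of suspicion.
#'
#' @param inflam_shift Named shifts (inflamed vs control) per marker.
#' @param sepsis_shift Named shifts (sepsis vs SINS) per marker.
#' @param noise_sd Residual SD of each marker (> 0).
#' @param seed RNG seed used by [generate_markers()].
#' @return An object of class \code{marker_spec}.
#' @export
marker_spec <- function(inflam_shift = c(IL6 = 1.0, CRP = 1.0, PCT = 1.0),
                        sepsis_shift = c(IL6 = 0.32, CRP = 0.10, PCT = 0.18),
                        noise_sd = 1,
                        seed = 1L) {
  if (noise_sd <= 0) config_error("noise_sd", "must be > 0")
  mk <- c("IL6", "CRP", "PCT")
  if (!all(mk %in% names(inflam_shift)) || !all(mk %in% names(sepsis_shift)))
    config_error("inflam_shift/sepsis_shift", "must name IL6, CRP and PCT")
  structure(list(inflam_shift = inflam_shift[mk], sepsis_shift = sepsis_shift[mk],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "marker_spec")
}

#' Quality-control thresholds
#'
#' Acceptance rules for measured metabolites: relative standard deviation in
#' pooled-QC replicates below \code{max_rsd_pct}, background signal in method
#' blanks below \code{max_blank_pct}, and missingness across study samples
#' below \code{max_missing_pct} (all strict inequalities), plus the
#' significance level and maximum outlier count for the Rosner (generalized
#' extreme studentized deviate) sample-outlier test on internal standards.
#'
#' @param max_rsd_pct Maximum pooled-QC RSD, percent (default 30).
#' @param max_blank_pct Maximum blank signal, percent of QC mean (default 40).
#' @param max_missing_pct Maximum missingness, percent (default 20).
#' @param rosner_alpha Significance level of the Rosner test (default 0.05).
#' @param rosner_kmax Maximum number of outliers tested (default 5).
#' @return An object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_rsd_pct = 30, max_blank_pct = 40,
                          max_missing_pct = 20, rosner_alpha = 0.05,
                          rosner_kmax = 5L) {
  for (nm in c("max_rsd_pct", "max_blank_pct", "max_missing_pct")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v > 100)
      config_error(nm, "must lie in (0, 100]")
  }
  if (rosner_alpha <= 0 || rosner_alpha >= 1)
    config_error("rosner_alpha", "must lie in (0, 1)")
  if (rosner_kmax < 1) config_error("rosner_kmax", "must be >= 1")
  structure(list(max_rsd_pct = max_rsd_pct, max_blank_pct = max_blank_pct,
                 max_missing_pct = max_missing_pct, rosner_alpha = rosner_alpha,
                 rosner_kmax = as.integer(rosner_kmax)),
            class = "qc_thresholds")
}
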