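#' Generate a synthetic cohort
#'
#' Draws subjects, assigns them to control / SINS / sepsis, and emits one row
#' per plasma sample. Control subjects contribute a single sample; SINS and
#' sepsis subjects contribute the suspected-episode sample and, with
#' probability \code{followup_prob}, one follow-up sample 6-48 h later that
#' inherits the episode's group label (mirroring consolidation of follow-ups
#' into their diagnosed group). All ten clinical confounders, the blood-culture
#' stratification of sepsis cases, and a per-sample internal-standard summary
#' (\code{is_log_mean}) are populated. Deterministic given \code{spec$seed}.
#'
#' @param spec A [cohort_spec()].
#' @return A \code{SampleMetadata} data frame, one row per sample.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_subjects
    groups <- c("control", "SINS", "sepsis")
    grp <- sample(groups, n, replace = TRUE, prob = spec$group_probs)
    sex <- ifelse(stats::runif(n) < spec$male_prob, "male", "female")
    cd <- spec$confounder_dists
    ga  <- stats::rnorm(n, cd$gestational_age[1], cd$gestational_age[2])
    bw  <- pmax(stats::rnorm(n, cd$birthweight[1], cd$birthweight[2]), 400)
    pna <- pmax(stats::rnorm(n, cd$postnatal_age[1], cd$postnatal_age[2]), 3)
    tpn <- pmin(pmax(stats::rnorm(n, cd$tpn_proportion[1], cd$tpn_proportion[2]), 0), 1)
    oxy <- pmin(pmax(stats::rnorm(n, cd$oxygen_pct[1], cd$oxygen_pct[2]), 21), 100)
    src <- ifelse(stats::runif(n) < cd$sample_source_artery, "artery", "capillary")
    sev <- ifelse(grp == "sepsis", 1, ifelse(grp == "SINS", 0.5, 0))
    mv  <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(cd$mechanical_ventilation[[1]]) +
                                               cd$mechanical_ventilation[[2]] * sev))
    ivh <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(cd$ivh[[1]]) +
                                               cd$ivh[[2]] * sev))
    abx <- stats::rbinom(n, 1, cd$antibiotics_24h)
    path <- rep("none", n)
    is_sep <- grp == "sepsis"
    path[is_sep] <- sample(c("culture_negative", "gram_positive", "gram_negative"),
                           sum(is_sep), replace = TRUE,
                           prob = spec$sepsis_culture_probs)
    culture <- ifelse(path %in% c("gram_positive", "gram_negative"), "positive",
                      ifelse(path == "culture_negative", "negative", "none"))
    fup <- grp != "control" & stats::runif(n) < spec$followup_prob

    idx <- rep(seq_len(n), times = 1L + fup)
    is_followup <- unlist(lapply(seq_len(n), function(i) {
      if (fup[i]) c(FALSE, TRUE) else FALSE
    }))
    md <- data.frame(
      sample_id = sprintf("S%04d", seq_along(idx)),
      subject_id = sprintf("P%03d", idx),
      group = grp[idx],
      is_followup = is_followup,
      episode_index = ifelse(grp[idx] == "control", 0L, 1L),
      sex = sex[idx],
      pathogen_type = path[idx],
      culture_outcome = culture[idx],
      gestational_age = ga[idx],
      birthweight = bw[idx],
      postnatal_age = pna[idx] + ifelse(is_followup, 1, 0),
      tpn_proportion = tpn[idx],
      oxygen_pct = oxy[idx],
      sample_source = src[idx],
      mechanical_ventilation = mv[idx],
      ivh = ivh[idx],
      antibiotics_24h = abx[idx],
      stringsAsFactors = FALSE
    )
    md$is_log_mean <- stats::rnorm(nrow(md), 0, spec$is_noise_sd)
    md$is_outlier_true <- FALSE
    if (spec$n_is_outliers > 0) {
      k <- min(spec$n_is_outliers, nrow(md))
      out_idx <- sample(nrow(md), k)
      md$is_log_mean[out_idx] <- md$is_log_mean[out_idx] +
        spec$is_outlier_shift * sample(c(-1, 1), k, replace = TRUE)
      md$is_outlier_true[out_idx] <- TRUE
    }
    md$IL6 <- NA_real_; md$CRP <- NA_real_; md$PCT <- NA_real_
    md
  })
}

#' Generate log2 abundances with known ground truth
#'
#' Simulates per-sample log2 peak-area ratios under the same model the
#' downstream screen assumes: for sample j of subject i,
#' \deqn{y_{ij} = b_f + \beta_f d_{ij} + \sum_k \gamma_{fk} c_{ijk} + u_i + e_{ij}}
#' with subject intercept \eqn{u_i \sim N(0, \tau^2)},
#' \eqn{\tau^2 = icc/(1-icc)\,\sigma^2}, residual \eqn{e \sim N(0, \sigma^2)},
#' and group effects determined by the feature's differential class:
#' shared inflammation (equal shift in SINS and sepsis), progressive
#' (half shift in SINS, full in sepsis), sepsis-specific, SINS-specific,
#' sex-specific (sepsis shift in males only) or pathogen-specific (sepsis
#' shift in gram-negative cases only).
#'
#' @param metadata A \code{SampleMetadata} data frame from [generate_cohort()].
#' @param effects An [effect_spec()].
#' @param seed RNG seed (default \code{effects$seed}).
#' @return List with \code{features} (uncensored feature table) and
#'   \code{truth} (planted parameters; class \code{ground_truth}).
#' @export
generate_abundances <- function(metadata, effects, seed = effects$seed) {
  stopifnot(inherits(effects, "effect_spec"), nrow(metadata) > 0)
  if (effects$subject_icc >= 1) config_error("subject_icc", "must be < 1")
  withr::with_seed(seed, {
    qv <- effects$qc_violators
    n_extra <- sum(qv)
    p <- effects$n_features + n_extra
    feat <- character(p)
    measured <- rep(TRUE, p)
    nm_meas <- effects$n_measured
    feat[seq_len(effects$n_features)] <-
      c(sprintf("M%03d", seq_len(nm_meas)),
        if (effects$n_features > nm_meas)
          sprintf("D%03d", seq_len(effects$n_features - nm_meas)))
    measured[seq_len(effects$n_features)] <-
      rep(c(TRUE, FALSE), c(nm_meas, effects$n_features - nm_meas))
    if (n_extra > 0)
      feat[effects$n_features + seq_len(n_extra)] <- sprintf("QCV%03d", seq_len(n_extra))
    classes <- c(effects$feature_classes, rep("null", n_extra))
    # planted violator parameter vectors
    cv <- rep(effects$technical_cv, p)
    blank <- rep(effects$blank_fraction, p)
    cq <- rep(effects$censor_quantile, length.out = p)
    viol_kind <- rep("none", p)
    if (n_extra > 0) {
      at <- effects$n_features
      vv <- effects$violator_values
      if (qv[["high_cv"]] > 0) {
        ii <- at + seq_len(qv[["high_cv"]]); cv[ii] <- vv[["cv"]]
        viol_kind[ii] <- "high_cv"; at <- at + qv[["high_cv"]]
      }
      if (qv[["high_blank"]] > 0) {
        ii <- at + seq_len(qv[["high_blank"]]); blank[ii] <- vv[["blank"]]
        viol_kind[ii] <- "high_blank"; at <- at + qv[["high_blank"]]
      }
      if (qv[["high_missing"]] > 0) {
        ii <- at + seq_len(qv[["high_missing"]]); cq[ii] <- vv[["missing"]]
        viol_kind[ii] <- "high_missing"
      }
    }
    sigma <- effects$residual_sd
    tau2 <- effects$subject_icc / (1 - effects$subject_icc) * sigma^2
    baseline <- stats::rnorm(p, 3, 1.5)
    mag <- stats::runif(p, effects$effect_range[1], effects$effect_range[2])
    sgn <- switch(effects$effect_sign,
                  random = sample(c(-1, 1), p, replace = TRUE),
                  up = rep(1, p), down = rep(-1, p))
    delta <- ifelse(classes == "null", 0, mag * sgn) * sigma

    sins_shift <- sepsis_shift <- numeric(p)
    sins_shift[classes == "shared_inflammation"] <- delta[classes == "shared_inflammation"]
    sepsis_shift[classes == "shared_inflammation"] <- delta[classes == "shared_inflammation"]
    sins_shift[classes == "progressive"] <- delta[classes == "progressive"] / 2
    sepsis_shift[classes == "progressive"] <- delta[classes == "progressive"]
    sepsis_shift[classes == "sepsis_specific"] <- delta[classes == "sepsis_specific"]
    sins_shift[classes == "sins_specific"] <- delta[classes == "sins_specific"]
    # sex-/pathogen-specific: sepsis shift applied only within the stratum

    load <- effects$confounder_loadings
    if (is.null(load)) {
      load <- matrix(0, p, length(CONTINUOUS_CONFOUNDERS),
                     dimnames = list(NULL, CONTINUOUS_CONFOUNDERS))
    } else {
      if (nrow(load) == effects$n_features && n_extra > 0)
        load <- rbind(load, matrix(0, n_extra, ncol(load)))
      stopifnot(nrow(load) == p, ncol(load) == length(CONTINUOUS_CONFOUNDERS))
      colnames(load) <- CONTINUOUS_CONFOUNDERS
    }

    n <- nrow(metadata)
    subj <- factor(metadata$subject_id)
    u <- stats::rnorm(nlevels(subj), 0, sqrt(tau2))
    conf_std <- scale(as.matrix(metadata[, CONTINUOUS_CONFOUNDERS]))
    conf_std[!is.finite(conf_std)] <- 0
    is_sins <- metadata$group == "SINS"
    is_sep <- metadata$group == "sepsis"
    male <- metadata$sex == "male"
    gneg <- metadata$pathogen_type == "gram_negative"

    Y <- matrix(stats::rnorm(n * p, 0, sigma), n, p)
    Y <- Y + conf_std %*% t(load * sigma)     # loadings in residual-SD units
    Y <- sweep(Y, 2, baseline, `+`)
    Y <- Y + u[as.integer(subj)]
    Y <- Y + outer(is_sins, sins_shift) + outer(is_sep, sepsis_shift)
    sx <- classes == "sex_specific"
    if (any(sx)) Y[, sx] <- Y[, sx] + outer(is_sep & male, delta[sx])
    pg <- classes == "pathogen_specific"
    if (any(pg)) Y[, pg] <- Y[, pg] + outer(is_sep & gneg, delta[pg])
    colnames(Y) <- feat
    rownames(Y) <- metadata$sample_id

    truth <- structure(list(
      feature_info = data.frame(feature = feat, class = classes,
                                measured = measured, viol_kind = viol_kind,
                                delta = delta, sins_shift = sins_shift,
                                sepsis_shift = sepsis_shift,
                                technical_cv = cv, blank_fraction = blank,
                                censor_quantile = cq,
                                stringsAsFactors = FALSE),
      confounder_loadings = load,
      baseline = baseline,
      subject_effects = stats::setNames(u, levels(subj)),
      sigma = sigma, tau2 = tau2,
      uncensored = Y,
      censor_threshold = rep(NA_real_, p)), class = "ground_truth")
    list(features = ft_table(Y), truth = truth)
  })
}

#' Apply left-censoring to a feature table
#'
#' Values below the per-feature empirical quantile threshold are set missing,
#' emulating below-detection-limit dropout (missing not at random, low tail).
#' Purely deterministic: observed-vs-missing status is a threshold function of
#' the value.
#'
#' @param table Feature table (log2 scale).
#' @param censor_quantile Per-feature censoring quantile(s) in [0, 0.5], or an
#'   [effect_spec()] / \code{ground_truth} carrying them.
#' @return List with \code{table} (censored) and \code{thresholds}
#'   (per-feature censor threshold; \code{-Inf} where the quantile is 0).
#' @export
apply_left_censoring <- function(table, censor_quantile) {
  if (inherits(censor_quantile, "effect_spec"))
    censor_quantile <- censor_quantile$censor_quantile
  if (inherits(censor_quantile, "ground_truth"))
    censor_quantile <- censor_quantile$feature_info$censor_quantile
  Y <- ft_matrix(table)
  q <- rep(censor_quantile, length.out = ncol(Y))
  if (any(q < 0 | q > 0.5)) config_error("censor_quantile", "must lie in [0, 0.5]")
  thr <- vapply(seq_len(ncol(Y)), function(j) {
    if (q[j] <= 0) -Inf else stats::quantile(Y[, j], q[j], na.rm = TRUE, names = FALSE)
  }, numeric(1))
  for (j in seq_len(ncol(Y))) if (is.finite(thr[j])) Y[Y[, j] < thr[j], j] <- NA
  list(table = ft_table(Y), thresholds = stats::setNames(thr, colnames(Y)))
}

#' Generate pooled-QC and method-blank replicate tables
#'
#' QC replicates are the per-feature grand mean of the study samples on the
#' linear scale multiplied by lognormal technical noise with the requested
#' coefficient of variation; blanks are \code{blank_fraction} of that mean with
#' the same noise model.
#'
#' @param table Feature table on the log2 scale (uncensored or censored).
#' @param technical_cv Per-feature technical CV (scalar or vector), or a
#'   \code{ground_truth} carrying per-feature values.
#' @param blank_fraction Per-feature blank fraction (scalar or vector).
#' @param n_qc Number of pooled-QC replicates (>= 3).
#' @param n_blank Number of blank replicates (>= 2).
#' @param seed RNG seed (NULL = current stream).
#' @return List with \code{qc} and \code{blanks} feature tables (linear scale).
#' @export
generate_qc_materials <- function(table, technical_cv = 0.1, blank_fraction = 0.05,
                                  n_qc = 10, n_blank = 5, seed = NULL) {
  if (inherits(technical_cv, "ground_truth")) {
    fi <- technical_cv$feature_info
    technical_cv <- fi$technical_cv
    blank_fraction <- fi$blank_fraction
  }
  if (n_qc < 3) stop("n_qc must be >= 3: RSD is undefined below 3 replicates")
  if (n_blank < 2) stop("n_blank must be >= 2")
  Y <- ft_matrix(table)
  p <- ncol(Y)
  cv <- rep(technical_cv, length.out = p)
  bf <- rep(blank_fraction, length.out = p)
  grand <- colMeans(2^Y, na.rm = TRUE)
  with_seed_if(seed, {
    noise <- function(k, cvj) {
      if (cvj <= 0) return(matrix(1, k, 1))
      sdlog <- sqrt(log(1 + cvj^2))
      matrix(stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog), k, 1)
    }
    qc <- sapply(seq_len(p), function(j) grand[j] * noise(n_qc, cv[j]))
    bl <- sapply(seq_len(p), function(j) bf[j] * grand[j] * noise(n_blank, cv[j]))
    qc <- matrix(qc, n_qc, p, dimnames = list(sprintf("QC%02d", seq_len(n_qc)), colnames(Y)))
    bl <- matrix(bl, n_blank, p, dimnames = list(sprintf("BL%02d", seq_len(n_blank)), colnames(Y)))
    list(qc = ft_table(qc), blanks = ft_table(bl))
  })
}

#' Populate inflammatory-marker columns
#'
#' Fills IL6, CRP and PCT (log scale, arbitrary units) according to a
#' [marker_spec()]: baseline 0 for controls, plus the inflamed shift for SINS
#' and sepsis samples and the additional sepsis shift for sepsis samples, with
#' Gaussian noise.
#'
#' @param metadata \code{SampleMetadata} with group labels.
#' @param mspec A [marker_spec()].
#' @param seed RNG seed (default \code{mspec$seed}).
#' @return \code{metadata} with IL6 / CRP / PCT columns populated.
#' @export
generate_markers <- function(metadata, mspec, seed = mspec$seed) {
  stopifnot(inherits(mspec, "marker_spec"))
  withr::with_seed(seed, {
    inflamed <- metadata$group %in% c("SINS", "sepsis")
    sepsis <- metadata$group == "sepsis"
    n <- nrow(metadata)
    for (mk in c("IL6", "CRP", "PCT")) {
      metadata[[mk]] <- mspec$inflam_shift[[mk]] * inflamed +
        mspec$sepsis_shift[[mk]] * sepsis +
        stats::rnorm(n, 0, mspec$noise_sd)
    }
    metadata
  })
}

#' Simulate a complete study data set
#'
#' Convenience wrapper running [generate_cohort()], [generate_abundances()],
#' [apply_left_censoring()], [generate_qc_materials()] and
#' [generate_markers()] with seeds derived from \code{seed}.
#'
#' @param cspec,espec,mspec Specifications (defaults as documented there).
#' @param n_qc,n_blank QC material sizes.
#' @param seed Master seed; sub-generators use \code{seed}, \code{seed + 1}, ...
#' @return List of class \code{sepsismet_simulation}: \code{metadata},
#'   \code{features} (censored), \code{qc}, \code{blanks}, \code{truth}.
#' @export
simulate_dataset <- function(cspec = cohort_spec(), espec = effect_spec(),
                             mspec = marker_spec(), n_qc = 10, n_blank = 5,
                             seed = 1L) {
  seed <- as.integer(seed)
  cspec$seed <- seed
  md <- generate_cohort(cspec)
  ab <- generate_abundances(md, espec, seed = seed + 1L)
  cen <- apply_left_censoring(ab$features, ab$truth)
  ab$truth$censor_threshold <- cen$thresholds
  qcb <- generate_qc_materials(ab$features, ab$truth, n_qc = n_qc,
                               n_blank = n_blank, seed = seed + 2L)
  md <- generate_markers(md, mspec, seed = seed + 3L)
  # study features are emitted on the linear peak-area-ratio scale, as an
  # instrument export would be; truth$uncensored keeps the log2 values
  lin <- ft_table(2^ft_matrix(cen$table))
  structure(list(metadata = md, features = lin, qc = qcb$qc,
                 blanks = qcb$blanks, truth = ab$truth, seed = seed),
            class = "sepsismet_simulation")
}
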