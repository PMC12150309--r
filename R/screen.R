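#' Welch's unequal-variance t-test
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @return List with \code{t} and \code{p}. Two constant, equal arms give
#'   t = 0, p = 1.
#' @export
welch_t <- function(x, y) {
  res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(list(t = 0, p = 1))
    stop("Welch test undefined: zero variance in both arms with unequal means")
  }
  list(t = unname(res$statistic), p = res$p.value)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List with \code{odds_ratio} (conditional MLE) and \code{p}.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: Fisher exact p set to 1 by convention")
    return(list(odds_ratio = NA_real_, p = 1))
  }
  res <- stats::fisher.test(tab)
  list(odds_ratio = unname(res$estimate), p = res$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment; \code{NA} p-values stay \code{NA} and are
#' excluded from the family size m.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Directed p-value
#'
#' \code{-log10(p) * sign(estimate)}; a zero estimate gives 0.
#'
#' @param p P-value(s) in (0, 1].
#' @param estimate Signed estimate(s).
#' @return Signed -log10 p.
#' @export
directed_pvalue <- function(p, estimate) {
  if (any(p <= 0, na.rm = TRUE)) stop("p = 0 has no finite -log10; clip upstream")
  stopifnot(all(p <= 1, na.rm = TRUE))
  -log10(p) * sign(estimate)
}

#' Fold change between two groups
#'
#' Ratio of group geometric means on the linear scale, computed from the
#' unscaled imputed log2 table prior to confounder correction:
#' \code{FC = 2^(mean_log2(B) - mean_log2(A))} with A the reference (the model
#' name's first group, e.g. control in C_SINS).
#'
#' @param log2tab Feature table, log2 scale (imputed, pre-scaling).
#' @param groups Group label per sample (aligned with the table rows).
#' @param pair \code{c(A, B)}: reference first. Either entry may be a vector of
#'   pooled group labels (e.g. \code{list(c("control","SINS"), "sepsis")}).
#' @return Named vector of fold changes per feature.
#' @export
fold_change <- function(log2tab, groups, pair) {
  M <- ft_matrix(log2tab)
  A <- groups %in% pair[[1]]
  B <- groups %in% pair[[2]]
  if (!any(A) || !any(B)) stop("fold change: empty group")
  2^(colMeans(M[B, , drop = FALSE]) - colMeans(M[A, , drop = FALSE]))
}

#' One-way ANOVA across the three study groups
#'
#' @param y Numeric response.
#' @param groups Group labels (3 levels, each n >= 2).
#' @return List with \code{F}, \code{p} and a degeneracy \code{flag}.
#' @export
anova_three_group <- function(y, groups) {
  g <- factor(groups)
  stopifnot(nlevels(g) == 3, all(table(g) >= 2))
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  Fv <- tab$`F value`[1]; pv <- tab$`Pr(>F)`[1]
  # zero within-group variance everywhere: the F ratio is 0/0
  if (!is.finite(Fv) || tab$`Mean Sq`[2] < .Machine$double.eps * mean(abs(y) + 1))
    return(list(F = NA_real_, p = NA_real_, flag = "degenerate"))
  list(F = Fv, p = pv, flag = "ok")
}

#' Identify confounders to adjust for
#'
#' A covariate is \emph{outcome-associated} when it differs by sepsis status
#' (Fisher exact test for categorical covariates, Welch t for continuous) at
#' level \code{alpha}, and \emph{metabolome-associated} when it associates with
#' any of the top \code{n_pcs} principal-component scores of the autoscaled
#' table (Spearman for continuous covariates; Welch t / one-way ANOVA for
#' categorical). The union of both sets is returned as the adjustment set.
#'
#' @param metadata Sample metadata.
#' @param scaled Autoscaled feature table aligned with \code{metadata}.
#' @param covariates Named character vector: covariate -> "continuous" or
#'   "categorical".
#' @param alpha Significance level (default 0.05).
#' @param n_pcs Number of leading PCs inspected (default 5).
#' @return A \code{confounder_set}: \code{covariates} (union) plus a
#'   provenance \code{detail} data frame.
#' @export
identify_confounders <- function(metadata, scaled,
                                 covariates = DEFAULT_COVARIATES,
                                 alpha = 0.05, n_pcs = 5) {
  M <- ft_matrix(scaled)
  stopifnot(nrow(M) == nrow(metadata))
  sepsis <- metadata$group == "sepsis"
  n_pcs <- min(n_pcs, ncol(M), nrow(M) - 1L)
  pcs <- stats::prcomp(M, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  det <- data.frame(covariate = names(covariates), type = unname(covariates),
                    outcome_p = NA_real_, metabolome_p = NA_real_,
                    outcome_associated = FALSE, metabolome_associated = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(det))) {
    cv <- metadata[[det$covariate[i]]]
    if (length(unique(cv)) < 2) {
      warning(sprintf("covariate '%s' has a single level; skipped", det$covariate[i]))
      next
    }
    both_outcomes <- length(unique(sepsis)) == 2
    if (det$type[i] == "categorical") {
      if (both_outcomes)
        det$outcome_p[i] <- stats::fisher.test(table(cv, sepsis))$p.value
      pc_p <- apply(pcs, 2, function(s) {
        f <- factor(cv)
        if (nlevels(f) == 2) welch_t(s[f == levels(f)[1]], s[f == levels(f)[2]])$p
        else stats::anova(stats::lm(s ~ f))$`Pr(>F)`[1]
      })
    } else {
      if (both_outcomes)
        det$outcome_p[i] <- welch_t(cv[sepsis], cv[!sepsis])$p
      pc_p <- apply(pcs, 2, function(s)
        suppressWarnings(stats::cor.test(cv, s, method = "spearman"))$p.value)
    }
    det$metabolome_p[i] <- min(pc_p)
    det$outcome_associated[i] <- isTRUE(det$outcome_p[i] < alpha)
    det$metabolome_associated[i] <- isTRUE(det$metabolome_p[i] < alpha)
  }
  sel <- det$covariate[det$outcome_associated | det$metabolome_associated]
  structure(list(covariates = sel, detail = det, alpha = alpha, n_pcs = n_pcs),
            class = "confounder_set")
}

#' Metabolome-wide mixed-model screen for one contrast
#'
#' Fits the random-intercept model of [fit_contrast_lmm()] to every feature of
#' the autoscaled table (via a profiled-REML engine sharing the design across
#' features), adjusts p-values by Benjamini-Hochberg over the full feature
#' family, and attaches directed p-values and fold changes (computed on the
#' unscaled imputed log2 table, reference = the contrast's 0-coded pool).
#'
#' @param ds A \code{processed_dataset} (or a list with \code{scaled} and
#'   \code{imputed} feature tables).
#' @param metadata Sample metadata covering the table's samples.
#' @param contrast A [contrast_spec()] or model name.
#' @param confounders A \code{confounder_set} or character vector (default
#'   none).
#' @return Data frame of per-feature results: feature, estimate, se, df, p, q,
#'   directed_p, fc, flag.
#' @export
run_screen <- function(ds, metadata, contrast = "Sepsis", confounders = character(0)) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  if (inherits(confounders, "confounder_set")) confounders <- confounders$covariates
  scaled <- ds$scaled
  md <- metadata[match(scaled$sample_id, metadata$sample_id), , drop = FALSE]
  in_groups <- md$group[md$group %in% contrast$groups]
  if (length(unique(in_groups %in% contrast$coded1)) < 2)
    stop(sprintf("contrast %s has a single class in these samples", contrast$name))
  des <- build_design(md, contrast, confounders)
  Y <- ft_matrix(scaled)[des$keep, , drop = FALSE]
  res <- reml_screen(Y, des$X, des$metadata$subject_id)
  ref <- setdiff(contrast$groups, contrast$coded1)
  keep_rows <- md$group %in% contrast$groups
  fc <- fold_change(ds$imputed[keep_rows, , drop = FALSE], md$group[keep_rows],
                    list(ref, contrast$coded1))
  out <- data.frame(feature = colnames(Y),
                    estimate = res$estimate, se = res$se, df = res$df,
                    p = res$p, q = bh_adjust(res$p),
                    directed_p = directed_pvalue(pmax(res$p, 1e-300), res$estimate),
                    fc = unname(fc[colnames(Y)]),
                    flag = ifelse(res$singular > 0, "singular_lm", "ok"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast$name
  attr(out, "confounders") <- confounders
  out
}

#' Stratified Sepsis-model screen
#'
#' Reruns the Sepsis contrast on a stratum of the comprehensive data set:
#' \code{sex} strata keep one sex entirely; \code{pathogen_type} strata keep
#' the named pathogen's sepsis samples plus all non-sepsis samples;
#' \code{culture_outcome} strata likewise restrict the sepsis arm by culture
#' result. The stratum variable is dropped from the confounder set
#' automatically.
#'
#' @param ds A \code{processed_dataset}.
#' @param metadata Sample metadata.
#' @param stratum One of \code{"sex"}, \code{"pathogen_type"},
#'   \code{"culture_outcome"}.
#' @param level Stratum level (e.g. \code{"male"}, \code{"gram_positive"},
#'   \code{"positive"}).
#' @param confounders \code{confounder_set} or character vector.
#' @return Screen result data frame as in [run_screen()].
#' @export
stratified_screen <- function(ds, metadata, stratum, level,
                              confounders = character(0)) {
  stratum <- match.arg(stratum, c("sex", "pathogen_type", "culture_outcome"))
  if (inherits(confounders, "confounder_set")) confounders <- confounders$covariates
  confounders <- setdiff(confounders, stratum)
  md <- metadata[match(ds$scaled$sample_id, metadata$sample_id), , drop = FALSE]
  keep <- if (stratum == "sex") md$sex == level
          else md$group != "sepsis" | md[[stratum]] == level
  if (!any(keep)) stop(sprintf("stratum %s=%s selects no samples", stratum, level))
  sub <- list(scaled = ds$scaled[keep, , drop = FALSE],
              imputed = ds$imputed[keep, , drop = FALSE])
  mds <- md[keep, , drop = FALSE]
  if (length(unique(mds$group == "sepsis")) < 2)
    stop(sprintf("stratum %s=%s has a single outcome class", stratum, level))
  out <- run_screen(sub, mds, "Sepsis", confounders)
  attr(out, "stratum") <- c(stratum = stratum, level = level)
  out
}

#' Classify a feature's trend across control, SINS and sepsis
#'
#' Implements the compact-letter logic of group-trend boxplots: with
#' uncorrected significance at \code{alpha} in the three pairwise models,
#' \itemize{
#'   \item shared inflammation: C_SINS and C_S significant with the same sign,
#'     SINS_S not;
#'   \item progressive (up/down): C_SINS and SINS_S significant with the same
#'     sign and monotone group means;
#'   \item sepsis-specific: SINS_S and C_S significant, C_SINS not;
#'   \item SINS-specific: C_SINS significant, C_S not, and SINS_S either not
#'     significant (letters a/b/ab, the underpowered variant) or significant
#'     with the opposite sign (letters a/b/a, sepsis back at control level);
#'   \item otherwise unclassified.
#' }
#'
#' @param c_sins,c_s,sins_s One-row results (estimate, p) for the three
#'   pairwise models.
#' @param means Named group means \code{c(control=, SINS=, sepsis=)} prior to
#'   confounder correction.
#' @param alpha Uncorrected significance level (default 0.05).
#' @return One of \code{TREND_CATEGORIES}.
#' @export
classify_trend <- function(c_sins, c_s, sins_s, means, alpha = 0.05) {
  ps <- c(c_sins$p, c_s$p, sins_s$p)
  es <- c(c_sins$estimate, c_s$estimate, sins_s$estimate)
  if (any(is.na(ps)) || any(is.na(es))) return("unclassified")
  sig <- ps < alpha
  if (sig[1] && sig[2] && !sig[3] && sign(es[1]) == sign(es[2]))
    return("shared_inflammation")
  mono_up <- means[["control"]] <= means[["SINS"]] && means[["SINS"]] <= means[["sepsis"]]
  mono_dn <- means[["control"]] >= means[["SINS"]] && means[["SINS"]] >= means[["sepsis"]]
  if (sig[1] && sig[3] && sign(es[1]) == sign(es[3]) && (mono_up || mono_dn))
    return(if (es[1] > 0) "progressive_up" else "progressive_down")
  if (sig[3] && sig[2] && !sig[1]) return("sepsis_specific")
  if (sig[1] && !sig[2] && (!sig[3] || sign(es[3]) == -sign(es[1])))
    return("sins_specific")
  "unclassified"
}

#' Trend classification for every feature of a processed data set
#'
#' Runs the three pairwise screens (C_SINS, C_S, SINS_S) and applies
#' [classify_trend()] per feature using pre-correction group means from the
#' imputed log2 table.
#'
#' @inheritParams run_screen
#' @param alpha Uncorrected significance level.
#' @return Data frame: feature, trend, plus the three pairwise p-values.
#' @export
classify_trends <- function(ds, metadata, confounders = character(0), alpha = 0.05) {
  rs <- lapply(c("C_SINS", "C_S", "SINS_S"), function(cn)
    run_screen(ds, metadata, cn, confounders))
  names(rs) <- c("C_SINS", "C_S", "SINS_S")
  md <- metadata[match(ds$imputed$sample_id, metadata$sample_id), , drop = FALSE]
  M <- ft_matrix(ds$imputed)
  gm <- sapply(c("control", "SINS", "sepsis"), function(g)
    colMeans(M[md$group == g, , drop = FALSE]))
  trend <- vapply(seq_len(nrow(rs$C_SINS)), function(i)
    classify_trend(rs$C_SINS[i, ], rs$C_S[i, ], rs$SINS_S[i, ],
                   c(control = gm[i, "control"], SINS = gm[i, "SINS"],
                     sepsis = gm[i, "sepsis"]), alpha = alpha),
    character(1))
  data.frame(feature = rs$C_SINS$feature, trend = trend,
             p_c_sins = rs$C_SINS$p, p_c_s = rs$C_S$p, p_sins_s = rs$SINS_S$p,
             stringsAsFactors = FALSE)
}
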