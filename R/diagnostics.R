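#' Curate the single-time-point (STP) data set
#'
#' One sample per subject, at the moment of clinical suspicion: per subject the
#' first sepsis episode's suspected (non-follow-up) sample if any, else the
#' first SINS episode's suspected sample; control samples only from subjects
#' with no SINS/sepsis episodes anywhere. Follow-up samples are never selected.
#'
#' @param metadata Sample metadata with \code{subject_id}, \code{group},
#'   \code{is_followup}, \code{episode_index} and \code{postnatal_age} (used to
#'   order episodes).
#' @return Character vector of selected sample IDs.
#' @export
curate_stp <- function(metadata) {
  sel <- character(0)
  for (sid in unique(metadata$subject_id)) {
    rows <- metadata[metadata$subject_id == sid, , drop = FALSE]
    episodes <- rows[rows$group %in% c("SINS", "sepsis"), , drop = FALSE]
    if (nrow(episodes) == 0) {
      ctrl <- rows[rows$group == "control" & !rows$is_followup, , drop = FALSE]
      if (nrow(ctrl)) sel <- c(sel, ctrl$sample_id[1])
      next
    }
    cand <- episodes[!episodes$is_followup, , drop = FALSE]
    if (nrow(cand) == 0) {
      warning(sprintf("subject '%s' has episodes but no suspected sample; excluded", sid))
      next
    }
    cand <- cand[order(cand$group != "sepsis",                 # sepsis first
                       cand$episode_index, cand$postnatal_age), , drop = FALSE]
    sel <- c(sel, cand$sample_id[1])
  }
  sel
}

#' Univariate logistic regression for one feature
#'
#' Maximum-likelihood fit of the binary label on a single (autoscaled)
#' feature with a Wald test for the slope. Perfect separation is detected and
#' resolved by a ridge-stabilized refit, flagged.
#'
#' @param x Feature values.
#' @param y Binary labels (0/1 or logical).
#' @return List: estimate, se, p, flag.
#' @export
univariate_logistic <- function(x, y) {
  y <- as.numeric(y)
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(y) < 10 || length(unique(y)) < 2)
    stop("univariate logistic regression needs n >= 10 with both classes")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  separated <- !fit$converged || any(abs(fit$coefficients) > 15)
  if (separated) {
    rf <- ridge_logistic(cbind(x), y)
    return(list(estimate = rf$beta[2], se = NA_real_, p = rf$p, flag = "separation"))
  }
  list(estimate = co["x", "Estimate"], se = co["x", "Std. Error"],
       p = co["x", "Pr(>|z|)"], flag = "ok")
}

# Weakly L2-penalized logistic fit used when ML estimates diverge; p-value
# from the penalized Wald statistic of the slope.
ridge_logistic <- function(X, y, lambda = 1e-2) {
  fit <- glmnet::glmnet(cbind(1, X), y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE, intercept = FALSE,
                        penalty.factor = c(0, rep(1, ncol(X))))
  beta <- as.numeric(fit$beta)
  eta <- drop(cbind(1, X) %*% beta)
  mu <- stats::plogis(eta)
  Wm <- mu * (1 - mu)
  XtWX <- crossprod(cbind(1, X) * sqrt(Wm)) + diag(c(0, rep(lambda * length(y), ncol(X))))
  se <- sqrt(diag(solve(XtWX)))
  z <- beta[2] / se[2]
  list(beta = beta, p = 2 * stats::pnorm(-abs(z)))
}

# Trapezoidal rank AUC (Mann-Whitney with tie correction).
rank_auc <- function(scores, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(pred, y, threshold = 0.5) {
  cls <- as.numeric(pred >= threshold)
  tp <- sum(cls == 1 & y == 1); tn <- sum(cls == 0 & y == 0)
  fp <- sum(cls == 1 & y == 0); fn <- sum(cls == 0 & y == 1)
  sens <- if (tp + fn) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  c(sensitivity = sens, specificity = spec, ppv = ppv, f1 = f1)
}

#' Bootstrap-aggregated LASSO logistic regression
#'
#' For each of \code{B} iterations: draw a class-stratified bootstrap sample,
#' fit an L1-penalized logistic regression with the penalty chosen by internal
#' 5-fold cross-validated deviance on the bootstrap sample (the one-standard-
#' error rule, which at panel-discovery sample sizes keeps chance-correlated
#' null features out of the per-iteration models), record which features carry
#' nonzero coefficients, and evaluate AUC / sensitivity / specificity
#' (threshold 0.5) on the out-of-bag samples. Selection frequencies over the B
#' fits feed stability selection.
#'
#' @param X Autoscaled feature matrix (samples x features, no missing).
#' @param y Binary labels (both classes with >= 5 members).
#' @param B Number of bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @param lambda_rule Penalty choice within each bootstrap fit:
#'   \code{"lambda.1se"} (default) or \code{"lambda.min"}.
#' @return A \code{bootstrap_result}: \code{selection_freq} (named, in [0,1]),
#'   \code{metrics} (B-row data frame of OOB AUC/sens/spec), \code{mean_auc},
#'   \code{mean_sensitivity}, \code{mean_specificity}, \code{B}, \code{seed}.
#' @export
bootstrap_lasso <- function(X, y, B = 100, seed = 1L,
                            lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(!anyNA(X), all(y %in% c(0, 1)))
  if (min(table(y)) < 5) stop("each class needs >= 5 members")
  n <- nrow(X)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  withr::with_seed(seed, {
    sel <- matrix(0, B, ncol(X))
    met <- matrix(NA_real_, B, 3, dimnames = list(NULL, c("auc", "sensitivity", "specificity")))
    for (b in seq_len(B)) {
      boot <- c(sample(idx1, length(idx1), replace = TRUE),
                sample(idx0, length(idx0), replace = TRUE))
      oob <- setdiff(seq_len(n), unique(boot))
      cv <- tryCatch(glmnet::cv.glmnet(X[boot, , drop = FALSE], y[boot],
                                       family = "binomial", nfolds = 5,
                                       type.measure = "deviance"),
                     error = function(e) NULL)
      if (is.null(cv)) next
      beta <- as.numeric(stats::coef(cv, s = lambda_rule))[-1]
      sel[b, ] <- as.numeric(beta != 0)
      if (length(oob) && length(unique(y[oob])) == 2) {
        pr <- as.numeric(stats::predict(cv, X[oob, , drop = FALSE],
                                        s = lambda_rule, type = "response"))
        cm <- confusion_metrics(pr, y[oob], 0.5)
        met[b, ] <- c(rank_auc(pr, y[oob]), cm[["sensitivity"]], cm[["specificity"]])
      }
    }
    structure(list(selection_freq = stats::setNames(colMeans(sel), colnames(X)),
                   metrics = as.data.frame(met),
                   mean_auc = mean(met[, "auc"], na.rm = TRUE),
                   mean_sensitivity = mean(met[, "sensitivity"], na.rm = TRUE),
                   mean_specificity = mean(met[, "specificity"], na.rm = TRUE),
                   B = B, seed = seed),
              class = "bootstrap_result")
  })
}

#' Stability selection of the diagnostic panel
#'
#' Features selected in strictly more than \code{threshold} of bootstrap fits
#' ("over 45\%" by default), ordered by decreasing frequency.
#'
#' @param freqs Named per-feature selection frequencies (or a
#'   \code{bootstrap_result}).
#' @param threshold Frequency threshold in (0, 1); default 0.45.
#' @return Character vector of panel features.
#' @export
select_panel <- function(freqs, threshold = 0.45) {
  if (inherits(freqs, "bootstrap_result")) freqs <- freqs$selection_freq
  stopifnot(threshold >= 0, threshold < 1)
  sel <- freqs[freqs > threshold]
  if (!length(sel)) warning("stability selection returned an empty panel")
  names(sort(sel, decreasing = TRUE))
}

#' Leave-one-out cross-validated panel evaluation
#'
#' For each sample, an unpenalized logistic model is fit on the remaining
#' samples (panel features plus optional marker columns) and used to predict
#' the held-out sample. Out-of-fold probabilities yield the ROC (trapezoidal
#' rank AUC) and sensitivity / specificity / PPV / F1 at the probability
#' threshold maximizing Youden's J. Folds with separation fall back to a
#' ridge-stabilized fit and are counted.
#'
#' @param X_panel Matrix/data frame of panel features (may have 0 columns when
#'   only markers are modelled).
#' @param y Binary labels.
#' @param markers Optional matrix/data frame of marker covariates.
#' @return A \code{panel_model}: predictions, auc, metrics at the Youden
#'   threshold, threshold, n_ridge_folds, feature names.
#' @export
loocv_evaluate <- function(X_panel, y, markers = NULL) {
  Xp <- if (is.null(X_panel)) NULL else as.matrix(X_panel)
  Z <- if (is.null(markers)) NULL else as.matrix(markers)
  X <- cbind(Xp, Z)
  y <- as.numeric(y)
  stopifnot(!is.null(X), ncol(X) >= 1, length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(y) < 10) stop("LOOCV evaluation needs n >= 10")
  n <- length(y)
  pred <- numeric(n)
  n_ridge <- 0L
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    fit <- suppressWarnings(stats::glm.fit(cbind(1, Xi), yi,
                                           family = stats::binomial()))
    if (!fit$converged || any(abs(fit$coefficients) > 15)) {
      rf <- ridge_logistic(Xi, yi)
      beta <- rf$beta
      n_ridge <- n_ridge + 1L
    } else beta <- fit$coefficients
    pred[i] <- stats::plogis(drop(c(1, X[i, ]) %*% beta))
  }
  auc <- rank_auc(pred, y)
  # Youden-optimal threshold over the observed prediction values
  cand <- sort(unique(pred))
  youden <- vapply(cand, function(th) {
    cm <- confusion_metrics(pred, y, th)
    cm[["sensitivity"]] + cm[["specificity"]] - 1
  }, numeric(1))
  thr <- cand[which.max(youden)]
  cm <- confusion_metrics(pred, y, thr)
  structure(list(features = colnames(X), predictions = pred, labels = y,
                 auc = auc, threshold = thr,
                 sensitivity = cm[["sensitivity"]], specificity = cm[["specificity"]],
                 ppv = cm[["ppv"]], f1 = cm[["f1"]],
                 n_ridge_folds = n_ridge),
            class = "panel_model")
}

#' McNemar comparison of two classifiers on the same samples
#'
#' Each sample is scored correct/incorrect per model at \code{threshold};
#' discordant counts b (A correct, B wrong) and c (A wrong, B correct) feed an
#' exact two-sided binomial test when b + c < 25, else the
#' continuity-corrected chi-square \eqn{(|b-c|-1)^2/(b+c)}.
#'
#' @param predsA,predsB Predicted probabilities from the two models.
#' @param y Shared binary labels.
#' @param threshold Classification threshold (default 0.5).
#' @return List: b, c, method, statistic (chi-square branch), p.
#' @export
compare_models_mcnemar <- function(predsA, predsB, y, threshold = 0.5) {
  stopifnot(length(predsA) == length(y), length(predsB) == length(y))
  y <- as.numeric(y)
  okA <- as.numeric(predsA >= threshold) == y
  okB <- as.numeric(predsB >= threshold) == y
  b <- sum(okA & !okB); cc <- sum(!okA & okB)
  if (b + cc == 0) return(list(b = b, c = cc, method = "exact", statistic = NA_real_, p = 1))
  if (b + cc < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    list(b = b, c = cc, method = "exact", statistic = NA_real_, p = p)
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    list(b = b, c = cc, method = "chisq",
         statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
  }
}

#' Run the full SINS-vs-sepsis diagnostic framework
#'
#' On the STP subset (SINS vs sepsis): univariate logistic screening with BH
#' correction, bootstrap-aggregated LASSO with stability selection of the
#' metabolite panel, then LOOCV evaluation of nine model variants — the panel
#' alone, each inflammatory marker alone, all markers combined, the panel plus
#' each marker, and the panel plus all markers — with McNemar comparisons of
#' every variant against the panel model.
#'
#' @param ds A \code{processed_dataset} covering the STP samples.
#' @param metadata Sample metadata (markers IL6/CRP/PCT populated).
#' @param B Bootstrap iterations (default 100).
#' @param threshold Stability-selection frequency threshold (default 0.45).
#' @param seed RNG seed.
#' @return A \code{diagnostic_report}: univariate table, bootstrap result,
#'   panel, \code{models} (list of \code{panel_model}s), \code{comparisons},
#'   \code{summary} data frame of per-model metrics.
#' @export
run_diagnostics <- function(ds, metadata, B = 100, threshold = 0.45, seed = 1L) {
  md <- metadata[match(ds$scaled$sample_id, metadata$sample_id), , drop = FALSE]
  keep <- md$group %in% c("SINS", "sepsis")
  if (sum(keep) < 10 || length(unique(md$group[keep])) < 2)
    stop("diagnostics need both SINS and sepsis samples")
  X <- ft_matrix(ds$scaled)[keep, , drop = FALSE]
  y <- as.numeric(md$group[keep] == "sepsis")
  # markers: log-scale values, autoscaled for comparability with the features
  Zm <- scale(as.matrix(md[keep, c("IL6", "CRP", "PCT")]))

  uni <- do.call(rbind, lapply(colnames(X), function(f) {
    r <- univariate_logistic(X[, f], y)
    data.frame(feature = f, estimate = r$estimate, se = r$se, p = r$p,
               flag = r$flag, stringsAsFactors = FALSE)
  }))
  uni$q <- bh_adjust(uni$p)

  boot <- bootstrap_lasso(X, y, B = B, seed = seed)
  panel <- select_panel(boot, threshold)

  models <- list()
  if (length(panel)) models$panel <- loocv_evaluate(X[, panel, drop = FALSE], y)
  for (mk in c("IL6", "CRP", "PCT"))
    models[[mk]] <- loocv_evaluate(NULL, y, markers = Zm[, mk, drop = FALSE])
  models$all_markers <- loocv_evaluate(NULL, y, markers = Zm)
  if (length(panel)) {
    for (mk in c("IL6", "CRP", "PCT"))
      models[[paste0("panel_", mk)]] <-
        loocv_evaluate(X[, panel, drop = FALSE], y, markers = Zm[, mk, drop = FALSE])
    models$panel_all_markers <- loocv_evaluate(X[, panel, drop = FALSE], y, markers = Zm)
  }

  comparisons <- NULL
  if (!is.null(models$panel)) {
    others <- setdiff(names(models), "panel")
    comparisons <- do.call(rbind, lapply(others, function(nm) {
      mc <- compare_models_mcnemar(models$panel$predictions,
                                   models[[nm]]$predictions, y)
      data.frame(model_a = "panel", model_b = nm, b = mc$b, c = mc$c,
                 method = mc$method, p = mc$p, stringsAsFactors = FALSE)
    }))
  }
  summ <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(model = nm, auc = m$auc, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, f1 = m$f1,
               stringsAsFactors = FALSE)
  }))
  structure(list(univariate = uni, bootstrap = boot, panel = panel,
                 models = models, comparisons = comparisons, summary = summ,
                 n = sum(keep), seed = seed),
            class = "diagnostic_report")
}
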