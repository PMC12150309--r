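#' Per-feature quality-control metrics
#'
#' Computes, on the linear (untransformed) scale: pooled-QC relative standard
#' deviation (`rsd_pct = 100 * sd / mean` over QC replicates, n-1 sd), blank
#' background (`blank_pct = 100 * mean(blank) / mean(QC)`), and study-sample
#' missingness (`missing_pct`). Features whose QC mean is zero cannot have an
#' RSD and auto-fail with a flagged reason.
#'
#' @param samples Study-sample feature table (linear scale; `NA` = missing).
#' @param qc Pooled-QC replicate table (>= 3 replicates).
#' @param blanks Method-blank replicate table (>= 2 replicates).
#' @return A \code{qc_report} data frame with per-feature metrics and pass
#'   flags (filled in by [filter_features()]).
#' @export
compute_feature_qc <- function(samples, qc, blanks) {
  S <- ft_matrix(samples); Q <- ft_matrix(qc); B <- ft_matrix(blanks)
  if (nrow(Q) < 3) stop("need >= 3 pooled-QC replicates to compute RSD")
  if (nrow(B) < 2) stop("need >= 2 blank replicates")
  feats <- colnames(S)
  if (!setequal(feats, colnames(Q)) || !setequal(feats, colnames(B)))
    stop("samples, qc and blanks must share the same feature set")
  Q <- Q[, feats, drop = FALSE]; B <- B[, feats, drop = FALSE]
  qm <- colMeans(Q); qs <- apply(Q, 2, stats::sd)
  rsd <- ifelse(qm == 0, NA_real_, 100 * qs / qm)
  blank <- ifelse(qm == 0, NA_real_, 100 * colMeans(B) / qm)
  miss <- 100 * colMeans(is.na(S))
  data.frame(feature = feats, rsd_pct = rsd, blank_pct = blank,
             missing_pct = miss, zero_qc_mean = qm == 0,
             pass_rsd = NA, pass_blank = NA, pass_missing = NA, pass = NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply QC acceptance rules
#'
#' A feature is retained iff `rsd_pct < max_rsd_pct` and
#' `blank_pct < max_blank_pct` and `missing_pct < max_missing_pct`, all strict
#' inequalities. Features with an undefined RSD (zero QC mean) fail.
#'
#' @param report Output of [compute_feature_qc()].
#' @param thr A [qc_thresholds()].
#' @return The report with pass flags filled; retained feature names in
#'   \code{attr(, "retained")}.
#' @export
filter_features <- function(report, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  report$pass_rsd <- !is.na(report$rsd_pct) & report$rsd_pct < thr$max_rsd_pct
  report$pass_blank <- !is.na(report$blank_pct) & report$blank_pct < thr$max_blank_pct
  report$pass_missing <- report$missing_pct < thr$max_missing_pct
  report$pass <- report$pass_rsd & report$pass_blank & report$pass_missing
  attr(report, "retained") <- report$feature[report$pass]
  attr(report, "n_retained") <- sum(report$pass)
  attr(report, "n_removed") <- sum(!report$pass)
  report
}

#' Rosner (generalized ESD) outlier test
#'
#' Iteratively removes the most extreme value and compares the extreme
#' studentized deviate \eqn{R_i = \max |x - \bar x| / s} against the critical
#' value \eqn{\lambda_i = (n-i)\,t_{p,n-i-1} / \sqrt{(n-i-1+t^2)(n-i+1)}} with
#' \eqn{p = 1 - \alpha / (2(n-i+1))}; the declared number of outliers is the
#' largest \eqn{i} with \eqn{R_i > \lambda_i}. Used on a per-sample
#' internal-standard summary to flag analytically aberrant samples.
#'
#' @param x Numeric vector (one statistic per sample).
#' @param alpha Significance level (default 0.05).
#' @param kmax Maximum number of outliers tested (default 5).
#' @return List with \code{n_outliers}, \code{outlier_index}, and the
#'   per-iteration table \code{stats} (R_i, lambda_i).
#' @export
rosner_test <- function(x, alpha = 0.05, kmax = 5L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < kmax + 3) stop("need at least kmax + 3 observations")
  if (stats::sd(x) == 0) {
    warning("constant statistic: no outliers detectable")
    return(list(n_outliers = 0L, outlier_index = integer(0),
                stats = data.frame(i = integer(0), R = numeric(0),
                                   lambda = numeric(0))))
  }
  keep <- seq_len(n)
  R <- lam <- numeric(kmax)
  removed <- integer(kmax)
  for (i in seq_len(kmax)) {
    xi <- x[keep]
    m <- mean(xi); s <- stats::sd(xi)
    if (s == 0) { R[i] <- 0 } else {
      dev <- abs(xi - m)
      j <- which.max(dev)
      R[i] <- dev[j] / s
      removed[i] <- keep[j]
      keep <- keep[-j]
    }
    ni <- n - i + 1L                     # size of the set tested at step i
    pp <- 1 - alpha / (2 * ni)
    tv <- stats::qt(pp, ni - 2L)
    lam[i] <- (ni - 1L) * tv / sqrt((ni - 2L + tv^2) * ni)
  }
  k <- if (any(R > lam)) max(which(R > lam)) else 0L
  list(n_outliers = k,
       outlier_index = removed[seq_len(k)],
       stats = data.frame(i = seq_len(kmax), R = R, lambda = lam))
}

#' Detect outlier samples from an internal-standard summary
#'
#' @param is_summary Named numeric vector (names = sample IDs) of the
#'   per-sample internal-standard statistic, typically the mean log response.
#' @param alpha,kmax Rosner test parameters.
#' @return Character vector of flagged sample IDs.
#' @export
detect_outlier_samples <- function(is_summary, alpha = 0.05, kmax = 5L) {
  rt <- rosner_test(as.numeric(is_summary), alpha = alpha, kmax = kmax)
  ids <- names(is_summary)
  if (is.null(ids)) ids <- as.character(seq_along(is_summary))
  ids[rt$outlier_index]
}

#' Derived-feature recipes
#'
#' @param name Derived feature name (unique).
#' @param kind One of \code{ratio}, \code{sum}, \code{mean}.
#' @param operands Operand feature names (ratio: exactly 2; sum/mean: >= 2).
#' @return A \code{feature_recipe}.
#' @export
feature_recipe <- function(name, kind = c("ratio", "sum", "mean"), operands) {
  kind <- match.arg(kind)
  if (kind == "ratio" && length(operands) != 2L)
    config_error(name, "ratio recipes need exactly 2 operands")
  if (kind != "ratio" && length(operands) < 2L)
    config_error(name, "sum/mean recipes need >= 2 operands")
  structure(list(name = name, kind = kind, operands = operands),
            class = "feature_recipe")
}

#' Compute derived features on the linear scale
#'
#' Ratios, sums and means of retained measured features, computed per sample on
#' the linear scale before log2 transformation (so that the log2 of a ratio is
#' the difference of log2 values). A derived value is missing whenever any
#' operand is missing; a ratio with a zero denominator is missing.
#'
#' @param raw Feature table (linear scale).
#' @param recipes List of [feature_recipe()]s.
#' @return Feature table containing only the derived columns.
#' @export
derive_features <- function(raw, recipes) {
  M <- ft_matrix(raw)
  out <- matrix(NA_real_, nrow(M), length(recipes))
  nms <- character(length(recipes))
  for (k in seq_along(recipes)) {
    r <- recipes[[k]]
    stopifnot(inherits(r, "feature_recipe"))
    missing_ops <- setdiff(r$operands, colnames(M))
    if (length(missing_ops))
      config_error(r$name, paste0("references unavailable feature(s): ",
                                  paste(missing_ops, collapse = ", ")))
    X <- M[, r$operands, drop = FALSE]
    v <- switch(r$kind,
                ratio = ifelse(X[, 2] == 0, NA_real_, X[, 1] / X[, 2]),
                sum = rowSums(X),
                mean = rowMeans(X))
    v[apply(X, 1, anyNA)] <- NA_real_
    out[, k] <- v
    nms[k] <- r$name
  }
  if (anyDuplicated(nms)) stop("duplicate derived feature names")
  colnames(out) <- nms
  rownames(out) <- rownames(M)
  ft_table(out)
}

#' Read derived-feature recipes from CSV
#'
#' Expected columns: \code{name,kind,operands} with operands separated by
#' \code{;}.
#'
#' @param path CSV path.
#' @return List of [feature_recipe()]s.
#' @export
read_recipes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "kind", "operands") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    feature_recipe(df$name[i], df$kind[i],
                   trimws(strsplit(df$operands[i], ";")[[1]])))
}
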