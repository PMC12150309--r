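#' Run the full preprocessing pipeline
#'
#' Fixed stage order: (1) per-feature QC filtering against pooled-QC RSD,
#' blank background and missingness thresholds; (2) Rosner outlier removal on
#' the per-sample internal-standard summary; (3) derived-feature construction
#' on the linear scale; (4) log2 transformation; (5) QRILC imputation of
#' left-censored missing values; (6) autoscaling. Derived features inherit
#' missingness from their operands and are not re-filtered.
#'
#' @param features Study feature table, linear scale (first column
#'   `sample_id`).
#' @param qc Pooled-QC replicate table (linear scale).
#' @param blanks Method-blank replicate table (linear scale).
#' @param metadata Sample metadata; must cover all feature-table samples. The
#'   column named by \code{is_column}, when present, feeds the Rosner test.
#' @param recipes Optional list of [feature_recipe()]s.
#' @param thresholds A [qc_thresholds()].
#' @param tune QRILC scale multiplier.
#' @param is_column Name of the internal-standard summary column.
#' @param seed Seed for the imputation draws.
#' @return A \code{processed_dataset}: raw linear table (retained + derived),
#'   \code{log2} (with missing), \code{imputed}, \code{scaled}, \code{qc_report},
#'   \code{outlier_samples}, \code{scaling_params}, \code{imputation_params},
#'   \code{accounting} (per-stage sample/feature counts).
#' @export
preprocess <- function(features, qc, blanks, metadata,
                       recipes = NULL, thresholds = qc_thresholds(),
                       tune = 1, is_column = "is_log_mean", seed = NULL) {
  n_feat_in <- ncol(features) - 1L
  n_samp_in <- nrow(features)

  report <- compute_feature_qc(features, qc, blanks)
  report <- filter_features(report, thresholds)
  retained <- attr(report, "retained")
  if (length(retained) == 0) stop("no features pass QC")
  raw <- features[, c("sample_id", retained), drop = FALSE]

  outliers <- character(0)
  if (!is.null(metadata) && is_column %in% names(metadata)) {
    st <- stats::setNames(metadata[[is_column]], metadata$sample_id)
    st <- st[features$sample_id]
    if (length(st) >= thresholds$rosner_kmax + 3 && stats::sd(st) > 0)
      outliers <- detect_outlier_samples(st, alpha = thresholds$rosner_alpha,
                                         kmax = thresholds$rosner_kmax)
  }
  raw <- raw[!raw$sample_id %in% outliers, , drop = FALSE]

  if (!is.null(recipes) && length(recipes)) {
    drv <- derive_features(raw, recipes)
    raw <- cbind(raw, drv[, -1, drop = FALSE])
  }

  logtab <- log2_transform(raw)
  imp <- qrilc_impute(logtab, tune = tune, seed = seed)
  sc <- autoscale(imp$table)

  accounting <- data.frame(
    stage = c("input", "qc_filter", "outlier_removal", "derive"),
    n_samples = c(n_samp_in, n_samp_in, n_samp_in - length(outliers),
                  nrow(raw)),
    n_features = c(n_feat_in, length(retained), length(retained),
                   ncol(raw) - 1L),
    stringsAsFactors = FALSE)

  structure(list(raw = raw, log2 = logtab, imputed = imp$table,
                 scaled = sc$table, qc_report = report,
                 outlier_samples = outliers,
                 scaling_params = sc$params, imputation_params = imp$params,
                 accounting = accounting),
            class = "processed_dataset")
}

#' @export
print.processed_dataset <- function(x, ...) {
  cat("Processed metabolomics dataset\n")
  cat(sprintf("  samples: %d (outliers removed: %d)\n",
              nrow(x$raw), length(x$outlier_samples)))
  cat(sprintf("  features: %d retained of %d measured (+%d derived)\n",
              attr(x$qc_report, "n_retained"), nrow(x$qc_report),
              ncol(x$raw) - 1L - attr(x$qc_report, "n_retained")))
  invisible(x)
}
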