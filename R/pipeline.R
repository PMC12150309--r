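#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if needed); NULL = write nothing.
#' @param seed Master seed recorded in every output header.
#' @param features,qc,blanks,metadata Optional paths to input CSVs; when NULL
#'   a synthetic data set is generated from the spec objects below.
#' @param cspec,espec,mspec Synthetic-data specifications.
#' @param thresholds A [qc_thresholds()].
#' @param recipes Optional list of [feature_recipe()]s.
#' @param contrasts Model names to screen (default all five).
#' @param strata Named list of stratified runs, e.g.
#'   \code{list(sex = c("male", "female"))}.
#' @param B,freq_threshold Diagnostic bootstrap parameters.
#' @param verbose Print per-stage accounting.
#' @return A \code{run_config} list.
#' @export
run_config <- function(out_dir = NULL, seed = 1L,
                       features = NULL, qc = NULL, blanks = NULL, metadata = NULL,
                       cspec = cohort_spec(n_is_outliers = 4),
                       espec = effect_spec(qc_violators = c(high_cv = 7, high_blank = 7,
                                                            high_missing = 6)),
                       mspec = marker_spec(), thresholds = qc_thresholds(),
                       recipes = NULL,
                       contrasts = c("Inflamed", "Sepsis", "C_SINS", "C_S", "SINS_S"),
                       strata = list(sex = c("male", "female"),
                                     pathogen_type = c("gram_positive", "gram_negative")),
                       B = 100, freq_threshold = 0.45, verbose = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 features = features, qc = qc, blanks = blanks,
                 metadata = metadata, cspec = cspec, espec = espec,
                 mspec = mspec, thresholds = thresholds, recipes = recipes,
                 contrasts = contrasts, strata = strata, B = B,
                 freq_threshold = freq_threshold, verbose = verbose),
            class = "run_config")
}

# Cheap stable fingerprint of the configuration for output headers.
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %% .Machine$integer.max)
}

#' Execute the full pipeline
#'
#' Fixed order: simulate (or read) -> preprocess -> confounder identification
#' -> five-contrast mixed-model screen (+ requested strata) -> trend
#' classification -> STP curation and diagnostic modelling -> metabolite-marker
#' correlations. Every output CSV carries the seed and a configuration hash in
#' commented header lines; the returned bundle includes a per-stage accounting
#' log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage's results and \code{log}.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (config$verbose) message(msg)
  }
  meta_hdr <- c(seed = config$seed, config_hash = config_hash(config),
                package_version = as.character(utils::packageVersion("sepsismet")))
  emit <- function(df, name) {
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
      write_csv_meta(df, file.path(config$out_dir, name), meta_hdr)
    }
  }

  if (is.null(config$features)) {
    sim <- simulate_dataset(config$cspec, config$espec, config$mspec,
                            seed = config$seed)
    features <- sim$features; qc <- sim$qc; blanks <- sim$blanks
    metadata <- sim$metadata; truth <- sim$truth
    say("simulate: %d samples, %d features", nrow(features), ncol(features) - 1L)
  } else {
    features <- read_feature_table(config$features)
    qc <- read_feature_table(config$qc)
    blanks <- read_feature_table(config$blanks)
    metadata <- read_metadata(config$metadata, features)
    truth <- NULL
    say("read: %d samples, %d features", nrow(features), ncol(features) - 1L)
  }
  emit(features, "features.csv"); emit(metadata, "metadata.csv")

  ds <- preprocess(features, qc, blanks, metadata,
                   recipes = config$recipes, thresholds = config$thresholds,
                   seed = config$seed + 10L)
  say("preprocess: retained %d/%d features; removed %d outlier sample(s)",
      attr(ds$qc_report, "n_retained"), nrow(ds$qc_report),
      length(ds$outlier_samples))
  emit(ds$qc_report, "qc_report.csv")
  emit(ds$log2, "processed_log2.csv")
  emit(ds$scaled, "processed_scaled.csv")
  emit(ds$imputation_params, "imputation_params.csv")

  md <- metadata[match(ds$scaled$sample_id, metadata$sample_id), , drop = FALSE]
  conf <- identify_confounders(md, ds$scaled)
  say("confounders: %s",
      if (length(conf$covariates)) paste(conf$covariates, collapse = ", ") else "(none)")

  screens <- list()
  for (cn in config$contrasts) {
    screens[[cn]] <- run_screen(ds, md, cn, conf)
    say("screen %s: %d/%d features at q<0.1", cn,
        sum(screens[[cn]]$q < 0.1, na.rm = TRUE), nrow(screens[[cn]]))
    emit(screens[[cn]], sprintf("screen_%s.csv", cn))
  }
  for (sv in names(config$strata)) for (lv in config$strata[[sv]]) {
    nm <- sprintf("%s_%s", sv, lv)
    screens[[nm]] <- tryCatch(stratified_screen(ds, md, sv, lv, conf),
                              error = function(e) {
                                say("stratified screen %s skipped: %s", nm,
                                    conditionMessage(e))
                                NULL
                              })
    if (!is.null(screens[[nm]])) emit(screens[[nm]], sprintf("screen_%s.csv", nm))
  }

  trends <- NULL
  if (all(c("control", "SINS", "sepsis") %in% md$group)) {
    trends <- classify_trends(ds, md, conf)
    say("trends: %s", paste(names(table(trends$trend)), table(trends$trend),
                            sep = "=", collapse = ", "))
    emit(trends, "trends.csv")
  } else {
    say("trends skipped: not all three groups present")
  }

  stp_ids <- curate_stp(md)
  stp <- list(scaled = ds$scaled[ds$scaled$sample_id %in% stp_ids, , drop = FALSE],
              imputed = ds$imputed[ds$imputed$sample_id %in% stp_ids, , drop = FALSE])
  md_stp <- md[md$sample_id %in% stp_ids, , drop = FALSE]
  diag <- NULL
  n_sins <- sum(md_stp$group == "SINS"); n_sep <- sum(md_stp$group == "sepsis")
  if (n_sins >= 5 && n_sep >= 5) {
    diag <- run_diagnostics(stp, md_stp, B = config$B,
                            threshold = config$freq_threshold,
                            seed = config$seed + 20L)
    say("diagnostics: panel of %d feature(s); panel AUC %s", length(diag$panel),
        if (!is.null(diag$models$panel)) sprintf("%.3f", diag$models$panel$auc) else "NA")
    emit(data.frame(feature = names(diag$bootstrap$selection_freq),
                    frequency = unname(diag$bootstrap$selection_freq)),
         "selection_frequencies.csv")
    emit(diag$bootstrap$metrics, "bootstrap_metrics.csv")
    emit(diag$summary, "model_report.csv")
    if (!is.null(diag$comparisons)) emit(diag$comparisons, "comparisons.csv")
  } else {
    say("diagnostics skipped: STP has %d SINS / %d sepsis samples", n_sins, n_sep)
  }

  corr <- NULL
  if (!is.null(diag) && length(diag$panel)) {
    corr <- correlate_markers(stp, md_stp, features = diag$panel)
    emit(corr$correlations, "correlations.csv")
    emit(corr$differential, "differential_correlations.csv")
  }

  if (!is.null(config$out_dir))
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(metadata = metadata, features = features, truth = truth,
                 processed = ds, confounders = conf, screens = screens,
                 trends = trends, stp_ids = stp_ids, diagnostics = diag,
                 correlations = corr, log = log_lines, seed = config$seed))
}
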