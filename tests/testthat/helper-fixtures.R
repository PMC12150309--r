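# Small fixtures shared across test files; everything is generated in code.

# A compact simulated study: ~60 subjects, all generator stages.
tiny_sim <- function(seed = 11, n_subjects = 60, ...) {
  simulate_dataset(
    cspec = cohort_spec(n_subjects = n_subjects, seed = seed, ...),
    espec = effect_spec(n_features = 40, n_measured = 36,
                        class_counts = c(sepsis_specific = 4, shared_inflammation = 4),
                        censor_quantile = 0.05, seed = seed + 1),
    mspec = marker_spec(seed = seed + 2),
    seed = seed)
}

# Feature table from a plain matrix with default names.
mat_ft <- function(M, ids = sprintf("S%03d", seq_len(nrow(M)))) {
  colnames(M) <- colnames(M) %||% sprintf("F%03d", seq_len(ncol(M)))
  sepsismet::ft_table(M, sample_id = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal metadata for direct model-level tests: one row per sample.
toy_metadata <- function(group, subject_id = seq_along(group),
                         sex = rep(c("male", "female"), length.out = length(group))) {
  data.frame(sample_id = sprintf("S%04d", seq_along(group)),
             subject_id = as.character(subject_id), group = group,
             is_followup = FALSE, episode_index = ifelse(group == "control", 0L, 1L),
             sex = sex, pathogen_type = ifelse(group == "sepsis", "culture_negative", "none"),
             gestational_age = 27, birthweight = 900, postnatal_age = 21,
             tpn_proportion = 0.4, oxygen_pct = 30, sample_source = "capillary",
             mechanical_ventilation = 0L, ivh = 0L, antibiotics_24h = 0L,
             IL6 = 0, CRP = 0, PCT = 0, stringsAsFactors = FALSE)
}
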