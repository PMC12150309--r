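#' Write a table as CSV with a commented metadata header
#'
#' All pipeline outputs are plain CSV prefixed with \code{#}-comment lines
#' carrying the seed, a configuration hash and the package version, so every
#' file is diffable and self-describing. Missing values are serialized as
#' empty cells.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named character/numeric vector written as \code{# key: value}.
#' @export
write_csv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double",
                     na = "")
  invisible(path)
}

#' Read a feature table from CSV/TSV
#'
#' Expects a header row with \code{sample_id} first and numeric feature
#' columns; empty cells are missing. Lines starting with \code{#} are ignored.
#'
#' @param path File path (comma- or tab-separated, by extension).
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (names(df)[1] != "sample_id") stop("first column must be 'sample_id'")
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample_id: %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  if (anyDuplicated(names(df))) stop("duplicate feature names")
  for (j in seq_along(df)[-1]) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], names(df)[j], v[bad[1]]))
      df[[j]] <- as.numeric(v)
    }
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read and validate sample metadata
#'
#' Checks required columns, normalizes whitespace/case in the group label, and
#' validates categorical vocabularies (\code{group} in control/SINS/sepsis,
#' \code{pathogen_type} in none/culture_negative/gram_positive/gram_negative).
#'
#' @param path CSV path.
#' @param features Optional feature table; every feature sample must appear in
#'   the metadata.
#' @return Typed metadata data frame; validation warnings attached as
#'   \code{attr(, "warnings")}.
#' @export
read_metadata <- function(path, features = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(METADATA_REQUIRED, names(df))
  if (length(missing_cols))
    stop(sprintf("metadata is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  warns <- character(0)
  grp <- trimws(df$group)
  canon <- c(control = "control", sins = "SINS", sepsis = "sepsis")
  grp_norm <- unname(canon[tolower(grp)])
  changed <- !is.na(grp_norm) & grp_norm != df$group
  if (any(changed)) {
    warns <- c(warns, sprintf("%d group label(s) normalized", sum(changed)))
    warning(warns[length(warns)])
  }
  if (anyNA(grp_norm))
    stop(sprintf("unknown group label(s): %s",
                 paste(unique(df$group[is.na(grp_norm)]), collapse = ", ")))
  df$group <- grp_norm
  bad_path <- !df$pathogen_type %in% c("none", "culture_negative",
                                       "gram_positive", "gram_negative")
  if (any(bad_path))
    stop(sprintf("unknown pathogen_type label(s): %s",
                 paste(unique(df$pathogen_type[bad_path]), collapse = ", ")))
  df$is_followup <- as.logical(df$is_followup)
  if (!is.null(features)) {
    orphan <- setdiff(features$sample_id, df$sample_id)
    if (length(orphan))
      stop(sprintf("feature-table sample(s) missing from metadata: %s",
                   paste(orphan, collapse = ", ")))
  }
  attr(df, "warnings") <- warns
  df
}

#' Read a MetaboLights metabolite-assignment TSV
#'
#' Metabolite-assignment files store features in rows and samples in columns;
#' this reader transposes them into the package's samples-by-features layout.
#' Provided for ingesting deposited study data; no analysis depends on it.
#'
#' @param path TSV path.
#' @param feature_col Column holding the feature identifier (default
#'   \code{metabolite_identification}).
#' @param sample_cols Optional explicit sample column names; default = all
#'   numeric columns.
#' @return Feature table data frame.
#' @export
read_maf_table <- function(path, feature_col = "metabolite_identification",
                           sample_cols = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (!feature_col %in% names(df))
    stop(sprintf("column '%s' not found", feature_col))
  if (is.null(sample_cols))
    sample_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  M <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  colnames(M) <- make.unique(df[[feature_col]])
  ft_table(M, sample_id = sample_cols)
}
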