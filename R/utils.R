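# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a feature table to a numeric matrix
#'
#' Feature tables throughout the package are data frames whose first column is
#' `sample_id` and whose remaining columns are numeric feature abundances
#' (`NA` = missing / below detection).
#'
#' @param tab A feature table data frame.
#' @return Numeric matrix with sample IDs as row names.
#' @export
ft_matrix <- function(tab) {
  stopifnot(is.data.frame(tab), names(tab)[1] == "sample_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab$sample_id)
  m
}

#' Build a feature table from a matrix
#'
#' @param m Numeric matrix, samples in rows (row names = sample IDs).
#' @param sample_id Optional sample IDs overriding row names.
#' @return Feature table data frame (first column `sample_id`).
#' @export
ft_table <- function(m, sample_id = rownames(m)) {
  stopifnot(is.matrix(m), !is.null(sample_id))
  out <- data.frame(sample_id = as.character(sample_id), m,
                    check.names = FALSE, row.names = NULL)
  out
}

# Stop with a field-naming configuration error.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob_vector <- function(p, field, len = NULL) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    config_error(field, "must be a nonnegative numeric vector")
  if (!is.null(len) && length(p) != len)
    config_error(field, sprintf("must have length %d", len))
  if (abs(sum(p) - 1) > 1e-12)
    config_error(field, sprintf("must sum to 1 (got %.15g)", sum(p)))
  invisible(p)
}

check_prob_scalar <- function(p, field) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    config_error(field, "must be a probability in [0, 1]")
  invisible(p)
}

# Run code under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses (and advances) the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
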