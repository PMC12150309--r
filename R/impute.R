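#' Log2-transform a feature table
#'
#' @param raw Feature table on the linear scale; all observed values must be
#'   positive. Missing values stay missing.
#' @return Feature table on the log2 scale.
#' @export
log2_transform <- function(raw) {
  M <- ft_matrix(raw)
  bad <- which(!is.na(M) & M <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive value at sample '%s', feature '%s': cannot log2-transform",
                 rownames(M)[bad[1, 1]], colnames(M)[bad[1, 2]]))
  ft_table(log2(M))
}

# Censored-normal fit for one sample: plotting-position quantile regression of
# the sorted observed values on standard-normal quantiles.
qrilc_fit <- function(obs, m) {
  x <- sort(obs)
  n_obs <- length(x)
  p <- m + (1 - m) * (seq_len(n_obs) - 0.5) / n_obs
  z <- stats::qnorm(p)
  fit <- stats::lm.fit(cbind(1, z), x)
  c(mu = unname(fit$coefficients[1]), sigma = unname(fit$coefficients[2]))
}

#' Quantile regression imputation of left-censored data (QRILC)
#'
#' Treats each sample (row of the study table, i.e. one plasma specimen across
#' all features) as a left-censored normal: the sorted observed log2 values are
#' assigned plotting positions \eqn{p_k = m + (1-m)(k-0.5)/n_{obs}} (m =
#' missing fraction) and regressed on \eqn{\Phi^{-1}(p_k)}, giving a location
#' \eqn{\hat\mu} (intercept) and scale \eqn{\hat\sigma} (slope) for the full,
#' uncensored distribution. Missing values are then drawn from
#' \eqn{N(\hat\mu, tune\,\hat\sigma)} truncated above at
#' \eqn{\hat\mu + tune\,\hat\sigma\,\Phi^{-1}(m)} — the censoring limit implied
#' by the fit — so imputed values land in the left tail below all plausible
#' observed mass. Observed entries are returned bitwise unchanged.
#'
#' @param logtab Feature table on the log2 scale with missing values.
#' @param tune Scale multiplier for the imputation distribution (default 1).
#' @param seed RNG seed (NULL = current stream).
#' @return List with \code{table} (imputed) and \code{params} (per-sample
#'   data frame: mu, sigma, missing fraction, fallback flag).
#' @export
qrilc_impute <- function(logtab, tune = 1, seed = NULL) {
  stopifnot(tune > 0)
  M <- ft_matrix(logtab)
  n_feat <- ncol(M)
  with_seed_if(seed, {
    params <- data.frame(sample_id = rownames(M), mu = NA_real_,
                         sigma = NA_real_, missing_frac = NA_real_,
                         fallback = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(M))) {
      y <- M[i, ]
      miss <- is.na(y)
      m <- mean(miss)
      params$missing_frac[i] <- m
      if (!any(miss)) next
      obs <- y[!miss]
      if (length(obs) < 0.3 * n_feat) {
        # too few observed values for a reliable censored-normal fit
        warning(sprintf("sample '%s' has fewer than 30%% of features observed; using half-minimum imputation",
                        rownames(M)[i]))
        M[i, miss] <- min(obs) - 1     # half-minimum on the linear scale
        params$fallback[i] <- TRUE
        next
      }
      fit <- qrilc_fit(obs, m)
      params$mu[i] <- fit[["mu"]]; params$sigma[i] <- fit[["sigma"]]
      if (!is.finite(fit[["sigma"]]) || fit[["sigma"]] <= 0) {
        warning(sprintf("sample '%s': nonpositive censored-normal scale; using half-minimum imputation",
                        rownames(M)[i]))
        M[i, miss] <- min(obs) - 1     # half-minimum on the linear scale
        params$fallback[i] <- TRUE
        next
      }
      mu <- fit[["mu"]]; sg <- tune * fit[["sigma"]]
      upper <- mu + sg * stats::qnorm(m)
      # inverse-CDF draw from N(mu, sg) truncated above at `upper`
      pu <- stats::pnorm(upper, mu, sg)
      u <- stats::runif(sum(miss), 0, pu)
      M[i, miss] <- stats::qnorm(u, mu, sg)
    }
    list(table = ft_table(M), params = params)
  })
}

#' Autoscale (unit-variance scale) a complete feature table
#'
#' @param tab Feature table with no missing values.
#' @return List with \code{table} (per-feature mean 0, sd 1) and
#'   \code{params} (per-feature mean and sd).
#' @export
autoscale <- function(tab) {
  M <- ft_matrix(tab)
  if (anyNA(M)) stop("autoscale requires a complete (imputed) table")
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  if (any(sd == 0))
    stop(sprintf("constant feature(s) cannot be scaled: %s",
                 paste(colnames(M)[sd == 0], collapse = ", ")))
  Z <- sweep(sweep(M, 2, mu), 2, sd, `/`)
  list(table = ft_table(Z),
       params = data.frame(feature = colnames(M), mean = mu, sd = sd,
                           row.names = NULL, stringsAsFactors = FALSE))
}
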