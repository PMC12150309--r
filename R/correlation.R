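#' Spearman correlation within a group
#'
#' Rank correlation with average ranks for ties; two-sided p from the t
#' approximation \eqn{t = \rho_s \sqrt{(n-2)/(1-\rho_s^2)}}.
#'
#' @param x,y Numeric vectors (n >= 4, each with >= 2 distinct values).
#' @return List: rho, n, p (p is NA when either vector is constant).
#' @export
spearman_group <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("Spearman correlation needs n >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, n = n, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, n = n, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, n = n, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Differential correlation between two groups
#'
#' Fisher r-to-z two-sample test:
#' \eqn{z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
#' \sqrt{1/(n_1-3) + 1/(n_2-3)}}, two-sided normal p. The Spearman-specific
#' 1.06 variance inflation can be switched on.
#'
#' @param r1,n1 Correlation and size in group 1.
#' @param r2,n2 Correlation and size in group 2.
#' @param spearman_adjust Multiply both variances by 1.06 (default FALSE).
#' @return List: z, p (z > 0 when r1 > r2).
#' @export
differential_correlation <- function(r1, n1, r2, n2, spearman_adjust = FALSE) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1: Fisher z-transform diverges")
  v <- 1 / (n1 - 3) + 1 / (n2 - 3)
  if (spearman_adjust) v <- 1.06 * v
  z <- (atanh(r1) - atanh(r2)) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Metabolite-marker correlation profiles in SINS and sepsis
#'
#' Spearman correlations of each feature with each inflammatory marker within
#' each condition, plus the differential-correlation test between the two
#' conditions.
#'
#' @param ds A \code{processed_dataset} (uses the imputed log2 table).
#' @param metadata Sample metadata with markers populated.
#' @param features Feature names (default: all).
#' @param markers Marker column names (default IL6, CRP, PCT).
#' @param groups The two conditions compared (default SINS, sepsis).
#' @return List with \code{correlations} (per feature x marker x group) and
#'   \code{differential} (per feature x marker).
#' @export
correlate_markers <- function(ds, metadata, features = NULL,
                              markers = c("IL6", "CRP", "PCT"),
                              groups = c("SINS", "sepsis")) {
  M <- ft_matrix(ds$imputed)
  md <- metadata[match(rownames(M), metadata$sample_id), , drop = FALSE]
  if (is.null(features)) features <- colnames(M)
  cor_rows <- list(); diff_rows <- list()
  for (f in features) for (mk in markers) {
    res <- lapply(groups, function(g) {
      sel <- md$group == g
      spearman_group(M[sel, f], md[[mk]][sel])
    })
    names(res) <- groups
    for (g in groups)
      cor_rows[[length(cor_rows) + 1L]] <-
        data.frame(feature = f, marker = mk, group = g, rho = res[[g]]$rho,
                   n = res[[g]]$n, p = res[[g]]$p, stringsAsFactors = FALSE)
    r1 <- res[[1]]; r2 <- res[[2]]
    dz <- if (anyNA(c(r1$rho, r2$rho)) || abs(r1$rho) >= 1 || abs(r2$rho) >= 1)
      list(z = NA_real_, p = NA_real_)
    else differential_correlation(r1$rho, r1$n, r2$rho, r2$n)
    diff_rows[[length(diff_rows) + 1L]] <-
      data.frame(feature = f, marker = mk, rho_1 = r1$rho, n_1 = r1$n,
                 rho_2 = r2$rho, n_2 = r2$n, z = dz$z, p = dz$p,
                 stringsAsFactors = FALSE)
  }
  list(correlations = do.call(rbind, cor_rows),
       differential = do.call(rbind, diff_rows))
}
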