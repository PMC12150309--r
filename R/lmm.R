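#' Contrast specifications for the five screening models
#'
#' \describe{
#'   \item{Inflamed}{all samples; SINS and sepsis coded 1 vs control 0.}
#'   \item{Sepsis}{all samples; sepsis coded 1 vs control + SINS 0.}
#'   \item{C_SINS}{control vs SINS only; SINS coded 1.}
#'   \item{C_S}{control vs sepsis only; sepsis coded 1.}
#'   \item{SINS_S}{SINS vs sepsis only; sepsis coded 1.}
#' }
#'
#' @param name One of the five model names.
#' @return A \code{contrast_spec} with \code{groups} (included groups) and
#'   \code{coded1} (groups mapped to 1).
#' @export
contrast_spec <- function(name = c("Inflamed", "Sepsis", "C_SINS", "C_S", "SINS_S")) {
  name <- match.arg(name)
  def <- switch(name,
    Inflamed = list(groups = c("control", "SINS", "sepsis"), coded1 = c("SINS", "sepsis")),
    Sepsis   = list(groups = c("control", "SINS", "sepsis"), coded1 = "sepsis"),
    C_SINS   = list(groups = c("control", "SINS"), coded1 = "SINS"),
    C_S      = list(groups = c("control", "sepsis"), coded1 = "sepsis"),
    SINS_S   = list(groups = c("SINS", "sepsis"), coded1 = "sepsis"))
  structure(c(list(name = name), def), class = "contrast_spec")
}

# Build the fixed-effects design for a contrast: intercept, 0/1 contrast code,
# confounder columns (factors expanded via model.matrix).
build_design <- function(metadata, contrast, confounders) {
  keep <- metadata$group %in% contrast$groups
  md <- metadata[keep, , drop = FALSE]
  code <- as.numeric(md$group %in% contrast$coded1)
  if (length(confounders)) {
    fml <- stats::as.formula(paste("~", paste(confounders, collapse = " + ")))
    mm <- stats::model.matrix(fml, data = md)
    X <- cbind(`(Intercept)` = 1, contrast = code, mm[, -1, drop = FALSE])
  } else {
    X <- cbind(`(Intercept)` = 1, contrast = code)
  }
  list(X = X, metadata = md, keep = which(keep))
}

#' Fit one feature's linear mixed model for a contrast
#'
#' Model: \code{y ~ contrast + confounders + (1 | subject)}, fit by REML with
#' a two-sided Satterthwaite-adjusted Wald test for the contrast coefficient
#' (via \pkg{lmerTest}). A singular random-intercept fit (subject variance
#' estimated at zero) is refit as a fixed-effects linear model and flagged; a
#' failed fit returns an NA row rather than an error so a metabolome-wide
#' screen never crashes on one feature.
#'
#' @param y Feature values (typically autoscaled log2), aligned to
#'   \code{metadata} rows.
#' @param metadata Sample metadata with \code{group} and \code{subject_id}.
#' @param contrast A [contrast_spec()] (samples outside its groups are dropped).
#' @param confounders Character vector of confounder column names.
#' @return One-row data frame: estimate, se, df, p, flag
#'   (\code{"ok"}, \code{"singular_lm"} or \code{"failed"}).
#' @export
fit_contrast_lmm <- function(y, metadata, contrast, confounders = character(0)) {
  stopifnot(inherits(contrast, "contrast_spec"), length(y) == nrow(metadata))
  keep <- metadata$group %in% contrast$groups
  md <- metadata[keep, , drop = FALSE]
  md$.y <- y[keep]
  md$.code <- as.numeric(md$group %in% contrast$coded1)
  rhs <- c(".code", confounders, "(1 | subject_id)")
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  lm_fallback <- function() {
    lfml <- stats::as.formula(paste(".y ~", paste(c(".code", confounders), collapse = " + ")))
    lf <- stats::lm(lfml, data = md)
    co <- summary(lf)$coefficients[".code", ]
    data.frame(estimate = co[["Estimate"]], se = co[["Std. Error"]],
               df = lf$df.residual, p = co[["Pr(>|t|)"]], flag = "singular_lm",
               stringsAsFactors = FALSE)
  }
  res <- tryCatch({
    fit <- suppressMessages(lmerTest::lmer(fml, data = md, REML = TRUE,
                                           control = lme4::lmerControl(calc.derivs = FALSE,
                                                                       check.conv.singular = "ignore")))
    if (lme4::isSingular(fit, tol = 1e-6)) {
      lm_fallback()
    } else {
      co <- stats::coef(summary(fit))[".code", ]
      data.frame(estimate = co[["Estimate"]], se = co[["Std. Error"]],
                 df = co[["df"]], p = co[["Pr(>|t|)"]], flag = "ok",
                 stringsAsFactors = FALSE)
    }
  }, error = function(e) {
    # e.g. one observation per subject: the random intercept is not estimable
    tryCatch(lm_fallback(), error = function(e2)
      data.frame(estimate = NA_real_, se = NA_real_, df = NA_real_, p = NA_real_,
                 flag = "failed", stringsAsFactors = FALSE))
  })
  res
}

# ---------------------------------------------------------------------------
# Fast profiled-REML random-intercept engine.
#
# The screen refits the identical design (X, subject grouping) for hundreds of
# features, so instead of rebuilding a full lmer fit per feature we profile the
# REML criterion in the single variance ratio lambda = tau2/sigma2. For the
# random-intercept model V = sigma2 (I + lambda Z Z'), cluster i of size n_i
# contributes (I + lambda J_i)^{-1} = I - ((1 - e_i)/n_i) J_i with
# e_i = 1/(1 + n_i lambda), so every GLS quantity reduces to cluster sums of X
# and y. Satterthwaite df come from the closed-form expected REML information
# of (sigma2, tau2). Agreement with lmerTest::lmer is enforced by tests.
# ---------------------------------------------------------------------------

reml_precompute <- function(X, cluster) {
  cl <- as.integer(factor(cluster))
  ncl <- max(cl)
  n_i <- tabulate(cl, ncl)
  # q x ncl matrix of cluster sums of X
  Sg <- t(rowsum(X, cl, reorder = TRUE))
  list(X = X, cl = cl, ncl = ncl, n_i = n_i, Sg = Sg,
       XtX = crossprod(X), n = nrow(X), q = ncol(X))
}

# weighted cluster outer-product sum: sum_i w_i S_i S_i'
wsum <- function(Sg, w) Sg %*% (w * t(Sg))

reml_fit_one <- function(pre, y, jcoef = 2L) {
  n <- pre$n; q <- pre$q; n_i <- pre$n_i
  ty <- rowsum(y, pre$cl, reorder = TRUE)[, 1]     # cluster sums of y
  Xty <- crossprod(pre$X, y)
  yty <- sum(y^2)

  gls <- function(lam) {
    e <- 1 / (1 + n_i * lam)
    cc <- (1 - e) / n_i                            # c_i
    XtWX <- pre$XtX - wsum(pre$Sg, cc)
    XtWy <- Xty - pre$Sg %*% (cc * ty)
    yWy <- yty - sum(cc * ty^2)
    R <- chol(XtWX)
    beta <- backsolve(R, forwardsolve(t(R), XtWy))
    rss <- yWy - sum(XtWy * beta)
    list(e = e, XtWX = XtWX, R = R, beta = beta, rss = max(rss, 1e-300))
  }
  obj <- function(lam) {
    g <- gls(lam)
    (n - q) * log(g$rss) + sum(log1p(n_i * lam)) + 2 * sum(log(diag(g$R)))
  }
  opt <- stats::optimize(function(u) obj(exp(u)), c(log(1e-8), log(1e3)), tol = 1e-10)
  lam <- exp(opt$minimum)
  singular <- obj(0) <= opt$objective + 1e-8
  if (singular) lam <- 0
  g <- gls(lam)
  sigma2 <- g$rss / (n - q)
  Cmat <- chol2inv(g$R) * sigma2                   # vcov of beta
  est <- g$beta[jcoef]
  se <- sqrt(Cmat[jcoef, jcoef])

  if (singular) {
    df <- n - q
  } else {
    e <- g$e
    a <- 1 / sigma2
    tau2 <- lam * sigma2
    XtWXi <- chol2inv(g$R)                         # (X'WX)^-1
    # weighted sums for powers of W and WJW combinations
    S2 <- pre$XtX - wsum(pre$Sg, (1 - e^2) / n_i)  # X'W^2X
    S3 <- pre$XtX - wsum(pre$Sg, (1 - e^3) / n_i)  # X'W^3X
    SJ <- wsum(pre$Sg, e^2)                        # X'WJWX
    SIJ <- wsum(pre$Sg, e^3)                       # X'W^2JWX (= X'WJW^2X)
    SJJ <- wsum(pre$Sg, e^3 * n_i)                 # X'WJWJWX
    # A_a = X'V^-1 V_a V^-1 X ; M_ab = X'V^-1 V_a V^-1 V_b V^-1 X
    A_I <- a^2 * S2; A_J <- a^2 * SJ
    M_II <- a^3 * S3; M_IJ <- a^3 * SIJ; M_JJ <- a^3 * SJJ
    # scalar traces of V^-1 products
    tr_II <- a^2 * sum(n_i - 1 + e^2)
    tr_IJ <- a^2 * sum(e^2 * n_i)
    tr_JJ <- a^2 * sum(e^2 * n_i^2)
    Cx <- XtWXi / a                                # (X'V^-1X)^-1
    tCM <- function(M) sum(Cx * M)                 # tr(Cx %*% M), M symmetric
    CAI <- Cx %*% A_I; CAJ <- Cx %*% A_J
    trP_II <- tr_II - 2 * tCM(M_II) + sum(CAI * t(CAI))
    trP_IJ <- tr_IJ - 2 * tCM(M_IJ) + sum(CAI * t(CAJ))
    trP_JJ <- tr_JJ - 2 * tCM(M_JJ) + sum(CAJ * t(CAJ))
    # observed REML information: I_ab = (2 y'P V_a P V_b P y - tr(P V_a P V_b))/2
    # with Py = V^-1 r (the GLS residual kills the projection term)
    cl <- pre$cl; cc <- (1 - e) / n_i
    r <- y - drop(pre$X %*% g$beta)
    tr_cl <- rowsum(r, cl, reorder = TRUE)[, 1]
    w <- a * (r - (cc * tr_cl)[cl])                # V^-1 r
    u_J <- a * (e * tr_cl)[cl]                     # Z Z' V^-1 r
    Vinv <- function(v) {
      sv <- rowsum(v, cl, reorder = TRUE)[, 1]
      a * (v - (cc * sv)[cl])
    }
    quad <- function(ua, ub) {
      xa <- crossprod(pre$X, Vinv(ua)); xb <- crossprod(pre$X, Vinv(ub))
      sum(ua * Vinv(ub)) - drop(t(xa) %*% Cx %*% xb)
    }
    I_ss <- 0.5 * (2 * quad(w, w) - trP_II)
    I_st <- 0.5 * (2 * quad(w, u_J) - trP_IJ)
    I_tt <- 0.5 * (2 * quad(u_J, u_J) - trP_JJ)
    Info <- matrix(c(I_ss, I_st, I_st, I_tt), 2, 2)
    Avar <- tryCatch(solve(Info), error = function(e) NULL)
    gI <- (Cx %*% A_I %*% Cx)[jcoef, jcoef]
    gJ <- (Cx %*% A_J %*% Cx)[jcoef, jcoef]
    df <- if (is.null(Avar)) n - q else {
      gvec <- c(gI, gJ)
      denom <- drop(t(gvec) %*% Avar %*% gvec)
      if (denom <= 0) n - q else 2 * Cmat[jcoef, jcoef]^2 / denom
    }
    df <- min(max(df, 1), n - q)
  }
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  c(estimate = est, se = se, df = df, p = p, singular = as.numeric(singular),
    sigma2 = sigma2, tau2 = lam * sigma2)
}

# Screen-scale engine: fit every column of Y against the shared design.
reml_screen <- function(Y, X, cluster) {
  pre <- reml_precompute(X, cluster)
  out <- t(apply(Y, 2, function(y) reml_fit_one(pre, y)))
  as.data.frame(out)
}
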