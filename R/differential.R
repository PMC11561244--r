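#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order. Inputs outside `[0, 1]` are a
#' validation error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

# Newton inversion of the trigamma function (for the variance prior fit).
.trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates a scaled-inverse-chi-squared prior (`d0` degrees of freedom,
#' `s0_sq` location) for per-site residual variances by moment-matching the
#' distribution of `log s^2`: if `s^2 ~ s0^2 * F(d, d0)`-scaled, then
#' `log s^2` has known digamma/trigamma moments, giving closed-form
#' estimating equations. Sites with zero residual variance carry no
#' information about the prior and are excluded from the fit (they are
#' still shrunk toward `s0_sq` afterwards).
#'
#' @param s2 per-site residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list of class `"ModerationPrior"`: `d0` (possibly `Inf`),
#'   `s0_sq`.
#' @export
fitModerationPrior <- function(s2, df) {
  stopifnot(df > 0)
  pos <- s2 > 0 & is.finite(s2)
  if (sum(pos) < 2L) {
    return(structure(list(d0 = Inf, s0_sq = mean(s2[pos], na.rm = TRUE)),
                     class = "ModerationPrior"))
  }
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ModerationPrior")
}

#' Shrink residual variances toward the prior
#'
#' @param s2 per-site residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param prior a `"ModerationPrior"` from [fitModerationPrior()].
#' @return moderated variances `(d0*s0_sq + df*s2) / (d0 + df)` (equal to
#'   `s0_sq` everywhere when `d0` is infinite).
#' @export
squeezeVariances <- function(s2, df, prior) {
  stopifnot(inherits(prior, "ModerationPrior"))
  if (!is.finite(prior$d0)) return(rep(prior$s0_sq, length(s2)))
  (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
}

# Build the per-site design matrix from a sample design data.frame.
# Constant covariate columns are uninformative and dropped with a warning;
# genuine collinearity among the remaining columns is an error.
.design_matrix <- function(design) {
  n <- nrow(design)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  add <- function(X, v, nm) {
    if (length(unique(v)) < 2L) {
      warning(sprintf("covariate '%s' is constant and was dropped", nm),
              call. = FALSE)
      return(X)
    }
    cbind(X, setNames(data.frame(v), nm))
  }
  if (is.null(design$group)) stop("design needs a 'group' column",
                                  call. = FALSE)
  X <- cbind(X, group = as.numeric(design$group == "postnatal"))
  if (length(unique(design$group)) < 2L)
    stop("both groups must be present in the design", call. = FALSE)
  if (!is.null(design$sex)) X <- add(X, as.numeric(design$sex == "M"), "sex")
  if (!is.null(design$adar_expr)) X <- add(X, design$adar_expr, "adar_expr")
  if (!is.null(design$adarb1_expr))
    X <- add(X, design$adarb1_expr, "adarb1_expr")
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  X
}

# one OLS pass over all sites; Y is sites x samples, X samples x p
.ols_all_sites <- function(Y, X) {
  n <- ncol(Y); p <- ncol(X)
  if (n - p <= 0)
    stop("zero residual degrees of freedom", call. = FALSE)
  XtXinv <- solve(crossprod(X))
  B <- Y %*% X %*% XtXinv               # sites x p coefficients
  resid <- Y - B %*% t(X)
  s2 <- rowSums(resid^2) / (n - p)
  s2[s2 < 1e-20] <- 0                   # numerically exact fits
  list(B = B, s2 = s2, df = n - p, v = diag(XtXinv))
}

#' Differential editing with covariate adjustment and variance moderation
#'
#' Fits, per site, an ordinary-least-squares model of editing level on
#' developmental group plus confounders (sex, ADAR expression, ADARB1
#' expression — whichever the design provides), then tests the group
#' coefficient. With `moderation = TRUE` the per-site residual variances
#' are shrunk toward an empirical-Bayes prior fitted across all sites
#' ([fitModerationPrior()]), and the moderated t-statistic uses
#' `d0 + df` degrees of freedom; with `moderation = FALSE` the plain OLS
#' t-statistic is returned. P-values are BH-adjusted ([bhAdjust()]), and
#' `delta` — the postnatal-minus-prenatal difference of group mean editing
#' — is reported from the *observed* (pre-imputation) matrix when one is
#' supplied, with the model coefficient `beta_group` reported separately.
#'
#' `x` may be a completed numeric matrix (or complete
#' [EditingMatrix-class]), or a `"RubinSet"` from
#' [consensusMatrix()] in which case each completion is fitted and the
#' results pooled by Rubin's rules: coefficients averaged, total variance
#' `W + (1 + 1/m) B` (within + between), with Barnard-Rubin style degrees
#' of freedom.
#'
#' @param x completed matrix, `EditingMatrix`, or `"RubinSet"`.
#' @param design sample design data.frame (`group`, optionally `sex`,
#'   `adar_expr`, `adarb1_expr`), rows matching the matrix columns.
#' @param moderation shrink variances (`TRUE`, default) or plain OLS.
#' @param observed optional sites x samples matrix with `NA`s — the
#'   pre-imputation data used for `delta`.
#' @return data.frame `site_id`, `delta`, `beta_group`, `t_mod`, `p`,
#'   `fdr`, `s2`, `s2_post`, `df_total`; the fitted prior is attached as
#'   attribute `prior`.
#' @export
fitDifferential <- function(x, design, moderation = TRUE, observed = NULL) {
  if (is(x, "EditingMatrix")) {
    if (is.null(observed)) observed <- editingLevels(x)
    x <- editingLevels(x)
    if (anyNA(x))
      stop("matrix still contains missing values; impute first",
           call. = FALSE)
  }
  if (inherits(x, "RubinSet")) {
    return(.fit_rubin(x, design, moderation, observed))
  }
  Y <- as.matrix(x)
  stopifnot(nrow(design) == ncol(Y))
  if (min(table(design$group)) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  X <- .design_matrix(design)
  fit <- .ols_all_sites(Y, X)
  gi <- match("group", colnames(X))
  beta <- fit$B[, gi]
  if (moderation) {
    prior <- fitModerationPrior(fit$s2, fit$df)
    s2_post <- squeezeVariances(fit$s2, fit$df, prior)
    df_total <- min(prior$d0, 1e6) + fit$df
  } else {
    prior <- structure(list(d0 = 0, s0_sq = NA_real_),
                       class = "ModerationPrior")
    s2_post <- fit$s2
    df_total <- fit$df
  }
  tstat <- beta / sqrt(s2_post * fit$v[gi])
  pval <- 2 * pt(-abs(tstat), df = df_total)
  exact <- s2_post == 0
  pval[exact] <- ifelse(abs(beta[exact]) < 1e-12, 1, 0)
  delta <- .observed_delta(if (is.null(observed)) Y else observed, design)
  out <- data.frame(site_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
                    delta = delta, beta_group = beta, t_mod = tstat,
                    p = pval, fdr = bhAdjust(pval), s2 = fit$s2,
                    s2_post = s2_post, df_total = df_total)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  out
}

.observed_delta <- function(obs, design) {
  post <- design$group == "postnatal"
  rowMeans(obs[, post, drop = FALSE], na.rm = TRUE) -
    rowMeans(obs[, !post, drop = FALSE], na.rm = TRUE)
}

.fit_rubin <- function(x, design, moderation, observed) {
  m <- length(x$matrices)
  fits <- lapply(x$matrices, fitDifferential, design = design,
                 moderation = moderation, observed = observed)
  beta <- rowMeans(sapply(fits, `[[`, "beta_group"))
  se2 <- sapply(fits, function(f) (f$beta_group / f$t_mod)^2)
  se2[!is.finite(se2)] <- 0
  W <- rowMeans(se2)
  B <- if (m > 1) apply(sapply(fits, `[[`, "beta_group"), 1L, var) else 0
  Tvar <- W + (1 + 1 / m) * B
  tstat <- beta / sqrt(Tvar)
  df_within <- fits[[1L]]$df_total
  r <- (1 + 1 / m) * B / W
  df_total <- ifelse(B > 0 & m > 1,
                     pmin((m - 1) * (1 + 1 / r)^2, df_within), df_within)
  pval <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(site_id = fits[[1L]]$site_id,
                    delta = if (is.null(observed)) fits[[1L]]$delta else
                      .observed_delta(observed, design),
                    beta_group = beta, t_mod = tstat, p = pval,
                    fdr = bhAdjust(pval),
                    s2 = rowMeans(sapply(fits, `[[`, "s2")),
                    s2_post = rowMeans(sapply(fits, `[[`, "s2_post")),
                    df_total = df_total)
  rownames(out) <- NULL
  attr(out, "prior") <- attr(fits[[1L]], "prior")
  out
}
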