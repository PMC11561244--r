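test_that("BH adjustment matches the closed forms and validates input", {
  expect_equal(bhAdjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bhAdjust(rep(0.03, 5L)), rep(0.03, 5L))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  expect_error(bhAdjust(c(0.5, -0.1)), "0, 1")
})

test_that("BH equals a brute-force step-up on random p-vectors", {
  set.seed(8)
  for (i in 1:1000) {
    p <- runif(sample(1:60, 1L))
    expect_equal(bhAdjust(p), brute_force_bh(p))
  }
})

test_that("noise-free fits recover coefficients exactly", {
  design <- two_group_design(5L, seed = 2L)
  g <- as.numeric(design$group == "postnatal")
  Y <- rbind(site1 = 0.1 + 0.2 * g,
             site2 = 0.3 + 0.0 * g)
  fit <- fitDifferential(Y, design, moderation = FALSE)
  expect_equal(fit$beta_group, c(0.2, 0), tolerance = 1e-12)
  expect_equal(fit$s2, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$delta, c(0.2, 0), tolerance = 1e-12)
  # zero-variance convention: exact effect -> p 0, exact null -> p 1
  expect_equal(fit$p, c(0, 1))
})

test_that("moderation off reproduces per-site OLS t-statistics exactly", {
  set.seed(5)
  design <- two_group_design(8L, seed = 5L)
  Y <- matrix(rnorm(40 * 16, 0.3, 0.05), 40L, 16L)
  rownames(Y) <- sprintf("s%02d", 1:40)
  colnames(Y) <- design$sample_id
  fit <- fitDifferential(Y, design, moderation = FALSE)
  for (i in c(1L, 7L, 40L)) {
    lmfit <- lm(Y[i, ] ~ I(design$group == "postnatal") +
                  I(design$sex == "M") + design$adar_expr +
                  design$adarb1_expr)
    sm <- summary(lmfit)$coefficients
    expect_equal(fit$t_mod[i], sm[2L, "t value"], tolerance = 1e-10)
    expect_equal(fit$p[i], sm[2L, "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("variance moderation matches the shrinkage formula and limma", {
  set.seed(9)
  design <- two_group_design(8L, seed = 9L)
  Y <- matrix(rnorm(200 * 16, 0.3,
                    rep(sqrt(rchisq(200, 5) / 5) * 0.05, 16L)),
              200L, 16L)
  colnames(Y) <- design$sample_id
  fit <- fitDifferential(Y, design, moderation = TRUE)
  prior <- attr(fit, "prior")
  expect_true(prior$d0 > 0)
  expect_true(prior$s0_sq > 0)

  # every moderated variance lies strictly between its own s2 and s0_sq
  off <- abs(fit$s2 - prior$s0_sq) > 1e-12
  between <- (fit$s2_post > pmin(fit$s2, prior$s0_sq)) &
    (fit$s2_post < pmax(fit$s2, prior$s0_sq))
  expect_true(all(between[off]))

  # degenerate case: identical residual variances give an infinite-df
  # prior, so every site is shrunk to one common value that differs from
  # the shared s2 only by the known finite-df bias of the log-variance
  # moment estimator, exp(log(df/2) - digamma(df/2))
  g <- as.numeric(design$group == "postnatal")
  resid_fix <- rnorm(16L)
  resid_fix <- resid(lm(resid_fix ~ g + design$adar_expr))
  Yfix <- 0.2 + outer(rep(1, 30L), resid_fix * 0.1)
  colnames(Yfix) <- design$sample_id
  dfix <- design[, c("sample_id", "group", "adar_expr")]
  ffix <- fitDifferential(Yfix, dfix, moderation = TRUE)
  pfix <- attr(ffix, "prior")
  expect_equal(pfix$d0, Inf)
  dffix <- 16L - 3L
  bias <- exp(log(dffix / 2) - digamma(dffix / 2))
  expect_equal(ffix$s2_post, ffix$s2 * bias, tolerance = 1e-8)
  expect_equal(ffix$s2_post, rep(ffix$s2_post[1L], 30L), tolerance = 1e-10)

  # independent oracle: limma's squeezeVar on the same variances
  skip_if_not_installed("limma")
  df_resid <- ncol(Y) - 5L
  sq <- limma::squeezeVar(fit$s2, df = df_resid)
  expect_equal(prior$d0, sq$df.prior, tolerance = 1e-4)
  expect_equal(prior$s0_sq, sq$var.prior, tolerance = 1e-4)
  expect_equal(fit$s2_post, sq$var.post, tolerance = 1e-8)

  # and limma's full moderated t on the same design
  X <- cbind(1, g, as.numeric(design$sex == "M"), design$adar_expr,
             design$adarb1_expr)
  lfit <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(fit$t_mod, unname(lfit$t[, 2L]), tolerance = 1e-8)
  expect_equal(fit$p, unname(lfit$p.value[, 2L]), tolerance = 1e-8)
})

test_that("infinite prior df shrinks every variance to the prior", {
  prior <- structure(list(d0 = Inf, s0_sq = 0.02),
                     class = "ModerationPrior")
  s2 <- c(0, 0.001, 0.02, 1)
  expect_equal(squeezeVariances(s2, 10, prior), rep(0.02, 4L))
  # large but finite d0 approaches the same limit
  prior2 <- structure(list(d0 = 1e9, s0_sq = 0.02),
                      class = "ModerationPrior")
  expect_equal(squeezeVariances(s2, 10, prior2), rep(0.02, 4L),
               tolerance = 1e-6)
})

test_that("design validation catches rank deficiency and tiny groups", {
  design <- two_group_design(4L, seed = 1L)
  design$adarb1_expr <- design$adar_expr  # collinear duplicate
  Y <- matrix(rnorm(10 * 8, 0.3, 0.05), 10L, 8L)
  colnames(Y) <- design$sample_id
  expect_error(fitDifferential(Y, design), "adarb1_expr")

  d1 <- two_group_design(4L, seed = 1L)
  d1$group <- c("prenatal", rep("postnatal", 7L))
  expect_error(fitDifferential(Y, d1), "2 samples per group")

  dconst <- two_group_design(4L, seed = 1L)
  dconst$sex <- "M"
  expect_warning(fitDifferential(Y, dconst), "constant")
})

test_that("Rubin pooling widens uncertainty with between-imputation spread", {
  design <- two_group_design(6L, seed = 3L)
  set.seed(13)
  base <- matrix(rnorm(30 * 12, 0.3, 0.05), 30L, 12L)
  colnames(base) <- design$sample_id
  imps <- lapply(1:5, function(i)
    base + matrix(rnorm(length(base), 0, 0.01), nrow(base)))
  rb <- consensusMatrix(imps, "rubin")
  fit_rb <- fitDifferential(rb, design, moderation = FALSE)
  fits <- lapply(imps, fitDifferential, design = design,
                 moderation = FALSE)
  beta_bar <- rowMeans(sapply(fits, `[[`, "beta_group"))
  expect_equal(fit_rb$beta_group, beta_bar, tolerance = 1e-12)
  # total variance >= average within-imputation variance
  W <- rowMeans(sapply(fits, function(f) (f$beta_group / f$t_mod)^2))
  T_implied <- (fit_rb$beta_group / fit_rb$t_mod)^2
  expect_true(all(T_implied >= W - 1e-12))

  # m = 1: within-variance only, identical to the single fit
  rb1 <- consensusMatrix(imps[1L], "rubin")
  f1 <- fitDifferential(rb1, design, moderation = FALSE)
  expect_equal(f1$t_mod, fits[[1L]]$t_mod, tolerance = 1e-12)
})

test_that("false discoveries stay controlled and true effects recover", {
  set.seed(31)
  n_sites <- 2000L; n_per <- 10L; n_reps <- 20L
  design <- two_group_design(n_per, seed = 31L)
  fdp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    Y <- matrix(rnorm(n_sites * 2L * n_per, 0.25, 0.05), n_sites)
    colnames(Y) <- design$sample_id
    fit <- fitDifferential(Y, design, moderation = TRUE)
    R <- sum(fit$fdr < 0.05)
    fdp[r] <- if (R > 0) 1 else 0  # all sites are null
  }
  mc_se <- sd(fdp) / sqrt(n_reps)
  expect_lte(mean(fdp), 0.05 + 2 * mc_se + 1e-9)

  # parameter recovery: delta 0.15 in 10% of sites
  truth_idx <- seq_len(n_sites / 10L)
  g <- as.numeric(design$group == "postnatal")
  Y <- matrix(rnorm(n_sites * 2L * n_per, 0.25, 0.05), n_sites)
  Y[truth_idx, ] <- Y[truth_idx, ] + 0.15 * rep(g, each = length(truth_idx))
  colnames(Y) <- design$sample_id
  fit <- fitDifferential(Y, design, moderation = TRUE)
  disc <- which(fit$fdr < 0.05)
  expect_gt(length(disc), 100L)
  expect_lt(abs(mean(fit$beta_group[disc]) - 0.15), 0.03)
})
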