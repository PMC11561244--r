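#' Multiple-imputation settings
#'
#' @param m number of imputed completions.
#' @param max_iter chained-equation sweeps per completion.
#' @param donors predictive-mean-matching donor pool size.
#' @param k_sites number of most-correlated other sites used as predictors
#'   in each site's imputation model (keeps the chained equations tractable
#'   on matrices with thousands of sites, in the spirit of quick-predictor
#'   selection).
#' @param seed integer seed; each of the `m` chains gets an independent
#'   child seed via [splitSeed()].
#' @return a list of class `"ImputationConfig"`.
#' @export
imputationConfig <- function(m = 5L, max_iter = 30L, donors = 5L,
                             k_sites = 10L, seed = 1L) {
  structure(list(m = .assert_count(m, "m", 1L),
                 max_iter = .assert_count(max_iter, "max_iter", 1L),
                 donors = .assert_count(donors, "donors", 1L),
                 k_sites = .assert_count(k_sites, "k_sites", 0L),
                 seed = .assert_count(seed, "seed", 0L)),
            class = "ImputationConfig")
}

# design covariates used in imputation models (numeric encoding)
.design_covariates <- function(sampleInfo) {
  Z <- NULL
  if (!is.null(sampleInfo$group))
    Z <- cbind(Z, group = as.numeric(sampleInfo$group == "postnatal"))
  if (!is.null(sampleInfo$sex))
    Z <- cbind(Z, sex = as.numeric(sampleInfo$sex == "M"))
  for (cov in c("adar_expr", "adarb1_expr"))
    if (!is.null(sampleInfo[[cov]]))
      Z <- cbind(Z, setNames(data.frame(sampleInfo[[cov]]), cov))
  if (is.null(Z)) matrix(numeric(0), nrow(sampleInfo), 0L) else as.matrix(Z)
}

# one PMM update for a single site row; returns the completed row
.pmm_update <- function(y, obs, X, donors) {
  Xo <- X[obs, , drop = FALSE]
  fit <- lm.fit(Xo, y[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- drop(X %*% beta)
  k <- min(donors, sum(obs))
  for (j in which(!obs)) {
    d <- abs(pred[obs] - pred[j])
    pool <- which(obs)[order(d)][seq_len(k)]
    y[j] <- y[sample(pool, 1L)]
  }
  y
}

#' Impute missing editing levels by chained predictive mean matching
#'
#' Runs multiple imputation by chained equations with predictive mean
#' matching (PMM): for every incomplete site, its observed levels are
#' regressed on the sample covariates (group, sex, ADAR and ADARB1
#' expression, where present in the matrix's `colData`) plus the `k_sites`
#' most-correlated other sites (complete-case correlation), missing
#' entries are predicted, and each is replaced by the observed value of a
#' donor drawn uniformly from the `donors` observed entries with closest
#' predictions. Sweeps repeat `max_iter` times and the whole chain runs
#' `m` times from independent child seeds, yielding `m` completed
#' matrices. By the donor property, every imputed value belongs to that
#' site's observed value set, so imputations can never leave `[0, 1]`.
#'
#' A site with fewer observed values than `donors` gets a shrunken donor
#' pool (with a warning); an all-missing site is an error — such sites
#' should have been removed by [harmonize()].
#'
#' @param em an [EditingMatrix-class] (typically harmonized).
#' @param config an [imputationConfig()].
#' @return a list of `m` completed numeric matrices (sites x samples),
#'   class `"ImputedEditingSet"`, with the original missingness mask in
#'   attribute `miss_mask`.
#' @export
imputePMM <- function(em, config = imputationConfig()) {
  stopifnot(is(em, "EditingMatrix"), inherits(config, "ImputationConfig"))
  Y0 <- editingLevels(em)
  miss <- is.na(Y0)
  if (any(rowSums(!miss) == 0L))
    stop("matrix contains all-missing sites; harmonize first", call. = FALSE)
  if (any(rowSums(!miss) < config$donors & rowSums(miss) > 0L))
    warning("donor pool shrunk for sites with few observed values",
            call. = FALSE)
  incomplete <- which(rowSums(miss) > 0L)
  if (!length(incomplete)) {
    out <- replicate(config$m, Y0, simplify = FALSE)
    attr(out, "miss_mask") <- miss
    class(out) <- "ImputedEditingSet"
    return(out)
  }
  Z <- .design_covariates(as.data.frame(SummarizedExperiment::colData(em)))

  # complete-case correlation between sites, for predictor selection
  neighbors <- vector("list", nrow(Y0))
  if (config$k_sites > 0L && nrow(Y0) > 1L) {
    suppressWarnings(cm <- cor(t(Y0), use = "pairwise.complete.obs"))
    diag(cm) <- NA
    for (s in incomplete) {
      r <- abs(cm[s, ])
      ok <- which(!is.na(r))
      neighbors[[s]] <- ok[order(-r[ok])][seq_len(min(config$k_sites,
                                                      length(ok)))]
    }
  }

  seeds <- splitSeed(config$seed, config$m)
  out <- lapply(seq_len(config$m), function(chain) {
    with_seed(seeds[chain], {
      Y <- Y0
      for (s in incomplete) {
        o <- Y0[s, !miss[s, ]]
        Y[s, miss[s, ]] <- sample(o, sum(miss[s, ]), replace = TRUE)
      }
      for (iter in seq_len(config$max_iter)) {
        for (s in incomplete) {
          X <- cbind(1, Z)
          if (length(neighbors[[s]]))
            X <- cbind(X, t(Y[neighbors[[s]], , drop = FALSE]))
          y <- Y0[s, ]
          y[miss[s, ]] <- Y[s, miss[s, ]]
          Y[s, ] <- .pmm_update(y, !miss[s, ], X, config$donors)
        }
      }
      Y
    })
  })
  attr(out, "miss_mask") <- miss
  class(out) <- "ImputedEditingSet"
  out
}

#' Combine multiple imputations
#'
#' `average` mode returns the element-wise mean of the completed matrices —
#' a single consensus matrix for downstream fitting. `rubin` mode defers
#' pooling to the model-fitting stage ([fitDifferential()] then fits each
#' completion and combines coefficients by Rubin's rules: coefficients
#' averaged, total variance = within + (1 + 1/m) * between).
#'
#' @param imps an `"ImputedEditingSet"` from [imputePMM()] (or any list of
#'   equal-shaped matrices).
#' @param mode `"average"` or `"rubin"`.
#' @return `average`: a numeric matrix; `rubin`: an object of class
#'   `"RubinSet"` wrapping the completions.
#' @export
consensusMatrix <- function(imps, mode = c("average", "rubin")) {
  mode <- match.arg(mode)
  stopifnot(length(imps) >= 1L)
  dims <- lapply(imps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("imputed matrices differ in shape", call. = FALSE)
  if (mode == "average") {
    Reduce(`+`, imps) / length(imps)
  } else {
    structure(list(matrices = imps), class = "RubinSet")
  }
}
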