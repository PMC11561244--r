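#' Developmental stage bins
#'
#' The default scheme bins samples into four developmental stages:
#' early gestation (4-10 weeks post conception), late gestation (11-20
#' wpc), newborn-teenager (0-20 years) and adult-senior (25-63 years).
#' Ages in no bin (e.g. 21-24 years) are left unassigned. With
#' `early_sub = TRUE` the early prenatal period is instead split into
#' 4-7 wpc and 8-11 wpc sub-bins for a finer look at the early-gestation
#' editing drop; the sub-bins are matched first, so 11 wpc goes to the
#' 8-11 wpc sub-bin in that mode.
#'
#' @param early_sub use the early-gestation sub-split.
#' @return data.frame (`bin`, `unit`, `lo`, `hi`) of class
#'   `"DevBinScheme"`, matched in row order.
#' @export
devBinScheme <- function(early_sub = FALSE) {
  scheme <- if (early_sub) {
    data.frame(
      bin = c("early_gestation_4_7", "early_gestation_8_11",
              "late_gestation", "newborn_teenager", "adult_senior"),
      unit = c("wpc", "wpc", "wpc", "years", "years"),
      lo = c(4, 8, 11, 0, 25), hi = c(7, 11, 20, 20, 63))
  } else {
    data.frame(
      bin = c("early_gestation", "late_gestation", "newborn_teenager",
              "adult_senior"),
      unit = c("wpc", "wpc", "years", "years"),
      lo = c(4, 11, 0, 25), hi = c(10, 20, 20, 63))
  }
  class(scheme) <- c("DevBinScheme", "data.frame")
  scheme
}

#' Assign samples to developmental bins
#'
#' @param designs data.frame with `age_value` and `age_unit` (`"wpc"` or
#'   `"years"`).
#' @param scheme a [devBinScheme()].
#' @return `designs` with a `bin` column (`NA` for unmappable ages, with a
#'   warning listing them). Negative ages are an error.
#' @export
assignBins <- function(designs, scheme = devBinScheme()) {
  stopifnot(inherits(scheme, "DevBinScheme"),
            all(c("age_value", "age_unit") %in% names(designs)))
  if (any(designs$age_value < 0)) stop("negative age", call. = FALSE)
  bin <- rep(NA_character_, nrow(designs))
  for (i in seq_len(nrow(scheme))) {
    hitb <- is.na(bin) & designs$age_unit == scheme$unit[i] &
      designs$age_value >= scheme$lo[i] & designs$age_value <= scheme$hi[i]
    bin[hitb] <- scheme$bin[i]
  }
  if (anyNA(bin))
    warning(sprintf("%d sample(s) fall in no bin (ages: %s)",
                    sum(is.na(bin)),
                    paste(unique(paste0(designs$age_value[is.na(bin)], " ",
                                        designs$age_unit[is.na(bin)])),
                          collapse = ", ")), call. = FALSE)
  designs$bin <- bin
  designs
}

#' Cohen's d with the pooled standard deviation
#'
#' `d = (mean(b) - mean(a)) / sqrt(((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2))`.
#'
#' @param a,b numeric vectors (reference group first; the sign of `d`
#'   follows `b` minus `a`).
#' @return Cohen's d; `NA` when the pooled SD is zero.
#' @export
cohensD <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Two-group developmental contrast
#'
#' Two-tailed Student's t-test (equal variances by default; Welch by flag)
#' plus Cohen's d with the pooled standard deviation, oriented as group B
#' minus group A. Used for sequential developmental-stage comparisons of
#' the Alu Editing Index and of ADAR-family expression.
#'
#' @param a,b numeric values in the two bins (each `n >= 2`).
#' @param contrast label for the output row.
#' @param welch use the Welch (unequal-variance) t-test instead.
#' @return one-row data.frame: `contrast`, `n1`, `n2`, `t`, `p`, `d`
#'   (`d = NA` flagged when the pooled SD is zero).
#' @export
binContrast <- function(a, b, contrast = "B_vs_A", welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need n >= 2", call. = FALSE)
  tt <- tryCatch(t.test(b, a, var.equal = !welch),
                 error = function(e) NULL)
  if (is.null(tt)) {  # constant data
    equal <- isTRUE(all.equal(mean(b), mean(a)))
    tt <- list(statistic = if (equal) 0 else sign(mean(b) - mean(a)) * Inf,
               p.value = if (equal) 1 else 0)
  }
  data.frame(contrast = contrast, n1 = length(a), n2 = length(b),
             t = unname(tt$statistic), p = unname(tt$p.value),
             d = cohensD(a, b))
}

#' Pool effect sizes across strata
#'
#' Sample-size-weighted mean of per-stratum Cohen's d values:
#' `sum(n_i * d_i) / sum(n_i)` with `n_i = n1_i + n2_i`. Used to summarise
#' an effect (e.g. the developmental rise in global editing) over cell
#' types or tissues.
#'
#' @param results data.frame with `d`, `n1`, `n2` columns (rows with
#'   undefined `d` are dropped).
#' @return pooled Cohen's d (scalar).
#' @export
pooledEffect <- function(results) {
  stopifnot(nrow(results) >= 1L)
  ok <- !is.na(results$d)
  if (!any(ok)) return(NA_real_)
  n <- results$n1[ok] + results$n2[ok]
  sum(n * results$d[ok]) / sum(n)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Omnibus F-test across three or more groups followed by Tukey's honest
#' significant differences on the studentized-range distribution for all
#' pairs — the standard analysis for comparing editing levels across
#' several knockout conditions at once. With fewer than three groups use
#' [binContrast()] instead (calling this with two groups is an error that
#' says so).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `p` (omnibus), `anova` (the [stats::aov] table) and
#'   `pairs` (data.frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anovaTukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3L)
    stop("fewer than 3 groups: use binContrast() for two-group comparisons",
         call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$groups
  pairs <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  rownames(pairs) <- NULL
  list(p = tab[["Pr(>F)"]][1L], anova = tab, pairs = pairs)
}
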