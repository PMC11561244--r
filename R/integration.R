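.cor_result <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance vector: correlation undefined", call. = FALSE)
    return(data.frame(r = NA_real_, r_squared = NA_real_, n = n,
                      p = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
             n = n, p = ct$p.value)
}

#' Correlate differential editing with expression change
#'
#' Pearson correlation between per-gene delta editing
#' (postnatal-minus-prenatal editing difference; sites sharing a gene are
#' averaged) and the gene's expression log-fold-change over the same
#' contrast. A negative correlation indicates genes whose editing rises as
#' their expression falls across development.
#'
#' @param differential data.frame with `delta` and `gene` columns
#'   (e.g. [fitDifferential()] output joined to a site-to-gene map).
#' @param logfc named numeric vector of expression log-fold-changes per
#'   gene.
#' @return data.frame `r`, `r_squared`, `n`, `p`.
#' @export
correlateDeltaExpression <- function(differential, logfc) {
  stopifnot(all(c("delta", "gene") %in% names(differential)))
  per_gene <- tapply(differential$delta, differential$gene, mean)
  common <- intersect(names(per_gene), names(logfc))
  .cor_result(unname(per_gene[common]), unname(logfc[common]))
}

#' Variance in AEI explained by a gene's expression
#'
#' Simple least-squares regression of per-unit (sample or cell-type) AEI
#' on expression; reports Pearson r and `r_squared`, the fraction of AEI
#' variance the gene's expression explains.
#'
#' @param aei numeric AEI values.
#' @param expr matched expression values.
#' @return data.frame `r`, `r_squared`, `n`, `p`.
#' @export
varianceExplained <- function(aei, expr) {
  .cor_result(expr, aei)
}

#' Gene-set score per sample
#'
#' A rank-free set-level summary: each member gene is z-scored across
#' samples and the set score is the mean member z-score per sample. This
#' mean-z scorer stands in for kernel-based set-variation methods; the
#' downstream use is only the Pearson correlation of the set score with
#' the AEI, which this summary supports directly.
#'
#' @param expr genes x samples numeric matrix.
#' @param genes character vector of member genes; members absent from
#'   `expr` are ignored, and an empty intersection is an error listing the
#'   set.
#' @param set_name label used in errors and output.
#' @return named numeric vector of per-sample scores.
#' @export
scoreGeneSet <- function(expr, genes, set_name = "gene_set") {
  members <- intersect(genes, rownames(expr))
  if (!length(members))
    stop(sprintf("no member genes of '%s' found in the expression table",
                 set_name), call. = FALSE)
  z <- t(apply(expr[members, , drop = FALSE], 1L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colMeans(z)
}

#' Correlate a gene-set score with the AEI
#'
#' @param scores per-sample scores from [scoreGeneSet()].
#' @param aei matched per-sample AEI values.
#' @return data.frame `r`, `r_squared`, `n`, `p`.
#' @export
correlateScoreAei <- function(scores, aei) {
  .cor_result(scores, aei)
}

#' Multi-lineage fitness fractions and contrasts
#'
#' Converts per-(germ layer, knockout condition, replicate) cell counts to
#' within-replicate condition fractions — absorbing per-replicate depth
#' differences — and contrasts each condition against the reference
#' condition across replicates with a two-tailed t-test and Cohen's d
#' ([binContrast()]). A condition depleted relative to the reference marks
#' a fitness defect in that lineage.
#'
#' @param counts data.frame with `stratum`, `condition`, `replicate`,
#'   `count`.
#' @param reference reference condition label (must appear in every
#'   replicate of every stratum).
#' @return list with `fractions` (the input plus a `fraction` column,
#'   summing to 1 over conditions within each stratum x replicate) and
#'   `contrasts` (per stratum x condition vs reference; empty with a
#'   warning when fewer than 2 replicates are available).
#' @export
fitnessFractions <- function(counts, reference) {
  stopifnot(all(c("stratum", "condition", "replicate", "count") %in%
                  names(counts)))
  if (!reference %in% counts$condition)
    stop(sprintf("reference condition '%s' absent", reference),
         call. = FALSE)
  key <- paste(counts$stratum, counts$replicate, sep = "\r")
  tot <- tapply(counts$count, key, sum)
  counts$fraction <- counts$count / as.numeric(tot[key])
  for (k in unique(key)) {
    sub <- counts[key == k, ]
    if (!reference %in% sub$condition)
      stop(sprintf("replicate '%s' of stratum '%s' lacks the reference",
                   sub$replicate[1L], sub$stratum[1L]), call. = FALSE)
  }
  contrasts <- list()
  for (st in unique(counts$stratum)) {
    sub <- counts[counts$stratum == st, ]
    ref_by_rep <- sub$fraction[sub$condition == reference]
    if (length(ref_by_rep) < 2L) {
      warning(sprintf(
        "stratum '%s': fewer than 2 replicates, contrasts not computed",
        st), call. = FALSE)
      next
    }
    for (cond in setdiff(unique(sub$condition), reference)) {
      cf <- sub$fraction[sub$condition == cond]
      if (length(cf) < 2L) next
      cc <- binContrast(ref_by_rep, cf,
                        contrast = sprintf("%s:%s_vs_%s", st, cond,
                                           reference))
      cc$stratum <- st; cc$condition <- cond
      contrasts[[length(contrasts) + 1L]] <- cc
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame(contrast = character(), n1 = integer(), n2 = integer(),
               t = numeric(), p = numeric(), d = numeric(),
               stratum = character(), condition = character())
  list(fractions = counts, contrasts = contrasts)
}
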