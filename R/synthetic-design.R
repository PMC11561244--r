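#' Describe a developmental trajectory for editing or expression
#'
#' A trajectory maps a sample's age to a mean level. Shapes:
#' \describe{
#'   \item{`constant`}{always `baseline`.}
#'   \item{`logistic_increase`}{rises sigmoidally through birth from near
#'     `baseline` prenatally to `baseline + amplitude` in adulthood — the
#'     dominant pattern of global Alu editing in brain tissue.}
#'   \item{`early_drop`}{declines across gestation from
#'     `baseline + amplitude` and recovers after birth — the
#'     early-gestation dip seen in heart and liver.}
#' }
#' Covariate effects add `slope * covariate` to the mean (e.g. coupling of
#' editing to ADAR expression); `noise_sd` is the per-observation Gaussian
#' noise applied by the consumers of the model.
#'
#' @param baseline level at the low end of the trajectory, in `[0,1]` for
#'   editing rates.
#' @param amplitude total rise (or drop) of the trajectory.
#' @param shape one of `"constant"`, `"logistic_increase"`, `"early_drop"`.
#' @param noise_sd standard deviation of added noise.
#' @param covariate_effects named list of slopes per design covariate, e.g.
#'   `list(adar_expr = 0.1)`.
#' @return a list of class `"TrajectoryModel"`.
#' @export
trajectoryModel <- function(baseline = 0.1, amplitude = 0,
                            shape = c("constant", "logistic_increase",
                                      "early_drop"),
                            noise_sd = 0, covariate_effects = list()) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(baseline), is.numeric(amplitude),
            is.numeric(noise_sd), noise_sd >= 0, is.list(covariate_effects))
  structure(list(baseline = baseline, amplitude = amplitude, shape = shape,
                 noise_sd = noise_sd, covariate_effects = covariate_effects),
            class = "TrajectoryModel")
}

# Age on a single developmental axis in years; prenatal ages are negative
# (40 wpc ~ birth).
.dev_time <- function(age_value, age_unit) {
  ifelse(age_unit == "wpc", (age_value - 40) / 52, age_value)
}

# Trajectory mean per sample (no noise, no covariates).
.trajectory_mean <- function(model, designs) {
  t <- .dev_time(designs$age_value, designs$age_unit)
  base <- switch(model$shape,
    constant = rep(model$baseline, nrow(designs)),
    logistic_increase = model$baseline +
      model$amplitude * stats::plogis(t / 0.5),
    early_drop = {
      prenatal <- designs$age_unit == "wpc"
      f <- numeric(nrow(designs))
      f[prenatal] <- exp(-(designs$age_value[prenatal] - 4) / 5)
      f[!prenatal] <- stats::plogis((t[!prenatal] - 1) / 2)
      model$baseline + model$amplitude * f
    })
  for (cov in names(model$covariate_effects)) {
    if (!cov %in% names(designs))
      stop(sprintf("covariate '%s' absent from design", cov), call. = FALSE)
    base <- base + model$covariate_effects[[cov]] * designs[[cov]]
  }
  base
}

#' Simulate a developmental sample design
#'
#' Draws prenatal (weeks post conception) and postnatal (years) samples with
#' sex and normalized ADAR / ADARB1 expression covariates. ADAR expression
#' is roughly constant across life with sample-to-sample scatter; ADARB1
#' rises with age, echoing its role in driving the postnatal editing
#' increase in neural tissue.
#'
#' @param n_prenatal,n_postnatal group sizes.
#' @param modality `"bulk"`, `"single_cell"` or `"single_nucleus"`.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `age_value`, `age_unit`
#'   (`"wpc"` or `"years"`), `sex`, `adar_expr`, `adarb1_expr`, `group`
#'   (`"prenatal"`/`"postnatal"`), `modality`.
#' @export
simulateDesigns <- function(n_prenatal = 8L, n_postnatal = 8L,
                            modality = "bulk", seed = 1L) {
  n_prenatal <- .assert_count(n_prenatal, "n_prenatal")
  n_postnatal <- .assert_count(n_postnatal, "n_postnatal")
  stopifnot(modality %in% c("bulk", "single_cell", "single_nucleus"))
  with_seed(seed, {
    n <- n_prenatal + n_postnatal
    age_unit <- rep(c("wpc", "years"), c(n_prenatal, n_postnatal))
    age_value <- c(sample(4:20, n_prenatal, replace = TRUE),
                   sample(c(0:20, 25:63), n_postnatal, replace = TRUE))
    d <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      age_value = age_value, age_unit = age_unit,
      sex = sample(c("M", "F"), n, replace = TRUE),
      group = rep(c("prenatal", "postnatal"), c(n_prenatal, n_postnatal)),
      modality = modality)
    t <- .dev_time(d$age_value, d$age_unit)
    d$adar_expr <- round(5 + rnorm(n, sd = 0.4), 3)
    d$adarb1_expr <- round(2 + 2 * stats::plogis(t / 2) + rnorm(n, sd = 0.3), 3)
    d
  })
}

# Candidate editable positions (strand-frame adenosines) for one repeat
# class; returns data.frame(chrom, pos, strand).
.editable_positions <- function(ref, class) {
  chars <- lapply(as.character(ref$reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  if (class %in% c("ALU", "NONALU_REP")) {
    gr <- ref$repeats[ref$repeats$repeat_class == class]
    out <- lapply(seq_along(gr), function(i) {
      ch <- as.character(GenomicRanges::seqnames(gr))[i]
      st <- as.character(GenomicRanges::strand(gr))[i]
      pos <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
      want <- if (st == "+") "A" else "T"
      pos <- pos[chars[[ch]][pos] == want]
      if (!length(pos)) return(NULL)
      data.frame(chrom = ch, pos = pos, strand = st)
    })
    df <- do.call(rbind, out)
  } else {
    # non-repetitive: strand from the hosting gene (+ by default)
    out <- lapply(names(chars), function(ch) {
      pos <- seq_along(chars[[ch]])
      rep_gr <- ref$repeats[GenomicRanges::seqnames(ref$repeats) == ch]
      in_rep <- rep(FALSE, length(pos))
      if (length(rep_gr)) {
        for (i in seq_along(rep_gr))
          in_rep[GenomicRanges::start(rep_gr)[i]:
                 GenomicRanges::end(rep_gr)[i]] <- TRUE
      }
      genes <- ref$genes[ref$genes$type == "gene" &
                         GenomicRanges::seqnames(ref$genes) == ch]
      strand <- rep("+", length(pos))
      for (i in seq_along(genes))
        strand[GenomicRanges::start(genes)[i]:GenomicRanges::end(genes)[i]] <-
          as.character(GenomicRanges::strand(genes))[i]
      want <- ifelse(strand == "+", "A", "T")
      keep <- !in_rep & chars[[ch]][pos] == want
      data.frame(chrom = ch, pos = pos[keep], strand = strand[keep])
    })
    df <- do.call(rbind, out)
  }
  if (is.null(df)) df <- data.frame(chrom = character(0), pos = integer(0),
                                    strand = character(0))
  rownames(df) <- NULL
  df
}

#' Simulate per-site editing truth across a sample design
#'
#' Draws editing sites on strand-frame adenosines of the requested repeat
#' classes and assigns each site a per-sample editing rate from a
#' developmental trajectory, optional covariate coupling, Gaussian noise,
#' and (for a configurable fraction of sites) a true postnatal-vs-prenatal
#' editing difference of stated size. Rates are clipped to `[0, 1]`.
#'
#' @param ref a `"SyntheticReference"`.
#' @param designs data.frame from [simulateDesigns()].
#' @param model a [trajectoryModel()].
#' @param sites_per_class named counts for `ALU`, `NONALU_REP`, `NONREP`.
#' @param delta_fraction fraction of sites given a true group difference.
#' @param delta_size size of that difference (added postnatally).
#' @param site_sd SD of a per-site baseline offset (0 = all sites share the
#'   trajectory exactly).
#' @param seed integer seed.
#' @return list of class `"EditingTruth"`: `sites` (data.frame `site_id`,
#'   `chrom`, `pos`, `strand`, `repeat_class`, `region`, `is_differential`,
#'   `true_delta`), `rates` (sites x samples matrix), `designs`.
#' @export
simulateTruth <- function(ref, designs, model,
                          sites_per_class = c(ALU = 40L, NONALU_REP = 5L,
                                              NONREP = 5L),
                          delta_fraction = 0, delta_size = 0.15,
                          site_sd = 0, seed = 1L) {
  stopifnot(inherits(ref, "SyntheticReference"),
            inherits(model, "TrajectoryModel"))
  .assert_fraction(delta_fraction, "delta_fraction")
  with_seed(seed, {
    sites <- list()
    for (cls in names(sites_per_class)) {
      k <- sites_per_class[[cls]]
      if (k == 0) next
      cand <- .editable_positions(ref, cls)
      if (nrow(cand) < k)
        stop(sprintf("only %d %s positions available, %d requested",
                     nrow(cand), cls, k), call. = FALSE)
      pick <- cand[sample.int(nrow(cand), k), , drop = FALSE]
      pick$repeat_class <- cls
      sites[[cls]] <- pick
    }
    sites <- do.call(rbind, sites)
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
    sites$site_id <- sprintf("site_%s_%d", sites$chrom, sites$pos)
    sites$region <- .annotate_positions(sites$chrom, sites$pos, ref$genes)

    n_site <- nrow(sites)
    n_diff <- round(delta_fraction * n_site)
    diff_idx <- if (n_diff > 0) sample.int(n_site, n_diff) else integer(0)
    sites$is_differential <- seq_len(n_site) %in% diff_idx
    sites$true_delta <- ifelse(sites$is_differential, delta_size, 0)

    mu <- .trajectory_mean(model, designs)      # per sample
    offset <- rnorm(n_site, sd = site_sd)       # per site
    postnatal <- as.numeric(designs$group == "postnatal")
    rates <- outer(offset, mu, `+`) +
      outer(sites$true_delta, postnatal) +
      matrix(rnorm(n_site * nrow(designs), sd = model$noise_sd),
             n_site, nrow(designs))
    rates <- pmin(pmax(rates, 0), 1)
    dimnames(rates) <- list(sites$site_id, designs$sample_id)

    structure(list(sites = sites[, c("site_id", "chrom", "pos", "strand",
                                     "repeat_class", "region",
                                     "is_differential", "true_delta")],
                   rates = rates, designs = designs),
              class = "EditingTruth")
  })
}

#' Truth with a uniform editing rate at every Alu adenosine
#'
#' Convenience constructor used to validate global-index recovery: every
#' strand-frame adenosine inside every Alu interval edits at the same rate
#' in every sample.
#'
#' @param ref a `"SyntheticReference"`.
#' @param rate common editing fraction.
#' @param designs sample design data.frame.
#' @return an `"EditingTruth"` as in [simulateTruth()].
#' @export
uniformAluTruth <- function(ref, rate, designs) {
  .assert_fraction(rate, "rate")
  pos <- .editable_positions(ref, "ALU")
  pos$repeat_class <- "ALU"
  pos$site_id <- sprintf("site_%s_%d", pos$chrom, pos$pos)
  pos$region <- .annotate_positions(pos$chrom, pos$pos, ref$genes)
  pos$is_differential <- FALSE
  pos$true_delta <- 0
  rates <- matrix(rate, nrow(pos), nrow(designs),
                  dimnames = list(pos$site_id, designs$sample_id))
  structure(list(sites = pos[, c("site_id", "chrom", "pos", "strand",
                                 "repeat_class", "region", "is_differential",
                                 "true_delta")],
                 rates = rates, designs = designs),
            class = "EditingTruth")
}

#' Simulate an expression table over a design
#'
#' @param designs sample design data.frame.
#' @param coupling named list of [trajectoryModel()]s, one per gene.
#' @param seed integer seed.
#' @return genes x samples numeric matrix.
#' @export
simulateExpression <- function(designs, coupling, seed = 1L) {
  stopifnot(length(coupling) > 0, !is.null(names(coupling)))
  with_seed(seed, {
    out <- t(vapply(coupling, function(model) {
      .trajectory_mean(model, designs) +
        rnorm(nrow(designs), sd = model$noise_sd)
    }, numeric(nrow(designs))))
    colnames(out) <- designs$sample_id
    out
  })
}
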