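#' Imputation reliability of one locus
#'
#' Squared Pearson correlation between imputed and true 0/1/2 genotypes at
#' a locus, computed with population (divide-by-n) moments:
#' `r2 = Cov(X, Y)^2 / (Var(X) Var(Y))`. The value is undefined (`NA`) when
#' either vector is constant, as for mono-allelic loci; such loci are
#' excluded from averages rather than scored.
#'
#' @param imputed,truth Equal-length numeric vectors of 0/1/2 genotypes
#'   (length >= 2).
#' @return `r2` in [0, 1], or `NA_real_` when undefined.
#' @examples
#' reliability(c(0, 1, 2, 1), c(0, 1, 2, 2))  # 0.7273
#' @export
reliability <- function(imputed, truth) {
  if (length(imputed) != length(truth)) stop("length mismatch")
  if (length(imputed) < 2L) stop("at least two individuals are required")
  mx <- mean(imputed); my <- mean(truth)
  vx <- mean((imputed - mx)^2); vy <- mean((truth - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  cv <- mean((imputed - mx) * (truth - my))
  cv^2 / (vx * vy)
}

#' Allelic imputation error rate
#'
#' Percentage of imputed alleles differing from the true alleles. For
#' unphased 0/1/2 genotypes the minimal allelic mismatch between an imputed
#' and a true genotype is `|g_imp - g_true|`, so
#' `er\% = sum(|G_imp - G_true|) / (2 * n_entries) * 100`.
#'
#' @param imputed,truth Numeric vectors or matrices (loci x individuals) of
#'   the same shape with entries in {0, 1, 2}.
#' @return Error rate in percent, in [0, 100].
#' @examples
#' error_rate(c(0, 1, 2), c(0, 2, 2))  # 1 mismatched allele of 6 = 16.67
#' @export
error_rate <- function(imputed, truth) {
  if (length(imputed) != length(truth) ||
      !identical(dim(imputed), dim(truth)))
    stop("imputed and truth must have the same shape")
  if (!all(imputed %in% 0:2) || !all(truth %in% 0:2))
    stop("genotypes must be coded 0/1/2")
  sum(abs(imputed - truth)) / (2 * length(imputed)) * 100
}

#' Bin a minor allele frequency
#'
#' Half-open binning `[e_k, e_{k+1})` over the given ascending edges, with
#' an implicit first bin below the first edge and the right edge of the
#' last bin closed so that MAF 0.5 falls in the last bin.
#'
#' @param maf MAF values in [0, 0.5] (vectorized).
#' @param edges Ascending bin edges spanning (0, 0.5].
#' @return Factor of bin labels.
#' @export
maf_bin <- function(maf, edges = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (any(maf < 0 | maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  brk <- unique(c(0, edges))
  lab <- paste0("[", utils::head(brk, -1L), ",", brk[-1L],
                c(rep(")", length(brk) - 2L), "]"))
  i <- findInterval(maf, brk, rightmost.closed = TRUE)
  factor(lab[i], levels = lab)
}

#' Marginal mean accuracy at one factor level
#'
#' Unweighted mean of cell-level accuracy values across all levels of the
#' other factors, i.e. the per-level averages displayed in factor-effect
#' plots of factorial imputation studies.
#'
#' @param results Data frame of cell-level results (one row per scenario
#'   cell).
#' @param factor Column name of the factor.
#' @param level Level of interest.
#' @param response Column name of the accuracy measure.
#' @return Mean of `response` over all rows at that level (NAs dropped).
#' @export
marginal_mean <- function(results, factor, level, response) {
  if (!factor %in% names(results)) stop("unknown factor: ", factor)
  if (!response %in% names(results)) stop("unknown response: ", response)
  rows <- results[[factor]] == level
  if (!any(rows)) stop("no cells at level ", level, " of ", factor)
  mean(results[[response]][rows], na.rm = TRUE)
}

#' Coefficient of variation of factor-level means
#'
#' Ratio of the standard deviation to the mean, computed with the
#' population (divide-by-n) standard deviation over the per-level means.
#' Used to rank the influence of design factors on imputation accuracy.
#'
#' @param level_means Numeric vector of per-level mean accuracies
#'   (length >= 2, nonzero mean).
#' @return The CV (>= 0).
#' @export
coefficient_of_variation <- function(level_means) {
  level_means <- level_means[!is.na(level_means)]
  if (length(level_means) < 2L) stop("at least two level means are required")
  m <- mean(level_means)
  if (m == 0) stop("mean of level means is zero; CV undefined")
  sqrt(mean((level_means - m)^2)) / m
}

#' Regression of accuracy on factor levels
#'
#' Ordinary least squares of an accuracy measure on (numeric) factor
#' levels, with the slope t-test p-value and the standardized slope (which
#' equals the Pearson correlation in simple regression).
#'
#' @param levels Numeric factor levels (>= 3 points, non-constant).
#' @param accuracy Accuracy values, same length.
#' @return List with `beta` (raw slope), `p_value`, and `beta_std`
#'   (standardized slope).
#' @export
factor_regression <- function(levels, accuracy) {
  ok <- !is.na(levels) & !is.na(accuracy)
  levels <- levels[ok]; accuracy <- accuracy[ok]
  if (length(levels) < 3L) stop("at least three points are required")
  if (stats::sd(levels) == 0) stop("factor levels are constant")
  fit <- stats::lm(accuracy ~ levels)
  sm <- summary(fit)$coefficients
  beta <- unname(sm["levels", "Estimate"])
  p <- unname(sm["levels", "Pr(>|t|)"])
  bstd <- if (stats::sd(accuracy) == 0) 0
          else beta * stats::sd(levels) / stats::sd(accuracy)
  list(beta = beta, p_value = p, beta_std = bstd)
}

#' Genomic kinship matrix
#'
#' VanRaden-style genomic relationship estimated from 0/1/2 genotypes,
#' `G(i,j) = sum_l (x_il - 2 p_l)(x_jl - 2 p_l) / sum_l 2 p_l (1 - p_l)`,
#' halved to the kinship scale.
#'
#' @param genotypes Individuals x loci matrix of 0/1/2 genotypes
#'   (>= 2 individuals, >= 1 polymorphic locus).
#' @param freqs Optional per-locus alternate-allele frequencies `p_l`;
#'   estimated from the data when omitted.
#' @return Symmetric individuals x individuals kinship matrix.
#' @seealso [kinship_blocks()]
#' @export
kinship <- function(genotypes, freqs = NULL) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2L) stop("at least two individuals are required")
  if (is.null(freqs)) {
    freqs <- colMeans(G) / 2
    # with frequencies estimated from the sample, a locus is usable only
    # if it actually varies among these individuals
    poly <- apply(G, 2L, function(x) any(x != x[1L]))
  } else poly <- freqs > 0 & freqs < 1
  if (!any(poly)) stop("no polymorphic loci")
  G <- G[, poly, drop = FALSE]; p <- freqs[poly]
  Z <- sweep(G, 2L, 2 * p)
  (Z %*% t(Z)) / (2 * sum(2 * p * (1 - p)))
}

#' Population-block summaries of a kinship matrix
#'
#' Mean (with min and max) kinship over all cross-population pairs for
#' every pair of populations, the summary used to express genetic distance
#' between demes.
#'
#' @param K Kinship matrix from [kinship()].
#' @param population Character vector of population labels, one per
#'   individual (row of `K`).
#' @return Data frame with `pop1`, `pop2`, `mean`, `min`, `max` for every
#'   unordered population pair (including within-population off-diagonal
#'   blocks).
#' @export
kinship_blocks <- function(K, population) {
  if (nrow(K) != length(population))
    stop("one population label per individual required")
  pops <- unique(population)
  out <- NULL
  for (i in seq_along(pops)) for (j in i:length(pops)) {
    ri <- population == pops[i]; rj <- population == pops[j]
    B <- K[ri, rj, drop = FALSE]
    if (i == j) {
      v <- B[upper.tri(B)]
      if (!length(v)) next
    } else v <- as.vector(B)
    out <- rbind(out, data.frame(pop1 = pops[i], pop2 = pops[j],
                                 mean = mean(v), min = min(v), max = max(v),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Panel-level kinship block means
#'
#' Convenience wrapper computing [kinship()] on a [haplotype_panel]'s
#' diploid genotypes and summarizing it with [kinship_blocks()].
#'
#' @param panel A [haplotype_panel].
#' @return As [kinship_blocks()].
#' @export
panel_kinship <- function(panel) {
  G <- panel_genotypes(panel)
  K <- kinship(G)
  pop <- panel$population[seq(1L, length(panel$population), by = 2L)]
  kinship_blocks(K, pop)
}
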