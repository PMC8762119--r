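#' Li-Stephens haplotype-copying model parameters
#'
#' The imputation engine models a target haplotype as an imperfect mosaic of
#' the K reference haplotypes: a hidden Markov chain over which reference
#' haplotype is being copied, with recombination-driven switches and a
#' per-site copying error.
#'
#' @param eps Per-site copying error probability (emission mismatch
#'   probability), in (0, 0.5).
#' @param ne Effective population size used to scale recombination
#'   (default 1,600, the largest descendant population of the packaged pig
#'   model).
#' @param rec_rate Recombination rate per bp per generation.
#' @param rho Population-scaled recombination parameter per bp; defaults to
#'   `4 * ne * rec_rate`.
#' @return An object of class `ls_params`.
#' @export
ls_params <- function(eps = 1e-3, ne = 1600, rec_rate = 1e-7,
                      rho = 4 * ne * rec_rate) {
  stopifnot(eps > 0, eps < 0.5, rho >= 0)
  structure(list(eps = eps, ne = ne, rec_rate = rec_rate, rho = rho),
            class = "ls_params")
}

#' @export
print.ls_params <- function(x, ...) {
  cat("Li-Stephens HMM parameters: eps =", x$eps, ", rho/bp =",
      format(x$rho), "(Ne =", x$ne, ")\n")
  invisible(x)
}

#' Haplotype-copying transition kernel
#'
#' Over a distance of `d` bp the copying chain switches with mass
#' `q = 1 - exp(-rho d / K)`, landing on each of the K reference states
#' (including the current one) with probability `q / K`; with the remaining
#' mass `1 - q` it stays put. Rows of the implied K x K matrix sum to 1,
#' and the kernel is a semigroup in `d` (consecutive distances compose).
#'
#' @param distance_bp Distance in bp (>= 0); vectorized.
#' @param K Number of reference haplotypes (>= 1).
#' @param rho Population-scaled recombination rate per bp.
#' @return List with `p_stay` (total probability of remaining in the current
#'   state, `1 - q + q/K`) and `p_switch_each` (probability `q/K` of moving
#'   to any one specific other state).
#' @export
transition_kernel <- function(distance_bp, K, rho) {
  if (any(distance_bp < 0)) stop("distance must be >= 0")
  stopifnot(K >= 1, rho >= 0)
  q <- 1 - exp(-rho * distance_bp / K)
  list(p_stay = 1 - q + q / K, p_switch_each = q / K)
}

#' Copying emission probability
#'
#' Probability of observing `obs_allele` on the target haplotype while
#' copying a reference haplotype carrying `ref_allele`: `1 - eps` on match,
#' `eps` on mismatch.
#'
#' @param ref_allele,obs_allele 0/1 alleles (vectorized).
#' @param eps Copying error probability in (0, 0.5).
#' @return Emission probabilities.
#' @export
emission_prob <- function(ref_allele, obs_allele, eps) {
  stopifnot(eps > 0, eps < 0.5)
  ifelse(ref_allele == obs_allele, 1 - eps, eps)
}

#' Forward-backward posteriors of the haplotype-copying chain
#'
#' Scaled (per-site normalized) forward-backward algorithm over the
#' scaffold sites of one target haplotype, giving the posterior probability
#' that each reference haplotype is being copied at each scaffold site.
#' Scaling constants are retained so the computation is stable for
#' reference panels of thousands of haplotypes over 1e5 sites.
#'
#' @param target Integer vector of 0/1 alleles at the scaffold sites.
#' @param reference K x M matrix of reference alleles at the scaffold sites
#'   (rows are reference haplotypes).
#' @param positions bp positions of the scaffold sites (strictly
#'   increasing).
#' @param params An [ls_params()] object.
#' @return List with `gamma` (M x K posterior matrix, rows sum to 1),
#'   `alpha` (M x K scaled forward), `bprod` (M x K, emission times scaled
#'   backward, used for propagation into unobserved sites), `scale`
#'   (per-site normalizers) and `loglik`.
#' @export
ls_forward_backward <- function(target, reference, positions, params = ls_params()) {
  reference <- as.matrix(reference)
  K <- nrow(reference); M <- ncol(reference)
  if (M < 1L) stop("at least one scaffold site is required")
  if (length(target) != M) stop("target length must match scaffold sites")
  if (length(positions) != M) stop("positions length must match scaffold sites")
  if (!all(target %in% c(0L, 1L)) || !all(reference %in% c(0L, 1L)))
    stop("allele codes must be 0 or 1")
  eps <- params$eps; rho <- params$rho
  # E[m, k]: emission at site m copying reference k
  E <- t(reference == rep(target, each = K)) * (1 - 2 * eps) + eps
  q <- c(0, 1 - exp(-rho * diff(positions) / K))

  alpha <- matrix(0, M, K)
  sc <- numeric(M)
  a <- E[1L, ] / K
  sc[1L] <- sum(a); alpha[1L, ] <- a / sc[1L]
  if (M > 1L) for (m in 2:M) {
    a <- E[m, ] * ((1 - q[m]) * alpha[m - 1L, ] + q[m] / K)
    sc[m] <- sum(a); alpha[m, ] <- a / sc[m]
  }

  bprod <- matrix(0, M, K)       # bprod[m, ] = E[m, ] * beta_hat[m, ]
  beta <- rep(1, K)
  bprod[M, ] <- E[M, ]
  if (M > 1L) for (m in (M - 1L):1L) {
    w <- bprod[m + 1L, ]
    beta <- ((1 - q[m + 1L]) * w + (q[m + 1L] / K) * sum(w)) / sc[m + 1L]
    bprod[m, ] <- E[m, ] * beta
  }

  gamma <- alpha * (bprod / E)
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, alpha = alpha, bprod = bprod, scale = sc,
       loglik = sum(log(sc)))
}

# log-space reference implementation of the same posteriors (used as an
# internal numerical cross-check; O(M K^2))
.ls_fb_log <- function(target, reference, positions, params = ls_params()) {
  reference <- as.matrix(reference)
  K <- nrow(reference); M <- ncol(reference)
  eps <- params$eps; rho <- params$rho
  logsumexp <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  lE <- t(ifelse(reference == rep(target, each = K), log1p(-eps), log(eps)))
  q <- c(0, 1 - exp(-rho * diff(positions) / K))
  la <- matrix(-Inf, M, K)
  la[1L, ] <- lE[1L, ] - log(K)
  for (m in seq_len(M)[-1L]) {
    Tm <- matrix(q[m] / K, K, K); diag(Tm) <- 1 - q[m] + q[m] / K
    for (k in seq_len(K))
      la[m, k] <- lE[m, k] + logsumexp(la[m - 1L, ] + log(Tm[, k]))
  }
  lb <- matrix(0, M, K)
  if (M > 1L) for (m in (M - 1L):1L) {
    Tm <- matrix(q[m + 1L] / K, K, K); diag(Tm) <- 1 - q[m + 1L] + q[m + 1L] / K
    for (k in seq_len(K))
      lb[m, k] <- logsumexp(log(Tm[k, ]) + lE[m + 1L, ] + lb[m + 1L, ])
  }
  lg <- la + lb
  g <- exp(lg - apply(lg, 1L, max))
  g / rowSums(g)
}

#' Impute one haplotype at unobserved sites
#'
#' Runs the copying-chain forward-backward over the scaffold sites and
#' propagates the chain exactly into each unobserved (hidden) site: the
#' state distribution at a hidden position between scaffold sites m and
#' m+1 combines the forward distribution at m advanced over the left
#' distance with the backward information at m+1 advanced over the right
#' distance (one-sided propagation at the flanks). The haploid allele
#' dosage at a hidden site is the posterior-weighted mean of the reference
#' alleles there.
#'
#' @param target Integer 0/1 vector of the target haplotype at the
#'   scaffold (observed) sites.
#' @param reference K x S matrix of reference haplotypes over all S sites.
#' @param observed Integer indices (into `1:S`) of the scaffold sites.
#' @param positions bp positions of all S sites.
#' @param params An [ls_params()].
#' @return List with `dosage` (haploid dosage per hidden site in [0, 1]),
#'   `max_posterior` (per hidden site, the largest single-state posterior),
#'   `hidden` (indices of hidden sites) and `loglik`.
#' @export
impute_haplotype <- function(target, reference, observed, positions,
                             params = ls_params()) {
  reference <- as.matrix(reference)
  S <- ncol(reference); K <- nrow(reference)
  observed <- sort(unique(as.integer(observed)))
  if (any(observed < 1L | observed > S)) stop("observed index out of range")
  hidden <- setdiff(seq_len(S), observed)
  fb <- ls_forward_backward(target, reference[, observed, drop = FALSE],
                            positions[observed], params)
  res <- propagate_hidden(fb, reference, observed, hidden, positions, params)
  c(res, list(hidden = hidden, loglik = fb$loglik))
}

#' Propagate copying posteriors into hidden sites
#'
#' Exact HMM propagation of scaffold-site posteriors into unobserved sites
#' (see [impute_haplotype()]). Exposed separately so one forward-backward
#' pass can serve several hidden-site queries.
#'
#' @param fb Result of [ls_forward_backward()] on the scaffold.
#' @param reference K x S reference matrix over all sites.
#' @param observed,hidden Disjoint site index sets partitioning `1:S`.
#' @param positions bp positions of all S sites.
#' @param params An [ls_params()].
#' @return List with `dosage` and `max_posterior`, each of length
#'   `length(hidden)`.
#' @export
propagate_hidden <- function(fb, reference, observed, hidden, positions,
                             params = ls_params()) {
  if (length(intersect(observed, hidden)))
    stop("hidden site coincides with a scaffold site")
  K <- nrow(reference)
  rho <- params$rho
  opos <- positions[observed]
  M <- length(opos)
  dosage <- numeric(length(hidden))
  maxpost <- numeric(length(hidden))
  for (i in seq_along(hidden)) {
    h <- hidden[i]
    p <- positions[h]
    m <- findInterval(p, opos)
    if (m >= 1L && opos[m] == p) stop("hidden site coincides with a scaffold site")
    if (m == 0L) {
      d <- opos[1L] - p
      q <- 1 - exp(-rho * d / K)
      w <- fb$bprod[1L, ]
      g <- (1 - q) * w + (q / K) * sum(w)
    } else if (m == M) {
      d <- p - opos[M]
      q <- 1 - exp(-rho * d / K)
      g <- (1 - q) * fb$alpha[M, ] + q / K
    } else {
      d1 <- p - opos[m]; d2 <- opos[m + 1L] - p
      q1 <- 1 - exp(-rho * d1 / K); q2 <- 1 - exp(-rho * d2 / K)
      f <- (1 - q1) * fb$alpha[m, ] + q1 / K
      w <- fb$bprod[m + 1L, ]
      b <- (1 - q2) * w + (q2 / K) * sum(w)
      g <- f * b
    }
    g <- g / sum(g)
    dosage[i] <- sum(g * reference[, h])
    maxpost[i] <- max(g)
  }
  list(dosage = dosage, max_posterior = maxpost)
}

#' Impute diploid genotypes at hidden sites
#'
#' The model-fitting entry point of the imputation engine. Each target
#' individual's two phased scaffold haplotypes are imputed independently
#' against the reference panel (K copying states per haplotype); the
#' genotype dosage at a hidden site is the sum of the two haploid dosages
#' and the best-guess 0/1/2 genotype is the nearest integer (ties round
#' half to even), clipped to {0, 1, 2}.
#'
#' @param scaffold A [haplotype_panel] of the target individuals restricted
#'   to the observed sites (e.g. from [mask_panel()]), or an integer matrix
#'   of phased target haplotypes (rows) at the observed sites.
#' @param reference A [haplotype_panel] of the reference individuals over
#'   all sites, or the corresponding haplotype matrix.
#' @param selection A [marker_selection] giving observed/hidden site
#'   indices into the reference site list.
#' @param params An [ls_params()].
#' @param positions bp positions of all sites; taken from `reference` when
#'   it is a panel.
#' @return An object of class `ls_imputation` with components `dosage`
#'   (individuals x hidden sites), `genotype` (best-guess 0/1/2),
#'   `confidence` (per hidden site, mean across target haplotypes of the
#'   maximum state posterior), `hidden`, `positions` (of hidden sites),
#'   `n_reference`, `params`.
#' @examples
#' m <- pig_demography(sequence_length = 5e4)
#' pan <- simulate_panel(m, c(P1 = 12), seed = 1)
#' sel <- select_random(ncol(pan$haplotypes),
#'                      marker_count(ncol(pan$haplotypes), 0.5), seed = 2)
#' sp <- mask_panel(pan, sel)
#' tgt <- subset_individuals(sp$scaffold, 1:4)
#' ref <- subset_individuals(pan, 5:12)
#' imp <- impute_genotypes(tgt, ref, sel)
#' imp
#' @export
impute_genotypes <- function(scaffold, reference, selection,
                             params = ls_params(), positions = NULL) {
  if (inherits(reference, "haplotype_panel")) {
    if (is.null(positions)) positions <- reference$positions
    ref <- reference$haplotypes
  } else ref <- as.matrix(reference)
  if (is.null(positions)) stop("positions are required")
  tg <- if (inherits(scaffold, "haplotype_panel")) scaffold$haplotypes
        else as.matrix(scaffold)
  observed <- selection$observed
  hidden <- selection$hidden
  if (ncol(tg) != length(observed))
    stop("scaffold has ", ncol(tg), " sites but the selection observes ",
         length(observed))
  if (nrow(tg) %% 2L != 0L) stop("target haplotypes must come in diploid pairs")
  n_ind <- nrow(tg) / 2L
  Th <- length(hidden)
  hap_dos <- matrix(0, nrow(tg), Th)
  conf <- matrix(0, nrow(tg), Th)
  for (r in seq_len(nrow(tg))) {
    fb <- ls_forward_backward(tg[r, ], ref[, observed, drop = FALSE],
                              positions[observed], params)
    pr <- propagate_hidden(fb, ref, observed, hidden, positions, params)
    hap_dos[r, ] <- pr$dosage
    conf[r, ] <- pr$max_posterior
  }
  odd <- seq(1L, nrow(tg), by = 2L)
  dosage <- hap_dos[odd, , drop = FALSE] + hap_dos[odd + 1L, , drop = FALSE]
  genotype <- matrix(pmin(2L, pmax(0L, as.integer(round(dosage)))),
                     nrow = n_ind)
  structure(
    list(dosage = dosage, genotype = genotype,
         confidence = colMeans(conf),
         hidden = hidden, positions = positions[hidden],
         n_reference = nrow(ref) / 2L, params = params),
    class = "ls_imputation")
}

#' @export
print.ls_imputation <- function(x, ...) {
  cat("Li-Stephens imputation:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "hidden sites (reference:", x$n_reference,
      "diploids)\n")
  cat("  mean per-site confidence:", format(round(mean(x$confidence), 3)), "\n")
  invisible(x)
}

#' @export
summary.ls_imputation <- function(object, ...) {
  het <- mean(object$genotype == 1L)
  out <- list(n_individuals = nrow(object$dosage),
              n_sites = ncol(object$dosage),
              n_reference = object$n_reference,
              mean_confidence = mean(object$confidence),
              genotype_frequencies = table(factor(object$genotype,
                                                  levels = 0:2)) /
                length(object$genotype))
  class(out) <- "summary.ls_imputation"
  out
}

#' @export
print.summary.ls_imputation <- function(x, ...) {
  cat("Imputation of", x$n_sites, "sites in", x$n_individuals,
      "individuals (reference:", x$n_reference, "diploids)\n")
  cat("  mean confidence:", format(round(x$mean_confidence, 3)), "\n")
  cat("  best-guess genotype frequencies:",
      paste(names(x$genotype_frequencies),
            format(round(as.numeric(x$genotype_frequencies), 3)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
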