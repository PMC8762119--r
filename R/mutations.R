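#' Overlay infinite-sites mutations on a simulated genealogy
#'
#' Mutations are placed on every marginal tree as a Poisson process with
#' intensity `mu` x branch length x interval length (per branch per bp).
#' Each mutation receives a continuous uniform position within its tree
#' interval which is then floored to an integer bp; integer collisions are
#' resolved by re-drawing so that every site is unique (infinite-sites
#' model). Carriers of the derived allele are the sample haplotypes below
#' the mutated branch. Only segregating sites are emitted, which the
#' construction guarantees: no branch above a local most recent common
#' ancestor exists in the genealogy.
#'
#' @param forest A `genealogy_forest` from [simulate_ancestry()].
#' @param mu Mutation rate per bp per generation.
#' @param seed Integer seed for the mutation stream.
#' @return A [haplotype_panel] (possibly with zero sites).
#' @export
overlay_mutations <- function(forest, mu, seed) {
  stopifnot(inherits(forest, "genealogy_forest"), mu >= 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  ed <- forest$edges
  nt <- forest$node_time
  nhap <- forest$n_samples
  L <- forest$sequence_length

  pos <- integer(0)
  carriers <- list()
  if (mu > 0 && nrow(ed) > 0L) {
    blen <- nt[ed$parent] - nt[ed$child]
    bps <- sort(unique(c(0, L, ed$left, ed$right)))
    a <- bps[-length(bps)]; b <- bps[-1L]
    cpos <- numeric(0); m_lo <- numeric(0); m_hi <- numeric(0)
    for (i in seq_along(a)) {
      act <- which(ed$left <= a[i] & ed$right >= b[i])
      lam <- mu * (b[i] - a[i]) * blen[act]
      nm <- stats::rpois(length(act), lam)
      tot <- sum(nm)
      if (tot == 0L) next
      mut_edges <- rep(act, nm)
      # carrier sets: leaves below each mutated edge's child in this tree
      kids <- split(ed$child[act], ed$parent[act])
      desc <- function(node) {
        stack <- node; leaves <- integer(0)
        while (length(stack)) {
          v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
          if (v <= nhap) leaves <- c(leaves, v)
          ch <- kids[[as.character(v)]]
          if (!is.null(ch)) stack <- c(stack, ch)
        }
        leaves
      }
      for (e in mut_edges) {
        carriers[[length(carriers) + 1L]] <- desc(ed$child[e])
        cpos <- c(cpos, stats::runif(1L, a[i], b[i]))
        m_lo <- c(m_lo, a[i]); m_hi <- c(m_hi, b[i])
      }
    }
    if (length(cpos)) {
      pos <- as.integer(floor(cpos))
      # resolve integer collisions by re-drawing within the same tree interval
      it <- 0L
      while (anyDuplicated(pos) && it < 200L) {
        it <- it + 1L
        dup <- which(duplicated(pos))
        for (d in dup)
          pos[d] <- as.integer(floor(stats::runif(1L, m_lo[d], m_hi[d])))
      }
      if (anyDuplicated(pos)) {
        drop <- which(duplicated(pos))
        warning("dropping ", length(drop), " mutation(s): no free integer bp")
        pos <- pos[-drop]; carriers <- carriers[-drop]
      }
    }
  }

  o <- order(pos)
  pos <- pos[o]; carriers <- carriers[o]
  S <- length(pos)
  H <- matrix(0L, nrow = nhap, ncol = S)
  for (j in seq_len(S)) H[carriers[[j]], j] <- 1L
  haplotype_panel(H, positions = pos,
                  population = forest$sample_population,
                  sequence_length = L,
                  seed = forest$seed, mutation_seed = seed)
}

#' Phased haplotype panel
#'
#' Container for phased 0/1 haplotypes at segregating sites. Rows are
#' haplotypes (rows `2k-1` and `2k` form diploid individual `k`), columns
#' are sites with strictly increasing 0-based bp positions; entries are 0
#' (ancestral) or 1 (derived).
#'
#' @param haplotypes Integer matrix (2n haplotypes x S sites) of 0/1 alleles.
#' @param positions Integer vector of 0-based bp positions, strictly
#'   increasing, within `[0, sequence_length)`.
#' @param population Character vector of population labels, one per
#'   haplotype.
#' @param sequence_length Chromosome length in bp.
#' @param seed,mutation_seed Optional provenance seeds.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions, population,
                            sequence_length, seed = NULL, mutation_seed = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  S <- ncol(haplotypes)
  if (length(positions) != S) stop("positions must match the number of sites")
  if (S && (any(diff(positions) <= 0)))
    stop("positions must be strictly increasing")
  if (S && (positions[1L] < 0 || positions[S] >= sequence_length))
    stop("positions must lie in [0, sequence_length)")
  if (nrow(haplotypes) %% 2L != 0L)
    stop("haplotype count must be even (diploid pairing)")
  if (length(population) != nrow(haplotypes))
    stop("one population label per haplotype required")
  if (S && !all(haplotypes %in% c(0L, 1L)))
    stop("haplotype entries must be 0 or 1")
  structure(
    list(haplotypes = haplotypes,
         positions = as.integer(positions),
         population = as.character(population),
         sequence_length = sequence_length,
         seed = seed, mutation_seed = mutation_seed),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$haplotypes) / 2, "diploids (",
      nrow(x$haplotypes), "haplotypes ) x", ncol(x$haplotypes), "sites\n")
  tab <- table(x$population[seq(1L, length(x$population), by = 2L)])
  cat("  populations:",
      paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  cat("  sequence length:", format(x$sequence_length, big.mark = ","), "bp (",
      format(round(ncol(x$haplotypes) / (x$sequence_length / 1000), 2)),
      "SNPs/kb )\n")
  invisible(x)
}

#' @export
summary.haplotype_panel <- function(object, ...) {
  dc <- colSums(object$haplotypes)
  n <- nrow(object$haplotypes)
  maf <- pmin(dc / n, 1 - dc / n)
  out <- list(n_diploids = n / 2, n_sites = ncol(object$haplotypes),
              density_per_kb = ncol(object$haplotypes) /
                (object$sequence_length / 1000),
              maf_quartiles = stats::quantile(maf, c(0.25, 0.5, 0.75)),
              mean_pairwise_diversity = mean(2 * dc / n * (n - dc) / (n - 1)))
  class(out) <- "summary.haplotype_panel"
  out
}

#' @export
print.summary.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", x$n_diploids, "diploids x", x$n_sites, "sites (",
      format(round(x$density_per_kb, 2)), "SNPs/kb )\n")
  cat("  MAF quartiles:", paste(format(round(x$maf_quartiles, 3)),
                                collapse = " / "), "\n")
  cat("  mean pairwise differences per site:",
      format(round(x$mean_pairwise_diversity, 4)), "\n")
  invisible(x)
}

#' Subset of haplotype rows for a population
#'
#' @param panel A [haplotype_panel].
#' @param population Population id.
#' @return Integer vector of haplotype row indices.
#' @export
population_haplotypes <- function(panel, population) {
  if (!population %in% panel$population)
    stop("unknown population: ", population)
  which(panel$population == population)
}

#' Diploid 0/1/2 genotypes from a haplotype panel
#'
#' @param panel A [haplotype_panel].
#' @param sites Optional site (column) indices.
#' @param individuals Optional diploid individual indices.
#' @return Integer matrix, individuals x sites.
#' @export
panel_genotypes <- function(panel, sites = NULL, individuals = NULL) {
  H <- panel$haplotypes
  if (!is.null(sites)) H <- H[, sites, drop = FALSE]
  odd <- seq(1L, nrow(H), by = 2L)
  G <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  if (!is.null(individuals)) G <- G[individuals, , drop = FALSE]
  G
}

#' Mean pairwise nucleotide diversity per bp
#'
#' @param panel A [haplotype_panel].
#' @return Average number of pairwise differences per bp.
#' @export
pairwise_diversity <- function(panel) {
  n <- nrow(panel$haplotypes)
  dc <- colSums(panel$haplotypes)
  sum(2 * dc * (n - dc) / (n * (n - 1))) / panel$sequence_length
}

# deterministic per-stage sub-seed derived from the run seed
.substream <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483647) + 1L
}

#' Simulate a phased haplotype panel
#'
#' Convenience wrapper running [simulate_ancestry()] and
#' [overlay_mutations()] with deterministic per-stage sub-seeds derived from
#' `seed`, so that the ancestry and mutation stages are independently
#' reproducible.
#'
#' @inheritParams simulate_ancestry
#' @return A [haplotype_panel].
#' @examples
#' m <- pig_demography(sequence_length = 5e4)
#' p <- simulate_panel(m, c(P1 = 5, P2 = 5), seed = 1)
#' p
#' @export
simulate_panel <- function(model, samples, seed) {
  forest <- simulate_ancestry(model, samples, seed = .substream(seed, 1L))
  overlay_mutations(forest, model$mutation_rate, seed = .substream(seed, 2L))
}
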