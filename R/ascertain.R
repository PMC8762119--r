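#' Minor allele frequency of one site
#'
#' @param genotypes Integer vector of 0/1/2 genotypes (one per diploid).
#' @return `min(f, 1 - f)` where `f` is the alternate-allele frequency
#'   `sum(g) / (2n)`.
#' @examples
#' compute_maf(c(1, 0))  # 0.25
#' @export
compute_maf <- function(genotypes) {
  if (length(genotypes) == 0L) stop("at least one genotype is required")
  if (!all(genotypes %in% 0:2)) stop("genotypes must be coded 0/1/2")
  f <- sum(genotypes) / (2 * length(genotypes))
  min(f, 1 - f)
}

#' Per-site minor allele frequencies of a panel
#'
#' @param panel A [haplotype_panel].
#' @param population Optional population id; when given, frequencies are
#'   computed over that population's haplotypes only.
#' @param haplotypes Optional explicit haplotype row indices (overrides
#'   `population`).
#' @return Numeric vector of per-site MAFs in [0, 0.5].
#' @export
site_maf <- function(panel, population = NULL, haplotypes = NULL) {
  H <- panel$haplotypes
  if (!is.null(haplotypes)) H <- H[haplotypes, , drop = FALSE]
  else if (!is.null(population))
    H <- H[population_haplotypes(panel, population), , drop = FALSE]
  f <- colMeans(H)
  pmin(f, 1 - f)
}

#' Build the target variant universe
#'
#' Restricts a simulated panel to biallelic sites with minor allele
#' frequency at or above `maf_min` in the target population (the filter is
#' inclusive: a site at exactly `maf_min` is kept). All simulated sites are
#' biallelic by the infinite-sites construction.
#'
#' @param panel A [haplotype_panel].
#' @param target_population Population id whose individuals define the MAF
#'   filter.
#' @param maf_min MAF threshold (default 0.01).
#' @param target_individuals Optional diploid indices (within the target
#'   population) defining the filter subset, e.g. the imputation target
#'   set; defaults to all individuals of the population.
#' @return A `variant_table` data frame with columns `site` (column index
#'   into the panel), `position`, `maf` (target-population MAF) and
#'   `biallelic`.
#' @export
filter_target_universe <- function(panel, target_population, maf_min = 0.01,
                                   target_individuals = NULL) {
  hrow <- population_haplotypes(panel, target_population)
  if (!is.null(target_individuals)) {
    ind <- matrix(hrow, nrow = 2L)[, target_individuals, drop = FALSE]
    hrow <- as.integer(ind)
  }
  maf <- site_maf(panel, haplotypes = hrow)
  keep <- which(maf >= maf_min)
  structure(data.frame(site = keep, position = panel$positions[keep],
                       maf = maf[keep], biallelic = TRUE),
            class = c("variant_table", "data.frame"))
}

#' Number of scaffold markers at a density level
#'
#' @param total_sites Total number of sites in the variant universe.
#' @param proportion Marker density level in (0, 1].
#' @return `floor(proportion * total_sites)`.
#' @examples
#' marker_count(212696, 0.01)  # 2126
#' @export
marker_count <- function(total_sites, proportion) {
  stopifnot(total_sites >= 0)
  if (any(proportion <= 0 | proportion > 1))
    stop("proportion must be in (0, 1]")
  as.integer(floor(proportion * total_sites + 1e-9))
}

# normalize the `variants` argument of the selection functions to a sorted
# vector of site indices
.universe_sites <- function(variants) {
  if (inherits(variants, "variant_table")) return(variants$site)
  if (is.numeric(variants) && length(variants) == 1L && variants >= 1)
    return(seq_len(variants))
  sort(unique(as.integer(variants)))
}

.new_selection <- function(scheme, sites, observed, seed = NULL,
                           proportion = NULL) {
  observed <- sort(observed)
  structure(list(scheme = scheme,
                 observed = observed,
                 hidden = setdiff(sites, observed),
                 sites = sites,
                 proportion = proportion,
                 seed = seed),
            class = "marker_selection")
}

#' Select evenly spaced scaffold markers (SNP-chip scheme)
#'
#' Deterministically picks `count` markers evenly spaced in site rank:
#' ranks `round(j (S-1) / (count-1))` for `j = 0..count-1` (half-up
#' rounding; `count = 1` picks the first site). Rank spacing rather than bp
#' spacing keeps the scheme deterministic and density-exact; index
#' collisions (possible only in degenerate cases) advance to the next
#' unused rank.
#'
#' @param variants A `variant_table` from [filter_target_universe()], a
#'   vector of site indices, or a single integer S meaning sites `1:S`.
#' @param count Number of markers to select (1 <= count <= S).
#' @return A `marker_selection` with `observed` (scaffold) and `hidden`
#'   (imputation target) site indices partitioning the universe.
#' @export
select_evenly_spaced <- function(variants, count) {
  sites <- .universe_sites(variants)
  S <- length(sites)
  if (count < 1L || count > S) stop("count must be in [1, ", S, "]")
  if (count == 1L) ranks <- 1L
  else {
    j <- 0:(count - 1L)
    ranks <- as.integer(floor(j * (S - 1) / (count - 1) + 0.5)) + 1L
    if (anyDuplicated(ranks)) {      # degenerate collisions: advance
      used <- logical(S)
      for (i in seq_along(ranks)) {
        r <- ranks[i]
        while (r <= S && used[r]) r <- r + 1L
        if (r > S) { r <- ranks[i]; while (used[r]) r <- r - 1L }
        ranks[i] <- r; used[r] <- TRUE
      }
      ranks <- sort(ranks)
    }
  }
  .new_selection("chip", sites, sites[ranks],
                 proportion = count / S)
}

#' Select random scaffold markers (low-coverage sequencing scheme)
#'
#' Uniform sample without replacement of `count` sites from the variant
#' universe; deterministic given `seed`.
#'
#' @inheritParams select_evenly_spaced
#' @param seed Integer seed.
#' @return A `marker_selection`.
#' @export
select_random <- function(variants, count, seed) {
  sites <- .universe_sites(variants)
  S <- length(sites)
  if (count < 1L || count > S) stop("count must be in [1, ", S, "]")
  set.seed(as.integer(seed %% .Machine$integer.max))
  .new_selection("lcwgs", sites, sites[sample.int(S, count)],
                 seed = seed, proportion = count / S)
}

#' @export
print.marker_selection <- function(x, ...) {
  cat("Marker selection (", x$scheme, "): ", length(x$observed),
      " observed / ", length(x$hidden), " hidden sites",
      if (!is.null(x$proportion))
        paste0(" (density ", format(round(x$proportion, 4)), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Split a panel into scaffold and hidden-truth panels
#'
#' @param panel A [haplotype_panel].
#' @param selection A `marker_selection` whose site indices refer to the
#'   panel's site columns.
#' @return List with `scaffold` (observed sites only) and `truth` (hidden
#'   sites only), both [haplotype_panel] objects with individuals
#'   unchanged.
#' @export
mask_panel <- function(panel, selection) {
  S <- ncol(panel$haplotypes)
  idx <- c(selection$observed, selection$hidden)
  if (length(idx) && (min(idx) < 1L || max(idx) > S))
    stop("selection index out of range for this panel")
  list(scaffold = subset_sites(panel, selection$observed),
       truth = subset_sites(panel, selection$hidden))
}

#' Subset a haplotype panel by site columns
#'
#' @param panel A [haplotype_panel].
#' @param sites Site column indices (kept in panel order).
#' @return A [haplotype_panel].
#' @export
subset_sites <- function(panel, sites) {
  sites <- sort(unique(as.integer(sites)))
  haplotype_panel(panel$haplotypes[, sites, drop = FALSE],
                  positions = panel$positions[sites],
                  population = panel$population,
                  sequence_length = panel$sequence_length,
                  seed = panel$seed, mutation_seed = panel$mutation_seed)
}

#' Subset a haplotype panel by diploid individuals
#'
#' @param panel A [haplotype_panel].
#' @param individuals Diploid individual indices.
#' @return A [haplotype_panel] (sites unchanged; possibly monomorphic in
#'   the subset).
#' @export
subset_individuals <- function(panel, individuals) {
  rows <- as.integer(rbind(2L * individuals - 1L, 2L * individuals))
  haplotype_panel(panel$haplotypes[rows, , drop = FALSE],
                  positions = panel$positions,
                  population = panel$population[rows],
                  sequence_length = panel$sequence_length,
                  seed = panel$seed, mutation_seed = panel$mutation_seed)
}

#' Merge two panels over disjoint site sets
#'
#' Inverse of [mask_panel()]: interleaves the sites of two panels over the
#' same individuals by bp position.
#'
#' @param a,b [haplotype_panel] objects with identical individuals and
#'   disjoint positions.
#' @return A [haplotype_panel] with the union of sites.
#' @export
merge_panels <- function(a, b) {
  if (nrow(a$haplotypes) != nrow(b$haplotypes))
    stop("panels have different individuals")
  pos <- c(a$positions, b$positions)
  if (anyDuplicated(pos)) stop("panels share positions")
  o <- order(pos)
  haplotype_panel(cbind(a$haplotypes, b$haplotypes)[, o, drop = FALSE],
                  positions = pos[o], population = a$population,
                  sequence_length = a$sequence_length,
                  seed = a$seed, mutation_seed = a$mutation_seed)
}
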