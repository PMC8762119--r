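#' Enumerate a factorial imputation design
#'
#' Builds the scenario grid of an imputation accuracy experiment as the
#' full cross of reference population x reference size x marker density x
#' ascertainment scheme x imputation method. Reference-size levels may
#' differ per population (in the packaged study design the P1 reference
#' ranges to 10,000 individuals while P2-P4 stop at 3,000).
#'
#' @param sizes Named list: population id -> numeric vector of reference
#'   sizes.
#' @param densities Numeric vector of marker density levels in (0, 1].
#' @param schemes Character vector among `"chip"` (evenly spaced) and
#'   `"lcwgs"` (random).
#' @param methods Character vector of imputation method labels.
#' @param base_seed Integer; scenario seeds are derived deterministically
#'   from it.
#' @return A `scenario_grid` data frame with one row per scenario and a
#'   unique `seed` column.
#' @export
build_grid <- function(sizes, densities, schemes = "lcwgs", methods = "ls",
                       base_seed = 1L) {
  stopifnot(is.list(sizes), !is.null(names(sizes)))
  if (any(densities <= 0 | densities > 1))
    stop("densities must be in (0, 1]")
  rows <- NULL
  for (pop in names(sizes))
    rows <- rbind(rows, expand.grid(
      reference_population = pop, reference_size = sizes[[pop]],
      proportion = densities, scheme = schemes, method = methods,
      stringsAsFactors = FALSE))
  rows$seed <- .substream(base_seed, seq_len(nrow(rows)))
  rows$scenario <- seq_len(nrow(rows))
  class(rows) <- c("scenario_grid", "data.frame")
  rows
}

#' The packaged factorial study design
#'
#' The full design evaluated by the packaged study: reference sizes
#' {100, 1,000, 3,000, 5,000, 10,000} for P1 and {100, 1,000, 3,000} for
#' P2-P4, six density levels (1, 5, 10, 30, 50, 90 percent), two
#' ascertainment schemes and two imputation methods:
#' (5 + 3 x 3) x 6 x 2 x 2 = 336 scenarios.
#'
#' @param methods Two imputation method labels.
#' @param schemes Two ascertainment schemes.
#' @param base_seed Integer seed for scenario-seed derivation.
#' @return A `scenario_grid` (336 rows with the defaults).
#' @export
study_grid <- function(methods = c("ls", "ls"), schemes = c("chip", "lcwgs"),
                       base_seed = 1L) {
  build_grid(sizes = list(P1 = c(100, 1000, 3000, 5000, 10000),
                          P2 = c(100, 1000, 3000),
                          P3 = c(100, 1000, 3000),
                          P4 = c(100, 1000, 3000)),
             densities = c(0.01, 0.05, 0.10, 0.30, 0.50, 0.90),
             schemes = schemes, methods = methods, base_seed = base_seed)
}

#' Scale a full-size design onto a smaller simulated panel
#'
#' Maps the reference-size levels of a grid proportionally onto a
#' desk-scale panel: each size s becomes `max(2, round(s * factor))`,
#' optionally capped at the available per-population reference pool.
#'
#' @param grid A `scenario_grid`.
#' @param factor Scaling factor (e.g. 0.01 for a panel 1 percent of full
#'   size).
#' @param pools Optional named vector of available reference-pool sizes
#'   per population used as caps.
#' @return The grid with scaled `reference_size`.
#' @export
scale_grid <- function(grid, factor, pools = NULL) {
  sz <- pmax(2, round(grid$reference_size * factor))
  if (!is.null(pools))
    sz <- pmin(sz, pools[grid$reference_population])
  grid$reference_size <- as.numeric(sz)
  grid
}

#' Run one imputation scenario
#'
#' Executes the simulate-ascertain-impute-evaluate chain for one cell of
#' the factorial design on a pre-simulated panel: draws the reference
#' individuals from the stated population (never overlapping the targets),
#' builds the marker selection for the scheme and density, imputes the
#' hidden sites with the Li-Stephens engine (or a caller-supplied engine)
#' and scores every hidden locus. Fully deterministic given
#' `(panel, seed)`.
#'
#' @param panel A [haplotype_panel] containing target and reference
#'   populations.
#' @param reference_population Population id supplying the reference
#'   panel.
#' @param reference_size Number of reference diploids to draw.
#' @param proportion Marker density level in (0, 1).
#' @param scheme `"chip"` (evenly spaced) or `"lcwgs"` (random).
#' @param seed Integer scenario seed (drives reference sampling and random
#'   ascertainment).
#' @param targets Diploid indices of the imputation targets (default: all
#'   individuals of `target_population`... see `n_target`).
#' @param target_population Population id of the targets (default `"P1"`).
#' @param n_target When `targets` is NULL, the first `n_target`
#'   individuals of the target population are used.
#' @param maf_min MAF filter for the variant universe (default 0.01,
#'   computed on the target individuals).
#' @param params [ls_params()] for the internal engine.
#' @param engine Either `"ls"` (internal Li-Stephens engine) or a function
#'   `(scaffold_targets, reference_panel, selection, params)` returning an
#'   object with `genotype` and `dosage` matrices over the hidden sites.
#' @param method Label stored with the result (defaults to `"ls"` or
#'   `"external"`).
#' @return A `scenario_result`: per-locus accuracy records (`loci`: MAF,
#'   reliability, error rate per hidden locus) plus cell aggregates
#'   (`mean_r2`, `error_rate`) and the scenario specification.
#' @export
run_scenario <- function(panel, reference_population, reference_size,
                         proportion, scheme = c("lcwgs", "chip"), seed,
                         targets = NULL, target_population = "P1",
                         n_target = NULL, maf_min = 0.01,
                         params = ls_params(), engine = "ls",
                         method = NULL) {
  scheme <- match.arg(scheme)
  pop_ind <- panel$population[seq(1L, length(panel$population), by = 2L)]
  if (is.null(targets)) {
    cand <- which(pop_ind == target_population)
    if (!length(cand)) stop("target population absent from panel")
    if (is.null(n_target)) stop("supply `targets` or `n_target`")
    if (length(cand) < n_target) stop("fewer target-population individuals than n_target")
    targets <- cand[seq_len(n_target)]
  }
  pool <- setdiff(which(pop_ind == reference_population), targets)
  if (length(pool) < reference_size)
    stop("insufficient reference individuals in ", reference_population,
         ": need ", reference_size, ", have ", length(pool))
  set.seed(.substream(seed, 3L))
  refs <- sort(pool[sample.int(length(pool), reference_size)])

  universe <- filter_target_universe(panel, target_population,
                                     maf_min = maf_min,
                                     target_individuals =
                                       match(targets,
                                             which(pop_ind == target_population)))
  S <- nrow(universe)
  count <- marker_count(S, proportion)
  if (count < 1L) stop("density level leaves no scaffold markers (S = ", S, ")")
  if (count >= S) stop("density level leaves no hidden sites to impute")
  sel <- if (scheme == "chip") select_evenly_spaced(universe, count)
         else select_random(universe, count, seed = .substream(seed, 4L))

  # local site indexing over the universe
  loc <- .new_selection(scheme, seq_len(S), match(sel$observed, universe$site),
                        seed = sel$seed, proportion = sel$proportion)
  upanel <- subset_sites(panel, universe$site)
  ref_panel <- subset_individuals(upanel, refs)
  tgt_panel <- subset_individuals(upanel, targets)
  tgt_scaffold <- subset_sites(tgt_panel, loc$observed)

  t0 <- proc.time()[["elapsed"]]
  imp <- if (is.function(engine))
    engine(tgt_scaffold, ref_panel, loc, params)
  else impute_genotypes(tgt_scaffold, ref_panel, loc, params)
  elapsed <- proc.time()[["elapsed"]] - t0

  truth <- panel_genotypes(tgt_panel, sites = loc$hidden)
  r2 <- vapply(seq_along(loc$hidden), function(j)
    reliability(imp$genotype[, j], truth[, j]), numeric(1))
  er <- vapply(seq_along(loc$hidden), function(j)
    error_rate(imp$genotype[, j], truth[, j]), numeric(1))
  loci <- data.frame(site = universe$site[loc$hidden],
                     position = universe$position[loc$hidden],
                     maf = universe$maf[loc$hidden],
                     r2 = r2, er = er)
  structure(
    list(spec = list(reference_population = reference_population,
                     reference_size = reference_size,
                     proportion = proportion, scheme = scheme,
                     method = method %||% if (is.function(engine)) "external" else "ls",
                     seed = seed, target_population = target_population,
                     n_target = length(targets)),
         loci = loci,
         mean_r2 = mean(r2, na.rm = TRUE),
         error_rate = error_rate(imp$genotype, truth),
         n_loci = nrow(loci),
         n_undefined = sum(is.na(r2)),
         n_scaffold = count,
         elapsed = elapsed),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Scenario [%s ref %s, density %s, %s, %s]: mean r2 = %.3f, error = %.2f%% (%d loci, %d undefined)\n",
              s$reference_population, s$reference_size, s$proportion,
              s$scheme, s$method, x$mean_r2, x$error_rate, x$n_loci,
              x$n_undefined))
  invisible(x)
}

#' Run a grid of scenarios
#'
#' @param panel A [haplotype_panel].
#' @param grid A `scenario_grid` (sizes already scaled to the panel, see
#'   [scale_grid()]).
#' @param ... Passed to [run_scenario()] (targets, params, engine, ...).
#' @param verbose Print one log line per scenario.
#' @return List of `scenario_result`, one per grid row.
#' @export
run_grid <- function(panel, grid, ..., verbose = FALSE) {
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    out[[i]] <- run_scenario(panel,
                             reference_population = g$reference_population,
                             reference_size = g$reference_size,
                             proportion = g$proportion,
                             scheme = g$scheme, seed = g$seed,
                             method = g$method, ...)
    if (verbose) print(out[[i]])
  }
  out
}

#' Cell-level table of scenario results
#'
#' @param results List of `scenario_result`.
#' @return Data frame with one row per scenario: the design factors plus
#'   `mean_r2`, `error_rate`, `n_loci`, `n_undefined`.
#' @export
scenario_cells <- function(results) {
  if (!length(results)) stop("no scenario results")
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$spec$method, scheme = r$spec$scheme,
               reference_population = r$spec$reference_population,
               reference_size = r$spec$reference_size,
               proportion = r$spec$proportion,
               mean_r2 = r$mean_r2, error_rate = r$error_rate,
               n_loci = r$n_loci, n_undefined = r$n_undefined,
               stringsAsFactors = FALSE)
  }))
}

#' Coefficient-of-variation factor ranking
#'
#' For each design factor, computes the per-level marginal means of an
#' accuracy measure over a cell table and their coefficient of variation;
#' the factor with the largest CV is flagged as most influential.
#'
#' @param cells Cell table (e.g. from [scenario_cells()] or
#'   [fixture_cells()]).
#' @param response Column name of the accuracy measure.
#' @param factors Factor column names to rank.
#' @return Data frame with `factor`, `cv` and `most_influential`.
#' @export
factor_cvs <- function(cells, response,
                       factors = intersect(c("proportion", "reference_size",
                                             "reference_population"),
                                           names(cells))) {
  cv <- vapply(factors, function(f) {
    lv <- sort(unique(cells[[f]]))
    if (length(lv) < 2L) return(NA_real_)
    means <- vapply(lv, function(l) marginal_mean(cells, f, l, response),
                    numeric(1))
    coefficient_of_variation(means)
  }, numeric(1))
  data.frame(factor = factors, cv = unname(cv),
             most_influential = seq_along(cv) == which.max(cv),
             stringsAsFactors = FALSE)
}

#' Summarize a factorial run
#'
#' Builds the headline summaries of a factorial imputation experiment:
#' size x density matrices of mean reliability and error rate per method
#' and scheme, marginal factor-level means, and the CV-based factor
#' ranking for both accuracy criteria.
#'
#' @param results List of `scenario_result`.
#' @return A `grid_summary` list with `cells`, `reliability` and
#'   `error_rate` (named lists of size x density matrices),
#'   `cv` (data frame over method/scheme/criterion/factor) and
#'   `most_influential` per method/scheme/criterion.
#' @export
summarize_scenarios <- function(results) {
  cells <- scenario_cells(results)
  mats_r2 <- list(); mats_er <- list()
  cvrows <- NULL
  for (m in unique(cells$method)) for (sc in unique(cells$scheme)) {
    sub <- cells[cells$method == m & cells$scheme == sc, ]
    if (!nrow(sub)) next
    key <- paste(m, sc, sep = ".")
    sizes <- sort(unique(sub$reference_size))
    dens <- sort(unique(sub$proportion))
    mk <- function(resp) {
      M <- matrix(NA_real_, length(sizes), length(dens),
                  dimnames = list(sizes, dens))
      for (i in seq_len(nrow(sub)))
        M[as.character(sub$reference_size[i]),
          as.character(sub$proportion[i])] <-
          mean(sub[[resp]][sub$reference_size == sub$reference_size[i] &
                             sub$proportion == sub$proportion[i]])
      M
    }
    mats_r2[[key]] <- mk("mean_r2")
    mats_er[[key]] <- mk("error_rate")
    for (resp in c("mean_r2", "error_rate")) {
      fc <- tryCatch(factor_cvs(sub, resp), error = function(e) NULL)
      if (!is.null(fc))
        cvrows <- rbind(cvrows,
                        cbind(method = m, scheme = sc, criterion = resp, fc,
                              stringsAsFactors = FALSE))
    }
  }
  structure(list(cells = cells, reliability = mats_r2,
                 error_rate = mats_er, cv = cvrows),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat("Factorial imputation summary:", nrow(x$cells), "scenario cells\n")
  for (key in names(x$reliability)) {
    cat("\nMean reliability (r2), ", key, " [size x density]:\n", sep = "")
    print(round(x$reliability[[key]], 3))
    cat("Error rate (%), ", key, ":\n", sep = "")
    print(round(x$error_rate[[key]], 3))
  }
  if (!is.null(x$cv)) {
    cat("\nCoefficient-of-variation factor ranking:\n")
    print(x$cv, row.names = FALSE)
  }
  invisible(x)
}
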