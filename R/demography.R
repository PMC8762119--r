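#' Specify a multi-population demographic model
#'
#' Builds the demographic model object consumed by [simulate_ancestry()] and
#' [simulate_panel()]: a set of demes with constant diploid effective sizes,
#' symmetric pairwise migration, and a list of backward-in-time events
#' (population splits, size changes, migration-rate changes).
#'
#' Time is continuous and measured in generations before present. A split
#' event is interpreted backward in time: at the event time all lineages of
#' the derived deme move into the ancestral deme and the derived deme ceases
#' to exist. Migration between a pair of demes is only active while both
#' demes exist (a deme exists from its `origin_time` until it is merged away
#' by a split).
#'
#' @param sequence_length Chromosome length in base pairs (L > 0).
#' @param mutation_rate Mutation rate per bp per generation.
#' @param recombination_rate Recombination rate per bp per generation.
#' @param populations Data frame with columns `id` (character),
#'   `effective_size` (diploid Ne > 0) and optionally `origin_time`
#'   (generations before present from which the deme can hold lineages;
#'   default 0, i.e. the deme exists at sampling time).
#' @param migration Data frame with columns `pop1`, `pop2`, `rate`:
#'   symmetric backward migration rates per lineage per generation.
#'   May be `NULL` (no migration).
#' @param events List of events; each event is a list with a `time`
#'   (generations > 0) and `kind` one of `"split"` (fields `derived`,
#'   `ancestral`), `"size_change"` (fields `population`, `size`) or
#'   `"migration_change"` (fields `pop1`, `pop2`, `rate`).
#' @param origin_time Optional age of the root population (generations);
#'   purely descriptive, the simulation runs as far back as coalescence
#'   requires.
#'
#' @return An object of class `demographic_model`.
#' @seealso [pig_demography()] for the packaged pig model.
#' @export
demographic_model <- function(sequence_length, mutation_rate, recombination_rate,
                              populations, migration = NULL, events = list(),
                              origin_time = NULL) {
  stopifnot(is.numeric(sequence_length), length(sequence_length) == 1L,
            sequence_length > 0)
  stopifnot(is.numeric(mutation_rate), mutation_rate >= 0)
  stopifnot(is.numeric(recombination_rate), recombination_rate >= 0)
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  if (!all(c("id", "effective_size") %in% names(populations)))
    stop("`populations` needs columns 'id' and 'effective_size'")
  if (is.null(populations$origin_time)) populations$origin_time <- 0
  populations$id <- as.character(populations$id)
  if (anyDuplicated(populations$id)) stop("duplicated population ids")
  if (any(populations$effective_size <= 0)) stop("all effective sizes must be > 0")

  if (!is.null(migration)) {
    migration <- as.data.frame(migration, stringsAsFactors = FALSE)
    if (!all(c("pop1", "pop2", "rate") %in% names(migration)))
      stop("`migration` needs columns 'pop1', 'pop2', 'rate'")
    bad <- !(migration$pop1 %in% populations$id) | !(migration$pop2 %in% populations$id)
    if (any(bad)) stop("migration references unknown population: ",
                       paste(unique(c(migration$pop1[bad], migration$pop2[bad])),
                             collapse = ", "))
    if (any(migration$rate < 0)) stop("migration rates must be >= 0")
  } else {
    migration <- data.frame(pop1 = character(), pop2 = character(),
                            rate = numeric(), stringsAsFactors = FALSE)
  }

  times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  if (length(times) && any(times <= 0)) stop("event times must be > 0")
  events <- events[order(times)]
  for (e in events) {
    if (!e$kind %in% c("split", "size_change", "migration_change"))
      stop("unknown event kind: ", e$kind)
    refs <- switch(e$kind,
                   split = c(e$derived, e$ancestral),
                   size_change = e$population,
                   migration_change = c(e$pop1, e$pop2))
    if (!all(refs %in% populations$id))
      stop("event references unknown population: ",
           paste(setdiff(refs, populations$id), collapse = ", "))
  }

  model <- structure(
    list(sequence_length = sequence_length,
         mutation_rate = mutation_rate,
         recombination_rate = recombination_rate,
         populations = populations,
         migration = migration,
         events = events,
         origin_time = origin_time),
    class = "demographic_model")
  model
}

#' Packaged four-population pig demography
#'
#' The demographic model used throughout the package's simulation study:
#' an ancestral pig population (diploid Ne 10,873) from which four related
#' populations P1--P4 (Ne 1,600, 1,200, 1,000 and 1,400) descend through a
#' chain of splits with bottleneck-scale sizes and symmetric migration, on a
#' 10 Mb chromosome with mutation and recombination rates of 1e-7 per bp per
#' generation.
#'
#' Backward in time the default split topology is a chain: P4 merges into P3
#' at 20 generations, P3 into P2 at 200, P2 into P1 at 3,000 and P1 into the
#' ancestral population at 9,000 generations before present; the ancestral
#' population originates 58,000 generations ago. Migration rates
#' (per lineage per generation): ANC-P1 2.1e-5, P1-P2 1.1e-3, P1-P4 3.7e-4,
#' P2-P3 5.2e-5, P3-P4 1.6e-3; each is active only while both demes exist.
#' The published description fixes the event times, sizes and rates but not
#' the split tree itself, so the chain topology used here is one consistent
#' reading and can be overridden via `splits`.
#'
#' @param sequence_length Chromosome length in bp (default 10 Mb).
#' @param splits Named character vector mapping each derived population to
#'   the deme it merges into (backward in time). Names must be
#'   `c("P4","P3","P2","P1")`; values are the corresponding ancestral demes.
#' @param split_times Named numeric vector of merge times in generations for
#'   the same four derived populations.
#'
#' @return A `demographic_model`.
#' @examples
#' m <- pig_demography()
#' m$sequence_length
#' m$populations$effective_size[m$populations$id == "ANC"]
#' @export
pig_demography <- function(sequence_length = 1e7,
                           splits = c(P4 = "P3", P3 = "P2", P2 = "P1", P1 = "ANC"),
                           split_times = c(P4 = 20, P3 = 200, P2 = 3000, P1 = 9000)) {
  stopifnot(setequal(names(splits), c("P1", "P2", "P3", "P4")),
            setequal(names(split_times), c("P1", "P2", "P3", "P4")))
  pops <- data.frame(
    id = c("ANC", "P1", "P2", "P3", "P4"),
    effective_size = c(10873, 1600, 1200, 1000, 1400),
    origin_time = c(unname(split_times["P1"]), 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  mig <- data.frame(
    pop1 = c("ANC", "P1", "P1", "P2", "P3"),
    pop2 = c("P1",  "P2", "P4", "P3", "P4"),
    rate = c(2.1e-5, 1.1e-3, 3.7e-4, 5.2e-5, 1.6e-3),
    stringsAsFactors = FALSE)
  events <- lapply(c("P4", "P3", "P2", "P1"), function(d) {
    list(time = unname(split_times[d]), kind = "split",
         derived = d, ancestral = unname(splits[d]))
  })
  demographic_model(sequence_length = sequence_length,
                    mutation_rate = 1e-7, recombination_rate = 1e-7,
                    populations = pops, migration = mig, events = events,
                    origin_time = 58000)
}

#' Migration rate between two demes
#'
#' @param model A `demographic_model`.
#' @param pop1,pop2 Population ids.
#' @return The symmetric migration rate (0 if none specified).
#' @export
migration_rate <- function(model, pop1, pop2) {
  m <- model$migration
  hit <- (m$pop1 == pop1 & m$pop2 == pop2) | (m$pop1 == pop2 & m$pop2 == pop1)
  if (any(hit)) m$rate[which(hit)[1L]] else 0
}

# symmetric migration matrix over the model's demes
.migration_matrix <- function(model) {
  ids <- model$populations$id
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m <- model$migration
  for (i in seq_len(nrow(m))) {
    M[m$pop1[i], m$pop2[i]] <- m$rate[i]
    M[m$pop2[i], m$pop1[i]] <- m$rate[i]
  }
  M
}

# check that all sampled demes can reach a common ancestor through
# splits and/or positive migration
.check_connected <- function(model, sampled) {
  ids <- model$populations$id
  comp <- stats::setNames(ids, ids)
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  link <- function(a, b) comp[[find(a)]] <<- find(b)
  for (e in model$events)
    if (e$kind == "split") link(e$derived, e$ancestral)
  m <- model$migration
  for (i in seq_len(nrow(m)))
    if (m$rate[i] > 0) link(m$pop1[i], m$pop2[i])
  roots <- vapply(sampled, find, character(1))
  if (length(unique(roots)) > 1L)
    stop("sampled populations cannot reach a common ancestor: ",
         "the split/migration graph is not connected")
  invisible(TRUE)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", nrow(x$populations), "populations,",
      length(x$events), "events\n")
  cat("  sequence length:", format(x$sequence_length, big.mark = ","), "bp;",
      "mu =", x$mutation_rate, "; r =", x$recombination_rate, "\n")
  for (i in seq_len(nrow(x$populations)))
    cat(sprintf("  %-4s Ne = %s%s\n", x$populations$id[i],
                format(x$populations$effective_size[i], big.mark = ","),
                if (x$populations$origin_time[i] > 0)
                  paste0(" (origin ", x$populations$origin_time[i], " gen)") else ""))
  for (e in x$events) {
    if (e$kind == "split")
      cat(sprintf("  t=%-6s split: %s -> %s\n", e$time, e$derived, e$ancestral))
    else if (e$kind == "size_change")
      cat(sprintf("  t=%-6s size: %s -> %s\n", e$time, e$population, e$size))
    else
      cat(sprintf("  t=%-6s migration: %s-%s -> %s\n", e$time, e$pop1, e$pop2, e$rate))
  }
  invisible(x)
}

#' Write / read a demographic model as a key-value text config
#'
#' Serializes a `demographic_model` to a plain-text config (one `key = value`
#' per line) and reads it back. Round-trip stable for models built from
#' numeric parameters.
#'
#' @param model A `demographic_model`.
#' @param path File path.
#' @return `read_model_config()` returns a `demographic_model`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  ln <- c(
    paste0("sequence_length = ", format(model$sequence_length, scientific = FALSE)),
    paste0("mutation_rate = ", model$mutation_rate),
    paste0("recombination_rate = ", model$recombination_rate))
  for (i in seq_len(nrow(model$populations)))
    ln <- c(ln, sprintf("population = %s %s %s", model$populations$id[i],
                        model$populations$effective_size[i],
                        model$populations$origin_time[i]))
  for (i in seq_len(nrow(model$migration)))
    ln <- c(ln, sprintf("migration = %s %s %s", model$migration$pop1[i],
                        model$migration$pop2[i], model$migration$rate[i]))
  for (e in model$events) {
    if (e$kind == "split")
      ln <- c(ln, sprintf("split = %s %s %s", e$time, e$derived, e$ancestral))
    else if (e$kind == "size_change")
      ln <- c(ln, sprintf("size_change = %s %s %s", e$time, e$population, e$size))
    else
      ln <- c(ln, sprintf("migration_change = %s %s %s %s",
                          e$time, e$pop1, e$pop2, e$rate))
  }
  if (!is.null(model$origin_time))
    ln <- c(ln, paste0("origin_time = ", model$origin_time))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1)))
  get1 <- function(k) as.numeric(vals[match(k, keys)])
  sp <- function(v) strsplit(v, "[[:space:]]+")[[1L]]
  pops <- do.call(rbind, lapply(vals[keys == "population"], function(v) {
    f <- sp(v)
    data.frame(id = f[1L], effective_size = as.numeric(f[2L]),
               origin_time = as.numeric(f[3L]), stringsAsFactors = FALSE)
  }))
  migs <- vals[keys == "migration"]
  mig <- if (length(migs)) do.call(rbind, lapply(migs, function(v) {
    f <- sp(v)
    data.frame(pop1 = f[1L], pop2 = f[2L], rate = as.numeric(f[3L]),
               stringsAsFactors = FALSE)
  })) else NULL
  events <- list()
  for (i in seq_along(keys)) {
    f <- sp(vals[i])
    ev <- switch(keys[i],
                 split = list(time = as.numeric(f[1L]), kind = "split",
                              derived = f[2L], ancestral = f[3L]),
                 size_change = list(time = as.numeric(f[1L]), kind = "size_change",
                                    population = f[2L], size = as.numeric(f[3L])),
                 migration_change = list(time = as.numeric(f[1L]),
                                         kind = "migration_change",
                                         pop1 = f[2L], pop2 = f[3L],
                                         rate = as.numeric(f[4L])),
                 NULL)
    if (!is.null(ev)) events <- c(events, list(ev))
  }
  ot <- if ("origin_time" %in% keys) get1("origin_time") else NULL
  demographic_model(sequence_length = get1("sequence_length"),
                    mutation_rate = get1("mutation_rate"),
                    recombination_rate = get1("recombination_rate"),
                    populations = pops, migration = mig, events = events,
                    origin_time = ot)
}
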