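#' Structured-coalescent event rates
#'
#' Instantaneous rates of the three event classes of the structured
#' coalescent with recombination, given the current lineage configuration.
#' Coalescence in deme j occurs at rate choose(k_j, 2) / (2 N_j) per
#' generation (diploid Ne); a lineage in deme x migrates to deme y at rate
#' m_xy, so the deme-pair rate is k_x m_xy; a lineage recombines at rate
#' r times the bp extent of its ancestral material.
#'
#' @param state List with `lineage_counts` (named integer vector, deme id ->
#'   number of lineages) and `spans` (numeric vector, per-lineage extent of
#'   ancestral material in bp, i.e. rightmost minus leftmost coordinate).
#' @param model A [demographic_model()].
#' @return List with components `coalescence` (named per-deme rates),
#'   `migration` (matrix, from-deme x to-deme rates), `recombination`
#'   (total rate) and `total`.
#' @export
event_rates <- function(state, model) {
  ids <- model$populations$id
  k <- state$lineage_counts
  if (is.null(names(k))) stop("lineage_counts must be a named vector of demes")
  unknown <- setdiff(names(k), ids)
  if (length(unknown))
    stop("unknown deme id: ", paste(unknown, collapse = ", "))
  if (any(k < 0)) stop("lineage counts must be >= 0")
  spans <- state$spans %||% numeric(0)
  if (any(spans < 0)) stop("ancestral spans must be >= 0")
  kfull <- stats::setNames(numeric(length(ids)), ids)
  kfull[names(k)] <- k
  N <- stats::setNames(model$populations$effective_size, ids)
  coal <- kfull * (kfull - 1) / 2 / (2 * N)
  M <- .migration_matrix(model)
  mig <- kfull * M                       # rows: from-deme, cols: to-deme
  rec <- model$recombination_rate * sum(spans)
  list(coalescence = coal, migration = mig, recombination = rec,
       total = sum(coal) + sum(mig) + rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ancestral recombination graph under a demographic model
#'
#' Hudson-style backward-in-time simulation of the structured coalescent
#' with recombination: exponential waiting times are drawn from the total
#' event rate; coalescence merges two lineages' ancestral-segment sets
#' (recording tree edges over the overlapping material), migration relabels
#' a lineage's deme, and recombination splits a lineage at a uniform
#' breakpoint within its ancestral extent. Split events move, backward in
#' time, all lineages of the derived deme into its ancestral deme. The
#' simulation ends when every position of the chromosome has reached its
#' most recent common ancestor.
#'
#' @param model A [demographic_model()].
#' @param samples Named integer vector of diploid sample counts per
#'   population (haplotypes sampled = 2 x diploids).
#' @param seed Integer seed; identical (model, samples, seed) triples give
#'   identical output.
#' @return An object of class `genealogy_forest`: an edge table
#'   (`parent`, `child`, `left`, `right` with half-open bp intervals),
#'   node times in generations (`node_time`), sample bookkeeping and
#'   provenance. Samples are nodes `1..2n`, haplotypes `2k-1, 2k` forming
#'   diploid individual `k`.
#' @seealso [tree_stats()], [overlay_mutations()], [simulate_panel()]
#' @export
simulate_ancestry <- function(model, samples, seed) {
  stopifnot(is.numeric(samples), !is.null(names(samples)))
  samples <- samples[samples > 0]
  if (length(samples) == 0L) stop("at least one population must be sampled")
  ids <- model$populations$id
  if (!all(names(samples) %in% ids))
    stop("unknown sampled population: ",
         paste(setdiff(names(samples), ids), collapse = ", "))
  ot <- stats::setNames(model$populations$origin_time, ids)
  if (any(ot[names(samples)] > 0))
    stop("sampled population does not exist at time 0: ",
         paste(names(samples)[ot[names(samples)] > 0], collapse = ", "))
  nhap <- as.integer(2 * sum(samples))
  if (nhap < 2L) stop("need at least one diploid sample")
  .check_connected(model, names(samples))

  L <- model$sequence_length
  rrate <- model$recombination_rate
  npop <- length(ids)
  N <- stats::setNames(as.numeric(model$populations$effective_size), ids)
  M <- .migration_matrix(model)
  origin <- stats::setNames(as.numeric(model$populations$origin_time), ids)
  endt <- stats::setNames(rep(Inf, npop), ids)
  for (e in model$events) if (e$kind == "split") endt[e$derived] <- e$time

  set.seed(as.integer(seed %% .Machine$integer.max))

  # --- mutable simulation state -------------------------------------------
  sample_pop <- rep(names(samples), times = 2 * samples)
  lin <- vector("list", nhap)            # each: list(seg = matrix(l, r, node))
  demes <- integer(nhap)                 # deme index per lineage
  spans <- numeric(nhap)                 # ancestral extent per lineage (bp)
  for (i in seq_len(nhap)) {
    lin[[i]] <- matrix(c(0, L, i), nrow = 1L)
    demes[i] <- match(sample_pop[i], ids)
    spans[i] <- L
  }
  node_time <- c(numeric(nhap), numeric(64L))
  n_nodes <- nhap

  # edge store (grows by doubling)
  ecap <- 1024L; en <- 0L
  e_par <- numeric(ecap); e_child <- numeric(ecap)
  e_l <- numeric(ecap); e_r <- numeric(ecap)
  push_edge <- function(p, ch, a, b) {
    if (en == ecap) {
      ecap <<- ecap * 2L
      length(e_par) <<- ecap; length(e_child) <<- ecap
      length(e_l) <<- ecap; length(e_r) <<- ecap
    }
    en <<- en + 1L
    e_par[en] <<- p; e_child[en] <<- ch; e_l[en] <<- a; e_r[en] <<- b
  }
  new_node <- function(t) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(node_time)) length(node_time) <<- 2L * length(node_time)
    node_time[n_nodes] <<- t
    n_nodes
  }

  # piecewise-constant count of lineages ancestral to each point:
  # breakpoints cbp (cbp[1] = 0, cbp[end] = L), counts ccnt per interval
  cbp <- c(0, L)
  ccnt <- nhap
  # split the count partition at x (no-op if x already a breakpoint)
  cut_at <- function(x) {
    i <- findInterval(x, cbp)
    if (cbp[i] != x) {
      cbp <<- append(cbp, x, after = i)
      ccnt <<- append(ccnt, ccnt[i], after = i)
    }
  }
  # decrement counts over [a, b); returns matrix (l, r, newcount)
  dec_count <- function(a, b) {
    cut_at(a); cut_at(b)
    i1 <- findInterval(a, cbp)
    i2 <- findInterval(b, cbp) - 1L
    idx <- i1:i2
    ccnt[idx] <<- ccnt[idx] - 1L
    cbind(cbp[idx], cbp[idx + 1L], ccnt[idx])
  }

  # node covering each elementary piece, NA where no material
  piece_nodes <- function(s, p) {
    f <- findInterval(p, s[, 1L])
    out <- rep(NA_real_, length(p))
    hit <- f >= 1L
    hit[hit] <- p[hit] < s[f[hit], 2L]
    out[hit] <- s[f[hit], 3L]
    out
  }

  # merge two coalescing segment lists at time t; returns parent seg matrix
  merge_coal <- function(s1, s2, t) {
    pts <- sort(unique(c(s1[, 1L], s1[, 2L], s2[, 1L], s2[, 2L])))
    p <- pts[-length(pts)]; q <- pts[-1L]
    n1 <- piece_nodes(s1, p); n2 <- piece_nodes(s2, p)
    u <- NA_real_
    ol <- numeric(0); or <- numeric(0); on <- numeric(0)
    for (i in seq_along(p)) {
      if (is.na(n1[i]) && is.na(n2[i])) next
      if (is.na(n2[i])) { ol <- c(ol, p[i]); or <- c(or, q[i]); on <- c(on, n1[i]); next }
      if (is.na(n1[i])) { ol <- c(ol, p[i]); or <- c(or, q[i]); on <- c(on, n2[i]); next }
      if (is.na(u)) u <- new_node(t)
      push_edge(u, n1[i], p[i], q[i])
      push_edge(u, n2[i], p[i], q[i])
      pieces <- dec_count(p[i], q[i])
      keep <- pieces[, 3L] >= 2
      if (any(keep)) {
        ol <- c(ol, pieces[keep, 1L]); or <- c(or, pieces[keep, 2L])
        on <- c(on, rep(u, sum(keep)))
      }
    }
    if (length(ol) == 0L) return(NULL)
    # compact touching rows with identical node labels
    o <- order(ol)
    ol <- ol[o]; or <- or[o]; on <- on[o]
    keep <- rep(TRUE, length(ol))
    for (i in seq_along(ol)[-1L]) {
      j <- max(which(keep[1:(i - 1L)]))
      if (on[i] == on[j] && ol[i] == or[j]) { or[j] <- or[i]; keep[i] <- FALSE }
    }
    cbind(ol[keep], or[keep], on[keep])
  }

  # --- event loop ---------------------------------------------------------
  ev <- Filter(function(e) TRUE, model$events)   # sorted by constructor
  ev_i <- 1L
  t <- 0
  while (length(lin) > 0L) {
    k <- tabulate(demes, nbins = npop)
    coal <- k * (k - 1) / 2 / (2 * N)
    exist_to <- origin <= t & t < endt
    mig <- (k * M) * rep(exist_to, each = npop)   # mask columns (destinations)
    rec_tot <- rrate * sum(spans)
    tot <- sum(coal) + sum(mig) + rec_tot
    dt <- if (tot > 0) stats::rexp(1L, tot) else Inf
    if (ev_i <= length(ev) && t + dt >= ev[[ev_i]]$time) {
      e <- ev[[ev_i]]; ev_i <- ev_i + 1L
      t <- e$time
      if (e$kind == "split") {
        di <- match(e$derived, ids); ai <- match(e$ancestral, ids)
        demes[demes == di] <- ai
      } else if (e$kind == "size_change") {
        N[e$population] <- e$size
      } else if (e$kind == "migration_change") {
        M[e$pop1, e$pop2] <- e$rate; M[e$pop2, e$pop1] <- e$rate
      }
      next
    }
    if (!is.finite(dt))
      stop("simulation stalled: remaining lineages can never coalesce")
    t <- t + dt
    u <- stats::runif(1L, 0, tot)
    csum <- sum(coal)
    if (u < csum) {
      # coalescence: pick deme, then an unordered pair of its lineages
      d <- which(u < cumsum(coal))[1L]
      members <- which(demes == d)
      pair <- members[sample.int(length(members), 2L)]
      i <- pair[1L]; j <- pair[2L]
      ps <- merge_coal(lin[[i]], lin[[j]], t)
      drop <- sort(c(i, j), decreasing = TRUE)
      lin[[drop[1L]]] <- NULL; lin[[drop[2L]]] <- NULL
      demes <- demes[-drop]; spans <- spans[-drop]
      if (!is.null(ps)) {
        lin[[length(lin) + 1L]] <- ps
        demes <- c(demes, d)
        spans <- c(spans, ps[nrow(ps), 2L] - ps[1L, 1L])
      }
    } else if (u < csum + sum(mig)) {
      v <- u - csum
      cell <- which(v < cumsum(mig))[1L]          # column-major index
      from <- (cell - 1L) %% npop + 1L
      to <- (cell - 1L) %/% npop + 1L
      cand <- which(demes == from)
      i <- cand[sample.int(length(cand), 1L)]
      demes[i] <- to
    } else {
      # recombination
      i <- sample.int(length(lin), 1L, prob = spans)
      s <- lin[[i]]
      l0 <- s[1L, 1L]; r0 <- s[nrow(s), 2L]
      x <- stats::runif(1L, l0, r0)
      left <- s[s[, 2L] <= x, , drop = FALSE]
      right <- s[s[, 1L] >= x, , drop = FALSE]
      mid <- s[s[, 1L] < x & s[, 2L] > x, , drop = FALSE]
      if (nrow(mid) == 1L) {
        left <- rbind(left, c(mid[1L, 1L], x, mid[1L, 3L]))
        right <- rbind(c(x, mid[1L, 2L], mid[1L, 3L]), right)
      }
      if (nrow(left) == 0L || nrow(right) == 0L) next  # breakpoint in flank
      lin[[i]] <- left
      spans[i] <- left[nrow(left), 2L] - left[1L, 1L]
      lin[[length(lin) + 1L]] <- right
      demes <- c(demes, demes[i])
      spans <- c(spans, right[nrow(right), 2L] - right[1L, 1L])
    }
  }

  structure(
    list(edges = data.frame(parent = e_par[seq_len(en)],
                            child = e_child[seq_len(en)],
                            left = e_l[seq_len(en)],
                            right = e_r[seq_len(en)]),
         node_time = node_time[seq_len(n_nodes)],
         n_samples = nhap,
         sample_population = sample_pop,
         sequence_length = L,
         seed = seed,
         model = model),
    class = "genealogy_forest")
}

#' Per-interval marginal tree statistics
#'
#' Sweeps the recombination breakpoints of a simulated genealogy and reports,
#' for every marginal tree interval, the time to the most recent common
#' ancestor and the total branch length (both in generations).
#'
#' @param forest A `genealogy_forest` from [simulate_ancestry()].
#' @return Data frame with columns `left`, `right` (bp, half-open),
#'   `tmrca`, `total_length` and `n_edges`.
#' @export
tree_stats <- function(forest) {
  ed <- forest$edges
  nt <- forest$node_time
  bps <- sort(unique(c(0, forest$sequence_length, ed$left, ed$right)))
  a <- bps[-length(bps)]; b <- bps[-1L]
  out <- data.frame(left = a, right = b, tmrca = NA_real_,
                    total_length = NA_real_, n_edges = NA_integer_)
  blen <- nt[ed$parent] - nt[ed$child]
  for (i in seq_along(a)) {
    act <- ed$left <= a[i] & ed$right >= b[i]
    out$tmrca[i] <- max(nt[ed$parent[act]])
    out$total_length[i] <- sum(blen[act])
    out$n_edges[i] <- sum(act)
  }
  out
}

#' @export
print.genealogy_forest <- function(x, ...) {
  nint <- length(unique(c(0, x$sequence_length, x$edges$left, x$edges$right))) - 1L
  cat("Genealogy forest:", x$n_samples, "sampled haplotypes,",
      nrow(x$edges), "edges,", nint, "marginal intervals\n")
  cat("  sequence length:", format(x$sequence_length, big.mark = ","),
      "bp; seed:", x$seed, "\n")
  invisible(x)
}
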