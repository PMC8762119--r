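test_that("packaged pig model carries the study parameterization", {
  m <- pig_demography()
  expect_equal(m$sequence_length, 1e7)
  expect_equal(m$mutation_rate, 1e-7)
  expect_equal(m$recombination_rate, 1e-7)
  sizes <- setNames(m$populations$effective_size, m$populations$id)
  expect_equal(sizes[["ANC"]], 10873)
  expect_equal(sizes[["P1"]], 1600)
  expect_equal(sizes[["P2"]], 1200)
  expect_equal(sizes[["P3"]], 1000)
  expect_equal(sizes[["P4"]], 1400)
  expect_equal(migration_rate(m, "P3", "P4"), 1.6e-3)
  expect_equal(migration_rate(m, "P4", "P3"), 1.6e-3)   # symmetric
  expect_equal(migration_rate(m, "ANC", "P1"), 2.1e-5)
  expect_equal(migration_rate(m, "P1", "P3"), 0)
  tm <- vapply(m$events, `[[`, numeric(1), "time")
  expect_equal(tm, c(20, 200, 3000, 9000))              # sorted
  expect_equal(m$origin_time, 58000)
})

test_that("model constructor validates its invariants", {
  pops <- data.frame(id = c("A", "B"), effective_size = c(100, 200))
  expect_error(demographic_model(-1, 1e-8, 0, pops), "sequence_length")
  expect_error(demographic_model(1e5, 1e-8, 0,
                                 data.frame(id = "A", effective_size = 0)),
               "effective sizes")
  expect_error(demographic_model(1e5, 1e-8, 0, pops,
                                 migration = data.frame(pop1 = "A", pop2 = "Z",
                                                        rate = 1e-4)),
               "unknown population")
  expect_error(demographic_model(1e5, 1e-8, 0, pops,
                                 events = list(list(time = -5, kind = "split",
                                                    derived = "B",
                                                    ancestral = "A"))),
               "event times")
  # events get sorted by time
  m <- demographic_model(1e5, 1e-8, 0, pops,
                         migration = data.frame(pop1 = "A", pop2 = "B",
                                                rate = 1e-4),
                         events = list(
                           list(time = 500, kind = "size_change",
                                population = "A", size = 50),
                           list(time = 100, kind = "split",
                                derived = "B", ancestral = "A")))
  expect_equal(vapply(m$events, `[[`, numeric(1), "time"), c(100, 500))
})

test_that("disconnected demes are rejected before simulating", {
  pops <- data.frame(id = c("A", "B"), effective_size = c(100, 100))
  m <- demographic_model(1e4, 1e-8, 0, pops)   # no migration, no splits
  expect_error(simulate_ancestry(m, c(A = 2, B = 2), seed = 1),
               "common ancestor")
  # migration connects them
  m2 <- demographic_model(1e4, 1e-8, 0, pops,
                          migration = data.frame(pop1 = "A", pop2 = "B",
                                                 rate = 1e-2))
  expect_s3_class(simulate_ancestry(m2, c(A = 1, B = 1), seed = 1),
                  "genealogy_forest")
})

test_that("model config files round-trip", {
  m <- pig_demography(sequence_length = 12345)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$sequence_length, m$sequence_length)
  expect_equal(m2$populations, m$populations)
  expect_equal(m2$migration, m$migration)
  expect_equal(length(m2$events), length(m$events))
  expect_equal(m2$events[[1L]], m$events[[1L]])
  expect_equal(m2$origin_time, 58000)
})

test_that("structured-coalescent event rates follow the standard formulas", {
  m <- demographic_model(1e6, 1e-8, 1e-8,
                         data.frame(id = c("A", "B"),
                                    effective_size = c(1000, 500)),
                         migration = data.frame(pop1 = "A", pop2 = "B",
                                                rate = 2e-3))
  r <- event_rates(list(lineage_counts = c(A = 3, B = 1),
                        spans = c(1e6, 5e5, 1e6, 1e6)), m)
  expect_equal(unname(r$coalescence["A"]), 3 / (2 * 1000))   # C(3,2)/2N
  expect_equal(unname(r$coalescence["B"]), 0)                # no pair
  expect_equal(r$migration["A", "B"], 3 * 2e-3)
  expect_equal(r$migration["B", "A"], 1 * 2e-3)
  expect_equal(r$recombination, 1e-8 * 3.5e6)
  expect_equal(r$total,
               sum(r$coalescence) + sum(r$migration) + r$recombination)
  expect_error(event_rates(list(lineage_counts = c(Z = 2), spans = 1e6), m),
               "unknown deme")
})

test_that("waiting time to first event matches the exponential rate", {
  # two lineages, one deme, no recombination: first (and only) event is the
  # pair coalescence at rate 1/(2N) -> mean waiting time 2N
  N <- 500
  m <- demographic_model(1e6, 1e-7, 0,
                         data.frame(id = "A", effective_size = N))
  set.seed(402)
  t1 <- vapply(sample.int(1e7, 3000), function(s)
    max(simulate_ancestry(m, c(A = 1), seed = s)$node_time), numeric(1))
  se <- sd(t1) / sqrt(length(t1))
  expect_lt(abs(mean(t1) - 2 * N), 3 * se)
})
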