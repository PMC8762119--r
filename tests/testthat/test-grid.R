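test_that("the packaged factorial design enumerates 336 scenarios", {
  g <- study_grid()
  expect_equal(nrow(g), 336L)
  expect_equal(anyDuplicated(g$seed), 0L)
  expect_equal(length(unique(g$proportion)), 6L)
  # per-population size levels
  expect_equal(sort(unique(g$reference_size[g$reference_population == "P1"])),
               c(100, 1000, 3000, 5000, 10000))
  expect_equal(sort(unique(g$reference_size[g$reference_population == "P3"])),
               c(100, 1000, 3000))
  # degenerate and small designs
  expect_equal(nrow(build_grid(list(P1 = 100), 0.1, "chip", "ls")), 1L)
  expect_equal(nrow(build_grid(list(P1 = c(10, 20)), c(0.1, 0.5),
                               "lcwgs", "ls")), 4L)
  expect_error(build_grid(list(P1 = 10), densities = 1.2), "densities")
})

test_that("scaling a grid maps sizes proportionally with caps", {
  g <- study_grid()
  s <- scale_grid(g, 0.01, pools = c(P1 = 100, P2 = 20, P3 = 20, P4 = 20))
  expect_equal(sort(unique(s$reference_size[s$reference_population == "P1"])),
               c(2, 10, 30, 50, 100))
  expect_true(all(s$reference_size[s$reference_population == "P2"] <= 20))
  expect_true(all(s$reference_size >= 2))
})

test_that("scenarios are deterministic and validate their inputs", {
  m <- pig_demography(sequence_length = 5e4)
  pan <- simulate_panel(m, c(P1 = 20, P2 = 8), seed = 6)
  r1 <- run_scenario(pan, "P1", 8, 0.3, "lcwgs", seed = 42, n_target = 6)
  r2 <- run_scenario(pan, "P1", 8, 0.3, "lcwgs", seed = 42, n_target = 6)
  expect_identical(r1$loci, r2$loci)
  expect_identical(r1$mean_r2, r2$mean_r2)
  r3 <- run_scenario(pan, "P1", 8, 0.3, "lcwgs", seed = 43, n_target = 6)
  expect_false(identical(r1$loci$r2, r3$loci$r2))
  # too large a reference request fails, as does an absent population
  expect_error(run_scenario(pan, "P1", 15, 0.3, "lcwgs", seed = 1,
                            n_target = 6), "insufficient reference")
  expect_error(run_scenario(pan, "P4", 5, 0.3, "lcwgs", seed = 1,
                            n_target = 6), "insufficient reference")
  expect_error(run_scenario(pan, "P1", 8, 0.3, "lcwgs", seed = 1,
                            target_population = "Z", n_target = 2),
               "target population")
  # density 1 leaves nothing to impute and is rejected
  expect_error(run_scenario(pan, "P1", 8, 1, "lcwgs", seed = 1,
                            n_target = 6), "hidden")
})

test_that("per-locus records are complete and consistent", {
  m <- pig_demography(sequence_length = 5e4)
  pan <- simulate_panel(m, c(P1 = 20), seed = 16)
  r <- run_scenario(pan, "P1", 10, 0.3, "chip", seed = 3, n_target = 6)
  expect_equal(r$n_loci, nrow(r$loci))
  expect_equal(r$n_undefined, sum(is.na(r$loci$r2)))
  expect_true(all(r$loci$maf >= 0.01))        # universe was MAF-filtered
  expect_true(all(r$loci$er >= 0 & r$loci$er <= 100))
  expect_true(all(r$loci$r2 >= 0 & r$loci$r2 <= 1, na.rm = TRUE))
  expect_equal(r$mean_r2, mean(r$loci$r2, na.rm = TRUE))
  # undefined loci are excluded from the mean, not scored as zero
  expect_gt(r$mean_r2, 0)
})

test_that("summaries aggregate cells and rank factors, order-invariantly", {
  m <- pig_demography(sequence_length = 5e4)
  pan <- simulate_panel(m, c(P1 = 24, P2 = 10), seed = 8)
  g <- build_grid(list(P1 = c(5, 12)), c(0.1, 0.4), "lcwgs", "ls",
                  base_seed = 3)
  res <- run_grid(pan, g, n_target = 6)
  sm <- summarize_scenarios(res)
  expect_equal(nrow(sm$cells), 4L)
  M <- sm$reliability[["ls.lcwgs"]]
  expect_equal(dim(M), c(2L, 2L))
  expect_false(anyNA(M))
  # permuting the result list leaves the summary unchanged
  sm2 <- summarize_scenarios(res[c(3, 1, 4, 2)])
  expect_equal(sm2$reliability, sm$reliability)
  expect_equal(sm2$error_rate, sm$error_rate)
  # a single scenario summarizes to its own aggregates
  sm1 <- summarize_scenarios(res[1])
  expect_equal(unname(as.vector(sm1$reliability[["ls.lcwgs"]])),
               res[[1]]$mean_r2)
  expect_error(summarize_scenarios(list()), "no scenario")
})

test_that("near-complete marker density saturates reliability on easy panels", {
  # easy regime: low recombination, large conspecific reference, few
  # targets; at 90 percent density the mean per-locus reliability should
  # approach the full-scale saturation value of ~1, up to Monte-Carlo
  # error of the pooled estimate
  m <- demographic_model(2e5, 1e-7, 1e-8,
                         data.frame(id = "A", effective_size = 1600))
  reps <- 6L
  v <- numeric(reps)
  for (i in seq_len(reps)) {
    pan <- simulate_panel(m, c(A = 60), seed = 9200 + i)
    v[i] <- run_scenario(pan, "A", 50, 0.9, "lcwgs", seed = 9,
                         target_population = "A", n_target = 10)$mean_r2
  }
  se <- sd(v) / sqrt(reps)
  expect_gte(mean(v), 0.99 - 2 * se)
  expect_gte(mean(v), 0.95)     # desk-scale floor holds outright
})

test_that("factor CV ranking recovers a dominant factor", {
  cells <- expand.grid(proportion = c(0.1, 0.5, 0.9),
                       reference_size = c(10, 20))
  cells$acc <- 10 * cells$proportion + 0.01 * cells$reference_size
  fc <- factor_cvs(cells, "acc")
  expect_equal(fc$factor[fc$most_influential], "proportion")
  expect_true(all(fc$cv >= 0))
})
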