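test_that("reliability is the squared population-moment correlation", {
  expect_equal(reliability(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  # hand computation: Cov = 0.5, VarX = 0.5, VarY = 0.6875
  expect_equal(reliability(c(0, 1, 2, 1), c(0, 1, 2, 2)), 0.25 / 0.34375,
               tolerance = 1e-4)
  expect_true(is.na(reliability(c(1, 1, 1), c(0, 1, 2))))   # constant imputed
  expect_true(is.na(reliability(c(0, 1, 2), c(2, 2, 2))))   # constant truth
  expect_error(reliability(c(0, 1), c(0, 1, 2)), "mismatch")
  expect_error(reliability(1, 1), "two individuals")
})

test_that("reliability is symmetric and allele-label invariant", {
  set.seed(12)
  for (i in 1:20) {
    x <- sample(0:2, 8, TRUE); y <- sample(0:2, 8, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(reliability(x, y), reliability(y, x))
    expect_equal(reliability(2 - x, 2 - y), reliability(x, y))
  }
})

test_that("error rate counts minimal allelic mismatches", {
  expect_equal(error_rate(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(error_rate(2, 0), 100)
  expect_equal(error_rate(c(0, 1, 2), c(0, 2, 2)), 1 / 6 * 100,
               tolerance = 1e-9)
  M <- matrix(c(0, 1, 2, 2), 2); Tr <- matrix(c(0, 2, 2, 1), 2)
  expect_equal(error_rate(M, Tr), sum(abs(M - Tr)) / 8 * 100)
  expect_error(error_rate(matrix(0, 2, 2), matrix(0, 1, 4)), "shape")
})

test_that("error rate is a metric on genotype matrices", {
  set.seed(4)
  for (i in 1:15) {
    x <- sample(0:2, 10, TRUE); y <- sample(0:2, 10, TRUE)
    z <- sample(0:2, 10, TRUE)
    expect_equal(error_rate(x, y), error_rate(y, x))
    expect_lte(error_rate(x, z), error_rate(x, y) + error_rate(y, z) + 1e-12)
  }
})

test_that("MAF binning is half-open with a closed top edge", {
  expect_equal(as.character(maf_bin(0.01)), "[0.01,0.05)")
  expect_equal(as.character(maf_bin(0.5)), "[0.4,0.5]")
  expect_equal(as.character(maf_bin(0.049999)), "[0.01,0.05)")
  expect_equal(as.character(maf_bin(0.05)), "[0.05,0.1)")
  expect_equal(as.character(maf_bin(0.004)), "[0,0.01)")
  expect_error(maf_bin(0.6), "MAF")
  # binning partitions a simulated panel
  m <- pig_demography(sequence_length = 2e4)
  p <- simulate_panel(m, c(P1 = 8), seed = 21)
  b <- maf_bin(site_maf(p))
  expect_false(anyNA(b))
  expect_equal(sum(table(b)), ncol(p$haplotypes))
})

test_that("marginal means average cells over the other factors", {
  cells <- expand.grid(size = c(10, 20), dens = c(0.1, 0.5))
  cells$acc <- c(1, 2, 3, 4)
  expect_equal(marginal_mean(cells, "size", 10, "acc"), 2)     # (1 + 3)/2
  expect_equal(marginal_mean(cells, "dens", 0.5, "acc"), 3.5)
  one <- cells[2, ]
  expect_equal(marginal_mean(one, "size", 20, "acc"), 2)       # single cell
  expect_error(marginal_mean(cells, "nope", 1, "acc"), "unknown factor")
  expect_error(marginal_mean(cells, "size", 99, "acc"), "no cells")
})

test_that("coefficient of variation uses population moments and scales out", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  v <- c(2, 4, 6, 9)
  expect_equal(coefficient_of_variation(v),
               sqrt(mean((v - mean(v))^2)) / mean(v))
  expect_equal(coefficient_of_variation(3.7 * v),
               coefficient_of_variation(v))                  # scale invariant
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
  expect_error(coefficient_of_variation(2), "two level means")
})

test_that("factor regression returns slope, p-value and standardized slope", {
  r <- suppressWarnings(factor_regression(1:10, 2 * (1:10) + 3))
  expect_equal(r$beta, 2, tolerance = 1e-10)
  expect_equal(r$beta_std, 1, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-10)
  r0 <- suppressWarnings(factor_regression(1:10, rep(5, 10)))
  expect_equal(r0$beta, 0)
  expect_error(factor_regression(rep(1, 5), 1:5), "constant")
})

test_that("regression p-values are uniform under the null", {
  set.seed(2024)
  reps <- 1500
  p <- vapply(seq_len(reps), function(i)
    factor_regression(rnorm(30), rnorm(30))$p_value, numeric(1))
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("kinship flags duplicates and panmictic unrelatedness", {
  # a large deme keeps background relatedness near zero, so the duplicate
  # stands out against every other pair
  m <- one_deme_model(N = 4000, L = 1e5)
  p <- simulate_panel(m, c(A = 20), seed = 41)
  G <- panel_genotypes(p)
  # a duplicated individual is more related to its copy than to anyone else
  G2 <- rbind(G, G[1, ])
  K <- kinship(G2)
  n <- nrow(G2)
  # sample-frequency estimation shrinks self-similarity on rare-variant
  # heavy panels, so assert dominance over unrelated pairs rather than the
  # idealized 0.5
  expect_gt(K[1, n], 0.25)
  expect_gt(K[1, n], max(K[1, 2:(n - 1)]))
  # two halves of one panmictic deme: between-block mean ~ 0
  K1 <- kinship(G)
  blocks <- kinship_blocks(K1, rep(c("a", "b"), each = 10))
  btw <- blocks$mean[blocks$pop1 == "a" & blocks$pop2 == "b"]
  expect_lt(abs(btw), 0.05)
  expect_error(kinship(matrix(1, 3, 2)), "polymorphic")
})

test_that("sister populations show the largest between-population kinship", {
  # under the packaged demography P3 and P4 split most recently and
  # exchange migrants most strongly; their kinship block mean should top
  # the between-population blocks in nearly all replicates
  m <- pig_demography(sequence_length = 1e5)
  hits <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    p <- simulate_panel(m, c(P1 = 10, P2 = 10, P3 = 10, P4 = 10),
                        seed = 500 + i)
    kb <- panel_kinship(p)
    off <- kb[kb$pop1 != kb$pop2, ]
    top <- off[which.max(off$mean), ]
    if (top$pop1 == "P3" && top$pop2 == "P4") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
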