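test_that("transition kernel obeys the switch-mass formula", {
  k0 <- transition_kernel(0, K = 5, rho = 1e-3)
  expect_equal(k0$p_stay, 1)
  expect_equal(k0$p_switch_each, 0)
  # K = 2, rho * d = 2: q = 1 - e^-1, stay = 1 - q + q/2
  k2 <- transition_kernel(2e3, K = 2, rho = 1e-3)
  q <- 1 - exp(-1)
  expect_equal(k2$p_switch_each, q / 2)
  expect_equal(k2$p_stay, 1 - q + q / 2)
  expect_equal(k2$p_stay + k2$p_switch_each, 1)          # K = 2 row sum
  # huge rho: stationary limit 1/K
  kinf <- transition_kernel(1e9, K = 4, rho = 10)
  expect_equal(kinf$p_stay, 0.25, tolerance = 1e-12)
  expect_equal(kinf$p_switch_each, 0.25, tolerance = 1e-12)
  expect_error(transition_kernel(-1, 2, 1e-3), "distance")
})

test_that("emission probabilities are a proper two-point kernel", {
  expect_equal(emission_prob(1, 1, 0.01), 0.99)
  expect_equal(emission_prob(1, 0, 0.01), 0.01)
  expect_equal(emission_prob(0, 0, 0.01) + emission_prob(0, 1, 0.01), 1)
  expect_error(emission_prob(1, 1, 0.7), "eps")
})

test_that("forward-backward handles degenerate panels", {
  prm <- ls_params()
  # single reference haplotype: posterior is identically 1
  fb <- ls_forward_backward(c(0L, 1L, 0L), matrix(c(1L, 1L, 0L), 1),
                            c(10, 50, 90), prm)
  expect_equal(as.vector(fb$gamma), c(1, 1, 1))
  # target identical to one reference: that state dominates everywhere
  set.seed(3)
  ref <- matrix(sample(0:1, 4 * 30, TRUE), 4)
  tgt <- ref[2, ]
  fb2 <- ls_forward_backward(tgt, ref, seq(10, by = 100, length.out = 30),
                             ls_params(eps = 1e-3))
  expect_true(all(apply(fb2$gamma, 1, which.max) == 2))
  expect_error(ls_forward_backward(c(0, 2), matrix(0:1, 1), c(1, 2), prm),
               "allele codes")
})

test_that("posteriors are normalized and match brute-force enumeration", {
  prm <- ls_params(eps = 0.02, rho = 4e-3)
  set.seed(61)
  for (case in 1:12) {
    K <- sample(2:3, 1); S <- sample(3:5, 1)
    ref <- matrix(sample(0:1, K * S, TRUE), K, S)
    positions <- sort(sample.int(3000, S))
    obs_idx <- sort(sample(seq_len(S), sample(seq_len(S - 1L), 1)))
    target <- sample(0:1, length(obs_idx), TRUE)
    bf <- brute_force_posteriors(target, ref, obs_idx, positions, prm)
    fb <- ls_forward_backward(target, ref[, obs_idx, drop = FALSE],
                              positions[obs_idx], prm)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-9))
    expect_lt(max(abs(fb$gamma - bf[obs_idx, , drop = FALSE])), 1e-10)
    hid <- setdiff(seq_len(S), obs_idx)
    pr <- propagate_hidden(fb, ref, obs_idx, hid, positions, prm)
    dos_bf <- vapply(hid, function(h) sum(bf[h, ] * ref[, h]), numeric(1))
    expect_lt(max(abs(pr$dosage - dos_bf)), 1e-10)
  }
})

test_that("scaled recursion agrees with the log-space reference", {
  set.seed(19)
  K <- 25; S <- 40
  ref <- matrix(sample(0:1, K * S, TRUE), K, S)
  tgt <- sample(0:1, S, TRUE)
  pos <- sort(sample.int(1e5, S))
  prm <- ls_params(eps = 1e-3)
  fb <- ls_forward_backward(tgt, ref, pos, prm)
  lg <- impsim:::.ls_fb_log(tgt, ref, pos, prm)
  expect_lt(max(abs(fb$gamma - lg)), 1e-9)
})

test_that("hidden sites coinciding with scaffold sites are rejected", {
  ref <- matrix(sample(0:1, 2 * 4, TRUE), 2)
  prm <- ls_params()
  fb <- ls_forward_backward(c(0L, 1L), ref[, c(1, 3)], c(10, 30), prm)
  expect_error(propagate_hidden(fb, ref, observed = c(1, 3), hidden = c(1, 4),
                                positions = c(10, 20, 30, 40), prm),
               "coincides")
})

test_that("dosages are invariant to reference haplotype permutations", {
  set.seed(7)
  K <- 6; S <- 25
  ref <- matrix(sample(0:1, K * S, TRUE), K, S)
  pos <- sort(sample.int(5e4, S))
  obs <- sort(sample(seq_len(S), 15))
  tgt <- sample(0:1, 15, TRUE)
  prm <- ls_params()
  d1 <- impute_haplotype(tgt, ref, obs, pos, prm)$dosage
  perm <- sample(K)
  d2 <- impute_haplotype(tgt, ref[perm, ], obs, pos, prm)$dosage
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("diploid imputation recovers a reference-matched individual", {
  set.seed(5)
  S <- 40
  ref <- matrix(sample(0:1, 8 * S, TRUE), 8)
  pos <- sort(sample.int(4e4, S))
  obs <- sort(sample(seq_len(S), 20))
  hid <- setdiff(seq_len(S), obs)
  # both target haplotypes copy reference haplotype 3 exactly
  tgt <- rbind(ref[3, obs], ref[3, obs])
  sel <- list(observed = obs, hidden = hid)
  imp <- impute_genotypes(tgt, ref, sel, ls_params(eps = 1e-3),
                          positions = pos)
  expect_equal(as.vector(imp$genotype), as.vector(2L * ref[3, hid]))
  expect_true(all(imp$dosage >= 0 & imp$dosage <= 2))
})

test_that("best-guess rounding is half-to-even and clipped", {
  # dosage 0.4 + 0.4 = 0.8 -> 1; 0.25 + 0.25 = 0.5 -> 0; 0.75+0.75 = 1.5 -> 2
  d <- c(0.8, 0.5, 1.5, 1.9, 0.1)
  expect_equal(pmin(2L, pmax(0L, as.integer(round(d)))),
               c(1L, 0L, 2L, 2L, 0L))
})

test_that("imputation confidence saturates on an unambiguous panel", {
  # references maximally distinct: posterior mass concentrates
  ref <- rbind(rep(0L, 30), rep(1L, 30))
  pos <- seq(100, by = 200, length.out = 30)
  obs <- seq(1, 30, by = 2)
  tgt <- rbind(ref[1, obs], ref[2, obs])
  sel <- list(observed = obs, hidden = setdiff(1:30, obs))
  imp <- impute_genotypes(tgt, ref, sel, ls_params(), positions = pos)
  expect_true(all(imp$genotype == 1L))   # one haplotype from each reference
  expect_gt(mean(imp$confidence), 0.99)
})
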