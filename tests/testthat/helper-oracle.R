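# Brute-force oracle for the haplotype-copying HMM: enumerates all K^S
# state paths over every site (scaffold sites emit, hidden sites are
# silent) and marginalizes exactly. Only feasible for tiny K and S.
brute_force_posteriors <- function(target, ref, obs_idx, positions, params) {
  K <- nrow(ref); S <- ncol(ref)
  trans <- function(d) {
    q <- 1 - exp(-params$rho * d / K)
    m <- matrix(q / K, K, K)
    diag(m) <- 1 - q + q / K
    m
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))
  pr <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    st <- paths[p, ]
    w <- 1 / K
    for (s in seq_len(S)) {
      if (s > 1L)
        w <- w * trans(positions[s] - positions[s - 1L])[st[s - 1L], st[s]]
      if (s %in% obs_idx) {
        t_allele <- target[which(obs_idx == s)]
        w <- w * if (ref[st[s], s] == t_allele) 1 - params$eps else params$eps
      }
    }
    pr[p] <- w
  }
  post <- matrix(0, S, K)
  for (s in seq_len(S)) for (k in seq_len(K))
    post[s, k] <- sum(pr[paths[, s] == k])
  post / rowSums(post)
}

# hand-built panel over explicit haplotype rows
toy_panel <- function(H, positions = seq_len(ncol(H)) * 10L,
                      population = rep("A", nrow(H)), L = max(positions) + 10L) {
  haplotype_panel(H, positions = positions, population = population,
                  sequence_length = L)
}

# single-deme model for quick simulations
one_deme_model <- function(N = 1000, L = 1e5, mu = 1e-7, r = 1e-7) {
  demographic_model(L, mu, r, data.frame(id = "A", effective_size = N))
}
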