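# Independent oracles used across tests. Deliberately naive implementations:
# they enumerate or sum exhaustively and share no code with the package.

# All permutations of a vector (n! columns of indices).
all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], sub, deparse.level = 0))
  }
  out
}

# Naive O(n^2) Jonckheere-Terpstra statistic.
jt_stat_naive <- function(x, g) {
  gs <- sort(unique(g))
  J <- 0
  for (i in seq_len(length(gs) - 1)) {
    for (j in (i + 1):length(gs)) {
      for (a in x[g == gs[i]]) for (b in x[g == gs[j]])
        J <- J + (a < b) + 0.5 * (a == b)
    }
  }
  J
}

# Exhaustive permutation p-values for the JT statistic.
jt_oracle <- function(x, g) {
  P <- all_permutations(seq_along(x))
  Jobs <- jt_stat_naive(x, g)
  Js <- apply(P, 1, function(idx) jt_stat_naive(x[idx], g))
  list(inc = mean(Js >= Jobs - 1e-9), dec = mean(Js <= Jobs + 1e-9))
}

# Hypergeometric tails by direct summation of the exact mass function
# (binomial coefficients, no distribution functions).
hyper_oracle <- function(k, n, K, N) {
  kk <- max(0, n + K - N):min(n, K)
  mass <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  list(enrich = sum(mass[kk >= k]), deplete = sum(mass[kk <= k]))
}

# Brute-force grid minimiser of the Hill RSS.
hill_grid_oracle <- function(ps, signal, top_grid, bottom_grid, ic_grid, h_grid) {
  best <- Inf
  par <- NULL
  for (top in top_grid) for (bot in bottom_grid) for (ic in ic_grid)
    for (h in h_grid) {
      r <- sum((signal - (bot + (top - bot) / (1 + (ps / ic)^h)))^2)
      if (r < best) {
        best <- r
        par <- c(top = top, bottom = bot, ic50 = ic, h = h)
      }
    }
  list(rss = best, par = par)
}

# Small helper: a noise-free expression dataset with one gene per archetype.
tiny_dataset <- function(noise_sd = 0, seed = 1,
                         ps_grid = c(0.32, 0.68, 0.95), ...) {
  simulate_expression(synth_config(
    n_ca_up = 1, n_ca_down = 1, n_nca = 1, n_fn = 1, n_opp = 1, n_null = 1,
    ps_grid = ps_grid, noise_sd = noise_sd, seed = seed, ...))
}
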