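# Shared fixtures, built in code.

toy_alignment <- function(seqs, pops = NULL, ids = NULL) {
  aln <- seq_alignment(seqs, ids = ids, locus_name = "toy")
  pm <- if (is.null(pops)) NULL else
    population_map(rownames(aln$seq), pops)
  list(aln = aln, pm = pm)
}

# Direct-summation Ewens oracle: expands the rising factorial
# x (x+1) ... (x+n-1) by plain polynomial convolution, giving the unsigned
# Stirling numbers |s(n, k)| as coefficients, then sums the tail mass in
# ordinary (non-log) arithmetic. Independent of the package's log-space
# recurrence.
ewens_tail_oracle <- function(n, theta, k_obs) {
  coefs <- 1 # polynomial "x": coefficient of x^1, after factoring one x out
  for (m in 1:(n - 1)) {
    # multiply by (x + m): new_j = old_{j-1} + m * old_j
    coefs <- c(0, coefs) + m * c(coefs, 0)
  }
  # coefs[k] = |s(n, k)|
  probs <- coefs * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
  sum(probs[k_obs:n]) / sum(probs)
}

fs_oracle <- function(k_obs, n, theta) {
  s <- ewens_tail_oracle(n, theta, k_obs)
  log(s / (1 - s))
}

# Term-by-term AMOVA oracle following the two-level variance-component
# algebra literally, written independently of phi_st().
phi_st_oracle <- function(d, pops) {
  pops <- as.factor(pops)
  N <- nrow(d)
  sizes <- as.numeric(table(pops))
  P <- length(sizes)
  ss_t <- sum(d[upper.tri(d)]) / N
  ss_w <- 0
  for (p in levels(pops)) {
    i <- which(pops == p)
    sub <- d[i, i, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(i)
  }
  ms_a <- (ss_t - ss_w) / (P - 1)
  ms_w <- ss_w / (N - P)
  n_prime <- (N - sum(sizes^2) / N) / (P - 1)
  s2_a <- (ms_a - ms_w) / n_prime
  s2_a / (s2_a + ms_w)
}

# a 5-deme line stepping-stone model with strong structure
strong_stepping_stone <- function(theta = 0.01, m = 10, n_demes = 5) {
  demes <- paste0("d", seq_len(n_demes))
  build_model("stepping_stone", demes, Theta = theta, M = m,
              neighbor_pairs = line_neighbors(demes))
}

# observed synthetic dataset summary under a model, via the infinite-sites
# engine (same statistic definitions as the ABC reference table)
observed_summary <- function(model, n_per_deme, L, seed,
                             deme_labels = NULL) {
  sizes <- setNames(rep(n_per_deme, length(model$demes)), model$demes)
  g <- simulate_genealogy(model, sizes, seed = seed)
  im <- infinite_sites_differences(g, rate = L)
  labels <- if (is.null(deme_labels)) g$tip_deme else deme_labels
  reefconnect:::summary_from_dm(im$d, labels, L)
}
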