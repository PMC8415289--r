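#' Unsigned Stirling numbers of the first kind, in log space
#'
#' Returns log |s(n, k)| for k = 1..n via the recurrence
#' |s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|, carried in log space so that
#' sample sizes typical of mtDNA surveys (n in the tens) do not overflow.
#'
#' @param n positive integer
#' @return numeric vector of length n: log |s(n, k)|
#' @export
log_stirling_first <- function(n) {
  stopifnot(n >= 1)
  row <- 0 # log|s(1,1)|
  if (n == 1) return(row)
  for (m in 2:n) {
    prev <- c(-Inf, row, -Inf)           # pad k-1 = 0 and k = m
    row <- vapply(seq_len(m), function(k) {
      logsumexp(c(prev[k], log(m - 1) + prev[k + 1]))
    }, numeric(1))
  }
  row
}

#' Ewens sampling distribution of the number of distinct haplotypes
#'
#' P(K = k | n, theta) = |s(n,k)| theta^k / (theta (theta+1) ... (theta+n-1))
#' for a neutral, non-recombining locus at mutation-scaled diversity theta.
#'
#' @param n sample size (>= 1)
#' @param theta positive scaled mutation parameter (per locus)
#' @return probability vector over k = 1..n (sums to 1 within 1e-12)
#' @export
ewens_k_distribution <- function(n, theta) {
  if (theta <= 0) stop("theta must be positive")
  stopifnot(n >= 1)
  ls <- log_stirling_first(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  p <- exp(lp - logsumexp(lp)) # renormalize away float drift
  p
}

# log P(K >= k_obs) under Ewens, for Fs; computed in log space
log_ewens_tail <- function(n, theta, k_obs) {
  ls <- log_stirling_first(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  lp <- lp - logsumexp(lp)
  logsumexp(lp[k_obs:n])
}

#' Fu's Fs for one population
#'
#' Fs = ln(S' / (1 - S')) with S' = P(K >= k_obs | theta_hat, n) under the
#' Ewens sampling distribution, theta_hat estimated as the mean number of
#' pairwise differences per locus (theta_pi). Strongly negative values mark
#' an excess of rare, recent haplotypes (demographic expansion or
#' hitchhiking). Undefined (NA, with attribute `reason`) when the sample is
#' monomorphic (k = 1) or theta_hat = 0.
#'
#' @param k_obs observed number of distinct haplotypes
#' @param n sample size
#' @param theta_hat mean pairwise differences per locus
#' @return Fs, or NA flagged with attribute `reason = "undefined"`
#' @export
fus_fs <- function(k_obs, n, theta_hat) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (k_obs == 1L || theta_hat <= 0) {
    return(structure(NA_real_, reason = "undefined"))
  }
  lS <- log_ewens_tail(n, theta_hat, k_obs)       # log S'
  l1mS <- log1p(-exp(lS))                         # log (1 - S')
  if (!is.finite(l1mS)) l1mS <- log(.Machine$double.xmin)
  lS - l1mS
}

#' Fu's Fs from a haplotype spectrum and difference matrix
#'
#' Convenience wrapper restricted to one population of a spectrum.
#' @param spec a [collapse_haplotypes()] spectrum for the population alone,
#'   or a count vector
#' @param dm a [pairwise_differences()] matrix for the same individuals
#' @return Fs as in [fus_fs()]
#' @export
fus_fs_from_data <- function(spec, dm) {
  counts <- if (inherits(spec, "haplotype_spectrum")) colSums(spec$counts) else spec
  counts <- counts[counts > 0]
  n <- sum(counts)
  theta_hat <- mean_pairwise_differences(dm)
  fus_fs(length(counts), n, theta_hat)
}

# theta_pi: mean pairwise differences per locus (not per site)
mean_pairwise_differences <- function(dm) {
  d <- dm$d
  n <- nrow(d)
  if (n < 2) return(0)
  sum(d[upper.tri(d)]) / choose(n, 2)
}

#' Significance of Fu's Fs by neutral coalescent simulation
#'
#' Simulates `nsim` neutral single-population coalescent datasets at the
#' observed theta_hat (infinite-sites mutation, same n), recomputes Fs for
#' each, and returns the lower-tail p-value with the add-one estimator
#' p = (1 + #\{Fs_sim <= Fs_obs\}) / (nsim + 1). The conventional
#' significance level for Fs is alpha = 0.02, reported alongside.
#'
#' @param observed_fs observed Fs
#' @param n sample size
#' @param theta_hat mean pairwise differences per locus
#' @param nsim number of neutral simulations (default 1000)
#' @param seed integer seed
#' @return list with `p_value`, `alpha` (0.02), `significant`, `nsim`
#' @export
fs_null_test <- function(observed_fs, n, theta_hat, nsim = 1000, seed = 1) {
  if (nsim < 1) stop("configuration error: nsim must be >= 1")
  if (is.na(observed_fs)) {
    return(list(p_value = NA_real_, alpha = 0.02, significant = NA, nsim = nsim))
  }
  ls <- log_stirling_first(n) # reused across simulations
  sims <- with_seed(seed, replicate(nsim, {
    sim <- sim_infinite_sites_single(n, theta_hat)
    fs_fast(sim$k, n, sim$theta_pi, ls)
  }))
  sims <- sims[!is.na(sims)]
  p <- (1 + sum(sims <= observed_fs)) / (nsim + 1)
  list(p_value = p, alpha = 0.02, significant = p < 0.02, nsim = nsim)
}

# Fs with a precomputed log-Stirling row (hot loop of fs_null_test).
# Monomorphic simulated datasets take the limiting value +Inf
# (S' = P(K >= 1) = 1), so they are never more extreme than a finite
# observed Fs in the lower-tail test.
fs_fast <- function(k_obs, n, theta_hat, ls) {
  if (k_obs == 1L || theta_hat <= 0) return(Inf)
  lp <- ls + seq_len(n) * log(theta_hat) - sum(log(theta_hat + 0:(n - 1)))
  lp <- lp - logsumexp(lp)
  lS <- logsumexp(lp[k_obs:n])
  l1mS <- log1p(-exp(lS))
  if (!is.finite(l1mS)) l1mS <- log(.Machine$double.xmin)
  lS - l1mS
}

# Single-population Kingman coalescent with infinite-sites mutation at
# per-locus theta; returns observed k and theta_pi without building
# sequences: each mutation is a fresh site, so haplotype identity and
# pairwise differences follow from mutation counts on the genealogy.
sim_infinite_sites_single <- function(n, theta) {
  g <- simulate_genealogy(build_model("panmixia", demes = "pop",
                                      Theta = theta),
                          sample_sizes = c(pop = n))
  im <- infinite_sites_differences(g)
  # under infinite sites, tips share a haplotype iff their distance is 0
  k <- length(unique(apply(im$d == 0, 1, function(r) which(r)[1])))
  list(k = k, theta_pi = sum(im$d[upper.tri(im$d)]) / choose(n, 2))
}
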