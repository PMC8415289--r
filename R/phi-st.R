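#' Pairwise PhiST from an AMOVA on molecular distances
#'
#' Two-level analysis of molecular variance with the raw pairwise
#' difference counts d_ij playing the role of squared distances:
#' SS_T = sum_\{i<j\} d_ij / N, SS_W summed within populations with the
#' analogous divisor, MS from the usual degrees of freedom, and
#' PhiST = sigma2_a / (sigma2_a + sigma2_w) with
#' sigma2_a = (MS_A - MS_W) / n' and n' = (N - sum n_p^2 / N) / (P - 1).
#' Negative estimates are returned as computed; zeroing is applied only in
#' display exports.
#'
#' @param dm a [pairwise_differences()] matrix (or any list with `d`)
#' @param pops factor/character of population labels, one per row of `d`
#' @return PhiST (may be negative; NA with attribute `reason` when the
#'   total variance is zero)
#' @export
phi_st <- function(dm, pops) {
  d <- dm$d
  pops <- as.factor(pops)
  N <- nrow(d)
  sizes <- table(pops)
  P <- length(sizes)
  if (P < 2) stop("need >= 2 populations")
  if (any(sizes < 2)) {
    stop("insufficient-sample error: every population needs >= 2 samples")
  }
  ss_t <- sum(d[upper.tri(d)]) / N
  ss_w <- 0
  for (p in levels(pops)) {
    idx <- which(pops == p)
    dp <- d[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(dp[upper.tri(dp)]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  ms_a <- ss_a / (P - 1)
  ms_w <- ss_w / (N - P)
  n_prime <- (N - sum(sizes^2) / N) / (P - 1)
  s2_w <- ms_w
  s2_a <- (ms_a - ms_w) / n_prime
  denom <- s2_a + s2_w
  if (denom == 0) return(structure(NA_real_, reason = "undefined"))
  s2_a / denom
}

#' PhiST permutation test
#'
#' Permutes individual-to-population labels holding sample sizes fixed;
#' p = (1 + #\{PhiST_perm >= PhiST_obs\}) / (nperm + 1).
#'
#' @inheritParams phi_st
#' @param nperm number of permutations (default 1000)
#' @param seed integer seed
#' @return list with `phi_st`, `p_value`, `n_permutations`
#' @export
phi_st_permutation <- function(dm, pops, nperm = 1000, seed = 1) {
  obs <- phi_st(dm, pops)
  if (is.na(obs)) {
    return(list(phi_st = obs, p_value = NA_real_, n_permutations = nperm))
  }
  pops <- as.factor(pops)
  n <- nrow(dm$d)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(nperm), function(i) {
      perm <- phi_st(dm, pops[sample.int(n)])
      !is.na(perm) && perm >= obs
    }, logical(1)))
  })
  list(phi_st = obs, p_value = (1 + exceed) / (nperm + 1),
       n_permutations = nperm)
}

#' All pairwise PhiST values with permutation p-values
#'
#' @param aln a [seq_alignment()]
#' @param pm a [population_map()]
#' @param nperm permutations per pair
#' @param seed integer seed (fans out per pair)
#' @param min_n smallest population size entering comparisons (default 2)
#' @return list with matrices `phi_st` (analytic, negatives retained),
#'   `phi_st_display` (negatives zeroed, as published matrices are shown),
#'   `p_value`, and `n_permutations`
#' @export
pairwise_phi_st_matrix <- function(aln, pm, nperm = 1000, seed = 1,
                                   min_n = 2) {
  pops <- pop_factor(aln, pm)
  dm <- pairwise_differences(aln)
  keep <- names(which(table(pops) >= min_n))
  if (length(keep) < 2) stop("need >= 2 populations with >= ", min_n,
                             " samples")
  P <- length(keep)
  phi <- p <- matrix(NA_real_, P, P, dimnames = list(keep, keep))
  diag(phi) <- 0
  for (a in seq_len(P - 1)) {
    for (b in (a + 1):P) {
      idx <- which(pops %in% c(keep[a], keep[b]))
      res <- phi_st_permutation(subset_dm(dm, idx), droplevels(pops[idx]),
                                nperm = nperm,
                                seed = derive_seed(seed,
                                  paste0("phi_perm_", keep[a], "_", keep[b])))
      phi[a, b] <- phi[b, a] <- res$phi_st
      p[a, b] <- p[b, a] <- res$p_value
    }
  }
  display <- phi
  display[!is.na(display) & display < 0] <- 0
  list(phi_st = phi, phi_st_display = display, p_value = p,
       n_permutations = nperm)
}
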