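#' Haplotype diversity (unbiased expected heterozygosity)
#'
#' h = (n / (n - 1)) (1 - sum p_i^2) over haplotype frequencies p_i.
#'
#' @param counts haplotype count vector
#' @param n sample size (defaults to sum of counts)
#' @return h in [0, 1]
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (n < 2) stop("insufficient-sample error: n must be >= 2")
  if (sum(counts) != n) stop("counts must sum to n")
  p <- counts / n
  h <- (n / (n - 1)) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

#' Nucleotide diversity (per site, pairwise deletion)
#'
#' Mean over all pairs of the per-pair proportion of differing sites among
#' jointly non-missing sites.
#'
#' @param dm a [pairwise_differences()] matrix
#' @return pi >= 0
#' @export
nucleotide_diversity <- function(dm) {
  n <- nrow(dm$d)
  if (n < 2) stop("need >= 2 sequences")
  ut <- upper.tri(dm$d)
  sc <- dm$sites_compared[ut]
  if (any(sc == 0)) {
    stop("incomparable-pair error: a pair shares no non-missing sites")
  }
  mean(dm$d[ut] / sc)
}

#' Per-population diversity summary
#'
#' One row per population: N, haplotype count, private haplotypes and
#' percentage, h, pi, theta_pi (mean pairwise differences per locus),
#' Fu's Fs and its simulation p-value.
#'
#' @param aln a [seq_alignment()]
#' @param pm a [population_map()]
#' @param nsim_fs neutral simulations for the Fs test (default 1000)
#' @param seed integer seed
#' @return data.frame, one row per population
#' @export
diversity_table <- function(aln, pm, nsim_fs = 1000, seed = 1) {
  spec <- collapse_haplotypes(aln, pm)
  pops <- pop_factor(aln, pm)
  dm <- pairwise_differences(aln)
  out <- lapply(levels(pops), function(p) {
    idx <- which(pops == p)
    n <- length(idx)
    counts <- spec$counts[p, ]
    k <- sum(counts > 0)
    priv <- private_haplotype_fraction(spec, p)
    sub <- subset_dm(dm, idx)
    if (n >= 2) {
      h <- haplotype_diversity(counts[counts > 0], n)
      pi <- nucleotide_diversity(sub)
      th <- mean_pairwise_differences(sub)
      fs <- fus_fs(k, n, th)
      fsp <- if (is.na(fs)) NA_real_ else {
        fs_null_test(fs, n, th, nsim = nsim_fs,
                     seed = derive_seed(seed, paste0("fs_null_", p)))$p_value
      }
    } else {
      h <- pi <- th <- fs <- fsp <- NA_real_
    }
    data.frame(population = p, N = n, n_haplotypes = k,
               private = priv$count, pct_private = priv$percent,
               h = h, pi = pi, theta_pi = th, Fs = as.numeric(fs),
               Fs_p = fsp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

subset_dm <- function(dm, idx) {
  structure(list(d = dm$d[idx, idx, drop = FALSE],
                 sites_compared = dm$sites_compared[idx, idx, drop = FALSE],
                 L = dm$L), class = "diff_matrix")
}

#' Two-sided t-test of a focal value against regional values
#'
#' One-sample t-test of the regional values with the focal population's
#' value as the null mean: is the focal reef's diversity atypical for its
#' region?
#'
#' @param focal_value the focal population's statistic
#' @param regional_values statistics of the comparison populations (>= 2,
#'   nonzero variance)
#' @return list with `t`, `df`, `p_value`
#' @export
region_comparison_ttest <- function(focal_value, regional_values) {
  m <- length(regional_values)
  if (m < 2) stop("need >= 2 regional values")
  if (var(regional_values) == 0) {
    return(list(t = NA_real_, df = m - 1, p_value = NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(regional_values, mu = focal_value)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}
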