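#' Summary-statistic vector for model choice
#'
#' Fixed-order vector: per-population haplotype diversity, per-site
#' nucleotide diversity and haplotype count, all pairwise PhiST values
#' (undefined imputed as 0 and flagged), and the global haplotype count.
#' Identical data give identical vectors.
#'
#' @param aln a [seq_alignment()]
#' @param pm a [population_map()]
#' @return named numeric vector with attributes `sizes` (per-population
#'   sample sizes) and `L` (alignment length)
#' @export
summarize_dataset <- function(aln, pm) {
  pops <- pop_factor(aln, pm)
  dm <- pairwise_differences(aln)
  summary_from_dm(dm$d, pops, aln$L)
}

# Core summary computation shared by observed data and the simulation
# reference table. Haplotype classes are zero-difference groups (identical
# to collapse_haplotypes when data are complete).
summary_from_dm <- function(d, pops, L) {
  pops <- as.factor(pops)
  n <- nrow(d)
  cls <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- match(TRUE, d[i, reps] == 0)
    if (is.na(hit)) { reps <- c(reps, i); hit <- length(reps) }
    cls[i] <- hit
  }
  lv <- levels(pops)
  nl <- length(lv)
  sizes <- tabulate(pops, nbins = nl)
  # block sums B[p, q] = sum of d over (i in p) x (j in q); diagonal blocks
  # double-count ordered pairs
  B <- rowsum(t(rowsum(d, pops)), pops)
  out <- c()
  flags <- character(0)
  for (a in seq_len(nl)) {
    idx <- which(as.integer(pops) == a)
    np <- sizes[a]
    counts <- tabulate(cls[idx])
    counts <- counts[counts > 0]
    h <- if (np >= 2) haplotype_diversity(counts, np) else 0
    pi <- if (np >= 2) B[a, a] / 2 / choose(np, 2) / L else 0
    out <- c(out, setNames(c(h, pi, length(counts)),
                           paste0(c("h_", "pi_", "k_"), lv[a])))
  }
  if (nl >= 2) {
    for (a in seq_len(nl - 1)) {
      for (b in (a + 1):nl) {
        nm <- paste0("phist_", lv[a], "_", lv[b])
        val <- if (sizes[a] >= 2 && sizes[b] >= 2) {
          phi_st_from_blocks(B[a, a] / 2, B[b, b] / 2, B[a, b],
                             sizes[a], sizes[b])
        } else NA_real_
        if (is.na(val)) { val <- 0; flags <- c(flags, nm) }
        out <- c(out, setNames(val, nm))
      }
    }
  }
  out <- c(out, k_global = length(reps))
  attr(out, "sizes") <- setNames(sizes, lv)
  attr(out, "L") <- L
  attr(out, "imputed") <- flags
  out
}

# two-population AMOVA PhiST from within-block (unordered-pair) and
# cross-block distance sums; algebraically identical to phi_st()
phi_st_from_blocks <- function(wa, wb, cross, na, nb) {
  N <- na + nb
  ss_t <- (wa + wb + cross) / N
  ss_w <- wa / na + wb / nb
  ss_a <- ss_t - ss_w
  ms_a <- ss_a                     # P - 1 = 1
  ms_w <- ss_w / (N - 2)
  n_prime <- (N - (na^2 + nb^2) / N)
  s2_w <- ms_w
  s2_a <- (ms_a - ms_w) / n_prime
  denom <- s2_a + s2_w
  if (denom == 0) return(NA_real_)
  s2_a / denom
}

#' Build the three candidate metapopulation templates
#'
#' @param populations population (deme) names of the sampled sites
#' @param neighbor_pairs stepping-stone neighbor pairs (default: the
#'   populations taken as a line in the given order)
#' @return named list of `metapop_model` templates (placeholder parameters;
#'   the ABC machinery overwrites Theta and M from the priors)
#' @export
model_templates <- function(populations,
                            neighbor_pairs = line_neighbors(populations)) {
  list(
    panmixia = build_model("panmixia", demes = "pooled", Theta = 0.01),
    island = build_model("island", demes = populations, Theta = 0.01, M = 1),
    stepping_stone = build_model("stepping_stone", demes = populations,
                                 Theta = 0.01, M = 1,
                                 neighbor_pairs = neighbor_pairs)
  )
}

# one reference-table simulation: summary vector under a template with
# Theta/m drawn from the priors; infinite-sites engine, strata = observed
# population labels
simulate_summary <- function(template, theta, m, sizes, L) {
  if (template$label == "panmixia") {
    model <- build_model("panmixia", demes = template$demes, Theta = theta)
    g <- simulate_genealogy(model,
                            setNames(sum(sizes), template$demes))
    strata <- rep(names(sizes), sizes)
  } else {
    model <- build_model(template$label, demes = template$demes,
                         Theta = theta, M = m,
                         neighbor_pairs = template$neighbor_pairs)
    g <- simulate_genealogy(model, setNames(as.integer(sizes), names(sizes)))
    strata <- g$tip_deme
  }
  im <- infinite_sites_differences(g, rate = L)
  summary_from_dm(im$d, strata, L)
}

#' Approximate Bayesian computation model choice
#'
#' Rejection ABC over the three-topology model space: parameters are drawn
#' from the windowed exponential priors, datasets simulated and summarized,
#' all statistics scaled by their median absolute deviation across the
#' pooled reference table, and the `accept_fraction` simulations closest to
#' the observed vector (Euclidean distance) are accepted. Per-model
#' acceptance rates at the common distance threshold serve as
#' marginal-likelihood proxies; probabilities, 2 ln Bayes factors and odds
#' follow from [bayes_factor_table()].
#'
#' @param observed a [summarize_dataset()] vector (carries sample sizes
#'   and L)
#' @param models list of three templates from [model_templates()]
#' @param priors a [prior_spec()]
#' @param nsim_per_model simulations per model (default 10000)
#' @param accept_fraction fraction of pooled simulations accepted
#'   (default 0.01)
#' @param seed integer seed
#' @return a `model_posterior` (see [bayes_factor_table()]) with extra
#'   fields `accepted` (counts per model), `n_accepted`, `threshold`
#' @export
abc_model_choice <- function(observed, models, priors,
                             nsim_per_model = 10000,
                             accept_fraction = 0.01, seed = 1) {
  if (nsim_per_model < 100) stop("nsim_per_model must be >= 100")
  if (accept_fraction <= 0 || accept_fraction > 1) {
    stop("accept_fraction must lie in (0, 1]")
  }
  sizes <- attr(observed, "sizes")
  L <- attr(observed, "L")
  if (is.null(sizes) || is.null(L)) {
    stop("observed must come from summarize_dataset()")
  }
  nm <- length(models)
  ref <- with_seed(seed, {
    draws <- sample_priors(priors, n = nsim_per_model * nm)
    mat <- matrix(NA_real_, nsim_per_model * nm, length(observed))
    lab <- character(nsim_per_model * nm)
    r <- 0L
    for (mi in seq_along(models)) {
      for (s in seq_len(nsim_per_model)) {
        r <- r + 1L
        sv <- simulate_summary(models[[mi]], draws$theta[r], draws$m[r],
                               sizes, L)
        mat[r, ] <- as.numeric(sv)
        lab[r] <- names(models)[mi]
      }
    }
    list(mat = mat, lab = lab)
  })
  scale <- apply(ref$mat, 2, mad)
  zero <- scale == 0
  scale[zero] <- apply(ref$mat[, zero, drop = FALSE], 2, sd)
  usable <- scale > 0
  z <- sweep(ref$mat[, usable, drop = FALSE], 2, scale[usable], "/")
  zo <- as.numeric(observed)[usable] / scale[usable]
  dist <- sqrt(rowSums(sweep(z, 2, zo, "-")^2))
  threshold <- quantile(dist, accept_fraction, names = FALSE)
  acc <- dist <= threshold
  counts <- vapply(names(models), function(m) sum(acc & ref$lab == m),
                   numeric(1))
  total <- sum(counts)
  flagged <- names(counts)[counts == 0]
  p <- counts / total
  p[counts == 0] <- 1 / (total + nm)  # probability floor, avoids -Inf
  p <- p / sum(p)
  # lnML proxies consistent with the floored shares: softmax recovers p
  lnml <- log(p * total / nsim_per_model)
  post <- bayes_factor_table(lnml)
  post$accepted <- counts
  post$n_accepted <- total
  post$threshold <- threshold
  post$floored <- flagged
  post
}

#' Bayes-factor arithmetic from log marginal likelihoods
#'
#' Relative model probabilities p_i = exp(lnML_i - max) / sum_j
#' exp(lnML_j - max); the antisymmetric matrix of 2 ln Bayes factors; and
#' the odds of the best over the second-best model.
#'
#' @param lnml named numeric vector of log marginal likelihoods (or
#'   proxies)
#' @return a `model_posterior`: list with `lnml`, `probabilities`,
#'   `two_ln_bf` (matrix), `best`, `second`, `two_ln_bf_best` (best vs
#'   second), `odds` (best:second), `support` (Kass-Raftery label)
#' @export
bayes_factor_table <- function(lnml) {
  stopifnot(all(is.finite(lnml)), length(lnml) >= 2)
  if (is.null(names(lnml))) names(lnml) <- paste0("model", seq_along(lnml))
  p <- exp(lnml - max(lnml))
  p <- p / sum(p)
  bf <- outer(lnml, lnml, function(a, b) 2 * (a - b))
  ord <- order(lnml, decreasing = TRUE)
  best <- names(lnml)[ord[1]]
  second <- names(lnml)[ord[2]]
  two_ln_bf <- 2 * (lnml[[best]] - lnml[[second]])
  structure(list(lnml = lnml, probabilities = p, two_ln_bf = bf,
                 best = best, second = second,
                 two_ln_bf_best = two_ln_bf,
                 odds = exp(lnml[[best]] - lnml[[second]]),
                 support = kass_raftery_label(two_ln_bf)),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("<model_posterior>\n")
  print(round(x$probabilities, 3))
  cat("best:", x$best, " 2lnBF:", signif(x$two_ln_bf_best, 4),
      " odds:", format_odds(x$odds), " support:", x$support, "\n")
  invisible(x)
}

#' Format odds as printed in model-comparison tables
#' @param odds numeric odds ratio
#' @return character like "11.6:1" or "1.78e+08:1"
#' @export
format_odds <- function(odds) {
  if (odds >= 1e4) paste0(format(odds, digits = 3, scientific = TRUE), ":1")
  else paste0(signif(odds, 3), ":1")
}

#' Kass-Raftery evidence label for a 2 ln Bayes factor
#'
#' Values above 6 mark strong support (odds > 20:1), above 3 substantial,
#' anything else weak.
#'
#' @param two_ln_bf numeric 2 ln Bayes factor
#' @return "strong", "substantial" or "weak"
#' @export
kass_raftery_label <- function(two_ln_bf) {
  stopifnot(is.finite(two_ln_bf))
  if (two_ln_bf > 6) "strong" else if (two_ln_bf > 3) "substantial" else "weak"
}

#' Permutation t-test over replicate marginal-likelihood estimates
#'
#' Exhaustively enumerates every relabeling of the pooled replicate values
#' into the two groups (C(6,3) = 20 for the standard 3 + 3 design) and
#' reports the one-tailed p-value: the proportion of relabelings whose
#' group-mean difference is at least the observed one (the observed
#' labeling counts, so the attainable floor for 3 + 3 is 0.05).
#'
#' @param lnml_model1 replicate values of the first-ranked model
#' @param lnml_model2 replicate values of the second-ranked model
#' @return list with `p_value`, `observed_diff`, `n_relabelings`
#' @export
replicate_support_test <- function(lnml_model1, lnml_model2) {
  m <- length(lnml_model1)
  k <- length(lnml_model2)
  if (m < 2 || k < 2) stop("insufficient-replicates error: need >= 2 per model")
  pooled <- c(lnml_model1, lnml_model2)
  obs <- mean(lnml_model1) - mean(lnml_model2)
  idx <- combn(m + k, m)
  diffs <- apply(idx, 2, function(sel) {
    mean(pooled[sel]) - mean(pooled[-sel])
  })
  list(p_value = mean(diffs >= obs - 1e-12),
       observed_diff = obs, n_relabelings = ncol(idx))
}
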