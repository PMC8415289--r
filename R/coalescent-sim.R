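#' Build a metapopulation model
#'
#' Three topologies of larval exchange are supported. `panmixia` is a single
#' deme; `island` has d equal-size demes exchanging migrants at one equal
#' rate between every ordered pair; `stepping_stone` allows migration only
#' between declared neighboring demes. Theta is the mutation-scaled
#' population size per deme (per locus, inheritance scalar absorbed) and M
#' the mutation-scaled backwards immigration rate m/mu: `M[i, j]` is the
#' rate at which a lineage currently in deme i jumps (backwards in time) to
#' deme j.
#'
#' @param label one of "panmixia", "island", "stepping_stone"
#' @param demes character vector of deme names (panmixia: exactly one)
#' @param Theta positive scalar (recycled) or per-deme vector
#' @param M scalar migration rate (island / stepping_stone) or full matrix
#' @param neighbor_pairs stepping-stone only: 2-column matrix or list of
#'   unordered deme-name pairs
#' @param inheritance_scalar carried as metadata (1 for haploid-maternal
#'   mtDNA in the time scaling used here)
#' @return a `metapop_model`
#' @export
build_model <- function(label = c("panmixia", "island", "stepping_stone"),
                        demes, Theta, M = NULL, neighbor_pairs = NULL,
                        inheritance_scalar = 1) {
  label <- match.arg(label)
  demes <- as.character(demes)
  d <- length(demes)
  if (anyDuplicated(demes)) stop("deme names must be unique")
  Theta <- rep_len(as.numeric(Theta), d)
  names(Theta) <- demes
  if (any(Theta <= 0)) stop("Theta must be positive")
  Mmat <- matrix(0, d, d, dimnames = list(demes, demes))
  if (label == "panmixia") {
    if (d != 1L) stop("panmixia has exactly one deme")
    if (!is.null(M) && any(M != 0)) stop("panmixia admits no migration rates")
    if (!is.null(neighbor_pairs)) stop("panmixia admits no neighbor pairs")
  } else if (label == "island") {
    if (d < 2L) stop("island model needs >= 2 demes")
    if (length(unique(Theta)) != 1L) {
      stop("invariant error: island model requires equal Theta across demes")
    }
    if (is.null(M) || length(M) != 1L || M <= 0) {
      stop("island model takes a single positive migration scalar")
    }
    Mmat[] <- M
    diag(Mmat) <- 0
  } else { # stepping_stone
    if (d < 2L) stop("stepping-stone model needs >= 2 demes")
    np <- normalize_pairs(neighbor_pairs, demes)
    if (nrow(np) == 0L) stop("stepping-stone model needs neighbor pairs")
    if (is.matrix(M)) {
      Mmat <- M
      dimnames(Mmat) <- list(demes, demes)
    } else {
      if (is.null(M) || length(M) != 1L || M <= 0) {
        stop("give a migration scalar or full matrix for stepping-stone")
      }
      for (r in seq_len(nrow(np))) {
        Mmat[np[r, 1], np[r, 2]] <- M
        Mmat[np[r, 2], np[r, 1]] <- M
      }
    }
    adj <- Mmat > 0
    want <- matrix(FALSE, d, d, dimnames = list(demes, demes))
    for (r in seq_len(nrow(np))) {
      want[np[r, 1], np[r, 2]] <- TRUE
      want[np[r, 2], np[r, 1]] <- TRUE
    }
    if (!identical(unname(adj), unname(want))) {
      stop("M[i,j] > 0 exactly for neighbor pairs is required")
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no != 1L) {
      stop("connectivity error: neighbor graph is disconnected")
    }
    neighbor_pairs <- np
  }
  if (any(diag(Mmat) != 0) || any(Mmat < 0)) stop("invalid migration matrix")
  structure(list(label = label, demes = demes, Theta = Theta, M = Mmat,
                 neighbor_pairs = neighbor_pairs,
                 inheritance_scalar = inheritance_scalar),
            class = "metapop_model")
}

normalize_pairs <- function(neighbor_pairs, demes) {
  if (is.null(neighbor_pairs)) return(matrix(character(0), 0, 2))
  if (is.list(neighbor_pairs)) {
    neighbor_pairs <- do.call(rbind, lapply(neighbor_pairs, as.character))
  }
  np <- matrix(as.character(neighbor_pairs), ncol = 2)
  if (!all(np %in% demes)) stop("neighbor pair names must be demes")
  if (any(np[, 1] == np[, 2])) stop("self-pairs are not neighbors")
  t(apply(np, 1, sort))
}

#' Demes of a linear (1-D stepping-stone) arrangement
#' @param demes ordered deme names along the line
#' @return 2-column matrix of adjacent pairs
#' @export
line_neighbors <- function(demes) {
  d <- length(demes)
  if (d < 2) stop("need >= 2 demes")
  cbind(demes[-d], demes[-1])
}

#' Simulate a structured-coalescent genealogy
#'
#' Backwards-time competing-exponentials simulation in the mutation time
#' scale (expected mutations per unit): with k_i lineages in deme i,
#' coalescence occurs at rate k_i (k_i - 1) / Theta_i, and each lineage in
#' i migrates backwards to deme j at rate `M[i, j]`. When the expected
#' number of migration events is astronomically large (draws near the top
#' of a migration prior), the process is exchanged for its strong-migration
#' limit: an unstructured coalescent with Theta_eff = d * mean(Theta).
#'
#' @param model a [build_model()] metapopulation model
#' @param sample_sizes named integer vector of tips per deme
#' @param seed optional integer seed (NULL: use current RNG state)
#' @param max_events guard against non-coalescing configurations
#' @param strong_migration_events expected-migration-event threshold above
#'   which the strong-migration limit is used
#' @return a `genealogy`: tip demes, merge table (child1, child2, parent,
#'   time), node times, migration events
#' @export
simulate_genealogy <- function(model, sample_sizes, seed = NULL,
                               max_events = 1e6,
                               strong_migration_events = 5e3) {
  run <- function() {
    sim_genealogy_impl(model, sample_sizes, max_events,
                       strong_migration_events)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

sim_genealogy_impl <- function(model, sample_sizes, max_events,
                               strong_migration_events) {
  demes <- model$demes
  if (is.null(names(sample_sizes))) {
    if (length(sample_sizes) != length(demes)) {
      stop("sample_sizes must be named or match deme count")
    }
    names(sample_sizes) <- demes
  } else {
    if (!all(names(sample_sizes) %in% demes)) {
      stop("sample_sizes names must be demes of the model")
    }
    full <- setNames(integer(length(demes)), demes)
    full[names(sample_sizes)] <- sample_sizes
    sample_sizes <- full
  }
  n <- sum(sample_sizes)
  if (n < 2) stop("need at least two sampled lineages")
  d <- length(demes)

  # strong-migration limit guard (see vignette): expected migration events
  # ~ mean positive M x total lineage length of the pooled coalescent
  if (d > 1) {
    mpos <- model$M[model$M > 0]
    if (length(mpos)) {
      theta_eff <- d * mean(model$Theta)
      exp_len <- theta_eff * (sum(1 / seq_len(max(n - 1, 1))) + d)
      if (mean(mpos) * exp_len > strong_migration_events) {
        pooled <- build_model("panmixia", demes = "pooled", Theta = theta_eff)
        g <- sim_genealogy_impl(pooled, c(pooled = n), max_events, Inf)
        g$tip_deme <- rep(demes, sample_sizes)
        g$tip_label <- make_tip_labels(sample_sizes)
        g$strong_migration_limit <- TRUE
        return(g)
      }
    }
  }

  tip_deme <- rep(seq_len(d), sample_sizes)
  lin_node <- seq_len(n)            # node id carried by each active lineage
  lin_deme <- tip_deme
  node_time <- numeric(2 * n - 1)
  merges <- matrix(0, n - 1, 4,
                   dimnames = list(NULL, c("child1", "child2", "parent", "time")))
  mig_rec <- matrix(0, 64, 4)
  n_mig <- 0L
  t <- 0
  next_node <- n + 0L
  n_merge <- 0L
  events <- 0L
  mig_out <- rowSums(model$M)          # per-lineage emigration rate by deme
  inv_theta <- 1 / model$Theta
  k <- tabulate(lin_deme, nbins = d)
  n_active <- n
  while (n_active > 1L) {
    events <- events + 1L
    if (events > max_events) {
      stop("non-coalescing error: event cap reached (disconnected demes?)")
    }
    coal_rate <- k * (k - 1) * inv_theta
    mig_rate <- k * mig_out
    total <- sum(coal_rate) + sum(mig_rate)
    if (total <= 0) {
      stop("non-coalescing error: no events possible with >1 lineage ",
           "(zero migration between occupied demes)")
    }
    t <- t + rexp(1, total)
    u <- runif(1) * total
    cum <- cumsum(c(coal_rate, mig_rate))
    ev <- findInterval(u, cum) + 1L
    if (ev <= d) {                          # coalescence in deme ev
      in_deme <- which(lin_deme[seq_len(n_active)] == ev)
      pair <- if (length(in_deme) == 2L) in_deme else sample(in_deme, 2L)
      next_node <- next_node + 1L
      n_merge <- n_merge + 1L
      merges[n_merge, 1] <- lin_node[pair[1]]
      merges[n_merge, 2] <- lin_node[pair[2]]
      merges[n_merge, 3] <- next_node
      merges[n_merge, 4] <- t
      node_time[next_node] <- t
      lin_node[pair[1]] <- next_node
      lin_node[pair[2]] <- lin_node[n_active]
      lin_deme[pair[2]] <- lin_deme[n_active]
      n_active <- n_active - 1L
      k[ev] <- k[ev] - 1L
    } else {                                # migration out of deme ev - d
      i <- ev - d
      in_deme <- which(lin_deme[seq_len(n_active)] == i)
      lin <- if (length(in_deme) == 1L) in_deme else sample(in_deme, 1L)
      rates <- model$M[i, ]
      j <- sample.int(d, 1L, prob = rates)
      n_mig <- n_mig + 1L
      if (n_mig > nrow(mig_rec)) {
        mig_rec <- rbind(mig_rec, matrix(0, nrow(mig_rec), 4))
      }
      mig_rec[n_mig, ] <- c(lin_node[lin], t, i, j)
      lin_deme[lin] <- j
      k[i] <- k[i] - 1L
      k[j] <- k[j] + 1L
    }
  }
  migrations <- if (n_mig > 0) {
    m <- as.data.frame(mig_rec[seq_len(n_mig), , drop = FALSE])
    names(m) <- c("lineage", "time", "from", "to")
    m
  } else NULL
  structure(list(n = n,
                 tip_deme = demes[tip_deme],
                 tip_label = make_tip_labels(sample_sizes),
                 merges = as.data.frame(merges),
                 node_time = node_time,
                 migrations = migrations,
                 strong_migration_limit = FALSE),
            class = "genealogy")
}

make_tip_labels <- function(sample_sizes) {
  unlist(lapply(names(sample_sizes), function(dm) {
    paste0(dm, "_", seq_len(sample_sizes[[dm]]))
  }), use.names = FALSE)
}

#' Convert a genealogy to an ape `phylo` tree
#' @param g a [simulate_genealogy()] genealogy
#' @return an `ape::phylo` with branch lengths in mutation time
#' @export
as_phylo_genealogy <- function(g) {
  n <- g$n
  # internal node i-th merge -> ape id: root (last merge) must be n+1
  remap <- integer(2 * n - 1)
  remap[seq_len(n)] <- seq_len(n)
  merge_nodes <- g$merges$parent                   # n+1 .. 2n-1 in order
  remap[merge_nodes] <- 2 * n - seq_len(n - 1)     # last merge -> n+1
  edge <- matrix(0L, 2 * (n - 1), 2)
  elen <- numeric(2 * (n - 1))
  r <- 0L
  for (i in seq_len(n - 1)) {
    for (child in c(g$merges$child1[i], g$merges$child2[i])) {
      r <- r + 1L
      edge[r, ] <- c(remap[g$merges$parent[i]], remap[child])
      elen[r] <- g$merges$time[i] - g$node_time[child]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = g$tip_label, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Expected pairwise coalescence time by first-step analysis
#'
#' Solves the exact linear system over the locations of two lineages: from
#' a same-deme state the pair coalesces at rate 2/Theta_i and either
#' lineage may migrate; from a split state only migration acts. Pairs that
#' can never reach a common deme (zero migration) are flagged infinite.
#'
#' @param model a [build_model()] model
#' @param deme_a,deme_b deme names of the two lineages
#' @return expected coalescence time in mutation units (Inf if unreachable)
#' @export
expected_pairwise_coalescence_time <- function(model, deme_a, deme_b) {
  d <- length(model$demes)
  ia <- match(deme_a, model$demes)
  ib <- match(deme_b, model$demes)
  if (is.na(ia) || is.na(ib)) stop("unknown deme")
  # unordered states (i <= j)
  states <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  sid <- function(i, j) which(states[, 1] == min(i, j) &
                              states[, 2] == max(i, j))
  ns <- nrow(states)
  A <- matrix(0, ns, ns)
  b <- numeric(ns)
  for (s in seq_len(ns)) {
    i <- states[s, 1]; j <- states[s, 2]
    coal <- if (i == j) 2 / model$Theta[i] else 0
    mig_i <- model$M[i, ]
    mig_j <- model$M[j, ]
    total <- coal + sum(mig_i) + sum(mig_j)
    if (total == 0) { A[s, s] <- 1; b[s] <- Inf; next }
    A[s, s] <- 1
    b[s] <- 1 / total
    for (k in seq_len(d)) {
      if (mig_i[k] > 0) {
        A[s, sid(k, j)] <- A[s, sid(k, j)] - mig_i[k] / total
      }
      if (mig_j[k] > 0) {
        A[s, sid(i, k)] <- A[s, sid(i, k)] - mig_j[k] / total
      }
    }
  }
  if (any(!is.finite(b))) {
    # reachability check: states that can never reach a same-deme state
    reach <- reachable_states(states, model)
    if (!reach[sid(ia, ib)]) return(Inf)
    keep <- reach & is.finite(b)
    sol <- rep(Inf, ns)
    sol[keep] <- solve(A[keep, keep, drop = FALSE], b[keep])
    return(unname(sol[sid(ia, ib)]))
  }
  unname(solve(A, b)[sid(ia, ib)])
}

reachable_states <- function(states, model) {
  d <- length(model$demes)
  ns <- nrow(states)
  adj <- matrix(FALSE, ns, ns)
  sid <- function(i, j) which(states[, 1] == min(i, j) &
                              states[, 2] == max(i, j))
  for (s in seq_len(ns)) {
    i <- states[s, 1]; j <- states[s, 2]
    for (k in seq_len(d)) {
      if (model$M[i, k] > 0) adj[s, sid(k, j)] <- TRUE
      if (model$M[j, k] > 0) adj[s, sid(i, k)] <- TRUE
    }
  }
  target <- states[, 1] == states[, 2]
  reach <- target
  repeat {
    new <- reach | apply(adj, 1, function(row) any(row & reach))
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

#' Expected pairwise coalescence times for a small lineage configuration
#'
#' Analytic oracle for the simulator: for every pair of sampled lineages in
#' the configuration, the expected time to their common ancestor from the
#' exact two-lineage first-step system (the marginal ancestral process of a
#' tagged pair does not depend on the other sampled lineages).
#'
#' @param model a [build_model()] model
#' @param config named integer vector of lineages per deme (total <= 4)
#' @return symmetric matrix of expected coalescence times, rows/cols
#'   labelled by lineage deme
#' @export
expected_coalescence_times <- function(model, config) {
  if (sum(config) > 4) stop("size error: configuration capped at 4 lineages")
  if (sum(config) < 2) stop("need at least two lineages")
  demes <- rep(names(config), config)
  n <- length(demes)
  out <- matrix(0, n, n, dimnames = list(demes, demes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <-
        expected_pairwise_coalescence_time(model, demes[i], demes[j])
    }
  }
  out
}

#' Pairwise differences under infinite-sites mutation on a genealogy
#'
#' Drops Poisson(branch length x rate) mutations on every branch; each
#' mutation hits a fresh site, so the difference count between two tips is
#' the number of mutations on the path joining them.
#'
#' @param g a [simulate_genealogy()] genealogy
#' @param rate mutations per unit time (use L for an L-site locus when
#'   Theta is per site; 1 when Theta is already per locus)
#' @return list with `d` (tip x tip difference counts) and `n_mutations`
#' @export
infinite_sites_differences <- function(g, rate = 1) {
  n <- g$n
  # edge list: child node and parent merge time, bottom-up
  child <- c(rbind(g$merges$child1, g$merges$child2))
  ptime <- rep(g$merges$time, each = 2)
  bl <- ptime - g$node_time[child]
  nm <- rpois(length(bl), bl * rate)
  hot <- which(nm > 0)
  d <- matrix(0, n, n, dimnames = list(g$tip_label, g$tip_label))
  if (length(hot)) {
    # X[e, i] = 1 if tip i descends through edge e; then the mutation
    # distance is d = A + t(A) with A = t(X * nm) (1 - X)
    desc <- matrix(FALSE, 2 * n - 1, n)
    desc[cbind(seq_len(n), seq_len(n))] <- TRUE
    for (i in seq_len(n - 1)) {
      desc[g$merges$parent[i], ] <- desc[g$merges$child1[i], ] |
        desc[g$merges$child2[i], ]
    }
    X <- desc[child[hot], , drop = FALSE] * 1
    Xw <- X * nm[hot]
    A <- crossprod(Xw, 1 - X)   # t(Xw) %*% (1 - X)
    d <- A + t(A)
    dimnames(d) <- list(g$tip_label, g$tip_label)
  }
  list(d = d, n_mutations = sum(nm))
}

#' HKY+G mutation model
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param base_freqs equilibrium frequencies (A, C, G, T), summing to 1
#' @param alpha gamma shape of among-site rate variation
#' @param n_categories discrete-gamma categories (default 4)
#' @return a `mutation_model`
#' @export
mutation_model <- function(kappa = 2, base_freqs = rep(0.25, 4),
                           alpha = 0.5, n_categories = 4) {
  stopifnot(kappa > 0, alpha > 0, n_categories >= 1,
            length(base_freqs) == 4)
  if (abs(sum(base_freqs) - 1) > 1e-12) stop("base_freqs must sum to 1")
  rates <- as.vector(phangorn::discrete.gamma(alpha, n_categories))
  structure(list(kappa = kappa, base_freqs = base_freqs, alpha = alpha,
                 n_categories = n_categories, category_rates = rates),
            class = "mutation_model")
}

#' Evolve sequences along a genealogy under HKY+G
#'
#' Sites are assigned to the equal-probability discrete-gamma categories and
#' each block evolves under the HKY model (transitions A<->G and C<->T at
#' kappa times the transversion rate) at its category rate, via
#' `phangorn::simSeq` on the genealogy tree.
#'
#' @param g a [simulate_genealogy()] genealogy
#' @param L sequence length (bp)
#' @param mm a [mutation_model()]
#' @param seed optional integer seed
#' @return a [seq_alignment()]; tips in deme order
#' @export
evolve_sequences <- function(g, L, mm, seed = NULL) {
  stopifnot(L > 0)
  run <- function() {
    tr <- as_phylo_genealogy(g)
    site_cat <- sample.int(mm$n_categories, L, replace = TRUE)
    Q <- c(1, mm$kappa, 1, 1, mm$kappa, 1)  # AC AG AT CG CT GT
    cols <- matrix("", length(g$tip_label), L)
    for (cat in seq_len(mm$n_categories)) {
      idx <- which(site_cat == cat)
      if (!length(idx)) next
      sim <- phangorn::simSeq(tr, l = length(idx), Q = Q,
                              bf = mm$base_freqs,
                              rate = mm$category_rates[cat], type = "DNA")
      chr <- toupper(as.character(sim))
      cols[, idx] <- chr[g$tip_label, , drop = FALSE]
    }
    seq_alignment(apply(cols, 1, paste, collapse = ""),
                  ids = g$tip_label, locus_name = "simulated")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete dataset under a metapopulation model
#'
#' Genealogy + HKY+G sequences + population map; deterministic under a
#' fixed seed.
#'
#' @inheritParams simulate_genealogy
#' @param L sequence length
#' @param mm a [mutation_model()]
#' @param seed integer seed
#' @return list with `aln` ([seq_alignment()]), `pm` ([population_map()])
#'   and `genealogy`
#' @export
simulate_dataset <- function(model, sample_sizes, L, mm, seed = 1) {
  g <- simulate_genealogy(model, sample_sizes,
                          seed = derive_seed(seed, "genealogy"))
  aln <- evolve_sequences(g, L, mm, seed = derive_seed(seed, "sequences"))
  pm <- population_map(g$tip_label, g$tip_deme)
  list(aln = aln, pm = pm, genealogy = g)
}

#' Prior specification for Theta and m/mu
#'
#' Windowed (truncated) exponential priors: the rate is fixed from the
#' stated pre-truncation mean and the distribution is restricted to
#' [lower, upper] by inverse-CDF sampling.
#'
#' @param theta_lower,theta_upper,theta_mean Theta window and mean
#' @param m_lower,m_upper,m_mean migration (m/mu) window and mean
#' @return a `prior_spec`
#' @export
prior_spec <- function(theta_lower = 1e-5, theta_upper = 1e-1,
                       theta_mean = 0.01,
                       m_lower = 1e-4, m_upper = 1e6, m_mean = 1e5) {
  stopifnot(theta_lower < theta_upper, m_lower < m_upper,
            theta_mean > theta_lower, theta_mean < theta_upper,
            m_mean > m_lower, m_mean < m_upper)
  structure(list(theta = c(lower = theta_lower, upper = theta_upper,
                           mean = theta_mean),
                 m = c(lower = m_lower, upper = m_upper, mean = m_mean)),
            class = "prior_spec")
}

# inverse-CDF draw from Exp(rate = 1/mean) truncated to [lower, upper]
rtrunc_exp <- function(n, lower, upper, mean) {
  Fl <- 1 - exp(-lower / mean)
  Fu <- 1 - exp(-upper / mean)
  u <- runif(n, Fl, Fu)
  -mean * log1p(-u)
}

#' Analytic mean of the truncated exponential prior
#' @param lower,upper truncation window
#' @param mean pre-truncation mean (rate = 1/mean)
#' @return mean of the truncated distribution
#' @export
truncated_exp_mean <- function(lower, upper, mean) {
  a <- lower / mean; b <- upper / mean
  mean * ((a + 1) * exp(-a) - (b + 1) * exp(-b)) / (exp(-a) - exp(-b))
}

#' Draw Theta and migration-rate values from the priors
#' @param ps a [prior_spec()]
#' @param seed optional integer seed
#' @param n number of draws
#' @return data.frame with columns `theta` and `m`
#' @export
sample_priors <- function(ps, seed = NULL, n = 1) {
  run <- function() {
    data.frame(theta = rtrunc_exp(n, ps$theta["lower"], ps$theta["upper"],
                                  ps$theta["mean"]),
               m = rtrunc_exp(n, ps$m["lower"], ps$m["upper"], ps$m["mean"]))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Export a genealogy as Newick
#' @param g a [simulate_genealogy()] genealogy
#' @param path optional file; migration events appended as `#` comment lines
#' @return the Newick string, invisibly if written to file
#' @export
genealogy_newick <- function(g, path = NULL) {
  nw <- ape::write.tree(as_phylo_genealogy(g))
  if (is.null(path)) return(nw)
  lines <- nw
  if (!is.null(g$migrations)) {
    lines <- c(lines, apply(g$migrations, 1, function(r) {
      sprintf("# migration lineage=%d time=%g from=%d to=%d",
              r[["lineage"]], r[["time"]], r[["from"]], r[["to"]])
    }))
  }
  writeLines(lines, path)
  invisible(nw)
}
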