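test_that("model construction enforces topology invariants", {
  expect_s3_class(build_model("panmixia", "p", Theta = 0.01), "metapop_model")
  expect_error(build_model("panmixia", c("a", "b"), Theta = 0.01),
               "exactly one")
  expect_error(build_model("panmixia", "p", Theta = 0.01, M = 1),
               "no migration")
  m <- build_model("island", paste0("d", 1:5), Theta = 0.01, M = 0.5)
  expect_equal(sum(m$M > 0), 20)
  expect_equal(unique(m$M[upper.tri(m$M)]), 0.5)
  expect_error(build_model("island", c("a", "b"), Theta = c(1, 2), M = 1),
               "equal Theta")
  demes <- paste0("d", 1:5)
  ss <- build_model("stepping_stone", demes, Theta = 0.01, M = 2,
                    neighbor_pairs = line_neighbors(demes))
  expect_equal(nrow(ss$neighbor_pairs), 4)
  expect_equal(sum(ss$M > 0), 8)
  expect_error(
    build_model("stepping_stone", demes, Theta = 0.01, M = 2,
                neighbor_pairs = rbind(c("d1", "d2"), c("d3", "d4"),
                                       c("d4", "d5"))),
    "disconnected")
})

test_that("genealogies have n-1 coalescences and positive branch lengths", {
  for (seed in 1:5) {
    g <- simulate_genealogy(strong_stepping_stone(),
                            setNames(c(3, 2, 4, 2, 3), paste0("d", 1:5)),
                            seed = seed)
    n <- g$n
    expect_equal(nrow(g$merges), n - 1)
    expect_true(all(diff(g$merges$time) >= 0))
    tr <- as_phylo_genealogy(g)
    expect_true(ape::is.binary(tr))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_true(all(tr$edge.length >= 0))
    expect_gt(sum(tr$edge.length), 0)
  }
})

test_that("zero migration between occupied demes fails to coalesce", {
  demes <- c("a", "b")
  M <- matrix(0, 2, 2)
  m <- build_model("island", demes, Theta = 0.01, M = 1)
  m$M[] <- 0   # sever migration after construction
  expect_error(simulate_genealogy(m, c(a = 2, b = 2), seed = 1),
               "non-coalescing")
})

test_that("pairwise coalescence times match closed forms and oracles", {
  # single deme: E[T2] = Theta / 2 exactly from the oracle
  m <- build_model("panmixia", "p", Theta = 0.03)
  expect_equal(expected_pairwise_coalescence_time(m, "p", "p"), 0.015)
  # disconnected pair flagged infinite
  demes <- c("a", "b")
  m2 <- build_model("island", demes, Theta = 0.02, M = 1)
  m2$M[] <- 0
  expect_equal(expected_pairwise_coalescence_time(m2, "a", "b"), Inf)
  # two demes symmetric: hand-solved 2-state system
  # states: together (T), apart (A). E_T = 1/(2/th + 2m) + 2m/(2/th+2m) E_A
  #         E_A = 1/(2m) + E_T
  th <- 0.02; mig <- 3
  m3 <- build_model("island", demes, Theta = th, M = mig)
  rT <- 2 / th + 2 * mig
  eT <- (1 / rT + (2 * mig / rT) * (1 / (2 * mig))) / (1 - 2 * mig / rT)
  eA <- 1 / (2 * mig) + eT
  expect_equal(expected_pairwise_coalescence_time(m3, "a", "a"), eT,
               tolerance = 1e-12)
  expect_equal(expected_pairwise_coalescence_time(m3, "a", "b"), eA,
               tolerance = 1e-12)
  # configuration wrapper
  cfg <- expected_coalescence_times(m3, c(a = 1, b = 1))
  expect_equal(cfg[1, 2], eA, tolerance = 1e-12)
  expect_error(expected_coalescence_times(m3, c(a = 3, b = 2)), "size error")
})

test_that("simulated mean coalescence times match the analytic system", {
  nrep <- 1500
  m <- build_model("panmixia", "p", Theta = 0.05)
  set.seed(2)
  t_pan <- replicate(nrep, simulate_genealogy(m, c(p = 2))$merges$time[1])
  expect_lt(abs(mean(t_pan) - 0.025), 3 * sd(t_pan) / sqrt(nrep))

  m2 <- build_model("island", c("a", "b"), Theta = 0.02, M = 3)
  want <- expected_pairwise_coalescence_time(m2, "a", "b")
  set.seed(3)
  t_ab <- replicate(nrep, simulate_genealogy(m2, c(a = 1, b = 1))$merges$time[1])
  expect_lt(abs(mean(t_ab) - want), 3 * sd(t_ab) / sqrt(nrep))
})

test_that("very fast migration behaves as panmixia with pooled Theta", {
  demes <- c("a", "b")
  m <- build_model("island", demes, Theta = 0.02, M = 1e7)
  g <- simulate_genealogy(m, c(a = 1, b = 1), seed = 4)
  expect_true(g$strong_migration_limit)
  # analytic: strong-migration limit is Theta_eff = 2 * 0.02
  set.seed(5)
  tt <- replicate(1500, simulate_genealogy(m, c(a = 1, b = 1))$merges$time[1])
  expect_lt(abs(mean(tt) - 0.02), 3 * sd(tt) / sqrt(1500))
  # the exact system agrees in the limit
  expect_equal(expected_pairwise_coalescence_time(
    build_model("island", demes, Theta = 0.02, M = 1e5), "a", "b"),
    0.02, tolerance = 1e-3)
})

test_that("infinite-sites differences have the right expectation", {
  # n=2 panmixia: E[d] = 2 E[T] rate = Theta x rate
  m <- build_model("panmixia", "p", Theta = 0.05)
  set.seed(6)
  d12 <- replicate(2000, {
    g <- simulate_genealogy(m, c(p = 2))
    infinite_sites_differences(g, rate = 100)$d[1, 2]
  })
  expect_lt(abs(mean(d12) - 5), 3 * sd(d12) / sqrt(2000))
})

test_that("sequence evolution responds to branch lengths and kappa", {
  mm <- mutation_model(kappa = 4, alpha = 0.6)
  expect_equal(length(mm$category_rates), 4)
  expect_equal(mean(mm$category_rates), 1, tolerance = 1e-6)
  # zero branch lengths: all tips identical to each other
  g <- simulate_genealogy(build_model("panmixia", "p", Theta = 1e-8),
                          c(p = 4), seed = 7)
  aln <- evolve_sequences(g, 200, mm, seed = 8)
  expect_true(all(apply(aln$seq, 2, function(col) length(unique(col)) == 1)))
  # fraction of variable sites grows with tree depth
  frac_var <- vapply(c(0.001, 0.01, 0.1), function(th) {
    g <- simulate_genealogy(build_model("panmixia", "p", Theta = th),
                            c(p = 6), seed = 11)
    a <- evolve_sequences(g, 400, mm, seed = 12)
    mean(apply(a$seq, 2, function(col) length(unique(col)) > 1))
  }, numeric(1))
  expect_true(all(diff(frac_var) > 0))
})

test_that("transition:transversion events approach kappa:2 on one branch", {
  # two tips joined by a deep root: count substitution types between them
  kappa <- 4
  mm <- mutation_model(kappa = kappa, alpha = 1000, n_categories = 1)
  g <- simulate_genealogy(build_model("panmixia", "p", Theta = 0.02),
                          c(p = 2), seed = 13)
  # short branches so multiple hits are rare; pool many loci
  g$merges$time <- 0.02
  g$node_time[3] <- 0.02
  set.seed(14)
  ts <- tv <- 0
  for (i in 1:40) {
    a <- evolve_sequences(g, 2000, mm)
    s <- a$seq
    diffp <- which(s[1, ] != s[2, ])
    pair <- paste0(pmin(s[1, diffp], s[2, diffp]),
                   pmax(s[1, diffp], s[2, diffp]))
    ts <- ts + sum(pair %in% c("AG", "CT"))
    tv <- tv + sum(!pair %in% c("AG", "CT"))
  }
  ratio <- ts / tv
  expect_gt(ratio, kappa / 2 * 0.8)
  expect_lt(ratio, kappa / 2 * 1.25)
})

test_that("simulate_dataset is deterministic under a fixed seed", {
  mm <- mutation_model()
  m <- strong_stepping_stone(n_demes = 3)
  s1 <- simulate_dataset(m, c(d1 = 4, d2 = 4, d3 = 4), 100, mm, seed = 9)
  s2 <- simulate_dataset(m, c(d1 = 4, d2 = 4, d3 = 4), 100, mm, seed = 9)
  expect_identical(s1$aln$seq, s2$aln$seq)
  expect_identical(s1$pm$population, s2$pm$population)
  s3 <- simulate_dataset(m, c(d1 = 4, d2 = 4, d3 = 4), 100, mm, seed = 10)
  expect_false(identical(s1$aln$seq, s3$aln$seq))
})

test_that("prior draws respect the window and the truncated mean", {
  ps <- prior_spec()
  dr <- sample_priors(ps, seed = 15, n = 1e5)
  expect_true(all(dr$theta >= 1e-5 & dr$theta <= 1e-1))
  expect_true(all(dr$m >= 1e-4 & dr$m <= 1e6))
  want_theta <- truncated_exp_mean(1e-5, 1e-1, 0.01)
  want_m <- truncated_exp_mean(1e-4, 1e6, 1e5)
  expect_lt(abs(mean(dr$theta) - want_theta) / want_theta, 0.02)
  expect_lt(abs(mean(dr$m) - want_m) / want_m, 0.02)
  # truncation window bounds the analytic mean
  expect_gt(want_theta, 1e-5)
  expect_lt(want_theta, 1e-1)
})

test_that("stepping-stone end demes are more differentiated than neighbors", {
  m <- strong_stepping_stone(theta = 0.01, m = 5)
  set.seed(16)
  phis <- replicate(25, {
    g <- simulate_genealogy(m, setNames(rep(8, 5), paste0("d", 1:5)))
    im <- infinite_sites_differences(g, rate = 500)
    s <- reefconnect:::summary_from_dm(im$d, g$tip_deme, 500)
    c(adj = unname(s["phist_d1_d2"]), end = unname(s["phist_d1_d5"]))
  })
  expect_gt(mean(phis["end", ]), mean(phis["adj", ]))
})

test_that("newick export round-trips through ape", {
  g <- simulate_genealogy(strong_stepping_stone(n_demes = 3),
                          c(d1 = 2, d2 = 2, d3 = 2), seed = 17)
  nw <- genealogy_newick(g)
  tr <- ape::read.tree(text = nw)
  expect_setequal(tr$tip.label, g$tip_label)
  path <- withr::local_tempfile(fileext = ".nwk")
  genealogy_newick(g, path)
  expect_true(file.exists(path))
})
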