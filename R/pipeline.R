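#' Assemble a run configuration
#'
#' One object drives the multi-species pipeline. Each species entry gives
#' either in-memory data (`aln`, `pm`) or file paths (`alignment_path`,
#' `population_map_path`), optional `neighbor_pairs` for its
#' stepping-stone template, and `pld_days` for the graph stage.
#'
#' @param species named list of per-species entries
#' @param nperm PhiST permutations (default 1000)
#' @param nsim_fs Fs null simulations (default 1000)
#' @param nsim_per_model ABC simulations per model (default 10000)
#' @param accept_fraction ABC acceptance fraction (default 0.01)
#' @param min_area_ha minimum reef patch area (default 25)
#' @param current_speed mean current speed km/day (default 18.7)
#' @param land_cost land traversal cost (default 10000)
#' @param seed master seed; every stage derives a named child stream
#' @return a `run_config`
#' @export
run_config <- function(species, nperm = 1000, nsim_fs = 1000,
                       nsim_per_model = 10000, accept_fraction = 0.01,
                       min_area_ha = 25, current_speed = 18.7,
                       land_cost = 10000, seed = 1) {
  stopifnot(length(species) >= 1, !is.null(names(species)),
            nperm >= 1, nsim_fs >= 1, nsim_per_model >= 100,
            accept_fraction > 0, accept_fraction <= 1,
            min_area_ha > 0, current_speed > 0, land_cost >= 1)
  for (nm in names(species)) {
    sp <- species[[nm]]
    if (!is.null(sp$alignment_path) && !file.exists(sp$alignment_path)) {
      stop("missing alignment for ", nm, ": ", sp$alignment_path)
    }
    if (!is.null(sp$population_map_path) &&
        !file.exists(sp$population_map_path)) {
      stop("missing population map for ", nm)
    }
  }
  structure(list(species = species, nperm = nperm, nsim_fs = nsim_fs,
                 nsim_per_model = nsim_per_model,
                 accept_fraction = accept_fraction,
                 min_area_ha = min_area_ha, current_speed = current_speed,
                 land_cost = land_cost, seed = seed),
            class = "run_config")
}

load_species_data <- function(sp) {
  aln <- if (!is.null(sp$aln)) sp$aln else read_alignment(sp$alignment_path)
  pm <- if (!is.null(sp$pm)) sp$pm else
    read_population_map(sp$population_map_path)
  list(aln = aln, pm = pm)
}

# run a per-species stage, quarantining failures so one bad dataset does
# not abort the multi-species run
per_species <- function(config, f) {
  out <- list()
  for (nm in names(config$species)) {
    res <- tryCatch(f(nm, config$species[[nm]]), error = function(e) {
      warning("species ", nm, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[nm]] <- res
  }
  out
}

#' Per-population diversity report across species
#'
#' One row per population per species: sample size, haplotype counts,
#' private haplotypes, h, pi, Fu's Fs with its simulation p-value, plus
#' regional means and the focal-vs-region two-sided t-test p-values when a
#' `focal` population is named in the species entry.
#'
#' @param config a [run_config()]
#' @return data.frame
#' @export
run_stats <- function(config) {
  blocks <- per_species(config, function(nm, sp) {
    dat <- load_species_data(sp)
    tab <- diversity_table(dat$aln, dat$pm, nsim_fs = config$nsim_fs,
                           seed = derive_seed(config$seed,
                                              paste0("stats_", nm)))
    tab <- cbind(species = nm, tab)
    if (!is.null(sp$focal) && sp$focal %in% tab$population) {
      reg <- tab[tab$population != sp$focal, ]
      foc <- tab[tab$population == sp$focal, ]
      tab$regional_mean_h <- mean(reg$h, na.rm = TRUE)
      tab$regional_mean_pi <- mean(reg$pi, na.rm = TRUE)
      tab$p_h_vs_region <-
        region_comparison_ttest(foc$h, reg$h)$p_value
      tab$p_pi_vs_region <-
        region_comparison_ttest(foc$pi, reg$pi)$p_value
    }
    tab
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Metapopulation model selection report across species
#'
#' For each species, runs the ABC model choice `n_replicates` times with
#' independent seeds (replicate marginal-likelihood proxies), averages the
#' proxies, derives probabilities / 2 ln Bayes factors / odds, and runs
#' the exhaustive permutation t-test comparing the replicate proxies of the
#' top two models.
#'
#' @param config a [run_config()]
#' @param n_replicates independent ABC replicates (default 3)
#' @param priors a [prior_spec()]
#' @return data.frame, one row per species
#' @export
run_model_selection <- function(config, n_replicates = 3,
                                priors = prior_spec()) {
  blocks <- per_species(config, function(nm, sp) {
    dat <- load_species_data(sp)
    obs <- summarize_dataset(dat$aln, dat$pm)
    pops <- sort(unique(dat$pm$population))
    templates <- model_templates(
      pops,
      neighbor_pairs = if (!is.null(sp$neighbor_pairs)) sp$neighbor_pairs
                       else line_neighbors(pops))
    reps <- lapply(seq_len(n_replicates), function(r) {
      abc_model_choice(obs, templates, priors,
                       nsim_per_model = config$nsim_per_model,
                       accept_fraction = config$accept_fraction,
                       seed = derive_seed(config$seed,
                                          paste0("abc_", nm, "_", r)))
    })
    lnml <- do.call(rbind, lapply(reps, function(x) x$lnml))
    post <- bayes_factor_table(colMeans(lnml))
    ptest <- replicate_support_test(lnml[, post$best], lnml[, post$second])
    data.frame(species = nm,
               model_1 = post$best,
               prob_1 = unname(post$probabilities[post$best]),
               model_2 = post$second,
               prob_2 = unname(post$probabilities[post$second]),
               replicate_p = ptest$p_value,
               two_ln_bf = post$two_ln_bf_best,
               odds = format_odds(post$odds),
               support = post$support,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Reef-graph connectivity report across species
#'
#' Shares one seascape (`raster` entry of the config species list or a
#' common `raster` argument): extracts patches once, computes the
#' least-cost linkset once, then thresholds per species by
#' D_max = PLD x current speed.
#'
#' @param config a [run_config()]
#' @param raster a [reef_raster()] (required unless every species entry
#'   carries one)
#' @param focal_patch patch id ranked in the report (default: none)
#' @return list with `patches`, `linkset`, and `report` (one row per
#'   species: D_max, nodes, edges, diameter, disconnection flag, focal
#'   rank)
#' @export
run_graph <- function(config, raster = NULL, focal_patch = NULL) {
  if (is.null(raster)) stop("config error: no raster supplied")
  ps <- extract_patches(raster, min_area_ha = config$min_area_ha)
  if (nrow(ps) == 0) stop("config error: seascape contains no patches")
  ls <- least_cost_linkset(ps, raster)
  rows <- per_species(config, function(nm, sp) {
    if (is.null(sp$pld_days)) stop("species entry lacks pld_days")
    sg <- build_species_graph(ls, sp$pld_days,
                              current_speed = config$current_speed)
    di <- graph_diameter(sg)
    data.frame(species = nm, pld_days = sp$pld_days,
               d_max_km = sg$d_max_km,
               n_patches = nrow(ps),
               n_edges = igraph::ecount(sg$graph),
               diameter = di$diameter,
               disconnected = di$disconnected,
               focal_rank = if (!is.null(focal_patch)) {
                 rank_focal_patch(sg, focal_patch)
               } else NA_integer_,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(patches = ps, linkset = ls, report = report)
}

#' PLD logistic regression over a model-selection report
#'
#' Codes stepping-stone outcomes as 1 and regresses on maximum PLD (plus
#' any further covariates given), with backward BIC selection when more
#' than one covariate is offered.
#'
#' @param report data.frame with columns `model_1` and `pld_days` (e.g.
#'   [run_model_selection()] joined to species PLDs)
#' @param covariates character vector of covariate columns
#'   (default "pld_days")
#' @return a `logistic_fit`
#' @export
run_pld_regression <- function(report, covariates = "pld_days") {
  y <- as.integer(report$model_1 == "stepping_stone")
  X <- report[, covariates, drop = FALSE]
  if (length(covariates) > 1) backward_bic(y, X) else fit_logistic(y, X)
}
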