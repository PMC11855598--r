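#' Simulation study of end-to-end clonal-reconstruction accuracy
#'
#' For each seed, simulates the reference polygenomic patient
#' ([patient1_config()]), runs CCF estimation, cluster inference, cluster
#' filtering, clone-tree construction, and seeding inference, and scores the
#' result against the simulation truth: the adjusted Rand index between
#' inferred and true mutation clusters, and whether every metastasis was
#' assigned its true seeding primary population.
#'
#' @param seeds integer vector of simulation seeds (default 1:20).
#' @param depth_mean mean sequencing depth (default 150).
#' @param k_max maximum cluster count for model selection (default 8).
#' @return data frame with one row per seed: `seed`, `k`, `ari`,
#'   `seeding_correct` (logical), `n_unplaced` (clusters that could not be
#'   attached to the clone tree).
#' @export
run_recovery_study <- function(seeds = 1:20, depth_mean = 150, k_max = 8) {
  rows <- lapply(seeds, function(s) {
    cfg <- patient1_config(seed = s, depth_mean = depth_mean)
    sim <- simulate_patient(cfg)
    ct <- ccf_table(sim$variants, sim$purity_postsort)
    cl <- cluster_ccfs(ct, sim$purity_postsort, k_max = k_max,
                       seed = derive_seed(s, 1))
    ari <- mclust::adjustedRandIndex(cl$assignment[names(sim$truth$cluster)],
                                     sim$truth$cluster)
    clf <- filter_clusters(cl)
    site <- stats::setNames(cfg$populations$site, cfg$populations$id)
    cors <- cn_correlation_matrix(sim$cn_profiles)
    # a degenerate reconstruction for one replicate counts as a miss,
    # it does not abort the study
    res <- tryCatch({
      tree <- build_clone_tree(clf)
      sd_res <- infer_seeding(clf, site, cors$r)
      assigned <- stats::setNames(sd_res$primary, sd_res$metastasis)
      ok <- !is.null(sim$truth$seeding) &&
        all(assigned[names(sim$truth$seeding)] == sim$truth$seeding)
      list(ok = ok, n_unplaced = length(tree$unplaced))
    }, error = function(e) list(ok = FALSE, n_unplaced = NA_integer_))
    data.frame(seed = s, k = cl$k, ari = ari, seeding_correct = res$ok,
               n_unplaced = res$n_unplaced)
  })
  do.call(rbind, rows)
}

#' Coverage study of the CCF confidence interval
#'
#' Simulates independent mutation sites with CCFs drawn uniformly, binomial
#' read sampling at the given depth, and checks how often the 95% interval
#' of [ccf_interval()] (computed with the true multiplicity) contains the
#' true CCF.
#'
#' @param n_sites number of simulated sites (default 2000).
#' @param depth sequencing depth per site (default 150).
#' @param purity tumor purity (default 0.9).
#' @param cn_t tumor copy number (default 2).
#' @param seed integer seed.
#' @return empirical coverage fraction.
#' @export
ccf_interval_coverage <- function(n_sites = 2000, depth = 150, purity = 0.9,
                                  cn_t = 2, seed = 1) {
  set.seed(as.integer(seed))
  ccf_true <- stats::runif(n_sites, 0.1, 1)
  v <- expected_vaf(ccf_true, purity, cn_t, 2, 1)
  alt <- stats::rbinom(n_sites, depth, v)
  ci <- ccf_interval(alt, depth, purity, cn_t, 2, 1)
  mean(ci[, "lo"] <= ccf_true & ccf_true <= ci[, "hi"])
}
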