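# small helper: long count table from a true cluster CCF matrix
sim_counts <- function(ccf_mat, sizes, purity, depth = 150, seed = 1) {
  set.seed(seed)
  pops <- colnames(ccf_mat)
  cluster_of <- rep(seq_len(nrow(ccf_mat)), sizes)
  ids <- sprintf("m%04d", seq_along(cluster_of))
  rows <- do.call(rbind, lapply(pops, function(p) {
    v <- expected_vaf(ccf_mat[cluster_of, p], purity[[p]], 2, 2, 1)
    d <- pmax(rpois(length(ids), depth), 1)
    data.frame(variant_id = ids, population = p,
               alt = rbinom(length(ids), d, v), depth = d,
               cn_t = 2, m = 1L, cluster = cluster_of)
  }))
  rows
}

test_that("a purely truncal patient collapses to a single clonal cluster", {
  purity <- c(A = 0.9, B = 0.9)
  ccf <- matrix(1, 1, 2, dimnames = list(NULL, names(purity)))
  counts <- sim_counts(ccf, 120, purity, seed = 2)
  cl <- cluster_ccfs(counts, purity, k_max = 4, seed = 5)
  expect_equal(cl$k, 1L)
  expect_true(all(cl$ccf > 0.97))
})

test_that("two well-separated clusters are found and preferred by BIC", {
  purity <- c(A = 0.95, B = 0.95)
  ccf <- matrix(c(1, 1, 0.3, 1), 2, 2, byrow = TRUE,
                dimnames = list(NULL, names(purity)))
  counts <- sim_counts(ccf, c(200, 200), purity, seed = 3)
  cl <- cluster_ccfs(counts, purity, k_max = 4, seed = 7)
  expect_equal(cl$k, 2L)
  expect_lt(cl$bic$bic[2], cl$bic$bic[1])
  ari <- mclust::adjustedRandIndex(
    cl$assignment, rep(1:2, each = 200))
  expect_gt(ari, 0.95)
})

test_that("clustering is deterministic under a fixed seed and EM ascends", {
  purity <- c(A = 0.9, B = 0.9)
  ccf <- matrix(c(1, 1, 0.4, 0.1), 2, 2, byrow = TRUE,
                dimnames = list(NULL, names(purity)))
  counts <- sim_counts(ccf, c(80, 80), purity, seed = 4)
  cl1 <- cluster_ccfs(counts, purity, k_max = 3, seed = 11)
  cl2 <- cluster_ccfs(counts, purity, k_max = 3, seed = 11)
  expect_identical(cl1$assignment, cl2$assignment)
  expect_identical(cl1$ccf, cl2$ccf)

  # log-likelihood is non-decreasing along the EM iterations
  ids <- unique(counts$variant_id)
  A <- matrix(counts$alt, ncol = 2); D <- matrix(counts$depth, ncol = 2)
  Cf <- matrix(0.5, nrow(A), 2)
  fit <- clonesort:::em_binomial_mixture(A, D, Cf, 2,
                                         matrix(c(0.9, 0.9, 0.2, 0.2), 2, 2))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("small clusters are discarded with mutation conservation", {
  ccf <- matrix(c(1, 1, 0.8, 0.2, 0.5, 0.1), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  cl <- fake_clusters(ccf, c(298, 199, 4))
  total <- length(cl$assignment)
  fl <- filter_clusters(cl, min_size = 5)
  expect_equal(nrow(fl$ccf), 2)
  expect_equal(sum(is.na(fl$assignment)), 4)
  expect_equal(sum(!is.na(fl$assignment)) + sum(is.na(fl$assignment)), total)
  # boundary: exactly 5 is kept
  cl5 <- fake_clusters(ccf, c(50, 30, 5))
  expect_equal(nrow(filter_clusters(cl5, 5)$ccf), 3)
})

test_that("clone tree attaches children to minimum containing supersets", {
  ccf <- matrix(c(1, 1, 0.4, 0), 2, 2, byrow = TRUE,
                dimnames = list(1:2, c("A", "B")))
  tree <- build_clone_tree(fake_clusters(ccf, c(100, 40)))
  expect_equal(tree$root, 1L)
  expect_equal(tree$edges$parent, 1L)
  expect_equal(tree$edges$child, 2L)

  # chain only when containment holds in every population: cluster 3 fits
  # under 2 in A but not in B, so both attach to the root
  ccf3 <- matrix(c(1, 1, 0.6, 0.2, 0.5, 0.6), 3, 2, byrow = TRUE,
                 dimnames = list(1:3, c("A", "B")))
  tree3 <- build_clone_tree(fake_clusters(ccf3, c(100, 50, 50)))
  expect_equal(sort(tree3$edges$child), c(2L, 3L))
  expect_equal(tree3$edges$parent, c(1L, 1L))
  # sum rule violation: both children hang off the root and jointly exceed
  # its CCF in population A (0.6 + 0.55 > 1 + tol)
  ccf4 <- matrix(c(1, 1, 0.7, 0.1, 0.5, 0.95), 3, 2, byrow = TRUE,
                 dimnames = list(1:3, c("A", "B")))
  tree4 <- build_clone_tree(fake_clusters(ccf4, c(100, 50, 50)))
  expect_false(is.null(tree4$sum_rule_violations))

  expect_error(build_clone_tree(fake_clusters(
    matrix(c(0.5, 0.5), 1, 2, dimnames = list(1, c("A", "B"))), 10)),
    "no truncal")
})

test_that("clone tree serializes to labelled Newick", {
  ccf <- matrix(c(1, 1, 0.4, 0), 2, 2, byrow = TRUE,
                dimnames = list(1:2, c("A", "B")))
  tree <- build_clone_tree(fake_clusters(ccf, c(100, 40)))
  nwk <- clone_tree_newick(tree)
  expect_match(nwk, "^\\(cluster2:40\\)cluster1:100;$")
})

test_that("seeding uses exclusive cluster sharing with correlation tiebreak", {
  pops <- c("PST1", "PST2", "MT1", "MT2")
  ccf <- matrix(c(1, 1, 1, 1,
                  1, 0, 0, 1,
                  0.5, 0, 0, 0.4,
                  0.3, 0, 0, 0.6,
                  0, 0.8, 0.7, 0), 5, 4, byrow = TRUE,
                dimnames = list(1:5, pops))
  site <- c(PST1 = "primary", PST2 = "primary",
            MT1 = "metastasis", MT2 = "metastasis")
  res <- infer_seeding(ccf, site)
  expect_equal(res$primary[res$metastasis == "MT2"], "PST1")
  expect_equal(res$n_exclusive[res$metastasis == "MT2"], 3L)
  expect_equal(res$primary[res$metastasis == "MT1"], "PST2")

  # truncal-only metastasis resolved by CNV correlation
  ccf2 <- ccf[1, , drop = FALSE]
  cors <- matrix(c(1, 0.5, 0.66, 0.99,
                   0.5, 1, 0.99, 0.66,
                   0.66, 0.99, 1, 0.2,
                   0.99, 0.66, 0.2, 1), 4, 4, dimnames = list(pops, pops))
  res2 <- infer_seeding(ccf2, site, cn_cor = cors)
  expect_equal(res2$primary[res2$metastasis == "MT1"], "PST2")
  expect_equal(res2$tiebreak[res2$metastasis == "MT1"], "cn_correlation")
  # without a correlation matrix the call is flagged unresolved
  res3 <- infer_seeding(ccf2, site)
  expect_true(all(res3$tiebreak == "unresolved"))
  # a single primary takes every metastasis
  site1 <- c(PST1 = "primary", PST2 = "metastasis",
             MT1 = "metastasis", MT2 = "metastasis")
  res4 <- infer_seeding(ccf, site1)
  expect_true(all(res4$primary == "PST1"))
})

test_that("ccf_trace yields flat truncal series and zero-touching absent bands", {
  purity <- c(A = 0.9, B = 0.9)
  ccf <- matrix(c(1, 1, 0.6, 0), 2, 2, byrow = TRUE,
                dimnames = list(NULL, names(purity)))
  counts <- sim_counts(ccf, c(150, 80), purity, seed = 6)
  cl <- cluster_ccfs(counts, purity, k_max = 3, seed = 9)
  tr <- ccf_trace(cl, c("B", "A"))
  expect_equal(levels(tr$population), c("B", "A"))
  trunk <- tr[tr$cluster == 1, ]
  expect_true(all(trunk$ccf_mean > 0.95))
  absent <- tr[tr$cluster == 2 & tr$population == "B", ]
  expect_lt(absent$ccf_mean, 0.05)
  expect_lt(absent$lo, 0.01)
})
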