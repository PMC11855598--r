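logsumexp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}

# k-means++-style seeding of K cluster centers from rows of X
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (K > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1, prob = p)
      centers[k, ] <- X[i, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

# EM for a K-component binomial mixture over per-population read counts.
# A, D: n x P alt and total depth; Cf: n x P linear CCF->VAF coefficients.
em_binomial_mixture <- function(A, D, Cf, K, phi0, max_iter = 200, tol = 1e-8) {
  n <- nrow(A); P <- ncol(A)
  eps <- 1e-4
  phi <- pmin(pmax(phi0, eps), 1)
  pi_k <- rep(1 / K, K)
  DC <- D * Cf
  lchoose_const <- sum(lchoose(D, A))
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll_ik <- matrix(0, n, K)
    for (k in seq_len(K)) {
      V <- Cf * matrix(phi[k, ], n, P, byrow = TRUE)
      V <- pmin(pmax(V, 1e-9), 1 - 1e-9)
      ll_ik[, k] <- rowSums(A * log(V) + (D - A) * log1p(-V))
    }
    lw <- sweep(ll_ik, 2, log(pi_k), "+")
    lse <- logsumexp(lw)
    ll <- sum(lse) + lchoose_const
    r <- exp(lw - lse)
    # M-step: moment update of phi (exact MLE when Cf is column-constant)
    for (k in seq_len(K)) {
      num <- colSums(r[, k] * A)
      den <- colSums(r[, k] * DC)
      phi[k, ] <- pmin(pmax(ifelse(den > 0, num / den, eps), eps), 1)
    }
    pi_k <- pmax(colMeans(r), 1e-9)
    pi_k <- pi_k / sum(pi_k)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(phi = phi, pi = pi_k, loglik = ll, resp = r,
       assignment = max.col(r, ties.method = "first"),
       loglik_trace = trace)
}

#' Cluster mutations by their multi-population CCF profiles
#'
#' Fits finite binomial-mixture models to the per-population read counts:
#' component k has a CCF vector over populations, mapped to an expected VAF
#' per mutation through the purity/copy-number/multiplicity coefficient of
#' [expected_vaf()]. For each K in `1..k_max` the EM is restarted
#' `n_restarts` times from k-means++-style draws on the per-mutation CCF
#' point estimates (seeded, hence deterministic), the best likelihood is
#' kept, and K is selected by BIC. Clusters are relabeled in order of
#' decreasing total CCF, so cluster 1 is the truncal cluster.
#'
#' @param counts long-format data frame with columns `variant_id`,
#'   `population`, `alt`, `depth`, `cn_t`, `m` (e.g. from [ccf_table()]);
#'   every mutation must be observed (possibly with 0 alt reads) in every
#'   population.
#' @param purity named per-population purity vector.
#' @param k_max largest number of clusters considered (>= 1).
#' @param seed integer seed controlling the restarts.
#' @param n_restarts EM restarts per K (default 20).
#' @return object of class `mutation_clusters`: list with `assignment`
#'   (named by `variant_id`), `ccf` (K x P cluster CCF matrix), `size`,
#'   `summary` (long data frame with pooled 95% bands per cluster and
#'   population), `k`, `loglik`, `bic` (per-K table).
#' @export
cluster_ccfs <- function(counts, purity, k_max = 8, seed = 1,
                         n_restarts = 20) {
  if (k_max < 1) stop("k_max must be >= 1")
  need <- c("variant_id", "population", "alt", "depth", "cn_t", "m")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  pops <- sort(unique(as.character(counts$population)))
  if (!all(pops %in% names(purity))) stop("purity missing for some populations")
  ids <- unique(counts$variant_id)
  n <- length(ids); P <- length(pops)
  idx <- cbind(match(counts$variant_id, ids),
               match(as.character(counts$population), pops))
  A <- D <- Cf <- matrix(NA_real_, n, P, dimnames = list(ids, pops))
  A[idx] <- counts$alt
  D[idx] <- counts$depth
  p_vec <- purity[pops]
  pur <- matrix(p_vec, n, P, byrow = TRUE)
  cn_n <- counts$cn_n %||% rep(2, nrow(counts))
  Cf[idx] <- counts$m * pur[idx] / (pur[idx] * counts$cn_t + (1 - pur[idx]) * cn_n)
  if (any(is.na(A))) {
    stop("every mutation must be observed in every population of the patient")
  }
  D <- pmax(D, 1)
  X <- pmin(ifelse(D > 0, A / D, 0) / Cf, 1.2)  # CCF point estimates for init

  set.seed(as.integer(seed))
  fits <- vector("list", k_max)
  bic <- numeric(k_max)
  for (K in seq_len(k_max)) {
    # short EM runs from each restart, then the best one run to convergence
    best <- NULL
    reps <- if (K == 1) 1 else n_restarts
    for (r in seq_len(reps)) {
      phi0 <- pmin(pmax(kmeanspp_centers(X, K), 0), 1)
      fit <- em_binomial_mixture(A, D, Cf, K, phi0, max_iter = 15)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best <- em_binomial_mixture(A, D, Cf, K, best$phi, max_iter = 300)
    fits[[K]] <- best
    bic[K] <- -2 * best$loglik + (K * P + (K - 1)) * log(n)
  }
  k_hat <- which.min(bic)
  fit <- fits[[k_hat]]

  ord <- order(-rowSums(fit$phi), -tabulate(fit$assignment, k_hat))
  relabel <- match(seq_len(k_hat), ord)
  assignment <- relabel[fit$assignment]
  names(assignment) <- ids
  phi <- fit$phi[ord, , drop = FALSE]
  rownames(phi) <- seq_len(k_hat)
  colnames(phi) <- pops
  size <- tabulate(assignment, k_hat)

  summary <- do.call(rbind, lapply(seq_len(k_hat), function(k) {
    mem <- assignment == k
    do.call(rbind, lapply(seq_len(P), function(p) {
      band <- pooled_ccf_band(A[mem, p], D[mem, p], Cf[mem, p])
      data.frame(cluster = k, population = pops[p], size = sum(mem),
                 ccf_mean = min(phi[k, p], 1),
                 lo = band[1], hi = band[2])
    }))
  }))

  structure(list(assignment = assignment, ccf = pmin(phi, 1), size = size,
                 summary = summary, k = k_hat, loglik = fit$loglik,
                 bic = data.frame(k = seq_len(k_max), bic = bic),
                 populations = pops),
            class = "mutation_clusters")
}

# pooled Jeffreys band on the cluster-level CCF in one population
pooled_ccf_band <- function(a, d, cf) {
  sa <- sum(a); sd_ <- sum(d)
  if (sd_ == 0 || length(a) == 0) return(c(0, 0))
  ji <- jeffreys_interval(sa, sd_)
  cbar <- sum(d * cf) / sd_
  pmin(pmax(as.numeric(ji) / cbar, 0), 1)
}

#' Discard small mutation clusters
#'
#' Clusters with fewer than `min_size` mutations are removed and their
#' mutations marked unassigned (`NA`); remaining clusters keep their labels.
#'
#' @param clusters a `mutation_clusters` object.
#' @param min_size minimum cluster size (default 5; a cluster of exactly 5
#'   is kept).
#' @return the filtered `mutation_clusters` object.
#' @export
filter_clusters <- function(clusters, min_size = 5) {
  stopifnot(inherits(clusters, "mutation_clusters"))
  drop <- which(clusters$size < min_size)
  if (length(drop)) {
    clusters$assignment[clusters$assignment %in% drop] <- NA_integer_
    keep <- setdiff(seq_along(clusters$size), drop)
    clusters$ccf <- clusters$ccf[keep, , drop = FALSE]
    clusters$size <- clusters$size[keep]
    clusters$summary <- clusters$summary[clusters$summary$cluster %in% keep, ]
    clusters$dropped <- drop
  }
  clusters
}

#' Build a clone tree from mutation clusters
#'
#' Arranges clusters into a rooted tree under the containment (pigeonhole)
#' rules: the root is the single cluster clonal in every population; the
#' parent of every other cluster is its minimum containing superset — the
#' cluster with the smallest total CCF whose CCF is at least the child's in
#' every population (within `tol`). After attachment the sum rule is
#' checked: in every population the children of a node may not jointly
#' exceed its CCF by more than `tol`; violations are reported, and clusters
#' with no containing cluster are flagged as unplaced rather than forced.
#'
#' @param clusters a `mutation_clusters` object (typically after
#'   [filter_clusters()]), or a numeric cluster-by-population CCF matrix.
#' @param tol containment tolerance on CCFs (default 0.05 absolute).
#' @return object of class `clone_tree`: list with `edges` (data frame
#'   `parent`, `child`, `n_mutations`), `root`, `ccf`, `size`,
#'   `unplaced` (cluster ids), `sum_rule_violations` (data frame).
#' @export
build_clone_tree <- function(clusters, tol = 0.05) {
  if (inherits(clusters, "mutation_clusters")) {
    ccf <- clusters$ccf
    size <- clusters$size
  } else {
    ccf <- as.matrix(clusters)
    size <- rep(NA_integer_, nrow(ccf))
  }
  k <- nrow(ccf)
  labs <- as.integer(rownames(ccf) %||% seq_len(k))
  is_root <- apply(ccf >= 1 - tol, 1, all)
  if (sum(is_root) == 0L) stop("no truncal cluster (no cluster clonal in all populations)")
  cand <- which(is_root)
  # several near-clonal clusters (e.g. an over-split trunk): the one with the
  # highest total CCF roots the tree and the others attach by containment
  root <- cand[order(-rowSums(ccf)[cand], -ifelse(is.na(size[cand]), 0,
                                                  size[cand]), cand)][1]

  parent <- rep(NA_integer_, k)
  unplaced <- integer(0)
  for (i in seq_len(k)) {
    if (i == root) next
    contains <- vapply(seq_len(k), function(j) {
      j != i && all(ccf[i, ] <= ccf[j, ] + tol)
    }, logical(1))
    cand <- which(contains)
    if (length(cand) == 0L) { unplaced <- c(unplaced, i); next }
    parent[i] <- cand[order(rowSums(ccf)[cand], cand)][1]
  }
  # guard against containment cycles among near-identical clusters
  for (i in seq_len(k)) {
    j <- parent[i]; seen <- i
    while (!is.na(j)) {
      if (j %in% seen) { parent[i] <- root; break }
      seen <- c(seen, j); j <- parent[j]
    }
  }

  viol <- list()
  for (j in seq_len(k)) {
    ch <- which(parent == j)
    if (!length(ch)) next
    over <- colSums(ccf[ch, , drop = FALSE]) - ccf[j, ] - tol
    bad <- which(over > 0)
    for (p in bad) {
      viol[[length(viol) + 1L]] <- data.frame(
        parent = labs[j], population = colnames(ccf)[p],
        children_sum = sum(ccf[ch, p]), parent_ccf = ccf[j, p])
    }
  }
  edges <- data.frame(parent = labs[parent[!is.na(parent)]],
                      child = labs[which(!is.na(parent))],
                      n_mutations = size[which(!is.na(parent))])
  structure(list(edges = edges, root = labs[root], ccf = ccf, size = size,
                 unplaced = labs[unplaced],
                 sum_rule_violations = if (length(viol)) do.call(rbind, viol)
                                       else NULL),
            class = "clone_tree")
}

#' Newick serialization of a clone tree
#'
#' @param tree a `clone_tree`.
#' @return single Newick string; node labels are cluster ids, branch lengths
#'   the number of mutations of the child cluster.
#' @export
clone_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  rec <- function(node) {
    ch <- tree$edges$child[tree$edges$parent == node]
    len <- tree$size[match(node, as.integer(rownames(tree$ccf)))]
    len <- if (is.na(len)) 0 else len
    lab <- paste0("cluster", node, ":", len)
    if (!length(ch)) return(lab)
    paste0("(", paste(vapply(sort(ch), rec, character(1)), collapse = ","),
           ")", lab)
  }
  paste0(rec(tree$root), ";")
}

#' Infer which primary population seeded each metastasis
#'
#' For every metastatic population M, each primary population P is scored by
#' the number of clusters present (CCF above `threshold`) in both M and P
#' while absent from every other primary — exclusively shared clusters. The
#' highest-scoring primary is assigned; ties or zero evidence fall back to
#' the highest copy-number profile correlation when one is supplied, and are
#' otherwise flagged unresolved.
#'
#' @param clusters `mutation_clusters` object or cluster-by-population CCF
#'   matrix.
#' @param site named character vector over populations, `"primary"` or
#'   `"metastasis"`.
#' @param cn_cor optional population-by-population correlation matrix
#'   (from [cn_correlation_matrix()]) used as tiebreak.
#' @param threshold presence threshold on cluster CCF (default 0.1,
#'   exclusive).
#' @return data frame, one row per metastasis: `metastasis`, `primary`
#'   (`NA` when unresolved), `n_exclusive`, `clusters` (comma-separated ids
#'   of the exclusively shared clusters), `tiebreak` (`"none"`,
#'   `"cn_correlation"`, or `"unresolved"`).
#' @export
infer_seeding <- function(clusters, site, cn_cor = NULL, threshold = 0.1) {
  ccf <- if (inherits(clusters, "mutation_clusters")) clusters$ccf
         else as.matrix(clusters)
  pops <- colnames(ccf)
  if (!all(pops %in% names(site))) stop("site label missing for some populations")
  site <- site[pops]
  prim <- pops[site == "primary"]
  mets <- pops[site == "metastasis"]
  if (!length(prim)) stop("at least one primary population is required")
  labs <- as.integer(rownames(ccf) %||% seq_len(nrow(ccf)))
  pres <- ccf > threshold

  out <- lapply(mets, function(M) {
    scores <- vapply(prim, function(P) {
      other <- setdiff(prim, P)
      sum(pres[, M] & pres[, P] &
            (if (length(other)) rowSums(pres[, other, drop = FALSE]) == 0 else TRUE))
    }, numeric(1))
    top <- which(scores == max(scores))
    tiebreak <- "none"
    if (length(prim) == 1L) {
      pick <- 1L
    } else if (length(top) == 1L && max(scores) > 0) {
      pick <- top
    } else if (!is.null(cn_cor)) {
      cand <- if (max(scores) > 0) prim[top] else prim
      pick <- match(cand[which.max(cn_cor[M, cand])], prim)
      tiebreak <- "cn_correlation"
    } else {
      pick <- NA_integer_
      tiebreak <- "unresolved"
    }
    best <- if (is.na(pick)) NA_character_ else prim[pick]
    excl <- if (!is.na(pick)) {
      other <- setdiff(prim, best)
      labs[pres[, M] & pres[, best] &
             (if (length(other)) rowSums(pres[, other, drop = FALSE]) == 0 else TRUE)]
    } else integer(0)
    data.frame(metastasis = M, primary = best,
               n_exclusive = if (is.na(pick)) 0L else length(excl),
               clusters = paste(excl, collapse = ","), tiebreak = tiebreak)
  })
  do.call(rbind, out)
}

#' CCF trace table for plotting cluster trajectories
#'
#' Orders the per-cluster, per-population CCF summary (means with pooled 95%
#' bands) along a given population order, ready for a trace/ribbon plot.
#'
#' @param clusters a `mutation_clusters` object.
#' @param population_order character vector giving the x-axis order;
#'   defaults to the clusters' population order.
#' @return data frame with columns `cluster`, `population` (ordered factor),
#'   `ccf_mean`, `lo`, `hi`, `size`.
#' @export
ccf_trace <- function(clusters, population_order = NULL) {
  stopifnot(inherits(clusters, "mutation_clusters"))
  s <- clusters$summary
  population_order <- population_order %||% clusters$populations
  if (!all(s$population %in% population_order)) {
    stop("population_order must cover all populations")
  }
  s$population <- factor(s$population, levels = population_order, ordered = TRUE)
  s[order(s$cluster, s$population), c("cluster", "population", "ccf_mean",
                                      "lo", "hi", "size")]
}
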