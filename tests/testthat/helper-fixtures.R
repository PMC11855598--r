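# shared fixtures and independent oracles, built in code at test time

# random binary presence matrix with no all-zero rows
random_presence_matrix <- function(n_mut, n_pop) {
  mat <- matrix(rbinom(n_mut * n_pop, 1, 0.45), n_mut, n_pop,
                dimnames = list(NULL, LETTERS[seq_len(n_pop)]))
  for (i in which(rowSums(mat) == 0)) mat[i, sample.int(n_pop, 1)] <- 1L
  mat
}

# independent small-parsimony oracle: enumerate every assignment of 0/1 to
# internal nodes and count state changes over edges; min over all topologies
brute_force_parsimony <- function(mat, outgroup_label = "germline") {
  taxa <- c(colnames(mat), outgroup_label)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  states <- rbind(t(mat), matrix(0L, 1, nrow(mat)))
  rownames(states) <- taxa
  best <- Inf
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]  # [[ reattaches tip labels on a compressed multiPhylo
    n_tip <- length(tr$tip.label)
    n_int <- tr$Nnode
    asg <- as.matrix(expand.grid(rep(list(0:1), n_int)))
    total <- 0
    for (j in seq_len(ncol(states))) {
      leaf_states <- states[tr$tip.label, j]
      S <- cbind(matrix(leaf_states, nrow(asg), n_tip, byrow = TRUE), asg)
      changes <- rowSums(sapply(seq_len(nrow(tr$edge)), function(e) {
        S[, tr$edge[e, 1]] != S[, tr$edge[e, 2]]
      }))
      total <- total + min(changes)
    }
    best <- min(best, total)
  }
  best
}

# long-format variant table with per-population binomial read sampling
toy_variant_table <- function(n_var = 50, pops = c("A", "B"), vaf = 0.25,
                              depth = 80, patient = "pt1") {
  rows <- expand.grid(variant_id = sprintf("v%03d", seq_len(n_var)),
                      population = pops, stringsAsFactors = FALSE)
  rows$patient <- patient
  rows$depth <- rpois(nrow(rows), depth)
  rows$alt <- rbinom(nrow(rows), rows$depth, vaf)
  rows
}

# minimal mutation_clusters object for tree/filter tests
fake_clusters <- function(ccf, size) {
  k <- nrow(ccf)
  rownames(ccf) <- seq_len(k)
  assignment <- rep(seq_len(k), size)
  names(assignment) <- sprintf("m%04d", seq_along(assignment))
  structure(list(assignment = assignment, ccf = ccf, size = size,
                 summary = NULL, k = k, populations = colnames(ccf)),
            class = "mutation_clusters")
}
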