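check_presence_matrix <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("presence matrix needs >= 2 populations")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("pop", seq_len(ncol(mat)))
  if (!all(mat %in% c(0, 1))) stop("presence matrix entries must be 0/1")
  if (any(rowSums(mat) == 0)) stop("all-zero mutation rows must be removed first")
  storage.mode(mat) <- "integer"
  mat
}

#' Maximum-parsimony tree from a binary presence/absence matrix
#'
#' Exhaustively enumerates every unrooted binary topology on the populations
#' plus an all-zero germline outgroup, scores each with Fitch small
#' parsimony over the mutation columns, and roots the minimum-score tree at
#' the outgroup. Among equally parsimonious topologies all are returned and
#' the one with the lexicographically smallest Newick string is selected as
#' primary. Branch lengths of the primary tree are mutation counts: each
#' homoplasy-free mutation (per-site score 1) is assigned to the branch
#' subtending exactly the populations that carry it.
#'
#' The number of topologies grows as (2L-5)!! in the leaf count L, so the
#' search is capped at 10 populations.
#'
#' @param mat binary matrix, rows = mutations, columns = populations.
#' @param outgroup_label tip label for the germline outgroup
#'   (default `"germline"`).
#' @return list with `tree` (rooted `phylo`, branch lengths = mutation
#'   counts), `score` (minimum parsimony score), `all_trees` (`multiPhylo`
#'   of all minimum-score rooted topologies), `branch_counts` (data frame:
#'   edge id, subtended populations, mutation count), and `n_homoplasic`
#'   (mutations needing more than one state change, left unassigned).
#' @export
max_parsimony_tree <- function(mat, outgroup_label = "germline") {
  mat <- check_presence_matrix(mat)
  n_pop <- ncol(mat)
  if (n_pop > 10L) {
    stop("more than 10 populations: exhaustive search infeasible; ",
         "a heuristic mode is not implemented")
  }
  taxa <- c(colnames(mat), outgroup_label)
  aln <- rbind(t(mat), matrix(0L, 1, nrow(mat),
                              dimnames = list(outgroup_label, NULL)))
  dat <- phangorn::phyDat(aln, type = "USER", levels = c(0L, 1L))

  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  # index via [[ so the multiPhylo tip labels are reattached to each tree
  scores <- vapply(seq_along(trees),
                   function(i) phangorn::fitch(trees[[i]], dat), numeric(1))
  best_idx <- which(scores == min(scores))

  rooted <- lapply(best_idx, function(i) {
    tr <- ape::root(trees[[i]], outgroup = outgroup_label, resolve.root = TRUE)
    ape::ladderize(tr)
  })
  nwk <- vapply(rooted, function(tr) ape::write.tree(tr), character(1))
  ord <- order(nwk)
  rooted <- rooted[ord]
  primary <- rooted[[1]]

  counts <- branch_mutation_counts(primary, mat, dat, outgroup_label)
  primary$edge.length <- counts$count[match(seq_len(nrow(primary$edge)),
                                            counts$edge)]
  primary$edge.length[is.na(primary$edge.length)] <- 0

  all_trees <- rooted
  class(all_trees) <- "multiPhylo"
  list(tree = primary, score = unname(min(scores)), all_trees = all_trees,
       branch_counts = counts$table,
       n_homoplasic = counts$n_homoplasic)
}

# assign homoplasy-free mutations to the branch subtending their carriers
branch_mutation_counts <- function(tree, mat, dat, outgroup_label) {
  site_scores <- phangorn::fitch(tree, dat, site = "site")
  site_scores <- site_scores[attr(dat, "index")]

  edge <- tree$edge
  tips <- tree$tip.label
  n_tip <- length(tips)
  # leafset below each edge (below = child node side)
  desc <- rep(list(character(0)), max(edge))
  for (i in seq_len(n_tip)) desc[[i]] <- tips[i]
  for (e in ape::postorder(tree)) {
    ch <- edge[e, 2]; pa <- edge[e, 1]
    desc[[pa]] <- c(desc[[pa]], desc[[ch]])
  }
  edge_key <- vapply(seq_len(nrow(edge)), function(e) {
    s <- setdiff(desc[[edge[e, 2]]], outgroup_label)
    paste(sort(s), collapse = "|")
  }, character(1))

  carrier_key <- vapply(seq_len(nrow(mat)), function(i) {
    paste(sort(colnames(mat)[mat[i, ] == 1]), collapse = "|")
  }, character(1))

  assigned <- ifelse(site_scores == 1, match(carrier_key, edge_key), NA)
  count <- tabulate(assigned[!is.na(assigned)], nbins = nrow(edge))
  tab <- data.frame(edge = seq_len(nrow(edge)),
                    parent = edge[, 1], child = edge[, 2],
                    populations = edge_key, count = count)
  list(table = tab, edge = tab$edge, count = count,
       n_homoplasic = sum(site_scores > 1))
}

#' Classify mutations as trunk, shared, or private
#'
#' Two conventions are provided. Mode `"strict"` (default, the whole-patient
#' reading used for tree drawings): trunk if present in all populations,
#' shared if in at least two but not all, private if in exactly one. Mode
#' `"paper"` (the biopsy-level wording): trunk if present in two or more
#' populations, private if in exactly one.
#'
#' @param mat binary presence matrix (rows = mutations, cols = populations).
#' @param mode `"strict"` or `"paper"`.
#' @return character vector per mutation: `"trunk"`, `"shared"`, or
#'   `"private"`.
#' @export
classify_trunk <- function(mat, mode = c("strict", "paper")) {
  mode <- match.arg(mode)
  mat <- check_presence_matrix(mat)
  k <- rowSums(mat)
  if (mode == "paper") {
    ifelse(k >= 2, "trunk", "private")
  } else {
    ifelse(k == ncol(mat), "trunk", ifelse(k >= 2, "shared", "private"))
  }
}
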