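#' Simulation configuration for a synthetic flow-sorted patient
#'
#' Describes a synthetic patient: its sorted tumor populations (with true
#' ploidy, pre- and post-sort purity), a rooted set of mutation clusters
#' with per-population true CCF vectors, sequencing depth, mutational
#' signature mixtures per cluster, and per-population copy-number profiles.
#' The configuration is validated against the tree invariants: the single
#' parentless (truncal) cluster must have CCF 1 in every population, and
#' every child's CCF may not exceed its parent's in any population.
#'
#' @param populations data frame with columns `id`, `biopsy`, `site`
#'   (`"primary"` or `"metastasis"`), `ploidy` (in `[1.5, 4.5]`), `purity`
#'   (pre-sort, in `(0, 1]`), `purity_postsort` (in `(0, 1]`), and
#'   optionally `marker_rate` (marker positivity of tumor nuclei,
#'   default 0.98).
#' @param clusters list of cluster specs; each a list with `ccf` (named
#'   numeric vector over population ids, entries in `[0, 1]`), `n`
#'   (mutation count), `parent` (index of the parent cluster, `NA` for the
#'   truncal root), and optionally `signature_mix` (named weights over the
#'   signature reference columns, summing to 1).
#' @param depth_mean mean sequencing depth; per-site depths are Poisson
#'   (default 150, typical exome coverage).
#' @param facs_cv coefficient of variation of the DAPI signal (> 0,
#'   default 0.05).
#' @param g2m_fraction fraction of each population's nuclei in G2/M (at
#'   twice the G0/G1 DNA content; default 0.1).
#' @param n_facs_events FACS events simulated per biopsy (default 10000).
#' @param signature_reference 96 x S signature matrix (default
#'   [toy_signature_reference()]).
#' @param cn_profiles optional named list of per-population segment tables;
#'   when omitted, near-uniform profiles at the rounded ploidy are built.
#' @param seed integer seed making the whole simulation deterministic.
#' @return validated `sim_config` object.
#' @export
sim_config <- function(populations, clusters, depth_mean = 150,
                       facs_cv = 0.05, g2m_fraction = 0.1,
                       n_facs_events = 10000,
                       signature_reference = toy_signature_reference(),
                       cn_profiles = NULL, seed = 1) {
  need <- c("id", "biopsy", "site", "ploidy", "purity", "purity_postsort")
  if (!is.data.frame(populations) || !all(need %in% names(populations))) {
    stop("populations must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(populations) < 2L) stop("need at least 2 populations")
  if (!all(populations$site %in% c("primary", "metastasis"))) {
    stop("site must be 'primary' or 'metastasis'")
  }
  if (any(populations$ploidy < 1.5 | populations$ploidy > 4.5)) {
    stop("ploidy must be in [1.5, 4.5]")
  }
  if (any(populations$purity <= 0 | populations$purity > 1) ||
      any(populations$purity_postsort <= 0 | populations$purity_postsort > 1)) {
    stop("purities must be in (0, 1]")
  }
  if (is.null(populations$marker_rate)) populations$marker_rate <- 0.98
  if (facs_cv <= 0) stop("facs_cv must be > 0")
  if (depth_mean <= 0) stop("depth_mean must be > 0")

  ids <- as.character(populations$id)
  roots <- which(vapply(clusters, function(cl) is.na(cl$parent %||% NA),
                        logical(1)))
  if (length(roots) != 1L) stop("exactly one truncal (parentless) cluster required")
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (!all(ids %in% names(cl$ccf))) {
      stop("cluster ", i, ": ccf vector must name every population")
    }
    if (any(cl$ccf < 0 | cl$ccf > 1)) stop("cluster ", i, ": CCFs must be in [0, 1]")
    if ((cl$n %||% 0) < 1) stop("cluster ", i, ": mutation count must be >= 1")
    if (!is.null(cl$signature_mix)) {
      if (any(cl$signature_mix < 0)) stop("cluster ", i, ": negative signature weight")
      if (abs(sum(cl$signature_mix) - 1) > 1e-9) {
        stop("cluster ", i, ": signature weights must sum to 1")
      }
      if (!all(names(cl$signature_mix) %in% colnames(signature_reference))) {
        stop("cluster ", i, ": unknown signature name")
      }
    }
  }
  root_ccf <- clusters[[roots]]$ccf[ids]
  if (any(abs(root_ccf - 1) > 1e-9)) {
    stop("truncal cluster must have CCF 1 in every population")
  }
  for (i in seq_along(clusters)) {
    pa <- clusters[[i]]$parent %||% NA
    if (is.na(pa)) next
    if (pa < 1 || pa > length(clusters)) stop("cluster ", i, ": invalid parent index")
    bad <- clusters[[i]]$ccf[ids] > clusters[[pa]]$ccf[ids] + 1e-9
    if (any(bad)) {
      stop("containment violated: cluster ", i, " exceeds parent ", pa,
           " in population(s) ", paste(ids[bad], collapse = ", "))
    }
  }
  if (is.null(cn_profiles)) {
    cn_profiles <- stats::setNames(lapply(seq_len(nrow(populations)), function(i) {
      default_cn_profile(populations$ploidy[i], variant_arm = i)
    }), ids)
  }
  if (!all(ids %in% names(cn_profiles))) stop("cn_profiles missing populations")
  for (p in cn_profiles) check_profile(p)

  structure(list(populations = populations, clusters = clusters,
                 depth_mean = depth_mean, facs_cv = facs_cv,
                 g2m_fraction = g2m_fraction, n_facs_events = n_facs_events,
                 signature_reference = signature_reference,
                 cn_profiles = cn_profiles, seed = as.integer(seed)),
            class = "sim_config")
}

# whole-genome profile at the rounded ploidy with a few population-specific
# altered chromosomes (keyed by variant_arm so different populations differ)
default_cn_profile <- function(ploidy, variant_arm = 1) {
  genome <- genome_definition()
  base <- max(1, round_half_up(ploidy))
  cn <- rep(base, length(genome))
  alt_idx <- ((variant_arm * 5 + c(1, 8, 15)) %% length(genome)) + 1
  cn[alt_idx[1]] <- base + 1
  cn[alt_idx[2]] <- max(1, base - 1)
  cn[alt_idx[3]] <- base + 2
  data.frame(chrom = names(genome), start = 0, end = unname(genome),
             total_cn = cn, minor_cn = pmin(1, cn),
             log_ratio = log2(cn / ploidy))
}

cn_at <- function(profile, chrom, pos) {
  cn <- rep(NA_real_, length(chrom))
  for (ch in unique(chrom)) {
    seg <- profile[profile$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    i <- which(chrom == ch)
    if (!nrow(seg)) next
    hit <- findInterval(pos[i], seg$start)
    ok <- hit >= 1 & pos[i] < seg$end[pmax(hit, 1)]
    cn[i[ok]] <- seg$total_cn[hit[ok]]
  }
  cn
}

#' Simulate mutation trinucleotide contexts from a signature mixture
#'
#' Draws 96-channel context counts from the multinomial whose channel
#' probabilities are the weighted mixture of signature reference columns.
#'
#' @param n_mutations number of mutations (>= 0).
#' @param signature_mix named non-negative weights summing to 1 over columns
#'   of `reference`.
#' @param reference 96 x S signature matrix with columns summing to 1.
#' @param seed optional integer seed.
#' @return named integer vector of 96 channel counts summing to
#'   `n_mutations`.
#' @export
simulate_signature_contexts <- function(n_mutations, signature_mix, reference,
                                        seed = NULL) {
  if (any(signature_mix < 0)) stop("signature weights must be non-negative")
  if (abs(sum(signature_mix) - 1) > 1e-9) stop("signature weights must sum to 1")
  if (!all(names(signature_mix) %in% colnames(reference))) {
    stop("unknown signature name(s)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  probs <- as.numeric(reference[, names(signature_mix), drop = FALSE] %*%
                        signature_mix)
  out <- if (n_mutations > 0) {
    as.integer(stats::rmultinom(1, n_mutations, probs))
  } else rep(0L, 96)
  stats::setNames(out, sbs96_channels())
}

#' Simulate a FACS event table for one biopsy
#'
#' Generates DAPI and marker intensities for the nuclei of a biopsy
#' containing one or more tumor populations plus a diploid marker-negative
#' normal compartment. DAPI is log-normal, centered per population at a
#' ploidy-proportional intensity with the stated coefficient of variation;
#' a `g2m_fraction` of each population's nuclei sits at twice its G0/G1
#' DNA content. Marker intensity is bimodal by true tumor/normal label.
#' Event shares are chosen so that each tumor population's events-vs-normal
#' fraction equals its stated pre-sort purity.
#'
#' @param populations data frame with columns `id`, `ploidy`, `purity`
#'   (pre-sort, each population against the normal compartment) and
#'   optionally `marker_rate`.
#' @param n_events total number of events (>= 100).
#' @param facs_cv DAPI coefficient of variation (> 0).
#' @param seed optional integer seed.
#' @param g2m_fraction fraction of nuclei in G2/M (default 0.1).
#' @param dapi_per_n DAPI intensity units per haploid DNA content
#'   (default 50; diploid nuclei center at 100).
#' @return data frame: `event_id`, `dapi`, `marker`, `population` (truth
#'   label; `"normal"` for the normal compartment), `tumor` (logical truth),
#'   `phase` (`"G0/G1"` or `"G2/M"`).
#' @export
simulate_facs_events <- function(populations, n_events = 10000, facs_cv = 0.05,
                                 seed = NULL, g2m_fraction = 0.1,
                                 dapi_per_n = 50) {
  if (n_events < 100) stop("n_events must be >= 100")
  if (facs_cv <= 0) stop("facs_cv must be > 0")
  if (any(populations$purity <= 0 | populations$purity > 1)) {
    stop("pre-sort purities must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  marker_rate <- populations$marker_rate %||% rep(0.98, nrow(populations))

  # shares s_i with s_i / (s_i + s_normal) = purity_i
  odds <- populations$purity / (1 - populations$purity)
  odds[!is.finite(odds)] <- 1e6
  s_norm <- 1 / (1 + sum(odds))
  shares <- c(odds * s_norm, s_norm)
  shares <- shares / sum(shares)
  lab <- c(as.character(populations$id), "normal")
  counts <- as.integer(stats::rmultinom(1, n_events, shares))

  sdlog <- sqrt(log(1 + facs_cv^2))
  rows <- lapply(seq_along(lab), function(i) {
    ni <- counts[i]
    if (ni == 0L) return(NULL)
    tumor <- lab[i] != "normal"
    ploidy <- if (tumor) populations$ploidy[i] else 2
    g2m <- stats::runif(ni) < g2m_fraction
    dapi <- stats::rlnorm(ni, log(dapi_per_n * ploidy), sdlog) * ifelse(g2m, 2, 1)
    pos <- if (tumor) stats::runif(ni) < marker_rate[i] else rep(FALSE, ni)
    marker <- ifelse(pos, stats::rlnorm(ni, log(1000), 0.4),
                     stats::rlnorm(ni, log(10), 0.4))
    data.frame(dapi = dapi, marker = marker, population = lab[i],
               tumor = tumor, phase = ifelse(g2m, "G2/M", "G0/G1"))
  })
  out <- do.call(rbind, rows)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic flow-sorted patient with full ground truth
#'
#' Forward-simulates everything the analysis consumes: per-mutation,
#' per-population read counts (`alt ~ Binomial(depth, expected VAF)` with
#' Poisson depths, the expected VAF from [expected_vaf()] at the cluster's
#' true CCF and the population's post-sort purity and local copy number),
#' per-population copy-number segment tables, FACS event tables per biopsy,
#' and trinucleotide contexts drawn from each cluster's signature mixture.
#' All randomness is governed by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (long data frame: `variant_id`, `chrom`,
#'   `pos` (0-based), `ref`, `alt_allele`, `gene`, `effect`, `context`,
#'   `cluster`, `patient`, `population`, `alt`, `depth`, `cn_t`, `m`,
#'   `vaf`), `cn_profiles`, `facs` (named list of event tables per biopsy),
#'   `purity_postsort` (named vector), and `truth` (cluster assignment,
#'   tree edges, seeding map, per-population ploidy/purity, signature
#'   mixtures).
#' @export
simulate_patient <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  ids <- as.character(pops$id)
  genome <- genome_definition()
  clusters <- config$clusters
  n_total <- sum(vapply(clusters, `[[`, numeric(1), "n"))
  cluster_of <- rep(seq_along(clusters),
                    vapply(clusters, `[[`, numeric(1), "n"))

  chrom <- sample(names(genome), n_total, replace = TRUE,
                  prob = genome / sum(genome))
  pos <- floor(stats::runif(n_total) * genome[chrom])
  gene <- sprintf("GENE%04d", sample.int(5000, n_total, replace = TRUE))
  effect <- sample(c("non_synonymous", "synonymous"), n_total,
                   replace = TRUE, prob = c(0.7, 0.3))

  default_mix <- stats::setNames(1, colnames(config$signature_reference)[1])
  context <- character(n_total)
  ch96 <- sbs96_channels()
  for (k in seq_along(clusters)) {
    mix <- clusters[[k]]$signature_mix %||% default_mix
    cnt <- simulate_signature_contexts(clusters[[k]]$n, mix,
                                       config$signature_reference)
    chan_idx <- rep.int(seq_len(96), cnt)
    context[cluster_of == k] <- ch96[chan_idx[sample.int(length(chan_idx))]]
  }
  ref <- substr(context, 3, 3)
  alt_allele <- substr(context, 5, 5)

  variant_id <- sprintf("mut%05d", seq_len(n_total))
  per_pop <- lapply(ids, function(pid) {
    i <- match(pid, ids)
    pur <- pops$purity_postsort[i]
    cn_t <- cn_at(config$cn_profiles[[pid]], chrom, pos)
    cn_t[is.na(cn_t)] <- max(1, round_half_up(pops$ploidy[i]))
    ccf <- vapply(clusters, function(cl) cl$ccf[[pid]], numeric(1))[cluster_of]
    v <- expected_vaf(ccf, pur, cn_t, 2, 1)
    depth <- pmax(stats::rpois(n_total, config$depth_mean), 1L)
    alt <- stats::rbinom(n_total, depth, pmin(v, 1))
    data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
               ref = ref, alt_allele = alt_allele, gene = gene,
               effect = effect, context = context, cluster = cluster_of,
               patient = "patient1", population = pid,
               alt = alt, depth = depth, cn_t = cn_t, m = 1L,
               vaf = alt / depth)
  })
  variants <- do.call(rbind, per_pop)
  rownames(variants) <- NULL

  facs <- lapply(split(seq_len(nrow(pops)), pops$biopsy), function(i) {
    simulate_facs_events(pops[i, , drop = FALSE],
                         n_events = config$n_facs_events,
                         facs_cv = config$facs_cv,
                         g2m_fraction = config$g2m_fraction)
  })

  parent <- vapply(clusters, function(cl) as.integer(cl$parent %||% NA), integer(1))
  edges <- data.frame(parent = parent[!is.na(parent)],
                      child = which(!is.na(parent)))
  seeding <- truth_seeding(clusters, pops)
  truth <- list(
    cluster = stats::setNames(cluster_of, variant_id),
    tree_edges = edges,
    root = which(is.na(parent)),
    seeding = seeding,
    ploidy = stats::setNames(pops$ploidy, ids),
    purity = stats::setNames(pops$purity, ids),
    purity_postsort = stats::setNames(pops$purity_postsort, ids),
    signature_mix = lapply(clusters, function(cl) cl$signature_mix %||% default_mix))

  list(variants = variants, cn_profiles = config$cn_profiles, facs = facs,
       purity_postsort = stats::setNames(pops$purity_postsort, ids),
       truth = truth, config = config)
}

# ground-truth seeding map: exclusive cluster sharing on the true CCFs
truth_seeding <- function(clusters, pops) {
  ids <- as.character(pops$id)
  ccf <- do.call(rbind, lapply(clusters, function(cl) cl$ccf[ids]))
  colnames(ccf) <- ids
  site <- stats::setNames(pops$site, ids)
  prim <- ids[site == "primary"]
  mets <- ids[site == "metastasis"]
  if (!length(mets) || length(prim) < 1) return(NULL)
  out <- vapply(mets, function(M) {
    scores <- vapply(prim, function(P) {
      other <- setdiff(prim, P)
      sum(ccf[, M] > 0.1 & ccf[, P] > 0.1 &
            (if (length(other)) rowSums(ccf[, other, drop = FALSE] > 0.1) == 0
             else TRUE))
    }, numeric(1))
    prim[which.max(scores)]
  }, character(1))
  stats::setNames(out, mets)
}

#' Reference synthetic patient: a polygenomic primary with two metastases
#'
#' Builds the package's reference simulation scenario: one primary-site
#' biopsy containing two tumor populations of different ploidies (PST1,
#' PST2) and two metastases (MT1 skin-like, MT2 lymph-node-like), with six
#' mutation clusters whose presence pattern encodes distinct clonal
#' origins: one trajectory (truncal -> cluster 2 -> cluster 3) shared by
#' PST1, PST2 and MT1, and another (truncal -> cluster 4 -> clusters 5, 6)
#' shared exclusively by PST1 and MT2. Under the truth, MT1 derives from
#' PST2 and MT2 from PST1. Ploidies and purities follow the sorted-
#' population characteristics of a polygenomic melanoma case (pre-sort
#' purities 19-80%, post-sort 88-95%); the UV-like signature dominates all
#' clusters except cluster 6, which carries a chemotherapy-like admixture.
#'
#' @param seed integer seed.
#' @param depth_mean mean sequencing depth (default 150).
#' @param n_facs_events FACS events per biopsy (default 10000).
#' @return a [sim_config()].
#' @export
patient1_config <- function(seed = 1, depth_mean = 150, n_facs_events = 10000) {
  populations <- data.frame(
    id = c("PST1", "PST2", "MT1", "MT2"),
    biopsy = c("primary", "primary", "skin_met", "ln_met"),
    site = c("primary", "primary", "metastasis", "metastasis"),
    ploidy = c(1.7, 2.7, 2.6, 2.7),
    purity = c(0.19, 0.41, 0.80, 0.40),
    purity_postsort = c(0.88, 0.95, 0.91, 0.93))
  cc <- function(...) stats::setNames(c(...), populations$id)
  uv <- c(UV.like = 1)
  chem <- c(UV.like = 0.6, Platinum.like = 0.4)
  clusters <- list(
    list(ccf = cc(1, 1, 1, 1),        n = 500, parent = NA, signature_mix = uv),
    list(ccf = cc(0.55, 1, 1, 0),     n = 298, parent = 1,  signature_mix = uv),
    list(ccf = cc(0, 0.6, 0.5, 0),    n = 150, parent = 2,  signature_mix = uv),
    list(ccf = cc(0.45, 0, 0, 1),     n = 199, parent = 1,  signature_mix = uv),
    list(ccf = cc(0.12, 0, 0, 0.30),  n = 34,  parent = 4,  signature_mix = uv),
    list(ccf = cc(0.30, 0, 0, 0.62),  n = 227, parent = 4,  signature_mix = chem))
  sim_config(populations, clusters, depth_mean = depth_mean,
             n_facs_events = n_facs_events, seed = seed)
}
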