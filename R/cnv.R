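#' Simplified autosome lengths
#'
#' Chromosome lengths (bp) for chr1-chr22, rounded to the nearest megabase
#' of the human reference, used as the shared genome definition for
#' simulation and binning.
#'
#' @return named numeric vector of 22 lengths.
#' @export
genome_definition <- function() {
  len_mb <- c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
              114, 107, 102, 90, 83, 80, 59, 64, 47, 51)
  stats::setNames(len_mb * 1e6, paste0("chr", 1:22))
}

check_profile <- function(profile) {
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(profile))) {
    stop("segment profile must have columns ", paste(need, collapse = ", "))
  }
  if (any(profile$total_cn < 0)) stop("negative copy number")
  if (any(profile$minor_cn < 0) || any(profile$minor_cn > profile$total_cn)) {
    stop("minor copy number must satisfy 0 <= minor <= total")
  }
  if (any(profile$end <= profile$start)) stop("segments must have end > start")
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, ]
    s <- s[order(s$start), ]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch)
    }
  }
  invisible(TRUE)
}

#' Copy-number category calls relative to ploidy
#'
#' Classifies each segment by its total copy number relative to the
#' population's rounded ploidy: total CN 0 is a homozygous deletion; below
#' round(ploidy) is a loss; equal is neutral; above by one or two is a gain;
#' at round(ploidy) + 3 or more is an amplification.
#'
#' @param profile data frame of segments with columns `chrom`, `start`,
#'   `end` (0-based half-open), `total_cn`, `minor_cn`.
#' @param ploidy population ploidy (DNA content, diploid = 2).
#' @param amplification_offset copies above rounded ploidy at which a gain
#'   becomes an amplification (default 3).
#' @return `profile` with a `category` factor appended (levels
#'   `homozygous_deletion`, `loss`, `neutral`, `gain`, `amplification`).
#' @export
call_cn_categories <- function(profile, ploidy, amplification_offset = 3) {
  check_profile(profile)
  if (ploidy <= 0) stop("ploidy must be positive")
  base <- round_half_up(ploidy)
  cn <- profile$total_cn
  cat <- ifelse(cn == 0, "homozygous_deletion",
         ifelse(cn < base, "loss",
         ifelse(cn == base, "neutral",
         ifelse(cn < base + amplification_offset, "gain", "amplification"))))
  profile$category <- factor(cat, levels = c("homozygous_deletion", "loss",
                                             "neutral", "gain", "amplification"))
  profile
}

# rasterize a segment profile's log ratios onto fixed genome bins
rasterize_log_ratio <- function(profile, bin_size = 1e6, genome = genome_definition()) {
  vals <- unlist(lapply(names(genome), function(ch) {
    n_bin <- ceiling(genome[[ch]] / bin_size)
    v <- rep(NA_real_, n_bin)
    seg <- profile[profile$chrom == ch, , drop = FALSE]
    if (nrow(seg)) {
      lr <- seg$log_ratio %||% log2(pmax(seg$total_cn, 0.5) / 2)
      for (i in seq_len(nrow(seg))) {
        b0 <- floor(seg$start[i] / bin_size) + 1L
        b1 <- min(ceiling(seg$end[i] / bin_size), n_bin)
        if (b1 >= b0) v[b0:b1] <- lr[i]
      }
    }
    v
  }), use.names = FALSE)
  vals
}

#' Pairwise Pearson correlation of copy-number profiles
#'
#' Profiles are rasterized to fixed genomic bins of log ratio; each pair is
#' correlated over the bins covered in both profiles, with a two-sided
#' p-value from the t transform of Pearson's R.
#'
#' @param profiles named list of segment data frames (columns `chrom`,
#'   `start`, `end`, `total_cn`, `minor_cn`, optionally `log_ratio`; when
#'   `log_ratio` is absent it is derived as `log2(total_cn / 2)` with CN 0
#'   floored at 0.5).
#' @param bin_size bin width in bp (default 1 Mb).
#' @param genome named vector of chromosome lengths.
#' @return list with matrices `r` (Pearson correlations, diagonal 1) and
#'   `p` (two-sided p-values, diagonal 0), and `n_bins` (bins used per pair).
#' @export
cn_correlation_matrix <- function(profiles, bin_size = 1e6,
                                  genome = genome_definition()) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  for (p in profiles) check_profile(p)
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  mat <- sapply(profiles, rasterize_log_ratio, bin_size = bin_size,
                genome = genome)
  k <- length(profiles)
  r <- diag(1, k); pv <- matrix(0, k, k); nb <- matrix(NA_integer_, k, k)
  dimnames(r) <- dimnames(pv) <- dimnames(nb) <- list(ids, ids)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(mat[, c(i, j)])
    if (sum(ok) < 2L) stop("fewer than 2 overlapping bins for a pair")
    ct <- suppressWarnings(stats::cor.test(mat[ok, i], mat[ok, j]))
    est <- unname(ct$estimate)
    if (is.na(est)) est <- 1  # zero-variance profiles: identical bins
    r[i, j] <- r[j, i] <- est
    pv[i, j] <- pv[j, i] <- if (is.na(ct$p.value)) 1 else ct$p.value
    nb[i, j] <- nb[j, i] <- sum(ok)
  }
  list(r = r, p = pv, n_bins = nb)
}

#' Find homozygously deleted genes
#'
#' Intersects total-CN-0 segments with a gene annotation table under 0-based
#' half-open overlap semantics (an interval ending where another starts does
#' not overlap it).
#'
#' @param profile segment data frame (see [call_cn_categories()]).
#' @param genes data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene`.
#' @return data frame of deleted loci: `chrom`, `start`, `end`, `genes`
#'   (comma-separated overlapping gene symbols); zero rows when there is no
#'   homozygous deletion.
#' @export
find_homozygous_deletions <- function(profile, genes) {
  check_profile(profile)
  if (!all(c("chrom", "start", "end", "gene") %in% names(genes))) {
    stop("gene table must have columns chrom, start, end, gene")
  }
  del <- profile[profile$total_cn == 0, , drop = FALSE]
  if (nrow(del) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), genes = character(0)))
  }
  hit_genes <- vapply(seq_len(nrow(del)), function(i) {
    g <- genes[genes$chrom == del$chrom[i] &
                 genes$start < del$end[i] &
                 genes$end > del$start[i], "gene"]
    paste(sort(unique(g)), collapse = ",")
  }, character(1))
  data.frame(chrom = del$chrom, start = del$start, end = del$end,
             genes = hit_genes)
}
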