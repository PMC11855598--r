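#' Expected variant allele frequency of a mutation
#'
#' Forward model linking cancer cell fraction to the allele fraction seen in
#' reads: a mutation carried on `m` copies by a fraction `ccf` of tumor cells
#' in a sample of purity `p`, at a locus with tumor total copy number `cn_t`
#' and normal copy number `cn_n`, is expected at
#' `VAF = m * ccf * p / (p * cn_t + (1 - p) * cn_n)`.
#'
#' @param ccf cancer cell fraction in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param cn_t tumor total copy number at the locus.
#' @param cn_n normal copy number at the locus (2 for autosomes).
#' @param m multiplicity: mutated copies per carrying cell (integer >= 1).
#' @return expected VAF.
#' @export
expected_vaf <- function(ccf, purity, cn_t, cn_n = 2, m = 1) {
  check_ccf_args(purity, cn_t, cn_n, m)
  m * ccf * purity / (purity * cn_t + (1 - purity) * cn_n)
}

check_ccf_args <- function(purity, cn_t, cn_n, m) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  if (any(cn_t < 0)) stop("tumor copy number must be >= 0")
  if (any(cn_n < 0)) stop("normal copy number must be >= 0")
  if (any(m < 1)) stop("multiplicity must be >= 1")
  if (any(m * purity == 0)) stop("degenerate denominator: m * purity = 0")
  invisible(TRUE)
}

#' Cancer cell fraction from a variant allele frequency
#'
#' Inverts the [expected_vaf()] model:
#' `CCF = VAF * (p * cn_t + (1 - p) * cn_n) / (p * m)`.
#' Estimates are clipped to `[0, 1.2]` (values modestly above 1 arise from
#' read-sampling noise or a misestimated multiplicity); the raw inversion is
#' attached as attribute `"raw"` for diagnostics. For clonality
#' classification the estimate is additionally capped at 1 (see
#' [classify_clonal()]).
#'
#' @inheritParams expected_vaf
#' @param vaf observed variant allele frequency in `[0, 1]`.
#' @return CCF point estimate, clipped to `[0, 1.2]`, with attribute `raw`.
#' @examples
#' compute_ccf(0.5, purity = 1, cn_t = 2)          # 1.0
#' compute_ccf(0.24, purity = 0.9, cn_t = 2)       # ~0.53
#' @export
compute_ccf <- function(vaf, purity, cn_t, cn_n = 2, m = 1) {
  if (any(vaf < 0 | vaf > 1)) stop("VAF must be in [0, 1]")
  check_ccf_args(purity, cn_t, cn_n, m)
  raw <- vaf * (purity * cn_t + (1 - purity) * cn_n) / (purity * m)
  out <- pmin(pmax(raw, 0), 1.2)
  attr(out, "raw") <- raw
  out
}

#' Integer multiplicity estimate for a mutation
#'
#' Rounds the copy-number-scaled VAF to the nearest mutated copy count:
#' `m = clamp(round(vaf * (p * cn_t + (1 - p) * cn_n) / p), 1, max(1, cn_t))`.
#' The quantity being rounded is really `m * CCF`, so the estimator is
#' reliable for clonal and near-clonal mutations; for a subclonal multi-copy
#' mutation (`m >= 2`, CCF well below 1) it deliberately under-calls `m`
#' rather than over-calling CCF.
#'
#' @inheritParams compute_ccf
#' @return integer multiplicity estimate, in `[1, max(1, cn_t)]`.
#' @export
estimate_multiplicity <- function(vaf, purity, cn_t, cn_n = 2) {
  if (any(vaf < 0 | vaf > 1)) stop("VAF must be in [0, 1]")
  check_ccf_args(purity, cn_t, cn_n, 1)
  m <- round_half_up(vaf * (purity * cn_t + (1 - purity) * cn_n) / purity)
  as.integer(pmin(pmax(m, 1), pmax(1, floor(cn_t))))
}

jeffreys_interval <- function(alt, depth, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(alt == 0, 0, stats::qbeta(a, alt + 0.5, depth - alt + 0.5))
  hi <- ifelse(alt == depth, 1, stats::qbeta(1 - a, alt + 0.5, depth - alt + 0.5))
  cbind(lo = lo, hi = hi)
}

#' Confidence interval for a mutation's CCF
#'
#' A Jeffreys binomial interval on the VAF (Beta(alt + 1/2, ref + 1/2)
#' posterior quantiles, with the usual boundary modification at 0 and n) is
#' pushed through the monotone VAF-to-CCF map and clipped to `[0, 1]`.
#'
#' @param alt alt-supporting read count.
#' @param depth total read depth (`alt + ref`), must be >= 1.
#' @inheritParams compute_ccf
#' @param level confidence level (default 0.95).
#' @return numeric vector (or matrix for vector input) with columns
#'   `lo`, `hi`.
#' @export
ccf_interval <- function(alt, depth, purity, cn_t, cn_n = 2, m = 1,
                         level = 0.95) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (any(alt < 0 | alt > depth)) stop("alt must satisfy 0 <= alt <= depth")
  ji <- jeffreys_interval(alt, depth, level)
  lo <- pmin(as.numeric(compute_ccf(ji[, "lo"], purity, cn_t, cn_n, m)), 1)
  hi <- pmin(as.numeric(compute_ccf(ji[, "hi"], purity, cn_t, cn_n, m)), 1)
  cbind(lo = lo, hi = hi)
}

#' Posterior probability that a mutation is clonal
#'
#' Mass of the Jeffreys Beta posterior on the VAF above the VAF expected at
#' `CCF = ccf_threshold`, i.e. `P(CCF >= ccf_threshold | alt, depth)`.
#'
#' @inheritParams ccf_interval
#' @param ccf_threshold CCF at or above which a mutation counts as clonal
#'   (default 0.9).
#' @return probability in `[0, 1]`.
#' @export
clonal_probability <- function(alt, depth, purity, cn_t, cn_n = 2, m = 1,
                               ccf_threshold = 0.9) {
  if (any(depth < 1)) stop("depth must be >= 1")
  v_thr <- expected_vaf(ccf_threshold, purity, cn_t, cn_n, m)
  p <- 1 - stats::pbeta(pmin(v_thr, 1), alt + 0.5, depth - alt + 0.5)
  p[v_thr > 1] <- 0
  p
}

#' Classify a mutation as clonal or subclonal
#'
#' A mutation is clonal if its probability of being clonal exceeds 0.5 or if
#' the lower bound of the 95% confidence interval of its CCF exceeds 0.9;
#' otherwise it is subclonal.
#'
#' @param p_clonal posterior probability of being clonal
#'   ([clonal_probability()]).
#' @param ci_lower lower bound of the 95% CCF confidence interval.
#' @param p_cut probability cutoff (default 0.5).
#' @param lower_cut CI lower-bound cutoff (default 0.9).
#' @return character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonal <- function(p_clonal, ci_lower, p_cut = 0.5, lower_cut = 0.9) {
  ifelse(p_clonal > p_cut | ci_lower > lower_cut, "clonal", "subclonal")
}

#' Per-mutation, per-population CCF table
#'
#' Applies multiplicity estimation, the closed-form CCF inversion, the
#' Jeffreys interval, and the clonality rule to a long-format read-count
#' table.
#'
#' @param counts data frame with columns `variant_id`, `population`, `alt`,
#'   `depth`, `cn_t` and optionally `cn_n` (default 2).
#' @param purity named vector of per-population tumor purities (post-sort).
#' @param level confidence level for the interval.
#' @param ccf_threshold clonal CCF threshold (default 0.9).
#' @return the input with columns `m`, `ccf`, `ccf_raw`, `lo`, `hi`,
#'   `p_clonal`, `clonality` appended.
#' @export
ccf_table <- function(counts, purity, level = 0.95, ccf_threshold = 0.9) {
  need <- c("variant_id", "population", "alt", "depth", "cn_t")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  if (!all(counts$population %in% names(purity))) {
    stop("purity missing for some populations")
  }
  p <- unname(purity[as.character(counts$population)])
  cn_n <- counts$cn_n %||% rep(2, nrow(counts))
  depth <- pmax(counts$depth, 1)
  vaf <- ifelse(counts$depth > 0, counts$alt / counts$depth, 0)
  m <- estimate_multiplicity(vaf, p, counts$cn_t, cn_n)
  cc <- compute_ccf(vaf, p, counts$cn_t, cn_n, m)
  ci <- ccf_interval(counts$alt, depth, p, counts$cn_t, cn_n, m, level)
  pc <- clonal_probability(counts$alt, depth, p, counts$cn_t, cn_n, m,
                           ccf_threshold)
  out <- counts
  out$m <- m
  out$ccf <- pmin(as.numeric(cc), 1)
  out$ccf_raw <- attr(cc, "raw")
  out$lo <- ci[, "lo"]
  out$hi <- ci[, "hi"]
  out$p_clonal <- pc
  out$clonality <- classify_clonal(pc, ci[, "lo"])
  out
}

#' Estimate post-sort purity from truncal heterozygous VAFs
#'
#' Simple purity estimator for when an allele-specific copy-number fit is not
#' available: candidate truncal heterozygous mutations (m = 1, CCF = 1) at a
#' known tumor copy number satisfy `vaf = p / (p * cn_t + (1 - p) * 2)`, which
#' is inverted at the median VAF.
#'
#' @param vaf VAFs of candidate truncal heterozygous mutations.
#' @param cn_t tumor total copy number at those loci (scalar or vector).
#' @return purity estimate in `(0, 1]`.
#' @export
purity_from_truncal_vaf <- function(vaf, cn_t = 2) {
  if (length(vaf) == 0L) stop("no truncal VAFs supplied")
  p_site <- 2 * vaf / (1 - vaf * cn_t + 2 * vaf)
  stats::median(pmin(pmax(p_site, 1e-3), 1))
}
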