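#' Estimate tumor ploidy from DAPI intensities
#'
#' DNA content (ploidy, expressed as N) of a flow-sorted tumor population is
#' the ratio of the geometric mean of its DAPI signal to that of the matched
#' marker-negative diploid (reference) population, scaled so that the
#' reference corresponds to N = 2.
#'
#' @param tumor_dapi numeric vector of DAPI intensities of tumor-gated events
#'   (G0/G1 nuclei); all values must be positive.
#' @param reference_dapi numeric vector of DAPI intensities of the diploid
#'   reference population; all values must be positive.
#' @param digits number of decimals the estimate is reported to (default 1,
#'   the precision used for sorted-population summary tables).
#' @return ploidy estimate N (diploid = 2), rounded to `digits`.
#' @examples
#' estimate_ploidy(rep(140, 50), rep(100, 50))  # 2.8
#' @export
estimate_ploidy <- function(tumor_dapi, reference_dapi, digits = 1) {
  if (length(tumor_dapi) == 0L || length(reference_dapi) == 0L) {
    stop("both tumor and reference DAPI samples must be non-empty")
  }
  if (any(tumor_dapi <= 0) || any(reference_dapi <= 0)) {
    stop("DAPI intensities must be positive (geometric mean undefined)")
  }
  round_half_up(2 * geomean(tumor_dapi) / geomean(reference_dapi), digits)
}

#' Convert a DNA index to ploidy
#'
#' The DNA index is the ratio of a population's DNA content to that of
#' diploid cells; ploidy is twice the DNA index (index 1.0 = diploid, N = 2).
#'
#' @param dna_index positive numeric vector of DNA indices.
#' @return ploidy values, `2 * dna_index`.
#' @examples
#' dna_index_to_ploidy(c(0.9, 1.4))  # 1.8, 2.8
#' @export
dna_index_to_ploidy <- function(dna_index) {
  if (any(!is.finite(dna_index)) || any(dna_index <= 0)) {
    stop("DNA index must be positive and finite")
  }
  2 * dna_index
}

#' Define a rectangular FACS analysis gate
#'
#' A gate selects events by marker status (above/below a marker-intensity
#' threshold) and a half-open DAPI window `[dapi_low, dapi_high)`. The tumor
#' gate can additionally include the G2/M window at twice the G0/G1 DAPI
#' position, mirroring manual gating practice where cycling tumor nuclei are
#' kept with their population.
#'
#' @param marker_threshold marker-intensity threshold separating positive
#'   from negative events.
#' @param marker_positive logical; `TRUE` selects events at or above the
#'   threshold, `FALSE` below.
#' @param dapi_low,dapi_high half-open DAPI window; `dapi_low < dapi_high`.
#' @param include_g2m logical; also accept events in
#'   `[2 * dapi_low, 2 * dapi_high)`.
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(marker_threshold, marker_positive = TRUE,
                      dapi_low, dapi_high, include_g2m = FALSE) {
  stopifnot_scalar(marker_threshold, "marker_threshold")
  stopifnot_scalar(dapi_low, "dapi_low")
  stopifnot_scalar(dapi_high, "dapi_high")
  if (dapi_low >= dapi_high) stop("gate requires dapi_low < dapi_high")
  structure(
    list(marker_threshold = marker_threshold,
         marker_positive = isTRUE(marker_positive),
         dapi_low = dapi_low, dapi_high = dapi_high,
         include_g2m = isTRUE(include_g2m)),
    class = "gate_spec")
}

gate_events <- function(events, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  m <- if (gate$marker_positive) events$marker >= gate$marker_threshold
       else events$marker < gate$marker_threshold
  d <- events$dapi >= gate$dapi_low & events$dapi < gate$dapi_high
  if (gate$include_g2m) {
    d <- d | (events$dapi >= 2 * gate$dapi_low & events$dapi < 2 * gate$dapi_high)
  }
  m & d
}

#' Pre-sort tumor purity from gate event fractions
#'
#' Purity of the unsorted material is the fraction of FACS events falling in
#' the tumor analysis gate among events falling in either the tumor or the
#' normal (marker-negative diploid) gate. Events outside both gates (debris,
#' doublets, other populations) are excluded from the denominator.
#'
#' @param events data frame with columns `dapi` and `marker`.
#' @param tumor_gate,normal_gate [gate_spec()] objects; must not overlap.
#' @return purity fraction in `[0, 1]`.
#' @export
presort_purity <- function(events, tumor_gate, normal_gate) {
  in_t <- gate_events(events, tumor_gate)
  in_n <- gate_events(events, normal_gate)
  if (any(in_t & in_n)) stop("tumor and normal gates overlap")
  nt <- sum(in_t); nn <- sum(in_n)
  if (nt + nn == 0L) stop("no events fall in either gate")
  nt / (nt + nn)
}

#' Summarize tumor purities across sorted populations
#'
#' @param purity numeric vector of purities, either fractions in `[0, 1]` or
#'   percentages in `[0, 100]` (values above 1 are taken as percentages).
#' @return list with `mean_pct` (arithmetic mean rounded to the nearest
#'   integer percent), `min_pct`, `max_pct`.
#' @examples
#' summarize_purity(c(88, 95, 91, 93, 88, 96, 91, 87))  # mean 91, range 87-96
#' @export
summarize_purity <- function(purity) {
  if (length(purity) == 0L) stop("purity table is empty")
  if (any(!is.finite(purity)) || any(purity < 0)) stop("invalid purity values")
  pct <- if (all(purity <= 1)) 100 * purity else purity
  if (any(pct > 100)) stop("purity above 100%")
  list(mean_pct = as.numeric(round_half_up(mean(pct))),
       min_pct = min(pct), max_pct = max(pct))
}

# 1D Otsu threshold on a numeric vector (histogram-based)
otsu_threshold <- function(x, n_breaks = 256L) {
  h <- hist(x, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# modes of a kernel-smoothed histogram of log intensities
density_peaks <- function(x, min_rel_height = 0.05, adjust = 1) {
  d <- stats::density(x, adjust = adjust)
  y <- d$y
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[y[i] >= min_rel_height * max(y)]
  data.frame(position = d$x[i], height = y[i])[order(-y[i]), , drop = FALSE]
}

#' Gate FACS events into tumor populations and estimate their ploidies
#'
#' Automatic, seedless gating of a FACS event table: the marker threshold is
#' placed by Otsu's method on log marker intensity, the diploid reference is
#' the G0/G1 peak of marker-negative events, and tumor populations are the
#' `n_populations` strongest G0/G1 peaks of marker-positive log-DAPI (peaks
#' sitting at twice an already-selected peak are treated as its G2/M
#' compartment, not as a separate population). Each population's ploidy is
#' estimated with [estimate_ploidy()] on its G0/G1-gated events, and its
#' pre-sort purity with [presort_purity()] against the normal gate.
#'
#' @param events data frame with columns `dapi` and `marker`.
#' @param n_populations expected number of tumor populations; `NULL` keeps
#'   every detected peak.
#' @param g01_halfwidth half-width of the G0/G1 gate on the log-DAPI axis
#'   (default 0.25, about five 5%-CV standard deviations).
#' @param include_g2m logical; tumor gates include the G2/M window.
#' @return data frame with one row per tumor population: `population`,
#'   `ploidy`, `presort_purity`, `n_events`, plus attributes `marker_threshold`
#'   and `reference_peak`.
#' @export
gate_populations <- function(events, n_populations = NULL,
                             g01_halfwidth = 0.25, include_g2m = TRUE) {
  stopifnot(is.data.frame(events), all(c("dapi", "marker") %in% names(events)))
  if (nrow(events) < 100L) stop("need at least 100 events for gating")
  if (any(events$dapi <= 0)) stop("DAPI intensities must be positive")
  lm_marker <- log(pmax(events$marker, 1e-9))
  thr <- otsu_threshold(lm_marker)
  pos <- lm_marker >= thr
  if (!any(pos) || all(pos)) stop("marker threshold failed to split events")

  ldapi <- log(events$dapi)
  ref_peaks <- density_peaks(ldapi[!pos])
  ref_mode <- ref_peaks$position[1]
  ref_gate01 <- gate_spec(exp(thr), FALSE,
                          exp(ref_mode - g01_halfwidth),
                          exp(ref_mode + g01_halfwidth))
  # purity denominator also counts normal G2/M nuclei (marker dimension keeps
  # the normal gate disjoint from every tumor gate)
  ref_gate <- gate_spec(exp(thr), FALSE,
                        exp(ref_mode - g01_halfwidth),
                        exp(ref_mode + g01_halfwidth),
                        include_g2m = include_g2m)
  ref_dapi <- events$dapi[gate_events(events, ref_gate01)]

  pk <- density_peaks(ldapi[pos])
  # drop peaks that are the G2/M echo (2x DAPI) of a stronger peak
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    echo <- abs(pk$position - (pk$position[i] + log(2))) < 0.15 & pk$height < pk$height[i]
    keep[echo] <- FALSE
  }
  pk <- pk[keep, , drop = FALSE]
  if (!is.null(n_populations)) {
    if (nrow(pk) < n_populations) {
      stop(sprintf("detected only %d tumor DAPI peak(s), expected %d",
                   nrow(pk), n_populations))
    }
    pk <- pk[seq_len(n_populations), , drop = FALSE]
  }
  pk <- pk[order(pk$position), , drop = FALSE]

  out <- lapply(seq_len(nrow(pk)), function(i) {
    ctr <- pk$position[i]
    # include G2/M only when its window collides with no other population's
    # G0/G1 window (overlapping windows would cross-contaminate the gates)
    others <- pk$position[-i]
    g2m_ok <- include_g2m &&
      (!length(others) ||
         all(abs((ctr + log(2)) - others) > 2 * g01_halfwidth))
    g01 <- gate_spec(exp(thr), TRUE,
                     exp(ctr - g01_halfwidth), exp(ctr + g01_halfwidth))
    full <- gate_spec(exp(thr), TRUE,
                      exp(ctr - g01_halfwidth), exp(ctr + g01_halfwidth),
                      include_g2m = g2m_ok)
    tum <- events$dapi[gate_events(events, g01)]
    data.frame(
      population = i,
      ploidy = estimate_ploidy(tum, ref_dapi),
      presort_purity = presort_purity(events, full, ref_gate),
      n_events = sum(gate_events(events, full)))
  })
  res <- do.call(rbind, out)
  attr(res, "marker_threshold") <- exp(thr)
  attr(res, "reference_peak") <- exp(ref_mode)
  res
}
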