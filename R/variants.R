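#' Somatic variant filter configuration
#'
#' Defaults encode the filtering cascade used for flow-sorted exomes: calls
#' with VAF below 1% or supported by fewer than three reads are discarded,
#' except that a relaxed two-read cutoff applies when the variant passes the
#' primary rule in at least one other sorted population of the same patient;
#' variants seen in two or more samples of a panel of normals are removed
#' everywhere.
#'
#' @param vaf_min minimum VAF per population (default 0.01).
#' @param min_alt_reads primary read cutoff (default 3).
#' @param shared_min_alt_reads relaxed cutoff for variants confirmed in a
#'   sibling population (default 2); must not exceed `min_alt_reads`.
#' @param pon_max_hits maximum tolerated panel-of-normals hit count
#'   (default 1; variants seen in `pon_max_hits + 1` or more panel samples
#'   are excluded).
#' @param count_mode which reads the read cutoffs count: `"alt"`
#'   (alt-supporting, default — consistent with the 2-read relaxation) or
#'   `"total"` (total depth).
#' @param panel_size optional panel size, recorded as metadata.
#' @return a `filter_config` list.
#' @export
filter_config <- function(vaf_min = 0.01, min_alt_reads = 3,
                          shared_min_alt_reads = 2, pon_max_hits = 1,
                          count_mode = c("alt", "total"), panel_size = NA) {
  count_mode <- match.arg(count_mode)
  if (shared_min_alt_reads > min_alt_reads) {
    stop("shared_min_alt_reads must be <= min_alt_reads")
  }
  structure(list(vaf_min = vaf_min, min_alt_reads = min_alt_reads,
                 shared_min_alt_reads = shared_min_alt_reads,
                 pon_max_hits = pon_max_hits, count_mode = count_mode,
                 panel_size = panel_size),
            class = "filter_config")
}

#' Apply the somatic filtering cascade
#'
#' Operates on a long-format variant table (one row per variant x population
#' observation). A row is retained when its population passes the primary
#' rule (VAF >= `vaf_min` and reads >= `min_alt_reads`), or the relaxed rule
#' (VAF >= `vaf_min`, reads >= `shared_min_alt_reads`, and the same variant
#' passes the primary rule in at least one other sorted population of the
#' same patient). Variants with panel-of-normals hits above `pon_max_hits`
#' are removed everywhere first. Each discarded row is tallied under the
#' first rule it fails, in the order panel-of-normals, VAF floor, read
#' support.
#'
#' @param records data frame with columns `variant_id`, `patient`,
#'   `population`, `alt`, `depth` (total reads).
#' @param config a [filter_config()].
#' @param patient_populations named list mapping patient to the character
#'   vector of that patient's population ids; every population appearing in
#'   `records` must be listed.
#' @param pon_hits named integer vector of panel-of-normals hit counts per
#'   `variant_id` (variants absent from the vector count 0 hits), or `NULL`.
#' @return list with `retained` (subset of `records`) and `tally`, a named
#'   integer vector over `retained`, `panel_of_normals`, `vaf_below_min`,
#'   `insufficient_reads` that partitions the input rows.
#' @export
apply_filters <- function(records, config = filter_config(),
                          patient_populations = NULL, pon_hits = NULL) {
  need <- c("variant_id", "patient", "population", "alt", "depth")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  if (!is.null(patient_populations)) {
    for (pat in unique(records$patient)) {
      pops <- unique(records$population[records$patient == pat])
      known <- patient_populations[[as.character(pat)]]
      if (is.null(known) || !all(pops %in% known)) {
        stop("population referenced in records but absent from patient map (",
             pat, ")")
      }
    }
  }
  n <- nrow(records)
  vaf <- ifelse(records$depth > 0, records$alt / records$depth, 0)
  reads <- if (config$count_mode == "alt") records$alt else records$depth

  hits <- rep(0L, n)
  if (!is.null(pon_hits) && length(pon_hits)) {
    idx <- match(records$variant_id, names(pon_hits))
    hits <- ifelse(is.na(idx), 0L, as.integer(pon_hits[idx]))
  }
  pon_fail <- hits > config$pon_max_hits
  vaf_ok <- vaf >= config$vaf_min
  primary <- vaf_ok & reads >= config$min_alt_reads & !pon_fail
  relaxed_reads <- vaf_ok & reads >= config$shared_min_alt_reads & !pon_fail

  # variant passes primary in >=1 other population of the same patient
  key <- paste(records$patient, records$variant_id, sep = "\r")
  n_primary <- tapply(primary, key, sum)[key]
  sibling_primary <- (n_primary - primary) >= 1
  keep <- primary | (relaxed_reads & sibling_primary)

  reason <- rep("retained", n)
  reason[!keep & !vaf_ok] <- "vaf_below_min"
  reason[!keep & vaf_ok] <- "insufficient_reads"
  reason[pon_fail] <- "panel_of_normals"
  keep <- keep & !pon_fail

  tally <- vapply(c("retained", "panel_of_normals", "vaf_below_min",
                    "insufficient_reads"),
                  function(r) sum(reason == r), integer(1))
  list(retained = records[keep, , drop = FALSE], tally = tally)
}

#' Flag driver-gene mutations
#'
#' A record is flagged as a driver when its gene is on the driver list and
#' its effect class is non-synonymous.
#'
#' @param records data frame with columns `gene` and `effect`
#'   (`"synonymous"`, `"non_synonymous"`, or other classes).
#' @param driver_genes character vector of driver gene symbols.
#' @return `records` with a logical `driver` column appended.
#' @export
annotate_drivers <- function(records, driver_genes) {
  if (!all(c("gene", "effect") %in% names(records))) {
    stop("records must have 'gene' and 'effect' columns")
  }
  records$driver <- records$gene %in% driver_genes &
    records$effect == "non_synonymous"
  records
}

#' Driver gene-by-population clonality matrix
#'
#' Builds the driver presence/clonality matrix: one row per (patient, gene)
#' driver mutation, one column per population, entries `"clonal"`,
#' `"subclonal"`, or `""` (absent). A driver mutation counts as clonal when
#' it is clonal in every population where it is present.
#'
#' @param records long-format records annotated by [annotate_drivers()] with
#'   a `clonality` column (from [ccf_table()]) and columns `patient`,
#'   `population`, `gene`.
#' @return list with `matrix` (character), `n_driver` (distinct
#'   patient-gene driver mutations), `n_clonal`, and `clonal_pct`
#'   (one decimal).
#' @export
driver_clonality_matrix <- function(records) {
  need <- c("patient", "population", "gene", "driver", "clonality")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  d <- records[records$driver, , drop = FALSE]
  pops <- sort(unique(records$population))
  keys <- unique(d[, c("patient", "gene")])
  if (nrow(keys) == 0L) {
    return(list(matrix = matrix(character(0), 0, length(pops),
                                dimnames = list(NULL, pops)),
                n_driver = 0L, n_clonal = 0L, clonal_pct = NA_real_))
  }
  mat <- matrix("", nrow(keys), length(pops),
                dimnames = list(paste(keys$patient, keys$gene, sep = ":"), pops))
  clonal_all <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- d[d$patient == keys$patient[i] & d$gene == keys$gene[i], ]
    mat[i, as.character(sub$population)] <- sub$clonality
    clonal_all[i] <- all(sub$clonality == "clonal")
  }
  list(matrix = mat, n_driver = nrow(keys), n_clonal = sum(clonal_all),
       clonal_pct = as.numeric(round_half_up(100 * mean(clonal_all), 1)))
}

#' Tumor mutational burden
#'
#' @param n_mutations number of retained somatic mutations (synonymous plus
#'   non-synonymous) in one population, or a data frame of retained records
#'   for one population (rows counted by distinct `variant_id`).
#' @param callable_mb callable exome territory in megabases (> 0). The
#'   default, 35.7 Mb, is a typical whole-exome capture footprint; the value
#'   is a required input, not a constant of the method.
#' @return mutations per megabase, one decimal.
#' @export
tmb <- function(n_mutations, callable_mb = 35.7) {
  if (callable_mb <= 0) stop("callable megabases must be > 0")
  if (is.data.frame(n_mutations)) {
    n_mutations <- length(unique(n_mutations$variant_id))
  }
  as.numeric(round_half_up(n_mutations / callable_mb, 1))
}

#' Shared and private mutation summary for one patient
#'
#' Counts each mutation once per patient and classifies it as shared by all
#' of the patient's sorted populations, shared by some (at least two but not
#' all), or private to a single population. Percentages are reported to one
#' decimal.
#'
#' @param records retained long-format records of one patient (columns
#'   `variant_id`, `population`); each row is a population where the
#'   mutation passed filtering.
#' @param populations character vector of the patient's population ids
#'   (>= 2).
#' @return data frame with rows `shared_by_all`, `shared_by_some`,
#'   `private`; columns `count` and `pct`.
#' @export
shared_private_summary <- function(records, populations) {
  if (length(unique(populations)) < 2L) {
    stop("shared/private summary requires >= 2 populations")
  }
  if (!all(records$population %in% populations)) {
    stop("records contain populations not in 'populations'")
  }
  npop <- tapply(records$population, records$variant_id,
                 function(p) length(unique(p)))
  total <- length(npop)
  counts <- c(shared_by_all = sum(npop == length(unique(populations))),
              shared_by_some = sum(npop >= 2 & npop < length(unique(populations))),
              private = sum(npop == 1))
  data.frame(count = as.integer(counts),
             pct = as.numeric(round_half_up(100 * counts / max(total, 1), 1)),
             row.names = names(counts))
}
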