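# File formats. Genomic coordinates are 0-based half-open internally and
# converted at the VCF boundary (VCF POS is 1-based).

#' Write a variant table as MAF-like TSV
#'
#' @param variants long-format variant data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a MAF-like variant TSV
#'
#' @param path input path.
#' @return data frame.
#' @export
read_variants_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write per-population variant read counts as a multi-sample VCF
#'
#' One VCF sample column per population, with `GT:AD:DP` fields (AD as
#' `ref,alt`). Internal 0-based positions are converted to 1-based VCF POS.
#'
#' @param variants long-format data frame with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt_allele`, `population`, `alt`, `depth`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  pops <- sort(unique(as.character(variants$population)))
  ids <- unique(variants$variant_id)
  first <- variants[match(ids, variants$variant_id), ]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pops), collapse = "\t"))
  ridx <- cbind(match(variants$variant_id, ids),
                match(as.character(variants$population), pops))
  ALT <- DP <- matrix(0L, length(ids), length(pops))
  ALT[ridx] <- as.integer(variants$alt)
  DP[ridx] <- as.integer(variants$depth)
  sample_cols <- sapply(seq_along(pops), function(j) {
    sprintf("%s:%d,%d:%d", ifelse(ALT[, j] > 0, "0/1", "0/0"),
            DP[, j] - ALT[, j], ALT[, j], DP[, j])
  })
  sample_cols <- matrix(sample_cols, nrow = length(ids))
  body <- paste(first$chrom, first$pos + 1L, ids, first$ref,
                first$alt_allele, ".", "PASS", ".", "GT:AD:DP",
                apply(sample_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into the long variant format
#'
#' Uses the `vcfR` package; each sample column becomes a population, with
#' alt/ref depths taken from the `AD` field. POS is converted back to the
#' internal 0-based convention.
#'
#' @param path VCF path.
#' @return long-format data frame with columns `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt_allele`, `population`, `alt`, `depth`, `vaf`.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  pops <- colnames(ad)
  out <- do.call(rbind, lapply(pops, function(p) {
    parts <- strsplit(ad[, p], ",", fixed = TRUE)
    ref_d <- as.integer(vapply(parts, `[`, character(1), 1))
    alt_d <- as.integer(vapply(parts, `[`, character(1), 2))
    depth <- ref_d + alt_d
    data.frame(variant_id = fix$ID, chrom = fix$CHROM,
               pos = as.integer(fix$POS) - 1L, ref = fix$REF,
               alt_allele = fix$ALT, population = p,
               alt = alt_d, depth = depth,
               vaf = ifelse(depth > 0, alt_d / depth, 0))
  }))
  rownames(out) <- NULL
  out
}

#' Write copy-number segments as TSV
#'
#' @param profile segment data frame (`chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn`, optionally `log_ratio`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cn_segments <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a copy-number segment TSV
#' @param path input path.
#' @return data frame validated as a segment profile.
#' @export
read_cn_segments <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_profile(p)
  p
}

#' Write FACS events as CSV
#' @param events event data frame (`event_id`, `dapi`, `marker`, ...).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_facs_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FACS event CSV
#' @param path input path.
#' @return data frame with at least `dapi` and `marker` columns.
#' @export
read_facs_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dapi", "marker") %in% names(ev))) {
    stop("FACS event table needs 'dapi' and 'marker' columns")
  }
  ev
}

#' Read a driver gene list (one symbol per line)
#' @param path input path.
#' @return character vector of gene symbols.
#' @export
read_driver_genes <- function(path) {
  g <- trimws(readLines(path))
  g[nzchar(g) & !startsWith(g, "#")]
}

#' Bundled characteristics of eight flow-sorted melanoma populations
#'
#' Loads the packaged summary table of eight sorted tumor populations from
#' three melanoma patients (FACS ploidy, pre-sort purity by FACS, post-sort
#' purity by WES), used in examples and the worked analyses.
#'
#' @return data frame with columns `patient`, `biopsy`, `population`,
#'   `ploidy_facs`, `purity_presort_pct`, `purity_postsort_pct`.
#' @export
sorted_population_characteristics <- function() {
  utils::read.delim(system.file("extdata", "sorted_population_characteristics.tsv",
                                package = "clonesort"),
                    stringsAsFactors = FALSE)
}
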