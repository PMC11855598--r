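#' The 96 single-base-substitution channels
#'
#' Pyrimidine-centered trinucleotide channels in the standard order:
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, and within each class
#' the 16 flank combinations with 5' and 3' bases cycling A, C, G, T.
#' Labels use the `A[C>A]A` convention.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(b5) {
      paste0(b5, "[", s, "]", bases)
    }))
  }))
}

#' Toy mutational-signature reference (synthetic)
#'
#' A small synthetic 96 x 4 reference for tests and simulations, so that no
#' external signature database is required. The four columns caricature
#' well-known processes without reproducing any real signature:
#' \describe{
#'   \item{UV.like}{C>T concentrated at dipyrimidines (5' C or T), the
#'     UV-exposure fingerprint (cf. SBS7a/b).}
#'   \item{Platinum.like}{C>A- and T>A-heavy, caricaturing platinum
#'     chemotherapy damage (cf. SBS31).}
#'   \item{Alkylating.like}{C>T at 5' G contexts, caricaturing alkylating
#'     agents (cf. SBS11).}
#'   \item{Flat}{uniform background.}
#' }
#' Columns sum to 1.
#'
#' @return 96 x 4 numeric matrix, rownames the channels, colnames as above.
#' @export
toy_signature_reference <- function() {
  ch <- sbs96_channels()
  sub <- sub(".*\\[(.+)\\].*", "\\1", ch)
  f5 <- substr(ch, 1, 1)

  uv <- ifelse(sub == "C>T" & f5 %in% c("C", "T"), 10,
        ifelse(sub == "C>T", 1, 0.1))
  platinum <- ifelse(sub == "C>A", 6, ifelse(sub == "T>A", 3, 0.2))
  alkyl <- ifelse(sub == "C>T" & f5 == "G", 12, ifelse(sub == "T>C", 1, 0.1))
  flat <- rep(1, 96)

  ref <- cbind(UV.like = uv / sum(uv),
               Platinum.like = platinum / sum(platinum),
               Alkylating.like = alkyl / sum(alkyl),
               Flat = flat / sum(flat))
  rownames(ref) <- ch
  ref
}

#' Read a COSMIC-format signature reference
#'
#' Expects a TSV with a `Type` column of channel labels (`A[C>A]A` style) and
#' one numeric column per signature. Rows are reordered to the standard
#' channel order and columns renormalized to sum to 1.
#'
#' @param path path to the TSV file.
#' @return 96 x S numeric matrix.
#' @export
read_signature_reference <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Type" %in% names(tab)) stop("signature reference needs a 'Type' column")
  ch <- sbs96_channels()
  if (!all(ch %in% tab$Type)) stop("signature reference is missing channels")
  m <- as.matrix(tab[match(ch, tab$Type), setdiff(names(tab), "Type"), drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) stop("malformed signature reference")
  rownames(m) <- ch
  sweep(m, 2, colSums(m), "/")
}

check_spectrum <- function(spectrum) {
  if (length(spectrum) != 96L) stop("spectrum must have 96 channels")
  if (any(spectrum < 0) || any(!is.finite(spectrum))) {
    stop("spectrum entries must be finite and non-negative")
  }
  if (sum(spectrum) <= 0) stop("cannot refit an all-zero spectrum")
  invisible(TRUE)
}

#' Refit a 96-channel spectrum against a signature reference
#'
#' Non-negative least squares of the observed spectrum on the reference
#' columns; the fitted weights are normalized to contribution fractions.
#'
#' @param spectrum numeric vector of 96 channel counts (standard order).
#' @param reference 96 x S matrix with columns summing to 1 (e.g.
#'   [toy_signature_reference()] or [read_signature_reference()]).
#' @return list with `fractions` (named, summing to 1), `weights` (raw NNLS
#'   solution, in mutation units), and `residual` (Euclidean norm of the
#'   fit residual).
#' @export
refit_signatures <- function(spectrum, reference) {
  check_spectrum(spectrum)
  if (!is.matrix(reference) || nrow(reference) != 96L) {
    stop("reference must be a 96-row matrix")
  }
  cs <- colSums(reference)
  if (any(abs(cs - 1) > 1e-6)) stop("reference columns must each sum to 1")
  if (sum(spectrum) < 10) {
    warning("refitting a spectrum with fewer than 10 mutations is unstable")
  }
  fit <- pracma::lsqnonneg(reference, as.numeric(spectrum))
  w <- fit$x
  names(w) <- colnames(reference)
  if (sum(w) <= 0) stop("degenerate NNLS solution (all-zero weights)")
  list(fractions = w / sum(w), weights = w,
       residual = sqrt(sum((spectrum - reference %*% w)^2)))
}

#' Pool minor signature contributions into "others"
#'
#' Signatures contributing strictly less than `threshold` are summed into a
#' single `others` component; the total is preserved.
#'
#' @param fractions named numeric vector of contribution fractions.
#' @param threshold pooling threshold (default 0.05; contributions exactly at
#'   the threshold are kept).
#' @return named numeric vector; minor components replaced by `others`.
#' @export
group_others <- function(fractions, threshold = 0.05) {
  minor <- fractions < threshold
  if (!any(minor)) return(fractions)
  out <- c(fractions[!minor], others = sum(fractions[minor]))
  out
}

#' 96-channel spectrum from variant trinucleotide contexts
#'
#' @param context character vector of channel labels (`A[C>A]A` style);
#'   `NA` entries (non-SNVs) are dropped.
#' @return named integer vector of length 96 in standard channel order.
#' @export
context_spectrum <- function(context) {
  ch <- sbs96_channels()
  context <- context[!is.na(context)]
  bad <- setdiff(unique(context), ch)
  if (length(bad)) stop("unknown context channel(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(context, levels = ch))
  out <- as.integer(tab)
  names(out) <- ch
  out
}
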