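#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq
#' @importFrom stats lm coef quantile rnorm runif rbinom rpois rnbinom
#'   plogis qlogis binom.test fisher.test wilcox.test rlnorm setNames
#'   aggregate weighted.mean predict
#' @importFrom utils read.delim write.table head
NULL

.STOP_CODONS <- c("TAA", "TGA", "TAG")
.DNA_BASES <- c("A", "C", "G", "T")
.KOZAK_LEVELS <- c("weak", "moderate", "strong")
.CONSEQUENCES <- c("uORF_created", "uORF_elongated", "oORF_out_of_frame",
                   "CDS_elongation")
.KINDS <- c("uAUG_created", "uSTOP_removed", "uORF_frameshifted")

#' TranscriptSet: spliced 5'UTR + CDS-prefix transcript models
#'
#' A container for transcript models used throughout the package. Each
#' element carries the spliced 5'UTR sequence (sense strand, 5'->3') and
#' the first bases of the coding sequence beginning with the canonical
#' AUG. All transcript coordinates in the package are 1-based positions
#' into the concatenation `utr + cdsPrefix`; the UTR occupies positions
#' `1..L` and the CDS starts at `L + 1`, where `L = utrLength()`.
#'
#' @slot geneId character vector of gene identifiers.
#' @slot txId character vector of transcript identifiers (unique).
#' @slot utr [Biostrings::DNAStringSet] of spliced 5'UTR sequences
#'   (width 0 allowed: transcripts with no annotated UTR are retained and
#'   flagged; they feed gene class 0).
#' @slot cds [Biostrings::DNAStringSet] of CDS prefixes (>= 3 nt, starting
#'   with ATG for canonical-complete transcripts).
#' @slot canonical logical; when TRUE the CDS-prefix-starts-with-ATG
#'   invariant is enforced for that transcript.
#' @slot exons list, one element per transcript: either NULL or a
#'   data.frame with columns chrom, start, end, strand giving the genomic
#'   exon blocks (5'->3' in transcript order) covering UTR + CDS prefix,
#'   used for genomic <-> transcript coordinate mapping.
#'
#' @seealso [loadTranscripts()], [applyVariant()], [findUorfs()]
#' @export
setClass("TranscriptSet",
  representation(
    geneId = "character",
    txId = "character",
    utr = "DNAStringSet",
    cds = "DNAStringSet",
    canonical = "logical",
    exons = "list"
  )
)

setValidity("TranscriptSet", function(object) {
  msgs <- character(0)
  n <- length(object@txId)
  if (length(object@geneId) != n) msgs <- c(msgs, "geneId length mismatch")
  if (length(object@utr) != n) msgs <- c(msgs, "utr length mismatch")
  if (length(object@cds) != n) msgs <- c(msgs, "cds length mismatch")
  if (length(object@canonical) != n) msgs <- c(msgs, "canonical length mismatch")
  if (length(object@exons) != n) msgs <- c(msgs, "exons length mismatch")
  if (anyDuplicated(object@txId)) msgs <- c(msgs, "duplicated transcript ids")
  if (n > 0 && length(msgs) == 0) {
    bad <- .nonACGTN(as.character(object@utr)) | .nonACGTN(as.character(object@cds))
    if (any(bad)) {
      msgs <- c(msgs, paste0("characters outside A/C/G/T/N in: ",
                             paste(object@txId[bad], collapse = ", ")))
    }
    short <- Biostrings::width(object@cds) < 3L
    if (any(short)) {
      msgs <- c(msgs, paste0("cds prefix shorter than 3 nt: ",
                             paste(object@txId[short], collapse = ", ")))
    }
    if (any(!short)) {
      starts <- substr(as.character(object@cds), 1L, 3L)
      badatg <- object@canonical & !short & starts != "ATG"
      if (any(badatg)) {
        msgs <- c(msgs, paste0("canonical cds prefix not starting with ATG: ",
                               paste(object@txId[badatg], collapse = ", ")))
      }
    }
    for (i in seq_len(n)) {
      ex <- object@exons[[i]]
      if (is.null(ex)) next
      if (!all(c("chrom", "start", "end", "strand") %in% names(ex))) {
        msgs <- c(msgs, paste0("exon block columns missing for ", object@txId[i]))
        next
      }
      w <- sum(ex$end - ex$start + 1L)
      need <- Biostrings::width(object@utr)[i] + Biostrings::width(object@cds)[i]
      if (w != need) {
        msgs <- c(msgs, paste0("exon blocks of ", object@txId[i],
                               " cover ", w, " bases, expected ", need))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

.nonACGTN <- function(x) {
  vapply(x, function(s) grepl("[^ACGTN]", s), logical(1), USE.NAMES = FALSE)
}

#' MutabilityTable: context-dependent mutation rates
#'
#' Scaled per-base, per-generation mutation rates keyed by trinucleotide
#' substitution context (e.g. `"ACG>ATG"`) and CpG methylation bin. Rates
#' are scaled so that the possible-site-weighted mean equals `targetMean`
#' (the human per-base per-generation rate, 1.2e-8, by default).
#'
#' @slot rates data.frame with columns context, methylation_bin,
#'   n_possible, n_observed, rate.
#' @slot targetMean numeric scalar, the weighted-mean constraint.
#' @export
setClass("MutabilityTable",
  representation(rates = "data.frame", targetMean = "numeric")
)

setValidity("MutabilityTable", function(object) {
  r <- object@rates
  msgs <- character(0)
  need <- c("context", "methylation_bin", "n_possible", "rate")
  if (!all(need %in% names(r))) {
    return(paste("rates must have columns", paste(need, collapse = ", ")))
  }
  if (any(r$rate <= 0)) msgs <- c(msgs, "all rates must be > 0")
  if (nrow(r)) {
    wm <- sum(r$rate * r$n_possible) / sum(r$n_possible)
    if (abs(wm - object@targetMean) > 1e-12 * object@targetMean) {
      msgs <- c(msgs, "possible-site-weighted mean rate != targetMean")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CalibrationModel: mutation rate -> expected singleton proportion
#'
#' Linear map from scaled mutation rate to the expected proportion of
#' singletons, fitted on a neutral (synonymous) variant class. Predictions
#' are clipped to \[0, 1\].
#'
#' @slot intercept,slope numeric regression coefficients.
#' @slot weighted logical; was the fit weighted by per-group variant count.
#' @slot groups data.frame of the per-(context, bin) fitting points
#'   (context, methylation_bin, rate, prop_singleton, n).
#' @export
setClass("CalibrationModel",
  representation(intercept = "numeric", slope = "numeric",
                 weighted = "logical", groups = "data.frame")
)

#' MapsResult: the MAPS statistic with resampling uncertainty
#'
#' MAPS = (observed singletons - expected singletons) / observed variants,
#' where the expectation is calibrated from mutation rates. `ci90` is the
#' 5th-95th bootstrap percentile interval (NA until computed).
#'
#' @slot nObserved,nSingletons integer counts.
#' @slot expectedSingletons numeric, calibrated expectation.
#' @slot maps numeric point estimate.
#' @slot ci90 numeric length-2 (low, high), possibly NA.
#' @slot nBoot integer, bootstrap replicates used (0 if none).
#' @slot seed integer seed used for the bootstrap (NA if none).
#' @export
setClass("MapsResult",
  representation(nObserved = "integer", nSingletons = "integer",
                 expectedSingletons = "numeric", maps = "numeric",
                 ci90 = "numeric", nBoot = "integer", seed = "integer")
)

setValidity("MapsResult", function(object) {
  msgs <- character(0)
  m <- (object@nSingletons - object@expectedSingletons) / object@nObserved
  if (abs(m - object@maps) > 1e-10) msgs <- c(msgs, "maps != (obs - exp)/n")
  if (object@maps < -1 || object@maps > 1) msgs <- c(msgs, "maps outside [-1, 1]")
  if (length(object@ci90) != 2) msgs <- c(msgs, "ci90 must have length 2")
  if (!anyNA(object@ci90) && object@ci90[1] > object@ci90[2]) {
    msgs <- c(msgs, "ci90 low > high")
  }
  if (length(msgs)) msgs else TRUE
})
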