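#' Construct a TranscriptSet
#'
#' @param geneId,txId character vectors of identifiers.
#' @param utr,cds character vectors or [Biostrings::DNAStringSet] of
#'   spliced 5'UTR sequences and CDS prefixes.
#' @param canonical logical; enforce the ATG-start invariant on the CDS
#'   prefix (recycled).
#' @param exons list of per-transcript exon-block data.frames (or NULL).
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT")
#' utrLength(ts)
#' @export
TranscriptSet <- function(geneId, txId, utr, cds, canonical = TRUE,
                          exons = NULL) {
  n <- length(txId)
  if (!is(utr, "DNAStringSet")) utr <- DNAStringSet(toupper(utr))
  if (!is(cds, "DNAStringSet")) cds <- DNAStringSet(toupper(cds))
  if (is.null(exons)) exons <- rep(list(NULL), n)
  new("TranscriptSet",
      geneId = as.character(geneId), txId = as.character(txId),
      utr = utr, cds = cds,
      canonical = rep_len(canonical, n), exons = exons)
}

#' @describeIn TranscriptSet Number of transcripts.
#' @param x A TranscriptSet.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@txId))

#' @describeIn TranscriptSet Transcript identifiers.
#' @export
setMethod("names", "TranscriptSet", function(x) x@txId)

#' @describeIn TranscriptSet Subset by index, logical or transcript id.
#' @param i index, logical mask or transcript id.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@txId)
    if (anyNA(idx)) stop("unknown transcript id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  new("TranscriptSet", geneId = x@geneId[i], txId = x@txId[i],
      utr = x@utr[i], cds = x@cds[i], canonical = x@canonical[i],
      exons = x@exons[i])
})

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object)
  cat("TranscriptSet with", n, "transcript(s)\n")
  if (n) {
    L <- Biostrings::width(object@utr)
    cat("  UTR length: min", min(L), "/ median", stats::median(L),
        "/ max", max(L), "| no-UTR:", sum(L == 0L), "\n")
    show_n <- min(n, 5L)
    for (i in seq_len(show_n)) {
      cat(sprintf("  %s (%s): L=%d, cds=%s...\n", object@txId[i],
                  object@geneId[i], L[i],
                  substr(as.character(object@cds[i]), 1, 6)))
    }
    if (n > show_n) cat("  ...\n")
  }
})

#' Accessors for TranscriptSet
#'
#' `utrSeq()` and `cdsPrefix()` return the sequences as
#' [Biostrings::DNAStringSet]; `utrLength()` the UTR lengths (the symbol
#' `L` used in all distance/frame arithmetic); `geneIds()`/`txIds()` the
#' identifiers; `hasUtr()` flags transcripts with a non-empty UTR;
#' `exonBlocks()` the genomic exon blocks (or NULL).
#'
#' @param x A [TranscriptSet-class].
#' @return See description.
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
setGeneric("utrSeq", function(x) standardGeneric("utrSeq"))
#' @rdname transcript-accessors
#' @export
setMethod("utrSeq", "TranscriptSet", function(x) setNames(x@utr, x@txId))

#' @rdname transcript-accessors
#' @export
setGeneric("cdsPrefix", function(x) standardGeneric("cdsPrefix"))
#' @rdname transcript-accessors
#' @export
setMethod("cdsPrefix", "TranscriptSet", function(x) setNames(x@cds, x@txId))

#' @rdname transcript-accessors
#' @export
setGeneric("utrLength", function(x) standardGeneric("utrLength"))
#' @rdname transcript-accessors
#' @export
setMethod("utrLength", "TranscriptSet",
          function(x) setNames(Biostrings::width(x@utr), x@txId))

#' @rdname transcript-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname transcript-accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x) setNames(x@geneId, x@txId))

#' @rdname transcript-accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @rdname transcript-accessors
#' @export
setMethod("txIds", "TranscriptSet", function(x) x@txId)

#' @rdname transcript-accessors
#' @export
setGeneric("hasUtr", function(x) standardGeneric("hasUtr"))
#' @rdname transcript-accessors
#' @export
setMethod("hasUtr", "TranscriptSet",
          function(x) setNames(Biostrings::width(x@utr) > 0L, x@txId))

#' @rdname transcript-accessors
#' @export
setGeneric("exonBlocks", function(x) standardGeneric("exonBlocks"))
#' @rdname transcript-accessors
#' @export
setMethod("exonBlocks", "TranscriptSet", function(x) setNames(x@exons, x@txId))

setMethod("show", "MutabilityTable", function(object) {
  cat("MutabilityTable:", nrow(object@rates), "(context, methylation bin) classes\n")
  cat("  weighted mean rate:", format(object@targetMean, digits = 4),
      "per base per generation\n")
  cat("  rate range:", format(range(object@rates$rate), digits = 4), "\n")
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel: p(singleton) =",
      format(object@intercept, digits = 5), "+",
      format(object@slope, digits = 5), "* rate",
      if (object@weighted) "(weighted fit)" else "(unweighted fit)", "\n")
  cat("  fitted on", nrow(object@groups), "context groups\n")
})

setMethod("show", "MapsResult", function(object) {
  cat("MapsResult\n")
  cat(sprintf("  observed variants : %d\n", object@nObserved))
  cat(sprintf("  observed singletons: %d\n", object@nSingletons))
  cat(sprintf("  expected singletons: %.2f\n", object@expectedSingletons))
  cat(sprintf("  MAPS              : %.4f\n", object@maps))
  if (!anyNA(object@ci90)) {
    cat(sprintf("  90%% bootstrap CI  : [%.4f, %.4f] (%d replicates, seed %d)\n",
                object@ci90[1], object@ci90[2], object@nBoot, object@seed))
  }
})

#' Extract the MAPS point estimate and components
#'
#' @param x A [MapsResult-class].
#' @return `maps()` the point estimate; `as.data.frame()` a one-row
#'   data.frame with all components.
#' @export
setGeneric("maps", function(x) standardGeneric("maps"))
#' @rdname maps
#' @export
setMethod("maps", "MapsResult", function(x) x@maps)

#' @rdname maps
#' @param row.names,optional,... passed conventions; ignored.
#' @export
setMethod("as.data.frame", "MapsResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(n_observed = x@nObserved, n_singletons = x@nSingletons,
               expected_singletons = x@expectedSingletons, maps = x@maps,
               ci90_low = x@ci90[1], ci90_high = x@ci90[2],
               n_boot = x@nBoot, seed = x@seed)
  })
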