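#' Build per-gene annotation for the triage
#'
#' Combines annotation-derived counts with externally supplied gene
#' metadata into the per-gene table consumed by [classifyGenes()].
#' Annotation-derived fields are computed, never sampled: `has_utr` from
#' the transcript models, `n_possible_perturbing` /
#' `n_possible_high_impact` from the enumerated SNV consequence records,
#' `has_high_confidence_oorf` from existing oORFs (uAUG with no in-frame
#' UTR stop) with a strong/moderate Kozak or translation evidence.
#' `max_high_impact_ac` is the highest population allele count among
#' high-impact SNVs (from `populationAc`, a data.frame keyed by
#' transcript_id, pos, alt with column allele_count); 0 when absent.
#'
#' @param transcripts a [TranscriptSet-class].
#' @param consequences enumerated SNV consequence records (uAUG-creating
#'   plus stop-removing).
#' @param uorfs output of [findUorfs()].
#' @param metadata data.frame keyed by gene_id with columns loeuf_sextile,
#'   curated_hi, ddg2p_lof, clinvar_lof_count (missing genes/columns are
#'   defaulted with a warning).
#' @param populationAc optional allele-count table (transcript_id, pos,
#'   alt, allele_count).
#' @return data.frame, one row per gene, ready for [classifyGenes()].
#' @export
buildGeneAnnotation <- function(transcripts, consequences, uorfs,
                                metadata = NULL, populationAc = NULL) {
  gid <- geneIds(transcripts)
  genes <- unique(unname(gid))
  txGene <- setNames(unname(gid), txIds(transcripts))
  hasU <- tapply(hasUtr(transcripts), txGene[txIds(transcripts)], any)

  cq <- consequences
  cq$gene_id <- txGene[cq$transcript_id]
  nPert <- tapply(rep(1L, nrow(cq)), cq$gene_id, sum)
  nHigh <- tapply(as.integer(cq$high_impact), cq$gene_id, sum)

  oo <- uorfs[uorfs$is_oorf, , drop = FALSE]
  hcOorf <- rep(FALSE, length(genes))
  names(hcOorf) <- genes
  if (nrow(oo)) {
    hc <- oo$kozak %in% c("strong", "moderate") | oo$evidence
    g <- tapply(hc, txGene[oo$transcript_id], any)
    hcOorf[names(g)] <- g
  }

  maxAc <- rep(0L, length(genes))
  names(maxAc) <- genes
  if (!is.null(populationAc) && nrow(populationAc)) {
    hi <- cq[cq$high_impact, , drop = FALSE]
    key <- paste(hi$transcript_id, hi$pos, hi$alt)
    pkey <- paste(populationAc$transcript_id, populationAc$pos, populationAc$alt)
    idx <- match(pkey, key)
    hit <- !is.na(idx)
    if (any(hit)) {
      ac <- tapply(populationAc$allele_count[hit],
                   hi$gene_id[idx[hit]], max)
      maxAc[names(ac)] <- as.integer(ac)
    }
  }

  ann <- data.frame(
    gene_id = genes,
    has_utr = as.logical(unname(hasU[genes])),
    n_possible_perturbing = as.integer(ifelse(is.na(nPert[genes]), 0L,
                                              nPert[genes])),
    n_possible_high_impact = as.integer(ifelse(is.na(nHigh[genes]), 0L,
                                               nHigh[genes])),
    has_high_confidence_oorf = unname(hcOorf[genes]),
    max_high_impact_ac = unname(maxAc[genes]),
    stringsAsFactors = FALSE)
  rownames(ann) <- NULL

  metaCols <- c("loeuf_sextile", "curated_hi", "ddg2p_lof", "clinvar_lof_count")
  defaults <- list(loeuf_sextile = NA_integer_, curated_hi = FALSE,
                   ddg2p_lof = FALSE, clinvar_lof_count = 0L)
  if (is.null(metadata)) {
    warning("no gene metadata supplied; LOEUF/curation fields defaulted")
    for (cl in metaCols) ann[[cl]] <- rep(defaults[[cl]], nrow(ann))
  } else {
    idx <- match(ann$gene_id, metadata$gene_id)
    for (cl in metaCols) {
      vals <- if (cl %in% names(metadata)) metadata[[cl]][idx] else {
        warning("metadata column '", cl, "' missing; defaulted")
        rep(defaults[[cl]], nrow(ann))
      }
      miss <- is.na(vals) & !is.na(defaults[[cl]])
      vals[miss] <- defaults[[cl]]
      ann[[cl]] <- vals
    }
    if (anyNA(idx)) warning(sum(is.na(idx)), " gene(s) missing from metadata")
  }
  ann
}

#' Nine-class gene triage for uORF-perturbing variation
#'
#' Assigns each gene to one of nine classes by the first matching rule,
#' evaluated in the order 0, 1, 2, 3, 4, 5, 8, 7, 6 (known
#' haploinsufficient/LoF disease genes are claimed by class 8 before the
#' intolerance rule of class 7):
#'
#' * 0 - no annotated 5'UTR;
#' * 1 - no possible uAUG-creating or stop-removing SNVs;
#' * 2 - none of the possible SNVs is high-impact;
#' * 3 - the UTR already has a high-confidence oORF (strong/moderate
#'   Kozak or documented translation), so creating another is low-impact;
#' * 4 - some high-impact SNV is already common in the population
#'   (allele count > `acThreshold`, i.e. AF > 0.1% at cohort scale);
#' * 5 - LoF-tolerant gene (LOEUF sextile 6);
#' * 8 - curated haploinsufficient, dominant-LoF developmental-disorder
#'   gene, or >= 10 high-confidence pathogenic LoF ClinVar variants;
#' * 7 - LoF-intolerant (LOEUF sextile 1) or >= 2 pathogenic LoF ClinVar
#'   variants;
#' * 6 - everything else.
#'
#' Classes map to the likelihood that a high-impact uORF-perturbing
#' variant would be deleterious: low (2-5), moderate (6), high (7-8),
#' unclassified (0-1).
#'
#' @param annotation data.frame from [buildGeneAnnotation()] (columns
#'   gene_id, has_utr, n_possible_perturbing, n_possible_high_impact,
#'   has_high_confidence_oorf, max_high_impact_ac, loeuf_sextile,
#'   curated_hi, ddg2p_lof, clinvar_lof_count; missing metadata treated
#'   as false/0 with a warning).
#' @param acThreshold population allele-count cutoff for class 4
#'   (default 15: AF > 0.1% in 15,708 genomes).
#' @return data.frame with columns gene_id, gene_class (0-8), likelihood.
#' @export
classifyGenes <- function(annotation, acThreshold = 15L) {
  a <- annotation
  for (cl in c("curated_hi", "ddg2p_lof")) {
    if (anyNA(a[[cl]])) {
      warning("NA in ", cl, " treated as FALSE")
      a[[cl]][is.na(a[[cl]])] <- FALSE
    }
  }
  if (anyNA(a$clinvar_lof_count)) {
    warning("NA in clinvar_lof_count treated as 0")
    a$clinvar_lof_count[is.na(a$clinvar_lof_count)] <- 0L
  }
  sext <- a$loeuf_sextile
  sext[is.na(sext)] <- 0L  # matches neither tolerant nor intolerant rule
  n <- nrow(a)
  cls <- rep(NA_integer_, n)
  rules <- list(
    `0` = !a$has_utr,
    `1` = a$n_possible_perturbing == 0L,
    `2` = a$n_possible_high_impact == 0L,
    `3` = a$has_high_confidence_oorf,
    `4` = a$max_high_impact_ac > acThreshold,
    `5` = sext == 6L,
    `8` = a$curated_hi | a$ddg2p_lof | a$clinvar_lof_count >= 10L,
    `7` = sext == 1L | a$clinvar_lof_count >= 2L,
    `6` = rep(TRUE, n)
  )
  for (k in names(rules)) {
    hit <- is.na(cls) & rules[[k]]
    cls[hit] <- as.integer(k)
  }
  likelihood <- rep("unclassified", n)
  likelihood[cls %in% 2:5] <- "low"
  likelihood[cls == 6L] <- "moderate"
  likelihood[cls %in% 7:8] <- "high"
  data.frame(gene_id = a$gene_id, gene_class = cls, likelihood = likelihood,
             stringsAsFactors = FALSE)
}

#' Summarise gene counts per likelihood group
#'
#' @param classifications output of [classifyGenes()].
#' @return named integer vector over low, moderate, high, unclassified
#'   (sums to the number of input genes).
#' @export
likelihoodSummary <- function(classifications) {
  lv <- c("low", "moderate", "high", "unclassified")
  out <- table(factor(classifications$likelihood, levels = lv))
  setNames(as.integer(out), lv)
}
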