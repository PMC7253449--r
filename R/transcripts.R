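#' Load transcript models from FASTA + transcript table
#'
#' Reads spliced transcript sequences (5'UTR followed by the CDS prefix,
#' sense strand, 5'->3') from a FASTA file keyed by transcript id, and a
#' TSV table with header `gene_id, transcript_id, utr_length,
#' cds_prefix_length` giving how each record splits into UTR and CDS
#' prefix. Zero-length UTRs are retained (see [hasUtr()]); they feed gene
#' class 0 in the triage.
#'
#' @param pathFasta path to the transcript FASTA.
#' @param pathTable path to the transcript table TSV.
#' @return A [TranscriptSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(">T1", "ACGTTTGATGGCT"), fa)
#' writeLines(c("gene_id\ttranscript_id\tutr_length\tcds_prefix_length",
#'              "G1\tT1\t7\t6"), tsv)
#' ts <- loadTranscripts(fa, tsv)
#' as.character(utrSeq(ts))
#' @export
loadTranscripts <- function(pathFasta, pathTable) {
  seqs <- readDNAStringSet(pathFasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- read.delim(pathTable, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "utr_length", "cds_prefix_length")
  if (!all(need %in% names(tab))) {
    stop("transcript table must have columns: ", paste(need, collapse = ", "))
  }
  miss <- setdiff(tab$transcript_id, names(seqs))
  if (length(miss)) {
    stop("missing FASTA record(s) for transcript(s): ",
         paste(miss, collapse = ", "))
  }
  seqs <- seqs[tab$transcript_id]
  chars <- as.character(seqs)
  if (any(.nonACGTN(chars))) {
    stop("characters outside A/C/G/T/N in FASTA record(s): ",
         paste(tab$transcript_id[.nonACGTN(chars)], collapse = ", "))
  }
  want <- tab$utr_length + tab$cds_prefix_length
  short <- nchar(chars) < want
  if (any(short)) {
    stop("sequence shorter than annotation for: ",
         paste(tab$transcript_id[short], collapse = ", "))
  }
  utr <- substr(chars, 1L, tab$utr_length)
  cds <- substr(chars, tab$utr_length + 1L, want)
  TranscriptSet(tab$gene_id, tab$transcript_id, utr, cds)
}

#' Load transcript models from GFF3 + genome FASTA
#'
#' Alternate reader consuming `five_prime_UTR` and `CDS` features from a
#' GFF3 file (grouped by the `Parent`/`transcript_id` attribute) plus a
#' genome FASTA. Minus-strand features are reverse-complemented and
#' ordered 5'->3' so that `utrSeq()` is always the sense-strand spliced
#' sequence. The genomic exon blocks are retained for coordinate mapping
#' (see [readVcfVariants()]).
#'
#' @param pathGff3 path to a GFF3 file.
#' @param pathGenome path to the genome FASTA (one record per chromosome).
#' @param cdsPrefixLength how many CDS bases to keep (default 9).
#' @return A [TranscriptSet-class] with exon blocks populated.
#' @export
readGff3Transcripts <- function(pathGff3, pathGenome, cdsPrefixLength = 9L) {
  gff <- rtracklayer::import(pathGff3, format = "gff3")
  genome <- readDNAStringSet(pathGenome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  df <- as.data.frame(gff)
  txOf <- function(d) {
    p <- if (!is.null(d$Parent)) as.character(unlist(d$Parent)) else NULL
    if (is.null(p) || !length(p)) p <- as.character(d$transcript_id)
    sub("^transcript:", "", p)
  }
  utrF <- df[df$type == "five_prime_UTR", , drop = FALSE]
  cdsF <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(utrF) && !nrow(cdsF)) stop("no five_prime_UTR or CDS features in GFF3")
  utrF$tx <- txOf(utrF); cdsF$tx <- txOf(cdsF)
  txs <- unique(c(utrF$tx, cdsF$tx))
  pull <- function(blocks) {
    # blocks in transcript (5'->3') order
    pieces <- vapply(seq_len(nrow(blocks)), function(i) {
      chrom <- as.character(blocks$seqnames[i])
      if (!chrom %in% names(genome)) stop("chromosome absent from genome FASTA: ", chrom)
      s <- as.character(subseq(genome[[chrom]], blocks$start[i], blocks$end[i]))
      if (blocks$strand[i] == "-") {
        s <- as.character(reverseComplement(DNAStringSet(s)))
      }
      s
    }, character(1))
    paste(pieces, collapse = "")
  }
  orderBlocks <- function(b) {
    minus <- any(b$strand == "-")
    b[order(b$start, decreasing = minus), , drop = FALSE]
  }
  geneOf <- function(d) {
    g <- if (!is.null(d$gene_id)) as.character(d$gene_id) else txOf(d)
    g
  }
  utrSeqs <- character(length(txs)); cdsSeqs <- character(length(txs))
  genes <- character(length(txs)); exons <- vector("list", length(txs))
  for (k in seq_along(txs)) {
    ub <- orderBlocks(utrF[utrF$tx == txs[k], , drop = FALSE])
    cb <- orderBlocks(cdsF[cdsF$tx == txs[k], , drop = FALSE])
    if (!nrow(cb)) stop("transcript ", txs[k], " has no CDS feature")
    utrSeqs[k] <- if (nrow(ub)) pull(ub) else ""
    cdsFull <- pull(cb)
    if (nchar(cdsFull) < cdsPrefixLength) {
      stop("CDS of ", txs[k], " shorter than cdsPrefixLength")
    }
    cdsSeqs[k] <- substr(cdsFull, 1L, cdsPrefixLength)
    genes[k] <- if (nrow(ub)) geneOf(ub)[1] else geneOf(cb)[1]
    blocks <- rbind(
      if (nrow(ub)) data.frame(chrom = as.character(ub$seqnames),
                               start = ub$start, end = ub$end,
                               strand = as.character(ub$strand)),
      .clipCdsBlocks(cb, cdsPrefixLength)
    )
    exons[[k]] <- blocks
  }
  TranscriptSet(genes, txs, utrSeqs, cdsSeqs, exons = exons)
}

# keep only the genomic bases covering the first cdsPrefixLength CDS bases
.clipCdsBlocks <- function(cb, n) {
  out <- list()
  left <- n
  for (i in seq_len(nrow(cb))) {
    w <- cb$end[i] - cb$start[i] + 1L
    take <- min(w, left)
    if (take <= 0) break
    if (cb$strand[i] == "-") {
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(cb$seqnames[i]),
        start = cb$end[i] - take + 1L, end = cb$end[i],
        strand = as.character(cb$strand[i]))
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(cb$seqnames[i]),
        start = cb$start[i], end = cb$start[i] + take - 1L,
        strand = as.character(cb$strand[i]))
    }
    left <- left - take
  }
  do.call(rbind, out)
}

#' Read transcript-space variants from TSV
#'
#' Expects header `transcript_id, pos, ref, alt` with `pos` the 1-based
#' transcript coordinate of the first affected base (for a pure insertion,
#' the base before which `alt` is inserted), `ref`/`alt` possibly empty
#' (pure insertion / deletion, encoded as "" or "-" or "."). Variants are
#' validated against the transcripts: `ref` must match the sequence.
#'
#' @param path TSV path.
#' @param transcripts a [TranscriptSet-class] used for validation.
#' @return data.frame with columns transcript_id, pos, ref, alt.
#' @export
readVariantsTsv <- function(path, transcripts = NULL) {
  v <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(ref = "character", alt = "character"))
  need <- c("transcript_id", "pos", "ref", "alt")
  if (!all(need %in% names(v))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  v$ref <- toupper(ifelse(v$ref %in% c("-", ".", NA), "", v$ref))
  v$alt <- toupper(ifelse(v$alt %in% c("-", ".", NA), "", v$alt))
  if (any(v$ref == "" & v$alt == "")) stop("variant with both ref and alt empty")
  if (!is.null(transcripts)) {
    for (i in seq_len(nrow(v))) {
      .checkVariant(transcripts, v$transcript_id[i], v$pos[i], v$ref[i], v$alt[i])
    }
  }
  v[need]
}

#' Read variants from VCF and map to transcript coordinates
#'
#' Reads a VCF (via [vcfR::read.vcfR]) and maps each record onto every
#' transcript whose exon blocks cover it, producing transcript-space
#' variants. Only variants falling entirely within a single exon block of
#' the UTR + CDS-prefix model are mapped; multi-allelic records are split.
#' Transcripts must carry exon blocks (see [readGff3Transcripts()]).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param transcripts a [TranscriptSet-class] with exon blocks.
#' @return data.frame with columns transcript_id, pos, ref, alt (1-based
#'   transcript coordinates, minus-strand alleles reverse-complemented).
#' @export
readVcfVariants <- function(path, transcripts) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      hit <- .mapGenomicVariant(transcripts, fix$CHROM[i],
                                as.integer(fix$POS[i]), fix$REF[i], alt)
      if (!is.null(hit)) out[[length(out) + 1L]] <- hit
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  do.call(rbind, out)
}

.mapGenomicVariant <- function(ts, chrom, gpos, ref, alt) {
  # trim shared leading base of indel VCF encoding
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) > 1 || nchar(alt) > 1) {
    if (substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
      gpos <- gpos + 1L
    }
  }
  rows <- list()
  for (k in seq_along(ts@txId)) {
    ex <- ts@exons[[k]]
    if (is.null(ex)) next
    offset <- 0L
    for (b in seq_len(nrow(ex))) {
      w <- ex$end[b] - ex$start[b] + 1L
      span <- max(nchar(ref), 1L)
      if (ex$chrom[b] == chrom && gpos >= ex$start[b] &&
          gpos + span - 1L <= ex$end[b]) {
        if (ex$strand[b] == "-") {
          tpos <- offset + (ex$end[b] - (gpos + span - 1L)) + 1L
          rc <- function(s) if (nchar(s)) as.character(
            reverseComplement(DNAStringSet(s))) else ""
          if (nchar(ref) == 0L) {
            # insertion before gpos on + strand = after on - strand
            tpos <- offset + (ex$end[b] - gpos) + 1L + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = ts@txId[k], pos = tpos, ref = rc(ref),
            alt = rc(alt), stringsAsFactors = FALSE)
        } else {
          tpos <- offset + (gpos - ex$start[b]) + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = ts@txId[k], pos = tpos, ref = ref, alt = alt,
            stringsAsFactors = FALSE)
        }
        break
      }
      offset <- offset + w
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

.fullSeq <- function(ts, i) {
  paste0(as.character(ts@utr[[i]]), as.character(ts@cds[[i]]))
}

.checkVariant <- function(ts, txid, pos, ref, alt) {
  i <- match(txid, ts@txId)
  if (is.na(i)) stop("unknown transcript id: ", txid)
  L <- Biostrings::width(ts@utr)[i]
  full <- .fullSeq(ts, i)
  tot <- nchar(full)
  if (ref == "" && alt == "") stop("variant with both ref and alt empty")
  maxPos <- if (ref == "") tot + 1L else tot
  if (pos < 1L || pos > maxPos) {
    stop("variant position ", pos, " outside transcript ", txid,
         " (length ", tot, ")")
  }
  if (nchar(ref)) {
    found <- substr(full, pos, pos + nchar(ref) - 1L)
    if (found != ref) {
      stop("ref mismatch at ", txid, ":", pos, " expected '", ref,
           "' found '", found, "'")
    }
    if (pos <= L && pos + nchar(ref) - 1L > L) {
      stop("variant spans the UTR/CDS junction (unsupported)")
    }
  }
  invisible(i)
}

#' Apply a variant to a transcript model
#'
#' Returns a new [TranscriptSet-class] in which the targeted transcript's
#' concatenated sequence equals the original with `ref` replaced by `alt`
#' at `pos` (1-based; an insertion with `ref = ""` is placed immediately
#' before `pos`). Indels in the UTR change the UTR length `L` and never
#' the CDS prefix; variants spanning the UTR/CDS junction are rejected.
#'
#' @param x a [TranscriptSet-class].
#' @param transcriptId transcript to edit.
#' @param pos 1-based transcript coordinate of the first affected base.
#' @param ref,alt reference/alternate allele strings ("" for pure
#'   insertion / deletion).
#' @return A new TranscriptSet with the edited transcript.
#' @examples
#' ts <- TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT")
#' as.character(utrSeq(applyVariant(ts, "T1", 2, "C", "T")))
#' @export
applyVariant <- function(x, transcriptId, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  i <- .checkVariant(x, transcriptId, pos, ref, alt)
  L <- Biostrings::width(x@utr)[i]
  full <- .fullSeq(x, i)
  newFull <- paste0(substr(full, 1L, pos - 1L), alt,
                    substr(full, pos + nchar(ref), nchar(full)))
  inUtr <- pos <= L
  newL <- if (inUtr) L + nchar(alt) - nchar(ref) else L
  utr <- as.character(x@utr)
  cds <- as.character(x@cds)
  utr[i] <- substr(newFull, 1L, newL)
  cds[i] <- substr(newFull, newL + 1L, nchar(newFull))
  TranscriptSet(x@geneId, x@txId, utr, cds, canonical = x@canonical,
                exons = x@exons)
}

#' Write transcript models to FASTA + table
#'
#' Writes the formats that [loadTranscripts()] reads back: one FASTA
#' record per transcript (UTR followed by CDS prefix) and the transcript
#' table TSV.
#'
#' @param x a [TranscriptSet-class].
#' @param pathFasta,pathTable output paths.
#' @return Invisibly, the table data.frame.
#' @export
writeTranscripts <- function(x, pathFasta, pathTable) {
  full <- vapply(seq_along(x@txId), function(i) .fullSeq(x, i), character(1))
  seqs <- DNAStringSet(full)
  names(seqs) <- x@txId
  writeXStringSet(seqs, pathFasta)
  tab <- data.frame(gene_id = x@geneId, transcript_id = x@txId,
                    utr_length = Biostrings::width(x@utr),
                    cds_prefix_length = Biostrings::width(x@cds))
  write.table(tab, pathTable, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
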