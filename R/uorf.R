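#' Classify Kozak context strength at an AUG
#'
#' Scores the translation-initiation context of an AUG by the two bases
#' known to matter most: position -3 (three bases 5' of the A) and +3
#' (the base immediately 3' of the G, i.e. offset `plusOffset` from the
#' A). Strong: -3 in \{A, G\} and +3 == G; moderate: exactly one of the
#' two conditions; weak: neither. An absent -3 (AUG within the first
#' three transcript bases) counts as non-matching.
#'
#' @param seq character, the full transcript context (UTR followed by CDS
#'   prefix, so the +3 base can be drawn from the CDS).
#' @param augStart 1-based index of the A of the AUG in `seq`.
#' @param plusOffset offset of the downstream context base from the A
#'   (default 3, the base right after the G).
#' @return list with elements `value` ("strong"/"moderate"/"weak"),
#'   `minus3` and `plus3` (characters, `minus3` NA if absent).
#' @examples
#' classifyKozak("AAGATGGCC", 4)$value   # strong
#' classifyKozak("GCCATGTTT", 4)$value   # moderate
#' @export
classifyKozak <- function(seq, augStart, plusOffset = 3L) {
  if (augStart + plusOffset > nchar(seq)) {
    stop("sequence context too short for +", plusOffset,
         " base at AUG ", augStart, " (cds prefix too short)")
  }
  minus3 <- if (augStart >= 4L) substr(seq, augStart - 3L, augStart - 3L) else NA_character_
  plus3 <- substr(seq, augStart + plusOffset, augStart + plusOffset)
  mOk <- !is.na(minus3) && minus3 %in% c("A", "G")
  pOk <- plus3 == "G"
  value <- if (mOk && pOk) "strong" else if (mOk || pOk) "moderate" else "weak"
  list(value = value, minus3 = minus3, plus3 = plus3)
}

.kozakRank <- function(v) match(v, .KOZAK_LEVELS)

# 1-based start positions of all length-3 windows equal to any of `pats`
.windowMatches <- function(seq, pats) {
  L <- nchar(seq)
  if (L < 3L) return(integer(0))
  w <- substring(seq, seq_len(L - 2L), 3:L)
  which(w %in% pats)
}

# core single-transcript scan; utr/cds are character strings
.scanUorfs <- function(utr, cds, evidenceStops = integer(0), plusOffset = 3L) {
  L <- nchar(utr)
  empty <- data.frame(start = integer(0), stop_start = integer(0),
                      frame_vs_cds = integer(0), kozak = character(0),
                      kozak_group = character(0), minus3 = character(0),
                      plus3 = character(0), n_alt_stops = integer(0),
                      alt_stops = character(0), evidence = logical(0),
                      is_oorf = logical(0), stringsAsFactors = FALSE)
  if (L < 3L) return(empty)
  full <- paste0(utr, cds)
  augs <- .windowMatches(utr, "ATG")
  if (!length(augs)) return(empty)
  stops <- .windowMatches(utr, .STOP_CODONS)
  rows <- lapply(augs, function(a) {
    inframe <- stops[stops >= a + 3L & (stops - a) %% 3L == 0L]
    kz <- classifyKozak(full, a, plusOffset)
    d <- L - a + 1L
    data.frame(start = a,
               stop_start = if (length(inframe)) inframe[1] else NA_integer_,
               frame_vs_cds = d %% 3L,
               kozak = kz$value, kozak_group = kz$value,
               minus3 = if (is.na(kz$minus3)) "" else kz$minus3,
               plus3 = kz$plus3,
               n_alt_stops = max(length(inframe) - 1L, 0L),
               alt_stops = paste(inframe[-1], collapse = ","),
               evidence = if (length(inframe)) inframe[1] %in% evidenceStops else FALSE,
               is_oorf = !length(inframe), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # strongest Kozak among uAUGs converging on the same stop
  withStop <- which(!is.na(res$stop_start))
  if (length(withStop)) {
    grp <- split(withStop, res$stop_start[withStop])
    for (g in grp) {
      res$kozak_group[g] <- .KOZAK_LEVELS[max(.kozakRank(res$kozak[g]))]
    }
  }
  res
}

#' Detect existing uORFs and overlapping ORFs in 5'UTRs
#'
#' Scans each UTR for every ATG. A uAUG with an in-frame stop codon (TAA,
#' TGA or TAG) lying entirely within the UTR defines a uORF: the first
#' (5'-most) in-frame stop is reported as `stop_start`, later ones in
#' `alt_stops`. uAUGs with no in-frame UTR stop are existing overlapping
#' ORFs (`is_oorf = TRUE`): in frame 0 they elongate the CDS, otherwise
#' the ribosome reads out of frame into the CDS. Per shared stop codon,
#' `kozak_group` reports the strongest Kozak among converging uAUGs (the
#' per-start strength stays in `kozak`). `evidence` flags stops matching
#' the supplied translation-evidence coordinates (ribosome-profiling
#' catalogues such as sorfs.org).
#'
#' @param x a [TranscriptSet-class].
#' @param evidence optional data.frame (transcript_id, stop_start) of
#'   1-based stop-codon start coordinates with translation evidence.
#' @param plusOffset Kozak downstream-context offset, see [classifyKozak()].
#' @return data.frame with one row per (uAUG, first in-frame stop) pair
#'   plus one per existing oORF: transcript_id, start, stop_start (NA for
#'   oORFs), frame_vs_cds, kozak, kozak_group, minus3, plus3, n_alt_stops,
#'   alt_stops, evidence, is_oorf.
#' @examples
#' ts <- TranscriptSet("G1", "T1", "ATGAAATGACC", "ATGGCT")
#' findUorfs(ts)
#' @export
findUorfs <- function(x, evidence = NULL, plusOffset = 3L) {
  stopifnot(is(x, "TranscriptSet"))
  out <- lapply(seq_along(x@txId), function(i) {
    ev <- if (is.null(evidence)) integer(0) else
      evidence$stop_start[evidence$transcript_id == x@txId[i]]
    r <- .scanUorfs(as.character(x@utr[[i]]), as.character(x@cds[[i]]),
                    ev, plusOffset)
    if (nrow(r)) cbind(transcript_id = x@txId[i], r, stringsAsFactors = FALSE)
    else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      stop_start = integer(0), frame_vs_cds = integer(0),
                      kozak = character(0), kozak_group = character(0),
                      minus3 = character(0), plus3 = character(0),
                      n_alt_stops = integer(0), alt_stops = character(0),
                      evidence = logical(0), is_oorf = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.emptyConsequences <- function() {
  data.frame(transcript_id = character(0), pos = integer(0),
             ref = character(0), alt = character(0), kind = character(0),
             consequence = character(0), kozak = character(0),
             minus3 = character(0), plus3 = character(0),
             distance_to_cds = integer(0), frame = integer(0),
             within_50bp = logical(0), evidence = logical(0),
             high_impact = logical(0), stringsAsFactors = FALSE)
}

.consequenceRow <- function(txid, pos, ref, alt, kind, hasStop, frame,
                            kozak, minus3, plus3, d, evidence,
                            stopKind = c("created", "existing")) {
  consequence <- if (hasStop) {
    if (kind == "uAUG_created") "uORF_created" else "uORF_elongated"
  } else if (frame == 0L) "CDS_elongation" else "oORF_out_of_frame"
  rec <- data.frame(transcript_id = txid, pos = pos, ref = ref, alt = alt,
                    kind = kind, consequence = consequence, kozak = kozak,
                    minus3 = minus3, plus3 = plus3, distance_to_cds = d,
                    frame = frame, within_50bp = d <= 50L,
                    evidence = evidence, high_impact = FALSE,
                    stringsAsFactors = FALSE)
  rec$high_impact <- isHighImpact(rec)
  rec
}

#' High-impact rule for uORF-perturbing variants
#'
#' A uAUG-creating variant is high-impact when the new start sits in a
#' strong or moderate Kozak context and the result is an out-of-frame
#' overlapping ORF or a CDS elongation. A stop-removing (or
#' uORF-frameshifting) variant is high-impact when the affected uORF has a
#' strong/moderate Kozak start or documented translation evidence, and
#' the result is an out-of-frame oORF or CDS elongation.
#'
#' @param records data.frame of consequence records (columns kind,
#'   consequence, kozak, evidence).
#' @return logical vector.
#' @export
isHighImpact <- function(records) {
  kozakOk <- records$kozak %in% c("strong", "moderate")
  conseqOk <- records$consequence %in% c("oORF_out_of_frame", "CDS_elongation")
  created <- records$kind == "uAUG_created"
  ifelse(created,
         kozakOk & conseqOk,
         (kozakOk | records$evidence) & conseqOk)
}

# first in-frame stop fully inside the UTR at/after start+3
.firstInframeStop <- function(utr, start) {
  stops <- .windowMatches(utr, .STOP_CODONS)
  inframe <- stops[stops >= start + 3L & (stops - start) %% 3L == 0L]
  if (length(inframe)) inframe[1] else NA_integer_
}

#' Enumerate all uAUG-creating SNVs in a 5'UTR
#'
#' Finds every single-nucleotide variant that turns a UTR trinucleotide
#' window differing from ATG at exactly one position into ATG (windows
#' containing N are skipped; windows already ATG yield nothing). Each
#' variant is annotated on the post-edit sequence: Kozak strength of the
#' new start, distance to the CDS (d = L - start + 1), reading frame
#' relative to the CDS (d mod 3), presence of an in-frame UTR stop, the
#' resulting consequence and the high-impact flag.
#'
#' @inheritParams findUorfs
#' @param evidence optional translation-evidence table (propagated to
#'   created uORFs whose first stop matches).
#' @return data.frame of consequence records (columns transcript_id, pos,
#'   ref, alt, kind, consequence, kozak, minus3, plus3, distance_to_cds,
#'   frame, within_50bp, evidence, high_impact).
#' @examples
#' ts <- TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT")
#' enumerateUaugSnvs(ts)
#' @export
enumerateUaugSnvs <- function(x, evidence = NULL, plusOffset = 3L) {
  stopifnot(is(x, "TranscriptSet"))
  out <- lapply(seq_along(x@txId), function(i) {
    .enumUaugSnvsOne(x@txId[i], as.character(x@utr[[i]]),
                     as.character(x@cds[[i]]), evidence, plusOffset)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(.emptyConsequences())
  rownames(res) <- NULL
  res
}

.enumUaugSnvsOne <- function(txid, utr, cds, evidence = NULL, plusOffset = 3L) {
  L <- nchar(utr)
  if (L < 3L) return(NULL)
  ev <- if (is.null(evidence)) integer(0) else
    evidence$stop_start[evidence$transcript_id == txid]
  w <- seq_len(L - 2L)
  c1 <- substring(utr, w, w)
  c2 <- substring(utr, w + 1L, w + 1L)
  c3 <- substring(utr, w + 2L, w + 2L)
  ok <- c1 %in% .DNA_BASES & c2 %in% .DNA_BASES & c3 %in% .DNA_BASES
  mk <- function(sel, off, alt) {
    w2 <- w[sel]
    data.frame(win = w2, off = rep(off, length(w2)),
               alt = rep(alt, length(w2)), stringsAsFactors = FALSE)
  }
  cand <- rbind(
    mk(ok & c2 == "T" & c3 == "G" & c1 != "A", 0L, "A"),
    mk(ok & c1 == "A" & c3 == "G" & c2 != "T", 1L, "T"),
    mk(ok & c1 == "A" & c2 == "T" & c3 != "G", 2L, "G")
  )
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand$win, cand$off), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(j) {
    a <- cand$win[j]
    pos <- a + cand$off[j]
    ref <- substr(utr, pos, pos)
    newUtr <- paste0(substr(utr, 1L, pos - 1L), cand$alt[j],
                     substr(utr, pos + 1L, L))
    kz <- classifyKozak(paste0(newUtr, cds), a, plusOffset)
    stop1 <- .firstInframeStop(newUtr, a)
    d <- L - a + 1L
    .consequenceRow(txid, pos, ref, cand$alt[j], "uAUG_created",
                    !is.na(stop1), d %% 3L, kz$value,
                    if (is.na(kz$minus3)) "" else kz$minus3, kz$plus3, d,
                    evidence = !is.na(stop1) && stop1 %in% ev)
  })
  do.call(rbind, rows)
}

#' Enumerate all uORF-stop-removing SNVs
#'
#' For each distinct uORF stop codon (uAUGs converging on the same stop
#' are collapsed: the reported start is the 5'-most and the Kozak the
#' strongest among them), enumerates every SNV whose resulting codon is
#' no longer one of TAA/TGA/TAG. Exactly 7 such SNVs exist for TAA and 8
#' each for TGA and TAG. The consequence is `uORF_elongated` when a
#' downstream in-frame UTR stop exists, otherwise `CDS_elongation` (frame
#' 0) or `oORF_out_of_frame`.
#'
#' @inheritParams findUorfs
#' @param uorfs output of [findUorfs()] for `x` (computed if missing).
#' @return data.frame of consequence records (see [enumerateUaugSnvs()]).
#' @export
enumerateStopRemovingSnvs <- function(x, uorfs = NULL, evidence = NULL,
                                      plusOffset = 3L) {
  stopifnot(is(x, "TranscriptSet"))
  if (is.null(uorfs)) uorfs <- findUorfs(x, evidence, plusOffset)
  uu <- uorfs[!is.na(uorfs$stop_start), , drop = FALSE]
  if (!nrow(uu)) return(.emptyConsequences())
  L <- setNames(Biostrings::width(x@utr), x@txId)
  utrs <- setNames(as.character(x@utr), x@txId)
  key <- paste(uu$transcript_id, uu$stop_start)
  out <- lapply(split(seq_len(nrow(uu)), key), function(idx) {
    g <- uu[idx, , drop = FALSE]
    txid <- g$transcript_id[1]
    s <- g$stop_start[1]
    start <- min(g$start)
    kz <- g$kozak_group[1]
    repRow <- g[which.min(g$start), , drop = FALSE]
    evd <- any(g$evidence)
    utr <- utrs[[txid]]
    Li <- L[[txid]]
    codon <- substr(utr, s, s + 2L)
    hasDownstream <- any(.windowMatches(utr, .STOP_CODONS) > s &
                         (.windowMatches(utr, .STOP_CODONS) - start) %% 3L == 0L)
    d <- Li - start + 1L
    rows <- list()
    for (j in 1:3) {
      refb <- substr(codon, j, j)
      for (alt in setdiff(.DNA_BASES, refb)) {
        newCodon <- codon
        substr(newCodon, j, j) <- alt
        if (newCodon %in% .STOP_CODONS) next
        rows[[length(rows) + 1L]] <- .consequenceRow(
          txid, s + j - 1L, refb, alt, "uSTOP_removed", hasDownstream,
          d %% 3L, kz, repRow$minus3, repRow$plus3, d, evd)
      }
    }
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$transcript_id, res$pos, res$alt), ]
}

#' Enumerate uAUG-creating deletions (1-5 bp)
#'
#' Enumerates every UTR deletion of length 1..`maxLen` whose post-edit
#' UTR contains an ATG absent at the corresponding alignment pre-edit: a
#' deletion creates a new ATG only in a window spanning the deletion
#' junction, and a post-edit ATG whose left-aligned pre-edit window was
#' already ATG is a mere shift of an existing start and is excluded.
#' Insertions are not enumerated (only annotated when supplied, see
#' [annotateVariant()]). Records are annotated on the post-edit sequence.
#'
#' @inheritParams findUorfs
#' @param maxLen maximum deletion length (default 5).
#' @return data.frame of consequence records with `alt = ""`.
#' @export
enumerateUaugDeletions <- function(x, maxLen = 5L, evidence = NULL,
                                   plusOffset = 3L) {
  stopifnot(is(x, "TranscriptSet"))
  out <- lapply(seq_along(x@txId), function(i) {
    txid <- x@txId[i]
    utr <- as.character(x@utr[[i]])
    cds <- as.character(x@cds[[i]])
    L <- nchar(utr)
    if (L < 4L) return(NULL)
    ev <- if (is.null(evidence)) integer(0) else
      evidence$stop_start[evidence$transcript_id == txid]
    rows <- list()
    for (pos in seq_len(L)) {
      for (len in seq_len(min(maxLen, L - pos + 1L))) {
        newL <- L - len
        for (q in c(pos - 2L, pos - 1L)) {
          if (q < 1L || q + 2L > newL) next
          # post-edit window chars straddling the junction
          ch <- character(3)
          for (t in 0:2) {
            p <- q + t
            ch[t + 1L] <- if (p < pos) substr(utr, p, p) else
              substr(utr, p + len, p + len)
          }
          if (paste(ch, collapse = "") != "ATG") next
          if (substr(utr, q, q + 2L) == "ATG") next  # mere shift
          newUtr <- paste0(substr(utr, 1L, pos - 1L),
                           substr(utr, pos + len, L))
          kz <- classifyKozak(paste0(newUtr, cds), q, plusOffset)
          stop1 <- .firstInframeStop(newUtr, q)
          d <- newL - q + 1L
          rows[[length(rows) + 1L]] <- .consequenceRow(
            txid, pos, substr(utr, pos, pos + len - 1L), "",
            "uAUG_created", !is.na(stop1), d %% 3L, kz$value,
            if (is.na(kz$minus3)) "" else kz$minus3, kz$plus3, d,
            evidence = !is.na(stop1) && stop1 %in% ev)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(.emptyConsequences())
  rownames(res) <- NULL
  res
}

#' Annotate an arbitrary supplied variant for uORF consequences
#'
#' Diff-based annotation of any UTR SNV or small indel: the uORF/oORF
#' structure is computed before and after applying the variant and the
#' differences are emitted as consequence records. New uAUGs give
#' `uAUG_created` records; a uORF whose stop codon is directly hit gives
#' `uSTOP_removed`; an indel between a uORF's start and stop that changes
#' its reading frame so the stop is bypassed gives `uORF_frameshifted`
#' (the mechanism of the recurrent NF2 5'UTR insertion). A single variant
#' may emit several records; a variant that changes no start or stop
#' emits none.
#'
#' @inheritParams findUorfs
#' @param transcriptId,pos,ref,alt the variant, as in [applyVariant()].
#' @return data.frame of consequence records (possibly empty).
#' @export
annotateVariant <- function(x, transcriptId, pos, ref, alt,
                            evidence = NULL, plusOffset = 3L) {
  ref <- toupper(ref); alt <- toupper(alt)
  i <- match(transcriptId, x@txId)
  if (is.na(i)) stop("unknown transcript id: ", transcriptId)
  x1 <- x[i]
  pre <- findUorfs(x1, evidence, plusOffset)
  x2 <- applyVariant(x1, transcriptId, pos, ref, alt)
  post <- findUorfs(x2, evidence, plusOffset)
  Lpre <- Biostrings::width(x1@utr)[1]
  Lpost <- Biostrings::width(x2@utr)[1]
  shift <- nchar(alt) - nchar(ref)
  inUtr <- pos <= Lpre
  # map a pre-edit position to post-edit coordinates (NA if destroyed)
  mapPos <- function(p) {
    if (!inUtr || p < pos) p
    else if (p >= pos + max(nchar(ref), 0L)) p + shift
    else NA_integer_
  }
  preStartsMapped <- vapply(pre$start, mapPos, integer(1))
  out <- list()
  # new uAUGs: post starts with no surviving pre counterpart
  for (j in seq_len(nrow(post))) {
    q <- post$start[j]
    if (q %in% preStartsMapped[!is.na(preStartsMapped)]) next
    d <- Lpost - q + 1L
    out[[length(out) + 1L]] <- .consequenceRow(
      transcriptId, pos, ref, alt, "uAUG_created",
      !post$is_oorf[j], post$frame_vs_cds[j], post$kozak[j],
      post$minus3[j], post$plus3[j], d, post$evidence[j])
  }
  # lost stops of existing uORFs (one record per distinct pre stop)
  uu <- pre[!is.na(pre$stop_start), , drop = FALSE]
  if (nrow(uu)) {
    for (s in unique(uu$stop_start)) {
      g <- uu[uu$stop_start == s, , drop = FALSE]
      start <- min(g$start)
      startPost <- mapPos(start)
      if (is.na(startPost)) next
      jpost <- which(post$start == startPost)
      if (!length(jpost)) next
      jpost <- jpost[1]
      sPost <- post$stop_start[jpost]
      sMapped <- mapPos(s)
      if (!is.na(sPost) && !is.na(sMapped) && sPost <= sMapped) next
      # stop lost (bypassed or destroyed)
      refEnd <- pos + max(nchar(ref) - 1L, 0L)
      hitsStop <- nchar(ref) > 0L && pos <= s + 2L && refEnd >= s
      frameshift <- inUtr && shift %% 3L != 0L && pos > start && pos <= s + 2L
      kind <- if (frameshift && !hitsStop) "uORF_frameshifted" else "uSTOP_removed"
      repRow <- g[which.min(g$start), , drop = FALSE]
      d <- Lpost - startPost + 1L
      out[[length(out) + 1L]] <- .consequenceRow(
        transcriptId, pos, ref, alt, kind,
        hasStop = !is.na(sPost), frame = d %% 3L,
        kozak = repRow$kozak_group, minus3 = repRow$minus3, plus3 = repRow$plus3,
        d = d, evidence = any(g$evidence))
    }
  }
  if (!length(out)) return(.emptyConsequences())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write consequence records to TSV
#'
#' Writes the stable 13-column format: transcript_id, pos, ref, alt,
#' kind, consequence, kozak, minus3, plus3, distance_to_cds, frame,
#' evidence, high_impact.
#'
#' @param records consequence data.frame.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeConsequences <- function(records, path) {
  cols <- c("transcript_id", "pos", "ref", "alt", "kind", "consequence",
            "kozak", "minus3", "plus3", "distance_to_cds", "frame",
            "evidence", "high_impact")
  out <- records[, cols, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
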