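# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (character vectors, full apply-and-rescan)
# rather than calling back into the package's scan machinery.

STOPS <- c("TAA", "TGA", "TAG")
BASES <- c("A", "C", "G", "T")

randomUtr <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

# all 1-based window starts equal to pat, via character vectors
atgPositionsOracle <- function(chars) {
  L <- length(chars)
  if (L < 3L) return(integer(0))
  i <- seq_len(L - 2L)
  which(chars[i] == "A" & chars[i + 1L] == "T" & chars[i + 2L] == "G")
}

stopPositionsOracle <- function(chars) {
  L <- length(chars)
  if (L < 3L) return(integer(0))
  i <- seq_len(L - 2L)
  codons <- paste0(chars[i], chars[i + 1L], chars[i + 2L])
  which(codons %in% STOPS)
}

kozakOracle <- function(fullChars, a) {
  m3 <- if (a >= 4L) fullChars[a - 3L] else NA_character_
  p3 <- fullChars[a + 3L]
  mOk <- !is.na(m3) && m3 %in% c("A", "G")
  pOk <- identical(p3, "G")
  if (mOk && pOk) "strong" else if (mOk || pOk) "moderate" else "weak"
}

consequenceOracle <- function(kind, hasStop, frame) {
  if (hasStop) {
    if (kind == "uAUG_created") "uORF_created" else "uORF_elongated"
  } else if (frame == 0L) "CDS_elongation" else "oORF_out_of_frame"
}

highImpactOracle <- function(kind, kozak, consequence, evidence = FALSE) {
  ok <- consequence %in% c("oORF_out_of_frame", "CDS_elongation")
  kz <- kozak %in% c("strong", "moderate")
  if (kind == "uAUG_created") kz && ok else (kz || evidence) && ok
}

# apply every possible SNV to the UTR and rescan the full post-edit
# sequence for newly created ATGs; annotate each from scratch
oracleUaugSnvs <- function(utr, cds) {
  uc <- strsplit(utr, "")[[1]]
  cc <- strsplit(cds, "")[[1]]
  L <- length(uc)
  preAtg <- atgPositionsOracle(uc)
  rows <- list()
  for (pos in seq_len(L)) {
    for (alt in setdiff(BASES, uc[pos])) {
      post <- uc
      post[pos] <- alt
      newAtg <- setdiff(atgPositionsOracle(post), preAtg)
      for (a in newAtg) {
        stops <- stopPositionsOracle(post)
        inframe <- stops[stops >= a + 3L & (stops - a) %% 3L == 0L]
        d <- L - a + 1L
        kz <- kozakOracle(c(post, cc), a)
        cons <- consequenceOracle("uAUG_created", length(inframe) > 0, d %% 3L)
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, ref = uc[pos], alt = alt, distance_to_cds = d,
          frame = d %% 3L, consequence = cons, kozak = kz,
          high_impact = highImpactOracle("uAUG_created", kz, cons),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), distance_to_cds = integer(0),
                      frame = integer(0), consequence = character(0),
                      kozak = character(0), high_impact = logical(0)))
  }
  do.call(rbind, rows)
}

# independent uORF scan (plain loops over char vectors)
oracleUorfs <- function(utr) {
  uc <- strsplit(utr, "")[[1]]
  atg <- atgPositionsOracle(uc)
  stops <- stopPositionsOracle(uc)
  out <- list()
  for (a in atg) {
    inframe <- stops[stops >= a + 3L & (stops - a) %% 3L == 0L]
    out[[length(out) + 1L]] <- list(start = a,
      stop = if (length(inframe)) inframe[1] else NA_integer_)
  }
  out
}

# for every distinct uORF stop, try all 9 codon SNVs and keep those whose
# post-edit codon is no longer a stop; annotate from the 5'-most
# converging start and the strongest converging Kozak
oracleStopRemovingSnvs <- function(utr, cds) {
  uc <- strsplit(utr, "")[[1]]
  cc <- strsplit(cds, "")[[1]]
  L <- length(uc)
  uorfs <- Filter(function(u) !is.na(u$stop), oracleUorfs(utr))
  if (!length(uorfs)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), distance_to_cds = integer(0),
                      frame = integer(0), consequence = character(0),
                      kozak = character(0)))
  }
  stopsOf <- vapply(uorfs, function(u) u$stop, integer(1))
  rows <- list()
  for (s in unique(stopsOf)) {
    conv <- uorfs[stopsOf == s]
    start <- min(vapply(conv, function(u) u$start, integer(1)))
    ranks <- vapply(conv, function(u) {
      match(kozakOracle(c(uc, cc), u$start), c("weak", "moderate", "strong"))
    }, integer(1))
    kz <- c("weak", "moderate", "strong")[max(ranks)]
    allStops <- stopPositionsOracle(uc)
    downstream <- any(allStops > s & (allStops - start) %% 3L == 0L)
    d <- L - start + 1L
    for (j in 0:2) {
      for (alt in setdiff(BASES, uc[s + j])) {
        post <- uc
        post[s + j] <- alt
        if (paste(post[s:(s + 2L)], collapse = "") %in% STOPS) next
        cons <- consequenceOracle("uSTOP_removed", downstream, d %% 3L)
        rows[[length(rows) + 1L]] <- data.frame(
          pos = s + j, ref = uc[s + j], alt = alt, distance_to_cds = d,
          frame = d %% 3L, consequence = cons, kozak = kz,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# apply every 1..maxLen bp deletion and rescan: a post-edit ATG at q is a
# NEW uAUG iff the pre-edit window left-aligned at q (q if q < pos, else
# q + len) was not ATG
oracleUaugDeletions <- function(utr, maxLen = 5L) {
  uc <- strsplit(utr, "")[[1]]
  L <- length(uc)
  rows <- list()
  for (pos in seq_len(L)) {
    for (len in seq_len(min(maxLen, L - pos + 1L))) {
      post <- uc[-(pos:(pos + len - 1L))]
      for (q in atgPositionsOracle(post)) {
        preq <- if (q < pos) q else q + len
        preWin <- if (preq + 2L <= L) paste(uc[preq:(preq + 2L)], collapse = "")
                  else ""
        if (identical(preWin, "ATG")) next  # mere shift of an existing start
        d <- (L - len) - q + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, len = len, distance_to_cds = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(0), len = integer(0),
                      distance_to_cds = integer(0)))
  }
  unique(do.call(rbind, rows))
}

# exact two-sided Fisher p by direct hypergeometric summation
oracleFisherP <- function(a, aTot, b, bTot) {
  k <- a + b                 # total hits
  probs <- stats::dhyper(0:k, aTot, bTot, k)
  pObs <- stats::dhyper(a, aTot, bTot, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact two-sided Wilcoxon p by enumeration of all group assignments
oracleWilcoxP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  pLe <- mean(us <= uObs + 1e-9)
  pGe <- mean(us >= uObs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# one-sided binomial tail by direct summation
oracleBinomTailP <- function(k, n, p) {
  sum(stats::dbinom(k:n, n, p))
}

# deterministic calibration fixture: two-context mutability table plus a
# zero-slope singleton model with the given constant probability
constantModel <- function(p) {
  new("CalibrationModel", intercept = p, slope = 0, weighted = FALSE,
      groups = data.frame())
}

twoContextTable <- function() {
  possible <- data.frame(context = c("ACA>AGA", "ACG>ATG"),
                         methylation_bin = c(0L, 0L),
                         n_possible = c(1000L, 1000L))
  neutral <- data.frame(
    context = rep(c("ACA>AGA", "ACG>ATG"), c(10L, 20L)),
    methylation_bin = 0L)
  buildMutabilityTable(neutral, possible)
}

obsFrame <- function(n, context = "ACA>AGA", bin = 0L, allele_count = 1L,
                     coverage = 30, gerp = 0, region = "test", chrom = "1",
                     pass = TRUE) {
  data.frame(variant_id = paste0("v", seq_len(n)), context = context,
             methylation_bin = bin,
             allele_count = rep_len(allele_count, n),
             coverage = rep_len(coverage, n), gerp = rep_len(gerp, n),
             region = region, chrom = rep_len(chrom, n),
             pass_filters = rep_len(pass, n), stringsAsFactors = FALSE)
}

# 12 genes engineered to cover every triage class 0-8, with order probes:
# gene_h is curated HI *and* LOEUF-intolerant (class 8 must win over 7);
# gene_l is tolerant *and* has a common high-impact SNV (4 beats 5)
geneFixture <- function() {
  data.frame(
    gene_id = paste0("gene_", letters[1:12]),
    has_utr = c(FALSE, rep(TRUE, 11)),
    n_possible_perturbing = c(5L, 0L, rep(10L, 10)),
    n_possible_high_impact = c(5L, 0L, 0L, rep(4L, 9)),
    has_high_confidence_oorf = c(rep(FALSE, 3), TRUE, rep(FALSE, 8)),
    max_high_impact_ac = c(rep(0L, 4), 40L, rep(0L, 6), 22L),
    loeuf_sextile = c(3L, 3L, 3L, 3L, 3L, 6L, 3L, 1L, 1L, 3L, 3L, 6L),
    curated_hi = c(rep(FALSE, 7), TRUE, FALSE, FALSE, FALSE, FALSE),
    ddg2p_lof = rep(FALSE, 12),
    clinvar_lof_count = c(rep(0L, 8), 0L, 12L, 3L, 0L),
    stringsAsFactors = FALSE)
}
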