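#' Proportion of conserved bases with binomial confidence interval
#'
#' Fraction of scored bases with a conservation (phyloP-like) score at or
#' above `threshold` (>= 2 is the conventional "conserved" call), with a
#' Clopper-Pearson 95% interval.
#'
#' @param scores numeric vector of per-base conservation scores.
#' @param threshold conserved cutoff (default 2).
#' @param strict use strictly greater-than instead of >= (default FALSE).
#' @param conf.level interval level (default 0.95).
#' @return list with proportion, k, n, ci (length-2).
#' @export
conservedProportion <- function(scores, threshold = 2, strict = FALSE,
                                conf.level = 0.95) {
  if (!length(scores)) stop("conservedProportion requires a non-empty input")
  k <- if (strict) sum(scores > threshold) else sum(scores >= threshold)
  n <- length(scores)
  bt <- binom.test(k, n, conf.level = conf.level)
  list(proportion = k / n, k = k, n = n, ci = as.numeric(bt$conf.int))
}

#' Matched control bases around uORF stop codons
#'
#' For each distinct uORF stop codon, the 3 bases immediately upstream
#' and the 3 immediately downstream of the stop, clipped at the UTR
#' bounds and deduplicated per (transcript, position). These control for
#' gene context and distance to the CDS when comparing conservation of
#' stop-codon bases against the surrounding UTR. The stop codon's own
#' bases are never included.
#'
#' @param uorfs output of [findUorfs()] (rows without a stop are ignored).
#' @param transcripts the [TranscriptSet-class] (for UTR bounds).
#' @return data.frame with columns transcript_id, pos, role
#'   ("matched_control").
#' @export
matchedStopControls <- function(uorfs, transcripts) {
  uu <- uorfs[!is.na(uorfs$stop_start), c("transcript_id", "stop_start")]
  uu <- unique(uu)
  if (!nrow(uu)) {
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      role = character(0)))
  }
  L <- setNames(Biostrings::width(transcripts@utr), transcripts@txId)
  out <- lapply(seq_len(nrow(uu)), function(i) {
    s <- uu$stop_start[i]
    Li <- L[[uu$transcript_id[i]]]
    pos <- c((s - 3L):(s - 1L), (s + 3L):(s + 5L))
    pos <- pos[pos >= 1L & pos <= Li]
    if (!length(pos)) return(NULL)
    data.frame(transcript_id = uu$transcript_id[i], pos = pos,
               role = "matched_control", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  unique(res)
}

#' Fisher's exact test on a 2x2 hit table
#'
#' Two-sided exact hypergeometric p-value for a difference in hit
#' proportions between two groups, with an odds ratio (Haldane 0.5
#' correction applied when any cell is zero).
#'
#' @param aHits,aTotal,bHits,bTotal counts (totals >= hits >= 0).
#' @return list with odds_ratio, p, and the 2x2 table.
#' @export
fisher2x2 <- function(aHits, aTotal, bHits, bTotal) {
  if (aTotal <= 0 || bTotal <= 0) stop("group totals must be positive")
  if (aHits > aTotal || bHits > bTotal || aHits < 0 || bHits < 0) {
    stop("hits must satisfy 0 <= hits <= total")
  }
  m <- matrix(c(aHits, aTotal - aHits, bHits, bTotal - bHits), nrow = 2,
              byrow = TRUE,
              dimnames = list(group = c("A", "B"), hit = c("yes", "no")))
  ft <- fisher.test(m)
  or <- if (any(m == 0)) {
    ((m[1, 1] + 0.5) * (m[2, 2] + 0.5)) / ((m[1, 2] + 0.5) * (m[2, 1] + 0.5))
  } else {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  }
  list(odds_ratio = unname(or), p = ft$p.value, table = m)
}

#' Wilcoxon rank-sum comparison of two score distributions
#'
#' Two-sided rank-sum test with tie correction; exact below `exactMax`
#' observations per group (and no ties), normal approximation otherwise.
#'
#' @param x,y numeric score vectors.
#' @param exactMax exact-enumeration size cutoff (default 50, the
#'   [stats::wilcox.test] convention).
#' @return list with statistic (W), p.
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 50L) {
  if (!length(x) || !length(y)) stop("both score vectors must be non-empty")
  exact <- length(x) < exactMax && length(y) < exactMax &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

.PREDICATES <- list(
  kozak_moderate_or_strong = function(r) r$kozak %in% c("strong", "moderate"),
  oorf_out_of_frame = function(r) r$consequence == "oORF_out_of_frame",
  within_50bp = function(r) r$distance_to_cds <= 50L,
  high_impact = function(r) r$high_impact
)

#' One-sided binomial enrichment of a property among disease variants
#'
#' Tests whether disease-ascertained uORF-perturbing variants are
#' enriched for a property (e.g. formation into a moderate/strong Kozak
#' context) relative to the background of all possible variants: the
#' background proportion pi is the fraction of possible variants with the
#' property, and the p-value is the one-sided binomial tail
#' P(X >= k | n, pi) for k of n disease variants with the property.
#'
#' @param observed consequence records for the disease variant set.
#' @param background consequence records for all possible variants.
#' @param predicate one of "kozak_moderate_or_strong",
#'   "oorf_out_of_frame", "within_50bp", "high_impact".
#' @return list with pi (background proportion), k, n, prop_observed, p.
#' @export
binomialEnrichment <- function(observed, background, predicate) {
  if (!nrow(background)) stop("background must be non-empty")
  f <- .PREDICATES[[predicate]]
  if (is.null(f)) {
    stop("unknown predicate '", predicate, "'; must be one of: ",
         paste(names(.PREDICATES), collapse = ", "))
  }
  pi0 <- mean(f(background))
  k <- sum(f(observed))
  n <- nrow(observed)
  p <- if (n == 0) NA_real_ else
    binom.test(k, n, p = pi0, alternative = "greater")$p.value
  list(pi = pi0, k = k, n = n,
       prop_observed = if (n) k / n else NA_real_, p = p)
}
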