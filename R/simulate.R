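#' Default context-dependent mutation-rate table for simulation
#'
#' True per-base, per-generation rates keyed by trinucleotide
#' substitution context (`"ACG>ATG"` style). Transitions are faster than
#' transversions; C>T at CpG sites is split into three methylation bins
#' of increasing rate (the hypermutability that MAPS must adjust for);
#' non-CpG rates are modulated by the GC content of the flanking bases.
#' `weight` is the relative genomic abundance of each class used when
#' sampling sites (CpG contexts are depleted in real genomes).
#'
#' @return data.frame with columns context, methylation_bin, mu, weight.
#' @export
defaultMutationRates <- function() {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  isTransition <- function(r, a) {
    paste0(r, a) %in% c("AG", "GA", "CT", "TC")
  }
  for (b1 in bases) for (ref in bases) for (b3 in bases) {
    for (alt in setdiff(bases, ref)) {
      ctx <- paste0(b1, ref, b3, ">", b1, alt, b3)
      cpg <- ref == "C" && alt == "T" && b3 == "G"
      if (cpg) {
        for (bin in 0:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            context = ctx, methylation_bin = bin,
            mu = c(3e-8, 6e-8, 1.2e-7)[bin + 1L], weight = 0.1,
            stringsAsFactors = FALSE)
        }
      } else {
        base <- if (isTransition(ref, alt)) 1.2e-8 else 5e-9
        gcFlank <- sum(c(b1, b3) %in% c("G", "C"))
        rows[[length(rows) + 1L]] <- data.frame(
          context = ctx, methylation_bin = 0L,
          mu = base * (0.75 + 0.25 * gcFlank), weight = 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulated study: transcript geometry,
#' planted uORF/oORF content, the true context-dependent mutation model,
#' the phenomenological selection signal (per-class singleton-probability
#' inflation delta - exactly the quantity MAPS estimates), conservation
#' score effects and cohort scale. Defaults describe the emulated study:
#' ~15,708 genomes (31,416 alleles), GC-rich 5'UTRs of log-normal length
#' (median ~150 nt), a baseline singleton proportion of 0.55 declining
#' logit-linearly with mutability, and target classes with delta of 0,
#' 0.05, 0.1 and 0.2.
#'
#' @param seed integer RNG seed; each generator stage derives its own
#'   stream from it.
#' @param nGenes number of genes/transcripts.
#' @param utrLengthMeanlog,utrLengthSdlog log-normal UTR length parameters.
#' @param gcContent GC fraction of simulated sequence.
#' @param noUtrFraction fraction of genes with a zero-length UTR.
#' @param uorfFraction fraction of genes with a planted uORF.
#' @param uorfKozak Kozak strength to plant ("strong"/"moderate"/"weak").
#' @param oorfFraction fraction of genes with a planted existing oORF
#'   (strong Kozak, no in-frame UTR stop).
#' @param evidenceProb probability a planted uORF stop appears in the
#'   translation-evidence list.
#' @param cdsPrefixLength CDS prefix length (>= 3).
#' @param mutationRates true rate table, see [defaultMutationRates()].
#' @param presenceScale kappa: P(site observed) = min(kappa * mu, 0.99).
#' @param p0Intercept,p0Slope logit-linear baseline singleton
#'   probability: p0 = plogis(p0Intercept + p0Slope * mu / 1e-8).
#' @param cohortAlleles cohort size in alleles (2 x 15,708 by default).
#' @param singletonInflation named numeric vector of per-class delta
#'   (selection strength); names become `region` labels.
#' @param nObservedPerClass target observed variants per labelled class.
#' @param nNeutralPossible possible sites in the neutral
#'   (intergenic/intronic) corpus used to build the mutability table.
#' @param nSynonymousObserved target observed synonymous variants for
#'   calibration.
#' @param scoreSd standard deviation of the null conservation score.
#' @param conservationEffect score shift added at functional bases.
#' @return list of class `uorf_sim_config`.
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 200L,
                             utrLengthMeanlog = log(150),
                             utrLengthSdlog = 0.6,
                             gcContent = 0.6,
                             noUtrFraction = 0.05,
                             uorfFraction = 0.4,
                             uorfKozak = "strong",
                             oorfFraction = 0.1,
                             evidenceProb = 0.3,
                             cdsPrefixLength = 9L,
                             mutationRates = defaultMutationRates(),
                             presenceScale = 4e6,
                             p0Intercept = 0.2,
                             p0Slope = -0.05,
                             cohortAlleles = 31416L,
                             singletonInflation = c(neutral = 0,
                                                    uorf_created = 0.05,
                                                    uaug_moderate_oorf = 0.1,
                                                    uaug_strong_oorf = 0.2),
                             nObservedPerClass = 20000L,
                             nNeutralPossible = 1500000L,
                             nSynonymousObserved = 20000L,
                             scoreSd = 1.5,
                             conservationEffect = 3) {
  stopifnot(all(singletonInflation >= 0), all(singletonInflation <= 1),
            gcContent >= 0, gcContent <= 1,
            noUtrFraction >= 0, noUtrFraction <= 1,
            uorfFraction >= 0, uorfFraction <= 1,
            evidenceProb >= 0, evidenceProb <= 1,
            cdsPrefixLength >= 3)
  cfg <- as.list(environment())
  class(cfg) <- "uorf_sim_config"
  cfg
}

.randSeq <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

.setChar <- function(s, pos, ch) {
  substr(s, pos, pos + nchar(ch) - 1L) <- ch
  s
}

#' Generate synthetic transcript models with planted uORF content
#'
#' Random GC-rich UTR/CDS-prefix sequences with, per config, a fraction of
#' zero-length UTRs (gene class 0 fodder), planted uORFs of requested
#' Kozak strength (ATG + one spacer codon + TGA, with the -3/+3 context
#' bases written explicitly) and planted existing oORFs (strong-Kozak ATG
#' near the UTR end with every downstream in-frame stop scrubbed). All
#' planted structure is re-detectable by [findUorfs()]; the generator
#' errors if a UTR drawn too short for the requested plant cannot be
#' regrown.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `transcripts` (a [TranscriptSet-class]), `evidence`
#'   (data.frame transcript_id, stop_start) and `planted` (bookkeeping:
#'   gene, kind, start).
#' @export
generateTranscripts <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$nGenes
  gid <- sprintf("G%04d", seq_len(n))
  tid <- sprintf("T%04d", seq_len(n))
  noUtr <- runif(n) < cfg$noUtrFraction
  L <- ifelse(noUtr, 0L,
              pmax(14L, round(rlnorm(n, cfg$utrLengthMeanlog, cfg$utrLengthSdlog))))
  utr <- vapply(L, .randSeq, character(1), gc = cfg$gcContent)
  cds <- vapply(seq_len(n), function(i) {
    paste0("ATG", .randSeq(cfg$cdsPrefixLength - 3L, cfg$gcContent))
  }, character(1))
  withUtr <- which(!noUtr)
  nPlant <- round(cfg$uorfFraction * n)
  nOorf <- round(cfg$oorfFraction * n)
  if (nPlant + nOorf > length(withUtr)) {
    stop("uorfFraction + oorfFraction exceed the genes with a UTR")
  }
  pick <- sample(withUtr, nPlant + nOorf)
  uorfGenes <- pick[seq_len(nPlant)]
  oorfGenes <- setdiff(pick, uorfGenes)
  evidence <- list()
  planted <- list()
  kozakCtx <- switch(cfg$uorfKozak,
                     strong = c("A", "G"), moderate = c("A", "C"),
                     weak = c("C", "C"),
                     stop("unknown uorfKozak"))
  for (i in uorfGenes) {
    if (L[i] < 14L) stop("UTR too short to plant a uORF in ", tid[i])
    cand <- seq(4L, L[i] - 8L)
    a <- cand[sample.int(length(cand), 1L)]  # needs a-3 and stop end a+8
    s <- a + 6L
    u <- utr[i]
    u <- .setChar(u, a - 3L, kozakCtx[1])
    u <- .setChar(u, a, "ATG")
    u <- .setChar(u, a + 3L, paste0(kozakCtx[2], "GC"))  # spacer, not a stop
    u <- .setChar(u, s, "TGA")
    utr[i] <- u
    if (runif(1) < cfg$evidenceProb) {
      evidence[[length(evidence) + 1L]] <- data.frame(
        transcript_id = tid[i], stop_start = s, stringsAsFactors = FALSE)
    }
    planted[[length(planted) + 1L]] <- data.frame(
      gene_id = gid[i], kind = "uorf", start = a, stop_start = s,
      stringsAsFactors = FALSE)
  }
  for (i in oorfGenes) {
    if (L[i] < 14L) stop("UTR too short to plant an oORF in ", tid[i])
    a <- L[i] - 8L  # near the UTR end: few downstream codons to scrub
    u <- utr[i]
    u <- .setChar(u, a - 3L, "A")
    u <- .setChar(u, a, "ATG")
    u <- .setChar(u, a + 3L, "G")
    # scrub in-frame UTR stops downstream of the planted start
    p <- a + 3L
    while (p + 2L <= L[i]) {
      if (substr(u, p, p + 2L) %in% .STOP_CODONS) u <- .setChar(u, p, "C")
      p <- p + 3L
    }
    utr[i] <- u
    planted[[length(planted) + 1L]] <- data.frame(
      gene_id = gid[i], kind = "oorf", start = a, stop_start = NA_integer_,
      stringsAsFactors = FALSE)
  }
  ts <- TranscriptSet(gid, tid, utr, cds)
  ev <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(transcript_id = character(0), stop_start = integer(0))
  list(transcripts = ts, evidence = ev,
       planted = if (length(planted)) do.call(rbind, planted) else NULL)
}

.simClass <- function(cfg, region, nPossible, delta, gerpMean,
                      keepPossibleCounts = FALSE) {
  r <- cfg$mutationRates
  idx <- sample.int(nrow(r), nPossible, replace = TRUE, prob = r$weight)
  mu <- r$mu[idx]
  present <- runif(nPossible) < pmin(cfg$presenceScale * mu, 0.99)
  possibleCounts <- NULL
  if (keepPossibleCounts) {
    tab <- table(factor(idx, levels = seq_len(nrow(r))))
    possibleCounts <- data.frame(context = r$context,
                                 methylation_bin = r$methylation_bin,
                                 n_possible = as.integer(tab),
                                 stringsAsFactors = FALSE)
  }
  idx <- idx[present]
  mu <- mu[present]
  m <- length(idx)
  p0 <- plogis(cfg$p0Intercept + cfg$p0Slope * mu / 1e-8)
  p <- pmin(p0 + delta, 0.999)
  singleton <- runif(m) < p
  ac <- ifelse(singleton, 1L,
               pmin(2L + rnbinom(m, size = 0.4, mu = 30), cfg$cohortAlleles))
  obs <- data.frame(
    variant_id = paste0(region, "_", seq_len(m)),
    context = r$context[idx],
    methylation_bin = r$methylation_bin[idx],
    allele_count = ac,
    coverage = rnorm(m, 30, 8),
    gerp = rnorm(m, gerpMean, 1.5),
    region = region,
    chrom = sample(c(as.character(1:22), "X", "Y"), m, replace = TRUE,
                   prob = c(rep(0.97 / 22, 22), 0.02, 0.01)),
    pass_filters = runif(m) < 0.98,
    stringsAsFactors = FALSE)
  list(obs = obs, possibleCounts = possibleCounts)
}

#' Simulate a population variant corpus under a mutation model with
#' tunable selection
#'
#' Emulates the inputs MAPS needs: a neutral intergenic/intronic corpus
#' (with possible-site counts, for the mutability table), a
#' synonymous-like calibration class, and one labelled class per entry of
#' `singletonInflation`. Each possible site draws a substitution context
#' (weighted by genomic abundance); it is observed with probability
#' proportional to its true rate mu; observed sites are singletons with
#' probability p0(mu) + delta, where p0 declines logit-linearly with mu
#' (the mutability confounder MAPS exists to remove) and delta is the
#' class's selection signal. Coverage, GERP, chromosome and QC columns
#' are drawn so the standard filters pass for a controlled fraction.
#'
#' @param cfg a [simulationConfig()].
#' @param transcripts optional (unused by the class corpora; accepted for
#'   pipeline symmetry).
#' @return list with `observations` (VariantObservation data.frame over
#'   all classes; `region` holds the class label) and `possibleSites`
#'   (per-(context, bin) possible-site counts of the neutral corpus).
#' @export
simulatePopulation <- function(cfg, transcripts = NULL) {
  set.seed(cfg$seed + 1L)
  meanP <- with(cfg$mutationRates,
                weighted.mean(pmin(cfg$presenceScale * mu, 0.99), weight))
  neutral <- .simClass(cfg, "intergenic_intronic", cfg$nNeutralPossible,
                       delta = 0, gerpMean = 0, keepPossibleCounts = TRUE)
  syn <- .simClass(cfg, "synonymous",
                   ceiling(cfg$nSynonymousObserved / meanP),
                   delta = 0, gerpMean = 0)
  classes <- lapply(names(cfg$singletonInflation), function(cl) {
    .simClass(cfg, cl, ceiling(cfg$nObservedPerClass / meanP),
              delta = cfg$singletonInflation[[cl]], gerpMean = 0)$obs
  })
  obs <- rbind(neutral$obs, syn$obs, do.call(rbind, classes))
  rownames(obs) <- NULL
  list(observations = obs, possibleSites = neutral$possibleCounts)
}

#' Simulate per-base conservation scores
#'
#' Every UTR base of every transcript receives a null score N(0,
#' scoreSd); bases listed in `functionalSites` are shifted upward by
#' `conservationEffect` and tagged with the supplied role (default
#' "uorf_stop"), all other bases are "utr_other".
#'
#' @param cfg a [simulationConfig()].
#' @param transcripts a [TranscriptSet-class].
#' @param functionalSites data.frame (transcript_id, pos) of functional
#'   bases, e.g. uORF stop-codon bases identified by [findUorfs()].
#' @param role role label for the functional bases.
#' @return ScoredBase data.frame (transcript_id, pos, score, role).
#' @export
simulateScores <- function(cfg, transcripts, functionalSites,
                           role = "uorf_stop") {
  set.seed(cfg$seed + 2L)
  L <- utrLength(transcripts)
  tx <- rep(txIds(transcripts), L)
  pos <- unlist(lapply(L, seq_len), use.names = FALSE)
  score <- rnorm(length(pos), 0, cfg$scoreSd)
  roles <- rep("utr_other", length(pos))
  if (!is.null(functionalSites) && nrow(functionalSites)) {
    hit <- paste(tx, pos) %in%
      paste(functionalSites$transcript_id, functionalSites$pos)
    score[hit] <- score[hit] + cfg$conservationEffect
    roles[hit] <- role
  }
  data.frame(transcript_id = tx, pos = pos, score = score, role = roles,
             stringsAsFactors = FALSE)
}

#' Generate the per-gene metadata table
#'
#' Annotation-derived fields (possible/high-impact SNV counts,
#' high-confidence oORF flags) are computed from the supplied annotation
#' results via [buildGeneAnnotation()], never sampled. External metadata
#' is sampled: LOEUF sextiles by quantile of a uniform intolerance score
#' (partitioning genes six ways within one gene), sparse curated
#' haploinsufficiency and DDG2P dominant-LoF flags, a zero-inflated
#' ClinVar pathogenic-LoF count, and population allele counts for the
#' enumerated high-impact SNVs (a small fraction common, AC > 15).
#'
#' @param cfg a [simulationConfig()].
#' @param transcripts a [TranscriptSet-class].
#' @param consequences enumerated SNV consequence records.
#' @param uorfs output of [findUorfs()].
#' @return list with `annotation` (input to [classifyGenes()]),
#'   `metadata` and `populationAc`.
#' @export
generateGeneTable <- function(cfg, transcripts, consequences, uorfs) {
  set.seed(cfg$seed + 3L)
  genes <- unique(unname(geneIds(transcripts)))
  score <- runif(length(genes))
  sextile <- as.integer(cut(rank(score, ties.method = "first"),
                            breaks = 6, labels = FALSE))
  metadata <- data.frame(
    gene_id = genes,
    loeuf_sextile = sextile,
    curated_hi = runif(length(genes)) < 0.05,
    ddg2p_lof = runif(length(genes)) < 0.05,
    clinvar_lof_count = ifelse(runif(length(genes)) < 0.12,
                               1L + rpois(length(genes), 6), 0L),
    stringsAsFactors = FALSE)
  hi <- consequences[consequences$high_impact, , drop = FALSE]
  populationAc <- NULL
  if (nrow(hi)) {
    common <- runif(nrow(hi)) < 0.02
    populationAc <- data.frame(
      transcript_id = hi$transcript_id, pos = hi$pos, alt = hi$alt,
      allele_count = ifelse(common, 16L + rpois(nrow(hi), 30),
                            1L + rpois(nrow(hi), 2)),
      stringsAsFactors = FALSE)
  }
  annotation <- buildGeneAnnotation(transcripts, consequences, uorfs,
                                    metadata = metadata,
                                    populationAc = populationAc)
  list(annotation = annotation, metadata = metadata,
       populationAc = populationAc)
}
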