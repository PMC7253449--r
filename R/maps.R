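#' Filter population variant observations
#'
#' Applies the site-quality filters used before any MAPS computation.
#' For `purpose = "maps_eval"`: autosomal variants only (no X/Y), passing
#' upstream QC filters, with mean coverage strictly between 15x and 60x.
#' For `purpose = "table_build"` (mutability-table construction) the same
#' plus -3.9885 < GERP < 2.6607 (removing conserved bases that would bias
#' the neutral rate) and region restricted to intergenic/intronic.
#'
#' @param obs data.frame of variant observations with columns variant_id,
#'   context, methylation_bin, allele_count, coverage, gerp, region,
#'   chrom, pass_filters (is_singleton derived as allele_count == 1).
#' @param purpose "maps_eval" or "table_build".
#' @return The filtered data.frame (warns if empty).
#' @export
filterObservations <- function(obs, purpose = c("maps_eval", "table_build")) {
  purpose <- match.arg(purpose)
  chrom <- sub("^chr", "", as.character(obs$chrom))
  keep <- !(chrom %in% c("X", "Y")) & obs$pass_filters &
    obs$coverage > 15 & obs$coverage < 60
  if (purpose == "table_build") {
    keep <- keep & obs$gerp > -3.9885 & obs$gerp < 2.6607 &
      obs$region == "intergenic_intronic"
  }
  out <- obs[keep, , drop = FALSE]
  if (!nrow(out)) warning("no observations left after filtering (", purpose, ")")
  out
}

#' Build the context-dependent mutability table
#'
#' For each substitution with one base of flanking context (e.g.
#' `"ACG>ATG"`), and separately for three methylation bins for C>T at CpG
#' sites, computes the proportion of possible sites observed as variant in
#' the neutral corpus, then rescales all proportions so that the
#' possible-site-weighted mean equals the human per-base, per-generation
#' mutation rate (`targetMean`, 1.2e-8). Contexts with zero possible
#' sites are excluded with a warning; zero observed counts get a 0.5
#' pseudocount so no rate is exactly zero.
#'
#' @param neutral data.frame of neutral observed variants (already passed
#'   through [filterObservations()] with `purpose = "table_build"`),
#'   columns context and methylation_bin.
#' @param possibleSites data.frame with columns context, methylation_bin,
#'   n_possible: the number of possible sites per class in the corpus.
#' @param targetMean the weighted-mean scaling constraint (default 1.2e-8).
#' @param pseudocount added to zero observed counts (default 0.5).
#' @return A [MutabilityTable-class].
#' @export
buildMutabilityTable <- function(neutral, possibleSites,
                                 targetMean = 1.2e-8, pseudocount = 0.5) {
  zero <- possibleSites$n_possible == 0
  if (any(zero)) {
    warning(sum(zero), " (context, bin) class(es) with zero possible sites excluded")
    possibleSites <- possibleSites[!zero, , drop = FALSE]
  }
  key <- paste(possibleSites$context, possibleSites$methylation_bin)
  obsKey <- paste(neutral$context, neutral$methylation_bin)
  counts <- table(factor(obsKey, levels = key))
  n_observed <- as.integer(counts)
  adj <- ifelse(n_observed == 0, pseudocount, n_observed)
  raw <- adj / possibleSites$n_possible
  scale <- targetMean / weighted.mean(raw, possibleSites$n_possible)
  rates <- data.frame(context = possibleSites$context,
                      methylation_bin = possibleSites$methylation_bin,
                      n_possible = possibleSites$n_possible,
                      n_observed = n_observed,
                      rate = raw * scale,
                      stringsAsFactors = FALSE)
  new("MutabilityTable", rates = rates, targetMean = targetMean)
}

.rateFor <- function(table, context, methylation_bin) {
  key <- paste(table@rates$context, table@rates$methylation_bin)
  idx <- match(paste(context, methylation_bin), key)
  if (anyNA(idx)) {
    bad <- unique(paste(context, methylation_bin)[is.na(idx)])
    stop("unknown (context, methylation bin) class(es): ",
         paste(head(bad, 10), collapse = ", "))
  }
  table@rates$rate[idx]
}

#' Calibrate the mutation-rate to singleton-proportion transformation
#'
#' Regresses the observed proportion of singletons against the scaled
#' mutation rate across (context, methylation-bin) groups of a neutral
#' calibration class (synonymous variants: neutral with respect to UTR
#' biology but distinct from the bases used to build the rate table).
#' Predictions from the fitted line are clipped to \[0, 1\] and give, for
#' any observed variant, the expected chance that it is a singleton.
#'
#' @param synonymous data.frame of calibration observations (filtered with
#'   `purpose = "maps_eval"`), columns context, methylation_bin,
#'   allele_count.
#' @param table a [MutabilityTable-class].
#' @param weighted weight the regression by per-group variant count
#'   (default FALSE: ordinary unweighted least squares).
#' @return A [CalibrationModel-class].
#' @export
calibrateSingletonModel <- function(synonymous, table, weighted = FALSE) {
  key <- paste(synonymous$context, synonymous$methylation_bin)
  singleton <- synonymous$allele_count == 1L
  n <- tapply(singleton, key, length)
  p <- tapply(singleton, key, mean)
  keys <- names(n)
  parts <- strsplit(keys, " ", fixed = TRUE)
  ctx <- vapply(parts, `[`, character(1), 1)
  bin <- vapply(parts, `[`, character(1), 2)
  rate <- .rateFor(table, ctx, bin)
  if (length(unique(rate)) < 2) {
    stop("degenerate calibration input: fewer than 2 distinct rate values")
  }
  groups <- data.frame(context = ctx, methylation_bin = bin, rate = rate,
                       prop_singleton = as.numeric(p), n = as.integer(n),
                       stringsAsFactors = FALSE)
  fit <- if (weighted) lm(prop_singleton ~ rate, data = groups, weights = n)
         else lm(prop_singleton ~ rate, data = groups)
  cf <- coef(fit)
  new("CalibrationModel", intercept = unname(cf[1]), slope = unname(cf[2]),
      weighted = weighted, groups = groups)
}

#' Predicted singleton probability per observation
#'
#' @param model a [CalibrationModel-class].
#' @param table a [MutabilityTable-class].
#' @param obs observations with columns context, methylation_bin.
#' @return numeric vector of probabilities clipped to \[0, 1\].
#' @export
predictSingletonProb <- function(model, table, obs) {
  rate <- .rateFor(table, obs$context, obs$methylation_bin)
  pmin(pmax(model@intercept + model@slope * rate, 0), 1)
}

#' Compute the mutability-adjusted proportion of singletons (MAPS)
#'
#' MAPS = (observed singletons - expected singletons) / observed
#' variants, where the expectation sums each observed variant's
#' calibrated singleton probability given its mutational context. An
#' excess of singletons over the mutability-calibrated expectation
#' (MAPS > 0) indicates negative selection on the variant class.
#'
#' @param obs filtered observations (columns context, methylation_bin,
#'   allele_count).
#' @param model a [CalibrationModel-class].
#' @param table a [MutabilityTable-class].
#' @param nBoot bootstrap replicates for the 90% CI (0 to skip).
#' @param seed RNG seed for the bootstrap (required when nBoot > 0).
#' @return A [MapsResult-class].
#' @export
computeMaps <- function(obs, model, table, nBoot = 0L, seed = NA_integer_) {
  n <- nrow(obs)
  if (n < 1) stop("computeMaps requires at least one observed variant")
  s <- obs$allele_count == 1L
  p <- predictSingletonProb(model, table, obs)
  ns <- sum(s)
  expected <- sum(p)
  m <- (ns - expected) / n
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    ci <- bootstrapCi(obs, model, table, nBoot = nBoot, seed = seed)
  }
  new("MapsResult", nObserved = as.integer(n), nSingletons = as.integer(ns),
      expectedSingletons = expected, maps = m, ci90 = as.numeric(ci),
      nBoot = as.integer(nBoot),
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}

# per-variant contribution: MAPS of a resample = mean(contrib[idx])
.mapsContrib <- function(obs, model, table) {
  (obs$allele_count == 1L) - predictSingletonProb(model, table, obs)
}

#' Bootstrap confidence interval for MAPS
#'
#' Resamples the n observed variants with replacement `nBoot` times,
#' recomputes MAPS on each resample, and returns the 5th and 95th
#' percentiles of the resulting distribution (a 90% interval).
#'
#' @inheritParams computeMaps
#' @param nBoot number of bootstrap replicates (default 10000).
#' @param seed RNG seed (integer).
#' @return numeric length-2 vector (low, high).
#' @export
bootstrapCi <- function(obs, model, table, nBoot = 10000L, seed = 1L) {
  contrib <- .mapsContrib(obs, model, table)
  n <- length(contrib)
  if (n < 1) stop("bootstrapCi requires at least one observed variant")
  if (!is.na(seed)) set.seed(seed)
  reps <- vapply(seq_len(nBoot), function(b) {
    mean(contrib[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  unname(quantile(reps, c(0.05, 0.95)))
}

#' Permutation p-value comparing MAPS of two variant classes
#'
#' Per permutation, both sets are independently bootstrap-resampled and
#' MAPS recomputed for each; the p-value is the proportion of
#' permutations in which MAPS(B) - MAPS(A) < 0, i.e. the evidence that
#' class B is under stronger selection than class A. A p of exactly 0 is
#' reported as "< 1/nPerm".
#'
#' @param obsA,obsB filtered observations for the two classes.
#' @inheritParams computeMaps
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with elements `p` (numeric), `label` (character, the
#'   printable form), `nPerm`, `mapsA`, `mapsB`.
#' @export
permutationPvalue <- function(obsA, obsB, model, table, nPerm = 10000L,
                              seed = 1L) {
  if (!nrow(obsA) || !nrow(obsB)) stop("both variant sets must be non-empty")
  ca <- .mapsContrib(obsA, model, table)
  cb <- .mapsContrib(obsB, model, table)
  na <- length(ca); nb <- length(cb)
  if (!is.na(seed)) set.seed(seed)
  diff <- vapply(seq_len(nPerm), function(b) {
    mean(cb[sample.int(nb, nb, replace = TRUE)]) -
      mean(ca[sample.int(na, na, replace = TRUE)])
  }, numeric(1))
  p <- mean(diff < 0)
  list(p = p,
       label = if (p == 0) paste0("< ", format(1 / nPerm)) else format(p),
       nPerm = as.integer(nPerm),
       mapsA = mean(ca), mapsB = mean(cb))
}
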