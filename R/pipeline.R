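#' Run the full analysis pipeline on simulated or supplied data
#'
#' Orchestrates every stage end to end: simulate (or accept) transcript
#' models and a population variant corpus; enumerate and classify all
#' uAUG-creating SNVs/deletions and stop-removing SNVs; build the
#' mutability table, calibrate the singleton model and compute MAPS with
#' bootstrap CIs per variant class plus permutation p-values against the
#' neutral class; compare conservation of uORF stop bases against matched
#' control bases (threshold proportion, Fisher, Wilcoxon); classify genes
#' into the nine triage classes and the low/moderate/high likelihood
#' groups. Writes TSV/JSON reports and a run manifest (config snapshot,
#' seed, per-stage row counts) to `outDir`; re-running with the same
#' config reproduces byte-identical outputs.
#'
#' @param cfg a [simulationConfig()]; its `seed` drives every stage.
#' @param outDir output directory (created if needed).
#' @param nBoot bootstrap replicates for MAPS CIs.
#' @param nPerm permutations for class-vs-neutral p-values.
#' @param acThreshold allele-count cutoff for gene class 4.
#' @param phylopThreshold conserved-base score cutoff.
#' @param dryRun print the stage plan and exit without computing.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(cfg = simulationConfig(), outDir,
                        nBoot = 1000L, nPerm = 1000L,
                        acThreshold = 15L, phylopThreshold = 2,
                        dryRun = FALSE) {
  stages <- c("simulate-transcripts", "enumerate", "simulate-population",
              "maps", "conservation", "classify-genes", "report")
  if (dryRun) {
    message("pipeline plan: ", paste(stages, collapse = " -> "))
    return(invisible(stages))
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list(tool = "uORFscan",
                   version = as.character(utils::packageVersion("uORFscan")),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "mutationRates")],
                   stages = list())
  rowCount <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # 1. transcripts
  sim <- generateTranscripts(cfg)
  ts <- sim$transcripts
  writeTranscripts(ts, file.path(outDir, "transcripts.fa"),
                   file.path(outDir, "transcripts.tsv"))
  write.table(sim$evidence, file.path(outDir, "evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rowCount("simulate-transcripts", n_transcripts = length(ts),
           n_evidence = nrow(sim$evidence))

  # 2. enumerate + classify
  uorfs <- findUorfs(ts, sim$evidence)
  snvs <- rbind(enumerateUaugSnvs(ts, sim$evidence),
                enumerateStopRemovingSnvs(ts, uorfs))
  dels <- enumerateUaugDeletions(ts, evidence = sim$evidence)
  write.table(uorfs, file.path(outDir, "uorfs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeConsequences(snvs, file.path(outDir, "consequences_snvs.tsv"))
  writeConsequences(dels, file.path(outDir, "consequences_deletions.tsv"))
  rowCount("enumerate", n_uorfs = sum(!is.na(uorfs$stop_start)),
           n_oorfs = sum(uorfs$is_oorf), n_snv_records = nrow(snvs),
           n_deletion_records = nrow(dels),
           n_high_impact = sum(snvs$high_impact))

  # 3. population + MAPS
  pop <- simulatePopulation(cfg, ts)
  neutralTab <- filterObservations(
    pop$observations[pop$observations$region == "intergenic_intronic", ],
    "table_build")
  mutTable <- buildMutabilityTable(neutralTab, pop$possibleSites)
  synEval <- filterObservations(
    pop$observations[pop$observations$region == "synonymous", ], "maps_eval")
  model <- calibrateSingletonModel(synEval, mutTable)
  classes <- names(cfg$singletonInflation)
  mapsRows <- list()
  classObs <- list()
  for (cl in classes) {
    o <- filterObservations(
      pop$observations[pop$observations$region == cl, ], "maps_eval")
    classObs[[cl]] <- o
    res <- computeMaps(o, model, mutTable, nBoot = nBoot, seed = cfg$seed)
    mapsRows[[cl]] <- cbind(class = cl, as.data.frame(res))
  }
  mapsTab <- do.call(rbind, mapsRows)
  rownames(mapsTab) <- NULL
  perms <- list()
  neutralName <- classes[which.min(cfg$singletonInflation)]
  for (cl in setdiff(classes, neutralName)) {
    pv <- permutationPvalue(classObs[[neutralName]], classObs[[cl]],
                            model, mutTable, nPerm = nPerm, seed = cfg$seed)
    perms[[cl]] <- pv
  }
  write.table(mapsTab, file.path(outDir, "maps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rowCount("maps", n_observations = nrow(pop$observations),
           n_table_build = nrow(neutralTab), n_calibration = nrow(synEval),
           n_classes = length(classes))

  # 4. conservation
  stopsIdx <- which(!is.na(uorfs$stop_start))
  funSites <- if (length(stopsIdx)) do.call(rbind, lapply(stopsIdx, function(i) {
    data.frame(transcript_id = uorfs$transcript_id[i],
               pos = uorfs$stop_start[i] + 0:2, stringsAsFactors = FALSE)
  })) else data.frame(transcript_id = character(0), pos = integer(0))
  funSites <- unique(funSites)
  scores <- simulateScores(cfg, ts, funSites)
  controls <- matchedStopControls(uorfs, ts)
  key <- paste(scores$transcript_id, scores$pos)
  stopScores <- scores$score[scores$role == "uorf_stop"]
  ctrlScores <- scores$score[key %in% paste(controls$transcript_id, controls$pos)]
  consStop <- conservedProportion(stopScores, phylopThreshold)
  consCtrl <- conservedProportion(ctrlScores, phylopThreshold)
  fish <- fisher2x2(consStop$k, consStop$n, consCtrl$k, consCtrl$n)
  wil <- wilcoxonRankSum(stopScores, ctrlScores)
  conservation <- list(
    threshold = phylopThreshold,
    stop_bases = consStop, matched_controls = consCtrl,
    fisher = list(odds_ratio = fish$odds_ratio, p = fish$p),
    wilcoxon = wil)
  jsonlite::write_json(conservation, file.path(outDir, "conservation.json"),
                       auto_unbox = TRUE, digits = NA)
  rowCount("conservation", n_stop_bases = consStop$n,
           n_control_bases = consCtrl$n)

  # 5. gene triage
  gt <- generateGeneTable(cfg, ts, snvs, uorfs)
  cls <- classifyGenes(gt$annotation, acThreshold = acThreshold)
  summ <- likelihoodSummary(cls)
  write.table(cls, file.path(outDir, "gene_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rowCount("classify-genes", n_genes = nrow(cls),
           low = summ[["low"]], moderate = summ[["moderate"]],
           high = summ[["high"]], unclassified = summ[["unclassified"]])

  # 6. report + manifest
  report <- list(
    maps = mapsTab,
    permutation_vs_neutral = lapply(perms, function(x)
      list(p = x$p, label = x$label, mapsA = x$mapsA, mapsB = x$mapsB)),
    conservation = conservation,
    likelihood_summary = as.list(summ))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- list.files(outDir)
  manifest$outputs <- files[files != "manifest.json"]
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
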