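#' Run the full SRPS discovery pipeline on simulated data
#'
#' Orchestrates simulate -> tracks -> end-site calling -> abundance ->
#' operon assembly -> PS categorization -> polarity classification ->
#' enrichment -> stem-loop analysis -> report, in dependency order,
#' from a single configuration and master seed. Stage randomness
#' derives deterministically from `config$seed`, so a fixed
#' configuration reproduces its outputs exactly.
#'
#' @param config a `SimConfig` from [simConfig].
#' @param outDir optional directory; when given, stage outputs are
#'   written as FASTA/GFF3/BED/TSV.
#' @param backend folding backend for the stem-loop stage.
#' @param stages character vector of stages to run, in order; later
#'   stages are skipped when their prerequisites are excluded.
#'   `"simulate"` alone emits only the synthetic data.
#' @param quiet suppress progress messages.
#' @return list with the stage outputs: `sim`, `tracks`, `endSites`
#'   (an \linkS4class{EndSiteSet}), `abundance`, `operonMap`,
#'   `psTable`, `psAssociation`, `enrichment` (both backgrounds),
#'   `stemLoops`, `flanks`, `dgComparison`, `protection`, `report`
#'   and `manifest`.
#' @export
runPipeline <- function(config = simConfig(), outDir = NULL,
                        backend = "builtin",
                        stages = c("simulate", "endsites", "abundance",
                                   "operons", "enrich", "structure"),
                        quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  res <- list()
  res$manifest <- list(config = config, seed = config$seed,
                       backend = backend, stages = stages,
                       package_version =
                         as.character(utils::packageVersion("SRPSseq")),
                       started = format(t0))

  say("stage: simulate")
  sim <- simulateGenome(config)
  tracks <- simulateTracks(sim, config)
  res$sim <- sim; res$tracks <- tracks
  if (!is.null(outDir)) writeSimulation(sim, tracks, outDir)
  if (!"endsites" %in% stages) return(res)

  say("stage: endsites")
  conds <- config$conditions
  esPerCond <- list()
  for (cc in conds) {
    hybW <- lapply(tracks$starts[[cc]]$Hyb, detectStartWindows,
                   chrom = sim$genome$id)
    exoW <- lapply(tracks$starts[[cc]]$Exo, detectStartWindows,
                   chrom = sim$genome$id)
    libS <- list(
      hyb = vapply(tracks$starts[[cc]]$Hyb, trackTotal, numeric(1)),
      exo = vapply(tracks$starts[[cc]]$Exo, trackTotal, numeric(1)))
    esPerCond[[cc]] <- callEndSites(hybW, exoW, tracks$starts[[cc]]$Hyb,
                                    tracks$starts[[cc]]$Exo, libS)
  }
  es <- mergeConditions(esPerCond)
  sites <- endSites(es)
  tsSites <- sites[S4Vectors::mcols(sites)$verdict == "TS"]
  S4Vectors::mcols(sites)$category[
    S4Vectors::mcols(sites)$verdict == "TS"] <-
    categorizeTs(tsSites, sim$genes)
  es@sites <- sites
  res$endSites <- es
  res$esPerCondition <- esPerCond
  if (!"abundance" %in% stages) return(res)

  say("stage: abundance")
  counts <- NULL; cond <- c(); repl <- c()
  for (cc in conds) for (r in 1:2) {
    counts <- cbind(counts, geneCounts(tracks$coverage[[cc]][[r]], sim$genes))
    cond <- c(cond, cc); repl <- c(repl, r)
  }
  colnames(counts) <- paste(cond, repl, sep = "_rep")
  abund <- normalizeTa(counts, condition = cond, replicate = repl)
  res$abundance <- abund
  if (!"operons" %in% stages) return(res)

  say("stage: operons")
  hybCov <- unlist(tracks$coverage, recursive = FALSE)
  opMap <- assembleOperons(sim$genes, es, hybCov)
  opMap <- classifyPolarity(opMap, abund)
  psSites <- sites[S4Vectors::mcols(sites)$verdict == "PS"]
  psTable <- categorizePs(psSites, opMap, sim$genes)
  S4Vectors::mcols(sites)$category[
    S4Vectors::mcols(sites)$verdict == "PS"] <- psTable$category
  es@sites <- sites
  res$endSites <- es
  assoc <- associatePs(opMap, psTable, abund)
  res$operonMap <- opMap; res$psTable <- psTable; res$psAssociation <- assoc
  if (!"enrich" %in% stages) { res$report <- srpsReport(res); return(res) }

  say("stage: enrich")
  res$enrichment <- list(
    psOperons = tryCatch(
      patternEnrichment(psTable, opMap, background = "psOperons"),
      error = function(e) NULL),
    allPolycistronic = tryCatch(
      patternEnrichment(psTable, opMap, background = "allPolycistronic"),
      error = function(e) NULL))
  fgGenes <- unique(c(psTable$upstream_gene, psTable$downstream_gene))
  fgGenes <- fgGenes[!is.na(fgGenes)]
  res$cogEnrichment <- cogEnrichment(fgGenes, sim$genes)
  if (!"structure" %in% stages) { res$report <- srpsReport(res); return(res) }

  say("stage: structure")
  flanksPs <- extractPsFlank(
    sim$genome,
    GenomicRanges::GRanges(sim$genome$id,
                           IRanges::IRanges(psTable$pos, width = 1L),
                           strand = psTable$strand,
                           category = psTable$category))
  flanksCtrl <- extractControlFlanks(sim$genome, opMap, psTable, sim$genes)
  flanks <- rbind(flanksPs, flanksCtrl)
  flanks$class[is.na(flanks$class)] <- "unassigned"
  flanks$dG <- vapply(flanks$seq, function(s)
    foldMfe(s, backend = backend)$dG, numeric(1), USE.NAMES = FALSE)
  res$flanks <- flanks
  grp <- ifelse(flanks$class == "control", "control", "PS")
  res$dgComparison <- if (all(table(grp) >= 2) && length(unique(grp)) == 2)
    compareDgGroups(flanks$dG, grp) else NULL
  sl <- scanStemLoops(sim$genome, psTable, backend = backend)
  S4Vectors::mcols(sl)$polyU <- polyUTerminatorFlag(sl, sim$genome)
  res$stemLoops <- sl
  res$protection <- tryCatch(
    protectionCorrelation(sl, res$abundance),
    error = function(e) NULL)

  res$report <- srpsReport(res)
  res$manifest$finished <- format(Sys.time())
  if (!is.null(outDir)) .writeStageOutputs(res, outDir)
  res
}

#' Tabulate headline pipeline results
#'
#' Category tallies (gTS/iTS/nTS and uPS/iPS/cPS), per-condition and
#' shared site counts, operon polarity-pattern tallies, enrichment and
#' stem-loop summaries, and the dG-ratio correlation — the machine
#' counterpart of the study's headline tables.
#'
#' @param results list of stage outputs from [runPipeline] (at least
#'   the end-site stage).
#' @return list of tallies; printable with [str] or written by
#'   `runPipeline(outDir=)`.
#' @export
srpsReport <- function(results) {
  stopifnot(!is.null(results$endSites))
  sites <- endSites(results$endSites)
  mc <- S4Vectors::mcols(sites)
  rep <- list()
  rep$nSites <- length(sites)
  rep$verdicts <- table(factor(mc$verdict, c("TS", "PS", "ambiguous")))
  rep$tsCategories <- table(factor(mc$category[mc$verdict == "TS"],
                                   c("gTS", "iTS", "nTS")))
  rep$psCategories <- table(factor(mc$category[mc$verdict == "PS"],
                                   c("uPS", "iPS", "cPS", "unassigned")))
  rep$perCondition <- conditionSummary(results$endSites)
  if (!is.null(results$operonMap)) {
    omc <- S4Vectors::mcols(operonRanges(results$operonMap))
    rep$nOperons <- length(results$operonMap)
    rep$monocistronic <- sum(omc$n_genes == 1L)
    rep$polycistronic <- sum(omc$n_genes > 1L)
    rep$patterns <- table(factor(omc$pattern[omc$n_genes > 1L],
                                 c("Down", "Flat", "Up", "Complex",
                                   "unknown")))
  }
  if (!is.null(results$enrichment)) rep$enrichment <- results$enrichment
  if (!is.null(results$psAssociation))
    rep$maxTaIpsFraction <- results$psAssociation$maxTaIpsFraction
  if (!is.null(results$stemLoops)) {
    rep$nStemLoops <- length(results$stemLoops)
    if (length(results$stemLoops))
      rep$polyUFraction <-
        mean(S4Vectors::mcols(results$stemLoops)$polyU)
  }
  if (!is.null(results$protection)) rep$protectionR <- results$protection$r
  if (!is.null(results$dgComparison)) rep$dgComparison <- results$dgComparison
  rep
}

.writeStageOutputs <- function(res, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  w <- function(df, name) write.table(
    df, file.path(outDir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sites <- endSites(res$endSites)
  w(as.data.frame(sites), "end_sites.tsv")
  if (!is.null(res$operonMap)) {
    odf <- as.data.frame(operonRanges(res$operonMap))
    odf$genes <- vapply(odf$genes, paste, "", collapse = ",")
    w(odf, "operons.tsv")
  }
  if (!is.null(res$psTable)) w(res$psTable, "ps_table.tsv")
  if (!is.null(res$enrichment$psOperons))
    w(res$enrichment$psOperons, "enrichment_psOperons.tsv")
  if (!is.null(res$enrichment$allPolycistronic))
    w(res$enrichment$allPolycistronic, "enrichment_allPolycistronic.tsv")
  if (!is.null(res$flanks)) w(res$flanks, "flanks.tsv")
  if (!is.null(res$stemLoops)) w(as.data.frame(res$stemLoops),
                                 "stem_loops.tsv")
  invisible(outDir)
}
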