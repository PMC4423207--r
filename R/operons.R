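#' Assemble operons from TSs, coverage contiguity and read-pair links
#'
#' Adjacent same-strand genes are joined into one operon when their
#' intergenic gap shows transcriptional contiguity — per-base coverage
#' of at least `covFloor` times the flanking genes' mean coverage over
#' at least `contFrac` of the gap — or when at least `minPairs` read
#' pairs bridge them; a same-strand TS inside the gap (a promoter for
#' the downstream gene) always splits. External operon predictions
#' break ties only: a pair failing the coverage rule but sharing a
#' predicted operon is joined when the gap still reaches half the
#' required contiguity. Every gene belongs to exactly one operon.
#'
#' @param genes gene annotation GRanges with `gene_id`.
#' @param tsSites GRanges of TS anchors (or an
#'   \linkS4class{EndSiteSet}, from which TS-verdict sites are taken).
#' @param coverage a \linkS4class{PositionTrack} of Hyb read coverage,
#'   or a list of them (averaged).
#' @param pairLinks optional data.frame (`gene_a`, `gene_b`,
#'   `n_pairs`) of read-pair bridge counts.
#' @param predictions optional data.frame (`gene_id`, `operon_id`) of
#'   external operon predictions (DOOR-style).
#' @param covFloor,contFrac,minPairs contiguity parameters.
#' @param utrMax maximal TS-to-first-gene distance when attaching an
#'   operon's primary TS.
#' @return an \linkS4class{OperonMap}.
#' @export
assembleOperons <- function(genes, tsSites, coverage, pairLinks = NULL,
                            predictions = NULL, covFloor = 0.2,
                            contFrac = 0.9, minPairs = 3L, utrMax = 700L) {
  if (is(tsSites, "EndSiteSet")) {
    s <- endSites(tsSites)
    tsSites <- s[S4Vectors::mcols(s)$verdict == "TS"]
  }
  if (is.list(coverage) && !is(coverage, "PositionTrack")) {
    acc <- coverage[[1]]
    plus <- acc@plus; minus <- acc@minus
    if (length(coverage) > 1) for (tr in coverage[-1]) {
      plus <- plus + tr@plus; minus <- minus + tr@minus
    }
    coverage <- PositionTrack(plus / length(coverage),
                              minus / length(coverage))
  }
  chrom <- if (length(genes)) as.character(GenomicRanges::seqnames(genes))[1]
           else "simchr"
  tsPos <- GenomicRanges::start(tsSites)
  tsStrand <- as.character(GenomicRanges::strand(tsSites))

  opList <- list()
  for (st in c("+", "-")) {
    g <- genes[as.character(GenomicRanges::strand(genes)) == st]
    if (!length(g)) next
    g <- g[order(GenomicRanges::start(g))]
    gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
    gid <- S4Vectors::mcols(g)$gene_id
    if (length(g) > 1 && any(gs[-1] <= ge[-length(g)]))
      warning("overlapping same-strand genes; forcing a split at overlap")
    cov <- trackStrand(coverage, st)
    covMean <- vapply(seq_along(g), function(i)
      mean(cov[gs[i]:ge[i]]), numeric(1))
    join <- logical(max(0L, length(g) - 1L))
    for (i in seq_along(join)) {
      gapS <- ge[i] + 1L; gapE <- gs[i + 1] - 1L
      overlap <- gapE < gapS
      if (!overlap) {
        floorLvl <- covFloor * mean(covMean[i:(i + 1)])
        frac <- mean(cov[gapS:gapE] >= floorLvl)
        covOK <- frac >= contFrac
      } else { covOK <- FALSE; frac <- 0 }
      pairOK <- FALSE
      if (!is.null(pairLinks)) {
        hit <- (pairLinks$gene_a == gid[i] & pairLinks$gene_b == gid[i + 1]) |
               (pairLinks$gene_a == gid[i + 1] & pairLinks$gene_b == gid[i])
        pairOK <- any(hit) && sum(pairLinks$n_pairs[hit]) >= minPairs
      }
      tsIn <- !overlap && any(tsStrand == st & tsPos >= gapS & tsPos <= gapE)
      join[i] <- (covOK || pairOK) && !tsIn
      if (!join[i] && !tsIn && !overlap && !is.null(predictions)) {
        pa <- predictions$operon_id[match(gid[i], predictions$gene_id)]
        pb <- predictions$operon_id[match(gid[i + 1], predictions$gene_id)]
        if (!is.na(pa) && !is.na(pb) && pa == pb && frac >= contFrac / 2)
          join[i] <- TRUE
      }
      if (overlap) join[i] <- FALSE
    }
    memb <- cumsum(c(1L, !join))
    for (mm in unique(memb)) {
      idx <- which(memb == mm)
      ids <- gid[idx]
      if (st == "-") ids <- rev(ids)      # 5' to 3' on the coding strand
      spanS <- min(gs[idx]); spanE <- max(ge[idx])
      # attach the nearest upstream same-strand TS within utrMax
      if (st == "+") {
        cand <- which(tsStrand == "+" & tsPos < spanS & tsPos >= spanS - utrMax)
        tsp <- if (length(cand)) max(tsPos[cand]) else NA_integer_
        if (!is.na(tsp)) spanS <- tsp
      } else {
        cand <- which(tsStrand == "-" & tsPos > spanE & tsPos <= spanE + utrMax)
        tsp <- if (length(cand)) min(tsPos[cand]) else NA_integer_
        if (!is.na(tsp)) spanE <- tsp
      }
      opList[[length(opList) + 1L]] <- list(
        strand = st, genes = ids, start = spanS, end = spanE, ts = tsp)
    }
  }
  o <- order(vapply(opList, `[[`, 0, "start"))
  opList <- opList[o]
  gr <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(vapply(opList, `[[`, 0, "start"),
                     vapply(opList, `[[`, 0, "end")),
    strand = vapply(opList, `[[`, "", "strand"),
    operon_id = sprintf("OP%04d", seq_along(opList)),
    genes = IRanges::CharacterList(lapply(opList, `[[`, "genes")),
    n_genes = lengths(lapply(opList, `[[`, "genes")),
    pattern = "unknown",
    ts_pos = vapply(opList, function(x)
      if (is.na(x$ts)) NA_integer_ else as.integer(x$ts), integer(1)))
  new("OperonMap", operons = gr)
}

#' Polarity pattern of a TA vector
#'
#' Classifies the consecutive-gene transcript-abundance steps of one
#' operon, genes ordered 5' to 3'. A step from gene X to the next gene
#' Y is `Down` when log2(TA_X/TA_Y) > 0.5, `Up` when < -0.5 and `Flat`
#' when within the closed interval [-0.5, 0.5]. The operon is labelled
#' by the common step class, or `Complex` when step classes mix. Fewer
#' than two genes, or any TA below `taFloor`, gives `unknown`.
#'
#' @param ta numeric vector of per-gene TA, 5' to 3'.
#' @param taFloor minimal TA for a reliable ratio.
#' @return one of "Down", "Flat", "Up", "Complex", "unknown".
#' @examples
#' polarityPattern(c(8, 4, 2, 1))   # Down
#' polarityPattern(c(5, 5, 5))      # Flat
#' @export
polarityPattern <- function(ta, taFloor = 1) {
  if (length(ta) < 2L) return("unknown")
  if (anyNA(ta) || any(ta < taFloor)) return("unknown")
  lr <- log2(ta[-length(ta)] / ta[-1])
  step <- ifelse(lr > 0.5, "Down", ifelse(lr < -0.5, "Up", "Flat"))
  if (all(step == "Down")) "Down"
  else if (all(step == "Flat")) "Flat"
  else if (all(step == "Up")) "Up"
  else "Complex"
}

#' Classify operon polarity patterns from transcript abundance
#'
#' Computes the per-condition pattern of every polycistronic operon and
#' a merged label (the condition-majority; ties give `Complex`).
#' Monocistronic operons keep `unknown`.
#'
#' @param operonMap an \linkS4class{OperonMap}.
#' @param abundance a \linkS4class{TranscriptAbundance} covering all
#'   member genes.
#' @param condition optional single condition to classify on; default
#'   uses all conditions plus the majority rule.
#' @param taFloor minimal replicate-mean TA for a reliable ratio.
#' @return the OperonMap with `pattern` (merged) and per-condition
#'   `pattern_<condition>` metadata columns filled in.
#' @export
classifyPolarity <- function(operonMap, abundance, condition = NULL,
                             taFloor = 1) {
  condTA <- conditionTA(abundance)
  conds <- if (is.null(condition)) colnames(condTA) else condition
  if (!all(conds %in% colnames(condTA)))
    stop("unknown condition: ", setdiff(conds, colnames(condTA))[1])
  ops <- operonRanges(operonMap)
  mc <- S4Vectors::mcols(ops)
  perCond <- matrix("unknown", nrow = length(ops), ncol = length(conds),
                    dimnames = list(NULL, conds))
  for (i in seq_along(ops)) {
    gid <- mc$genes[[i]]
    if (length(gid) < 2L) next
    if (!all(gid %in% rownames(condTA)))
      stop("missing TA for gene: ", setdiff(gid, rownames(condTA))[1])
    for (cc in conds)
      perCond[i, cc] <- polarityPattern(condTA[gid, cc], taFloor)
  }
  merged <- apply(perCond, 1, function(x) {
    x <- x[x != "unknown"]
    if (!length(x)) return("unknown")
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "Complex" else names(tab)[1]
  })
  mc$pattern <- unname(merged)
  for (cc in conds) mc[[paste0("pattern_", cc)]] <- perCond[, cc]
  S4Vectors::mcols(ops) <- mc
  new("OperonMap", operons = ops)
}

#' Associate PSs with operons and flag iPS-flanked genes
#'
#' Assigns each categorized PS to the operon whose span contains it,
#' flags every gene's 5'- and 3'-flanking iPSs (an iPS between genes X
#' and Y gives X a 3'-iPS flag and Y a 5'-iPS flag), and — when
#' abundance is supplied — reports, among operons harbouring at least
#' one iPS, the fraction whose maximal-TA gene is iPS-flanked.
#'
#' @param operonMap an \linkS4class{OperonMap}.
#' @param psTable data.frame from [categorizePs].
#' @param abundance optional \linkS4class{TranscriptAbundance}.
#' @param condition optional condition for the max-TA computation
#'   (default: mean over conditions).
#' @return list with `table` (PSs assigned to operons), `geneFlags`
#'   (per-gene logical `five_prime_ips`, `three_prime_ips`) and
#'   `maxTaIpsFraction` (NA without abundance).
#' @export
associatePs <- function(operonMap, psTable, abundance = NULL,
                        condition = NULL) {
  tab <- psTable[!is.na(psTable$operon_id), , drop = FALSE]
  ipsTab <- tab[tab$category == "iPS", , drop = FALSE]
  allGenes <- unique(unlist(operonGenes(operonMap)))
  geneFlags <- data.frame(
    gene_id = allGenes,
    five_prime_ips = allGenes %in% ipsTab$downstream_gene,
    three_prime_ips = allGenes %in% ipsTab$upstream_gene,
    stringsAsFactors = FALSE)
  frac <- NA_real_
  if (!is.null(abundance) && nrow(ipsTab)) {
    condTA <- conditionTA(abundance)
    ta <- if (is.null(condition)) rowMeans(condTA) else condTA[, condition]
    mc <- S4Vectors::mcols(operonRanges(operonMap))
    flanked <- vapply(unique(ipsTab$operon_id), function(oid) {
      gid <- mc$genes[[match(oid, mc$operon_id)]]
      maxGene <- gid[which.max(ta[gid])]
      fl <- geneFlags[match(maxGene, geneFlags$gene_id), ]
      isTRUE(fl$five_prime_ips || fl$three_prime_ips)
    }, logical(1))
    frac <- mean(flanked)
  }
  list(table = tab, geneFlags = geneFlags, maxTaIpsFraction = frac)
}
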