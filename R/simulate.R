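#' Simulation configuration
#'
#' Parameters of the synthetic dRNA-Seq study. Defaults emulate a small
#' cellulolytic-clostridium-like chromosome segment: a low-GC genome,
#' operons whose polarity-pattern mix mirrors published genome-wide
#' tallies, a single genuine promoter per operon 20-700 bases upstream
#' of the first gene, and intergenic processed sites whose downstream
#' segment is protected by a 3' stem-loop of planted folding energy.
#'
#' @param genomeLength genome size in bases.
#' @param nOperons number of operons to plant.
#' @param genesPerOperon length-2 integer range of genes per operon.
#' @param patternMix named proportions over Down/Flat/Up/Complex for
#'   polycistronic operons; must sum to 1.
#' @param plantedPsRate per-intergenic-junction probability scale for
#'   planting processed sites (0 disables all PSs).
#' @param stemloopDgRange kcal/mol interval (low, high) for planted
#'   stem-loop folding energies; both entries must be below -5.
#' @param depthPerSite expected read starts at a planted site.
#' @param dispersion negative-binomial dispersion of site counts
#'   (0 gives Poisson noise).
#' @param exoRetention fraction of processed-transcript start signal
#'   surviving the 5'-monophosphate-dependent exonuclease (0-1). The
#'   true digestion efficiency of the enzyme is unknown; 0.05 is a
#'   model choice, not a measured value.
#' @param decayLength bases of geometric downstream smear of read
#'   starts around the true 5' end.
#' @param conditions names of growth conditions to emit.
#' @param gcContent genome GC fraction.
#' @param seed master seed; all stage seeds derive from it.
#' @return validated configuration list of class `SimConfig`.
#' @export
simConfig <- function(genomeLength = 60000L,
                      nOperons = 12L,
                      genesPerOperon = c(1L, 5L),
                      patternMix = c(Down = 0.25, Flat = 0.16,
                                     Up = 0.28, Complex = 0.31),
                      plantedPsRate = 0.4,
                      stemloopDgRange = c(-25, -8),
                      depthPerSite = 200,
                      dispersion = 0.1,
                      exoRetention = 0.05,
                      decayLength = 3,
                      conditions = c("cellulose", "cellobiose", "glucose"),
                      gcContent = 0.37,
                      seed = 1L) {
  patternMix <- unlist(patternMix)
  genesPerOperon <- as.integer(unlist(genesPerOperon))
  stemloopDgRange <- as.numeric(unlist(stemloopDgRange))
  if (genomeLength <= 0) stop("genomeLength must be positive")
  if (!setequal(names(patternMix), c("Down", "Flat", "Up", "Complex")))
    stop("patternMix must name Down, Flat, Up, Complex")
  patternMix <- patternMix[c("Down", "Flat", "Up", "Complex")]
  if (abs(sum(patternMix) - 1) > 1e-6) stop("patternMix must sum to 1")
  if (exoRetention < 0 || exoRetention > 1)
    stop("exoRetention must be in [0, 1]")
  if (length(genesPerOperon) != 2L || genesPerOperon[1] > genesPerOperon[2] ||
      genesPerOperon[1] < 1L)
    stop("genesPerOperon must be a non-degenerate or fixed range >= 1")
  if (length(stemloopDgRange) != 2L ||
      stemloopDgRange[1] > stemloopDgRange[2] ||
      stemloopDgRange[2] >= -5)
    stop("stemloopDgRange must be an interval below -5 kcal/mol")
  if (plantedPsRate < 0 || plantedPsRate > 1)
    stop("plantedPsRate must be in [0, 1]")
  if (decayLength <= 0) stop("decayLength must be positive")
  cfg <- list(genomeLength = as.integer(genomeLength),
              nOperons = as.integer(nOperons),
              genesPerOperon = genesPerOperon,
              patternMix = patternMix,
              plantedPsRate = plantedPsRate,
              stemloopDgRange = stemloopDgRange,
              depthPerSite = depthPerSite,
              dispersion = dispersion,
              exoRetention = exoRetention,
              decayLength = decayLength,
              conditions = as.character(conditions),
              gcContent = gcContent,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# design a DNA hairpin (coding-strand orientation) whose builtin-model
# folding energy is near dgTarget; returns list(seq, dg)
designHairpin <- function(dgTarget) {
  nstack <- max(4L, round((abs(dgTarget) + 5.6) / 3.1))
  draw <- function(n) {
    pairs <- matrix(c("G", "C", "C", "G", "A", "T", "T", "A"), ncol = 2,
                    byrow = TRUE)
    idx <- sample(1:4, n, replace = TRUE, prob = c(0.38, 0.38, 0.12, 0.12))
    pairs[idx, , drop = FALSE]
  }
  pr <- draw(nstack)
  mk <- function(pr) {
    paste0(paste(pr[, 1], collapse = ""), "GAAA",
           paste(rev(pr[, 2]), collapse = ""))
  }
  sq <- mk(pr)
  dg <- foldMfe(sq, backend = "builtin")$dG
  tries <- 0L
  while (dg > min(-5.5, dgTarget + 3) && tries < 12L) {
    pr <- rbind(c("G", "C"), pr, deparse.level = 0)
    sq <- mk(pr)
    dg <- foldMfe(sq, backend = "builtin")$dG
    tries <- tries + 1L
  }
  list(seq = sq, dg = dg)
}

#' Simulate a genome, annotation and SRPS ground truth
#'
#' Plants `nOperons` stranded operons on a random genome: each operon
#' carries exactly one genuine TS 20-700 bases upstream of its first
#' gene, an intended per-gene relative abundance profile drawn from its
#' polarity pattern, and (at the configured rate) processed sites in
#' its 5'-UTR (uPS), intergenic junctions (iPS) or CDSs (cPS). Complex
#' operons realise the SRPS configuration: an interior "protected" gene
#' whose downstream junction carries an iPS preceded by an embedded
#' stem-loop; the protected gene's intended abundance exceeds both
#' neighbours by a factor that grows as the stem-loop energy drops.
#'
#' @param config a `SimConfig` from [simConfig].
#' @return list with `genome` (list id/seq/circular), `genes` (GRanges),
#'   `truth` (list of data.frames: `ts`, `ps`, `stemLoops`, `taProfile`,
#'   `operons`) and `config`.
#' @export
simulateGenome <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  glen <- config$genomeLength
  gc <- config$gcContent
  seqv <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  nOp <- config$nOperons
  rate <- config$plantedPsRate
  # operon skeletons in local (transcription-direction) coordinates
  skel <- vector("list", nOp)
  for (k in seq_len(nOp)) {
    ng <- sample(seq(config$genesPerOperon[1], config$genesPerOperon[2]), 1)
    pattern <- if (ng >= 2)
      sample(names(config$patternMix), 1, prob = config$patternMix)
    else "unknown"
    if (pattern == "Complex" && ng < 3) ng <- 3L
    geneLens <- sample(seq(300L, 900L, 3L), ng, replace = TRUE)
    gaps <- if (ng > 1) sample(60:160, ng - 1, replace = TRUE) else integer(0)
    utr <- sample(20:700, 1)
    strand <- sample(c("+", "-"), 1)
    skel[[k]] <- list(ng = ng, pattern = pattern, geneLens = geneLens,
                      gaps = gaps, utr = utr, strand = strand,
                      blockLen = utr + sum(geneLens) + sum(gaps))
  }
  minSpacer <- 300L
  need <- sum(vapply(skel, `[[`, 0, "blockLen")) + (nOp + 1L) * minSpacer
  if (need > glen)
    stop("genome too short for requested operon content: need ", need,
         " bases, have ", glen, " (deficit ", need - glen, ")")
  extra <- glen - need
  w <- runif(nOp + 1L)
  spacers <- minSpacer + floor(w / sum(w) * extra)
  spacers[nOp + 1L] <- spacers[nOp + 1L] + (glen - need - sum(spacers - minSpacer))

  geneRows <- list(); tsRows <- list(); psRows <- list()
  slRows <- list(); taRows <- list(); opRows <- list()
  gi <- 0L
  cur <- 1L
  cogAlphabet <- c("C", "E", "G", "J", "K", "L", "M", "O", "R", "T")

  for (k in seq_len(nOp)) {
    sk <- skel[[k]]
    cur <- cur + spacers[k]
    s <- cur; e <- s + sk$blockLen - 1L
    cur <- e + 1L
    opid <- sprintf("OP%03d", k)
    toGenome <- function(local) if (sk$strand == "+") s + local else e - local
    # local gene intervals (0-based local axis, TS at 0)
    gs <- integer(sk$ng); ge <- integer(sk$ng)
    pos <- sk$utr
    for (i in seq_len(sk$ng)) {
      gs[i] <- pos; ge[i] <- pos + sk$geneLens[i] - 1L
      pos <- ge[i] + 1L + if (i < sk$ng) sk$gaps[i] else 0L
    }
    gids <- sprintf("g%03d", gi + seq_len(sk$ng)); gi <- gi + sk$ng

    # intended relative abundance by pattern
    ng <- sk$ng
    ta <- rep(1, ng)
    protected <- NA_integer_; plantIps <- integer(0); slLocal <- list()
    if (sk$pattern == "Down") {
      ta <- 2^(-cumsum(c(0, runif(ng - 1, 0.7, 1.5))))
    } else if (sk$pattern == "Up") {
      ta <- 2^(cumsum(c(0, runif(ng - 1, 0.7, 1.5))))
    } else if (sk$pattern == "Flat") {
      ta <- 2^runif(ng, -0.25, 0.25)
    } else if (sk$pattern == "Complex") {
      ta <- 2^runif(ng, -0.2, 0.2)
      protected <- if (ng > 2) sample(2:(ng - 1), 1) else 2L
      if (runif(1) < min(1, rate * 2.5)) plantIps <- protected
      if (length(plantIps)) {
        dgT <- runif(1, config$stemloopDgRange[1], config$stemloopDgRange[2])
        hp <- designHairpin(dgT)
        boost <- 2^(0.6 + 0.15 * (-5 - hp$dg))
        ta[protected] <- ta[protected] * boost
        slLocal[[1]] <- hp
      } else {
        # no iPS planted: zigzag profile still yields a Complex pattern
        ta[protected] <- ta[protected] * 2^runif(1, 0.8, 1.5)
      }
    }

    # PS planting (local positions)
    psLocal <- list()
    if (ng > 1 && rate > 0) {
      for (j in seq_len(ng - 1)) {              # junction after gene j
        gapStart <- ge[j] + 1L; gapEnd <- gs[j + 1] - 1L
        if (length(plantIps) && j == plantIps[1]) {
          hp <- slLocal[[1]]
          hl <- nchar(hp$seq)
          psPos <- min(gapEnd - 8L, max(gapStart + hl + 6L,
                                        gapStart + (gapEnd - gapStart) %/% 2L))
          hpEnd <- psPos - 4L; hpStart <- hpEnd - hl + 1L
          psLocal[[length(psLocal) + 1L]] <-
            list(pos = psPos, cat = "iPS", up = gids[j], dn = gids[j + 1])
          slRows[[length(slRows) + 1L]] <- data.frame(
            start = min(toGenome(hpStart), toGenome(hpEnd)),
            end = max(toGenome(hpStart), toGenome(hpEnd)),
            strand = sk$strand, dG = hp$dg, protected_gene = gids[j],
            ips_pos = toGenome(psPos), operon_id = opid, seq = hp$seq,
            stringsAsFactors = FALSE)
          # embed hairpin on the coding strand
          gpos <- if (sk$strand == "+") (s + hpStart):(s + hpEnd)
                  else (e - hpEnd):(e - hpStart)
          emb <- if (sk$strand == "+") hp$seq else revcompChar(hp$seq)
          seqv[gpos] <- strsplit(emb, "")[[1]]
        } else if (runif(1) < rate * 0.2 && gapEnd - gapStart >= 20L) {
          psLocal[[length(psLocal) + 1L]] <- list(
            pos = gapStart + sample(8L:(gapEnd - gapStart - 8L), 1),
            cat = "iPS", up = gids[j], dn = gids[j + 1])
        }
      }
    }
    if (rate > 0 && sk$utr >= 60L && runif(1) < rate * 0.5)
      psLocal[[length(psLocal) + 1L]] <- list(
        pos = sample(15L:(sk$utr - 15L), 1), cat = "uPS",
        up = NA_character_, dn = gids[1])
    if (rate > 0) for (i in seq_len(ng)) if (runif(1) < rate * 0.25)
      psLocal[[length(psLocal) + 1L]] <- list(
        pos = gs[i] + sample(50L:(sk$geneLens[i] - 50L), 1), cat = "cPS",
        up = gids[i], dn = gids[i])

    condSupport <- function() {
      if (runif(1) < 0.75) config$conditions
      else sample(config$conditions, length(config$conditions) - 1L)
    }
    tsRows[[k]] <- data.frame(
      pos = toGenome(0L), strand = sk$strand, operon_id = opid,
      conditions = paste(condSupport(), collapse = ","),
      stringsAsFactors = FALSE)
    for (p in psLocal)
      psRows[[length(psRows) + 1L]] <- data.frame(
        pos = toGenome(p$pos), strand = sk$strand, category = p$cat,
        operon_id = opid, upstream_gene = p$up, downstream_gene = p$dn,
        conditions = paste(condSupport(), collapse = ","),
        stringsAsFactors = FALSE)

    opBase <- exp(rnorm(1, log(30), 0.4))
    for (i in seq_len(ng)) {
      a <- toGenome(gs[i]); b <- toGenome(ge[i])
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        start = min(a, b), end = max(a, b), strand = sk$strand,
        gene_id = gids[i], cog = sample(cogAlphabet, 1),
        stringsAsFactors = FALSE)
      taRows[[length(taRows) + 1L]] <- data.frame(
        gene_id = gids[i], operon_id = opid, strand = sk$strand,
        ta = ta[i], op_base = opBase, order = i, stringsAsFactors = FALSE)
    }
    opRows[[k]] <- data.frame(
      operon_id = opid, strand = sk$strand, n_genes = ng,
      pattern = sk$pattern, ts_pos = toGenome(0L),
      span_start = s, span_end = e,
      genes = paste(gids, collapse = ","), stringsAsFactors = FALSE)
  }

  genesDf <- do.call(rbind, geneRows)
  genes <- GenomicRanges::GRanges(
    seqnames = "simchr",
    ranges = IRanges::IRanges(start = genesDf$start, end = genesDf$end),
    strand = genesDf$strand,
    gene_id = genesDf$gene_id, feature_type = "CDS", cog = genesDf$cog)
  genes <- genes[order(GenomicRanges::start(genes))]
  truth <- list(
    ts = do.call(rbind, tsRows),
    ps = if (length(psRows)) do.call(rbind, psRows) else
      data.frame(pos = integer(0), strand = character(0),
                 category = character(0), operon_id = character(0),
                 upstream_gene = character(0), downstream_gene = character(0),
                 conditions = character(0)),
    stemLoops = if (length(slRows)) do.call(rbind, slRows) else
      data.frame(start = integer(0), end = integer(0), strand = character(0),
                 dG = numeric(0), protected_gene = character(0),
                 ips_pos = integer(0), operon_id = character(0),
                 seq = character(0)),
    taProfile = do.call(rbind, taRows),
    operons = do.call(rbind, opRows))
  list(genome = list(id = "simchr",
                     seq = Biostrings::DNAString(paste(seqv, collapse = "")),
                     circular = FALSE),
       genes = genes, truth = truth, config = config)
}

# expected (mean) Hyb/Exo start rates at each planted site
expectedSiteRates <- function(truth, config) {
  d <- config$depthPerSite
  rbind(
    if (nrow(truth$ts)) data.frame(pos = truth$ts$pos, strand = truth$ts$strand,
                                   kind = "TS", hyb = d, exo = d),
    if (nrow(truth$ps)) data.frame(pos = truth$ps$pos, strand = truth$ps$strand,
                                   kind = "PS", hyb = d,
                                   exo = config$exoRetention * d))
}

# one negative-binomial draw around mu (Poisson when dispersion == 0)
rSiteCount <- function(mu, dispersion) {
  if (mu <= 0) return(0L)
  if (dispersion <= 0) rpois(1, mu) else rnbinom(1, mu = mu, size = 1 / dispersion)
}

# scatter n starts downstream of pos with geometric positional smear
smearStarts <- function(vec, pos, n, strand, decayLength) {
  if (n <= 0) return(vec)
  q <- exp(-1 / decayLength)
  offs <- 0:ceiling(6 * decayLength)
  pr <- (1 - q) * q^offs
  counts <- as.vector(rmultinom(1, n, pr))
  tgt <- if (strand == "+") pos + offs else pos - offs
  ok <- tgt >= 1 & tgt <= length(vec)
  vec[tgt[ok]] <- vec[tgt[ok]] + counts[ok]
  vec
}

#' Simulate paired Hyb/Exo read-start and coverage tracks
#'
#' Emits, per condition, two replicates of each of the Hyb (all
#' transcripts) and Exo (primary transcripts only) start tracks, plus
#' two replicates of Hyb read coverage. Expected start counts are
#' `depthPerSite` at every planted TS in both libraries; at planted PSs
#' the Exo expectation is `exoRetention` times the Hyb expectation.
#' Counts are negative-binomial around expectation, start positions
#' smear downstream geometrically over `decayLength` bases, and
#' uniform background starts totalling 1% of the summed per-site depth
#' are scattered over the genome.
#'
#' @param sim output of [simulateGenome].
#' @param config a `SimConfig`; defaults to the one in `sim`.
#' @return list with `starts[[condition]][[library]][[replicate]]`
#'   (\linkS4class{PositionTrack}), `coverage[[condition]][[replicate]]`
#'   and `libSizes` (named per condition/library/replicate).
#' @export
simulateTracks <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  glen <- config$genomeLength
  truth <- sim$truth
  sites <- rbind(
    data.frame(pos = truth$ts$pos, strand = truth$ts$strand, kind = "TS",
               conditions = truth$ts$conditions),
    if (nrow(truth$ps)) data.frame(pos = truth$ps$pos, strand = truth$ps$strand,
                                   kind = "PS", conditions = truth$ps$conditions))
  nSites <- nrow(sites)
  bgTotal <- 0.01 * config$depthPerSite * nSites

  starts <- list(); coverage <- list(); libSizes <- c()
  ta <- truth$taProfile
  geneIdx <- match(S4Vectors::mcols(sim$genes)$gene_id, ta$gene_id)

  for (cond in config$conditions) {
    starts[[cond]] <- list(Hyb = list(), Exo = list())
    coverage[[cond]] <- list()
    for (lib in c("Hyb", "Exo")) for (r in 1:2) {
      plus <- numeric(glen); minus <- numeric(glen)
      for (i in seq_len(nSites)) {
        if (!cond %in% strsplit(sites$conditions[i], ",")[[1]]) next
        mu <- if (sites$kind[i] == "TS") config$depthPerSite
              else if (lib == "Hyb") config$depthPerSite
              else config$exoRetention * config$depthPerSite
        n <- rSiteCount(mu, config$dispersion)
        if (sites$strand[i] == "+")
          plus <- smearStarts(plus, sites$pos[i], n, "+", config$decayLength)
        else
          minus <- smearStarts(minus, sites$pos[i], n, "-", config$decayLength)
      }
      nbg <- rpois(1, bgTotal)
      if (nbg > 0) {
        bp <- sample.int(glen, nbg, replace = TRUE)
        bs <- sample(c(TRUE, FALSE), nbg, replace = TRUE)
        tb <- table(bp[bs]); plus[as.integer(names(tb))] <-
          plus[as.integer(names(tb))] + as.vector(tb)
        tb <- table(bp[!bs]); minus[as.integer(names(tb))] <-
          minus[as.integer(names(tb))] + as.vector(tb)
      }
      tr <- PositionTrack(plus, minus)
      starts[[cond]][[lib]][[r]] <- tr
      libSizes[paste(cond, lib, r, sep = "_")] <- trackTotal(tr)
    }
    for (r in 1:2) {
      plus <- numeric(glen); minus <- numeric(glen)
      condScale <- exp(rnorm(1, 0, 0.1))
      for (k in seq_len(nrow(truth$operons))) {
        op <- truth$operons[k, ]
        gids <- strsplit(op$genes, ",")[[1]]
        lv <- ta$op_base[match(gids, ta$gene_id)] *
          ta$ta[match(gids, ta$gene_id)] * condScale
        g <- sim$genes[match(gids, S4Vectors::mcols(sim$genes)$gene_id)]
        gstart <- GenomicRanges::start(g); gend <- GenomicRanges::end(g)
        fill <- function(a, b, level) {
          idx <- a:b
          noise <- exp(rnorm(length(idx), 0, 0.05))
          if (op$strand == "+") plus[idx] <<- plus[idx] + level * noise
          else minus[idx] <<- minus[idx] + level * noise
        }
        for (i in seq_along(gids)) fill(gstart[i], gend[i], lv[i])
        # 5'-UTR covered at first-gene level; intra-operon gaps carry
        # read-through at 60% of the flanking mean (continuity signal)
        if (op$strand == "+") {
          fill(op$span_start, gstart[1] - 1L, lv[1])
          if (length(gids) > 1) for (i in seq_len(length(gids) - 1))
            if (gend[i] + 1L <= gstart[i + 1] - 1L)
              fill(gend[i] + 1L, gstart[i + 1] - 1L,
                   0.6 * mean(c(lv[i], lv[i + 1])))
        } else {
          fill(gend[1] + 1L, op$span_end, lv[1])
          if (length(gids) > 1) for (i in seq_len(length(gids) - 1))
            if (gend[i + 1] + 1L <= gstart[i] - 1L)
              fill(gend[i + 1] + 1L, gstart[i] - 1L,
                   0.6 * mean(c(lv[i], lv[i + 1])))
        }
      }
      # sparse background coverage
      plus <- plus + rpois(glen, 0.02)
      minus <- minus + rpois(glen, 0.02)
      coverage[[cond]][[r]] <- PositionTrack(plus, minus)
    }
  }
  list(starts = starts, coverage = coverage, libSizes = libSizes)
}

#' Write a simulation to disk in standard formats
#'
#' Genome as FASTA, annotation as GFF3, each start track as BED6,
#' coverage as 3-column TSV, truth tables as TSV and the configuration
#' as YAML.
#'
#' @param sim output of [simulateGenome].
#' @param tracks output of [simulateTracks] (optional).
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, tracks = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeGenomeFasta(sim$genome, file.path(dir, "genome.fasta"))
  writeGff(sim$genes, file.path(dir, "annotation.gff3"))
  for (nm in names(sim$truth))
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  writeConfig(sim$config, file.path(dir, "config.yaml"))
  if (!is.null(tracks)) {
    for (cond in names(tracks$starts))
      for (lib in names(tracks$starts[[cond]]))
        for (r in seq_along(tracks$starts[[cond]][[lib]]))
          writeStartTrack(tracks$starts[[cond]][[lib]][[r]],
                          file.path(dir, sprintf("starts_%s_%s_rep%d.bed",
                                                 cond, lib, r)),
                          chrom = sim$genome$id)
  }
  invisible(dir)
}
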