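# shared in-code fixtures for the test suite

# a blank start track of the given genome length
blankTrack <- function(glen) PositionTrack(numeric(glen), numeric(glen))

# a start track with counts at given positions on one strand
spikeTrack <- function(glen, pos, counts, strand = "+") {
  v <- numeric(glen)
  v[pos] <- counts
  if (strand == "+") PositionTrack(v, numeric(glen))
  else PositionTrack(numeric(glen), v)
}

# minimal genome list around a given sequence string
makeGenome <- function(seqstr, id = "simchr", circular = FALSE) {
  list(id = id, seq = Biostrings::DNAString(seqstr), circular = circular)
}

# random genome of length n (fixed composition, caller sets the seed)
randomGenome <- function(n) {
  makeGenome(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                          prob = c(0.33, 0.17, 0.17, 0.33)), collapse = ""))
}

# gene annotation GRanges from a coordinate table
makeGenes <- function(start, end, strand, gene_id = NULL, cog = NA) {
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_along(start))
  GenomicRanges::GRanges("simchr", IRanges::IRanges(start, end),
                         strand = strand, gene_id = gene_id,
                         feature_type = "CDS", cog = cog)
}

# an OperonMap built directly from membership lists
makeOperonMap <- function(spanStart, spanEnd, strand, genes,
                          pattern = "unknown", tsPos = NA_integer_) {
  gr <- GenomicRanges::GRanges(
    "simchr", IRanges::IRanges(spanStart, spanEnd), strand = strand,
    operon_id = sprintf("OP%04d", seq_along(spanStart)),
    genes = IRanges::CharacterList(genes),
    n_genes = lengths(genes),
    pattern = rep_len(pattern, length(spanStart)),
    ts_pos = rep_len(as.integer(tsPos), length(spanStart)))
  new("OperonMap", operons = gr)
}

# a TranscriptAbundance with unit factors from a plain TA table
makeAbundance <- function(ta, condition = "c1") {
  m <- as.matrix(ta)
  if (is.null(colnames(m))) colnames(m) <- paste0(condition, "_rep1")
  normalizeTa(m, factors = setNames(rep(1, ncol(m)), colnames(m)),
              libSizes = setNames(rep(1, ncol(m)), colnames(m)),
              condition = rep_len(condition, ncol(m)),
              replicate = seq_len(ncol(m)), scale = 1)
}

# planted-site recovery of the end-site caller against simulator truth
recoveryRates <- function(seed, config = simConfig(seed = seed)) {
  res <- runPipeline(config, stages = c("simulate", "endsites"))
  sites <- endSites(res$endSites)
  mc <- S4Vectors::mcols(sites)
  called <- data.frame(pos = GenomicRanges::start(sites),
                       strand = as.character(GenomicRanges::strand(sites)),
                       verdict = mc$verdict)
  tr <- res$sim$truth
  truth <- rbind(
    data.frame(pos = tr$ts$pos, strand = tr$ts$strand, kind = "TS"),
    if (nrow(tr$ps)) data.frame(pos = tr$ps$pos, strand = tr$ps$strand,
                                kind = "PS"))
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(called$strand == truth$strand[i] &
        abs(called$pos - truth$pos[i]) <= 2 &
        called$verdict == truth$kind[i]), logical(1))
  def <- called[called$verdict != "ambiguous", ]
  prec <- vapply(seq_len(nrow(def)), function(i)
    any(truth$strand == def$strand[i] &
        abs(truth$pos - def$pos[i]) <= 2 &
        truth$kind == def$verdict[i]), logical(1))
  c(nTruth = nrow(truth), nHit = sum(hit),
    nCalled = nrow(def), nPrec = sum(prec))
}
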