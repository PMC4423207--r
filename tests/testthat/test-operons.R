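.covTrack <- function(glen, from, to, level, strand = "+") {
  v <- numeric(glen); v[from:to] <- level
  if (strand == "+") PositionTrack(v, numeric(glen))
  else PositionTrack(numeric(glen), v)
}

test_that("coverage contiguity joins genes unless a TS splits the gap", {
  glen <- 3000L
  genes <- makeGenes(c(100L, 700L), c(600L, 1200L), c("+", "+"))
  cov <- .covTrack(glen, 100L, 1200L, 10)
  noTs <- GenomicRanges::GRanges()
  om <- assembleOperons(genes, noTs, cov)
  expect_length(om, 1L)
  expect_equal(operonGenes(om)[[1]], c("g01", "g02"))
  # a TS in the gap (promoter of the downstream gene) splits
  ts <- GenomicRanges::GRanges("simchr", IRanges::IRanges(650L, width = 1L),
                               strand = "+")
  om2 <- assembleOperons(genes, ts, cov)
  expect_length(om2, 2L)
  # an uncovered gap splits too
  cov0 <- .covTrack(glen, 100L, 600L, 10)
  cov0@plus[700:1200] <- 10
  om3 <- assembleOperons(genes, noTs, cov0)
  expect_length(om3, 2L)
})

test_that("read-pair bridges can join what coverage cannot", {
  glen <- 3000L
  genes <- makeGenes(c(100L, 700L), c(600L, 1200L), c("+", "+"))
  cov <- .covTrack(glen, 100L, 600L, 10); cov@plus[700:1200] <- 10
  noTs <- GenomicRanges::GRanges()
  links <- data.frame(gene_a = "g01", gene_b = "g02", n_pairs = 3L)
  expect_length(assembleOperons(genes, noTs, cov, pairLinks = links), 1L)
  links$n_pairs <- 2L
  expect_length(assembleOperons(genes, noTs, cov, pairLinks = links), 2L)
})

test_that("external predictions break borderline coverage ties only", {
  glen <- 3000L
  genes <- makeGenes(c(100L, 700L), c(600L, 1200L), c("+", "+"))
  cov <- .covTrack(glen, 100L, 1200L, 10)
  gap <- 601:699
  cov@plus[gap[seq_along(gap) %% 3 == 0]] <- 0   # ~67% contiguity
  noTs <- GenomicRanges::GRanges()
  expect_length(assembleOperons(genes, noTs, cov), 2L)
  pred <- data.frame(gene_id = c("g01", "g02"), operon_id = "ext1")
  expect_length(assembleOperons(genes, noTs, cov, predictions = pred), 1L)
  # predictions cannot overcome an essentially uncovered gap
  cov@plus[gap] <- 0
  expect_length(assembleOperons(genes, noTs, cov, predictions = pred), 2L)
})

test_that("planted operons are recovered exactly from low-noise tracks", {
  cfg <- simConfig(dispersion = 0, seed = 12L)
  sim <- simulateGenome(cfg)
  tracks <- simulateTracks(sim, cfg)
  ts <- GenomicRanges::GRanges("simchr",
                               IRanges::IRanges(sim$truth$ts$pos, width = 1L),
                               strand = sim$truth$ts$strand)
  om <- assembleOperons(sim$genes, ts,
                        unlist(tracks$coverage, recursive = FALSE))
  expect_length(om, nrow(sim$truth$operons))
  got <- sort(vapply(operonGenes(om), paste, "", collapse = ","))
  expect_equal(got, sort(sim$truth$operons$genes))
})

test_that("polarity steps classify Down, Flat, Up and Complex", {
  expect_equal(polarityPattern(c(8, 4, 2, 1)), "Down")
  expect_equal(polarityPattern(c(5, 5, 5)), "Flat")
  expect_equal(polarityPattern(c(1, 2, 4, 8)), "Up")
  expect_equal(polarityPattern(c(4, 1, 8, 2)), "Complex")
  # near the log2 threshold of 0.5: 1.4x is Flat, 1.45x is Down
  expect_equal(polarityPattern(c(1.40, 1)), "Flat")
  expect_equal(polarityPattern(c(1.45, 1)), "Down")
  expect_equal(polarityPattern(c(5)), "unknown")
  expect_equal(polarityPattern(c(5, 0.5), taFloor = 1), "unknown")
  # scale invariance
  for (v in list(c(8, 4, 2, 1), c(4, 1, 8, 2), c(5, 5, 5)))
    expect_equal(polarityPattern(v * 1000), polarityPattern(v))
})

test_that("every complete polycistronic TA vector gets exactly one pattern", {
  set.seed(21)
  for (i in 1:50) {
    v <- 2^runif(sample(2:6, 1), 0, 6)
    expect_true(polarityPattern(v, taFloor = 0) %in%
                c("Down", "Flat", "Up", "Complex"))
  }
})

test_that("operon-level polarity uses the condition majority, ties Complex", {
  om <- makeOperonMap(100L, 2000L, "+", list(c("g01", "g02")))
  ta <- cbind(a_rep1 = c(8, 2), b_rep1 = c(8, 2), c_rep1 = c(2, 8))
  rownames(ta) <- c("g01", "g02")
  ab <- normalizeTa(ta, factors = rep(1, 3), libSizes = rep(1, 3),
                    condition = c("a", "b", "c"), replicate = c(1, 1, 1),
                    scale = 1)
  om2 <- classifyPolarity(om, ab)
  expect_equal(unname(operonPatterns(om2)), "Down")
  ta2 <- cbind(a_rep1 = c(8, 2), c_rep1 = c(2, 8))
  rownames(ta2) <- c("g01", "g02")
  ab2 <- normalizeTa(ta2, factors = rep(1, 2), libSizes = rep(1, 2),
                     condition = c("a", "c"), replicate = c(1, 1), scale = 1)
  expect_equal(unname(operonPatterns(classifyPolarity(om, ab2))), "Complex")
  # a missing gene is an error naming it
  om3 <- makeOperonMap(100L, 2000L, "+", list(c("g01", "gX")))
  expect_error(classifyPolarity(om3, ab), "gX")
})

test_that("iPS association flags flanking genes and max-TA fractions", {
  om <- makeOperonMap(c(100L, 5000L), c(3000L, 6000L), "+",
                      list(c("g01", "g02", "g03"), "g04"))
  psTab <- data.frame(
    pos = 1650L, strand = "+", category = "iPS", operon_id = "OP0001",
    upstream_gene = "g02", downstream_gene = "g03",
    stringsAsFactors = FALSE)
  ab <- makeAbundance(matrix(c(1, 9, 2, 5), ncol = 1,
                             dimnames = list(paste0("g0", 1:4), "c1_rep1")))
  out <- associatePs(om, psTab, ab)
  fl <- out$geneFlags
  expect_true(fl$three_prime_ips[fl$gene_id == "g02"])
  expect_true(fl$five_prime_ips[fl$gene_id == "g03"])
  expect_false(any(fl[fl$gene_id == "g01", -1] == TRUE))
  # the operon without PSs is absent from the association table
  expect_false("OP0002" %in% out$table$operon_id)
  # max-TA gene (g02) is iPS-flanked -> fraction 1 here
  expect_equal(out$maxTaIpsFraction, 1)
})

test_that("the flanked-max-TA fraction is a direct count", {
  # 10 three-gene operons, one iPS each between genes 1 and 2; in 7 the
  # flanked first gene is on top, in 3 the non-flanking third gene is
  genes <- sprintf("h%02d", 1:30)
  byOp <- split(genes, rep(1:10, each = 3))
  starts <- seq(1L, 30000L, 3000L)[1:10]
  om <- makeOperonMap(starts, starts + 2500L, "+", byOp)
  psTab <- data.frame(
    pos = starts + 700L, strand = "+", category = "iPS",
    operon_id = sprintf("OP%04d", 1:10),
    upstream_gene = genes[seq(1, 30, 3)],
    downstream_gene = genes[seq(2, 30, 3)], stringsAsFactors = FALSE)
  ta <- rep(c(5, 1, 2), 10)
  ta[seq(3, 30, 3)[8:10]] <- 9          # three operons: third gene on top
  m <- matrix(ta, ncol = 1, dimnames = list(genes, "c1_rep1"))
  out <- associatePs(om, psTab, makeAbundance(m))
  expect_equal(out$maxTaIpsFraction, 0.7)
})
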