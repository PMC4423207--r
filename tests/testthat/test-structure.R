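test_that("PS flanks are 49 + 1 + 50 bases in coding orientation", {
  set.seed(31)
  g <- randomGenome(3000)
  ps <- GenomicRanges::GRanges("simchr",
                               IRanges::IRanges(c(1001L, 1001L), width = 1L),
                               strand = c("+", "-"))
  fl <- extractPsFlank(g, ps)
  expect_equal(nchar(fl$seq), c(100L, 100L))
  expect_equal(fl$start[1], 952L); expect_equal(fl$end[1], 1051L)
  expect_equal(fl$start[2], 951L); expect_equal(fl$end[2], 1050L)
  expect_identical(fl$seq[1],
                   as.character(Biostrings::subseq(g$seq, 952, 1051)))
  expect_identical(fl$seq[2],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::subseq(g$seq, 951, 1050))))
  # off the end of a linear contig
  edge <- GenomicRanges::GRanges("simchr", IRanges::IRanges(21L, width = 1L),
                                 strand = "+")
  expect_error(extractPsFlank(g, edge), "linear contig")
  # circular genomes wrap instead
  gc <- randomGenome(3000); gc$circular <- TRUE
  expect_equal(nchar(extractPsFlank(gc, edge)$seq), 100L)
})

test_that("control flanks center on non-PS intergenic regions", {
  set.seed(32)
  g <- randomGenome(4000)
  # operon with a 60-nt gap (g01|g02) and a 240-nt gap (g02|g03)
  genes <- makeGenes(c(500L, 1061L, 1801L), c(1000L, 1560L, 2300L),
                     c("+", "+", "+"))
  om <- makeOperonMap(500L, 2300L, "+", list(c("g01", "g02", "g03")))
  psTab <- data.frame(pos = 1700L, strand = "+", category = "iPS",
                      operon_id = "OP0001", upstream_gene = "g02",
                      downstream_gene = "g03", stringsAsFactors = FALSE)
  ctrl <- extractControlFlanks(g, om, psTab, genes)
  # the PS-containing 240-nt gap is excluded; the 60-nt gap is the control
  expect_equal(nrow(ctrl), 1L)
  expect_equal(nchar(ctrl$seq), 100L)
  cen <- (1001L + 1060L) %/% 2L
  expect_equal(ctrl$start, cen - 49L)
  expect_equal(ctrl$end, cen + 50L)
  # with the PS moved to the short gap, the long gap contributes its
  # central 100 nt instead
  psTab2 <- transform(psTab, pos = 1030L)
  ctrl2 <- extractControlFlanks(g, om, psTab2, genes)
  expect_equal(nrow(ctrl2), 1L)
  cen2 <- (1561L + 1800L) %/% 2L
  expect_equal(ctrl2$start, cen2 - 49L)
  expect_equal(ctrl2$end, cen2 + 50L)
})

test_that("folding finds hairpins and reports zero for unstructured input", {
  f <- foldMfe("AAAAAAAAAAAAAAAAAAAA", backend = "builtin")
  expect_equal(f$dG, 0)
  expect_equal(f$structure, strrep(".", 20))
  f2 <- foldMfe("GGGGGAAAACCCCC", backend = "builtin")
  expect_lt(f2$dG, 0)
  expect_equal(f2$structure, "(((((....)))))")
  # a palindromic-stem design folds identically to its reverse complement
  hp <- "GGCGCGAAAACGCGCC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hp)))
  expect_equal(foldMfe(hp, backend = "builtin")$dG,
               foldMfe(rc, backend = "builtin")$dG)
  expect_error(foldMfe("ACGX", backend = "builtin"), "invalid characters")
  expect_error(foldMfe("ACGU", backend = "nope"), "arg")
})

test_that("builtin and external backends agree on hairpin calls", {
  skip_if(!hasRnaFold())
  ext <- foldMfe("GGGGGAAAACCCCC", backend = "external")
  blt <- foldMfe("GGGGGAAAACCCCC", backend = "builtin")
  expect_lt(ext$dG, 0)
  expect_equal(ext$structure, blt$structure)
  # agreement on qualifying-hairpin presence for planted stems
  sim <- simulateGenome(simConfig(seed = 3L))
  sl <- sim$truth$stemLoops
  expect_gt(nrow(sl), 0)
  agree <- vapply(sl$seq, function(s)
    (foldMfe(s, backend = "builtin")$dG < -5) ==
      (foldMfe(s, backend = "external")$dG < -5), logical(1))
  expect_true(all(agree))
})

test_that("stem-loop scan returns the qualifying lowest-energy hairpin", {
  set.seed(33)
  # A/C-only background cannot base-pair, so planted hairpins are the
  # only structures present
  bg <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")
  weak <- "GCGCGAAAACGCGC"                       # ~5 pairs
  strong <- "GGCGCCGCGCGAAAACGCGCGGCGCC"         # ~11 pairs
  seqstr <- paste0(bg(300), strong, bg(20), weak, bg(12), bg(300))
  g <- makeGenome(seqstr)
  ipsPos <- 300L + nchar(strong) + 20L + nchar(weak) + 6L
  ips <- data.frame(pos = ipsPos, strand = "+", category = "iPS",
                    operon_id = "OP0001", upstream_gene = "gA",
                    downstream_gene = "gB", stringsAsFactors = FALSE)
  sl <- scanStemLoops(g, ips, backend = "builtin")
  expect_length(sl, 1L)
  mc <- S4Vectors::mcols(sl)
  dgStrong <- foldMfe(strong, backend = "builtin")$dG
  dgWeak <- foldMfe(weak, backend = "builtin")$dG
  expect_lt(dgStrong, dgWeak)
  expect_equal(mc$dG, dgStrong, tolerance = 0.5)
  # both hairpins are 5' of the iPS: the protective 3' side configuration
  expect_equal(mc$side, "3prime")
  expect_equal(mc$protected_gene, "gA")
  # a pairing-free neighbourhood returns no stem-loop
  ips2 <- data.frame(pos = 300L, strand = "+", category = "iPS",
                     operon_id = "OP0001", upstream_gene = "gA",
                     downstream_gene = "gB", stringsAsFactors = FALSE)
  g2 <- makeGenome(bg(800))
  expect_length(scanStemLoops(g2, ips2, backend = "builtin"), 0L)
})

test_that("retained stem-loops satisfy the energy and mispair filters", {
  res <- runPipeline(simConfig(seed = 3L), backend = "builtin")
  sl <- res$stemLoops
  expect_gt(length(sl), 0)
  mc <- S4Vectors::mcols(sl)
  expect_true(all(mc$dG < -5))
  for (i in seq_along(sl)) {
    stx <- SRPSseq:::.structureStats(mc$structure[i])
    expect_true(stx$singleHairpin)
    expect_lte(stx$mispairs, 5L)
    expect_lte(stx$places, 3L)
  }
  # flank windows are always exactly 100 nt
  expect_true(all(nchar(res$flanks$seq) == 100L))
})

test_that("structure bookkeeping counts mispairs and interruptions", {
  s <- SRPSseq:::.structureStats("..(((..((....))..))).")
  expect_true(s$singleHairpin)
  expect_equal(s$mispairs, 4L)        # a 2x2 internal loop
  expect_equal(s$places, 1L)          # ... is one helix interruption
  s1 <- SRPSseq:::.structureStats("(((.((..((....)).)))))")
  expect_equal(s1$places, 2L)         # a bulge plus an internal loop
  expect_equal(s1$mispairs, 4L)
  s2 <- SRPSseq:::.structureStats("((..))((..))")
  expect_false(s2$singleHairpin)
})

test_that("poly-U terminator flags follow the run-within-window rule", {
  stemSeq <- "GGGGGAAAACCCCC"
  mkCase <- function(tail) {
    g <- makeGenome(paste0(strrep("A", 50), stemSeq, tail, strrep("A", 50)))
    sl <- GenomicRanges::GRanges(
      "simchr", IRanges::IRanges(51L, 50L + nchar(stemSeq)), strand = "+")
    polyUTerminatorFlag(sl, g)
  }
  expect_true(mkCase("TTTTTT"))
  expect_false(mkCase("GACGAC"))
  expect_true(mkCase("ATTTTG"))     # run of 4 beginning inside the window
  expect_false(mkCase("AGAGAGTTTT"))  # run starts beyond the window
})

test_that("protection correlation is signed and guards degenerate input", {
  mkSl <- function(dG, up, dn) {
    gr <- GenomicRanges::GRanges("simchr",
                                 IRanges::IRanges(seq_along(dG) * 100L,
                                                  width = 10L),
                                 strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      dG = dG, side = "3prime", protected_gene = up, downstream_gene = dn)
    gr
  }
  genes <- c("u1", "u2", "u3", "d1", "d2", "d3")
  ab <- makeAbundance(matrix(c(2, 4, 8, 1, 1, 1), ncol = 1,
                             dimnames = list(genes, "c1_rep1")))
  sl <- mkSl(c(-10, -20, -30), c("u1", "u2", "u3"), c("d1", "d2", "d3"))
  out <- protectionCorrelation(sl, ab)
  expect_lt(out$r, -0.9)
  expect_false(out$degenerate)
  # constant ratios: r reported as 0 with the degenerate flag
  ab2 <- makeAbundance(matrix(c(2, 2, 2, 1, 1, 1), ncol = 1,
                              dimnames = list(genes, "c1_rep1")))
  out2 <- protectionCorrelation(sl, ab2)
  expect_equal(out2$r, 0)
  expect_true(out2$degenerate)
  expect_error(
    protectionCorrelation(sl[1:2], ab), "at least 3")
})

test_that("group dG comparison reports means and both t-test forms", {
  x <- c(-30, -31, -29, -30.5); y <- c(-5, -5.5, -4.5, -5.2)
  out <- compareDgGroups(c(x, y), rep(c("PS", "control"), each = 4))
  expect_setequal(out$stats$group, c("control", "PS"))
  expect_lt(out$tests$welch_p, 1e-4)
  expect_lt(out$tests$pooled_p, 1e-4)
  expect_equal(out$tests$mean_diff, mean(x) - mean(y))
  # identical groups: zero difference, p = 1
  out2 <- compareDgGroups(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(out2$tests$mean_diff, 0)
  expect_equal(out2$tests$welch_p, 1, tolerance = 1e-12)
  expect_error(compareDgGroups(c(-1, -2, -3), c("a", "a", "b")),
               "size < 2")
})

test_that("a planted dG shift between groups is recovered in simulation", {
  set.seed(35)
  diffs <- replicate(100, {
    ctrl <- rnorm(70, -15.9, 4)
    psfl <- rnorm(70, -18.9, 4)
    out <- compareDgGroups(c(psfl, ctrl),
                           rep(c("PS", "control"), each = 70))
    out$tests$mean_diff
  })
  expect_lt(abs(mean(diffs) - (-3)), 1)
})
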