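test_that("start-window detection applies threshold, merge and anchor rules", {
  glen <- 2000L
  # single spike of 50 -> one window anchored there
  w <- detectStartWindows(spikeTrack(glen, 1000L, 50))
  expect_length(w, 1L)
  expect_equal(S4Vectors::mcols(w)$anchor, 1000L)
  # spike of 5 (< minStarts) -> no window
  expect_length(detectStartWindows(spikeTrack(glen, 1000L, 5)), 0L)
  # two spikes 3 bases apart -> one merged window anchored at the larger
  w2 <- detectStartWindows(spikeTrack(glen, c(1000L, 1003L), c(20, 40)))
  expect_length(w2, 1L)
  expect_equal(S4Vectors::mcols(w2)$anchor, 1003L)
  # local-background enrichment: a candidate barely above the dense
  # local floor is suppressed, a sharp one is kept
  mkFloor <- function(from, to, value) {
    v <- numeric(glen)
    v[700:990] <- 1; v[1013:1300] <- 1          # dense flank floor
    v[from:to] <- value                         # separated candidate run
    PositionTrack(v, numeric(glen))
  }
  anchors <- function(w) S4Vectors::mcols(w)$anchor
  # density 2 vs flank median 1: below the 3x enrichment floor
  weak <- detectStartWindows(mkFloor(998L, 1005L, 2), bgFold = 3)
  expect_false(any(abs(anchors(weak) - 1000L) <= 6))
  sharp <- detectStartWindows(mkFloor(998L, 1002L, 20), bgFold = 3)
  expect_true(any(abs(anchors(sharp) - 1000L) <= 6))
})

.esFixture <- function(hyb, exo, glen = 2000L, pos = 1000L,
                       exoWindows = NULL) {
  hybT <- list(spikeTrack(glen, pos, hyb), spikeTrack(glen, pos, hyb))
  exoT <- list(spikeTrack(glen, pos, exo), spikeTrack(glen, pos, exo))
  hybW <- lapply(hybT, detectStartWindows)
  exoW <- if (is.null(exoWindows)) lapply(exoT, detectStartWindows)
          else exoWindows
  callEndSites(hybW, exoW, hybT, exoT,
               libSizes = list(hyb = c(1000, 1000), exo = c(1000, 1000)))
}

test_that("verdicts follow the configured Exo/Hyb enrichment thresholds", {
  ts <- .esFixture(hyb = 50, exo = 200)
  expect_equal(S4Vectors::mcols(ts)$verdict, "TS")
  expect_equal(S4Vectors::mcols(ts)$rho1, 4)
  ps <- .esFixture(hyb = 200, exo = 20)
  expect_equal(S4Vectors::mcols(ps)$verdict, "PS")
  # balanced counts with no independently detected Exo window -> ambiguous
  empty <- detectStartWindows(blankTrack(2000L))
  amb <- .esFixture(hyb = 100, exo = 100, exoWindows = list(empty, empty))
  expect_equal(S4Vectors::mcols(amb)$verdict, "ambiguous")
})

test_that("an Exo-only site with zero Hyb starts is a TS candidate with infinite rho", {
  glen <- 2000L
  hybT <- list(blankTrack(glen), blankTrack(glen))
  exoT <- list(spikeTrack(glen, 800L, 120), spikeTrack(glen, 800L, 120))
  res <- callEndSites(lapply(hybT, detectStartWindows),
                      lapply(exoT, detectStartWindows), hybT, exoT,
                      libSizes = list(hyb = c(1000, 1000),
                                      exo = c(1000, 1000)))
  expect_equal(S4Vectors::mcols(res)$verdict, "TS")
  expect_true(is.infinite(S4Vectors::mcols(res)$rho1))
})

test_that("a missing replicate is an error", {
  glen <- 500L
  tr <- spikeTrack(glen, 100L, 50)
  w <- detectStartWindows(tr)
  expect_error(callEndSites(list(w), list(w, w), list(tr), list(tr, tr),
                            libSizes = list(hyb = 1, exo = c(1, 1))),
               "missing replicate")
})

test_that("raising Exo signal at fixed Hyb never demotes a TS to PS", {
  levels <- c(PS = 1L, ambiguous = 2L, TS = 3L)
  verdicts <- vapply(c(20, 45, 100, 220, 400), function(exo)
    S4Vectors::mcols(.esFixture(hyb = 100, exo = exo))$verdict, "")
  expect_true(all(diff(levels[verdicts]) >= 0))
})

test_that("condition merging computes union and intersection correctly", {
  mk <- function(pos, verdict) GenomicRanges::GRanges(
    "simchr", IRanges::IRanges(pos, width = 1L), strand = "+",
    verdict = verdict)
  one <- mk(c(100L, 500L), c("TS", "PS"))
  es <- mergeConditions(list(a = one, b = one, c = one))
  pc <- conditionSummary(es)
  expect_equal(length(es), 2L)
  expect_equal(unname(pc[, "union"]), unname(pc[, "shared"]))
  expect_equal(sum(pc[, "shared"]), 2L)
  # disjoint lists -> empty intersection
  es2 <- mergeConditions(list(a = mk(100L, "TS"), b = mk(900L, "TS")))
  expect_equal(sum(conditionSummary(es2)[, "shared"]), 0L)
  expect_equal(sum(conditionSummary(es2)[, "union"]), 2L)
  # anchors within +/-2 bases are one site
  es3 <- mergeConditions(list(a = mk(100L, "TS"), b = mk(102L, "TS")))
  expect_equal(length(es3), 1L)
})

test_that("per-condition site support in the merged set matches planted truth", {
  cfg <- simConfig(dispersion = 0, depthPerSite = 400, seed = 8L)
  res <- runPipeline(cfg, stages = c("simulate", "endsites"))
  truth <- res$sim$truth
  nCondTruth <- function(df) lengths(strsplit(df$conditions, ","))
  pc <- conditionSummary(res$endSites)
  expect_equal(unname(pc["TS", "shared"]),
               sum(nCondTruth(truth$ts) == 3L))
  expect_equal(unname(pc["PS", "shared"]),
               sum(nCondTruth(truth$ps) == 3L))
  expect_equal(unname(pc["TS", "union"]), nrow(truth$ts))
  expect_equal(unname(pc["PS", "union"]), nrow(truth$ps))
})

test_that("TS categorization distinguishes gTS, iTS and nTS", {
  genes <- makeGenes(c(1000L, 5000L), c(1600L, 5600L), c("+", "-"))
  ts <- GenomicRanges::GRanges("simchr",
                               IRanges::IRanges(c(900L, 1300L, 20000L, 5700L),
                                                width = 1L),
                               strand = c("+", "+", "+", "-"))
  expect_equal(categorizeTs(ts, genes),
               c("gTS", "iTS", "nTS", "gTS"))
  # beyond utrMax upstream -> orphan
  far <- GenomicRanges::GRanges("simchr", IRanges::IRanges(300L, width = 1L),
                                strand = "+")
  expect_equal(categorizeTs(far, genes, utrMax = 500L), "nTS")
})

test_that("PS categorization assigns uPS, iPS and cPS within the operon", {
  genes <- makeGenes(c(1000L, 1700L, 2400L), c(1600L, 2300L, 3000L),
                     c("+", "+", "+"))
  # operon with a 643-base 5'-UTR, mirroring a cip-cel-like leader
  om <- makeOperonMap(357L, 3000L, "+", list(c("g01", "g02", "g03")),
                      tsPos = 357L)
  ps <- GenomicRanges::GRanges(
    "simchr", IRanges::IRanges(c(387L, 1650L, 1800L, 50L), width = 1L),
    strand = "+")
  tab <- categorizePs(ps, om, genes)
  expect_equal(tab$category, c("uPS", "iPS", "cPS", "unassigned"))
  expect_equal(tab$upstream_gene[2], "g01")
  expect_equal(tab$downstream_gene[2], "g02")
})

test_that("every merged PS gets exactly one category and tallies sum", {
  res <- runPipeline(simConfig(seed = 3L),
                     stages = c("simulate", "endsites", "abundance",
                                "operons"))
  sites <- endSites(res$endSites)
  mc <- S4Vectors::mcols(sites)
  psCat <- mc$category[mc$verdict == "PS"]
  expect_true(all(psCat %in% c("uPS", "iPS", "cPS", "unassigned")))
  expect_equal(length(psCat), sum(mc$verdict == "PS"))
  expect_equal(sum(table(psCat)), sum(mc$verdict == "PS"))
})
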