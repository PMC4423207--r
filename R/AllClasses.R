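#' @import methods
#' @importFrom stats median quantile rnbinom rpois runif rnorm rmultinom
#'   setNames t.test cor p.adjust
#' @importFrom utils read.table write.table head tail
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Stranded per-position read 5'-start (or coverage) track
#'
#' A minimal container for a single-contig, stranded, per-base signal:
#' one numeric vector per strand, index = 1-based genomic position.
#' Used both for read 5'-start counts and for read coverage.
#'
#' @slot plus numeric vector, signal on the plus strand.
#' @slot minus numeric vector, signal on the minus strand (same length).
#'
#' @export
setClass("PositionTrack", representation(plus = "numeric", minus = "numeric"))

setValidity("PositionTrack", function(object) {
  if (length(object@plus) != length(object@minus))
    return("plus and minus strand vectors differ in length")
  if (any(object@plus < 0) || any(object@minus < 0))
    return("track values must be non-negative")
  TRUE
})

#' Construct a PositionTrack
#'
#' @param plus,minus non-negative numeric vectors of equal length
#'   (per-base signal, 1-based positions).
#' @return A \linkS4class{PositionTrack}.
#' @export
PositionTrack <- function(plus, minus) {
  new("PositionTrack", plus = as.numeric(plus), minus = as.numeric(minus))
}

#' @describeIn PositionTrack-class genome length covered by the track
#' @param x a PositionTrack
#' @export
setMethod("length", "PositionTrack", function(x) length(x@plus))

#' Extract one strand of a track
#'
#' @param x a \linkS4class{PositionTrack}
#' @param strand `"+"` or `"-"`
#' @return numeric vector of per-base signal.
#' @export
trackStrand <- function(x, strand) {
  stopifnot(is(x, "PositionTrack"), strand %in% c("+", "-"))
  if (strand == "+") x@plus else x@minus
}

#' Total signal in a track (used as library size for start tracks)
#' @param x a \linkS4class{PositionTrack}
#' @return numeric scalar.
#' @export
trackTotal <- function(x) sum(x@plus) + sum(x@minus)

setMethod("show", "PositionTrack", function(object) {
  cat("PositionTrack over", length(object@plus), "bases;",
      "total signal:", format(trackTotal(object), digits = 6), "\n")
})

#' Set of called RNA 5' end sites
#'
#' Container for merged end sites (ESs) after TS/PS discrimination.
#' The core is a width-1 \link[GenomicRanges]{GRanges} whose metadata
#' columns carry, per site, the verdict (`TS`, `PS` or `ambiguous`), the
#' genomic-context category (`gTS`/`iTS`/`nTS` for TSs, `uPS`/`iPS`/`cPS`/
#' `unassigned` for PSs), the Exo/Hyb enrichment ratio per condition and
#' the set of supporting conditions.
#'
#' @slot sites width-1 GRanges of site anchors with verdict metadata.
#' @slot conditions character vector of condition names the set was
#'   merged over.
#' @slot perCondition named integer matrix of per-condition site counts
#'   (rows TS/PS/ambiguous).
#' @slot params list of calling parameters used.
#'
#' @export
setClass("EndSiteSet", representation(
  sites        = "GRanges",
  conditions   = "character",
  perCondition = "matrix",
  params       = "list"
))

setValidity("EndSiteSet", function(object) {
  s <- object@sites
  if (length(s) && !all(GenomicRanges::width(s) == 1L))
    return("end-site anchors must have width 1")
  if (length(s)) {
    v <- S4Vectors::mcols(s)$verdict
    if (is.null(v)) return("sites must carry a 'verdict' metadata column")
    if (!all(v %in% c("TS", "PS", "ambiguous")))
      return("verdict must be TS, PS or ambiguous")
  }
  TRUE
})

#' @describeIn EndSiteSet-class the site GRanges
#' @param x an EndSiteSet
#' @export
endSites <- function(x) x@sites

#' @describeIn EndSiteSet-class number of sites
#' @export
setMethod("length", "EndSiteSet", function(x) length(x@sites))

#' @describeIn EndSiteSet-class per-condition and merged count summary
#' @export
conditionSummary <- function(x) x@perCondition

setMethod("show", "EndSiteSet", function(object) {
  v <- S4Vectors::mcols(object@sites)$verdict
  cat("EndSiteSet with", length(object@sites), "sites (",
      sum(v == "TS"), "TS,", sum(v == "PS"), "PS,",
      sum(v == "ambiguous"), "ambiguous ) over",
      length(object@conditions), "condition(s)\n")
})

#' Experimentally determined operon map
#'
#' Operon spans as a \link[GenomicRanges]{GRanges} (one range per operon,
#' covering the 5'-UTR from the operon TS through the end of the last
#' gene) with metadata columns: `operon_id`, `genes` (a CharacterList of
#' member gene ids in 5' to 3' order on the coding strand), `n_genes`,
#' `pattern` (Down/Flat/Up/Complex/unknown) and `ts_pos` (anchor of the
#' operon's primary TS, NA if none).
#'
#' @slot operons GRanges as described above.
#'
#' @export
setClass("OperonMap", representation(operons = "GRanges"))

setValidity("OperonMap", function(object) {
  mc <- S4Vectors::mcols(object@operons)
  need <- c("operon_id", "genes", "n_genes", "pattern")
  if (!all(need %in% colnames(mc)))
    return(paste("operon metadata must include:", paste(need, collapse = ", ")))
  if (length(object@operons) &&
      any(mc$n_genes != lengths(mc$genes)))
    return("n_genes must equal the number of member genes")
  ok <- c("Down", "Flat", "Up", "Complex", "unknown")
  if (length(object@operons) && !all(mc$pattern %in% ok))
    return("pattern must be one of Down/Flat/Up/Complex/unknown")
  TRUE
})

#' @describeIn OperonMap-class operon spans with metadata
#' @param x an OperonMap
#' @export
operonRanges <- function(x) x@operons

#' @describeIn OperonMap-class member gene ids per operon
#' @export
operonGenes <- function(x) S4Vectors::mcols(x@operons)$genes

#' @describeIn OperonMap-class polarity pattern labels per operon
#' @export
operonPatterns <- function(x) {
  setNames(S4Vectors::mcols(x@operons)$pattern,
           S4Vectors::mcols(x@operons)$operon_id)
}

#' @describeIn OperonMap-class number of operons
#' @export
setMethod("length", "OperonMap", function(x) length(x@operons))

setMethod("show", "OperonMap", function(object) {
  mc <- S4Vectors::mcols(object@operons)
  n <- length(object@operons)
  poly <- sum(mc$n_genes > 1L)
  cat("OperonMap with", n, "operons (", n - poly, "monocistronic,",
      poly, "polycistronic );", sum(mc$n_genes), "genes\n")
  if (poly) {
    tab <- table(factor(mc$pattern[mc$n_genes > 1L],
                        levels = c("Down", "Flat", "Up", "Complex", "unknown")))
    cat("  polycistronic patterns:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

#' TMM-normalized transcript abundance
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment} with two
#' assays, `counts` (raw coverage-weighted gene counts) and `ta`
#' (TMM-normalized transcript abundance), and per-library `colData`
#' columns `condition`, `library`, `replicate`, `lib_size` and
#' `tmm_factor`.
#'
#' @export
setClass("TranscriptAbundance", contains = "SummarizedExperiment")

setValidity("TranscriptAbundance", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "ta") %in% a))
    return("assays 'counts' and 'ta' are required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("condition", "library", "replicate", "lib_size", "tmm_factor")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must include:", paste(need, collapse = ", ")))
  f <- cd$tmm_factor
  if (any(f <= 0)) return("TMM factors must be positive")
  if (abs(mean(log(f))) > 1e-9)
    return("TMM factors must have geometric mean 1")
  if (any(SummarizedExperiment::assay(object, "counts") < 0))
    return("raw counts must be non-negative")
  TRUE
})

#' @describeIn TranscriptAbundance-class the TA assay matrix
#' @param x a TranscriptAbundance
#' @export
taMatrix <- function(x) SummarizedExperiment::assay(x, "ta")

#' @describeIn TranscriptAbundance-class per-library TMM scaling factors
#' @export
normFactors <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(cd$tmm_factor, cd$library)
}

#' @describeIn TranscriptAbundance-class replicate-mean TA per condition
#' @export
conditionTA <- function(x) {
  ta <- taMatrix(x)
  cond <- SummarizedExperiment::colData(x)$condition
  res <- vapply(unique(cond), function(cc)
    rowMeans(ta[, cond == cc, drop = FALSE]), numeric(nrow(ta)))
  rownames(res) <- rownames(x)
  res
}

setMethod("show", "TranscriptAbundance", function(object) {
  cat("TranscriptAbundance:", nrow(object), "genes x", ncol(object),
      "libraries (conditions:",
      paste(unique(SummarizedExperiment::colData(object)$condition),
            collapse = ", "), ")\n")
})
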