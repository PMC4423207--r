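#' Coverage-weighted raw gene counts
#'
#' Sums the stranded per-base coverage over each gene's interval on its
#' own strand. Overlapping genes each receive their own interval's
#' signal (double counting is allowed and documented); genes with no
#' signal get 0.
#'
#' @param track a \linkS4class{PositionTrack} of read coverage.
#' @param genes GRanges of gene annotation with `gene_id`.
#' @return named numeric vector of counts (one per gene).
#' @export
geneCounts <- function(track, genes) {
  if (length(genes) && max(GenomicRanges::end(genes)) > length(track))
    stop("track and genes do not share the genome (gene beyond track end)")
  out <- numeric(length(genes))
  st <- as.character(GenomicRanges::strand(genes))
  for (i in seq_along(genes)) {
    v <- trackStrand(track, if (st[i] == "-") "-" else "+")
    out[i] <- sum(v[GenomicRanges::start(genes)[i]:GenomicRanges::end(genes)[i]])
  }
  names(out) <- S4Vectors::mcols(genes)$gene_id
  out
}

# quantile of each library's counts relative to its size; used to pick
# the TMM reference library
.factorQuantile <- function(counts, libSizes, p = 0.75) {
  f <- apply(counts, 2, function(x) quantile(x, p = p))
  f / libSizes
}

# single-pair TMM factor (obs vs ref), published TMM defaults:
# 30% two-sided trim on M, 5% on A, inverse-delta-method weighting
.tmmPair <- function(obs, ref, nO, nR, logratioTrim = 0.3, sumTrim = 0.05,
                     doWeighting = TRUE, Acutoff = -1e10) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > Acutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  if (n < 10L) {
    warning("fewer than 10 genes available for TMM trimming; ",
            "using untrimmed weighted mean")
    keep <- rep(TRUE, n)
  } else {
    loL <- floor(n * logratioTrim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1
    hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
            (rank(absE) >= loS & rank(absE) <= hiS)
  }
  f <- if (doWeighting)
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  else mean(logR[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM scaling factors for a count matrix
#'
#' Trimmed-mean-of-M-values normalization factors across libraries.
#' The reference library is the one whose upper-quartile count (relative
#' to library size) is closest to the mean upper quartile. For each
#' library, genes with zero count in either the library or the reference
#' are excluded; the 30% most extreme log-ratios (M) and the 5% most
#' extreme average log-abundances (A) are trimmed two-sided, and the
#' factor is 2 to the inverse-variance-weighted mean of the surviving M
#' values. Factors are rescaled so their geometric mean is 1.
#'
#' @param counts numeric matrix, genes x libraries.
#' @param libSizes optional library sizes (default column sums).
#' @param logratioTrim,sumTrim two-sided trim fractions for M and A.
#' @param doWeighting use delta-method precision weights.
#' @return named numeric vector of scaling factors (geometric mean 1).
#' @export
tmmFactors <- function(counts, libSizes = colSums(counts),
                       logratioTrim = 0.3, sumTrim = 0.05,
                       doWeighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least 2 libraries")
  if (any(counts < 0)) stop("negative counts")
  if (any(libSizes == 0)) stop("all-zero library: ",
                               colnames(counts)[which(libSizes == 0)[1]])
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("need at least one gene with positive count in all libraries")
  f75 <- .factorQuantile(counts, libSizes)
  refColumn <- if (min(f75) == 0) which.max(colSums(sqrt(counts)))
               else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i)
    .tmmPair(counts[, i], counts[, refColumn], libSizes[i],
             libSizes[refColumn], logratioTrim, sumTrim, doWeighting),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' TMM-normalized transcript abundance (TA)
#'
#' TA = count / (library size x TMM factor), scaled to a common
#' constant (`scale`, default 1e6, i.e. normalized counts per million).
#'
#' @param counts genes x libraries count matrix; column names are
#'   library names.
#' @param factors scaling factors from [tmmFactors] (computed if NULL).
#' @param libSizes library sizes (default column sums).
#' @param condition,replicate per-library design labels (defaults:
#'   each library its own condition, replicate 1).
#' @param scale common scaling constant.
#' @return a \linkS4class{TranscriptAbundance}.
#' @export
normalizeTa <- function(counts, factors = NULL, libSizes = colSums(counts),
                        condition = colnames(counts),
                        replicate = rep(1L, ncol(counts)),
                        scale = 1e6) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  if (is.null(factors)) factors <- tmmFactors(counts, libSizes)
  ta <- sweep(counts, 2, libSizes * factors, "/") * scale
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, ta = ta),
    colData = S4Vectors::DataFrame(
      condition = as.character(condition),
      library = colnames(counts),
      replicate = as.integer(replicate),
      lib_size = as.numeric(libSizes),
      tmm_factor = as.numeric(factors),
      row.names = colnames(counts)))
  new("TranscriptAbundance", se)
}
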