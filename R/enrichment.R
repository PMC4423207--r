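#' Upper-tail hypergeometric probability
#'
#' Probability of observing `m` or more marked items in a class of size
#' `M`, when `n` of `N` items are marked:
#' \deqn{P = \sum_{i=m}^{\min(n,M)} C(M,i)\, C(N-M,\,n-i) / C(N,n)}
#' Summation is carried out in log space (log-binomials combined by
#' log-sum-exp) so that very small tail probabilities are returned
#' without underflow.
#'
#' @param N background size (e.g. all PS-harbouring operons).
#' @param n number of marked items (e.g. iPS-harbouring operons).
#' @param M size of the tested class (e.g. Complex-pattern operons).
#' @param m marked items observed in the tested class.
#' @return the upper-tail p-value, in (0, 1].
#' @examples
#' hypergeomUpper(10, 4, 5, 3)   # 55/210
#' @export
hypergeomUpper <- function(N, n, M, m) {
  if (length(N) != 1L || length(n) != 1L || length(M) != 1L || length(m) != 1L)
    stop("scalar arguments required")
  if (any(c(N, n, M, m) < 0) || any(c(N, n, M, m) != floor(c(N, n, M, m))))
    stop("domain error: arguments must be non-negative integers")
  if (M > N || n > N || m > M || m > n)
    stop("domain error: require m <= min(n, M) and n, M <= N")
  if (m == 0L) return(1)
  i <- seq.int(m, min(n, M))
  lg <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(lg)
  p <- exp(mx + log(sum(exp(lg - mx))))
  min(p, 1)
}

#' Enrichment of PS categories across operon polarity patterns
#'
#' For every (PS category, pattern) pair, tests whether operons
#' harbouring that PS category are over-represented among operons of
#' that pattern, by the upper-tail hypergeometric test. Two background
#' definitions are available: `"psOperons"` takes N = polycistronic,
#' pattern-classified operons that harbour at least one PS;
#' `"allPolycistronic"` takes N = all polycistronic, pattern-classified
#' operons. Both are reported by [runPipeline].
#'
#' @param psTable data.frame as returned by [associatePs] (one row per
#'   PS with `operon_id` and `category`).
#' @param operonMap an \linkS4class{OperonMap} with patterns assigned.
#' @param background `"psOperons"` or `"allPolycistronic"`.
#' @return data.frame with columns `category`, `pattern`, `N`, `n`, `M`,
#'   `m`, `p_value`, `bh_q`, sorted by p-value. BH-adjusted q-values are
#'   reported alongside but significance calls use the raw p-values.
#' @export
patternEnrichment <- function(psTable, operonMap,
                              background = c("psOperons", "allPolycistronic")) {
  background <- match.arg(background)
  mc <- S4Vectors::mcols(operonRanges(operonMap))
  classified <- mc$n_genes > 1L & mc$pattern %in% c("Down", "Flat", "Up", "Complex")
  ops <- mc$operon_id[classified]
  pat <- setNames(mc$pattern[classified], ops)
  psTable <- psTable[psTable$operon_id %in% ops, , drop = FALSE]
  psOps <- unique(psTable$operon_id)
  bg <- if (background == "psOperons") psOps else ops
  if (!length(bg)) stop("empty background: no classified operons")
  N <- length(bg)
  cats <- intersect(c("uPS", "iPS", "cPS"), unique(psTable$category))
  pats <- c("Down", "Flat", "Up", "Complex")
  rows <- list()
  for (cc in cats) {
    marked <- unique(psTable$operon_id[psTable$category == cc])
    marked <- intersect(marked, bg)
    for (tt in pats) {
      cls <- bg[pat[bg] == tt]
      m <- length(intersect(marked, cls))
      rows[[paste(cc, tt)]] <- data.frame(
        category = cc, pattern = tt, N = N, n = length(marked),
        M = length(cls), m = m,
        p_value = hypergeomUpper(N, length(marked), length(cls), m))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$bh_q <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}

#' COG-slim term enrichment of PS-associated genes
#'
#' Upper-tail hypergeometric enrichment of each COG category letter
#' among a foreground gene set, against all annotated genes. Genes
#' without a COG assignment are excluded from both foreground and
#' background. Multi-letter assignments count the gene in each letter.
#'
#' @param fgGenes character vector of foreground gene ids (e.g. genes
#'   flanking PSs).
#' @param genes GRanges of gene annotation with `gene_id` and `cog`
#'   metadata columns (or a data.frame with those columns).
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame with `term`, `N`, `n`, `M`, `m`, `p_value`,
#'   `bh_q`, `significant`, sorted by p-value.
#' @export
cogEnrichment <- function(fgGenes, genes, alpha = 0.05) {
  if (is(genes, "GRanges")) genes <- as.data.frame(S4Vectors::mcols(genes))
  ann <- genes[!is.na(genes$cog) & nzchar(genes$cog), c("gene_id", "cog")]
  fg <- intersect(unique(fgGenes), ann$gene_id)
  N <- nrow(ann); n <- length(fg)
  letters_by_gene <- strsplit(ann$cog, "")
  terms <- sort(unique(unlist(letters_by_gene)))
  rows <- lapply(terms, function(tt) {
    inTerm <- vapply(letters_by_gene, function(x) tt %in% x, logical(1))
    M <- sum(inTerm)
    m <- sum(ann$gene_id[inTerm] %in% fg)
    data.frame(term = tt, N = N, n = n, M = M, m = m,
               p_value = hypergeomUpper(N, n, M, m))
  })
  out <- do.call(rbind, rows)
  out$bh_q <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= alpha
  out[order(out$p_value), ]
}
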