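#' Detect read-start windows on a stranded start track
#'
#' Step (i) of end-site annotation: per strand, maximal runs of nonzero
#' start positions lying within `mergeGap` bases of each other are
#' merged into candidate windows; a window is kept if its summed starts
#' reach `minStarts` and its start density is at least `bgFold` times
#' the median per-base start density in a +/-`flank`-base neighbourhood
#' (a zero median background always passes). The window anchor is the
#' position of maximal count, ties broken 5'-most.
#'
#' @param track a \linkS4class{PositionTrack} of read 5'-start counts.
#' @param mergeGap maximal gap (bases) merged into one run.
#' @param minStarts minimal summed starts per window.
#' @param bgFold required fold enrichment over local background.
#' @param flank background neighbourhood half-width (bases).
#' @param chrom contig name for the returned ranges.
#' @return GRanges of windows with metadata `anchor` (position of the
#'   maximal count) and `starts` (summed counts).
#' @export
detectStartWindows <- function(track, mergeGap = 5L, minStarts = 15,
                               bgFold = 3, flank = 250L, chrom = "simchr") {
  res <- list()
  for (st in c("+", "-")) {
    v <- trackStrand(track, st)
    nz <- which(v > 0)
    if (!length(nz)) next
    grp <- cumsum(c(1L, diff(nz) > mergeGap))
    for (g in split(nz, grp)) {
      total <- sum(v[g])
      if (total < minStarts) next
      a <- g[1]; b <- g[length(g)]
      fl <- c(max(1L, a - flank):max(1L, a - 1L),
              min(length(v), b + 1L):min(length(v), b + flank))
      fl <- setdiff(unique(fl), a:b)
      med <- if (length(fl)) median(v[fl]) else 0
      dens <- total / (b - a + 1L)
      if (med > 0 && dens < bgFold * med) next
      peak <- g[v[g] == max(v[g])]
      anchor <- if (st == "+") min(peak) else max(peak)
      res[[length(res) + 1L]] <- data.frame(
        start = a, end = b, strand = st, anchor = anchor, starts = total)
    }
  }
  if (!length(res)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(anchor = integer(0),
                                                 starts = numeric(0))
    return(gr)
  }
  df <- do.call(rbind, res)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand,
                         anchor = df$anchor, starts = df$starts)
}

# match window anchors of gr against reference anchors (same strand,
# within tol); returns index into gr for each reference anchor (NA if none)
.matchAnchors <- function(refAnchor, refStrand, gr, tol) {
  if (!length(gr)) return(rep(NA_integer_, length(refAnchor)))
  a <- S4Vectors::mcols(gr)$anchor
  s <- as.character(GenomicRanges::strand(gr))
  vapply(seq_along(refAnchor), function(i) {
    hit <- which(s == refStrand[i] & abs(a - refAnchor[i]) <= tol)
    if (!length(hit)) NA_integer_
    else hit[which.min(abs(a[hit] - refAnchor[i]))]
  }, integer(1))
}

.sumTrack <- function(track, strand, from, to) {
  v <- trackStrand(track, strand)
  sum(v[max(1L, from):min(length(v), to)])
}

#' Call end sites and discriminate TS from PS (one condition)
#'
#' Steps (ii)-(iv): end sites are the union of Hyb windows whose
#' anchors agree within `anchorTol` bases across both Hyb replicates,
#' plus replicate-consistent Exo-only windows (TS candidates). For each
#' site and replicate, the library-size-normalized enrichment ratio is
#' rho = (Exo starts / Exo library size) / (Hyb starts / Hyb library
#' size). The verdict is `TS` when rho >= `tsRatio` in both replicates,
#' or when the replicate-pooled rho is >= 1 and an Exo window was
#' independently detected in both Exo replicates; `PS` when rho <=
#' `psRatio` in both replicates; otherwise `ambiguous`. A site with
#' zero Hyb starts is a TS candidate with rho = +Inf.
#'
#' @param hybWindows,exoWindows lists of two GRanges (one per
#'   replicate) from [detectStartWindows].
#' @param hybTracks,exoTracks lists of the two underlying
#'   \linkS4class{PositionTrack}s; start counts are re-read from them
#'   over each site's window so that sub-threshold Exo signal still
#'   contributes to rho.
#' @param libSizes list with numeric 2-vectors `hyb` and `exo`.
#' @param tsRatio,psRatio verdict thresholds on rho.
#' @param anchorTol replicate/library anchor matching tolerance (bases).
#' @return width-1 GRanges of site anchors with metadata `hyb1`, `hyb2`,
#'   `exo1`, `exo2`, `rho1`, `rho2`, `rho_pooled`, `exo_detected`,
#'   `verdict`.
#' @export
callEndSites <- function(hybWindows, exoWindows, hybTracks, exoTracks,
                         libSizes, tsRatio = 2, psRatio = 0.5,
                         anchorTol = 2L) {
  if (length(hybWindows) != 2L || length(exoWindows) != 2L)
    stop("missing replicate: two replicates per library are required")
  w1 <- hybWindows[[1]]; w2 <- hybWindows[[2]]
  a1 <- S4Vectors::mcols(w1)$anchor
  s1 <- as.character(GenomicRanges::strand(w1))
  m12 <- .matchAnchors(a1, s1, w2, anchorTol)
  keep <- !is.na(m12)
  anchors <- a1[keep]; strands <- s1[keep]
  win1 <- w1[keep]; win2 <- w2[m12[keep]]

  # replicate-consistent Exo-only windows (candidate TSs missing from Hyb)
  e1 <- exoWindows[[1]]
  if (length(e1)) {
    ea <- S4Vectors::mcols(e1)$anchor
    es <- as.character(GenomicRanges::strand(e1))
    inExo2 <- !is.na(.matchAnchors(ea, es, exoWindows[[2]], anchorTol))
    inHyb <- !is.na(.matchAnchors(ea, es, win1, anchorTol)) |
      vapply(seq_along(ea), function(i)
        any(strands == es[i] & abs(anchors - ea[i]) <= anchorTol), logical(1))
    exoOnly <- e1[inExo2 & !inHyb]
  } else exoOnly <- e1

  mkRow <- function(anchor, strand, from, to) {
    h1 <- .sumTrack(hybTracks[[1]], strand, from, to)
    h2 <- .sumTrack(hybTracks[[2]], strand, from, to)
    x1 <- .sumTrack(exoTracks[[1]], strand, from, to)
    x2 <- .sumTrack(exoTracks[[2]], strand, from, to)
    r1 <- (x1 / libSizes$exo[1]) / (h1 / libSizes$hyb[1])
    r2 <- (x2 / libSizes$exo[2]) / (h2 / libSizes$hyb[2])
    rp <- ((x1 + x2) / sum(libSizes$exo)) / ((h1 + h2) / sum(libSizes$hyb))
    data.frame(anchor = anchor, strand = strand, hyb1 = h1, hyb2 = h2,
               exo1 = x1, exo2 = x2, rho1 = r1, rho2 = r2, rho_pooled = rp)
  }
  rows <- list()
  for (i in seq_along(anchors)) {
    from <- min(GenomicRanges::start(win1)[i], GenomicRanges::start(win2)[i]) -
      anchorTol
    to <- max(GenomicRanges::end(win1)[i], GenomicRanges::end(win2)[i]) +
      anchorTol
    rows[[length(rows) + 1L]] <- mkRow(anchors[i], strands[i], from, to)
  }
  if (length(exoOnly)) {
    eo <- S4Vectors::mcols(exoOnly)
    for (i in seq_along(exoOnly))
      rows[[length(rows) + 1L]] <- mkRow(
        eo$anchor[i], as.character(GenomicRanges::strand(exoOnly))[i],
        GenomicRanges::start(exoOnly)[i] - anchorTol,
        GenomicRanges::end(exoOnly)[i] + anchorTol)
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(verdict = character(0))
    return(gr)
  }
  df <- do.call(rbind, rows)
  # Exo window independently detected (both Exo replicates) at the site?
  exoDet <- !is.na(.matchAnchors(df$anchor, df$strand, exoWindows[[1]],
                                 anchorTol)) &
            !is.na(.matchAnchors(df$anchor, df$strand, exoWindows[[2]],
                                 anchorTol))
  zeroHyb <- (df$hyb1 + df$hyb2) == 0
  verdict <- ifelse(
    (df$rho1 >= tsRatio & df$rho2 >= tsRatio) |
      (df$rho_pooled >= 1 & exoDet) | zeroHyb, "TS",
    ifelse(df$rho1 <= psRatio & df$rho2 <= psRatio, "PS", "ambiguous"))
  chrom <- if (length(w1)) as.character(GenomicRanges::seqnames(w1))[1]
           else "simchr"
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(df$anchor, width = 1L), strand = df$strand,
    hyb1 = df$hyb1, hyb2 = df$hyb2, exo1 = df$exo1, exo2 = df$exo2,
    rho1 = df$rho1, rho2 = df$rho2, rho_pooled = df$rho_pooled,
    exo_detected = exoDet, verdict = verdict)
}

#' Merge per-condition end-site lists
#'
#' Sites from different conditions are identified when their anchors
#' agree within `anchorTol` bases on the same strand. The merged verdict
#' is the majority verdict among supporting conditions; a TS/PS tie is
#' merged as `ambiguous`. Emits per-condition counts, the union count
#' and the all-condition intersection count.
#'
#' @param esList named list of per-condition GRanges from
#'   [callEndSites].
#' @param anchorTol anchor matching tolerance (bases).
#' @return an \linkS4class{EndSiteSet}.
#' @export
mergeConditions <- function(esList, anchorTol = 2L) {
  stopifnot(length(esList) >= 1L, !is.null(names(esList)))
  conds <- names(esList)
  all <- do.call(rbind, lapply(conds, function(cc) {
    gr <- esList[[cc]]
    if (!length(gr)) return(NULL)
    data.frame(pos = GenomicRanges::start(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               verdict = S4Vectors::mcols(gr)$verdict,
               condition = cc, stringsAsFactors = FALSE)
  }))
  chrom <- if (!is.null(all)) {
    nonEmpty <- which(vapply(esList, length, integer(1)) > 0)[1]
    as.character(GenomicRanges::seqnames(esList[[nonEmpty]]))[1]
  } else "simchr"
  if (is.null(all) || !nrow(all)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      verdict = character(0), conditions = character(0),
      n_conditions = integer(0), category = character(0))
    pc <- matrix(0L, 3, length(conds) + 2,
                 dimnames = list(c("TS", "PS", "ambiguous"),
                                 c(conds, "union", "shared")))
    return(new("EndSiteSet", sites = gr, conditions = conds,
               perCondition = pc, params = list(anchorTol = anchorTol)))
  }
  all <- all[order(all$strand, all$pos), ]
  cl <- integer(nrow(all)); cl[1] <- 1L
  if (nrow(all) > 1) for (i in 2:nrow(all)) {
    cl[i] <- if (all$strand[i] == all$strand[i - 1] &&
                 all$pos[i] - all$pos[i - 1] <= anchorTol) cl[i - 1] else
                   cl[i - 1] + 1L
  }
  merged <- lapply(split(seq_len(nrow(all)), cl), function(idx) {
    sub <- all[idx, ]
    tab <- sort(table(sub$verdict), decreasing = TRUE)
    v <- if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
    supp <- unique(sub$condition)
    data.frame(pos = round(median(sub$pos)), strand = sub$strand[1],
               verdict = v, conditions = paste(sort(supp), collapse = ","),
               n_conditions = length(supp), stringsAsFactors = FALSE)
  })
  mdf <- do.call(rbind, merged)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(mdf$pos, width = 1L), strand = mdf$strand,
    verdict = mdf$verdict, conditions = mdf$conditions,
    n_conditions = mdf$n_conditions, category = NA_character_)
  gr <- gr[order(GenomicRanges::start(gr))]
  pc <- matrix(0L, 3, length(conds) + 2,
               dimnames = list(c("TS", "PS", "ambiguous"),
                               c(conds, "union", "shared")))
  for (cc in conds) {
    sub <- all[all$condition == cc, ]
    t <- table(factor(sub$verdict, levels = rownames(pc)))
    pc[, cc] <- as.integer(t)
  }
  t <- table(factor(mdf$verdict, levels = rownames(pc)))
  pc[, "union"] <- as.integer(t)
  shared <- mdf[mdf$n_conditions == length(conds), ]
  t <- table(factor(shared$verdict, levels = rownames(pc)))
  pc[, "shared"] <- as.integer(t)
  new("EndSiteSet", sites = gr, conditions = conds, perCondition = pc,
      params = list(anchorTol = anchorTol))
}

#' Categorize a TS by genomic context
#'
#' `iTS` if positioned within a same-strand CDS; otherwise `gTS` if
#' within `utrMax` bases upstream of a same-strand gene start and not
#' inside any CDS; otherwise `nTS` (orphan).
#'
#' @param ts GRanges of TS anchors (width 1).
#' @param genes gene annotation GRanges.
#' @param utrMax maximal 5'-UTR length considered for gTS assignment.
#' @return character vector of categories.
#' @export
categorizeTs <- function(ts, genes, utrMax = 500L) {
  if (!length(ts)) return(character(0))
  pos <- GenomicRanges::start(ts)
  st <- as.character(GenomicRanges::strand(ts))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gst <- as.character(GenomicRanges::strand(genes))
  isCDS <- S4Vectors::mcols(genes)$feature_type == "CDS"
  vapply(seq_along(ts), function(i) {
    inSame <- which(isCDS & gst == st[i] & gs <= pos[i] & ge >= pos[i])
    if (length(inSame)) return("iTS")
    inAny <- any(isCDS & gs <= pos[i] & ge >= pos[i])
    d <- if (st[i] == "+") {
      cand <- which(gst == "+" & gs >= pos[i]); if (length(cand))
        min(gs[cand] - pos[i]) else Inf
    } else {
      cand <- which(gst == "-" & ge <= pos[i]); if (length(cand))
        min(pos[i] - ge[cand]) else Inf
    }
    if (!inAny && d <= utrMax) "gTS" else "nTS"
  }, character(1))
}

#' Categorize a PS by position within its operon
#'
#' `cPS` if inside a same-strand CDS; `uPS` if between an operon's TS
#' and the start of its first gene; `iPS` if in an intergenic region
#' between two member genes of one operon (the flanking gene ids are
#' recorded); otherwise `unassigned`.
#'
#' @param ps GRanges of PS anchors (width 1).
#' @param operonMap an \linkS4class{OperonMap}.
#' @param genes gene annotation GRanges.
#' @return data.frame with `pos`, `strand`, `category`, `operon_id`,
#'   `upstream_gene`, `downstream_gene`.
#' @export
categorizePs <- function(ps, operonMap, genes) {
  n <- length(ps)
  out <- data.frame(pos = GenomicRanges::start(ps),
                    strand = as.character(GenomicRanges::strand(ps)),
                    category = rep("unassigned", n),
                    operon_id = rep(NA_character_, n),
                    upstream_gene = rep(NA_character_, n),
                    downstream_gene = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gst <- as.character(GenomicRanges::strand(genes))
  gid <- S4Vectors::mcols(genes)$gene_id
  isCDS <- S4Vectors::mcols(genes)$feature_type == "CDS"
  ops <- operonRanges(operonMap)
  omc <- S4Vectors::mcols(ops)
  for (i in seq_len(n)) {
    p <- out$pos[i]; st <- out$strand[i]
    inCds <- which(isCDS & gst == st & gs <= p & ge >= p)
    if (length(inCds)) {
      out$category[i] <- "cPS"
      out$upstream_gene[i] <- out$downstream_gene[i] <- gid[inCds[1]]
      hit <- which(as.character(GenomicRanges::strand(ops)) == st &
                   GenomicRanges::start(ops) <= p &
                   GenomicRanges::end(ops) >= p)
      if (length(hit)) out$operon_id[i] <- omc$operon_id[hit[1]]
      next
    }
    hit <- which(as.character(GenomicRanges::strand(ops)) == st &
                 GenomicRanges::start(ops) <= p &
                 GenomicRanges::end(ops) >= p)
    if (!length(hit)) next
    hit <- hit[1]
    out$operon_id[i] <- omc$operon_id[hit]
    members <- omc$genes[[hit]]
    mi <- match(members, gid)
    ms <- gs[mi]; me <- ge[mi]
    if (st == "+") {
      if (p < ms[1]) { out$category[i] <- "uPS"; out$downstream_gene[i] <- members[1]; next }
      j <- which(p > me[-length(members)] & p < ms[-1])
    } else {
      if (p > me[1]) { out$category[i] <- "uPS"; out$downstream_gene[i] <- members[1]; next }
      j <- which(p < ms[-length(members)] & p > me[-1])
    }
    if (length(j)) {
      out$category[i] <- "iPS"
      out$upstream_gene[i] <- members[j[1]]
      out$downstream_gene[i] <- members[j[1] + 1L]
    }
  }
  out
}
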