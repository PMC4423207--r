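## Single-hairpin nearest-neighbour folding model ("builtin" backend)
##
## Minimum free energy over all structures consisting of one helix
## (possibly interrupted by bulges and internal loops) closing one
## terminal loop. Stacking energies and loop penalties are an
## approximate 37C nearest-neighbour parameter set bundled with the
## package; values are NOT numerically identical to Mfold or ViennaRNA,
## but share their sign convention (more stable => more negative,
## kcal/mol) and rank hairpins equivalently for the filters used here.

.NT <- c(A = 1L, C = 2L, G = 3L, U = 4L, T = 4L)

# pair type indices: AU=1 UA=2 CG=3 GC=4 GU=5 UG=6; 0 = non-pairing
.PAIRTYPE <- local({
  m <- matrix(0L, 4, 4)
  m[1, 4] <- 1L; m[4, 1] <- 2L; m[2, 3] <- 3L; m[3, 2] <- 4L
  m[3, 4] <- 5L; m[4, 3] <- 6L
  m
})

# stack energy: row = outer pair (i,j), column = inner pair (i+1,j-1)
.STACK <- matrix(c(
  -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,
  -1.33, -0.93, -2.35, -2.24, -1.00, -1.27,
  -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,
  -2.24, -2.35, -3.42, -3.26, -1.53, -2.51,
  -1.27, -1.36, -2.51, -2.11, -0.50,  1.30,
  -1.00, -0.55, -1.53, -1.41,  0.30, -0.50), 6, 6, byrow = TRUE)

.RT <- 0.616

.hairpinLoopE <- function(n) {
  init <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)   # n = 3..9
  ifelse(n < 3, Inf,
         ifelse(n <= 9, init[pmax(1, n - 2)],
                6.4 + 1.75 * .RT * log(n / 9)))
}

.bulgeE <- function(n) {
  init <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)        # n = 1..6
  ifelse(n <= 6, init[n], 4.4 + 1.08 * log(n / 6))
}

.internalE <- function(a, b) {
  n <- a + b
  init <- c(NA, 1.5, 1.6, 1.7, 2.1, 2.5)         # n = 2..6
  base <- ifelse(n <= 6, init[n], 2.5 + 1.08 * log(n / 6))
  base + pmin(3, 0.6 * abs(a - b))
}

# interruption penalty matrix indexed [a+1, b+1]; [1,1] is a stack and
# is filled per closing pair during the DP
.interruptionPenalty <- function(maxSide) {
  p <- matrix(Inf, maxSide + 1L, maxSide + 1L)
  for (a in 0:maxSide) for (b in 0:maxSide) {
    if (a == 0 && b == 0) next
    p[a + 1L, b + 1L] <- if (a == 0 || b == 0) .bulgeE(a + b)
                         else .internalE(a, b)
  }
  p
}

# DP over all closing pairs: V[i,j] = MFE of the single hairpin closed
# by pair (i,j). maxSpan caps j-i+1; maxSide caps each side of an
# interior-loop interruption.
.foldDP <- function(s, maxSpan = Inf, maxSide = 6L) {
  n <- length(s)
  V <- matrix(Inf, n, n)
  if (n < 5L) return(V)
  pt <- matrix(0L, n, n)
  for (i in 1:(n - 1)) pt[i, (i + 1):n] <- .PAIRTYPE[s[i], s[(i + 1):n]]
  pen <- .interruptionPenalty(maxSide)
  for (span in 5:min(n, maxSpan)) {
    for (i in 1:(n - span + 1L)) {
      j <- i + span - 1L
      p0 <- pt[i, j]
      if (p0 == 0L) next
      best <- .hairpinLoopE(span - 2L)
      amax <- min(maxSide, span - 7L)
      if (amax >= 0L) {
        kv <- i + 1L + 0:amax
        lv <- j - 1L - 0:amax
        sub <- V[kv, lv, drop = FALSE]
        pp <- pen[1:(amax + 1L), 1:(amax + 1L), drop = FALSE]
        ptin <- pt[i + 1L, j - 1L]
        pp[1L, 1L] <- if (ptin > 0L) .STACK[p0, ptin] else Inf
        tot <- sub + pp
        m <- min(tot)
        if (m < best) best <- m
      }
      V[i, j] <- best
    }
  }
  V
}

# trace the optimal hairpin closed by (i,j); returns pairs, mispair and
# interruption ("place") counts
.traceHairpin <- function(V, s, i, j, maxSide = 6L) {
  pt <- function(a, b) .PAIRTYPE[s[a], s[b]]
  pairs <- matrix(integer(0), ncol = 2)
  mispairs <- 0L; places <- 0L
  repeat {
    pairs <- rbind(pairs, c(i, j))
    e <- V[i, j]
    span <- j - i + 1L
    if (abs(e - .hairpinLoopE(span - 2L)) < 1e-9) break
    found <- FALSE
    amax <- min(maxSide, span - 7L)
    for (a in 0:amax) {
      for (b in 0:amax) {
        k <- i + 1L + a; l <- j - 1L - b
        if (k + 4L > l) next
        pen <- if (a == 0 && b == 0) {
          if (pt(k, l) > 0L) .STACK[pt(i, j), pt(k, l)] else Inf
        } else if (a == 0 || b == 0) .bulgeE(a + b) else .internalE(a, b)
        if (is.finite(pen) && is.finite(V[k, l]) &&
            abs(e - (pen + V[k, l])) < 1e-9) {
          if (a + b > 0) { mispairs <- mispairs + a + b; places <- places + 1L }
          i <- k; j <- l; found <- TRUE; break
        }
      }
      if (found) break
    }
    if (!found) break
  }
  list(pairs = pairs, mispairs = mispairs, places = places)
}

.dotBracket <- function(n, pairs) {
  db <- rep(".", n)
  if (nrow(pairs)) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }
  paste(db, collapse = "")
}

.seqToIdx <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  idx <- .NT[ch]
  if (anyNA(idx))
    stop("invalid characters in sequence: ",
         paste(unique(ch[is.na(idx)]), collapse = ","))
  unname(idx)
}

#' Is the RNAfold executable available?
#' @return logical.
#' @export
hasRnaFold <- function() nzchar(Sys.which("RNAfold"))

.resolveBackend <- function(backend) {
  backend <- match.arg(backend, c("auto", "builtin", "external"))
  if (backend == "auto") {
    if (hasRnaFold()) "external" else "builtin"
  } else backend
}

# batch RNAfold on a character vector of sequences
.foldExternal <- function(seqs) {
  if (!hasRnaFold()) stop("RNAfold executable not found")
  input <- as.vector(rbind(paste0(">s", seq_along(seqs)), seqs))
  out <- system2("RNAfold", args = c("--noPS"), input = input, stdout = TRUE)
  res <- list()
  k <- 0L
  for (line in out) {
    if (grepl("^>", line)) { k <- k + 1L; next }
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) == 3L)
      res[[k]] <- list(structure = m[2], dG = as.numeric(m[3]))
  }
  res
}

#' Minimum folding free energy of an RNA sequence
#'
#' The `"external"` backend delegates to ViennaRNA's RNAfold (full MFE
#' structure). The `"builtin"` backend computes a hairpin-restricted
#' nearest-neighbour MFE from the bundled parameter table: the best
#' structure consisting of a single (possibly interrupted) helix and
#' one terminal loop. The two backends are not numerically identical;
#' both report kcal/mol and 0 for a sequence with no stabilizing
#' structure. T is read as U.
#'
#' @param sequence RNA/DNA sequence (character).
#' @param backend `"auto"` (external when RNAfold is installed, else
#'   builtin), `"builtin"` or `"external"`.
#' @param maxSpan builtin only: cap on hairpin extent (bases).
#' @return list with `dG` (kcal/mol, <= 0) and `structure`
#'   (dot-bracket).
#' @examples
#' foldMfe("GGGGGAAAACCCCC", backend = "builtin")
#' @export
foldMfe <- function(sequence, backend = "auto", maxSpan = Inf) {
  backend <- .resolveBackend(backend)
  if (backend == "external") {
    r <- .foldExternal(toupper(chartr("T", "U", sequence)))[[1]]
    if (r$dG >= 0)
      return(list(dG = 0, structure = strrep(".", nchar(sequence))))
    return(list(dG = r$dG, structure = r$structure))
  }
  s <- .seqToIdx(sequence)
  V <- .foldDP(s, maxSpan = maxSpan)
  if (!any(is.finite(V)) || min(V) >= 0)
    return(list(dG = 0, structure = strrep(".", length(s))))
  ij <- which(V == min(V), arr.ind = TRUE)[1, ]
  tr <- .traceHairpin(V, s, ij[1], ij[2])
  list(dG = min(V), structure = .dotBracket(length(s), tr$pairs))
}

# single-hairpin check + mispair accounting on an arbitrary dot-bracket
# (used for external-backend structures): a single hairpin has no ")("
# transition; mispairs are the unpaired bases inside helix
# interruptions (bulges + internal loops), places are the number of
# interruption events walking the helix outside-in
.structureStats <- function(db) {
  ch <- strsplit(db, "")[[1]]
  open <- which(ch == "(")
  if (!length(open))
    return(list(singleHairpin = FALSE, mispairs = NA, places = NA,
                span = c(NA, NA)))
  singleHairpin <- !grepl("\\)[.]*\\(", db)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  mispairs <- 0L; places <- 0L
  if (nrow(pairs) > 1L) for (k in 2:nrow(pairs)) {
    a <- pairs[k, 1] - pairs[k - 1, 1] - 1L
    b <- pairs[k - 1, 2] - pairs[k, 2] - 1L
    if (a + b > 0L) { mispairs <- mispairs + a + b; places <- places + 1L }
  }
  list(singleHairpin = singleHairpin, mispairs = mispairs, places = places,
       span = c(pairs[1, 1], pairs[1, 2]))
}

#' Extract the 100-nt flank of a PS
#'
#' The flank is the 49 bases upstream of the PS, the PS base itself and
#' the 50 bases downstream, in coding-strand orientation (reverse
#' complement on the minus strand). An error is raised when the window
#' runs off a linear contig; circular genomes wrap.
#'
#' @param genome genome list (id/seq/circular) from [readGenomeFasta]
#'   or [simulateGenome].
#' @param ps GRanges of PS anchors (width 1), optionally with a
#'   `category` metadata column used as the flank class.
#' @return data.frame with `origin`, `class`, `start`, `end`, `strand`,
#'   `seq` (always exactly 100 nt).
#' @export
extractPsFlank <- function(genome, ps) {
  glen <- length(genome$seq)
  pos <- GenomicRanges::start(ps)
  st <- as.character(GenomicRanges::strand(ps))
  cls <- S4Vectors::mcols(ps)$category
  if (is.null(cls)) cls <- rep(NA_character_, length(ps))
  rows <- lapply(seq_along(ps), function(i) {
    win <- if (st[i] == "+") c(pos[i] - 49L, pos[i] + 50L)
           else c(pos[i] - 50L, pos[i] + 49L)
    sq <- .windowSeq(genome, win[1], win[2], st[i])
    data.frame(origin = paste0("PS_", pos[i], st[i]), class = cls[i],
               start = win[1], end = win[2], strand = st[i], seq = sq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# coding-strand window sequence with circular wrapping
.windowSeq <- function(genome, from, to, strand) {
  glen <- length(genome$seq)
  if (from < 1L || to > glen) {
    if (!isTRUE(genome$circular))
      stop("flank window [", from, ", ", to,
           "] off the end of a linear contig")
    idx <- ((seq.int(from, to) - 1L) %% glen) + 1L
    sq <- paste(strsplit(as.character(genome$seq), "")[[1]][idx],
                collapse = "")
  } else {
    sq <- as.character(Biostrings::subseq(genome$seq, from, to))
  }
  if (strand == "-") sq <- revcompChar(sq)
  sq
}

#' Extract 100-nt control flanks from non-PS intergenic regions
#'
#' Controls are taken from intergenic regions within PS-harbouring
#' operons that contain no PS themselves: each control window is 100 nt
#' centred on the region's midpoint — extended symmetrically into the
#' flanking genes when the region is shorter than 100 nt, truncated to
#' the central 100 nt when longer.
#'
#' @param genome genome list.
#' @param operonMap an \linkS4class{OperonMap}.
#' @param psTable data.frame from [categorizePs].
#' @param genes gene annotation GRanges.
#' @return data.frame in the layout of [extractPsFlank] with
#'   class `"control"`.
#' @export
extractControlFlanks <- function(genome, operonMap, psTable, genes) {
  psOps <- unique(psTable$operon_id[!is.na(psTable$operon_id)])
  ops <- operonRanges(operonMap)
  mc <- S4Vectors::mcols(ops)
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gid <- S4Vectors::mcols(genes)$gene_id
  glen <- length(genome$seq)
  rows <- list()
  for (oid in psOps) {
    k <- match(oid, mc$operon_id)
    if (is.na(k) || mc$n_genes[k] < 2L) next
    st <- as.character(GenomicRanges::strand(ops))[k]
    members <- mc$genes[[k]]
    mi <- match(members, gid)
    for (j in seq_len(length(members) - 1L)) {
      if (st == "+") { a <- ge[mi[j]] + 1L; b <- gs[mi[j + 1]] - 1L }
      else { a <- ge[mi[j + 1]] + 1L; b <- gs[mi[j]] - 1L }
      if (b < a) next
      hasPs <- any(psTable$pos >= a & psTable$pos <= b &
                   psTable$strand == st, na.rm = TRUE)
      if (hasPs) next
      cen <- (a + b) %/% 2L
      from <- cen - 49L; to <- cen + 50L
      if (from < 1L || to > glen) next
      rows[[length(rows) + 1L]] <- data.frame(
        origin = paste0("ctrl_", oid, "_", j), class = "control",
        start = from, end = to, strand = st,
        seq = .windowSeq(genome, from, to, st), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(origin = character(0), class = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0)))
  do.call(rbind, rows)
}

#' Scan for a stem-loop near an intergenic PS
#'
#' Enumerates candidate hairpins whose full extent lies within
#' `window` bases of each iPS, keeps those with a single-hairpin
#' structure passing the mispair filter (at most `maxMispairs`
#' unpaired stem positions distributed over at most `maxPlaces` helix
#' interruptions) and folding energy below `dgMax`, and returns the
#' lowest-energy survivor per iPS (ties resolved to the hairpin
#' closest to the iPS). The hairpin's side is recorded relative to the
#' iPS on the coding strand: a hairpin 5' of the iPS is the 3'
#' stem-loop of the upstream flanking gene (the protective
#' configuration) and carries its gene id as `protected_gene`.
#'
#' @param genome genome list.
#' @param ipsTable data.frame from [categorizePs], restricted to
#'   `category == "iPS"` rows (other rows are ignored).
#' @param window scan half-width around the iPS (bases).
#' @param backend folding backend; candidates are enumerated with the
#'   builtin single-hairpin model, and `"external"` re-scores and
#'   re-filters each candidate with RNAfold.
#' @param dgMax retain hairpins with dG strictly below this (kcal/mol).
#' @param maxMispairs,maxPlaces mispair filter.
#' @param maxSpan cap on hairpin extent (bases).
#' @return GRanges of retained stem-loops (possibly empty) with
#'   metadata `dG`, `structure`, `seq`, `ips_pos`, `side`,
#'   `protected_gene`, `upstream_gene`, `downstream_gene`.
#' @export
scanStemLoops <- function(genome, ipsTable, window = 100L,
                          backend = "auto", dgMax = -5,
                          maxMispairs = 5L, maxPlaces = 3L, maxSpan = 80L) {
  backend <- .resolveBackend(backend)
  ips <- ipsTable[ipsTable$category == "iPS", , drop = FALSE]
  glen <- length(genome$seq)
  rows <- list()
  for (i in seq_len(nrow(ips))) {
    pos <- ips$pos[i]; st <- ips$strand[i]
    from <- max(1L, pos - window); to <- min(glen, pos + window)
    sq <- .windowSeq(genome, from, to, st)
    s <- .seqToIdx(sq)
    L <- length(s)
    ipsLocal <- if (st == "+") pos - from + 1L else to - pos + 1L
    V <- .foldDP(s, maxSpan = maxSpan)
    cand <- which(is.finite(V) & V < dgMax, arr.ind = TRUE)
    if (!nrow(cand)) next
    cv <- V[cand]
    o <- order(cv)
    best <- NULL
    for (ci in o) {
      ii <- cand[ci, 1]; jj <- cand[ci, 2]
      if (!is.null(best) && cv[ci] > best$dG + 0.01) break
      tr <- .traceHairpin(V, s, ii, jj)
      dg <- V[ii, jj]
      db <- .dotBracket(jj - ii + 1L,
                        cbind(tr$pairs[, 1] - ii + 1L, tr$pairs[, 2] - ii + 1L))
      mp <- tr$mispairs; pl <- tr$places
      if (backend == "external") {
        ext <- .foldExternal(chartr("T", "U", substr(sq, ii, jj)))[[1]]
        stx <- .structureStats(ext$structure)
        if (!stx$singleHairpin) next
        dg <- ext$dG; db <- ext$structure
        mp <- stx$mispairs; pl <- stx$places
      }
      if (!(dg < dgMax) || mp > maxMispairs || pl > maxPlaces) next
      mid <- (ii + jj) / 2
      candRow <- list(i = ii, j = jj, dG = dg, structure = db,
                      dist = abs(mid - ipsLocal))
      if (is.null(best) || candRow$dG < best$dG - 1e-9 ||
          (abs(candRow$dG - best$dG) <= 0.01 && candRow$dist < best$dist))
        best <- candRow
    }
    if (is.null(best)) next
    gpos <- if (st == "+") from + c(best$i, best$j) - 1L
            else to - c(best$i, best$j) + 1L
    side <- if (best$i + (best$j - best$i) / 2 < ipsLocal) "3prime" else "5prime"
    rows[[length(rows) + 1L]] <- data.frame(
      start = min(gpos), end = max(gpos), strand = st, dG = best$dG,
      structure = best$structure, seq = substr(sq, best$i, best$j),
      ips_pos = pos, side = side,
      protected_gene = if (side == "3prime") ips$upstream_gene[i]
                       else NA_character_,
      upstream_gene = ips$upstream_gene[i],
      downstream_gene = ips$downstream_gene[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      dG = numeric(0), structure = character(0), seq = character(0),
      ips_pos = integer(0), side = character(0),
      protected_gene = character(0), upstream_gene = character(0),
      downstream_gene = character(0))
    return(gr)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(genome$id,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    dG = df$dG, structure = df$structure, seq = df$seq,
    ips_pos = df$ips_pos, side = df$side,
    protected_gene = df$protected_gene, upstream_gene = df$upstream_gene,
    downstream_gene = df$downstream_gene)
  gr
}

#' Flag rho-independent-terminator-like poly-U runs after stem-loops
#'
#' TRUE when a run of at least `uRun` U (T) residues begins within
#' `window` bases downstream of the hairpin's 3' base on the coding
#' strand.
#'
#' @param stemLoops GRanges from [scanStemLoops].
#' @param genome genome list.
#' @param uRun minimal run length.
#' @param window downstream window (bases).
#' @return logical vector, one flag per stem-loop.
#' @export
polyUTerminatorFlag <- function(stemLoops, genome, uRun = 4L, window = 5L) {
  if (!length(stemLoops)) return(logical(0))
  glen <- length(genome$seq)
  st <- as.character(GenomicRanges::strand(stemLoops))
  vapply(seq_along(stemLoops), function(i) {
    win <- if (st[i] == "+") {
      a <- GenomicRanges::end(stemLoops)[i] + 1L
      c(a, a + window + uRun - 2L)
    } else {
      b <- GenomicRanges::start(stemLoops)[i] - 1L
      c(b - window - uRun + 2L, b)
    }
    win <- pmax(1L, pmin(glen, win))
    if (win[2] < win[1]) return(FALSE)
    sq <- .windowSeq(genome, win[1], win[2], st[i])
    sq <- chartr("U", "T", sq)
    runs <- gregexpr("T+", sq)[[1]]
    if (runs[1] == -1) return(FALSE)
    lens <- attr(runs, "match.length")
    any(runs <= window & lens >= uRun)
  }, logical(1))
}

#' Correlate stem-loop folding energy with flanking abundance ratio
#'
#' For each 3'-side stem-loop (one protecting the upstream gene's
#' processed transcript), computes the TA ratio of the protected gene
#' to its downstream flanking gene and the Pearson correlation of this
#' ratio with stem-loop dG. A protective effect appears as a negative
#' signed correlation: more stable stem-loops (more negative dG) give
#' larger ratios.
#'
#' @param stemLoops GRanges from [scanStemLoops].
#' @param abundance a \linkS4class{TranscriptAbundance}.
#' @param condition optional condition (default: mean over conditions).
#' @return list with `r` (signed Pearson correlation; 0 with
#'   `degenerate = TRUE` when either variable is constant), `table`
#'   (the paired ratios) and `n`.
#' @export
protectionCorrelation <- function(stemLoops, abundance, condition = NULL) {
  mc <- S4Vectors::mcols(stemLoops)
  keep <- mc$side == "3prime" & !is.na(mc$protected_gene)
  sl <- mc[keep, , drop = FALSE]
  condTA <- conditionTA(abundance)
  ta <- if (is.null(condition)) rowMeans(condTA) else condTA[, condition]
  ok <- sl$protected_gene %in% names(ta) & sl$downstream_gene %in% names(ta)
  sl <- sl[ok, , drop = FALSE]
  if (nrow(sl) < 3L)
    stop("need at least 3 stem-loops with both flanking genes quantified")
  ratio <- as.numeric(ta[sl$protected_gene] / ta[sl$downstream_gene])
  tab <- data.frame(protected_gene = sl$protected_gene,
                    downstream_gene = sl$downstream_gene,
                    dG = sl$dG, ratio = ratio, stringsAsFactors = FALSE)
  degenerate <- stats::sd(ratio) == 0 || stats::sd(sl$dG) == 0
  r <- if (degenerate) 0 else cor(ratio, sl$dG, method = "pearson")
  list(r = r, table = tab, n = nrow(tab), degenerate = degenerate)
}

#' Compare folding free energy between flank groups
#'
#' Per-group mean and standard deviation of dG, plus two-sample tests
#' (both the Welch and the pooled-variance Student forms are reported)
#' for each non-control group against the control group, or between
#' the two groups when exactly two are present.
#'
#' @param dG numeric vector of folding energies (kcal/mol).
#' @param group character/factor of group labels (e.g. uPS/iPS/cPS/
#'   control), parallel to `dG`.
#' @return list with `stats` (per-group n/mean/sd) and `tests`
#'   (comparison, mean difference, Welch p, pooled p).
#' @export
compareDgGroups <- function(dG, group) {
  group <- as.character(group)
  stopifnot(length(dG) == length(group))
  sizes <- table(group)
  if (any(sizes < 2L))
    stop("group of size < 2: ", names(sizes)[which(sizes < 2)[1]])
  stats <- do.call(rbind, lapply(names(sizes), function(g) {
    x <- dG[group == g]
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x))
  }))
  lv <- names(sizes)
  refs <- if (length(lv) == 2L) lv[2] else "control"
  tests <- NULL
  if (refs %in% lv) {
    others <- setdiff(lv, refs)
    tests <- do.call(rbind, lapply(others, function(g) {
      x <- dG[group == g]; y <- dG[group == refs]
      if (stats::sd(c(x, y)) == 0) {
        wp <- pp <- 1
      } else {
        wp <- t.test(x, y)$p.value
        pp <- t.test(x, y, var.equal = TRUE)$p.value
      }
      data.frame(comparison = paste(g, "vs", refs),
                 mean_diff = mean(x) - mean(y),
                 welch_p = wp, pooled_p = pp)
    }))
  }
  list(stats = stats, tests = tests)
}
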