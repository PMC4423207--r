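#' Read a single-contig genome from FASTA
#'
#' @param path FASTA file with exactly one record.
#' @param circular logical; whether the contig is circular.
#' @return A named list with `id`, `seq` (a \link[Biostrings]{DNAString})
#'   and `circular`.
#' @export
readGenomeFasta <- function(path, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one FASTA record, found ", length(ss))
  sq <- Biostrings::DNAString(toupper(as.character(ss[[1]])))
  if (length(sq) == 0L) stop("genome sequence is empty")
  bad <- setdiff(unique(strsplit(as.character(sq), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("genome alphabet restricted to A/C/G/T/N; found: ",
         paste(bad, collapse = ","))
  list(id = sub("\\s.*$", "", names(ss)[1]), seq = sq, circular = circular)
}

#' Write a genome list (as returned by [readGenomeFasta]) to FASTA
#' @param genome list with `id` and `seq`.
#' @param path output path.
#' @export
writeGenomeFasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Minimal GFF3 reader for CDS/rRNA/tRNA features. Returns a
#' \link[GenomicRanges]{GRanges} (1-based, closed intervals — the
#' Bioconductor convention used throughout the package) sorted by start,
#' with metadata columns `gene_id`, `feature_type` and `cog` (NA when
#' absent). Coordinates are validated against `genomeLength` when given.
#'
#' @param path GFF3 file.
#' @param genomeLength optional integer; features ending beyond it raise
#'   a validation error.
#' @return GRanges of gene features.
#' @export
readGff <- function(path, genomeLength = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = character(0), feature_type = character(0), cog = character(0))
    return(gr)
  }
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GFF3 line ", idx[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1])
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end   <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("malformed GFF3 line ", idx[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinates")
  if (any(end < start))
    stop("validation error: end < start at GFF3 line ",
         idx[which(end < start)[1]])
  if (!is.null(genomeLength) && any(end > genomeLength))
    stop("validation error: feature end ", max(end),
         " beyond genome length ", genomeLength)
  if (!all(m[, 7] %in% c("+", "-")))
    stop("strand must be + or - at GFF3 line ",
         idx[which(!m[, 7] %in% c("+", "-"))[1]])
  attr_field <- m[, 9]
  getAttr <- function(key) {
    re <- paste0("(^|;)\\s*", key, "=([^;]*)")
    out <- rep(NA_character_, length(attr_field))
    hit <- regexpr(re, attr_field)
    has <- hit > 0
    out[has] <- sub(re, "\\2", regmatches(attr_field, hit))
    out
  }
  gene_id <- getAttr("gene_id")
  gene_id[is.na(gene_id)] <- getAttr("ID")[is.na(gene_id)]
  if (anyNA(gene_id))
    stop("GFF3 line ", idx[which(is.na(gene_id))[1]],
         ": no gene_id or ID attribute")
  ftype <- m[, 3]
  ftype[!ftype %in% c("CDS", "rRNA", "tRNA")] <- "other"
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = m[, 7],
    gene_id = gene_id, feature_type = ftype, cog = getAttr("cog"))
  gr[order(GenomicRanges::start(gr), as.character(GenomicRanges::strand(gr)))]
}

#' Write gene annotation to GFF3
#' @param genes GRanges with `gene_id`, `feature_type` metadata columns.
#' @param path output path.
#' @param source source column value.
#' @export
writeGff <- function(genes, path, source = "SRPSseq") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(genes)) {
    mc <- S4Vectors::mcols(genes)
    attrs <- paste0("ID=", mc$gene_id, ";gene_id=", mc$gene_id)
    if (!is.null(mc$cog)) {
      has <- !is.na(mc$cog)
      attrs[has] <- paste0(attrs[has], ";cog=", mc$cog[has])
    }
    writeLines(paste(
      as.character(GenomicRanges::seqnames(genes)), source,
      mc$feature_type, GenomicRanges::start(genes),
      GenomicRanges::end(genes), ".",
      as.character(GenomicRanges::strand(genes)), ".", attrs,
      sep = "\t"), con)
  }
  invisible(path)
}

#' Read a stranded read 5'-start track
#'
#' Accepts BED6 (0-based half-open; the score column is the start count
#' at the interval's 5' base) or a 3-column TSV (`position` 1-based,
#' `count`, `strand`). Counts on duplicate positions are summed; missing
#' positions imply count 0.
#'
#' @param path input file.
#' @param genome genome list (from [readGenomeFasta]) providing the
#'   contig id and length.
#' @return A \linkS4class{PositionTrack}.
#' @export
readStartTrack <- function(path, genome) {
  glen <- length(genome$seq)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 6L) {                 # BED6
    bad <- setdiff(unique(tab[[1]]), genome$id)
    if (length(bad))
      stop("track row on undeclared contig: ", paste(bad, collapse = ","))
    strand <- tab[[6]]
    count <- tab[[5]]
    # 5' base of a stranded interval: start for +, end-1 (0-based) for -
    pos0 <- ifelse(strand == "+", tab[[2]], tab[[3]] - 1L)
    pos <- as.integer(pos0) + 1L
  } else if (ncol(tab) == 3L) {          # position, count, strand
    pos <- as.integer(tab[[1]])
    count <- tab[[2]]
    strand <- tab[[3]]
  } else stop("expected BED6 or 3-column TSV, found ", ncol(tab), " columns")
  if (any(count < 0)) stop("validation error: negative start count")
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(pos < 1L | pos > glen))
    stop("start position outside genome [1, ", glen, "]")
  plus <- numeric(glen); minus <- numeric(glen)
  ip <- strand == "+"
  if (any(ip)) {
    agg <- rowsum(count[ip], pos[ip])
    plus[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (any(!ip)) {
    agg <- rowsum(count[!ip], pos[!ip])
    minus[as.integer(rownames(agg))] <- agg[, 1]
  }
  PositionTrack(plus, minus)
}

#' Write a start track as BED6
#'
#' One row per nonzero position; score = start count at the row's 5'
#' base; coordinates 0-based half-open.
#'
#' @param track a \linkS4class{PositionTrack}.
#' @param path output path.
#' @param chrom contig name.
#' @export
writeStartTrack <- function(track, path, chrom = "chr") {
  rows <- list()
  for (st in c("+", "-")) {
    v <- trackStrand(track, st)
    nz <- which(v > 0)
    if (length(nz))
      rows[[st]] <- data.frame(chrom = chrom, start = nz - 1L, end = nz,
                               name = ".", score = v[nz], strand = st)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0))
  out <- out[order(out$start), ]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a simulation or pipeline configuration (YAML)
#' @param path YAML file of SimConfig fields.
#' @return list of configuration values (validated via [simConfig]).
#' @export
readConfig <- function(path) do.call(simConfig, yaml::read_yaml(path))

#' @rdname readConfig
#' @param config a SimConfig list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config[setdiff(names(config), "patternMix")], path)
  # patternMix written as an explicit map to keep names
  cat("patternMix:\n", file = path, append = TRUE)
  for (nm in names(config$patternMix))
    cat(sprintf("  %s: %s\n", nm, format(config$patternMix[[nm]])),
        file = path, append = TRUE)
  invisible(path)
}
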