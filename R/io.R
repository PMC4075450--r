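# Readers/writers and domain containers.
#
# Coordinate convention: all internal coordinates are 0-based half-open on the
# forward strand. GFF3 (1-based inclusive) is converted at I/O only. A "base
# position" (TSS, summit, 3' end) is a single 0-based position.

#' Read a multi-record FASTA file as a genome
#'
#' Contig names are the header text up to the first whitespace; sequences are
#' uppercased. Only the alphabet \{A,C,G,T,N\} is accepted after
#' normalisation; N never matches any motif downstream.
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}, one element per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop_fmt("duplicate contig name(s): %s",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0))
    stop_fmt("empty record(s): %s", paste(nm[Biostrings::width(x) == 0],
                                          collapse = ", "))
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    stop_fmt("non-{A,C,G,T,N} character '%s' in contig '%s'", ch, nm[bad][1])
  }
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- nm
  g
}

#' Write a genome to FASTA
#' @param genome A named DNAStringSet.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Construct a gene-model table
#'
#' The container for gene annotations: one row per gene with 0-based
#' half-open body interval and strand-aware TSS / 3' end base positions
#' (TSS = start for "+", end - 1 for "-").
#'
#' @param gene_id,contig,strand,start,end Parallel vectors; strand in
#'   \code{c("+", "-")}, \code{start < end} 0-based half-open.
#' @return data.frame with columns gene_id, contig, strand, start, end,
#'   tss, three_prime_end.
#' @export
gene_models <- function(gene_id, contig, strand, start, end) {
  if (anyDuplicated(gene_id))
    stop_fmt("duplicate gene_id(s): %s",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop_fmt("unknown strand value(s): %s",
             paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  if (any(start < 0) || any(start >= end))
    stop_fmt("invalid gene interval (need 0 <= start < end)")
  data.frame(
    gene_id = as.character(gene_id), contig = as.character(contig),
    strand = strand,
    start = as.integer(start), end = as.integer(end),
    tss = as.integer(ifelse(strand == "+", start, end - 1L)),
    three_prime_end = as.integer(ifelse(strand == "+", end - 1L, start)),
    stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#'
#' Only features of type \code{gene} are consumed. GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention;
#' for minus-strand genes the TSS is the record's end coordinate.
#'
#' @param path Path to a GFF3 file.
#' @return Gene-model data.frame (see \code{\link{gene_models}}).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_fmt("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) stop_fmt("no 'gene' features in %s", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop_fmt("gene record(s) with unknown strand ('.') in %s", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids))
    stop_fmt("gene records missing ID attribute in %s", path)
  gene_models(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr))            # inclusive end == half-open end
}

#' Write gene models to GFF3
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "cisgrammar"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a BED-like peak table
#'
#' Expected columns (tab-delimited, with header): contig, start, end,
#' peak_id, score, summit_offset and optionally fdr. The summit base
#' position is \code{start + summit_offset} and must lie inside
#' \code{[start, end)}. When an \code{fdr} column is present, peaks are kept
#' only if \code{fdr < fdr_threshold} (the usual "FDR < 0.01" peak-calling
#' filter); set \code{fdr_threshold = NULL} to disable.
#'
#' @param path Path to the peak file.
#' @param factor Factor (transcription factor) label attached to all peaks.
#' @param fdr_threshold Keep peaks with fdr strictly below this (default 0.01).
#' @return data.frame: peak_id, factor, contig, start, end, summit, score
#'   and fdr (NA when absent from the file).
#' @export
read_peaks <- function(path, factor = NA_character_, fdr_threshold = 0.01) {
  if (!file.exists(path)) stop_fmt("peak file not found: %s", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("contig", "start", "end", "peak_id", "score", "summit_offset")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_fmt("peak file %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  summit <- d$start + d$summit_offset
  bad <- which(summit < d$start | summit >= d$end)
  if (length(bad))
    stop_fmt("summit outside [start,end) at data line(s): %s",
             paste(bad, collapse = ", "))
  if (any(d$score < 0)) stop_fmt("negative peak score(s) in %s", path)
  fdr <- if ("fdr" %in% names(d)) as.numeric(d$fdr) else
    rep(NA_real_, nrow(d))
  if (any(!is.na(fdr) & (fdr < 0 | fdr > 1)))
    stop_fmt("fdr values outside [0,1] in %s", path)
  out <- data.frame(
    peak_id = as.character(d$peak_id), factor = factor,
    contig = as.character(d$contig),
    start = as.integer(d$start), end = as.integer(d$end),
    summit = as.integer(summit), score = as.numeric(d$score),
    fdr = fdr, stringsAsFactors = FALSE)
  if (!is.null(fdr_threshold) && any(!is.na(out$fdr)))
    out <- out[is.na(out$fdr) | out$fdr < fdr_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a peak table in the BED-like format read by [read_peaks()]
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(
    contig = peaks$contig, start = peaks$start, end = peaks$end,
    peak_id = peaks$peak_id, score = peaks$score,
    summit_offset = peaks$summit - peaks$start)
  if (!is.null(peaks$fdr) && any(!is.na(peaks$fdr))) out$fdr <- peaks$fdr
  write_tsv(out, path)
}

#' The default cis-element motif set
#'
#' Literal motif strings used throughout: the core AuxRE (TGTC), the
#' canonical AuxRE (TGTCTC) and its TGTCGG variant, the two E-box elements
#' G-box (CACGTG) and HUD (CACATG), and GATCG as a negative control.
#'
#' @return data.frame: name, pattern, is_palindrome.
#' @export
default_motifs <- function() {
  m <- data.frame(
    name = c("AuxRE-core", "AuxRE", "AuxRE-alt", "G-box", "HUD", "control"),
    pattern = c("TGTC", "TGTCTC", "TGTCGG", "CACGTG", "CACATG", "GATCG"),
    stringsAsFactors = FALSE)
  m$is_palindrome <- vapply(m$pattern, is_palindrome, logical(1))
  rownames(m) <- NULL
  m
}

# Deterministic TSV writer used for every report/fixture table.
write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
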