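# Peak-to-gene assignment and peak position classification.
#
# A peak is judged by its summit (the best point estimate of the binding
# site). A gene's target region is the strand-aware union
#   [TSS - promoter_bp, TSS) U gene body U (3' end, 3' end + downstream_bp]
# which, because the three pieces abut, is a single contiguous interval of
# base positions on the forward strand.

# Strand-aware signed distance from summit position to TSS: negative =
# upstream of the TSS, positive = downstream (into or past the gene body).
signed_distance_to_tss <- function(summit, tss, strand) {
  ifelse(strand == "+", summit - tss, tss - summit)
}

# Region-class label from gene geometry; positions are base positions.
# Returns NA when outside all windows given the promoter/downstream spans.
region_class_for <- function(summit, gene, promoter_bp, downstream_bp) {
  sdist <- signed_distance_to_tss(summit, gene$tss, gene$strand)
  in_body <- summit >= gene$start & summit < gene$end
  dd <- signed_distance_to_tss(summit, gene$three_prime_end, gene$strand)
  cls <- rep(NA_character_, length(summit))
  cls[in_body] <- "d0"
  up <- !in_body & sdist < 0 & -sdist <= promoter_bp
  cls[up] <- paste0("u", 1000L * ceiling(-sdist[up] / 1000))
  down <- !in_body & dd > 0 & dd <= downstream_bp
  cls[down] <- paste0("d", 1000L * ceiling(dd[down] / 1000))
  cls
}

#' Assign peaks to target genes by the promoter/body/downstream window rule
#'
#' A peak links to a gene iff its summit lies within the strand-aware union
#' of the promoter (default -3 kb, half-open at the TSS), the gene body, or
#' the downstream window (default 1 kb past the 3' end, half-open at the far
#' end). One peak may link to several genes and vice versa.
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param genes Gene-model data.frame (see [gene_models()]).
#' @param promoter_bp Upstream window size in bp (default 3000).
#' @param downstream_bp Downstream window size in bp (default 1000).
#' @return data.frame sorted by (gene_id, peak_id): peak_id, gene_id, factor,
#'   region_class (u1000/u2000/u3000/d0/d1000), signed_distance (bp from
#'   summit to TSS; negative = upstream, strand-aware).
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter_bp = 3000,
                                  downstream_bp = 1000) {
  stopifnot(promoter_bp >= 0, downstream_bp >= 0)
  unknown <- !(peaks$contig %in% unique(genes$contig))
  if (any(unknown))
    stop_fmt("peak(s) on contig absent from the annotation: %s",
             paste(peaks$peak_id[unknown], collapse = ", "))
  if (nrow(peaks) == 0 || nrow(genes) == 0)
    return(data.frame(peak_id = character(), gene_id = character(),
                      factor = character(), region_class = character(),
                      signed_distance = integer()))
  # Contiguous forward-strand target interval per gene (base positions).
  lo <- ifelse(genes$strand == "+", genes$start - promoter_bp,
               genes$start - downstream_bp)
  hi <- ifelse(genes$strand == "+", genes$end - 1L + downstream_bp,
               genes$end - 1L + promoter_bp)
  ggr <- GenomicRanges::GRanges(genes$contig,
                                IRanges::IRanges(lo + 1L, hi + 1L))
  pgr <- GenomicRanges::GRanges(peaks$contig,
                                IRanges::IRanges(peaks$summit + 1L,
                                                 width = 1L))
  ov <- GenomicRanges::findOverlaps(pgr, ggr, ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  g <- genes[gi, , drop = FALSE]
  links <- data.frame(
    peak_id = peaks$peak_id[pi],
    gene_id = g$gene_id,
    factor = if (is.null(peaks$factor)) NA_character_ else peaks$factor[pi],
    region_class = region_class_for(peaks$summit[pi], g,
                                    promoter_bp, downstream_bp),
    signed_distance = as.integer(
      signed_distance_to_tss(peaks$summit[pi], g$tss, g$strand)),
    stringsAsFactors = FALSE)
  links <- links[order(links$gene_id, links$peak_id), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Deduplicated target-gene sets per factor
#'
#' @param links Link table from [assign_peaks_to_genes()].
#' @return Named list of character vectors (sorted, unique gene ids), one per
#'   factor; links with no factor label are pooled under "all".
#' @export
target_genes <- function(links) {
  if (nrow(links) == 0) stop_fmt("empty link table")
  fac <- links$factor
  fac[is.na(fac)] <- "all"
  lapply(split(links$gene_id, fac), function(g) sort(unique(g)))
}

#' Descriptive distribution of peak positions relative to gene structure
#'
#' Each peak is assigned to its nearest gene (smallest absolute signed
#' summit-to-TSS distance; ties broken by lexicographically smaller gene_id)
#' and binned over \code{[-upstream_bp, 3' end + downstream_bp]}:
#' u5000..u1000 upstream 1-kb bins, d0 = gene body, d1000 = downstream
#' window. Peaks beyond all windows are reported as "intergenic"; fractions
#' are over binned (non-intergenic) peaks and sum to 1.
#'
#' @param peaks,genes As in [assign_peaks_to_genes()].
#' @param upstream_bp Span of the upstream binning (default 5000).
#' @param downstream_bp Downstream window (default 1000).
#' @return data.frame: bin, count, fraction (NA for intergenic).
#' @export
peak_position_distribution <- function(peaks, genes, upstream_bp = 5000,
                                       downstream_bp = 1000) {
  ubins <- paste0("u", seq(upstream_bp, 1000, by = -1000))
  bins <- c(ubins, "d0", paste0("d", downstream_bp))
  assigned <- rep("intergenic", nrow(peaks))
  for (ct in unique(peaks$contig)) {
    gi <- which(genes$contig == ct)
    pi <- which(peaks$contig == ct)
    if (!length(gi) || !length(pi)) next
    g <- genes[gi, , drop = FALSE]
    # |signed distance| matrix peaks x genes, strand-aware
    sm <- outer(peaks$summit[pi], g$tss, "-")
    sm[, g$strand == "-"] <- -sm[, g$strand == "-", drop = FALSE]
    ord <- order(g$gene_id)                     # tie-break: smaller gene_id
    nearest <- ord[apply(abs(sm[, ord, drop = FALSE]), 1, which.min)]
    ng <- g[nearest, , drop = FALSE]
    cls <- region_class_for(peaks$summit[pi], ng, upstream_bp, downstream_bp)
    assigned[pi] <- ifelse(is.na(cls), "intergenic", cls)
  }
  counts <- vapply(bins, function(b) sum(assigned == b), integer(1))
  n_binned <- sum(counts)
  out <- data.frame(bin = c(bins, "intergenic"),
                    count = c(counts, sum(assigned == "intergenic")),
                    fraction = c(if (n_binned > 0) counts / n_binned
                                 else rep(NA_real_, length(bins)), NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
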