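# Multi-factor target-set overlap, peak-to-peak distances, ChIP-qPCR ratio.

#' Overlap statistics for two or three target-gene sets
#'
#' Computes all pairwise (and, with three sets, the triple) intersection
#' counts, the percentage each intersection represents of each constituent
#' set, the hypergeometric expected pairwise overlap |A||B|/N, and the
#' upper-tail hypergeometric p-value for observing at least the observed
#' pairwise overlap when drawing from a universe of size N. The universe
#' size is an explicit required parameter; the triple overlap is reported as
#' a count (no 3-way exact test).
#'
#' @param setA,setB Character vectors of gene identifiers.
#' @param setC Optional third set.
#' @param universe_size Size N of the gene universe the sets are drawn from.
#' @param set_names Labels for the sets (default A, B, C).
#' @return list of class "overlap_result": sizes, pairs (data.frame with
#'   n_overlap, pct_of_first, pct_of_second, expected, p per pair),
#'   triple (count and per-set percentages, NULL without setC),
#'   universe_size.
#' @export
target_overlap <- function(setA, setB, setC = NULL, universe_size,
                           set_names = c("A", "B", "C")) {
  sets <- list(unique(setA), unique(setB))
  if (!is.null(setC)) sets <- c(sets, list(unique(setC)))
  names(sets) <- set_names[seq_along(sets)]
  n_union <- length(unique(unlist(sets)))
  if (universe_size < n_union)
    stop_fmt("universe_size %d smaller than the union of the sets (%d)",
             universe_size, n_union)
  sizes <- vapply(sets, length, integer(1))
  idx <- utils::combn(seq_along(sets), 2)
  pairs <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    k <- length(intersect(sets[[i1]], sets[[i2]]))
    data.frame(
      first = names(sets)[i1], second = names(sets)[i2],
      n_first = sizes[i1], n_second = sizes[i2], n_overlap = k,
      pct_of_first = 100 * k / sizes[i1],
      pct_of_second = 100 * k / sizes[i2],
      expected = sizes[i1] * as.numeric(sizes[i2]) / universe_size,
      p = phyper(k - 1, sizes[i1], universe_size - sizes[i1], sizes[i2],
                 lower.tail = FALSE),
      stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  triple <- NULL
  if (length(sets) == 3) {
    k3 <- length(Reduce(intersect, sets))
    triple <- data.frame(n_overlap = k3,
                         t(setNames(100 * k3 / sizes,
                                    paste0("pct_of_", names(sets)))))
  }
  structure(list(sizes = sizes, pairs = pairs, triple = triple,
                 universe_size = universe_size),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Target-set overlap (universe N =", x$universe_size, ")\n")
  cat("Set sizes:", paste(names(x$sizes), x$sizes, sep = "=",
                          collapse = ", "), "\n")
  print(x$pairs, row.names = FALSE)
  if (!is.null(x$triple)) {
    cat("Triple overlap:\n")
    print(x$triple, row.names = FALSE)
  }
  invisible(x)
}

#' Distance distribution between two factors' peaks on common target genes
#'
#' For each common target gene, the distance is the minimum over all peak
#' pairs of the absolute summit-to-summit distance between the two factors'
#' peaks linked to that gene. Genes missing peaks from either factor are
#' skipped and counted.
#'
#' @param peaksA,peaksB Peak data.frames of the two factors.
#' @param linksA,linksB Link tables (from [assign_peaks_to_genes()]) for the
#'   two factors' peaks.
#' @param common_genes Character vector of common target gene ids.
#' @param breaks Histogram break points in bp (default 0..2000 by 100;
#'   distances beyond the last break are pooled in an overflow bin).
#' @return list: distances (gene_id, distance), histogram (bin_lo, bin_hi,
#'   count, fraction), n_skipped.
#' @export
peak_distance_distribution <- function(peaksA, peaksB, linksA, linksB,
                                       common_genes,
                                       breaks = seq(0, 2000, by = 100)) {
  sa <- setNames(peaksA$summit, peaksA$peak_id)
  sb <- setNames(peaksB$summit, peaksB$peak_id)
  res <- lapply(common_genes, function(g) {
    pa <- linksA$peak_id[linksA$gene_id == g]
    pb <- linksB$peak_id[linksB$gene_id == g]
    pa <- pa[pa %in% names(sa)]; pb <- pb[pb %in% names(sb)]
    if (!length(pa) || !length(pb)) return(NULL)
    data.frame(gene_id = g,
               distance = min(abs(outer(sa[pa], sb[pb], "-"))),
               stringsAsFactors = FALSE)
  })
  kept <- res[!vapply(res, is.null, logical(1))]
  distances <- if (length(kept)) do.call(rbind, kept) else
    data.frame(gene_id = character(), distance = numeric())
  rownames(distances) <- NULL
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  cnt <- vapply(seq_along(lo), function(i)
    sum(distances$distance >= lo[i] & distances$distance < hi[i]),
    integer(1))
  cnt <- c(cnt, sum(distances$distance >= breaks[length(breaks)]))
  hist <- data.frame(bin_lo = c(lo, breaks[length(breaks)]),
                     bin_hi = c(hi, NA), count = cnt,
                     fraction = cnt / max(1L, sum(cnt)))
  rownames(hist) <- NULL
  list(distances = distances, histogram = hist,
       n_skipped = length(common_genes) - nrow(distances))
}

#' ChIP-qPCR enrichment ratio
#'
#' Enrichment of precipitated DNA at a target locus, as the ratio between
#' the test sample (e.g. the tagged transgenic line) and the control sample
#' (e.g. wild type), each first normalised to an internal reference region:
#' \code{(target_test/ref_test) / (target_ctrl/ref_ctrl)}. Quantities are
#' linear-scale amounts (100\% amplification efficiency assumed).
#'
#' @param target_test,ref_test Target and reference quantities in the test
#'   sample.
#' @param target_ctrl,ref_ctrl Same in the control sample.
#' @return Enrichment ratio (vectorised).
#' @export
qpcr_enrichment <- function(target_test, ref_test, target_ctrl, ref_ctrl) {
  check_positive(target_test, ref_test, target_ctrl, ref_ctrl,
                 .what = "qPCR")
  (target_test / ref_test) / (target_ctrl / ref_ctrl)
}
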