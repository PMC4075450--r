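# Cis-element grammar: exact-string motif scanning in summit-centred windows
# and the derived statistics (enrichment vs genomic background, AuxRE/E-box
# co-occurrence classes, element spacing, association with activated genes,
# binding-score by class).
#
# Matching is literal (IUPAC codes in the pattern are honoured; N in the
# subject never matches). Both strands are scanned; palindromic patterns
# yield exactly one hit per position.

#' Scan a summit-centred window for motif hits
#'
#' The window is \code{[center - halfwidth, center + halfwidth + 1)} clipped
#' to the contig. Forward-strand matches of each pattern are reported along
#' with matches of its reverse complement (strand "-", at forward-strand
#' offsets); palindromes are deduplicated. Offsets are relative to the
#' (clipped) window start; \code{width} is the match footprint length.
#'
#' @param genome Named DNAStringSet (see [read_genome()]).
#' @param contig Contig name.
#' @param center Base position of the window center (e.g. a peak summit).
#' @param halfwidth Window half-width in bp (default 100).
#' @param motifs Motif table (see [default_motifs()]).
#' @return data.frame sorted by offset: name, offset, strand, width.
#' @export
scan_window <- function(genome, contig, center, halfwidth = 100,
                        motifs = default_motifs()) {
  if (!contig %in% names(genome)) stop_fmt("unknown contig '%s'", contig)
  len <- length(genome[[contig]])
  if (center < 0 || center >= len)
    stop_fmt("center %d outside contig '%s' [0,%d)", center, contig, len)
  lo <- max(0L, as.integer(center - halfwidth))
  hi <- min(len, as.integer(center + halfwidth + 1L))
  win <- Biostrings::subseq(genome[[contig]], lo + 1L, hi)
  scan_sequence(win, motifs)
}

# Scan one DNAString/character window; offsets relative to its start.
scan_sequence <- function(win, motifs = default_motifs()) {
  if (is.character(win)) win <- Biostrings::DNAString(win)
  res <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[i]
    if (nchar(pat) > length(win)) next
    fwd <- Biostrings::matchPattern(pat, win, fixed = "subject")
    if (length(fwd))
      res[[length(res) + 1L]] <- data.frame(
        name = motifs$name[i], offset = Biostrings::start(fwd) - 1L,
        strand = "+", width = nchar(pat), stringsAsFactors = FALSE)
    if (!isTRUE(motifs$is_palindrome[i])) {
      rev <- Biostrings::matchPattern(revcomp(pat), win, fixed = "subject")
      if (length(rev))
        res[[length(res) + 1L]] <- data.frame(
          name = motifs$name[i], offset = Biostrings::start(rev) - 1L,
          strand = "-", width = nchar(pat), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(name = character(), offset = integer(),
                      strand = character(), width = integer()))
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Edge-to-edge gap between two match footprints [a1,a1+w1), [a2,a2+w2);
# overlapping or abutting footprints give 0.
footprint_gap <- function(a1, w1, a2, w2) {
  pmax(0L, pmax(a2 - (a1 + w1), a1 - (a2 + w2)))
}

# Class + nearest-pair gap from one window's hit table.
profile_from_hits <- function(hits, ebox_names, core_name) {
  core <- hits[hits$name == core_name, , drop = FALSE]
  ebox <- hits[hits$name %in% ebox_names, , drop = FALSE]
  has_core <- nrow(core) > 0; has_ebox <- nrow(ebox) > 0
  cls <- if (has_core && has_ebox) "both" else if (has_core) "auxre_only"
         else if (has_ebox) "ebox_only" else "neither"
  gap <- NA_integer_
  if (cls == "both") {
    gaps <- outer(seq_len(nrow(ebox)), seq_len(nrow(core)),
                  function(i, j) footprint_gap(ebox$offset[i], ebox$width[i],
                                               core$offset[j], core$width[j]))
    gap <- as.integer(min(gaps))
  }
  list(class = cls, min_gap = gap,
       n_core = nrow(core), n_ebox = nrow(ebox))
}

#' Per-peak motif profiles within a summit-centred window
#'
#' For every peak, scans \code{halfwidth} bp either side of the summit and
#' records the AuxRE/E-box co-occurrence class and, for class "both", the
#' edge-to-edge gap between the nearest E-box and core-AuxRE footprints.
#'
#' @inheritParams scan_window
#' @param peaks Peak data.frame.
#' @param ebox_names Motif names counted as E-boxes (default G-box and HUD).
#' @param core_name Motif name of the core AuxRE (default "AuxRE-core").
#' @return data.frame: peak_id, factor, cooccurrence_class
#'   (both/auxre_only/ebox_only/neither), min_gap (NA unless "both"),
#'   n_core, n_ebox.
#' @export
peak_motif_profiles <- function(genome, peaks, motifs = default_motifs(),
                                halfwidth = 100,
                                ebox_names = c("G-box", "HUD"),
                                core_name = "AuxRE-core") {
  stopifnot(core_name %in% motifs$name, all(ebox_names %in% motifs$name))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    hits <- scan_window(genome, peaks$contig[i], peaks$summit[i],
                        halfwidth, motifs)
    p <- profile_from_hits(hits, ebox_names, core_name)
    data.frame(peak_id = peaks$peak_id[i],
               factor = if (is.null(peaks$factor)) NA_character_
                        else peaks$factor[i],
               cooccurrence_class = p$class, min_gap = p$min_gap,
               n_core = p$n_core, n_ebox = p$n_ebox,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-occurrence class fractions
#'
#' @param profiles Profile table from [peak_motif_profiles()].
#' @return data.frame over the four classes: class, count, fraction
#'   (fractions sum to 1).
#' @export
classify_cooccurrence <- function(profiles) {
  classes <- c("both", "auxre_only", "ebox_only", "neither")
  counts <- vapply(classes,
                   function(k) sum(profiles$cooccurrence_class == k),
                   integer(1))
  data.frame(class = classes, count = counts,
             fraction = counts / max(1L, sum(counts)),
             stringsAsFactors = FALSE)
}

# Sample n background window centers uniformly from the genome, excluding
# positions whose window would intersect any peak window or contig edge.
sample_background_centers <- function(genome, peaks, n, halfwidth, seed) {
  contigs <- names(genome)
  lens <- Biostrings::width(genome)
  with_seed(seed, {
    out <- data.frame(contig = character(), center = integer())
    guard <- 0L
    while (nrow(out) < n && guard < 200L) {
      guard <- guard + 1L
      m <- 2L * (n - nrow(out)) + 10L
      ci <- sample.int(length(contigs), m, replace = TRUE,
                       prob = lens / sum(lens))
      pos <- floor(runif(m, halfwidth, lens[ci] - halfwidth - 1))
      cand <- data.frame(contig = contigs[ci], center = as.integer(pos),
                         stringsAsFactors = FALSE)
      if (nrow(peaks)) {
        cgr <- GenomicRanges::GRanges(
          cand$contig, IRanges::IRanges(cand$center - halfwidth + 1L,
                                        cand$center + halfwidth + 1L))
        pgr <- GenomicRanges::GRanges(
          peaks$contig, IRanges::IRanges(peaks$summit - halfwidth + 1L,
                                         peaks$summit + halfwidth + 1L))
        keep <- !IRanges::overlapsAny(cgr, pgr)
        cand <- cand[keep, , drop = FALSE]
      }
      out <- rbind(out, cand)
    }
    out[seq_len(min(n, nrow(out))), , drop = FALSE]
  })
}

#' Motif enrichment in peak windows versus genomic background
#'
#' For each motif, windows are scored for presence of at least one hit
#' (either strand); the peak-vs-background 2x2 table gives a fold change
#' with 0.5-count continuity correction,
#' \code{fold = ((k_peak + 0.5)/n_peak) / ((k_bg + 0.5)/n_bg)}, and a
#' two-sided Fisher exact p-value. The default background is
#' \code{background_ratio} windows per peak sampled uniformly from the
#' genome excluding peak windows, with a fixed seed.
#'
#' @inheritParams peak_motif_profiles
#' @param background_ratio Background windows per peak window (default 10).
#' @param seed Seed for background sampling (default 1).
#' @param background_centers Optional data.frame(contig, center) overriding
#'   the sampled background.
#' @return data.frame: name, pattern, n_peak, k_peak, n_bg, k_bg, fold, p.
#' @export
motif_enrichment <- function(genome, peaks, motifs = default_motifs(),
                             halfwidth = 100, background_ratio = 10,
                             seed = 1, background_centers = NULL) {
  if (is.null(background_centers))
    background_centers <- sample_background_centers(
      genome, peaks, background_ratio * nrow(peaks), halfwidth,
      derive_seed(seed, "background"))
  if (nrow(background_centers) == 0) stop_fmt("empty background")
  has_hit <- function(contig, center) {
    h <- scan_window(genome, contig, center, halfwidth, motifs)
    vapply(motifs$name, function(nm) any(h$name == nm), logical(1))
  }
  pk <- vapply(seq_len(nrow(peaks)),
               function(i) has_hit(peaks$contig[i], peaks$summit[i]),
               logical(nrow(motifs)))
  bg <- vapply(seq_len(nrow(background_centers)),
               function(i) has_hit(background_centers$contig[i],
                                   background_centers$center[i]),
               logical(nrow(motifs)))
  pk <- matrix(pk, nrow = nrow(motifs)); bg <- matrix(bg, nrow = nrow(motifs))
  np <- ncol(pk); nb <- ncol(bg)
  out <- lapply(seq_len(nrow(motifs)), function(i) {
    kp <- sum(pk[i, ]); kb <- sum(bg[i, ])
    fold <- ((kp + 0.5) / np) / ((kb + 0.5) / nb)
    p <- fisher.test(matrix(c(kp, np - kp, kb, nb - kb), nrow = 2))$p.value
    data.frame(name = motifs$name[i], pattern = motifs$pattern[i],
               n_peak = np, k_peak = kp, n_bg = nb, k_bg = kb,
               fold = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' E-box to core-AuxRE spacing distribution
#'
#' Uses the nearest-pair edge-to-edge gaps of class-"both" windows
#' (\code{min_gap} from [peak_motif_profiles()]); overlapping footprints
#' count as gap 0. Gaps are histogrammed in \code{binwidth}-bp bins and the
#' fraction of gaps at most 20 bp is reported; when a background profile
#' table is supplied the same summary is computed on its "both" windows.
#'
#' @param profiles Profile table for the peak windows.
#' @param background_profiles Optional profile table for background windows.
#' @param binwidth Histogram bin width in bp (default 5).
#' @param max_gap Upper edge of the last closed bin (default 100; larger
#'   gaps are pooled in an overflow bin).
#' @return list: histogram (bin_lo, bin_hi, count, fraction, bg_count,
#'   bg_fraction), frac_le_20, bg_frac_le_20, gaps, bg_gaps.
#' @export
spacing_distribution <- function(profiles, background_profiles = NULL,
                                 binwidth = 5, max_gap = 100) {
  gaps <- profiles$min_gap[profiles$cooccurrence_class == "both"]
  gaps <- gaps[!is.na(gaps)]
  bg_gaps <- if (!is.null(background_profiles)) {
    g <- background_profiles$min_gap[
      background_profiles$cooccurrence_class == "both"]
    g[!is.na(g)]
  } else integer(0)
  lo <- seq(0, max_gap - binwidth, by = binwidth)
  hist_of <- function(g) {
    cnt <- vapply(lo, function(b) sum(g >= b & g < b + binwidth), integer(1))
    c(cnt, sum(g >= max_gap))
  }
  cnt <- hist_of(gaps); bcnt <- hist_of(bg_gaps)
  hist <- data.frame(
    bin_lo = c(lo, max_gap), bin_hi = c(lo + binwidth - 1L, NA),
    count = cnt, fraction = cnt / max(1L, sum(cnt)),
    bg_count = bcnt, bg_fraction = bcnt / max(1L, sum(bcnt)))
  rownames(hist) <- NULL
  list(histogram = hist,
       frac_le_20 = if (length(gaps)) mean(gaps <= 20) else NA_real_,
       bg_frac_le_20 = if (length(bg_gaps)) mean(bg_gaps <= 20) else NA_real_,
       gaps = gaps, bg_gaps = bg_gaps)
}

#' Association of motif co-occurrence with hormone activation
#'
#' Compares the percentage of activated peaks between class "both" and class
#' "auxre_only" with a two-sided Fisher exact test. Stars follow the usual
#' figure-legend convention (* p < 0.05, ** p < 0.01). If either class is
#' empty the result is defined with p = 1 and a warning flag.
#'
#' @param profiles Profile table from [peak_motif_profiles()].
#' @param activated_peaks Character vector of peak_ids linked to at least
#'   one activated gene.
#' @return list: table (class, n, n_activated, percent), p, stars,
#'   empty_class_warning.
#' @export
activation_association <- function(profiles, activated_peaks) {
  act <- profiles$peak_id %in% activated_peaks
  tab <- lapply(c("both", "auxre_only"), function(k) {
    sel <- profiles$cooccurrence_class == k
    data.frame(class = k, n = sum(sel), n_activated = sum(act & sel),
               percent = if (sum(sel)) 100 * sum(act & sel) / sum(sel)
                         else NA_real_, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  warn <- any(tab$n == 0)
  p <- if (warn) 1 else fisher.test(matrix(
    c(tab$n_activated[1], tab$n[1] - tab$n_activated[1],
      tab$n_activated[2], tab$n[2] - tab$n_activated[2]), nrow = 2))$p.value
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(table = tab, p = p, stars = stars, empty_class_warning = warn)
}

#' Peak-score summaries by co-occurrence class
#'
#' Median and quartiles of the caller peak score per class, plus a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test between classes "both" and
#' "auxre_only" (binding-affinity proxy comparison). The test is skipped
#' (p = NA) when either class holds fewer than 2 peaks.
#'
#' @param peaks Peak data.frame carrying scores.
#' @param profiles Profile table from [peak_motif_profiles()].
#' @return list: summary (class, n, q1, median, q3), p, U (rank-sum
#'   statistic of the "both" group, NA when untested).
#' @export
score_by_class <- function(peaks, profiles) {
  m <- merge(profiles[, c("peak_id", "cooccurrence_class")],
             peaks[, c("peak_id", "score")], by = "peak_id")
  classes <- c("both", "auxre_only", "ebox_only", "neither")
  summ <- lapply(classes, function(k) {
    s <- m$score[m$cooccurrence_class == k]
    data.frame(class = k, n = length(s),
               q1 = if (length(s)) unname(quantile(s, 0.25)) else NA_real_,
               median = if (length(s)) median(s) else NA_real_,
               q3 = if (length(s)) unname(quantile(s, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  a <- m$score[m$cooccurrence_class == "both"]
  b <- m$score[m$cooccurrence_class == "auxre_only"]
  if (length(a) >= 2 && length(b) >= 2) {
    wt <- wilcox.test(a, b, alternative = "two.sided", exact = NULL)
    list(summary = summ, p = wt$p.value, U = unname(wt$statistic))
  } else {
    list(summary = summ, p = NA_real_, U = NA_real_)
  }
}
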