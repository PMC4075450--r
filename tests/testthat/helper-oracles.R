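# Independent oracles: brute-force / enumeration implementations used to
# cross-check the package's fast paths. These deliberately share no code
# with R/.

# Exhaustive all-pairs interval-membership oracle for peak->gene linking.
oracle_link <- function(peaks, genes, promoter_bp = 3000,
                        downstream_bp = 1000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (peaks$contig[i] != g$contig) next
      hit <- if (g$strand == "+") {
        (s >= g$tss - promoter_bp && s < g$tss) ||
          (s >= g$start && s < g$end) ||
          (s > g$end - 1 && s <= g$end - 1 + downstream_bp)
      } else {
        (s > g$tss && s <= g$tss + promoter_bp) ||
          (s >= g$start && s < g$end) ||
          (s >= g$start - downstream_bp && s < g$start)
      }
      if (hit)
        out[[length(out) + 1L]] <- c(peaks$peak_id[i], g$gene_id)
    }
  }
  if (!length(out))
    return(data.frame(peak_id = character(), gene_id = character()))
  m <- do.call(rbind, out)
  d <- data.frame(peak_id = m[, 1], gene_id = m[, 2],
                  stringsAsFactors = FALSE)
  d[order(d$gene_id, d$peak_id), , drop = FALSE]
}

# Two-sided Fisher exact p by full enumeration over tables with the
# observed margins (probabilities from choose(), not dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- pr[ks == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments of
# the pooled (tie-free) sample; matches wilcox.test's doubled-tail rule.
oracle_mw_p <- function(x, y) {
  pool <- c(x, y); nx <- length(x)
  stopifnot(!anyDuplicated(pool))
  idx <- utils::combn(length(pool), nx)
  us <- apply(idx, 2, function(ii) {
    xx <- pool[ii]; yy <- pool[-ii]
    sum(outer(xx, yy, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Upper-tail hypergeometric P(X >= k) by explicit summation.
oracle_hyper_upper <- function(k, nA, nB, N) {
  js <- max(k, 0, nA + nB - N):min(nA, nB)
  sum(choose(nA, js) * choose(N - nA, nB - js) / choose(N, nB))
}

# Random linking instance on a small multi-contig genome.
random_link_instance <- function(n_peaks, n_genes, seed,
                                 contigs = c("c1", "c2"),
                                 contig_len = 100000L) {
  set.seed(seed)
  starts <- sort(sample.int(contig_len - 3000L, n_genes))
  genes <- gene_models(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    contig = sample(contigs, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = starts,
    end = starts + sample(500:2500, n_genes, replace = TRUE))
  summit <- sample.int(contig_len, n_peaks)
  peaks <- data.frame(
    peak_id = sprintf("p%04d", seq_len(n_peaks)),
    factor = "TF",
    contig = sample(contigs, n_peaks, replace = TRUE),
    start = pmax(0L, summit - 100L), end = summit + 100L,
    summit = summit, score = runif(n_peaks, 1, 10),
    stringsAsFactors = FALSE)
  list(peaks = peaks, genes = genes)
}

# Small deterministic annotation used across tests.
toy_genes <- function() {
  gene_models(gene_id = c("gA", "gB", "gC"),
              contig = c("chr1", "chr1", "chr2"),
              strand = c("+", "-", "+"),
              start = c(10000L, 30000L, 5000L),
              end = c(12000L, 33000L, 6000L))
}

toy_peak <- function(peak_id, contig, summit, factor = "TF", score = 5,
                     width = 200L) {
  data.frame(peak_id = peak_id, factor = factor, contig = contig,
             start = summit - width %/% 2L, end = summit + width %/% 2L,
             summit = summit, score = score, stringsAsFactors = FALSE)
}

# In-memory genome from named character sequences.
make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# Fast synthetic bundle for tests that do not need the full default size.
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, genome_length = 6e5, n_genes = 60, ...)
}
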