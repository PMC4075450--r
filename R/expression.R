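# Threshold-rule differential expression and cross-pathway dependence
# statistics. The DE rule is the simple printed definition: a gene is
# differentially expressed when |fold change| >= fc_threshold and the raw
# p-value of a two-sided Welch t-test on log2-CPM(+1) replicate values is
# below alpha (no multiple-testing adjustment).

# design -> condition labels per library; accepts an explicit `condition`
# column or builds one as <genotype>_<treatment>.
design_conditions <- function(design) {
  if (!is.null(design$condition)) return(as.character(design$condition))
  if (is.null(design$genotype) || is.null(design$treatment))
    stop_fmt("design needs either a 'condition' column or 'genotype' and 'treatment'")
  paste(design$genotype, design$treatment, sep = "_")
}

#' Call differential expression under the fold-change + p-value rule
#'
#' Counts are library-size normalised to a counts-per-million-like scale;
#' the reported log2 fold change is
#' \code{log2((mean norm_A + 1) / (mean norm_B + 1))} and the p-value comes
#' from a two-sided Welch t-test on per-replicate log2(norm + 1) values.
#' Flags: "up" iff log2fc >= log2(fc_threshold) and p < alpha; "down"
#' symmetric; otherwise "ns". Genes with zero counts in every library are
#' dropped.
#'
#' Normalisation: the default "median_ratio" uses median-of-ratios size
#' factors (each library's median count ratio to the per-gene geometric
#' mean, over genes detected everywhere), which keeps null genes centred at
#' log2fc = 0 even when responding genes dominate library totals in one
#' direction. "cpm" divides by raw library totals instead; it is the
#' textbook counts-per-million and is only unbiased when up- and
#' down-regulation balance in linear scale.
#'
#' @param counts Nonnegative integer matrix, genes x libraries, with
#'   rownames (gene ids) and colnames (library names).
#' @param design data.frame with a \code{library} column plus either
#'   \code{condition} or \code{genotype}+\code{treatment}.
#' @param contrast "A:B" string or length-2 character vector (numerator
#'   condition A vs denominator B).
#' @param fc_threshold Linear fold-change cutoff (default 1.5).
#' @param alpha Raw p-value cutoff (default 0.01).
#' @param normalization "median_ratio" (default) or "cpm".
#' @return data.frame (a contrast table): gene_id, log2fc, p, de_flag.
#' @export
call_differential <- function(counts, design, contrast, fc_threshold = 1.5,
                              alpha = 0.01,
                              normalization = c("median_ratio", "cpm")) {
  normalization <- match.arg(normalization)
  if (is.character(contrast) && length(contrast) == 1)
    contrast <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(contrast) != 2) stop_fmt("contrast must name two conditions")
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_fmt("counts must be nonnegative integers")
  cond <- design_conditions(design)
  libA <- design$library[cond == contrast[1]]
  libB <- design$library[cond == contrast[2]]
  if (length(libA) < 2 || length(libB) < 2)
    stop_fmt("need >= 2 replicates per condition (have %d and %d)",
             length(libA), length(libB))
  if (!all(c(libA, libB) %in% colnames(counts)))
    stop_fmt("design libraries missing from the count matrix")
  tot <- colSums(counts)
  if (any(tot[c(libA, libB)] == 0)) stop_fmt("library with zero total counts")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  libs <- c(libA, libB)
  if (normalization == "median_ratio") {
    sub <- counts[, libs, drop = FALSE]
    pos <- rowSums(sub == 0) == 0
    if (sum(pos) >= 10) {
      geo <- exp(rowMeans(log(sub[pos, , drop = FALSE])))
      sf <- apply(sub[pos, , drop = FALSE], 2,
                  function(cl) median(cl / geo))
      eff <- setNames(rep(NA_real_, ncol(counts)), colnames(counts))
      eff[libs] <- sf * mean(tot[libs] / sf) / 1e6
    } else {
      eff <- tot / 1e6   # too few fully-detected genes: fall back to totals
    }
  } else {
    eff <- tot / 1e6
  }
  cpm <- sweep(counts, 2, eff, "/")
  la <- log2(cpm[, libA, drop = FALSE] + 1)
  lb <- log2(cpm[, libB, drop = FALSE] + 1)
  mA <- rowMeans(cpm[, libA, drop = FALSE])
  mB <- rowMeans(cpm[, libB, drop = FALSE])
  log2fc <- log2((mA + 1) / (mB + 1))
  p <- welch_p(la, lb)
  thr <- log2(fc_threshold)
  flag <- ifelse(log2fc >= thr & p < alpha, "up",
                 ifelse(log2fc <= -thr & p < alpha, "down", "ns"))
  out <- data.frame(gene_id = rownames(counts), log2fc = log2fc, p = p,
                    de_flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Row-wise two-sided Welch t-test p-values for two replicate matrices.
welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  # zero variance in both groups: replication carries no information, so no
  # call is made (guards low-count ties like (0,0,0) vs (1,1,1))
  p[se2 == 0] <- 1
  p
}

#' Pearson correlation of log2 fold changes between two contrasts
#'
#' @param tableA,tableB Contrast tables from [call_differential()].
#' @param genes Optional explicit gene subset (overrides \code{subset}).
#' @param subset "de_both" (default; genes DE in both contrasts) or "all"
#'   (all shared genes with finite log2fc).
#' @return list: r (Pearson correlation), n (genes used).
#' @export
fc_correlation <- function(tableA, tableB, genes = NULL,
                           subset = c("de_both", "all")) {
  subset <- match.arg(subset)
  m <- merge(tableA, tableB, by = "gene_id", suffixes = c(".a", ".b"))
  m <- m[is.finite(m$log2fc.a) & is.finite(m$log2fc.b), , drop = FALSE]
  if (!is.null(genes)) m <- m[m$gene_id %in% genes, , drop = FALSE]
  else if (subset == "de_both")
    m <- m[m$de_flag.a != "ns" & m$de_flag.b != "ns", , drop = FALSE]
  if (nrow(m) < 3) stop_fmt("need >= 3 shared genes (have %d)", nrow(m))
  if (sd(m$log2fc.a) == 0 || sd(m$log2fc.b) == 0)
    stop_fmt("zero variance in a log2 fold-change vector")
  list(r = cor(m$log2fc.a, m$log2fc.b), n = nrow(m))
}

#' Sign-pattern co-regulation across contrasts
#'
#' For each gene in \code{gene_set}, the pattern is the tuple of DE flags
#' across the contrasts (e.g. "up/up/down"); genes that are "ns" in any
#' contrast form their own class "any_ns". With three or more contrasts the
#' concordant-opposing fraction is also reported: among genes DE in every
#' contrast, the fraction whose first two flags agree while the third
#' opposes them.
#'
#' @param tables Named list (>= 2) of contrast tables.
#' @param gene_set Genes to classify (default: genes present in all tables).
#' @return list: patterns (pattern, count, fraction; fractions sum to 1),
#'   concordant_opposing_fraction (among fully-DE genes; NA if < 3 tables
#'   or no fully-DE genes), n_full_de, per_gene (gene_id, pattern).
#' @export
coregulation_pattern <- function(tables, gene_set = NULL) {
  stopifnot(length(tables) >= 2)
  ids <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  if (is.null(gene_set)) gene_set <- ids
  miss <- setdiff(gene_set, ids)
  if (length(miss))
    stop_fmt("gene(s) missing from some contrast table: %s",
             paste(head(miss, 5), collapse = ", "))
  flags <- vapply(tables, function(t)
    t$de_flag[match(gene_set, t$gene_id)], character(length(gene_set)))
  flags <- matrix(flags, nrow = length(gene_set))
  any_ns <- apply(flags == "ns", 1, any)
  pattern <- ifelse(any_ns, "any_ns",
                    apply(flags, 1, paste, collapse = "/"))
  tab <- table(pattern)
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         fraction = as.integer(tab) / length(gene_set),
                         stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$count, patterns$pattern), ,
                       drop = FALSE]
  rownames(patterns) <- NULL
  co_frac <- NA_real_; n_full <- sum(!any_ns)
  if (ncol(flags) >= 3 && n_full > 0) {
    f <- flags[!any_ns, , drop = FALSE]
    co <- f[, 1] == f[, 2] & f[, 3] != f[, 1]
    co_frac <- mean(co)
  }
  list(patterns = patterns, concordant_opposing_fraction = co_frac,
       n_full_de = n_full,
       per_gene = data.frame(gene_id = gene_set, pattern = pattern,
                             stringsAsFactors = FALSE))
}

#' Retention of a transcriptional response in a mutant genotype
#'
#' Counts genes responding in the given direction in the wild-type contrast
#' and the subset still responding in that direction in the mutant contrast
#' (same treatment-vs-mock definition in both genotypes).
#'
#' @param table_wt,table_mut Contrast tables (treatment vs mock) for the
#'   two genotypes.
#' @param direction "up" or "down".
#' @return list: n_wt, n_retained, percent (one decimal; NA with
#'   \code{undefined = TRUE} when n_wt = 0).
#' @export
response_retention <- function(table_wt, table_mut, direction = c("up", "down")) {
  direction <- match.arg(direction)
  wt_genes <- table_wt$gene_id[table_wt$de_flag == direction]
  mut_genes <- table_mut$gene_id[table_mut$de_flag == direction]
  n_wt <- length(wt_genes)
  n_ret <- length(intersect(wt_genes, mut_genes))
  if (n_wt == 0)
    return(list(n_wt = 0L, n_retained = 0L, percent = NA_real_,
                undefined = TRUE))
  list(n_wt = n_wt, n_retained = n_ret,
       percent = round(100 * n_ret / n_wt, 1), undefined = FALSE)
}

#' RT-qPCR relative expression level
#'
#' Target quantity normalised to an internal reference (e.g. PP2A) and
#' expressed relative to a baseline sample (e.g. wild type):
#' \code{(quant_target/quant_ref) / (baseline_target/baseline_ref)}.
#'
#' @param quant_target,quant_ref Target and reference quantities in the
#'   sample of interest.
#' @param baseline_target,baseline_ref Same in the baseline sample.
#' @return Relative expression level (vectorised).
#' @export
rtqpcr_relative_expression <- function(quant_target, quant_ref,
                                       baseline_target, baseline_ref) {
  check_positive(quant_target, quant_ref, baseline_target, baseline_ref,
                 .what = "qPCR")
  (quant_target / quant_ref) / (baseline_target / baseline_ref)
}

#' Treated-to-mock expression ratio
#' @param level_treated,level_mock Relative expression levels.
#' @return Ratio (vectorised).
#' @export
ratio_treated_mock <- function(level_treated, level_mock) {
  check_positive(level_treated, level_mock, .what = "expression level")
  level_treated / level_mock
}
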