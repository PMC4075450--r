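# Deterministic synthetic-data generator: toy genome + annotation,
# Venn-structured multi-factor peak sets with planted cis-elements at
# configurable spacing, and negative-binomial expression bundles with
# planted effect retention, fold-change correlation and sign-pattern mix.
# Every planted quantity is emitted as ground truth so downstream modules
# can be tested by parameter recovery.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale world: a 2-Mb single-contig genome at
#' Arabidopsis-like GC content (0.36) carrying 200 well-separated genes;
#' three factors (ARF6/BZR1/PIF4-like) whose target sets follow a 3-set
#' Venn with strong co-binding (region fractions chosen so the first
#' factor's pairwise/triple overlap percentages are about 51\%, 71\% and
#' 42\%); one peak per (factor, target gene) with the summit in the 1 kb
#' upstream of the TSS and co-bound summits within 200 bp; ARF6 windows
#' carry planted AuxRE/E-box content with an E-box-to-AuxRE gap drawn
#' uniformly from 0..20 bp; expression follows a negative-binomial
#' replicate model with a planted BL response, mutant retention of 17\% of
#' responses, a -0.6 fold-change correlation with the mutant-genotype
#' contrast, and a 0.7 concordant-opposing sign-pattern mix in the
#' three-regulator panel.
#'
#' @param seed Integer seed; same seed + config gives byte-identical output.
#' @param genome_length Genome size in bp.
#' @param n_genes Number of genes.
#' @param gc_content GC fraction of the background sequence.
#' @param promoter_window Promoter size in bp used for flank clearance.
#' @param venn_fractions Named fractions over the 7 Venn regions of the
#'   3 factor target sets (A, B, C, AB, AC, BC, ABC) plus "none"; must sum
#'   to 1.
#' @param factors Names of the three factors (A, B, C slots).
#' @param peak_width Length-2 range of peak widths in bp.
#' @param motif_class_probs Named probabilities over \{both, auxre_only,
#'   ebox_only, neither\} for the planted class of each first-factor peak.
#' @param spacing_law list(kind = "uniform", lo, hi) or
#'   list(kind = "geometric", p) for the planted E-box to AuxRE gap.
#' @param summit_jitter Max +/- jitter of each factor summit around the
#'   shared gene anchor (co-bound summits end up within 2x this).
#' @param gene_length Length-2 range of gene body lengths in bp.
#' @param n_replicates Replicates per condition.
#' @param lfc_mean,lfc_sd Mean and sd of planted |log2 effect| sizes.
#' @param responsive_fraction Fraction of genes with a BL response in WT.
#' @param retention_fraction Fraction of WT-responsive genes whose response
#'   is retained in the mutant.
#' @param target_corr Planted Pearson correlation between the true WT
#'   BL-response and mutant-genotype log2-effect vectors.
#' @param pattern_fraction Fraction of co-regulated genes in the regulator
#'   panel with the concordant-opposing sign pattern (+,+,-).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean
#'   parameters for expression counts.
#' @return list of class "synthetic_config".
#' @export
synthetic_config <- function(
    seed = 1L,
    genome_length = 2e6,
    n_genes = 200L,
    gc_content = 0.36,
    promoter_window = 3000L,
    venn_fractions = c(A = 0.092, B = 0.050, C = 0.060, AB = 0.041,
                       AC = 0.133, BC = 0.060, ABC = 0.193, none = 0.371),
    factors = c(A = "ARF6", B = "BZR1", C = "PIF4"),
    peak_width = c(200L, 400L),
    motif_class_probs = c(both = 0.5, auxre_only = 0.4, ebox_only = 0.05,
                          neither = 0.05),
    spacing_law = list(kind = "uniform", lo = 0L, hi = 20L),
    summit_jitter = 100L,
    gene_length = c(800L, 1500L),
    n_replicates = 3L,
    lfc_mean = 2.5,
    lfc_sd = 0.5,
    responsive_fraction = 0.4,
    retention_fraction = 0.17,
    target_corr = -0.6,
    pattern_fraction = 0.7,
    nb_dispersion = 0.02,
    baseline_meanlog = log(300),
    baseline_sdlog = 1) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_genes = as.integer(n_genes), gc_content = gc_content,
              promoter_window = as.integer(promoter_window),
              venn_fractions = venn_fractions, factors = factors,
              peak_width = as.integer(peak_width),
              motif_class_probs = motif_class_probs,
              spacing_law = spacing_law,
              summit_jitter = as.integer(summit_jitter),
              gene_length = as.integer(gene_length),
              n_replicates = as.integer(n_replicates),
              lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              responsive_fraction = responsive_fraction,
              retention_fraction = retention_fraction,
              target_corr = target_corr,
              pattern_fraction = pattern_fraction,
              nb_dispersion = nb_dispersion,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  vf <- cfg$venn_fractions
  need <- c("A", "B", "C", "AB", "AC", "BC", "ABC", "none")
  if (!setequal(names(vf), need))
    stop_fmt("venn_fractions must name exactly: %s",
             paste(need, collapse = ", "))
  if (abs(sum(vf) - 1) > 1e-9)
    stop_fmt("venn_fractions must sum to 1 (got %.12f)", sum(vf))
  probs <- c(vf, cfg$motif_class_probs, cfg$gc_content,
             cfg$responsive_fraction, cfg$retention_fraction,
             cfg$pattern_fraction)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must lie in [0,1]")
  if (abs(sum(cfg$motif_class_probs) - 1) > 1e-9)
    stop_fmt("motif_class_probs must sum to 1")
  if (abs(cfg$target_corr) > 1)
    stop_fmt("|target_corr| must be <= 1 (got %g)", cfg$target_corr)
  if (!cfg$spacing_law$kind %in% c("uniform", "geometric"))
    stop_fmt("spacing_law kind must be 'uniform' or 'geometric'")
  if (cfg$n_genes * (mean(cfg$gene_length) + cfg$promoter_window) >=
      cfg$genome_length)
    stop_fmt("infeasible packing: n_genes x (mean gene length + promoter) >= genome_length")
  invisible(cfg)
}

#' Generate a toy genome and gene annotation
#'
#' Bases are i.i.d. at the configured GC content; genes are non-overlapping,
#' placed with at least promoter_window + 1000 bp of clear flank on both
#' sides, on random strands.
#'
#' @param config A [synthetic_config()].
#' @return list: genome (named DNAStringSet, one contig "chr1"), genes
#'   (gene-model data.frame).
#' @export
generate_genome <- function(config) {
  cfg <- validate_synthetic_config(config)
  with_seed(derive_seed(cfg$seed, "genome"), {
    gl <- as.integer(cfg$genome_length)
    pAT <- (1 - cfg$gc_content) / 2; pGC <- cfg$gc_content / 2
    seqchars <- sample(c("A", "C", "G", "T"), gl, replace = TRUE,
                       prob = c(pAT, pGC, pGC, pAT))
    genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
    names(genome) <- "chr1"
    lens <- sample(seq(cfg$gene_length[1], cfg$gene_length[2]), cfg$n_genes,
                   replace = TRUE)
    flank <- cfg$promoter_window + 1000L
    slots <- lens + 2L * flank
    slack <- gl - sum(slots)
    if (slack < cfg$n_genes + 1L)
      stop_fmt("infeasible packing: %d genes do not fit in %d bp",
               cfg$n_genes, gl)
    gap <- slack %/% (cfg$n_genes + 1L)
    starts <- cumsum(c(gap + flank, slots[-cfg$n_genes] + gap))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- gene_models(
      gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
      contig = "chr1", strand = strand,
      start = as.integer(starts), end = as.integer(starts + lens))
    list(genome = genome, genes = genes)
  })
}

# --- motif planting helpers -------------------------------------------------

# Patterns whose incidental occurrences are scrubbed from first-factor scan
# windows before planting (forward + reverse-complement footprints of the
# core AuxRE and both E-boxes; G-box is palindromic).
scrub_patterns <- function() c("TGTC", "GACA", "CACGTG", "CACATG", "CATGTG")

# Mutate window bases until no scrub pattern matches, never touching
# positions in `protect` (planted footprints). Returns the edited window.
scrub_window <- function(win, protect = integer(0)) {
  pats <- scrub_patterns()
  for (iter in 1:200) {
    hit <- NULL
    for (p in pats) {
      m <- gregexpr(p, win, fixed = TRUE)[[1]]
      if (m[1] != -1) {
        for (s in as.integer(m)) {
          pos <- s:(s + nchar(p) - 1L)
          free <- setdiff(pos, protect)
          if (length(free)) { hit <- free; break }
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(win)
    i <- hit[ceiling(length(hit) / 2)]
    old <- substr(win, i, i)
    repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(win, i, i) <- repl
  }
  stop_fmt("window scrubbing did not converge")
}

# Draw one planted E-box/AuxRE arrangement; returns the window string and
# the planted annotation.
plant_motifs_in_window <- function(win, class, spacing_law) {
  W <- nchar(win)
  # class "both" plants the bare core so the planted gap equals the
  # core-footprint edge gap the scanner measures; full AuxRE variants are
  # planted in auxre_only windows (enrichment signal for the named motifs)
  auxre <- if (class == "both") "TGTC" else
    sample(c("TGTC", "TGTCTC", "TGTCGG"), 1)
  ebox <- sample(c("CACGTG", "CACATG"), 1)
  gap <- NA_integer_
  if (class == "both") {
    gap <- if (spacing_law$kind == "uniform")
      sample(spacing_law$lo:spacing_law$hi, 1)
    else min(rgeom(1, spacing_law$p), W - nchar(auxre) - nchar(ebox) - 2L)
    first_auxre <- runif(1) < 0.5
    a <- if (first_auxre) auxre else ebox
    b <- if (first_auxre) ebox else auxre
    L <- nchar(a) + gap + nchar(b)
    o <- sample(0:(W - L), 1)
    substr(win, o + 1L, o + nchar(a)) <- a
    o2 <- o + nchar(a) + gap
    substr(win, o2 + 1L, o2 + nchar(b)) <- b
    protect <- c((o + 1L):(o + nchar(a)), (o2 + 1L):(o2 + nchar(b)))
  } else if (class == "auxre_only") {
    o <- sample(0:(W - nchar(auxre)), 1)
    substr(win, o + 1L, o + nchar(auxre)) <- auxre
    protect <- (o + 1L):(o + nchar(auxre))
    ebox <- NA_character_
  } else if (class == "ebox_only") {
    o <- sample(0:(W - nchar(ebox)), 1)
    substr(win, o + 1L, o + nchar(ebox)) <- ebox
    protect <- (o + 1L):(o + nchar(ebox))
    auxre <- NA_character_
  } else {
    protect <- integer(0)
    auxre <- NA_character_; ebox <- NA_character_
  }
  # planting can create spurious matches at junctions; scrub around the
  # protected footprints
  win <- scrub_window(win, protect)
  list(win = win, auxre = auxre, ebox = ebox, gap = gap)
}

#' Plant Venn-structured multi-factor peaks with cis-element content
#'
#' Assigns each gene to one region of the 3-set Venn (or none) per
#' \code{venn_fractions}; every (factor, target gene) pair gets one peak
#' whose summit falls in the 1 kb upstream of the TSS, with the summits of
#' co-bound genes jittered around a shared anchor (within
#' 2 x summit_jitter of each other). For the first factor, each scan
#' window (+/- 100 bp of the summit) is first cleared of incidental
#' AuxRE-core/E-box matches and then planted according to
#' \code{motif_class_probs}, with the E-box-to-AuxRE edge gap drawn from
#' \code{spacing_law}. Motifs overwrite sequence in place, so all
#' coordinates stay valid.
#'
#' @param config A [synthetic_config()].
#' @param genome,genes Output of [generate_genome()].
#' @return list: genome (modified), peaks (all factors, with scores and
#'   sub-threshold fdr values), truth_targets (gene_id, venn_region,
#'   is_A/is_B/is_C flags named by factor), truth_motifs (peak_id, class,
#'   gap, auxre_pattern, ebox_pattern).
#' @export
plant_peaks <- function(config, genome, genes) {
  cfg <- validate_synthetic_config(config)
  with_seed(derive_seed(cfg$seed, "peaks"), {
    n <- nrow(genes)
    region <- sample(names(cfg$venn_fractions), n, replace = TRUE,
                     prob = cfg$venn_fractions)
    isA <- grepl("A", region); isB <- grepl("B", region)
    isC <- grepl("C", region)
    truth_targets <- data.frame(gene_id = genes$gene_id,
                                venn_region = region,
                                stringsAsFactors = FALSE)
    truth_targets[[paste0("is_", cfg$factors[["A"]])]] <- isA
    truth_targets[[paste0("is_", cfg$factors[["B"]])]] <- isB
    truth_targets[[paste0("is_", cfg$factors[["C"]])]] <- isC
    # shared per-gene anchor summit in [TSS-1000, TSS) strand-aware, kept
    # >= jitter away from the window ends so jittered summits stay inside
    j <- cfg$summit_jitter
    d_anchor <- sample((1L + j):(1000L - j), n, replace = TRUE)
    anchor <- ifelse(genes$strand == "+", genes$tss - d_anchor,
                     genes$tss + d_anchor)
    seqstr <- as.character(genome[[1]])
    contig <- names(genome)[1]
    peaks <- list(); truth_motifs <- list()
    counters <- setNames(rep(0L, 3), cfg$factors)
    for (slot in c("A", "B", "C")) {
      fac <- cfg$factors[[slot]]
      bound <- which(switch(slot, A = isA, B = isB, C = isC))
      for (gi in bound) {
        counters[fac] <- counters[fac] + 1L
        pid <- sprintf("%s_p%04d", fac, counters[fac])
        summit <- anchor[gi] + sample(-j:j, 1)
        w <- sample(cfg$peak_width[1]:cfg$peak_width[2], 1)
        off <- sample(0:(w - 1L), 1)
        start <- max(0L, summit - off)
        end <- start + w
        score <- round(rgamma(1, shape = 2, scale = 2) + 0.5, 3)
        fdr <- round(runif(1, 0, 0.009), 5)
        peaks[[length(peaks) + 1L]] <- data.frame(
          peak_id = pid, factor = fac, contig = contig,
          start = start, end = end, summit = as.integer(summit),
          score = score, fdr = fdr, stringsAsFactors = FALSE)
        if (slot == "A") {
          cls <- sample(names(cfg$motif_class_probs), 1,
                        prob = cfg$motif_class_probs)
          lo <- summit - 100L; hi <- summit + 100L   # 201-bp scan window
          win <- substr(seqstr, lo + 1L, hi + 1L)
          win <- scrub_window(win)
          pl <- plant_motifs_in_window(win, cls, cfg$spacing_law)
          substr(seqstr, lo + 1L, hi + 1L) <- pl$win
          truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
            peak_id = pid, gene_id = genes$gene_id[gi], class = cls,
            gap = pl$gap, auxre_pattern = pl$auxre, ebox_pattern = pl$ebox,
            stringsAsFactors = FALSE)
        }
      }
    }
    genome2 <- Biostrings::DNAStringSet(seqstr)
    names(genome2) <- contig
    peaks <- if (length(peaks)) do.call(rbind, peaks) else
      data.frame(peak_id = character(), factor = character(),
                 contig = character(), start = integer(), end = integer(),
                 summit = integer(), score = numeric(), fdr = numeric())
    truth_motifs <- if (length(truth_motifs)) do.call(rbind, truth_motifs)
      else data.frame(peak_id = character(), gene_id = character(),
                      class = character(), gap = integer(),
                      auxre_pattern = character(), ebox_pattern = character())
    rownames(peaks) <- NULL; rownames(truth_motifs) <- NULL
    list(genome = genome2, peaks = peaks, truth_targets = truth_targets,
         truth_motifs = truth_motifs)
  })
}

# Exact-correlation construction: returns y with sample cor(x, y) == rho
# and sd(y) == sd(x) (Gram-Schmidt on a fresh Gaussian draw).
correlated_vector <- function(x, rho) {
  if (sd(x) == 0) return(numeric(length(x)))  # correlation undefined: null
  if (abs(rho) == 1) return(rho * x)
  z <- rnorm(length(x))
  xs <- (x - mean(x)) / sd(x)
  zc <- z - mean(z)
  zr <- zc - xs * sum(zc * xs) / sum(xs^2)   # orthogonal to xs exactly
  zr <- zr / sd(zr)
  (rho * xs + sqrt(1 - rho^2) * zr) * sd(x)
}

#' Simulate the hormone-response expression bundle
#'
#' Negative-binomial replicate counts for the four conditions WT_mock,
#' WT_BL, mut_mock and mut_BL. A \code{responsive_fraction} of genes gets a
#' signed planted log2 BL effect ~ N(lfc_mean, lfc_sd) in the wild type; a
#' \code{retention_fraction} of those keep the effect in the mutant, the
#' rest are nulled. The mutant-genotype contrast (mut_mock vs WT_mock) gets
#' a true log2-effect vector constructed so its sample Pearson correlation
#' with the WT BL-effect vector equals \code{target_corr} exactly.
#'
#' @param config A [synthetic_config()].
#' @param truth_targets Optional truth table from [plant_peaks()] supplying
#'   gene ids; otherwise \code{n_genes} ids are synthesised.
#' @param n_genes Override for the number of genes (e.g. 2000 for
#'   correlation recovery at tight tolerance).
#' @return list: counts (genes x 4*n_replicates integer matrix), design
#'   (library, genotype, treatment, replicate), truth (gene_id, responsive,
#'   retained, effect_wt, effect_mut, effect_geno).
#' @export
simulate_expression <- function(config, truth_targets = NULL, n_genes = NULL) {
  cfg <- validate_synthetic_config(config)
  with_seed(derive_seed(cfg$seed, "expression"), {
    ids <- if (!is.null(truth_targets)) truth_targets$gene_id else
      sprintf("g%04d", seq_len(if (is.null(n_genes)) cfg$n_genes
                               else n_genes))
    n <- length(ids)
    responsive <- runif(n) < cfg$responsive_fraction
    sign <- sample(c(-1, 1), n, replace = TRUE)
    effect_wt <- ifelse(responsive,
                        sign * rnorm(n, cfg$lfc_mean, cfg$lfc_sd), 0)
    retained <- responsive & (runif(n) < cfg$retention_fraction)
    effect_mut <- ifelse(retained, effect_wt, 0)
    effect_geno <- correlated_vector(effect_wt, cfg$target_corr)
    mu0 <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    cond_mu <- cbind(WT_mock = mu0,
                     WT_BL = mu0 * 2^effect_wt,
                     mut_mock = mu0 * 2^effect_geno,
                     mut_BL = mu0 * 2^(effect_geno + effect_mut))
    reps <- cfg$n_replicates
    libs <- character(0); counts <- NULL
    design <- NULL
    for (cc in colnames(cond_mu)) {
      for (r in seq_len(reps)) {
        sfac <- runif(1, 0.8, 1.2)
        y <- rnbinom(n, mu = sfac * cond_mu[, cc],
                     size = 1 / cfg$nb_dispersion)
        counts <- cbind(counts, y)
        lib <- sprintf("%s_r%d", cc, r)
        libs <- c(libs, lib)
        gt <- sub("_.*$", "", cc); tr <- sub("^.*_", "", cc)
        design <- rbind(design,
                        data.frame(library = lib, genotype = gt,
                                   treatment = tr, replicate = r,
                                   stringsAsFactors = FALSE))
      }
    }
    colnames(counts) <- libs; rownames(counts) <- ids
    rownames(design) <- NULL
    list(counts = counts, design = design,
         truth = data.frame(gene_id = ids, responsive = responsive,
                            retained = retained, effect_wt = effect_wt,
                            effect_mut = effect_mut,
                            effect_geno = effect_geno,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate the three-regulator co-regulation panel
#'
#' Three independent 2-condition contrasts (BZR1-, PIF- and IAA3-like
#' perturbations, each ctrl vs trt with \code{n_replicates} replicates). A
#' \code{responsive_fraction} of genes is co-regulated: nonzero planted
#' effects in all three contrasts, with the concordant-opposing sign
#' pattern (s, s, -s) in a \code{pattern_fraction} of them and (s, s, s)
#' otherwise. Remaining genes respond independently per contrast with
#' probability 0.1.
#'
#' @param config A [synthetic_config()].
#' @param n_genes Override for the number of genes.
#' @return list: counts, design (library, condition, replicate), truth
#'   (gene_id, coregulated, concordant_opposing, effect_1..3).
#' @export
simulate_regulator_panel <- function(config, n_genes = NULL) {
  cfg <- validate_synthetic_config(config)
  with_seed(derive_seed(cfg$seed, "panel"), {
    n <- if (is.null(n_genes)) cfg$n_genes else n_genes
    ids <- sprintf("g%04d", seq_len(n))
    coreg <- runif(n) < cfg$responsive_fraction
    opp <- coreg & (runif(n) < cfg$pattern_fraction)
    s <- sample(c(-1, 1), n, replace = TRUE)
    mag <- function() abs(rnorm(n, cfg$lfc_mean, cfg$lfc_sd))
    solo <- function() ifelse(runif(n) < 0.1,
                              sample(c(-1, 1), n, replace = TRUE) * mag(), 0)
    e1 <- ifelse(coreg, s * mag(), solo())
    e2 <- ifelse(coreg, s * mag(), solo())
    e3 <- ifelse(coreg, ifelse(opp, -s, s) * mag(), solo())
    eff <- cbind(e1, e2, e3)
    mu0 <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    counts <- NULL; libs <- character(0); design <- NULL
    for (k in 1:3) {
      for (cond in c("ctrl", "trt")) {
        mu <- if (cond == "ctrl") mu0 else mu0 * 2^eff[, k]
        for (r in seq_len(cfg$n_replicates)) {
          sfac <- runif(1, 0.8, 1.2)
          counts <- cbind(counts, rnbinom(n, mu = sfac * mu,
                                          size = 1 / cfg$nb_dispersion))
          lib <- sprintf("f%d_%s_r%d", k, cond, r)
          libs <- c(libs, lib)
          design <- rbind(design, data.frame(
            library = lib, condition = sprintf("f%d_%s", k, cond),
            replicate = r, stringsAsFactors = FALSE))
        }
      }
    }
    colnames(counts) <- libs; rownames(counts) <- ids
    rownames(design) <- NULL
    list(counts = counts, design = design,
         truth = data.frame(gene_id = ids, coregulated = coreg,
                            concordant_opposing = opp,
                            effect_1 = e1, effect_2 = e2, effect_3 = e3,
                            stringsAsFactors = FALSE))
  })
}

#' Generate and optionally write the full synthetic bundle
#'
#' Runs [generate_genome()], [plant_peaks()], [simulate_expression()] and
#' [simulate_regulator_panel()] under one config and, when \code{dir} is
#' given, writes genome.fa, genes.gff3, peaks_<factor>.tsv, counts.tsv,
#' design.tsv, panel_counts.tsv, panel_design.tsv and truth/*.tsv.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @return list with all in-memory pieces (genome, genes, peaks,
#'   truth_targets, truth_motifs, expression, panel) and, when written,
#'   the path list in \code{$paths}.
#' @export
simulate_bundle <- function(config, dir = NULL) {
  cfg <- validate_synthetic_config(config)
  gg <- generate_genome(cfg)
  pp <- plant_peaks(cfg, gg$genome, gg$genes)
  ex <- simulate_expression(cfg, pp$truth_targets)
  pan <- simulate_regulator_panel(cfg)
  out <- list(config = cfg, genome = pp$genome, genes = gg$genes,
              peaks = pp$peaks, truth_targets = pp$truth_targets,
              truth_motifs = pp$truth_motifs, expression = ex, panel = pan)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  genes = file.path(dir, "genes.gff3"))
    write_genome(pp$genome, paths$genome)
    write_gene_models(gg$genes, paths$genes)
    for (fac in unique(pp$peaks$factor)) {
      p <- file.path(dir, sprintf("peaks_%s.tsv", fac))
      write_peaks(pp$peaks[pp$peaks$factor == fac, , drop = FALSE], p)
      paths[[paste0("peaks_", fac)]] <- p
    }
    paths$counts <- file.path(dir, "counts.tsv")
    write_tsv(data.frame(gene_id = rownames(ex$counts), ex$counts,
                         check.names = FALSE), paths$counts)
    paths$design <- file.path(dir, "design.tsv")
    write_tsv(ex$design, paths$design)
    paths$panel_counts <- file.path(dir, "panel_counts.tsv")
    write_tsv(data.frame(gene_id = rownames(pan$counts), pan$counts,
                         check.names = FALSE), paths$panel_counts)
    paths$panel_design <- file.path(dir, "panel_design.tsv")
    write_tsv(pan$design, paths$panel_design)
    write_tsv(pp$truth_targets, file.path(dir, "truth", "targets.tsv"))
    write_tsv(pp$truth_motifs, file.path(dir, "truth", "motifs.tsv"))
    write_tsv(ex$truth, file.path(dir, "truth", "expression.tsv"))
    write_tsv(pan$truth, file.path(dir, "truth", "panel.tsv"))
    out$paths <- paths
  }
  out
}
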