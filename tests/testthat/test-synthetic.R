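# Synthetic-data generator: determinism, config contracts, parameter
# recovery against planted ground truth.

test_that("config validation catches inconsistent worlds", {
  expect_error(synthetic_config(venn_fractions = c(A = 0.5, B = 0.5)),
               "venn_fractions")
  vf <- c(A = 0.2, B = 0.2, C = 0.2, AB = 0.1, AC = 0.1, BC = 0.1,
          ABC = 0.05, none = 0.06)
  expect_error(synthetic_config(venn_fractions = vf), "sum to 1")
  expect_error(synthetic_config(target_corr = -1.5), "target_corr")
  expect_error(synthetic_config(genome_length = 5e5), "packing")
  expect_error(synthetic_config(
    motif_class_probs = c(both = 0.9, auxre_only = 0.2, ebox_only = 0,
                          neither = 0)), "motif_class_probs")
})

test_that("generate_genome honors config and is deterministic", {
  cfg <- small_config(seed = 4)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_equal(nrow(g1$genes), 60)
  # byte-identical FASTA on disk
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g1$genome, f1); write_genome(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # genes have the promised clear flanks
  gs <- g1$genes[order(g1$genes$start), ]
  expect_true(all(diff(gs$start) > gs$end[-nrow(gs)] - gs$start[-nrow(gs)]))
  gaps <- gs$start[-1] - gs$end[-nrow(gs)]
  expect_true(all(gaps >= 2 * (cfg$promoter_window + 1000)))
})

test_that("GC content is recovered within the binomial bound", {
  g <- generate_genome(synthetic_config(seed = 2, genome_length = 5e5,
                                        n_genes = 40))
  freq <- Biostrings::alphabetFrequency(g$genome[[1]])
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_lt(abs(gc - 0.36), 0.01)
})

test_that("degenerate venn: triple-only region makes all target sets equal", {
  cfg <- small_config(seed = 9, venn_fractions = c(
    A = 0, B = 0, C = 0, AB = 0, AC = 0, BC = 0, ABC = 0.5, none = 0.5))
  gg <- generate_genome(cfg)
  pp <- plant_peaks(cfg, gg$genome, gg$genes)
  tt <- pp$truth_targets
  expect_identical(tt$is_ARF6, tt$is_BZR1)
  expect_identical(tt$is_ARF6, tt$is_PIF4)
  links <- assign_peaks_to_genes(pp$peaks, gg$genes)
  tg <- target_genes(links)
  expect_setequal(tg$ARF6, tg$BZR1)
  expect_setequal(tg$ARF6, tg$PIF4)
})

test_that("degenerate motif class: both:1 puts core AuxRE and E-box in every window", {
  cfg <- small_config(seed = 12, motif_class_probs = c(
    both = 1, auxre_only = 0, ebox_only = 0, neither = 0))
  gg <- generate_genome(cfg)
  pp <- plant_peaks(cfg, gg$genome, gg$genes)
  pa <- pp$peaks[pp$peaks$factor == "ARF6", ]
  pr <- peak_motif_profiles(pp$genome, pa)
  expect_true(all(pr$cooccurrence_class == "both"))
})

test_that("planted class probabilities and gaps are recovered exactly", {
  cfg <- small_config(seed = 31)
  gg <- generate_genome(cfg)
  pp <- plant_peaks(cfg, gg$genome, gg$genes)
  pa <- pp$peaks[pp$peaks$factor == "ARF6", ]
  pr <- peak_motif_profiles(pp$genome, pa)
  m <- merge(pr, pp$truth_motifs, by = "peak_id")
  # scrub-then-plant makes the class label exact, not just approximate
  expect_equal(m$cooccurrence_class, m$class)
  both <- m[m$class == "both", ]
  expect_equal(both$min_gap, both$gap)
  # class fractions recover the configured probabilities within 3 SE
  cc <- classify_cooccurrence(pr)
  n <- sum(cc$count)
  for (k in cc$class) {
    p0 <- cfg$motif_class_probs[[k]]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(cc$fraction[cc$class == k] - p0), 3 * se + 1e-9)
  }
})

test_that("co-bound summits are within 200 bp and summits sit upstream", {
  b <- simulate_bundle(small_config(seed = 6))
  co <- b$truth_targets$gene_id[b$truth_targets$is_ARF6 &
                                  b$truth_targets$is_BZR1]
  links <- assign_peaks_to_genes(b$peaks, b$genes)
  for (g in co) {
    sA <- b$peaks$summit[b$peaks$factor == "ARF6" &
      b$peaks$peak_id %in% links$peak_id[links$gene_id == g]]
    sB <- b$peaks$summit[b$peaks$factor == "BZR1" &
      b$peaks$peak_id %in% links$peak_id[links$gene_id == g]]
    expect_lte(min(abs(outer(sA, sB, "-"))), 200)
  }
  # every linked ARF6 summit is upstream within 1 kb + jitter of its TSS
  la <- links[links$factor == "ARF6", ]
  expect_true(all(la$signed_distance < 0 | la$region_class == "d0"))
  expect_true(all(abs(la$signed_distance) <= 1100))
})

test_that("expression bundle: degenerate retention and exact correlation", {
  cfg <- small_config(seed = 3, retention_fraction = 1)
  ex <- simulate_expression(cfg, n_genes = 400)
  expect_identical(ex$truth$retained, ex$truth$responsive)
  de_wt <- call_differential(ex$counts, ex$design, "WT_BL:WT_mock")
  de_mut <- call_differential(ex$counts, ex$design, "mut_BL:mut_mock")
  n_wt <- sum(de_wt$de_flag != "ns"); n_mut <- sum(de_mut$de_flag != "ns")
  expect_lt(abs(n_wt - n_mut) / n_wt, 0.15)   # ~equal responsive counts
  # exact anticorrelation construction
  cfg2 <- small_config(seed = 3, target_corr = -1)
  ex2 <- simulate_expression(cfg2, n_genes = 200)
  expect_equal(cor(ex2$truth$effect_wt, ex2$truth$effect_geno), -1)
  # default -0.6 is planted exactly on the true effect vectors
  ex3 <- simulate_expression(small_config(seed = 5), n_genes = 2000)
  expect_equal(cor(ex3$truth$effect_wt, ex3$truth$effect_geno), -0.6,
               tolerance = 1e-9)
})

test_that("regulator panel plants the concordant-opposing mix", {
  pan <- simulate_regulator_panel(small_config(seed = 13), n_genes = 1500)
  tr <- pan$truth
  co <- tr[tr$coregulated, ]
  expect_true(all(sign(co$effect_1) == sign(co$effect_2)))
  expect_identical(sign(co$effect_3) != sign(co$effect_1),
                   co$concordant_opposing)
  p0 <- 0.7; n <- nrow(co)
  expect_lt(abs(mean(co$concordant_opposing) - p0),
            3 * sqrt(p0 * (1 - p0) / n))
})

test_that("simulate_bundle writes a complete, re-readable, stable bundle", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 8)
  simulate_bundle(cfg, dir = d1)
  simulate_bundle(cfg, dir = d2)
  files <- c("genome.fa", "genes.gff3", "peaks_ARF6.tsv", "counts.tsv",
             "design.tsv", "panel_counts.tsv", "panel_design.tsv",
             "truth/targets.tsv", "truth/motifs.tsv",
             "truth/expression.tsv", "truth/panel.tsv")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # written bundle re-reads into the in-memory objects
  g <- read_genome(file.path(d1, "genome.fa"))
  genes <- read_gene_models(file.path(d1, "genes.gff3"))
  peaks <- read_peaks(file.path(d1, "peaks_ARF6.tsv"), factor = "ARF6")
  b <- simulate_bundle(cfg)
  expect_identical(as.character(g), as.character(b$genome))
  expect_equal(nrow(genes), nrow(b$genes))
  pa <- b$peaks[b$peaks$factor == "ARF6", ]
  expect_equal(peaks$summit, pa$summit)
  expect_equal(peaks$score, pa$score)
})
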