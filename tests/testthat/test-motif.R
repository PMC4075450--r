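# Motif scanning and cis-element grammar statistics.

test_that("scan_window: palindromes, strands, substring containment", {
  g <- make_genome(chr1 = "AAACACGTGAAA")
  # palindrome counted once
  h <- scan_window(g, "chr1", 6, halfwidth = 6)
  gbox <- h[h$name == "G-box", ]
  expect_equal(nrow(gbox), 1)
  expect_equal(gbox$offset, 3)
  # reverse-complement hit reported on - strand at forward offsets
  g2 <- make_genome(chr1 = "CATGTGAAAAAA")
  h2 <- scan_window(g2, "chr1", 3, halfwidth = 3)
  hud <- h2[h2$name == "HUD", ]
  expect_equal(hud$strand, "-")
  expect_equal(hud$offset, 0)
  # TGTCTC contains a TGTC hit at the same offset
  g3 <- make_genome(chr1 = "TGTCTCAAAAAA")
  h3 <- scan_window(g3, "chr1", 3, halfwidth = 3)
  expect_equal(h3$offset[h3$name == "AuxRE-core"], 0)
  expect_equal(h3$offset[h3$name == "AuxRE"], 0)
  expect_error(scan_window(g3, "chr1", 50), "outside contig")
  expect_error(scan_window(g3, "chrX", 3), "unknown contig")
})

test_that("scan is strand-symmetric under reverse complement", {
  set.seed(5)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "T", "G"), 80, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- cisgrammar:::scan_sequence(s)
    h2 <- cisgrammar:::scan_sequence(rc)
    # mirrored offsets: a width-w hit at offset o maps to nchar - o - w
    key1 <- sort(paste(h1$name, nchar(s) - h1$offset - h1$width))
    key2 <- sort(paste(h2$name, h2$offset))
    expect_equal(key1, key2)
  }
})

test_that("co-occurrence classification and fractions", {
  g <- make_genome(chr1 = paste0("CACGTGAAAAATGTCAAA",          # both
                                 strrep("A", 200),
                                 "AATGTCAAAAAAAAAAAA",          # auxre_only
                                 strrep("A", 200),
                                 "AACACATGAAAAAAAAAA",          # ebox_only
                                 strrep("A", 200),
                                 "AAAAAAAAAAAAAAAAAA",          # neither
                                 strrep("A", 200)))
  peaks <- do.call(rbind, lapply(seq_along(c(9, 227, 445, 663)),
    function(i) toy_peak(paste0("p", i), "chr1",
                         c(9, 227, 445, 663)[i], width = 20L)))
  pr <- peak_motif_profiles(g, peaks, halfwidth = 9)
  expect_equal(pr$cooccurrence_class,
               c("both", "auxre_only", "ebox_only", "neither"))
  cc <- classify_cooccurrence(pr)
  expect_equal(sum(cc$fraction), 1, tolerance = 1e-12)
  expect_equal(cc$count, rep(1L, 4))
})

test_that("footprint gaps: separated, abutting, overlapping", {
  # TGTC [0,4), CACGTG [6,12): two bases strictly between
  g <- make_genome(chr1 = "TGTCAACACGTGAAAA")
  pr <- peak_motif_profiles(g, toy_peak("p1", "chr1", 8, width = 16L),
                            halfwidth = 8)
  expect_equal(pr$min_gap, 2)
  # abutting footprints: gap 0
  g2 <- make_genome(chr1 = "TGTCCACGTGAAAAAA")
  pr2 <- peak_motif_profiles(g2, toy_peak("p1", "chr1", 8, width = 16L),
                             halfwidth = 8)
  expect_equal(pr2$min_gap, 0)
  # overlapping footprints (CACATGTC: HUD [0,6) and TGTC [4,8)): gap 0
  g3 <- make_genome(chr1 = "CACATGTCAAAAAAAA")
  pr3 <- peak_motif_profiles(g3, toy_peak("p1", "chr1", 8, width = 16L),
                             halfwidth = 8)
  expect_equal(pr3$cooccurrence_class, "both")
  expect_equal(pr3$min_gap, 0)
})

test_that("motif enrichment arithmetic and Fisher p vs enumeration", {
  # 30/100 peak windows vs 10/100 background windows -> fold ~ 3
  kp <- 30; np <- 100; kb <- 10; nb <- 100
  fold <- ((kp + 0.5) / np) / ((kb + 0.5) / nb)
  expect_equal(fold, 3.0, tolerance = 0.12)
  # identical fractions -> fold ~ 1, p = 1
  p_same <- fisher.test(matrix(c(20, 80, 20, 80), 2))$p.value
  expect_equal(p_same, 1.0)
  # Fisher p equals exhaustive hypergeometric enumeration on small tables
  tabs <- list(c(8, 2, 2, 8), c(6, 4, 1, 9), c(5, 0, 3, 7), c(3, 3, 3, 3))
  for (tt in tabs) {
    expect_equal(fisher.test(matrix(tt, 2, byrow = TRUE))$p.value,
                 oracle_fisher_p(tt[1], tt[2], tt[3], tt[4]),
                 tolerance = 1e-12, info = paste(tt, collapse = ","))
  }
})

test_that("motif_enrichment runs end to end on a planted genome", {
  set.seed(3)
  bases <- sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
                  prob = c(0.32, 0.18, 0.18, 0.32))
  s <- paste(bases, collapse = "")
  # plant G-boxes at 10 summits
  summits <- seq(1000, 10000, by = 1000)
  for (x in summits) substr(s, x, x + 5) <- "CACGTG"
  g <- make_genome(chr1 = s)
  peaks <- do.call(rbind, lapply(seq_along(summits), function(i)
    toy_peak(paste0("p", i), "chr1", summits[i])))
  enr <- motif_enrichment(g, peaks, halfwidth = 50, seed = 11)
  gb <- enr[enr$name == "G-box", ]
  expect_equal(gb$k_peak, 10)
  expect_gt(gb$fold, 3)
  expect_lt(gb$p, 0.01)
  # determinism under the same seed
  enr2 <- motif_enrichment(g, peaks, halfwidth = 50, seed = 11)
  expect_identical(enr, enr2)
  expect_error(motif_enrichment(g, peaks, background_centers =
                                  data.frame(contig = character(),
                                             center = integer())),
               "empty background")
})

test_that("activation association percentages, Fisher p, empty classes", {
  prof <- data.frame(
    peak_id = sprintf("p%03d", 1:200),
    cooccurrence_class = rep(c("both", "auxre_only"), each = 100),
    stringsAsFactors = FALSE)
  act <- c(sprintf("p%03d", 1:60), sprintf("p%03d", 101:130))
  a <- activation_association(prof, act)
  expect_equal(a$table$percent, c(60, 30))
  expect_equal(a$p, fisher.test(matrix(c(60, 40, 30, 70), 2))$p.value)
  expect_equal(a$stars, "**")
  # equal proportions -> p = 1
  a2 <- activation_association(prof, c(sprintf("p%03d", 1:50),
                                       sprintf("p%03d", 101:150)))
  expect_equal(a2$p, 1.0)
  # small table agrees with exhaustive enumeration
  prof3 <- data.frame(peak_id = sprintf("q%02d", 1:16),
                      cooccurrence_class = rep(c("both", "auxre_only"),
                                               each = 8))
  a3 <- activation_association(prof3, c(sprintf("q%02d", 1:6),
                                        sprintf("q%02d", 9:10)))
  expect_equal(a3$p, oracle_fisher_p(6, 2, 2, 6), tolerance = 1e-12)
  # empty class: defined result with p = 1 and warning flag
  a4 <- activation_association(prof[prof$cooccurrence_class == "both", ],
                               act)
  expect_true(a4$empty_class_warning)
  expect_equal(a4$p, 1)
})

test_that("score_by_class summaries and Mann-Whitney vs enumeration", {
  peaks <- rbind(toy_peak("a1", "c", 1000, score = 1),
                 toy_peak("a2", "c", 2000, score = 2),
                 toy_peak("a3", "c", 3000, score = 3),
                 toy_peak("b1", "c", 4000, score = 4),
                 toy_peak("b2", "c", 5000, score = 5),
                 toy_peak("b3", "c", 6000, score = 6))
  prof <- data.frame(peak_id = peaks$peak_id,
                     cooccurrence_class = rep(c("both", "auxre_only"),
                                              each = 3))
  r <- score_by_class(peaks, prof)
  expect_equal(r$U, 0)                       # {1,2,3} vs {4,5,6}
  expect_equal(r$p, oracle_mw_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(r$summary$median[r$summary$class == "both"], 2)
  # identical score multisets in both classes: median difference 0
  peaks_t <- peaks
  peaks_t$score <- c(1, 2, 3, 1, 2, 3)
  r2 <- suppressWarnings(score_by_class(peaks_t, prof))
  s <- r2$summary
  expect_equal(s$median[s$class == "both"],
               s$median[s$class == "auxre_only"])
  # a class with < 2 peaks: summaries only, no test
  prof3 <- prof
  prof3$cooccurrence_class <- c("auxre_only", "both", "both",
                                "neither", "neither", "neither")
  r3 <- score_by_class(peaks, prof3)
  expect_true(is.na(r3$p))
  expect_equal(r3$summary$n[r3$summary$class == "auxre_only"], 1)
  # random small samples agree with the enumeration oracle
  set.seed(8)
  for (i in 1:4) {
    x <- sample(100, 5); y <- setdiff(sample(100, 12), x)[1:5]
    pk <- do.call(rbind, lapply(seq_along(c(x, y)), function(j)
      toy_peak(paste0("s", j), "c", j * 1000, score = c(x, y)[j])))
    pf <- data.frame(peak_id = pk$peak_id,
                     cooccurrence_class = rep(c("both", "auxre_only"),
                                              each = 5))
    expect_equal(score_by_class(pk, pf)$p, oracle_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("power: a +2 score shift in class-both peaks is detected", {
  set.seed(21)
  n <- 60
  sc <- c(rgamma(n, 2, 1) + 2, rgamma(n, 2, 1))
  pk <- do.call(rbind, lapply(seq_len(2 * n), function(j)
    toy_peak(paste0("p", j), "c", j * 1000, score = sc[j])))
  pf <- data.frame(peak_id = pk$peak_id,
                   cooccurrence_class = rep(c("both", "auxre_only"),
                                            each = n))
  expect_lt(score_by_class(pk, pf)$p, 0.01)
})

test_that("spacing histogram fractions and threshold summary", {
  prof <- data.frame(peak_id = sprintf("p%02d", 1:12),
                     cooccurrence_class = c(rep("both", 10),
                                            "auxre_only", "neither"),
                     min_gap = c(0, 2, 4, 5, 7, 12, 19, 20, 21, 60, NA, NA))
  sp <- spacing_distribution(prof)
  h <- sp$histogram
  expect_equal(sum(h$count), 10)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  expect_equal(h$count[h$bin_lo == 0], 3)     # gaps 0, 2, 4
  expect_equal(sp$frac_le_20, 0.8)
})
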