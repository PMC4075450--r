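# Pipeline orchestration: run every stage on one config and emit the
# paper-style report tables plus a machine-readable manifest. The report
# layer only formats numbers produced by the module operations; it never
# recomputes a statistic.

pipeline_required_keys <- function() {
  c("out_dir", "seed", "promoter_bp", "downstream_bp", "halfwidth",
    "fc_threshold", "alpha")
}

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed driving every stochastic stage.
#' @param synthetic A [synthetic_config()] (the pipeline always simulates
#'   its inputs; file-based stages are available individually and through
#'   the CLI subcommands).
#' @param promoter_bp,downstream_bp Target-rule windows (default 3000/1000).
#' @param halfwidth Motif scan half-window (default 100).
#' @param fc_threshold,alpha DE rule parameters (default 1.5, 0.01).
#' @param universe Gene universe size for overlap statistics (default: the
#'   synthetic gene count).
#' @param motifs Motif table (default [default_motifs()]).
#' @return list of class "run_config".
#' @export
run_config <- function(out_dir, seed = 1L,
                       synthetic = synthetic_config(seed = seed),
                       promoter_bp = 3000, downstream_bp = 1000,
                       halfwidth = 100, fc_threshold = 1.5, alpha = 0.01,
                       universe = synthetic$n_genes,
                       motifs = default_motifs()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, promoter_bp = promoter_bp,
                 downstream_bp = downstream_bp, halfwidth = halfwidth,
                 fc_threshold = fc_threshold, alpha = alpha,
                 universe = universe, motifs = motifs),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Diagnostic operation: returns (not raises) a character vector describing
#' every problem found — missing required keys, out-of-range parameters,
#' and unused keys. An empty vector means the config is valid.
#'
#' @param config A list or [run_config()].
#' @return Character vector of diagnostics (length 0 when valid).
#' @export
validate_config <- function(config) {
  diag <- character(0)
  known <- c(pipeline_required_keys(), "synthetic", "universe", "motifs")
  for (k in setdiff(pipeline_required_keys(), names(config)))
    diag <- c(diag, sprintf("missing required key: %s", k))
  extra <- setdiff(names(config), known)
  for (k in extra) diag <- c(diag, sprintf("unused key: %s", k))
  num_in <- function(key, lo, hi, open = FALSE) {
    v <- config[[key]]
    if (is.null(v)) return(invisible(NULL))
    bad <- !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
      (open && (v <= lo || v >= hi)) || (!open && (v < lo || v > hi))
    if (bad) diag <<- c(diag, sprintf(
      "out of range: %s = %s (expected %s %g..%g)", key,
      paste(format(v), collapse = ","), if (open) "open" else "closed",
      lo, hi))
  }
  num_in("alpha", 0, 1, open = TRUE)
  num_in("fc_threshold", 1, Inf, open = TRUE)
  num_in("promoter_bp", 0, 1e7)
  num_in("downstream_bp", 0, 1e7)
  num_in("halfwidth", 1, 1e5)
  if (!is.null(config$synthetic))
    tryCatch(validate_synthetic_config(config$synthetic),
             error = function(e) diag <<- c(diag, conditionMessage(e)))
  diag
}

fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
}

#' Run the full pipeline and write the report bundle
#'
#' Executes simulate, link, grammar, cobind, express and integrate stages
#' in order and writes one TSV per summary panel: position_distribution,
#' overlap, motif_enrichment, cooccurrence, spacing, activation_association,
#' score_by_class, de_summary, correlation, patterns and retention, plus
#' inputs/ (the simulated bundle) and manifest.tsv (parameters, seed,
#' per-stage row counts). Identical config + seed produces byte-identical
#' outputs. A stage failure aborts with the stage name; partial outputs are
#' kept next to a FAILED marker file.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result and \code{$tables},
#'   the named vector of written table paths.
#' @export
run_pipeline <- function(config) {
  diag <- validate_config(config)
  if (length(diag))
    stop_fmt("invalid config:\n%s", paste(" -", diag, collapse = "\n"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 failed_marker)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  res <- list(); tables <- character(0)
  emit <- function(name, d) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv(d, p)
    tables[[name]] <<- p
    p
  }

  message("stage simulate")
  bundle <- stage("simulate",
                  simulate_bundle(config$synthetic,
                                  dir = file.path(config$out_dir, "inputs")))
  res$bundle <- bundle
  facs <- unname(config$synthetic$factors)

  message("stage link")
  links <- stage("link", assign_peaks_to_genes(
    bundle$peaks, bundle$genes, config$promoter_bp, config$downstream_bp))
  res$links <- links
  tg <- target_genes(links)

  message("stage express")
  ex <- bundle$expression
  de_wt <- stage("express", call_differential(
    ex$counts, ex$design, "WT_BL:WT_mock", config$fc_threshold,
    config$alpha))
  de_mut <- call_differential(ex$counts, ex$design, "mut_BL:mut_mock",
                              config$fc_threshold, config$alpha)
  de_geno <- call_differential(ex$counts, ex$design, "mut_mock:WT_mock",
                               config$fc_threshold, config$alpha)
  res$de <- list(wt = de_wt, mut = de_mut, geno = de_geno)

  message("stage grammar")
  res$grammar <- stage("grammar", {
    pa <- bundle$peaks[bundle$peaks$factor == facs[1], , drop = FALSE]
    profiles <- peak_motif_profiles(bundle$genome, pa, config$motifs,
                                    config$halfwidth)
    enr <- motif_enrichment(bundle$genome, pa, config$motifs,
                            config$halfwidth, seed = config$seed)
    bg_centers <- sample_background_centers(
      bundle$genome, pa, 10L * nrow(pa), config$halfwidth,
      derive_seed(config$seed, "background"))
    bg_peaks <- data.frame(peak_id = sprintf("bg_%05d",
                                             seq_len(nrow(bg_centers))),
                           factor = "background",
                           contig = bg_centers$contig,
                           start = bg_centers$center,
                           end = bg_centers$center + 1L,
                           summit = bg_centers$center, score = 0,
                           stringsAsFactors = FALSE)
    bg_profiles <- peak_motif_profiles(bundle$genome, bg_peaks,
                                       config$motifs, config$halfwidth)
    spc <- spacing_distribution(profiles, bg_profiles)
    up_genes <- de_wt$gene_id[de_wt$de_flag == "up"]
    act_peaks <- unique(links$peak_id[links$factor == facs[1] &
                                        links$gene_id %in% up_genes])
    assoc <- activation_association(profiles, act_peaks)
    sbc <- score_by_class(pa, profiles)
    list(profiles = profiles, enrichment = enr, spacing = spc,
         association = assoc, score = sbc)
  })

  message("stage cobind")
  res$overlap <- stage("cobind", target_overlap(
    tg[[facs[1]]], tg[[facs[2]]], tg[[facs[3]]],
    universe_size = config$universe, set_names = facs))
  common <- Reduce(intersect, tg[facs])
  pA <- bundle$peaks[bundle$peaks$factor == facs[1], , drop = FALSE]
  pC <- bundle$peaks[bundle$peaks$factor == facs[3], , drop = FALSE]
  res$distance <- peak_distance_distribution(
    pA, pC, links[links$factor == facs[1], ], links[links$factor == facs[3], ],
    common)

  message("stage integrate")
  res$correlation <- stage("integrate", fc_correlation(
    de_wt, de_geno, subset = "all"))
  pan <- bundle$panel
  pan_tables <- lapply(1:3, function(k) call_differential(
    pan$counts, pan$design, sprintf("f%d_trt:f%d_ctrl", k, k),
    config$fc_threshold, config$alpha))
  names(pan_tables) <- paste0("f", 1:3)
  full_de <- Reduce(intersect, lapply(pan_tables, function(t)
    t$gene_id[t$de_flag != "ns"]))
  res$patterns <- coregulation_pattern(pan_tables)
  res$retention <- list(up = response_retention(de_wt, de_mut, "up"),
                        down = response_retention(de_wt, de_mut, "down"))

  message("stage report")
  stage("report", {
    emit("position_distribution",
         peak_position_distribution(pA, bundle$genes))
    ov <- res$overlap
    emit("overlap", cbind(ov$pairs,
                          triple_overlap = ov$triple$n_overlap,
                          universe = ov$universe_size))
    emit("motif_enrichment", res$grammar$enrichment)
    emit("cooccurrence", classify_cooccurrence(res$grammar$profiles))
    emit("spacing", res$grammar$spacing$histogram)
    a <- res$grammar$association
    emit("activation_association",
         cbind(a$table, p = a$p, stars = a$stars))
    emit("score_by_class", cbind(res$grammar$score$summary,
                                 p = res$grammar$score$p))
    de_counts <- function(t) table(factor(t$de_flag,
                                          c("up", "down", "ns")))
    emit("de_summary", data.frame(
      contrast = c("WT_BL:WT_mock", "mut_BL:mut_mock", "mut_mock:WT_mock"),
      do.call(rbind, lapply(res$de, de_counts))))
    emit("correlation", data.frame(r = res$correlation$r,
                                   n = res$correlation$n))
    emit("patterns", cbind(res$patterns$patterns,
                           concordant_opposing =
                             res$patterns$concordant_opposing_fraction,
                           n_full_de = res$patterns$n_full_de))
    ret <- res$retention
    emit("retention", data.frame(
      direction = c("up", "down"),
      n_wt = c(ret$up$n_wt, ret$down$n_wt),
      n_retained = c(ret$up$n_retained, ret$down$n_retained),
      percent = c(ret$up$percent, ret$down$percent)))
    manifest <- data.frame(
      key = c("package_version", "seed", "promoter_bp", "downstream_bp",
              "halfwidth", "fc_threshold", "alpha", "universe",
              "n_genes", "genome_length", "n_peaks", "n_links",
              "n_de_wt", "n_tables"),
      value = c(as.character(utils::packageVersion("cisgrammar")),
                fmt_num(config$seed), fmt_num(config$promoter_bp),
                fmt_num(config$downstream_bp), fmt_num(config$halfwidth),
                fmt_num(config$fc_threshold), fmt_num(config$alpha),
                fmt_num(config$universe),
                fmt_num(config$synthetic$n_genes),
                fmt_num(config$synthetic$genome_length),
                fmt_num(nrow(bundle$peaks)), fmt_num(nrow(links)),
                fmt_num(sum(de_wt$de_flag != "ns")),
                fmt_num(length(tables) + 1L)))
    emit("manifest", manifest)
  })
  res$tables <- unlist(tables)
  invisible(res)
}

# ---------------------------------------------------------------------------
# Minimal CLI: `pipeline_cli(c("run", "--config", "run.dcf"))` etc. The
# config file is DCF (key: value); numeric keys are coerced.

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_fmt("unexpected argument: %s", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop_fmt("missing value for --%s", key)
    out[[key]] <- args[i + 1]
    i <- i + 2L
  }
  out
}

read_run_config_file <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  d <- read.dcf(path)
  kv <- setNames(as.list(d[1, ]), colnames(d))
  num_keys <- c("seed", "promoter_bp", "downstream_bp", "halfwidth",
                "fc_threshold", "alpha", "universe", "n_genes",
                "genome_length")
  for (k in intersect(names(kv), num_keys)) kv[[k]] <- as.numeric(kv[[k]])
  syn_args <- list(seed = if (is.null(kv$seed)) 1L else as.integer(kv$seed))
  if (!is.null(kv$n_genes)) syn_args$n_genes <- kv$n_genes
  if (!is.null(kv$genome_length)) syn_args$genome_length <- kv$genome_length
  syn <- do.call(synthetic_config, syn_args)
  args <- list(out_dir = kv$out_dir,
               seed = if (is.null(kv$seed)) 1L else as.integer(kv$seed),
               synthetic = syn)
  for (k in c("promoter_bp", "downstream_bp", "halfwidth", "fc_threshold",
              "alpha", "universe"))
    if (!is.null(kv[[k]])) args[[k]] <- kv[[k]]
  do.call(run_config, args)
}

#' Command-line entry point
#'
#' Subcommands: \code{run --config <dcf>}, \code{validate --config <dcf>},
#' \code{simulate --seed <n> --out <dir>},
#' \code{link --peaks <tsv> --genes <gff3> --out <tsv>} (optional
#' \code{--promoter}, \code{--downstream}, \code{--factor}),
#' \code{express --counts <tsv> --design <tsv> --contrast A:B --out <tsv>}
#' (optional \code{--fc}, \code{--alpha}).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: pipeline <run|validate|simulate|link|express> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  status <- 0L
  if (cmd == "run") {
    cfg <- read_run_config_file(opt$config)
    run_pipeline(cfg)
  } else if (cmd == "validate") {
    cfg <- read_run_config_file(opt$config)
    diag <- validate_config(cfg)
    if (length(diag)) { writeLines(diag); status <- 1L }
    else message("config OK")
  } else if (cmd == "simulate") {
    cfg <- synthetic_config(seed = as.integer(opt$seed %||% 1L))
    simulate_bundle(cfg, dir = opt$out)
  } else if (cmd == "link") {
    peaks <- read_peaks(opt$peaks, factor = opt$factor %||% NA_character_)
    genes <- read_gene_models(opt$genes)
    links <- assign_peaks_to_genes(
      peaks, genes,
      promoter_bp = as.numeric(opt$promoter %||% 3000),
      downstream_bp = as.numeric(opt$downstream %||% 1000))
    write_tsv(links, opt$out)
  } else if (cmd == "express") {
    cm <- read_tsv(opt$counts)
    counts <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts) <- cm[[1]]
    design <- read_tsv(opt$design)
    tab <- call_differential(counts, design, opt$contrast,
                             fc_threshold = as.numeric(opt$fc %||% 1.5),
                             alpha = as.numeric(opt$alpha %||% 0.01))
    write_tsv(tab, opt$out)
  } else {
    message("unknown subcommand: ", cmd)
    status <- 1L
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
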