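#' @keywords internal
"_PACKAGE"

#' @importFrom stats chisq.test cor fisher.test median na.omit p.adjust
#'   phyper pt quantile rbinom rgamma rgeom rlnorm rnbinom rnorm runif sd
#'   setNames t.test var wilcox.test
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-stage sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(genome = 11L, peaks = 23L, expression = 37L, panel = 41L,
               background = 53L, pipeline = 67L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(as.character(stage)))
  as.integer((abs(seed) * 7919 + off * 104729) %% 2147483647)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Reverse complement of a plain character pattern (IUPAC-safe).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_palindrome <- function(pattern) pattern == revcomp(pattern)

check_positive <- function(..., .what = "quantity") {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_fmt("all %s values must be finite and > 0", .what)
  invisible(vals)
}
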