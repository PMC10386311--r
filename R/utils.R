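#' @useDynLib rdnavar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run expr with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derived from a parent seed and a string tag,
# kept below 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Round-half-up to `digits` decimals (base round() is round-half-even, which
# would print 48.1 as 48.1 but 0.125 as 0.12).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# 1-based inclusive interval -> length
interval_length <- function(iv) iv[2] - iv[1] + 1L

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
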