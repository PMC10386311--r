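# Shared fixtures: built once per test run, all in code.

CAT <- load_catalog()
UNIT <- make_reference_unit(CAT, seed = 16L)

# Small simulated genome + reads used by several mapping/profiling tests.
small_genome <- function(copies = 10L, mixture = NULL, backbone = 20000L,
                         seed = 1L) {
  make_genome(genome_spec(copies, mixture, backbone_length = backbone,
                          seed = seed), CAT, UNIT)
}

# Independent in-silico PCR oracle: scan every template position for
# primer/reverse-complement sites by direct substring comparison, then pair
# each forward site with the nearest downstream reverse site within
# max_len. Deliberately naive (no regex machinery).
pcr_brute_force <- function(template, forward, reverse, max_len) {
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  rev_rc <- rc(reverse)
  scan_sites <- function(tmpl, word) {
    w <- nchar(word)
    hits <- integer()
    for (i in seq_len(nchar(tmpl) - w + 1L))
      if (substr(tmpl, i, i + w - 1L) == word) hits <- c(hits, i)
    hits
  }
  out <- integer()
  for (tmpl in template) {
    f <- scan_sites(tmpl, forward)
    r <- scan_sites(tmpl, rev_rc)
    rend <- r + nchar(rev_rc) - 1L
    for (i in f) {
      lens <- rend - i + 1L
      lens <- lens[lens >= nchar(forward) + nchar(rev_rc) & lens <= max_len]
      if (length(lens)) out <- c(out, min(lens))
    }
  }
  sort(out)
}

# Depth from the simulator's truth table alone (no mapper): per-base
# fragment coverage of one record, counting both mates of every fragment.
truth_coverage <- function(readset, record, record_length,
                           read_len = readset$params$read_len) {
  tr <- readset$truth[readset$truth$record == record, , drop = FALSE]
  cov <- numeric(record_length)
  add <- function(s, e) {
    for (i in seq_along(s))
      cov[s[i]:e[i]] <<- cov[s[i]:e[i]] + 1
  }
  s1 <- tr$frag_start
  e2 <- tr$frag_start + tr$frag_len - 1L
  add(s1, pmin(s1 + read_len - 1L, record_length))
  add(pmax(e2 - read_len + 1L, 1L), pmin(e2, record_length))
  cov
}

# A quick genotype-call table for cohort tests.
fake_calls <- function(individual, label, region = "ETS3") {
  data.frame(individual = individual, region = region, label = label)
}
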