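test_that("published amplicon lengths hold in the default catalog", {
  expect_identical(variant_amplicon_length(CAT, "VARA", "P1P3"), 1260L)
  expect_identical(variant_amplicon_length(CAT, "VARB", "P1P3"), 950L)
  expect_identical(variant_amplicon_length(CAT, "BRASSICA200", "P1P3"), 200L)
  expect_identical(variant_amplicon_length(CAT, "AC800", "P1P3"), 800L)
  # VARB is VARA minus one 310 bp C repeat
  expect_identical(variant_amplicon_length(CAT, "VARA") -
                     variant_amplicon_length(CAT, "VARB"), 310L)
  expect_error(variant_amplicon_length(CAT, "VARX"), "unknown variant")
  expect_error(variant_amplicon_length(CAT, "VARA", "P4P5"),
               "primer pair targets region")
})

test_that("3'ETS variant length ordering matches the variant structure", {
  len <- vapply(paste0("VAR", 1:7), function(v)
    variant_amplicon_length(CAT, v), 1L)
  # VAR6 is the longest 3'ETS variant
  expect_true(all(len["VAR6"] > len[setdiff(names(len), "VAR6")]))
  # VAR7 is slightly smaller than VAR3, by the post-R2b deletion length
  expect_lt(len["VAR7"], len["VAR3"])
  post_r2b <- CAT$elements$length[CAT$elements$name == "post_r2b"]
  expect_identical(unname(len["VAR3"] - len["VAR7"]), post_r2b)
})

test_that("default catalog ships 12 3R and 10 5R genotype definitions", {
  regions <- vapply(CAT$genotypes, `[[`, "", "region")
  expect_identical(sum(regions == "ETS3"), 12L)
  expect_identical(sum(regions == "ETS5"), 10L)
  expect_false(anyDuplicated(names(CAT$genotypes)) > 0)
})

test_that("derive_variant applies element edits with additive lengths", {
  cat2 <- derive_variant(CAT, "VARA",
                         list(list(op = "delete", element = "C2")), "VARBp")
  expect_identical(variant_amplicon_length(cat2, "VARBp"), 950L)
  cat3 <- derive_variant(CAT, "VARA", list(), "X")
  expect_identical(variant_amplicon_length(cat3, "X"), 1260L)
  # A. cebennensis-like: VARB without D1a, checked by independent summation
  cat4 <- derive_variant(CAT, "VARB",
                         list(list(op = "delete", element = "D1a")), "ACp")
  d1a <- CAT$elements$length[CAT$elements$name == "D1a"]
  expect_identical(variant_amplicon_length(cat4, "ACp"), 950L - d1a)
  expect_identical(variant_amplicon_length(cat4, "ACp"),
                   sum(CAT$elements$length[match(
                     cat4$variants$ACp$elements, CAT$elements$name)]))
  expect_error(derive_variant(CAT, "VARB",
                              list(list(op = "delete", element = "C2")),
                              "bad"),
               "not present")
})

test_that("variant realizations are deterministic and primer-anchored", {
  a1 <- build_variant_sequence(CAT, "VARA", seed = 1)
  a2 <- build_variant_sequence(CAT, "VARA", seed = 1)
  expect_identical(a1, a2)
  expect_identical(nchar(a1), 1260L)
  expect_true(grepl(CAT$primers$P1P3$forward, a1, fixed = TRUE))
  expect_true(startsWith(a1, CAT$primers$P1P3$forward))
  b1 <- build_variant_sequence(CAT, "VARB", seed = 1)
  expect_false(identical(a1, build_variant_sequence(CAT, "VARA", seed = 2)))
  # VARB lacks exactly one contiguous 310 bp block of VARA: find the
  # longest common prefix, then splice
  n <- nchar(b1)
  lcp <- 0L
  while (substr(a1, lcp + 1L, lcp + 1L) == substr(b1, lcp + 1L, lcp + 1L))
    lcp <- lcp + 1L
  expect_identical(nchar(a1) - n, 310L)
  expect_identical(b1, paste0(substr(a1, 1, lcp),
                              substr(a1, lcp + 311L, nchar(a1))))
})

test_that("every C-class realization begins with the 59 bp C3 repeat", {
  seqs <- rdnavar:::realize_elements(CAT, seed = 4)
  c3 <- seqs[["C3"]]
  expect_identical(nchar(c3), 59L)
  for (el in c("C1", "C2", "C-like"))
    expect_true(startsWith(seqs[[el]], c3))
})

test_that("catalog serialization round-trips to an identical catalog", {
  txt <- write_catalog(CAT)
  cat2 <- load_catalog(txt)
  expect_identical(write_catalog(cat2), txt)
  expect_identical(cat2$elements, CAT$elements)
  expect_identical(names(cat2$variants), names(CAT$variants))
  expect_identical(cat2$genotypes[["3R9"]]$relations,
                   CAT$genotypes[["3R9"]]$relations)
  # and via a file
  f <- tempfile(fileext = ".yaml")
  write_catalog(CAT, f)
  expect_identical(write_catalog(load_catalog(f)), txt)
})

test_that("malformed or dangling catalog configs are rejected by name", {
  expect_error(load_catalog("elements: ["), "malformed catalog config")
  raw <- yaml::yaml.load(write_catalog(CAT))
  raw$genotypes[[1]]$required <- list("NOPE")
  expect_error(load_catalog(yaml::as.yaml(raw)), "NOPE")
})

test_that("in-silico PCR reproduces published products and edge cases", {
  vara <- build_variant_sequence(CAT, "VARA", 1)
  varb <- build_variant_sequence(CAT, "VARB", 1)
  expect_identical(insilico_pcr(vara, "P1P3", 3000, CAT), 1260L)
  expect_identical(
    insilico_pcr(build_variant_sequence(CAT, "BRASSICA200", 1),
                 "P1P3", 3000, CAT), 200L)
  # no primer sites -> no product
  expect_identical(insilico_pcr(strrep("AC", 500), "P1P3", 3000, CAT),
                   integer())
  # two variants on one template, separated by a spacer
  joint <- paste0(vara, strrep("T", 5000), varb)
  expect_identical(insilico_pcr(joint, "P1P3", 3000, CAT),
                   c(950L, 1260L))
  expect_error(insilico_pcr("", "P1P3", 3000, CAT), "non-empty")
  expect_error(insilico_pcr("ACGT", "P1P3", 0, CAT), "max_len")
})

test_that("in-silico PCR agrees with a brute-force primer-site scan", {
  pp <- CAT$primers$P1P3
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2000:6000, 1)
    tmpl <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    # implant a random number of primer sites at random positions
    for (i in seq_len(sample(0:4, 1))) {
      word <- sample(c(pp$forward,
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(pp$reverse)))), 1)
      p <- sample(n - nchar(word), 1)
      substr(tmpl, p, p + nchar(word) - 1L) <- word
    }
    expect_identical(insilico_pcr(tmpl, pp, 3000),
                     pcr_brute_force(tmpl, pp$forward, pp$reverse, 3000))
  }
})
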