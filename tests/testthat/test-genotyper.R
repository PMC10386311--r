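test_that("truth-mode band patterns apply the detection threshold", {
  g <- small_genome(5L, list(list(spec = unit_spec(ets3 = "VAR1"),
                                  prop = 1.0)))
  bp <- band_pattern(g, "ETS3")
  expect_equal(bp$abundances, c(VAR1 = 1.0))
  # Col-0-like: VAR4 at ~1% drops below the 5% detection limit
  mix <- list(list(spec = unit_spec(ets3 = "VAR1"), prop = 0.50),
              list(spec = unit_spec(ets3 = "VAR2"), prop = 0.30),
              list(spec = unit_spec(ets3 = "VAR3"), prop = 0.19),
              list(spec = unit_spec(ets3 = "VAR4"), prop = 0.01))
  g2 <- make_genome(genome_spec(2000L, mix, backbone_length = 1000L,
                                seed = 12L), CAT, UNIT, realize = FALSE)
  bp2 <- band_pattern(g2, "ETS3")
  expect_false("VAR4" %in% names(bp2$abundances))
  expect_equal(sum(bp2$abundances), 1.0)
  # a 3% variant survives a 2% threshold
  bp3 <- new_band_pattern(c(VAR1 = 0.97, VAR6 = 0.03), "ETS3",
                          detection_threshold = 0.02)
  expect_setequal(names(bp3$abundances), c("VAR1", "VAR6"))
  g_empty <- make_genome(genome_spec(1L, seed = 1L), CAT, UNIT,
                         realize = FALSE)
  g_empty$copies <- g_empty$copies[0, ]
  expect_error(band_pattern_truth(g_empty, "ETS3"), "empty")
})

test_that("classification reproduces the published genotype examples", {
  cl <- function(ab, region = "ETS3") {
    p <- new_band_pattern(ab, region, 0.05)
    if (region == "ETS3") classify_3R(p, CAT)$label
    else classify_5R(p, CAT)$label
  }
  expect_identical(cl(c(VAR1 = 1)), "3R1")
  expect_identical(cl(c(VAR3 = 1)), "3R3")
  expect_identical(cl(c(VAR1 = 0.5, VAR2 = 0.5)), "3R4.1")
  expect_identical(cl(c(VAR1 = 0.8, VAR2 = 0.2)), "3R4.2")
  expect_identical(cl(c(VAR1 = 0.2, VAR2 = 0.8)), "3R4.3")
  expect_identical(cl(c(VAR1 = 0.33, VAR3 = 0.33, VAR7 = 0.34)), "3R9")
  expect_identical(cl(c(VARA = 0.8, VARB = 0.2), "ETS5"), "5R1")
  expect_identical(cl(c(VARA = 0.5, VARB = 0.5), "ETS5"), "5R2")
  expect_identical(cl(c(VARA = 0.2, VARB = 0.8), "ETS5"), "5R3")
  expect_identical(cl(c(VARA = 0.33, VARB = 0.33, BRASSICA200 = 0.34),
                      "ETS5"), "5R4")
  # VARA as a trace (but detectable) component is 5R10, not 5R3
  expect_identical(cl(c(VARA = 0.06, VARB = 0.94), "ETS5"), "5R10")
  # unknown combinations stay unclassified with diagnostics
  call <- classify_3R(new_band_pattern(c(VAR1 = 0.6, VAR6 = 0.1,
                                         VAR3 = 0.3), "ETS3", 0.05), CAT)
  expect_identical(call$label, "unclassified")
  expect_match(call$diagnostics, "matching definitions")
  expect_error(classify_3R(new_band_pattern(c(VARA = 1), "ETS5", 0.05),
                           CAT), "expected ETS3")
  expect_error(classify_5R(new_band_pattern(c(VAR1 = 1), "ETS3", 0.05),
                           CAT), "expected ETS5")
})

test_that("every shipped genotype definition round-trips", {
  for (g in CAT$genotypes) {
    p <- synthesize_band_pattern(g)
    call <- if (g$region == "ETS3") classify_3R(p, CAT)
      else classify_5R(p, CAT)
    expect_identical(call$label, g$label)
  }
})

test_that("classification is invariant to abundance rescaling", {
  for (ab in list(c(VAR1 = 0.5, VAR2 = 0.5), c(VAR1 = 4, VAR3 = 1),
                  c(VAR1 = 1, VAR3 = 1, VAR7 = 1.2))) {
    l1 <- classify_3R(new_band_pattern(ab / sum(ab), "ETS3", 0.01),
                      CAT)$label
    l2 <- classify_3R(new_band_pattern(ab * 7, "ETS3", 0.01), CAT)$label
    expect_identical(l1, l2)
  }
})

test_that("VAR4 never changes a 3R call", {
  base <- c(VAR1 = 0.8, VAR2 = 0.2)
  ref_label <- classify_3R(new_band_pattern(base, "ETS3", 0.01),
                           CAT)$label
  for (v4 in c(0.01, 0.1, 0.4)) {
    ab <- c(base * (1 - v4), VAR4 = v4)
    expect_identical(classify_3R(new_band_pattern(ab, "ETS3", 0.001),
                                 CAT)$label, ref_label)
  }
})

test_that("dominance_ratio moves the equivalent/dominant boundary", {
  p <- new_band_pattern(c(VAR1 = 8, VAR2 = 5), "ETS3", 0.05)  # ratio 1.6
  expect_identical(classify_3R(p, CAT, dominance_ratio = 2)$label, "3R4.1")
  expect_identical(classify_3R(p, CAT, dominance_ratio = 1.5)$label,
                   "3R4.2")
  q <- new_band_pattern(c(VAR1 = 0.7, VAR2 = 0.3), "ETS3", 0.05) # ratio 2.33
  expect_identical(classify_3R(q, CAT, dominance_ratio = 2)$label, "3R4.2")
  expect_identical(classify_3R(q, CAT, dominance_ratio = 3)$label, "3R4.1")
})

test_that("truth-mode and depth-mode patterns yield identical calls", {
  mix <- list(list(spec = unit_spec(ets3 = "VAR1"), prop = 0.7),
              list(spec = unit_spec(ets3 = "VAR3"), prop = 0.3))
  g <- make_genome(genome_spec(100L, mix, backbone_length = 10000L,
                               seed = 13L), CAT, UNIT)
  rs <- simulate_reads(g, depth = 10, error_rate = 0, seed = 13L)
  pt <- band_pattern_truth(g, "ETS3")
  pd <- band_pattern_depth(rs, "ETS3", CAT, UNIT)
  expect_identical(classify_3R(pt, CAT)$label, classify_3R(pd, CAT)$label)
  expect_lt(max(abs(pd$abundances[names(pt$abundances)] - pt$abundances)),
            0.05)
})
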