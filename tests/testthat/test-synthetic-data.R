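test_that("genome construction follows the mixture and is reproducible", {
  # degenerate mixture: every copy is the single component
  g <- small_genome(5L, list(list(spec = unit_spec(ets3 = "VAR1"),
                                  prop = 1.0)))
  expect_identical(nrow(g$copies), 5L)
  expect_true(all(g$copies$label == "VARA/VAR1"))
  expect_identical(nchar(g$array), sum(g$copies$length))

  # multinomial draws stay within 3 binomial SDs of expectation
  mix <- list(list(spec = unit_spec(ets3 = "VAR1"), prop = 0.5),
              list(spec = unit_spec(ets3 = "VAR2"), prop = 0.3),
              list(spec = unit_spec(ets3 = "VAR3"), prop = 0.2))
  spec <- genome_spec(1000L, mix, backbone_length = 1000L, seed = 8L)
  g2 <- make_genome(spec, CAT, UNIT, realize = FALSE)
  cnt <- tabulate(g2$copies$component, 3L)
  p <- c(0.5, 0.3, 0.2)
  expect_true(all(abs(cnt - 1000 * p) <= 3 * sqrt(1000 * p * (1 - p))))

  # law of large numbers at 10,000 copies
  spec3 <- genome_spec(10000L, mix, backbone_length = 1000L, seed = 9L)
  g3 <- make_genome(spec3, CAT, UNIT, realize = FALSE)
  phat <- tabulate(g3$copies$component, 3L) / 10000
  expect_true(all(abs(phat - p) < 3 * sqrt(p * (1 - p) / 10000)))

  # determinism of the truth table
  expect_identical(make_genome(spec, CAT, UNIT, realize = FALSE)$copies,
                   g2$copies)

  expect_error(genome_spec(0L), "copy_number")
  expect_error(genome_spec(5L, list(list(spec = unit_spec(), prop = 0.7))),
               "sum to 1")
})

test_that("read simulation honors depth, errors and duplicates", {
  g <- small_genome(2L, backbone = 200000L, seed = 3L)
  # depth 0 -> empty read set
  empty <- simulate_reads(g, depth = 0, seed = 1L)
  expect_identical(nrow(empty$reads), 0L)
  expect_error(simulate_reads(g, depth = -1), "depth")
  expect_error(simulate_reads(g, depth = 1, read_len = 400L), "insert_mean")

  rs <- simulate_reads(g, depth = 10, seed = 3L)
  # fragment count = round(depth * G / (2 * read_len))
  G <- 200000L + nchar(g$array)
  expect_identical(nrow(rs$reads), as.integer(round(10 * G / 300)))
  # mean backbone coverage near 10x (Poisson oracle from the truth table)
  cov <- truth_coverage(rs, "backbone", 200000L)
  expect_gt(mean(cov), 9)
  expect_lt(mean(cov), 11)
  # error-free reads are exact substrings of their origin record
  tr <- rs$truth[rs$truth$record == "backbone", ][1:50, ]
  m1 <- rs$reads$seq1[match(tr$name, rs$reads$name)]
  expect_identical(m1, substring(g$backbone, tr$frag_start,
                                 tr$frag_start + 149L))
  # with errors, reads differ from the reference but names/truth persist
  rs_err <- simulate_reads(g, depth = 1, error_rate = 0.01, seed = 3L)
  tr2 <- rs_err$truth[rs_err$truth$record == "backbone", ]
  m2 <- rs_err$reads$seq1[match(tr2$name, rs_err$reads$name)]
  expect_false(all(m2 == substring(g$backbone, tr2$frag_start,
                                   tr2$frag_start + 149L)))
  # duplicates: unique-pair count equals the pre-duplication count
  rs_dup <- simulate_reads(g, depth = 2, dup_rate = 0.1, seed = 4L)
  n_frag <- round(2 * G / 300)
  expect_identical(nrow(rs_dup$reads),
                   as.integer(n_frag + round(0.1 * n_frag)))
  expect_lte(length(unique(paste(rs_dup$reads$seq1, rs_dup$reads$seq2))),
             n_frag)
  expect_identical(anyDuplicated(rs_dup$reads$name), 0L)
})

test_that("collapsed rDNA depth over backbone depth recovers copy number", {
  for (cn in c(1L, 10L, 100L)) {
    bb <- 50000L
    g <- make_genome(genome_spec(cn, backbone_length = bb,
                                 seed = 20L + cn), CAT, UNIT)
    rs <- simulate_reads(g, depth = 3, seed = 20L + cn)
    pl <- map_reads(rs, c(rdna_unit = UNIT$sequence,
                          backbone = g$backbone))
    ratio <- estimate_cnv(compute_depth(pl, "rdna_unit"),
                          compute_depth(pl, "backbone"))
    # 3-SD corridor from the expected fragment counts per compartment
    total <- bb + nchar(g$array)
    n_frag <- round(3 * total / 300)
    n_arr <- n_frag * nchar(g$array) / total
    n_bb <- n_frag * bb / total
    tol <- 3 * sqrt(1 / n_arr + 1 / n_bb)
    # fragment starts cannot fall within one insert of a record end, which
    # concentrates coverage in the interior; the short unit record feels
    # this more than the long backbone
    edge <- (10500 / (10500 - 350)) / (bb / (bb - 350))
    expect_gt(ratio, cn * (1 - tol))
    expect_lt(ratio, cn * (1 + tol) * edge)
  }
})

test_that("FASTQ round-trip preserves names, sequences and qualities", {
  g <- small_genome(2L, backbone = 5000L, seed = 5L)
  rs <- simulate_reads(g, depth = 3, error_rate = 0.001, seed = 5L)
  pre <- tempfile()
  write_fastq(rs, pre)
  back <- read_fastq(paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
  expect_identical(back$reads$name, rs$reads$name)
  expect_identical(back$reads$seq1, rs$reads$seq1)
  expect_identical(back$reads$seq2, rs$reads$seq2)
  expect_identical(back$reads$qual1, rs$reads$qual1)
  # writing the round-tripped set reproduces the file byte-for-byte
  pre2 <- tempfile()
  write_fastq(back, pre2)
  expect_identical(readLines(paste0(pre2, "_1.fastq")),
                   readLines(paste0(pre, "_1.fastq")))
})
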