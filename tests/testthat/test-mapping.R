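make_readset <- function(name, seq1, seq2) {
  structure(list(reads = data.frame(name = name, seq1 = seq1,
                                    qual1 = strrep("I", nchar(seq1)),
                                    seq2 = seq2,
                                    qual2 = strrep("I", nchar(seq2))),
                 truth = NULL, params = list(read_len = nchar(seq1[1]))),
            class = "rdna_reads")
}

test_that("duplicate removal keeps one representative per identical pair", {
  rs <- make_readset(c("r3", "r1", "r2", "r4"),
                     c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGA"),
                     c("TTTTAAAA", "TTTTAAAA", "TTTTACAA", "TTTTAAAA"))
  dd <- remove_duplicates(rs)
  # r3 and r1 are identical pairs; r1 wins lexicographically; input order
  # of survivors is preserved
  expect_identical(dd$reads$name, c("r1", "r2", "r4"))
  # idempotent
  expect_identical(remove_duplicates(dd)$reads, dd$reads)
  # near-duplicates (one base apart) are not duplicates
  expect_true(all(c("r2", "r4") %in% dd$reads$name))
  # hash-set oracle on a simulated set with duplicates
  g <- small_genome(2L, backbone = 10000L, seed = 6L)
  sim <- simulate_reads(g, depth = 3, dup_rate = 0.15, seed = 6L)
  dd2 <- remove_duplicates(sim)
  expect_identical(nrow(dd2$reads),
                   length(unique(paste(sim$reads$seq1, sim$reads$seq2))))
  # unpaired input is rejected
  bad <- rs; bad$reads$seq2 <- NULL
  expect_error(remove_duplicates(bad), "paired")
})

test_that("error-free reads map back to their true origins", {
  g <- small_genome(10L, backbone = 30000L, seed = 7L)
  rs <- simulate_reads(g, depth = 4, error_rate = 0, seed = 7L)
  pl <- map_reads(rs, c(rdna_unit = UNIT$sequence, backbone = g$backbone))
  m1 <- pl[pl$mate == 1L, ]
  tr <- rs$truth[match(m1$name, rs$truth$name), ]
  # backbone mate-1 placements at the true fragment start
  bb <- tr$record == "backbone"
  acc_bb <- mean(m1$start[bb] == tr$frag_start[bb] &
                   m1$target[bb] == "backbone")
  expect_gte(acc_bb, 0.99)
  # rDNA reads collapse onto the unit at the true within-unit offset,
  # regardless of copy index (modular-coordinate oracle)
  ar <- tr$record == "rdna_array"
  exp_off <- ((tr$frag_start[ar] - 1L) %% 10500L) + 1L
  acc_u <- mean(m1$target[ar] == "rdna_unit" & m1$start[ar] == exp_off)
  expect_gte(acc_u, 0.99)
})

test_that("foreign reads stay unmapped and junction reads wrap", {
  g <- small_genome(3L, backbone = 5000L, seed = 8L)
  alien <- paste(sample(c("A", "C", "G", "T"), 150, TRUE,
                        prob = c(0.1, 0.4, 0.4, 0.1)), collapse = "")
  junction <- paste0(substr(UNIT$sequence, 10451, 10500),
                     substr(UNIT$sequence, 1, 100))
  rs <- make_readset(c("alien", "junction"), c(alien, junction),
                     c(alien, junction))
  pl <- map_reads(rs, c(rdna_unit = UNIT$sequence, backbone = g$backbone))
  expect_false("alien" %in% pl$name)
  jm <- pl[pl$name == "junction" & pl$mate == 1L, ]
  expect_identical(jm$target, "rdna_unit")
  expect_identical(jm$start, 10451L)
})

test_that("depth conservation holds, including across the circular junction", {
  g <- small_genome(4L, backbone = 10000L, seed = 9L)
  rs <- simulate_reads(g, depth = 3, error_rate = 0.001, seed = 9L)
  pl <- map_reads(rs, c(rdna_unit = UNIT$sequence, backbone = g$backbone))
  d_u <- compute_depth(pl, "rdna_unit")
  d_b <- compute_depth(pl, "backbone")
  expect_identical(sum(d_u$depth) + sum(d_b$depth), sum(pl$aln_len))
  expect_true(all(d_u$depth >= 0))
  # single placement depth profile
  one <- pl[1, , drop = FALSE]
  attr(one, "target_lengths") <- attr(pl, "target_lengths")
  attr(one, "circular") <- attr(pl, "circular")
  d1 <- compute_depth(one, one$target)
  expect_identical(sum(d1$depth), one$aln_len)
  expect_true(all(d1$depth %in% c(0L, 1L)))
})

test_that("pileups report aligned bases and recover edited copy fractions", {
  # error-free, edit-free: no non-reference counts anywhere
  g <- small_genome(3L, backbone = 5000L, seed = 10L)
  rs <- simulate_reads(g, depth = 5, error_rate = 0, seed = 10L)
  pl <- map_reads(rs, c(rdna_unit = UNIT$sequence, backbone = g$backbone))
  pup <- build_pileup(pl, rs, UNIT$sequence)
  f <- alt_allele_freq(pup, min_depth = 1L)
  expect_true(all(f[!is.na(f)] == 0))
  # depth-0 positions have empty counts
  expect_true(all(rowSums(pup$counts[rowSums(pup$counts) == 0, ,
                                     drop = FALSE]) == 0))
  # a SNP carried by ~40% of copies shows ~40% alternative alleles
  mix <- list(list(spec = unit_spec(), prop = 0.6),
              list(spec = unit_spec(snp_edits = data.frame(pos = 2500L,
                                                           alt = "A")),
                   prop = 0.4))
  g2 <- small_genome(60L, mix, backbone = 5000L, seed = 11L)
  rs2 <- simulate_reads(g2, depth = 4, error_rate = 0, seed = 11L)
  pl2 <- map_reads(rs2, c(rdna_unit = UNIT$sequence,
                          backbone = g2$backbone))
  pup2 <- build_pileup(pl2, rs2, UNIT$sequence)
  truth_frac <- mean(g2$copies$component == 2L)
  est <- alt_allele_freq(pup2, 2500L)
  n <- sum(pup2$counts[2500L, ])
  expect_lt(abs(est - truth_frac),
            3 * sqrt(truth_frac * (1 - truth_frac) / n))
})

test_that("SAM and BEDGraph exports are well-formed", {
  g <- small_genome(2L, backbone = 4000L, seed = 12L)
  rs <- simulate_reads(g, depth = 1, seed = 12L)
  pl <- map_reads(rs, c(rdna_unit = UNIT$sequence, backbone = g$backbone))
  sam <- tempfile(fileext = ".sam")
  export_sam(pl, rs, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  body <- lines[!startsWith(lines, "@")]
  expect_identical(length(body), nrow(pl))
  expect_true(all(vapply(strsplit(body, "\t"), length, 1L) == 11L))
  bg <- tempfile(fileext = ".bedgraph")
  export_bedgraph(compute_depth(pl, "backbone"), bg)
  b <- utils::read.table(bg, sep = "\t")
  expect_identical(max(b$V3), 4000L)
  expect_identical(sum((b$V3 - b$V2) * b$V4),
                   sum(pl$aln_len[pl$target == "backbone"]))
})
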