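#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly over the genome (backbone plus rDNA
#' array) with normal insert sizes truncated at the read length; each
#' fragment yields a 2 x `read_len` pair. Substitution errors are i.i.d.
#' per base; a `dup_rate` fraction of fragments is emitted twice with
#' distinct names and identical sequences (PCR/optical duplicates). Truth
#' placements are recorded before errors are applied. Qualities are
#' constant ("I"); the downstream pipeline never uses them.
#'
#' @param genome An `rdna_genome` built with `realize = TRUE`.
#' @param depth Target mean per-base depth (>= 0).
#' @param read_len Read length (default 150).
#' @param insert_mean,insert_sd Fragment length distribution (defaults
#'   350 and 35; the fragment length is truncated below at `read_len`).
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param dup_rate Duplicate fragment fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of class `rdna_reads`: list with `reads` (data.frame:
#'   name, seq1, qual1, seq2, qual2), `truth` (name, record, frag_start,
#'   frag_len, copy, unit_offset, duplicate) and `params`.
#' @export
simulate_reads <- function(genome, depth, read_len = 150L,
                           insert_mean = 350L, insert_sd = 35,
                           error_rate = 0, dup_rate = 0, seed = 1L) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (read_len > insert_mean)
    stop("read_len must be <= insert_mean", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1 || dup_rate < 0 || dup_rate >= 1)
    stop("error_rate and dup_rate must lie in [0, 1)", call. = FALSE)
  if (is.null(genome$array))
    stop("genome was built with realize = FALSE", call. = FALSE)
  records <- c(backbone = genome$backbone, rdna_array = genome$array)
  rec_len <- nchar(records)
  total <- sum(rec_len)
  n_frag <- round(depth * total / (2 * read_len))
  params <- list(depth = depth, read_len = as.integer(read_len),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = insert_sd, error_rate = error_rate,
                 dup_rate = dup_rate, seed = as.integer(seed))
  if (n_frag == 0) {
    empty <- data.frame(name = character(), seq1 = character(),
                        qual1 = character(), seq2 = character(),
                        qual2 = character())
    return(structure(list(reads = empty, truth = empty_truth(),
                          params = params), class = "rdna_reads"))
  }
  with_seed(sub_seed(seed, "reads"), {
    rec <- sample.int(length(records), n_frag, replace = TRUE,
                      prob = rec_len / total)
    fl <- pmax(read_len, round(stats::rnorm(n_frag, insert_mean, insert_sd)))
    fl <- pmin(fl, rec_len[rec])
    start <- floor(stats::runif(n_frag) * (rec_len[rec] - fl + 1)) + 1L
    seq1 <- substring(records[rec], start, start + read_len - 1L)
    end <- start + fl - 1L
    seq2 <- revcomp(substring(records[rec], end - read_len + 1L, end))
    name <- sprintf("frag%07d", seq_len(n_frag))
    truth <- fragment_truth(genome, names(records)[rec], start, fl, name)
    if (error_rate > 0) {
      seq1 <- inject_errors(seq1, error_rate)
      seq2 <- inject_errors(seq2, error_rate)
    }
    if (dup_rate > 0) {
      ndup <- round(dup_rate * n_frag)
      if (ndup > 0) {
        di <- sample.int(n_frag, ndup)
        dup_names <- sprintf("frag%07d", n_frag + seq_len(ndup))
        seq1 <- c(seq1, seq1[di]); seq2 <- c(seq2, seq2[di])
        name <- c(name, dup_names)
        dup_truth <- truth[di, , drop = FALSE]
        dup_truth$name <- dup_names
        dup_truth$duplicate <- TRUE
        truth <- rbind(truth, dup_truth)
      }
    }
    qual <- strrep("I", read_len)
    reads <- data.frame(name = name, seq1 = seq1, qual1 = qual,
                        seq2 = seq2, qual2 = qual)
    rownames(truth) <- NULL
    structure(list(reads = reads, truth = truth, params = params),
              class = "rdna_reads")
  })
}

empty_truth <- function() {
  data.frame(name = character(), record = character(),
             frag_start = integer(), frag_len = integer(),
             copy = integer(), unit_offset = integer(),
             duplicate = logical())
}

# True origin of each fragment; array fragments get copy index and 1-based
# within-unit offset of the fragment start.
fragment_truth <- function(genome, record, start, frag_len, name) {
  copy <- rep(NA_integer_, length(start))
  unit_offset <- rep(NA_integer_, length(start))
  arr <- record == "rdna_array"
  if (any(arr)) {
    idx <- findInterval(start[arr], genome$copies$array_start)
    copy[arr] <- genome$copies$copy[idx]
    unit_offset[arr] <- start[arr] - genome$copies$array_start[idx] + 1L
  }
  data.frame(name = name, record = record, frag_start = start,
             frag_len = frag_len, copy = copy, unit_offset = unit_offset,
             duplicate = FALSE)
}

# Vectorized i.i.d. substitution errors: always substitute to a different
# base.
inject_errors <- function(seqs, rate) {
  L <- nchar(seqs[1])
  nerr <- stats::rbinom(length(seqs), L, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample.int(L, nerr[i])
    s <- seqs[i]
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(BASES, old), 1)
    }
    seqs[i] <- s
  }
  seqs
}

#' @export
print.rdna_reads <- function(x, ...) {
  cat(sprintf("Paired read set: %d pairs (2 x %d bp)\n",
              nrow(x$reads), x$params$read_len))
  invisible(x)
}

#' Write a paired read set to FASTQ
#'
#' @param readset An `rdna_reads` object.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (`.gz` appended when `gzip = TRUE`).
#' @param gzip Compress output.
#' @return Character vector of the two file paths.
#' @export
write_fastq <- function(readset, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  write_one <- function(path, nm, sq, ql) {
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", nm, "\n", sq, "\n+\n", ql), con)
  }
  write_one(paths[1], readset$reads$name, readset$reads$seq1,
            readset$reads$qual1)
  write_one(paths[2], readset$reads$name, readset$reads$seq2,
            readset$reads$qual2)
  invisible(paths)
}

#' Read paired FASTQ files into a read set
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return An `rdna_reads` object (without truth placements).
#' @export
read_fastq <- function(path1, path2) {
  read_quiet <- function(path) {
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  r1 <- read_quiet(path1)
  r2 <- read_quiet(path2)
  if (length(r1) != length(r2))
    stop("mate files differ in read count", call. = FALSE)
  nm1 <- sub("\\s.*$", "", names(r1))
  nm2 <- sub("\\s.*$", "", names(r2))
  if (!identical(nm1, nm2))
    stop("mate files differ in read names/order", call. = FALSE)
  reads <- data.frame(
    name = nm1,
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)))
  rownames(reads) <- NULL
  structure(list(reads = reads, truth = NULL,
                 params = list(read_len = nchar(reads$seq1[1]))),
            class = "rdna_reads")
}
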