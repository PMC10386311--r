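#' Remove duplicate read pairs
#'
#' Among pairs with byte-identical (mate1, mate2) sequences, exactly one
#' representative is kept: the lexicographically smallest name. The output
#' otherwise preserves input order. Idempotent.
#'
#' @param readset An `rdna_reads` object.
#' @return The deduplicated `rdna_reads`.
#' @export
remove_duplicates <- function(readset) {
  reads <- readset$reads
  if (is.null(reads$seq2) || anyNA(reads$seq2))
    stop("remove_duplicates requires paired reads", call. = FALSE)
  if (!nrow(reads)) return(readset)
  key <- paste(reads$seq1, reads$seq2, sep = "\r")
  # representative per key: smallest name
  rep_name <- tapply(reads$name, key, function(v) min(v))
  keep <- reads$name == rep_name[key]
  readset$reads <- reads[keep, , drop = FALSE]
  rownames(readset$reads) <- NULL
  if (!is.null(readset$truth)) {
    readset$truth <- readset$truth[readset$truth$name %in% reads$name[keep], ,
                                   drop = FALSE]
    rownames(readset$truth) <- NULL
  }
  readset
}

#' Map reads to the collapsed reference
#'
#' A minimal deterministic mapper: each mate is placed by exact-match k-mer
#' seeding (the first seed offset that yields a verified placement) followed
#' by full-length verification allowing at most `max_mm` substitutions.
#' The rDNA unit reference is treated as circular (head-to-tail arrays make
#' junction-spanning reads legitimate unit reads), so reads from any rDNA
#' copy collapse onto the single unit. Reads with multiple equally good
#' placements are discarded when `discard_ambiguous` is `TRUE`; ties are
#' otherwise broken by the leftmost placement.
#'
#' @param readset An `rdna_reads` object.
#' @param targets Named character vector of reference sequences, e.g.
#'   `c(rdna_unit = ..., backbone = ...)`.
#' @param circular Logical vector (recycled) marking circular targets. The
#'   default treats a target named `"rdna_unit"` as circular.
#' @param k Seed length (default 31).
#' @param max_mm Maximum substitutions per read (default 5).
#' @param discard_ambiguous Drop reads with several equally good placements
#'   (default `TRUE`).
#' @return A data.frame of placements (name, mate, target, start, strand,
#'   nmm, aln_len) with attributes `n_unmapped` and `n_ambiguous`, and the
#'   target lengths in attribute `target_lengths`.
#' @export
map_reads <- function(readset, targets, circular = NULL, k = 31L,
                      max_mm = 5L, discard_ambiguous = TRUE) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  read_len <- readset$params$read_len %||% nchar(readset$reads$seq1[1])
  if (k > read_len) stop("k must be <= read length", call. = FALSE)
  circular <- circular %||% (names(targets) == "rdna_unit")
  circular <- rep_len(circular, length(targets))
  reads <- readset$reads
  n <- nrow(reads)
  all_seqs <- c(reads$seq1, reads$seq2)
  res <- cpp_map_reads(unname(targets), circular, all_seqs,
                       as.integer(k), as.integer(max_mm),
                       as.integer(read_len - 1L))
  pl <- data.frame(name = rep(reads$name, 2L),
                   mate = rep(c(1L, 2L), each = n),
                   target = names(targets)[res$target],
                   start = res$start, strand = res$strand, nmm = res$nmm,
                   aln_len = nchar(all_seqs), n_best = res$n_best)
  unmapped <- is.na(pl$start)
  ambiguous <- !unmapped & pl$n_best > 1L
  keep <- !unmapped & (!discard_ambiguous | pl$n_best == 1L)
  out <- pl[keep, setdiff(names(pl), "n_best"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(unmapped)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "target_lengths") <- stats::setNames(nchar(targets),
                                                 names(targets))
  attr(out, "circular") <- stats::setNames(circular, names(targets))
  out
}

# Oriented read sequence for each placement (reverse-complemented for "-"
# strand placements).
oriented_sequences <- function(placements, readset) {
  idx <- match(paste(placements$name, placements$mate),
               c(paste(readset$reads$name, 1L),
                 paste(readset$reads$name, 2L)))
  seqs <- c(readset$reads$seq1, readset$reads$seq2)[idx]
  neg <- placements$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  seqs
}

#' Per-base read depth on one target
#'
#' @param placements Placement data.frame from [map_reads()].
#' @param target Target name.
#' @param target_length Length of the target; taken from the placements'
#'   attributes when missing.
#' @param circular Whether placements wrap past the end; taken from
#'   attributes when missing.
#' @return Object of class `rdna_depth`: list with `target` and integer
#'   `depth` of length `target_length`.
#' @export
compute_depth <- function(placements, target, target_length = NULL,
                          circular = NULL) {
  target_length <- target_length %||%
    attr(placements, "target_lengths")[[target]]
  circular <- circular %||%
    isTRUE(attr(placements, "circular")[[target]])
  p <- placements[placements$target == target, , drop = FALSE]
  delta <- numeric(target_length + 1L)
  if (nrow(p)) {
    s <- p$start
    e <- p$start + p$aln_len - 1L
    over <- e > target_length
    if (any(over) && !circular) e[over] <- target_length
    add <- function(from, to) {
      tab_s <- tabulate(from, nbins = target_length)
      tab_e <- tabulate(pmin(to, target_length) + 1L,
                        nbins = target_length + 1L)
      delta[seq_len(target_length)] <<-
        delta[seq_len(target_length)] + tab_s
      delta <<- delta - tab_e
    }
    if (circular && any(over)) {
      add(s[!over], e[!over])
      add(s[over], rep(target_length, sum(over)))
      add(rep(1L, sum(over)), e[over] - target_length)
    } else {
      add(s, e)
    }
  }
  structure(list(target = target,
                 depth = as.integer(cumsum(delta[seq_len(target_length)]))),
            class = "rdna_depth")
}

#' @export
print.rdna_depth <- function(x, ...) {
  cat(sprintf("Depth profile on %s: %d bp, mean %.2fx\n",
              x$target, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Export a depth profile as BEDGraph (0-based half-open)
#' @param depth An `rdna_depth`.
#' @param path Output path.
#' @export
export_bedgraph <- function(depth, path) {
  d <- depth$depth
  r <- rle(d)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  utils::write.table(data.frame(depth$target, start, end, r$values),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a substitution-only pileup on one target
#'
#' Tallies the aligned read base at every reference position (A/C/G/T plus
#' a deletion column, which stays zero for mapper-derived placements: only
#' substitutions are scored; indel polymorphisms show up as coverage dips).
#'
#' @param placements Placements from [map_reads()].
#' @param readset The read set the placements came from.
#' @param reference Reference sequence of the target.
#' @param target Target name (default `"rdna_unit"`).
#' @param circular Whether the target wraps (default: from attributes).
#' @return Object of class `rdna_pileup`: list with `target`, `ref`
#'   (per-position reference base) and `counts` (position x {A,C,G,T,del}
#'   integer matrix).
#' @export
build_pileup <- function(placements, readset, reference,
                         target = "rdna_unit", circular = NULL) {
  circular <- circular %||% isTRUE(attr(placements, "circular")[[target]])
  p <- placements[placements$target == target, , drop = FALSE]
  seqs <- oriented_sequences(p, readset)
  m <- cpp_pileup(reference, p$start, seqs, circular)
  counts <- cbind(t(m), del = 0L)
  colnames(counts) <- c("A", "C", "G", "T", "del")
  structure(list(target = target,
                 ref = strsplit(reference, "")[[1]],
                 counts = counts),
            class = "rdna_pileup")
}

#' Construct a pileup from explicit counts
#'
#' Mainly for analysis of externally produced per-position base counts and
#' for worked examples.
#'
#' @param ref Character vector of reference bases.
#' @param counts Matrix (positions x A,C,G,T,del).
#' @param target Target name.
#' @export
pileup_from_counts <- function(ref, counts, target = "rdna_unit") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- c("A", "C", "G", "T", "del")[seq_len(ncol(counts))]
  if (!"del" %in% colnames(counts)) counts <- cbind(counts, del = 0L)
  stopifnot(nrow(counts) == length(ref))
  structure(list(target = target, ref = ref, counts = counts),
            class = "rdna_pileup")
}

#' @export
print.rdna_pileup <- function(x, ...) {
  cat(sprintf("Pileup on %s: %d positions, median depth %d\n",
              x$target, nrow(x$counts),
              stats::median(rowSums(x$counts))))
  invisible(x)
}

#' Export a pileup as TSV (pos, ref, A, C, G, T, del)
#' @param pileup An `rdna_pileup`.
#' @param path Output path.
#' @export
export_pileup <- function(pileup, path) {
  df <- data.frame(pos = seq_along(pileup$ref), ref = pileup$ref,
                   pileup$counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Export placements as minimal SAM
#'
#' Header plus the mandatory fields; flags encode strand and mate only.
#'
#' @param placements Placements from [map_reads()].
#' @param readset The corresponding read set.
#' @param path Output path.
#' @export
export_sam <- function(placements, readset, path) {
  lens <- attr(placements, "target_lengths")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  seqs <- oriented_sequences(placements, readset)
  flag <- 1L + ifelse(placements$mate == 1L, 64L, 128L) +
    ifelse(placements$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                 placements$name, flag, placements$target,
                 placements$start, placements$aln_len, seqs)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
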