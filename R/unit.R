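#' Annotation of the 45S rDNA unit
#'
#' Defines the coordinate layout of the ~10.5 kb 45S rDNA unit used as the
#' collapsed mapping reference. Coordinates are 1-based inclusive; the 18S
#' and 25S rRNA genes default to 1841-3644 and 4264-7639. The 5.8S/ITS
#' coordinates are not published for this reference and default to a 164 bp
#' 5.8S centered between the 18S end and 25S start. Two "slots" mark where
#' the 5'ETS and 3'ETS variant sequences (VARA and VAR1 in the reference)
#' are embedded.
#'
#' @param unit_length Total unit length in bp (default 10500; includes the
#'   intergenic spacer).
#' @param intervals Named list of 1-based inclusive `c(start, end)`
#'   intervals: ETS5, 18S, ITS1, 5.8S, ITS2, 25S, ETS3. Must be disjoint,
#'   ordered and within the unit.
#' @param slots Named list with `ets5` and `ets3` intervals where the
#'   variant realizations sit inside the ETS regions.
#' @return An object of class `rdna_annotation`.
#' @export
unit_annotation <- function(unit_length = 10500L,
                            intervals = list(
                              ETS5   = c(1L, 1840L),
                              `18S`  = c(1841L, 3644L),
                              ITS1   = c(3645L, 3871L),
                              `5.8S` = c(3872L, 4035L),
                              ITS2   = c(4036L, 4263L),
                              `25S`  = c(4264L, 7639L),
                              ETS3   = c(7640L, 10500L)),
                            slots = list(ets5 = c(401L, 1660L),
                                         ets3 = c(7700L, 8183L))) {
  ann <- structure(list(unit_length = as.integer(unit_length),
                        intervals = lapply(intervals, as.integer),
                        slots = lapply(slots, as.integer)),
                   class = "rdna_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  iv <- ann$intervals
  m <- do.call(rbind, iv)
  if (any(m < 1L) || any(m > ann$unit_length))
    stop("annotation intervals must lie within [1, unit_length]",
         call. = FALSE)
  if (any(m[, 2] < m[, 1]))
    stop("annotation intervals must have start <= end", call. = FALSE)
  o <- order(m[, 1])
  if (any(m[o, 1][-1] <= m[o, 2][-nrow(m)]))
    stop("annotation intervals overlap", call. = FALSE)
  invisible(ann)
}

#' Per-position region labels along the unit
#'
#' @param annotation An `rdna_annotation`.
#' @param collapse If `TRUE`, collapse ETS5/ETS3 to "ETS" and ITS1/ITS2 to
#'   "ITS" (the display classes used for polymorphism tracks).
#' @return Character vector of length `unit_length`; positions outside all
#'   intervals (none in the default layout) are labeled "ETS".
#' @export
annotate_positions <- function(annotation, collapse = FALSE) {
  validate_annotation(annotation)
  lab <- rep("ETS", annotation$unit_length)
  for (nm in names(annotation$intervals)) {
    iv <- annotation$intervals[[nm]]
    lab[iv[1]:iv[2]] <- nm
  }
  if (collapse) {
    lab[lab %in% c("ETS5", "ETS3")] <- "ETS"
    lab[lab %in% c("ITS1", "ITS2")] <- "ITS"
  }
  lab
}

#' Build the annotated 45S rDNA reference unit
#'
#' The reference unit carries the most abundant Col-0 variants: VARA in the
#' 5'ETS slot and VAR1 in the 3'ETS slot. All other positions are seeded
#' random sequence, so two calls with the same seed are identical. The 25S
#' region embeds the P7/P8 control primer sites at its boundaries.
#'
#' @param catalog An `rdna_catalog`.
#' @param annotation An `rdna_annotation` (defaults to [unit_annotation()]).
#' @param seed Integer seed.
#' @return Object of class `rdna_unit`: list with `sequence`, `annotation`,
#'   `seed` and the embedded `ets5_variant`/`ets3_variant` ids.
#' @export
make_reference_unit <- function(catalog, annotation = unit_annotation(),
                                seed = 1L) {
  validate_annotation(annotation)
  vara <- build_variant_sequence(catalog, "VARA", seed)
  var1 <- build_variant_sequence(catalog, "VAR1", seed)
  s5 <- annotation$slots$ets5
  s3 <- annotation$slots$ets3
  if (interval_length(s5) != nchar(vara))
    stop("ets5 slot length (", interval_length(s5),
         ") does not match the VARA realization (", nchar(vara), ")",
         call. = FALSE)
  if (interval_length(s3) != nchar(var1))
    stop("ets3 slot length (", interval_length(s3),
         ") does not match the VAR1 realization (", nchar(var1), ")",
         call. = FALSE)
  seq <- with_seed(sub_seed(seed, "unit_backdrop"),
                   random_dna(annotation$unit_length))
  substr(seq, s5[1], s5[2]) <- vara
  substr(seq, s3[1], s3[2]) <- var1
  iv25 <- annotation$intervals$`25S`
  p7 <- catalog$primers$P7P8$forward
  p8rc <- revcomp(catalog$primers$P7P8$reverse)
  substr(seq, iv25[1], iv25[1] + nchar(p7) - 1L) <- p7
  substr(seq, iv25[2] - nchar(p8rc) + 1L, iv25[2]) <- p8rc
  structure(list(sequence = seq, annotation = annotation, seed = seed,
                 ets5_variant = "VARA", ets3_variant = "VAR1"),
            class = "rdna_unit")
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat(sprintf("45S rDNA reference unit: %d bp (%s in 5'ETS, %s in 3'ETS)\n",
              nchar(x$sequence), x$ets5_variant, x$ets3_variant))
  for (nm in names(x$annotation$intervals)) {
    iv <- x$annotation$intervals[[nm]]
    cat(sprintf("  %-5s %6d-%6d\n", nm, iv[1], iv[2]))
  }
  invisible(x)
}

#' Export the unit as FASTA plus a BED annotation
#'
#' BED files on disk are 0-based half-open; internal coordinates are
#' 1-based inclusive.
#'
#' @param unit An `rdna_unit`.
#' @param fasta_path,bed_path Output paths.
#' @param name Sequence record name.
#' @export
export_unit <- function(unit, fasta_path, bed_path = NULL,
                        name = "rdna_unit") {
  dss <- Biostrings::DNAStringSet(unit$sequence)
  names(dss) <- name
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(bed_path)) {
    iv <- unit$annotation$intervals
    bed <- data.frame(chrom = name,
                      start = vapply(iv, function(v) v[1] - 1L, 1L),
                      end = vapply(iv, function(v) v[2], 1L),
                      name = names(iv))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

# Splice a unit spec (ETS variant choice + edits) into the reference unit.
# Returns the realized unit sequence for one rDNA copy.
build_unit_sequence <- function(unit, catalog, unit_spec) {
  ann <- unit$annotation
  s5 <- ann$slots$ets5
  s3 <- ann$slots$ets3
  seq5 <- if (identical(unit_spec$ets5, unit$ets5_variant)) NULL else
    build_variant_sequence(catalog, unit_spec$ets5, unit$seed)
  seq3 <- if (identical(unit_spec$ets3, unit$ets3_variant)) NULL else
    build_variant_sequence(catalog, unit_spec$ets3, unit$seed)
  ref <- unit$sequence
  pre   <- substr(ref, 1L, s5[1] - 1L)
  mid   <- substr(ref, s5[2] + 1L, s3[1] - 1L)
  post  <- substr(ref, s3[2] + 1L, nchar(ref))
  v5 <- seq5 %||% substr(ref, s5[1], s5[2])
  v3 <- seq3 %||% substr(ref, s3[1], s3[2])
  seq <- paste0(pre, v5, mid, v3, post)
  d5 <- nchar(v5) - interval_length(s5)
  d3 <- nchar(v3) - interval_length(s3)
  # SNP/indel positions are reference-unit coordinates; shift across the
  # variant slots. Edits inside a slot are rejected.
  shift_pos <- function(pos) {
    if (any(pos >= s5[1] & pos <= s5[2]) || any(pos >= s3[1] & pos <= s3[2]))
      stop("unit edits must not fall inside ETS variant slots", call. = FALSE)
    pos + ifelse(pos > s3[2], d5 + d3, ifelse(pos > s5[2], d5, 0L))
  }
  snps <- unit_spec$snp_edits
  if (!is.null(snps) && nrow(snps)) {
    if (any(snps$pos < 1L | snps$pos > nchar(ref)))
      stop("SNP edit positions outside unit", call. = FALSE)
    at <- shift_pos(snps$pos)
    for (i in seq_along(at)) substr(seq, at[i], at[i]) <- snps$alt[i]
  }
  indels <- unit_spec$indel_edits
  if (!is.null(indels) && length(indels)) {
    at <- shift_pos(vapply(indels, function(e) as.integer(e$pos), 1L))
    ord <- order(at, decreasing = TRUE)
    for (i in ord) {
      e <- indels[[i]]
      if (identical(e$op, "ins")) {
        seq <- paste0(substr(seq, 1L, at[i]), e$bases,
                      substr(seq, at[i] + 1L, nchar(seq)))
      } else if (identical(e$op, "del")) {
        seq <- paste0(substr(seq, 1L, at[i] - 1L),
                      substr(seq, at[i] + e$n, nchar(seq)))
      } else stop("unknown indel op: ", e$op %||% "<missing>", call. = FALSE)
    }
  }
  seq
}
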