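#' Specify one class of rDNA unit within an individual
#'
#' @param ets5,ets3 Variant identifiers for the 5' and 3' External
#'   Transcribed Spacers (defaults: the Col-0 reference variants VARA and
#'   VAR1).
#' @param snp_edits Optional data.frame with columns `pos` (1-based
#'   reference-unit coordinate) and `alt` (alternative base).
#' @param indel_edits Optional list of edits,
#'   `list(op = "ins", pos =, bases =)` or `list(op = "del", pos =, n =)`.
#' @param label Optional label used in truth tables.
#' @return A list of class `rdna_unit_spec`.
#' @export
unit_spec <- function(ets5 = "VARA", ets3 = "VAR1", snp_edits = NULL,
                      indel_edits = NULL, label = NULL) {
  structure(list(ets5 = ets5, ets3 = ets3, snp_edits = snp_edits,
                 indel_edits = indel_edits,
                 label = label %||% paste(ets5, ets3, sep = "/")),
            class = "rdna_unit_spec")
}

#' Specify a simulated genome
#'
#' A genome is a single-copy backbone plus a head-to-tail tandem array of
#' 45S rDNA units. The mixture gives the within-individual proportions of
#' unit classes (ETS variant combinations and polymorphisms); per-copy
#' classes are drawn multinomially.
#'
#' @param copy_number Integer >= 1; number of rDNA units in the array
#'   (Col-0 reference: ~800 per haploid genome).
#' @param mixture List of components, each
#'   `list(spec = unit_spec(...), prop = <proportion>)`; proportions must
#'   sum to 1. Default: a pure reference-unit array.
#' @param backbone_length Length of the single-copy backbone (default 1e6;
#'   a 10 Mb backbone mirrors the "first 10 Mb of chromosome 3" baseline).
#' @param seed Integer seed for all stochastic draws.
#' @return A list of class `rdna_genome_spec`.
#' @export
genome_spec <- function(copy_number, mixture = NULL,
                        backbone_length = 1000000L, seed = 1L) {
  if (!is.numeric(copy_number) || copy_number < 1)
    stop("copy_number must be an integer >= 1", call. = FALSE)
  if (is.null(mixture))
    mixture <- list(list(spec = unit_spec(), prop = 1.0))
  props <- vapply(mixture, function(m) m$prop, 1.0)
  if (any(props < 0) || any(props > 1) || abs(sum(props) - 1) > 1e-9)
    stop("mixture proportions must lie in [0,1] and sum to 1", call. = FALSE)
  structure(list(copy_number = as.integer(copy_number), mixture = mixture,
                 backbone_length = as.integer(backbone_length),
                 seed = as.integer(seed)),
            class = "rdna_genome_spec")
}

#' Simulate a genome with a tandem 45S rDNA array
#'
#' Draws a unit class for every rDNA copy from the mixture, realizes the
#' head-to-tail array and a random single-copy backbone, and records the
#' full per-copy truth table.
#'
#' @param spec An `rdna_genome_spec`.
#' @param catalog An `rdna_catalog` (default catalog if `NULL`).
#' @param unit Optional `rdna_unit` reference; built from `spec$seed` when
#'   missing.
#' @param realize If `FALSE`, skip sequence realization and return only the
#'   truth table (useful for truth-mode genotyping at large copy numbers).
#' @return Object of class `rdna_genome`: list with `backbone`, `unit`
#'   (reference unit), `array` (realized array sequence or `NULL`),
#'   `copies` (truth table: copy, component, label, length, array_start)
#'   and `spec`.
#' @export
make_genome <- function(spec, catalog = NULL, unit = NULL, realize = TRUE) {
  stopifnot(inherits(spec, "rdna_genome_spec"))
  catalog <- catalog %||% load_catalog()
  unit <- unit %||% make_reference_unit(catalog, seed = spec$seed)
  k <- length(spec$mixture)
  props <- vapply(spec$mixture, function(m) m$prop, 1.0)
  assign_idx <- with_seed(sub_seed(spec$seed, "copy_assignment"),
    sample.int(k, spec$copy_number, replace = TRUE, prob = props))
  unit_seqs <- if (realize)
    vapply(spec$mixture, function(m)
      build_unit_sequence(unit, catalog, m$spec), "")
  else rep(NA_character_, k)
  lens <- if (realize) nchar(unit_seqs) else
    rep(nchar(unit$sequence), k)  # nominal lengths when not realized
  copy_lens <- lens[assign_idx]
  labels <- vapply(spec$mixture, function(m) m$spec$label, "")
  copies <- data.frame(
    copy = seq_len(spec$copy_number),
    component = assign_idx,
    label = labels[assign_idx],
    length = copy_lens,
    array_start = cumsum(c(0L, copy_lens[-length(copy_lens)])) + 1L)
  array_seq <- if (realize)
    paste(unit_seqs[assign_idx], collapse = "") else NULL
  backbone <- if (realize)
    with_seed(sub_seed(spec$seed, "backbone"),
              random_dna(spec$backbone_length)) else NULL
  structure(list(backbone = backbone, unit = unit, array = array_seq,
                 unit_seqs = unit_seqs, copies = copies, spec = spec,
                 catalog = catalog),
            class = "rdna_genome")
}

#' @export
print.rdna_genome <- function(x, ...) {
  cat(sprintf("Simulated rDNA genome: %d copies, %s backbone%s\n",
              x$spec$copy_number,
              format(x$spec$backbone_length, big.mark = ","),
              if (is.null(x$array)) " (truth table only)" else ""))
  tab <- table(x$copies$label)
  for (nm in names(tab))
    cat(sprintf("  %-12s %6d copies\n", nm, tab[[nm]]))
  invisible(x)
}

#' Export a simulated genome as FASTA plus truth TSV
#' @param genome An `rdna_genome` (realized).
#' @param fasta_path,truth_path Output paths.
#' @export
export_genome <- function(genome, fasta_path, truth_path = NULL) {
  if (is.null(genome$array))
    stop("genome was built with realize = FALSE", call. = FALSE)
  dss <- Biostrings::DNAStringSet(c(backbone = genome$backbone,
                                    rdna_array = genome$array))
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(truth_path)) write_tsv(genome$copies, truth_path)
  invisible(fasta_path)
}
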