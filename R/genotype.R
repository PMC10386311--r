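#' Variant abundance patterns (in-silico gel lanes)
#'
#' A band pattern is the in-silico analogue of a PCR genotyping lane: the
#' set of ETS variants detected in one individual with their relative
#' abundances. Variants below the detection threshold are absent from the
#' pattern (PCR detection limit; this is how a sub-detectable variant such
#' as VAR5 drops out) and the retained proportions are renormalized to 1.
#'
#' Truth mode reads proportions straight from a simulated genome's
#' per-copy truth table; depth mode recovers them from reads via a panel
#' of context-flanked variant templates (see [band_pattern_depth()]).
#'
#' @param source An `rdna_genome` (truth mode) or `rdna_reads` (depth
#'   mode).
#' @param region `"ETS3"` or `"ETS5"`.
#' @param detection_threshold Minimum detectable proportion (default
#'   0.05).
#' @param ... Passed on to [band_pattern_depth()] in depth mode.
#' @return Object of class `rdna_band_pattern`.
#' @export
band_pattern <- function(source, region, detection_threshold = 0.05, ...) {
  if (inherits(source, "rdna_genome"))
    band_pattern_truth(source, region, detection_threshold)
  else if (inherits(source, "rdna_reads"))
    band_pattern_depth(source, region = region,
                       detection_threshold = detection_threshold, ...)
  else stop("source must be an rdna_genome or rdna_reads", call. = FALSE)
}

#' Construct a band pattern from abundances
#'
#' Applies the detection threshold (variants strictly below it are absent)
#' and renormalizes the retained proportions.
#'
#' @param abundances Named numeric vector of variant proportions.
#' @param region `"ETS3"` or `"ETS5"`.
#' @param detection_threshold Minimum detectable proportion.
#' @param id Individual identifier.
#' @return An `rdna_band_pattern`.
#' @export
new_band_pattern <- function(abundances, region, detection_threshold = 0.05,
                             id = "individual") {
  abundances <- abundances[abundances >= detection_threshold]
  if (!length(abundances))
    stop("no variant reaches the detection threshold", call. = FALSE)
  abundances <- abundances / sum(abundances)
  structure(list(region = region,
                 abundances = abundances[order(names(abundances))],
                 detection_threshold = detection_threshold, id = id),
            class = "rdna_band_pattern")
}

#' @export
print.rdna_band_pattern <- function(x, ...) {
  cat(sprintf("%s band pattern (%s): %s\n", x$region, x$id,
              paste(sprintf("%s=%.2f", names(x$abundances), x$abundances),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname band_pattern
#' @param genome An `rdna_genome`.
#' @param id Individual identifier attached to the pattern.
#' @export
band_pattern_truth <- function(genome, region,
                               detection_threshold = 0.05,
                               id = "individual") {
  if (!nrow(genome$copies)) stop("empty truth table", call. = FALSE)
  field <- if (region == "ETS3") "ets3" else if (region == "ETS5") "ets5"
    else stop("region must be ETS3 or ETS5", call. = FALSE)
  variant_of <- vapply(genome$spec$mixture, function(m) m$spec[[field]], "")
  v <- variant_of[genome$copies$component]
  tab <- table(v) / length(v)
  new_band_pattern(stats::setNames(as.numeric(tab), names(tab)),
                   region, detection_threshold, id)
}

#' Depth-mode band pattern from reads
#'
#' Maps reads against a panel of variant templates (each variant's
#' realized sequence flanked by its unit context), keeps uniquely placed
#' reads, and converts per-template unique read counts into abundances
#' with an effective-length correction: counts are divided by the number
#' of read-length start positions whose substring is unique within the
#' panel. The correction is needed because the indel variants are nested
#' and share most of their sequence; only junction-spanning reads are
#' informative, and the informative territory differs between variants.
#'
#' @param readset An `rdna_reads` object.
#' @param region `"ETS3"` or `"ETS5"`.
#' @param catalog An `rdna_catalog` (default catalog if `NULL`).
#' @param unit The `rdna_unit` providing flanking context (rebuilt from
#'   `seed` when `NULL`).
#' @param detection_threshold Minimum detectable proportion.
#' @param exclude Variants excluded from the panel (default `"VAR5"`,
#'   which has no unique junction and is undetectable by PCR).
#' @param context Flanking context length in bp (default 300).
#' @param k,max_mm Mapper parameters (see [map_reads()]).
#' @param seed Seed used when rebuilding the unit.
#' @param id Individual identifier.
#' @export
band_pattern_depth <- function(readset, region, catalog = NULL,
                               unit = NULL, detection_threshold = 0.05,
                               exclude = "VAR5", context = 300L,
                               k = 31L, max_mm = 5L, seed = 1L,
                               id = "individual") {
  catalog <- catalog %||% load_catalog()
  unit <- unit %||% make_reference_unit(catalog, seed = seed)
  panel <- variant_panel(catalog, unit, region, exclude, context)
  read_len <- readset$params$read_len %||% nchar(readset$reads$seq1[1])
  u <- panel_unique_positions(panel, read_len)
  if (any(u == 0))
    stop("panel template(s) without unique read-length positions: ",
         paste(names(u)[u == 0], collapse = ", "), call. = FALSE)
  pl <- map_reads(readset, panel, circular = FALSE, k = k,
                  max_mm = max_mm, discard_ambiguous = TRUE)
  n <- table(factor(pl$target, levels = names(panel)))
  ab <- as.numeric(n) / u
  if (sum(ab) == 0)
    stop("no reads mapped to the variant panel", call. = FALSE)
  ab <- ab / sum(ab)
  new_band_pattern(stats::setNames(ab, names(panel)), region,
                   detection_threshold, id)
}

# Context-flanked variant templates for one ETS region.
variant_panel <- function(catalog, unit, region, exclude = character(),
                          context = 300L) {
  slot <- if (region == "ETS3") unit$annotation$slots$ets3 else
    unit$annotation$slots$ets5
  left <- substr(unit$sequence, max(1L, slot[1] - context), slot[1] - 1L)
  right <- substr(unit$sequence, slot[2] + 1L,
                  min(nchar(unit$sequence), slot[2] + context))
  ids <- names(catalog$variants)[vapply(catalog$variants, function(v)
    v$region == region, TRUE)]
  ids <- setdiff(ids, exclude)
  tpl <- vapply(ids, function(id)
    paste0(left, build_variant_sequence(catalog, id, unit$seed), right), "")
  tpl
}

# Number of start positions per template whose read-length substring is
# unique across the whole panel.
panel_unique_positions <- function(panel, read_len) {
  words <- lapply(panel, function(s) {
    n <- nchar(s) - read_len + 1L
    if (n < 1L) character() else substring(s, 1:n, read_len:(n + read_len - 1L))
  })
  all_words <- unlist(words, use.names = FALSE)
  dup <- all_words[duplicated(all_words)]
  vapply(words, function(w) sum(!w %in% dup), 1L)
}

# ---- genotype classification ---------------------------------------------

# Canonical pairwise relation tiers. For each unordered pair of detected
# variants the ratio r = high/low falls in exactly one tier:
#   r <  dominance_ratio              -> "equal"  (a, b alphabetical)
#   dominance_ratio <= r < rare_ratio -> "dominant" (a = the abundant one)
#   r >= rare_ratio                   -> "rare"     (a = the abundant one)
pattern_tiers <- function(abund, dominance_ratio, rare_ratio) {
  ids <- sort(names(abund))
  if (length(ids) < 2) return(character())
  out <- character()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      a <- ids[i]; b <- ids[j]
      r <- abund[[a]] / abund[[b]]
      hi <- if (r >= 1) a else b
      lo <- if (r >= 1) b else a
      rr <- max(r, 1 / r)
      out <- c(out, if (rr < dominance_ratio) paste(a, b, "equal", sep = "|")
               else if (rr < rare_ratio) paste(hi, lo, "dominant", sep = "|")
               else paste(hi, lo, "rare", sep = "|"))
    }
  }
  sort(out)
}

def_tiers <- function(def) {
  rel <- def$relations
  if (!nrow(rel)) return(character())
  out <- vapply(seq_len(nrow(rel)), function(i) {
    if (rel$tier[i] == "equal") {
      p <- sort(c(rel$a[i], rel$b[i]))
      paste(p[1], p[2], "equal", sep = "|")
    } else paste(rel$a[i], rel$b[i], rel$tier[i], sep = "|")
  }, "")
  sort(out)
}

classify_pattern <- function(pattern, catalog, region, dominance_ratio,
                             rare_ratio, drop = character()) {
  if (!identical(pattern$region, region))
    stop("pattern region is ", pattern$region, "; expected ", region,
         call. = FALSE)
  abund <- pattern$abundances
  abund <- abund[setdiff(names(abund), drop)]
  if (!length(abund))
    return(new_genotype_call("unclassified", region, NULL, pattern,
                             "no variants left after exclusions"))
  abund <- abund / sum(abund)
  tiers <- pattern_tiers(abund, dominance_ratio, rare_ratio)
  detected <- sort(names(abund))
  defs <- Filter(function(g) g$region == region, catalog$genotypes)
  hits <- Filter(function(g) identical(g$required, detected) &&
                   identical(def_tiers(g), tiers), defs)
  if (length(hits) == 1L)
    new_genotype_call(hits[[1]]$label, region, hits[[1]], pattern, NULL)
  else
    new_genotype_call("unclassified", region, NULL, pattern,
                      sprintf("%d matching definitions for {%s} with tiers {%s}",
                              length(hits), paste(detected, collapse = ","),
                              paste(tiers, collapse = "; ")))
}

new_genotype_call <- function(label, region, matched, evidence,
                              diagnostics) {
  structure(list(label = label, region = region, matched = matched,
                 evidence = evidence, diagnostics = diagnostics,
                 individual = evidence$id %||% "individual"),
            class = "rdna_genotype_call")
}

#' @export
print.rdna_genotype_call <- function(x, ...) {
  cat(sprintf("%s genotype call for %s: %s\n", x$region, x$individual,
              x$label))
  if (!is.null(x$diagnostics)) cat("  ", x$diagnostics, "\n")
  invisible(x)
}

#' Classify a 3'ETS band pattern into a 3R genotype
#'
#' VAR4 is removed before matching (it is too variable and too rare to
#' define genotypes). Two variants are "equivalent" when their abundance
#' ratio is below `dominance_ratio`, the larger "dominates" up to
#' `rare_ratio`, beyond which the smaller one is a trace ("rare")
#' component. The detected variant set and relation tiers are matched
#' against the catalog definitions; exactly one match yields its label,
#' anything else is "unclassified" with diagnostics.
#'
#' @param pattern An `rdna_band_pattern` with region ETS3.
#' @param catalog An `rdna_catalog`.
#' @param dominance_ratio Ratio separating "most abundant" from
#'   "equivalent" (default 2).
#' @param rare_ratio Ratio beyond which the minor variant is "rare"
#'   (default 10).
#' @return An `rdna_genotype_call`.
#' @examples
#' cat45 <- load_catalog()
#' p <- new_band_pattern(c(VAR1 = 0.5, VAR2 = 0.5), "ETS3", 0.05)
#' classify_3R(p, cat45)$label  # "3R4.1"
#' @export
classify_3R <- function(pattern, catalog, dominance_ratio = 2,
                        rare_ratio = 10) {
  classify_pattern(pattern, catalog, "ETS3", dominance_ratio, rare_ratio,
                   drop = "VAR4")
}

#' Classify a 5'ETS band pattern into a 5R genotype
#'
#' @inheritParams classify_3R
#' @param pattern An `rdna_band_pattern` with region ETS5.
#' @return An `rdna_genotype_call`.
#' @export
classify_5R <- function(pattern, catalog, dominance_ratio = 2,
                        rare_ratio = 10) {
  classify_pattern(pattern, catalog, "ETS5", dominance_ratio, rare_ratio)
}

#' Synthesize a band pattern satisfying a genotype definition
#'
#' Builds abundances realizing each relation tier at a representative
#' ratio (1 for equal, 3 for dominant, 20 for rare); classifying the
#' result recovers the definition's label for every shipped definition.
#'
#' @param def A genotype definition from the catalog.
#' @return An `rdna_band_pattern`.
#' @export
synthesize_band_pattern <- function(def) {
  ids <- def$required
  val <- stats::setNames(rep(NA_real_, length(ids)), ids)
  val[1] <- 1
  mult <- c(equal = 1, dominant = 3, rare = 20)
  rel <- def$relations
  for (pass in seq_len(length(ids) + 1L)) {
    for (i in seq_len(nrow(rel))) {
      a <- rel$a[i]; b <- rel$b[i]; m <- mult[[rel$tier[i]]]
      if (!is.na(val[a]) && is.na(val[b])) val[b] <- val[a] / m
      if (is.na(val[a]) && !is.na(val[b])) val[a] <- val[b] * m
    }
  }
  val[is.na(val)] <- 1
  new_band_pattern(val / sum(val), def$region, detection_threshold = 0,
                   id = def$label)
}
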