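#' Per-position alternative-allele frequency
#'
#' The alternative-allele frequency at a position is the sum of
#' non-reference base counts plus deletion counts divided by the total
#' count. Positions below `min_depth` are missing (`NA`), not zero: a 5%
#' frequency is not measurable from a handful of reads.
#'
#' @param pileup An `rdna_pileup`.
#' @param position 1-based position(s); defaults to all positions.
#' @param min_depth Minimum evaluable depth (default 10).
#' @return Numeric vector of frequencies in `[0, 1]` with `NA` at
#'   low-depth positions.
#' @examples
#' p <- pileup_from_counts("C", matrix(c(25, 60, 15, 0, 0), 1,
#'                         dimnames = list(NULL, c("A","C","G","T","del"))))
#' alt_allele_freq(p)  # (25 + 15) / 100 = 0.4
#' @export
alt_allele_freq <- function(pileup, position = NULL, min_depth = 10L) {
  counts <- pileup$counts
  position <- position %||% seq_len(nrow(counts))
  cnt <- counts[position, , drop = FALSE]
  tot <- rowSums(cnt)
  ref_idx <- match(pileup$ref[position], colnames(counts))
  ref_cnt <- cnt[cbind(seq_along(position), ref_idx)]
  f <- (tot - ref_cnt) / tot
  f[tot < min_depth] <- NA_real_
  unname(f)
}

#' Within-individual allele profile with the >5% flagging rule
#'
#' Computes per-position alternative-allele frequencies and flags
#' positions where the alternative alleles exceed `threshold` of the
#' individual's rRNA gene copies. The threshold is strict: a frequency of
#' exactly 0.05 is not flagged.
#'
#' @param pileup An `rdna_pileup` over the rDNA unit.
#' @param id Individual identifier.
#' @param threshold Flagging threshold (default 0.05).
#' @param min_depth Minimum evaluable depth (default 10).
#' @param annotation Optional `rdna_annotation` used to attach region
#'   labels.
#' @return Object of class `rdna_allele_profile`: data.frame (pos, region,
#'   alt_freq, flag) with the id and threshold as attributes.
#' @export
allele_profile <- function(pileup, id = "individual", threshold = 0.05,
                           min_depth = 10L, annotation = NULL) {
  f <- alt_allele_freq(pileup, min_depth = min_depth)
  region <- if (is.null(annotation)) NA_character_ else
    annotate_positions(annotation, collapse = TRUE)[seq_along(f)]
  out <- data.frame(pos = seq_along(f), region = region, alt_freq = f,
                    flag = !is.na(f) & f > threshold)
  attr(out, "id") <- id
  attr(out, "threshold") <- threshold
  class(out) <- c("rdna_allele_profile", "data.frame")
  out
}

#' Proportion of flagged individuals at a position
#'
#' @param profiles List of `rdna_allele_profile` objects over the same
#'   unit.
#' @param position 1-based position(s); defaults to all.
#' @return Proportion of flagged individuals among those with a
#'   non-missing value; `NA` where every individual is missing.
#' @export
cohort_proportion <- function(profiles, position = NULL) {
  stopifnot(length(profiles) >= 1)
  flags <- do.call(cbind, lapply(profiles, function(p) p$flag))
  miss <- do.call(cbind, lapply(profiles, function(p) is.na(p$alt_freq)))
  flags[miss] <- NA
  position <- position %||% seq_len(nrow(flags))
  res <- rowMeans(flags[position, , drop = FALSE], na.rm = TRUE)
  res[rowSums(!miss[position, , drop = FALSE]) == 0] <- NA_real_
  unname(res)
}

#' Cohort polymorphism track with region annotation
#'
#' @param profiles List of `rdna_allele_profile` objects.
#' @param annotation An `rdna_annotation`.
#' @return data.frame (pos, region, proportion) -- the plot-ready track of
#'   the proportion of individuals with an alternative allele along the
#'   unit.
#' @export
cohort_profile <- function(profiles, annotation) {
  prop <- cohort_proportion(profiles)
  data.frame(pos = seq_along(prop),
             region = annotate_positions(annotation,
                                         collapse = TRUE)[seq_along(prop)],
             proportion = prop)
}

#' Per-group polymorphism tracks and group-specific positions
#'
#' Splits the cohort by a grouping (e.g. sea level versus mid/high
#' altitude), computes one proportion track per group and reports
#' positions where exactly one group shows alternative alleles.
#'
#' @param profiles List of `rdna_allele_profile` objects.
#' @param grouping Character vector: group of each profile (recycling not
#'   allowed; every individual needs a group).
#' @param annotation Optional annotation for region labels.
#' @return List with `tracks` (long data.frame: pos, region, group,
#'   proportion) and `group_specific` (data.frame: pos, group for
#'   positions polymorphic in exactly one group).
#' @export
group_compare <- function(profiles, grouping, annotation = NULL) {
  if (length(grouping) != length(profiles))
    stop("grouping must assign a group to every individual", call. = FALSE)
  groups <- if (is.factor(grouping)) levels(grouping) else unique(grouping)
  grouping <- as.character(grouping)
  if (any(table(factor(grouping, levels = groups)) == 0))
    stop("empty group: every group must contain at least one individual",
         call. = FALSE)
  region <- if (is.null(annotation)) NA_character_ else
    annotate_positions(annotation, collapse = TRUE)
  tracks <- do.call(rbind, lapply(groups, function(g) {
    prop <- cohort_proportion(profiles[grouping == g])
    data.frame(pos = seq_along(prop),
               region = region[seq_along(prop)],
               group = g, proportion = prop)
  }))
  wide <- do.call(cbind, lapply(groups, function(g)
    tracks$proportion[tracks$group == g]))
  colnames(wide) <- groups
  pos_mat <- !is.na(wide) & wide > 0
  nz <- rowSums(pos_mat)
  sp <- which(nz == 1L)
  group_specific <- if (length(sp))
    data.frame(pos = sp,
               group = groups[apply(pos_mat[sp, , drop = FALSE], 1, which)])
  else data.frame(pos = integer(), group = character())
  list(tracks = tracks, group_specific = group_specific)
}

#' Export per-individual and cohort profiles as TSV
#' @param profile An `rdna_allele_profile`.
#' @param path Output path.
#' @export
export_profile <- function(profile, path) {
  write_tsv(as.data.frame(profile), path)
}
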