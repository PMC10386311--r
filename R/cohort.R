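#' Build or validate a sample sheet
#'
#' Individuals follow the PO naming scheme: two letters, a two-digit site
#' number and one letter (e.g. "PO10A" belongs to site PO10). The site can
#' be given explicitly or parsed from the id.
#'
#' @param id Character vector of unique individual identifiers.
#' @param site Optional site of each individual; parsed from the id when
#'   missing.
#' @param locality,altitude Optional per-individual locality labels and
#'   altitudes (meters, >= 0).
#' @return data.frame (id, site, locality, altitude) of class
#'   `rdna_sample_sheet`.
#' @export
sample_sheet <- function(id, site = NULL, locality = NA_character_,
                         altitude = NA_real_) {
  if (anyDuplicated(id)) stop("individual ids must be unique", call. = FALSE)
  if (is.null(site)) {
    m <- regmatches(id, regexec("^([A-Z]{2}[0-9]{2})[A-Z]+$", id))
    site <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
    if (anyNA(site))
      stop("cannot parse site from id(s): ",
           paste(id[is.na(site)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(altitude) & altitude < 0))
    stop("altitude must be >= 0", call. = FALSE)
  out <- data.frame(id = id, site = site, locality = locality,
                    altitude = altitude)
  class(out) <- c("rdna_sample_sheet", "data.frame")
  out
}

#' Read a sample sheet TSV (id, site, locality, altitude_m)
#' @param path TSV path.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  sample_sheet(df$id, site = df$site, locality = df$locality,
               altitude = df$altitude_m %||% df$altitude)
}

# Normalize a set of genotype calls to a data.frame.
calls_table <- function(calls) {
  if (is.data.frame(calls)) return(calls)
  do.call(rbind, lapply(calls, function(cl)
    data.frame(individual = cl$individual, region = cl$region,
               label = cl$label)))
}

#' Genotype frequency table
#'
#' Counts and percentages per genotype label, sorted by descending count
#' (ties by label). Percentages use round-half-up to one decimal, so that
#' 154/320 prints as 48.1 and 229/320 as 71.6.
#'
#' @param calls List of `rdna_genotype_call` objects or a data.frame with
#'   columns individual and label.
#' @param sheet Optional `rdna_sample_sheet`; every call's individual must
#'   appear in it.
#' @return data.frame (label, count, percent) with total n as attribute
#'   `n`.
#' @export
genotype_frequencies <- function(calls, sheet = NULL) {
  tab <- calls_table(calls)
  if (!is.null(sheet)) {
    unknown <- setdiff(tab$individual, sheet$id)
    if (length(unknown))
      stop("individual(s) not in sample sheet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(tab)
  cnt <- table(tab$label)
  df <- data.frame(label = names(cnt), count = as.integer(cnt))
  df <- df[order(-df$count, df$label), , drop = FALSE]
  df$percent <- round_half_up(100 * df$count / n, 1L)
  rownames(df) <- NULL
  attr(df, "n") <- n
  df
}

#' Per-site genotype composition (pie-chart data)
#'
#' @inheritParams genotype_frequencies
#' @param sheet An `rdna_sample_sheet` assigning each individual to a
#'   site.
#' @return Long data.frame (site, label, count, percent); sites without
#'   individuals are omitted with a message.
#' @export
site_composition <- function(calls, sheet) {
  tab <- calls_table(calls)
  unknown <- setdiff(tab$individual, sheet$id)
  if (length(unknown))
    stop("individual(s) not in sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tab$site <- sheet$site[match(tab$individual, sheet$id)]
  empty <- setdiff(unique(sheet$site), tab$site)
  if (length(empty))
    message("site(s) without genotyped individuals omitted: ",
            paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(split(tab, tab$site), function(s) {
    f <- genotype_frequencies(s)
    cbind(site = s$site[1], f)
  }))
  rownames(out) <- NULL
  out
}

#' Distinct-genotype diversity per group
#'
#' Number of distinct genotype labels per group of sites (e.g. sea level
#' versus altitude); "unclassified" calls are excluded from the counts.
#'
#' @inheritParams site_composition
#' @param grouping Named character vector mapping every site to a group.
#' @return Named integer vector: distinct genotype count per group (0 for
#'   empty groups).
#' @export
diversity_by_group <- function(calls, sheet, grouping) {
  tab <- calls_table(calls)
  tab$site <- sheet$site[match(tab$individual, sheet$id)]
  missing <- setdiff(unique(tab$site), names(grouping))
  if (length(missing))
    stop("grouping does not cover site(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab$group <- grouping[tab$site]
  tab <- tab[tab$label != "unclassified", , drop = FALSE]
  groups <- unique(unname(grouping))
  out <- vapply(groups, function(g)
    length(unique(tab$label[tab$group == g])), 1L)
  stats::setNames(out, groups)
}
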