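#' The 45S rDNA variant catalog
#'
#' The catalog is a declarative model of the 45S rDNA unit: repeat elements
#' with fixed lengths, External Transcribed Spacer (ETS) length variants as
#' ordered element lists, the diagnostic PCR primer pairs, and the 3R/5R
#' genotype definitions used to classify individuals from relative variant
#' abundances.
#'
#' The default catalog encodes the Arabidopsis thaliana Col-0 5'ETS variants
#' VARA (1260 bp P1/P3 amplicon) and VARB (950 bp; VARA minus one 310 bp C
#' repeat), the insertion-free 200 bp Brassica-type variant, the ~800 bp
#' A. cebennensis-like variant (VARB without the 150 bp D1a repeat), the
#' 3'ETS variants VAR1-VAR7, 12 3'ETS (3R) genotype definitions and 10 5'ETS
#' (5R) genotype definitions. Individual D and R repeat lengths are catalog
#' configuration values chosen so that the published amplicon totals hold;
#' they can be overridden through a plain-text (YAML) config.
#'
#' @param config Optional catalog configuration: a file path or a YAML
#'   string, as produced by [write_catalog()]. `NULL` loads built-in
#'   defaults.
#' @return An object of class `rdna_catalog`: a list with components
#'   `elements` (data.frame: name, length, class), `variants` (named list),
#'   `primers` (named list), `genotypes` (named list) and `annotation`
#'   (unit annotation, see [unit_annotation()]).
#' @examples
#' cat45 <- load_catalog()
#' variant_amplicon_length(cat45, "VARA", "P1P3")  # 1260
#' @export
load_catalog <- function(config = NULL) {
  if (is.null(config)) return(default_catalog())
  txt <- if (length(config) == 1L && file.exists(config))
    paste(readLines(config), collapse = "\n") else paste(config, collapse = "\n")
  raw <- tryCatch(yaml::yaml.load(txt),
                  error = function(e) stop("malformed catalog config: ",
                                           conditionMessage(e), call. = FALSE))
  catalog_from_list(raw)
}

# ---- default catalog ------------------------------------------------------

# Primer sequences for PCR genotyping: P1/P3 amplify the 5'ETS, P4/P5 the
# 3'ETS, P7/P8 an internal 25S control.
PRIMERS <- list(
  P1P3 = list(forward = "CTTTTCCGGGCACTTTTCCGG",
              reverse = "GTTCGGCGTATGAGTGGTGATCGG", region = "ETS5"),
  P4P5 = list(forward = "GACAGACTTGTCCAAAACGCCCACC",
              reverse = "CTGGTCGAGGAATCCTGGACGATT", region = "ETS3"),
  P7P8 = list(forward = "TGTTCACCCACCAATAGGGAA",
              reverse = "GGCGGTCCGAACGACCGTTCCGCC", region = "25S")
)

default_elements <- function() {
  el <- rbind(
    # 5'ETS: primer landing sites, five D repeats, C repeats (all C-class
    # sequences begin with the 59 bp C3 repeat), flanking spacers.
    data.frame(name = "P1site",    length = 21L,  class = "primer"),
    data.frame(name = "ets5_lead", length = 80L,  class = "spacer"),
    data.frame(name = "D1a",       length = 150L, class = "D"),
    data.frame(name = "D1b",       length = 66L,  class = "D"),
    data.frame(name = "D2a",       length = 55L,  class = "D"),
    data.frame(name = "D12",       length = 55L,  class = "D"),
    data.frame(name = "D2b",       length = 55L,  class = "D"),
    data.frame(name = "C1",        length = 310L, class = "C"),
    data.frame(name = "C2",        length = 310L, class = "C"),
    data.frame(name = "C-like",    length = 310L, class = "C"),
    data.frame(name = "C3",        length = 59L,  class = "C3"),
    data.frame(name = "ets5_tail", length = 75L,  class = "spacer"),
    data.frame(name = "P3rc",      length = 24L,  class = "primer"),
    # 3'ETS: R repeats and the two deletion-bearing spacers. `rdel` is the
    # segment removed by the deletion shared by VAR3-5 and VAR7; `post_r2b`
    # is the segment additionally deleted in VAR7 right after R2b.
    data.frame(name = "P4site",    length = 25L,  class = "primer"),
    data.frame(name = "ets3_lead", length = 40L,  class = "spacer"),
    data.frame(name = "R1",        length = 90L,  class = "R"),
    data.frame(name = "R2a",       length = 90L,  class = "R"),
    data.frame(name = "R2b",       length = 90L,  class = "R"),
    data.frame(name = "R3",        length = 90L,  class = "R"),
    data.frame(name = "R4",        length = 90L,  class = "R"),
    data.frame(name = "R5",        length = 90L,  class = "R"),
    data.frame(name = "post_r2b",  length = 30L,  class = "spacer"),
    data.frame(name = "rdel",      length = 54L,  class = "spacer"),
    data.frame(name = "ets3_tail", length = 41L,  class = "spacer"),
    data.frame(name = "P5rc",      length = 24L,  class = "primer")
  )
  rownames(el) <- NULL
  el
}

default_variants <- function() {
  v5 <- function(id, elements, species = "A. thaliana")
    list(id = id, region = "ETS5", elements = elements, species = species)
  v3 <- function(id, elements, species = "A. thaliana")
    list(id = id, region = "ETS3", elements = elements, species = species)
  d5 <- c("D1a", "D1b", "D2a", "D12", "D2b")
  list(
    VARA = v5("VARA", c("P1site", "ets5_lead", d5, "C1", "C2", "C3",
                        "ets5_tail", "P3rc")),
    VARB = v5("VARB", c("P1site", "ets5_lead", d5, "C-like", "C3",
                        "ets5_tail", "P3rc")),
    BRASSICA200 = v5("BRASSICA200", c("P1site", "ets5_lead", "ets5_tail",
                                      "P3rc"), species = "Brassica"),
    AC800 = v5("AC800", c("P1site", "ets5_lead", "D1b", "D2a", "D12", "D2b",
                          "C-like", "C3", "ets5_tail", "P3rc"),
               species = "A. cebennensis"),
    VAR1 = v3("VAR1", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "post_r2b", "rdel", "ets3_tail", "P5rc")),
    VAR2 = v3("VAR2", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "post_r2b", "R3", "rdel", "ets3_tail", "P5rc")),
    VAR3 = v3("VAR3", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "post_r2b", "R3", "ets3_tail", "P5rc")),
    VAR4 = v3("VAR4", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "post_r2b", "R3", "R4", "ets3_tail", "P5rc")),
    VAR5 = v3("VAR5", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "R3", "R4", "ets3_tail", "P5rc")),
    VAR6 = v3("VAR6", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "post_r2b", "R3", "R4", "rdel", "ets3_tail", "P5rc")),
    VAR7 = v3("VAR7", c("P4site", "ets3_lead", "R1", "R2a", "R2b",
                        "R3", "ets3_tail", "P5rc"))
  )
}

default_genotypes <- function() {
  gd <- function(label, region, required, relations = NULL) {
    rel <- if (is.null(relations))
      data.frame(a = character(), b = character(), tier = character())
    else do.call(rbind, lapply(relations, function(r)
      data.frame(a = r[1], b = r[2], tier = r[3])))
    list(label = label, region = region, required = sort(required),
         relations = rel)
  }
  # Relation tiers for an ordered pair (a, b): "equal" (ratio below the
  # dominance cutoff; a < b alphabetically), "dominant" (a at least
  # dominance_ratio times b, but below rare_ratio) and "rare" (a at least
  # rare_ratio times b, i.e. b is a trace component).
  list(
    # 3'ETS (3R) genotypes.  VAR4 is excluded from 3R definitions.
    `3R1`   = gd("3R1",   "ETS3", "VAR1"),
    `3R3`   = gd("3R3",   "ETS3", "VAR3"),
    `3R4.1` = gd("3R4.1", "ETS3", c("VAR1", "VAR2"),
                 list(c("VAR1", "VAR2", "equal"))),
    `3R4.2` = gd("3R4.2", "ETS3", c("VAR1", "VAR2"),
                 list(c("VAR1", "VAR2", "dominant"))),
    `3R4.3` = gd("3R4.3", "ETS3", c("VAR1", "VAR2"),
                 list(c("VAR2", "VAR1", "dominant"))),
    `3R5.1` = gd("3R5.1", "ETS3", c("VAR1", "VAR3"),
                 list(c("VAR1", "VAR3", "equal"))),
    `3R5.2` = gd("3R5.2", "ETS3", c("VAR1", "VAR3"),
                 list(c("VAR1", "VAR3", "dominant"))),
    `3R5.3` = gd("3R5.3", "ETS3", c("VAR1", "VAR3"),
                 list(c("VAR3", "VAR1", "dominant"))),
    # 3R6/3R7 are rare (<1%) and not described in detail; these
    # compositions are configurable placeholders.
    `3R6`   = gd("3R6",   "ETS3", c("VAR1", "VAR6"),
                 list(c("VAR1", "VAR6", "equal"))),
    `3R7`   = gd("3R7",   "ETS3", c("VAR1", "VAR6"),
                 list(c("VAR1", "VAR6", "dominant"))),
    # 3R8: VAR6 much less abundant than VAR1.
    `3R8`   = gd("3R8",   "ETS3", c("VAR1", "VAR6"),
                 list(c("VAR1", "VAR6", "rare"))),
    `3R9`   = gd("3R9",   "ETS3", c("VAR1", "VAR3", "VAR7"),
                 list(c("VAR1", "VAR3", "equal"),
                      c("VAR1", "VAR7", "equal"),
                      c("VAR3", "VAR7", "equal"))),
    # 5'ETS (5R) genotypes.
    `5R1`  = gd("5R1",  "ETS5", c("VARA", "VARB"),
                list(c("VARA", "VARB", "dominant"))),
    `5R2`  = gd("5R2",  "ETS5", c("VARA", "VARB"),
                list(c("VARA", "VARB", "equal"))),
    `5R3`  = gd("5R3",  "ETS5", c("VARA", "VARB"),
                list(c("VARB", "VARA", "dominant"))),
    `5R4`  = gd("5R4",  "ETS5", c("VARA", "VARB", "BRASSICA200"),
                list(c("BRASSICA200", "VARA", "equal"),
                     c("BRASSICA200", "VARB", "equal"),
                     c("VARA", "VARB", "equal"))),
    # 5R5-5R9 carry intermediate or longer variants; the text does not
    # enumerate their compositions, so these are configurable placeholders
    # built around the intermediate-length AC800-like variant.
    `5R5`  = gd("5R5",  "ETS5", c("VARA", "AC800"),
                list(c("VARA", "AC800", "dominant"))),
    `5R6`  = gd("5R6",  "ETS5", c("VARA", "AC800"),
                list(c("AC800", "VARA", "equal"))),
    `5R7`  = gd("5R7",  "ETS5", c("VARA", "VARB", "AC800"),
                list(c("VARA", "VARB", "dominant"),
                     c("VARA", "AC800", "dominant"),
                     c("AC800", "VARB", "equal"))),
    `5R8`  = gd("5R8",  "ETS5", c("VARA", "VARB", "AC800"),
                list(c("AC800", "VARA", "equal"),
                     c("AC800", "VARB", "equal"),
                     c("VARA", "VARB", "equal"))),
    `5R9`  = gd("5R9",  "ETS5", c("VARB", "AC800"),
                list(c("AC800", "VARB", "equal"))),
    `5R10` = gd("5R10", "ETS5", c("VARA", "VARB"),
                list(c("VARB", "VARA", "rare")))
  )
}

default_catalog <- function() {
  cat45 <- structure(list(
    elements = default_elements(),
    variants = default_variants(),
    primers = PRIMERS,
    genotypes = default_genotypes(),
    annotation = unit_annotation()
  ), class = "rdna_catalog")
  validate_catalog(cat45)
  cat45
}

# ---- validation -----------------------------------------------------------

validate_catalog <- function(catalog) {
  el <- catalog$elements
  if (anyDuplicated(el$name))
    stop("catalog validation: duplicated element names", call. = FALSE)
  if (any(el$length < 1L))
    stop("catalog validation: element lengths must be >= 1", call. = FALSE)
  for (v in catalog$variants) {
    missing <- setdiff(v$elements, el$name)
    if (length(missing))
      stop("catalog validation: variant ", v$id,
           " references unknown element(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (!v$region %in% c("ETS5", "ETS3"))
      stop("catalog validation: variant ", v$id, " has invalid region ",
           v$region, call. = FALSE)
  }
  for (p in catalog$primers) {
    for (s in c(p$forward, p$reverse))
      if (!nzchar(s) || grepl("[^ACGT]", s))
        stop("catalog validation: primers must be non-empty ACGT strings",
             call. = FALSE)
  }
  labels <- vapply(catalog$genotypes, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("catalog validation: duplicated genotype labels", call. = FALSE)
  for (g in catalog$genotypes) {
    missing <- setdiff(c(g$required, g$relations$a, g$relations$b),
                       names(catalog$variants))
    if (length(missing))
      stop("catalog validation: genotype ", g$label,
           " references unknown variant(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(catalog)
}

#' @export
print.rdna_catalog <- function(x, ...) {
  n3 <- sum(vapply(x$genotypes, function(g) g$region == "ETS3", TRUE))
  n5 <- sum(vapply(x$genotypes, function(g) g$region == "ETS5", TRUE))
  cat("45S rDNA variant catalog\n")
  cat(sprintf("  %d repeat/spacer elements, %d variants (%s)\n",
              nrow(x$elements), length(x$variants),
              paste(names(x$variants), collapse = ", ")))
  cat(sprintf("  %d primer pairs; %d ETS3 (3R) and %d ETS5 (5R) genotype definitions\n",
              length(x$primers), n3, n5))
  invisible(x)
}

# ---- serialization --------------------------------------------------------

catalog_to_list <- function(catalog) {
  list(
    elements = lapply(seq_len(nrow(catalog$elements)), function(i)
      list(name = catalog$elements$name[i],
           length = catalog$elements$length[i],
           class = catalog$elements$class[i])),
    variants = lapply(unname(catalog$variants), function(v)
      list(id = v$id, region = v$region, elements = as.list(v$elements),
           species = v$species)),
    primers = lapply(names(catalog$primers), function(nm)
      c(list(name = nm), catalog$primers[[nm]])),
    genotypes = lapply(unname(catalog$genotypes), function(g)
      list(label = g$label, region = g$region,
           required = as.list(g$required),
           relations = lapply(seq_len(nrow(g$relations)), function(i)
             list(a = g$relations$a[i], b = g$relations$b[i],
                  tier = g$relations$tier[i])))),
    annotation = list(unit_length = catalog$annotation$unit_length,
                      intervals = lapply(catalog$annotation$intervals,
                                         as.list))
  )
}

catalog_from_list <- function(raw) {
  need <- function(x, key, where) {
    if (is.null(x[[key]]))
      stop("malformed catalog config: missing key '", key, "' in ", where,
           call. = FALSE)
    x[[key]]
  }
  elements <- do.call(rbind, lapply(need(raw, "elements", "top level"),
    function(e) data.frame(name = need(e, "name", "elements"),
                           length = as.integer(need(e, "length", "elements")),
                           class = need(e, "class", "elements"))))
  variants <- lapply(need(raw, "variants", "top level"), function(v)
    list(id = need(v, "id", "variants"),
         region = need(v, "region", "variants"),
         elements = unlist(need(v, "elements", "variants")),
         species = v$species %||% "unknown"))
  names(variants) <- vapply(variants, `[[`, "", "id")
  primers <- lapply(need(raw, "primers", "top level"), function(p)
    list(forward = need(p, "forward", "primers"),
         reverse = need(p, "reverse", "primers"),
         region = p$region %||% NA_character_))
  names(primers) <- vapply(need(raw, "primers", "top level"),
                           function(p) need(p, "name", "primers"), "")
  genotypes <- lapply(need(raw, "genotypes", "top level"), function(g) {
    rel <- g$relations
    reldf <- if (length(rel))
      do.call(rbind, lapply(rel, function(r)
        data.frame(a = r$a, b = r$b, tier = r$tier)))
    else data.frame(a = character(), b = character(), tier = character())
    list(label = need(g, "label", "genotypes"),
         region = need(g, "region", "genotypes"),
         required = sort(unlist(need(g, "required", "genotypes"))),
         relations = reldf)
  })
  names(genotypes) <- vapply(genotypes, `[[`, "", "label")
  ann_raw <- raw$annotation
  annotation <- if (is.null(ann_raw)) unit_annotation() else
    unit_annotation(unit_length = as.integer(ann_raw$unit_length),
                    intervals = lapply(ann_raw$intervals,
                                       function(iv) as.integer(unlist(iv))))
  cat45 <- structure(list(elements = elements, variants = variants,
                          primers = primers, genotypes = genotypes,
                          annotation = annotation),
                     class = "rdna_catalog")
  validate_catalog(cat45)
  cat45
}

#' Serialize a catalog to a plain-text config
#'
#' @param catalog An `rdna_catalog`.
#' @param path Optional file path; if `NULL` the YAML text is returned.
#' @return The YAML string (invisibly, when written to a file).
#' @seealso [load_catalog()] for the inverse; the round trip is the identity.
#' @export
write_catalog <- function(catalog, path = NULL) {
  txt <- yaml::as.yaml(catalog_to_list(catalog))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---- amplicon arithmetic --------------------------------------------------

element_length <- function(catalog, name) {
  i <- match(name, catalog$elements$name)
  if (anyNA(i)) stop("unknown element(s): ",
                     paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  catalog$elements$length[i]
}

get_variant <- function(catalog, variant_id) {
  v <- catalog$variants[[variant_id]]
  if (is.null(v)) stop("unknown variant: ", variant_id, call. = FALSE)
  v
}

#' Predicted PCR amplicon length of a variant
#'
#' Sum of the variant's element and spacer lengths between (and including)
#' the primer landing sites of its diagnostic primer pair.
#'
#' @param catalog An `rdna_catalog`.
#' @param variant_id Variant identifier, e.g. `"VARA"`.
#' @param primers Primer-pair name (`"P1P3"` or `"P4P5"`) or a list with
#'   `forward`/`reverse`/`region`.
#' @return Integer amplicon length in bp.
#' @export
variant_amplicon_length <- function(catalog, variant_id, primers = NULL) {
  v <- get_variant(catalog, variant_id)
  pp <- resolve_primers(catalog, primers %||%
                          if (v$region == "ETS5") "P1P3" else "P4P5")
  if (!is.null(pp$region) && !is.na(pp$region) && pp$region != v$region)
    stop("primer pair targets region ", pp$region, " but variant ",
         variant_id, " is in ", v$region, call. = FALSE)
  sum(element_length(catalog, v$elements))
}

resolve_primers <- function(catalog, primers) {
  if (is.character(primers)) {
    pp <- catalog$primers[[primers]]
    if (is.null(pp)) stop("unknown primer pair: ", primers, call. = FALSE)
    pp
  } else primers
}

#' Derive a new variant from an existing one
#'
#' Applies insert/delete element edits to a base variant and registers the
#' result in the catalog, e.g. deriving the 950 bp VARB-like structure from
#' VARA by deleting one 310 bp C repeat.
#'
#' @param catalog An `rdna_catalog`.
#' @param base_id Identifier of the base variant.
#' @param edits List of edits; each edit is
#'   `list(op = "delete", element = <name>)` or
#'   `list(op = "insert", element = <name>, after = <name>)`.
#' @param new_id Identifier for the derived variant.
#' @return The catalog with the new variant registered.
#' @export
derive_variant <- function(catalog, base_id, edits, new_id) {
  v <- get_variant(catalog, base_id)
  els <- v$elements
  for (e in edits) {
    if (identical(e$op, "delete")) {
      i <- match(e$element, els)
      if (is.na(i)) stop("cannot delete element ", e$element,
                         ": not present in ", base_id, call. = FALSE)
      els <- els[-i]
    } else if (identical(e$op, "insert")) {
      element_length(catalog, e$element)  # must exist
      i <- match(e$after, els)
      if (is.na(i)) stop("cannot insert after ", e$after,
                         ": not present in ", base_id, call. = FALSE)
      els <- append(els, e$element, after = i)
    } else stop("unknown edit op: ", e$op %||% "<missing>", call. = FALSE)
  }
  catalog$variants[[new_id]] <- list(id = new_id, region = v$region,
                                     elements = els, species = v$species)
  validate_catalog(catalog)
  catalog
}

# ---- sequence realization -------------------------------------------------

# Realize one random sequence per element, deterministically in `seed`.
# C-class elements (C1, C2, C-like) all begin with the 59 bp C3 sequence;
# C-like shares its full realization with C1 (it derives from a fusion of
# the VARA C repeats). Primer-site elements carry the primer sequences
# verbatim. Rejection sampling excludes accidental primer-site matches.
realize_elements <- function(catalog, seed) {
  el <- catalog$elements
  primer_words <- unlist(lapply(catalog$primers, function(p)
    c(p$forward, p$reverse, revcomp(p$forward), revcomp(p$reverse))))
  clean_dna <- function(n) {
    for (i in 1:100) {
      s <- random_dna(n)
      hit <- any(vapply(primer_words, function(w)
        n >= nchar(w) && grepl(w, s, fixed = TRUE), TRUE))
      if (!hit) return(s)
    }
    stop("rejection sampling failed to avoid primer collisions")
  }
  seqs <- character(nrow(el))
  names(seqs) <- el$name
  with_seed(sub_seed(seed, "elements"), {
    c3 <- clean_dna(element_length(catalog, "C3"))
    for (i in seq_len(nrow(el))) {
      nm <- el$name[i]; n <- el$length[i]; cls <- el$class[i]
      seqs[nm] <- switch(cls,
        primer = primer_site_sequence(catalog, nm),
        C3 = c3,
        C = paste0(c3, clean_dna(n - nchar(c3))),
        clean_dna(n))
    }
    # The C3 prefix is maximal: the first base after it differs between C1
    # and C2, so the shared C prefix is exactly the C3 repeat
    if (all(c("C1", "C2", "C3") %in% el$name)) {
      at <- nchar(c3) + 1L
      if (substr(seqs["C1"], at, at) == substr(seqs["C2"], at, at)) {
        alt <- setdiff(BASES, substr(seqs["C1"], at, at))[1]
        substr(seqs["C2"], at, at) <- alt
      }
    }
    # C-like is the C1 sequence (fusion of C1/C2, not an independent repeat)
    if (all(c("C1", "C-like") %in% el$name))
      seqs["C-like"] <- seqs["C1"]
  })
  seqs
}

primer_site_sequence <- function(catalog, name) {
  switch(name,
    P1site = catalog$primers$P1P3$forward,
    P3rc   = revcomp(catalog$primers$P1P3$reverse),
    P4site = catalog$primers$P4P5$forward,
    P5rc   = revcomp(catalog$primers$P4P5$reverse),
    stop("unknown primer-site element: ", name, call. = FALSE))
}

#' Realize the nucleotide sequence of a catalog variant
#'
#' Concatenates the seeded realizations of the variant's elements. Repeated
#' elements share an identical sequence; the forward primer site appears
#' verbatim at the 5' end and the reverse complement of the reverse primer
#' at the 3' end, so in-silico PCR on the realization reproduces the
#' catalog amplicon length.
#'
#' @inheritParams variant_amplicon_length
#' @param seed Integer seed; the realization is deterministic in it.
#' @return A nucleotide string.
#' @export
build_variant_sequence <- function(catalog, variant_id, seed = 1L) {
  v <- get_variant(catalog, variant_id)
  seqs <- realize_elements(catalog, seed)
  paste(seqs[v$elements], collapse = "")
}

# ---- in-silico PCR --------------------------------------------------------

#' In-silico PCR
#'
#' Predicts amplicon lengths from exact primer matching on one or more
#' template sequences: for every forward-primer site, the nearest
#' downstream reverse-complemented reverse-primer site with a product not
#' exceeding `max_len` yields one amplicon.
#'
#' @param template Character vector of template sequences.
#' @param primers Primer-pair name resolved against `catalog`, or a list
#'   with `forward` and `reverse` sequences.
#' @param max_len Maximum product length considered (default 3000 bp).
#' @param catalog Catalog used to resolve `primers` by name (default
#'   catalog if missing).
#' @return Sorted integer vector of amplicon lengths (empty when no site
#'   pair amplifies).
#' @export
insilico_pcr <- function(template, primers, max_len = 3000L,
                         catalog = NULL) {
  if (!length(template) || any(!nzchar(template)))
    stop("template must be non-empty", call. = FALSE)
  if (max_len <= 0) stop("max_len must be > 0", call. = FALSE)
  pp <- resolve_primers(catalog %||% default_catalog(), primers)
  fwd <- pp$forward
  rev_rc <- revcomp(pp$reverse)
  out <- integer()
  for (tmpl in template) {
    fpos <- find_fixed(tmpl, fwd)
    rpos <- find_fixed(tmpl, rev_rc)
    if (!length(fpos) || !length(rpos)) next
    rend <- rpos + nchar(rev_rc) - 1L
    for (f in fpos) {
      lens <- rend - f + 1L
      ok <- which(lens >= nchar(fwd) + nchar(rev_rc) & lens <= max_len)
      if (length(ok)) out <- c(out, min(lens[ok]))
    }
  }
  sort(out)
}

find_fixed <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# ---- exports --------------------------------------------------------------

#' Export realized variant sequences as FASTA
#' @inheritParams build_variant_sequence
#' @param path Output FASTA path.
#' @param variant_ids Variants to export (default: all).
#' @export
export_variant_fasta <- function(catalog, path, seed = 1L,
                                 variant_ids = names(catalog$variants)) {
  seqs <- vapply(variant_ids, function(id)
    build_variant_sequence(catalog, id, seed), "")
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- variant_ids
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Amplicon report for all catalog variants
#'
#' @inheritParams variant_amplicon_length
#' @param path Optional TSV output path.
#' @return data.frame with columns variant_id, primer_pair, length_bp.
#' @export
amplicon_report <- function(catalog, path = NULL) {
  rows <- lapply(catalog$variants, function(v) {
    pp <- if (v$region == "ETS5") "P1P3" else "P4P5"
    data.frame(variant_id = v$id, primer_pair = pp,
               length_bp = variant_amplicon_length(catalog, v$id, pp))
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(path)) write_tsv(df, path)
  df
}
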