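#' Run the full simulation-and-analysis pipeline
#'
#' Executes, for every configured individual: simulate genome -> simulate
#' reads -> remove duplicates -> map to the collapsed reference (rDNA
#' unit + backbone) -> depth and pileup -> copy-number estimation ->
#' allele profiling -> ETS genotyping; then summarizes the cohort
#' (genotype frequencies, per-site composition, diversity by group,
#' polymorphism track). All tabular outputs are TSV; a JSON manifest
#' records the configuration, seed and output checksums. Rerunning with
#' the same configuration and seed reproduces byte-identical outputs.
#'
#' @param config A configuration list or path to a YAML file. Top-level
#'   keys: `individuals` (list of `id`, `copy_number`, optional `altitude`
#'   and `mixture`, each mixture component `ets5`/`ets3`/`prop` plus
#'   optional `snps` as a list of `pos`/`alt`), and optional `depth`,
#'   `read_len`, `insert_mean`, `insert_sd`, `error_rate`, `dup_rate`,
#'   `backbone_length`, `genotype_mode` ("truth" or "depth"), `grouping`
#'   (site -> group), `seed`.
#' @param outdir Output directory (created if needed).
#' @param seed Overrides the config seed when given.
#' @return Invisibly, a list with the cohort tables (`cnv`, `calls`,
#'   `frequencies_3R`, `frequencies_5R`, `site_composition`, `diversity`,
#'   `cohort_track`, `summary`) and the manifest.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$individuals) || !length(config$individuals))
    stop("pipeline config stage: no individuals configured", call. = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  depth <- config$depth %||% 2
  params <- list(read_len = config$read_len %||% 150L,
                 insert_mean = config$insert_mean %||% 350L,
                 insert_sd = config$insert_sd %||% 35,
                 error_rate = config$error_rate %||% 0.001,
                 dup_rate = config$dup_rate %||% 0.02)
  backbone_length <- config$backbone_length %||% 100000L
  genotype_mode <- config$genotype_mode %||% "truth"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  catalog <- load_catalog(config$catalog)
  unit <- make_reference_unit(catalog, seed = seed)
  ann <- unit$annotation

  ids <- vapply(config$individuals, `[[`, "", "id")
  altitude <- vapply(config$individuals, function(ind)
    as.numeric(ind$altitude %||% NA_real_), 1.0)
  sheet <- sample_sheet(ids, altitude = altitude)

  cnv_rows <- list(); calls <- list(); profiles <- list()
  for (ind in config$individuals) {
    id <- ind$id
    stage <- function(what) paste0("pipeline stage ", what, " (", id, ")")
    res <- tryCatch(
      process_individual(ind, catalog, unit, ann, depth, params,
                         backbone_length, genotype_mode,
                         sub_seed(seed, id)),
      error = function(e) stop(stage("processing"), ": ",
                               conditionMessage(e), call. = FALSE))
    cnv_rows[[id]] <- res$cnv
    profiles[[id]] <- res$profile
    calls <- c(calls, res$calls)
  }

  cnv <- do.call(rbind, c(cnv_rows, make.row.names = FALSE))
  cnv$site <- sheet$site[match(cnv$id, sheet$id)]
  cnv$altitude <- sheet$altitude[match(cnv$id, sheet$id)]
  cnv <- cnv[order(cnv$altitude, cnv$id), , drop = FALSE]

  call_tab <- calls_table(calls)
  freq3 <- genotype_frequencies(call_tab[call_tab$region == "ETS3", ], sheet)
  freq5 <- genotype_frequencies(call_tab[call_tab$region == "ETS5", ], sheet)
  sites <- site_composition(call_tab, sheet)
  diversity <- if (!is.null(config$grouping)) {
    grouping <- unlist(config$grouping)
    d3 <- diversity_by_group(call_tab[call_tab$region == "ETS3", ], sheet,
                             grouping)
    d5 <- diversity_by_group(call_tab[call_tab$region == "ETS5", ], sheet,
                             grouping)
    data.frame(group = names(d3), n_3R = as.integer(d3),
               n_5R = as.integer(d5[names(d3)]))
  }
  track <- cohort_profile(profiles, ann)
  summary_tab <- cnv_cohort_summary(cnv)

  files <- c(cnv = "cnv.tsv", calls = "calls.tsv",
             frequencies_3R = "frequencies_3R.tsv",
             frequencies_5R = "frequencies_5R.tsv",
             site_composition = "site_composition.tsv",
             cohort_track = "cohort_track.tsv",
             summary = "cnv_summary.tsv")
  write_tsv(cnv, file.path(outdir, files["cnv"]))
  write_tsv(call_tab, file.path(outdir, files["calls"]))
  write_tsv(freq3, file.path(outdir, files["frequencies_3R"]))
  write_tsv(freq5, file.path(outdir, files["frequencies_5R"]))
  write_tsv(sites, file.path(outdir, files["site_composition"]))
  write_tsv(track, file.path(outdir, files["cohort_track"]))
  write_tsv(summary_tab, file.path(outdir, files["summary"]))
  if (!is.null(diversity))
    write_tsv(diversity, file.path(outdir, "diversity.tsv"))

  out_files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = seed,
    parameters = c(list(depth = depth,
                        backbone_length = backbone_length,
                        genotype_mode = genotype_mode), params),
    individuals = ids,
    outputs = as.list(stats::setNames(unname(tools::md5sum(out_files)),
                                      basename(out_files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cnv = cnv, calls = call_tab, frequencies_3R = freq3,
                 frequencies_5R = freq5, site_composition = sites,
                 diversity = diversity, cohort_track = track,
                 summary = summary_tab, manifest = manifest))
}

# One individual: simulate, dedup, map, depth/pileup, CNV, profile,
# genotype.
process_individual <- function(ind, catalog, unit, ann, depth, params,
                               backbone_length, genotype_mode, seed) {
  mixture <- if (is.null(ind$mixture))
    list(list(spec = unit_spec(), prop = 1.0))
  else lapply(ind$mixture, function(m) {
    snps <- if (!is.null(m$snps))
      data.frame(pos = vapply(m$snps, function(s) as.integer(s$pos), 1L),
                 alt = vapply(m$snps, function(s) s$alt, ""))
    list(spec = unit_spec(ets5 = m$ets5 %||% "VARA",
                          ets3 = m$ets3 %||% "VAR1",
                          snp_edits = snps),
         prop = m$prop %||% 1.0)
  })
  gspec <- genome_spec(ind$copy_number, mixture,
                       backbone_length = backbone_length, seed = seed)
  genome <- make_genome(gspec, catalog, unit)
  reads <- simulate_reads(genome, depth = depth,
                          read_len = params$read_len,
                          insert_mean = params$insert_mean,
                          insert_sd = params$insert_sd,
                          error_rate = params$error_rate,
                          dup_rate = params$dup_rate, seed = seed)
  reads <- remove_duplicates(reads)
  targets <- c(rdna_unit = unit$sequence, backbone = genome$backbone)
  pl <- map_reads(reads, targets)
  unit_depth <- compute_depth(pl, "rdna_unit")
  bg_depth <- compute_depth(pl, "backbone")
  cnv <- estimate_cnv_18S_25S(unit_depth, bg_depth, ann, id = ind$id)
  pup <- build_pileup(pl, reads, unit$sequence)
  profile <- allele_profile(pup, id = ind$id, annotation = ann)
  mk_call <- function(region) {
    pat <- if (identical(genotype_mode, "depth"))
      band_pattern_depth(reads, region, catalog, unit, id = ind$id)
    else band_pattern_truth(genome, region, id = ind$id)
    if (region == "ETS3") classify_3R(pat, catalog)
    else classify_5R(pat, catalog)
  }
  list(cnv = cnv, profile = profile,
       calls = list(mk_call("ETS3"), mk_call("ETS5")))
}
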