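## Orchestration: one YAML config document with full defaulting and strict
## unknown-key rejection, subcommands mapping 1:1 onto the module chains, and
## a manifest (content hash per output) making re-runs verifiable. Outputs
## contain no timestamps, so identical inputs + config + seed reproduce
## byte-identical files.

#' Default pipeline configuration
#'
#' @return nested list mirroring the YAML config schema.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 42L,
    screen = list(cluster_identity = 0.80, cluster_coverage = 0.80,
                  background_evalue_max = 1e-3, min_gene_length_bp = 300L,
                  exclude_hypothetical = TRUE, max_candidates = 25L,
                  focal_strain = "focal"),
    primer = list(min_amplicon_bp = 301L, gc_min_pct = 40, gc_max_pct = 60,
                  selfcomp_max = 4L, primer_len_min = 18L,
                  primer_len_max = 24L, tm_min_c = 57, tm_max_c = 63,
                  max_pair_tm_diff_c = 2.0, pairs_per_target = 5L),
    pcr = list(max_mismatch = 2L, anchor3_len = 3L, max_product_bp = 2000L,
               comparable_fraction = 0.25),
    melt = list(temp_start_c = 72.0, temp_end_c = 95.0, temp_step_c = 0.5,
                na_mM = 50),
    qpcr = list(ct_max = 30, tm_tol_c = 0.5,
                control_tm = list(xoxF = 90.3, copG = 84.6, ubik = 93.2)),
    novelty = list(seed_k = 15L, evalue_max = 1e-10, min_region_bp = 10L,
                   xdrop = 20),
    simulate = list(n_background = 4L, n_core = 50L, core_identity = 0.95,
                    n_planted_singletons = 5L, qpcr_rate = 0.8,
                    n_per_group = 6L, reference_len_bp = 20000L,
                    n_insertions = 4L),
    io = list(proteome_dir = NULL, focal_proteome = NULL,
              background_panel = NULL, genes_fasta = NULL,
              primers_tsv = NULL, target_fasta = NULL,
              offtarget_fasta = NULL, amplicons_fasta = NULL,
              qpcr_csv = NULL, query_fasta = NULL, reference_fasta = NULL,
              annotations = NULL))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: '",
         if (nzchar(path)) paste0(path, ".", unknown[1]) else unknown[1],
         "'", call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], user[[k]],
                   if (nzchar(path)) paste0(path, ".", k) else k)
    else user[[k]]
  }
  defaults
}

#' Load a pipeline configuration
#'
#' Reads a YAML document and merges it over [default_pipeline_config()].
#' Unknown keys at any level are a hard error (no silent typos).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged last (same strict checking).
#' @return resolved config list.
#' @export
load_pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

screen_config_from <- function(cfg) {
  s <- cfg$screen
  screen_config(s$cluster_identity, s$cluster_coverage,
                s$background_evalue_max, s$min_gene_length_bp,
                s$exclude_hypothetical, s$max_candidates)
}

primer_criteria_from <- function(cfg) {
  p <- cfg$primer
  primer_criteria(p$min_amplicon_bp, p$gc_min_pct, p$gc_max_pct,
                  p$selfcomp_max, c(p$primer_len_min, p$primer_len_max),
                  c(p$tm_min_c, p$tm_max_c), p$max_pair_tm_diff_c)
}

write_manifest <- function(out_dir, files, cfg) {
  rel <- sort(files)
  hashes <- unname(tools::md5sum(file.path(out_dir, rel)))
  cfg_path <- file.path(out_dir, "config.yaml")
  manifest <- list(
    package = "strainmark",
    version = as.character(utils::packageVersion("strainmark")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(seq_along(rel),
                   function(i) list(path = rel[i], md5 = hashes[i])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Run one pipeline subcommand
#'
#' Subcommands map 1:1 onto the module chains: `simulate` writes the
#' seed-driven synthetic fixture set; `screen` clusters proteomes, extracts
#' focal singletons, refines and filters them; `design` designs primer pairs
#' on candidate genes; `validate` predicts amplicons and checks off-target
#' mispriming; `melt` predicts amplicon melt Tm and simulates the derivative
#' curve; `classify` applies the Ct/dTm rule and tabulates detection rates;
#' `novelty` scans a query assembly against a reference. Every run writes the
#' resolved config and a `manifest.json` with an md5 per output file. On
#' error, partial outputs of the run are removed.
#'
#' @param subcommand one of `screen`, `design`, `validate`, `melt`,
#'   `classify`, `novelty`, `simulate`.
#' @param config a config list from [load_pipeline_config()], or a YAML path.
#' @param out_dir output directory (created).
#' @param seed overrides `config$seed` when given.
#' @return invisible manifest list.
#' @export
run_pipeline <- function(subcommand = c("screen", "design", "validate",
                                        "melt", "classify", "novelty",
                                        "simulate"),
                         config = NULL, out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- if (is.character(config)) load_pipeline_config(config)
         else if (is.null(config)) default_pipeline_config()
         else merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    writer(file.path(out_dir, name))
    written <<- c(written, name)
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, written)))

  fn <- switch(subcommand,
    simulate = cmd_simulate, screen = cmd_screen, design = cmd_design,
    validate = cmd_validate, melt = cmd_melt, classify = cmd_classify,
    novelty = cmd_novelty)
  fn(cfg, out_dir, emit)

  emit("config.yaml", function(p) yaml::write_yaml(cfg, p))
  manifest <- write_manifest(out_dir, written, cfg)
  ok <- TRUE
  invisible(manifest)
}

need_io <- function(cfg, key, sub) {
  v <- cfg$io[[key]]
  if (is.null(v)) stop("subcommand '", sub, "' requires config io.", key,
                       call. = FALSE)
  if (!file.exists(v)) stop("input not found: ", v, call. = FALSE)
  v
}

cmd_simulate <- function(cfg, out_dir, emit) {
  sim <- cfg$simulate
  # distinct sub-seeds per generator: a shared stream would correlate the
  # reference with the inserted sequence and erase the planted novelty
  sub_seed <- (as.integer(cfg$seed) + c(0L, 1L, 2L, 3L)) %% .Machine$integer.max
  pg <- generate_pangenome(sim$n_background, sim$n_core, sim$core_identity,
                           sim$n_planted_singletons, seed = sub_seed[1])
  pg_files <- write_pangenome(pg, file.path(out_dir, "pangenome"))
  qd <- generate_qpcr_dataset(n_per_group = sim$n_per_group,
                              true_positive_rate = sim$qpcr_rate,
                              control_tm = unlist(cfg$qpcr$control_tm),
                              seed = sub_seed[2])
  emit("qpcr_observations.csv", function(p)
    utils::write.csv(qd$observations, p, row.names = FALSE, quote = FALSE))
  emit("qpcr_truth.json", function(p)
    jsonlite::write_json(qd$truth, p, auto_unbox = TRUE, pretty = TRUE))
  ref <- with_seed(sub_seed[3], random_dna(sim$reference_len_bp, 0.6))
  pi <- plant_insertions(genome_record("reference", ref),
                         sim$n_insertions, seed = sub_seed[4])
  emit("reference.fna", function(p)
    write_fasta(setNames(ref, "reference"), p))
  emit("query.fna", function(p)
    write_fasta(setNames(pi$query$sequence, pi$query$id), p))
  emit("insertion_truth.json", function(p)
    jsonlite::write_json(pi$truth, p, auto_unbox = TRUE, pretty = TRUE))
  for (f in pg_files) emit(file.path("pangenome", basename(f)),
                           function(p) invisible(p))
}

read_proteome_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(faa|fa|fasta)$",
                           full.names = TRUE))
  if (!length(files)) stop("no proteome FASTA files in ", dir, call. = FALSE)
  prots <- list()
  for (f in files) {
    strain <- sub("\\.[^.]*$", "", basename(f))
    prots <- c(prots, read_fasta(f, "aa", strain = strain))
  }
  prots
}

cmd_screen <- function(cfg, out_dir, emit) {
  dir <- need_io(cfg, "proteome_dir", "screen")
  prots <- read_proteome_dir(dir)
  ann_path <- cfg$io$annotations %||% file.path(dir, "annotations.tsv")
  if (file.exists(ann_path)) {
    ann <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
    len_by_id <- setNames(as.integer(ann$end) - as.integer(ann$start) + 1L,
                          ann$feature_id)
    for (i in seq_along(prots)) {
      bp <- len_by_id[prots[[i]]$id]
      if (!is.na(bp)) prots[[i]]$coding_length_bp <- unname(bp)
    }
  }
  scfg <- screen_config_from(cfg)
  cl <- cluster_proteins(prots, scfg)
  singles <- find_singletons(cl, cfg$screen$focal_strain)
  panel <- if (!is.null(cfg$io$background_panel))
    read_fasta(cfg$io$background_panel, "aa")
  else Filter(function(p) p$strain != cfg$screen$focal_strain, prots)
  cands <- refine_by_background(singles, prots, panel, scfg)
  filt <- filter_candidates(cands, scfg)
  emit("candidates.tsv", function(p)
    write_tsv_report(as.data.frame(filt$retained), p))
  emit("candidates_dropped.tsv", function(p)
    write_tsv_report(filt$dropped, p))
  emit("clusters.tsv", function(p) write_tsv_report(data.frame(
    representative = vapply(cl, `[[`, "", "representative"),
    size = vapply(cl, function(x) length(x$members), 0L),
    n_strains = vapply(cl, function(x) length(x$strains_present), 0L),
    members = vapply(cl, function(x) paste(x$members, collapse = ";"), "")),
    p))
}

cmd_design <- function(cfg, out_dir, emit) {
  genes <- read_fasta(need_io(cfg, "genes_fasta", "design"), "nt")
  crit <- primer_criteria_from(cfg)
  rows <- list()
  for (g in genes) {
    tab <- design_primer_pairs(g$sequence, crit,
                               na_mM = cfg$melt$na_mM)
    if (nrow(tab)) {
      tab <- tab[seq_len(min(nrow(tab), cfg$primer$pairs_per_target)), ]
      tab <- cbind(target = g$id, tab)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else cbind(target = character(0), empty_pair_table())
  emit("primers.tsv", function(p) write_tsv_report(out, p))
}

cmd_validate <- function(cfg, out_dir, emit) {
  primers <- utils::read.delim(need_io(cfg, "primers_tsv", "validate"),
                               stringsAsFactors = FALSE)
  if (!nrow(primers)) stop("empty primer table", call. = FALSE)
  target <- read_fasta(need_io(cfg, "target_fasta", "validate"), "nt",
                       role = "focal")[[1]]
  offt <- read_fasta(need_io(cfg, "offtarget_fasta", "validate"), "nt",
                     role = "offtarget")
  pair <- list(forward = primers$forward[1], reverse = primers$reverse[1])
  rep <- specificity_check(pair, target, offt,
                           cfg$pcr$comparable_fraction,
                           cfg$pcr$max_product_bp, cfg$pcr$max_mismatch,
                           cfg$pcr$anchor3_len)
  amps <- rbind(rep$target_amplicons,
                do.call(rbind, rep$offtarget_amplicons))
  emit("amplicons.tsv", function(p)
    write_tsv_report(amps[, setdiff(names(amps), "sequence")], p))
  emit("specificity.json", function(p) jsonlite::write_json(
    list(verdict = rep$verdict, target_length = rep$target_length,
         comparable_fraction = rep$comparable_fraction,
         mispriming_flags = as.list(rep$mispriming_flags)),
    p, auto_unbox = TRUE, pretty = TRUE))
  emit("amplicons.bed", function(p) write_bed(
    data.frame(chrom = amps$genome_id, start = amps$start, end = amps$end),
    p))
}

cmd_melt <- function(cfg, out_dir, emit) {
  amps <- read_fasta(need_io(cfg, "amplicons_fasta", "melt"), "nt")
  mcfg <- melt_config(cfg$melt$temp_start_c, cfg$melt$temp_end_c,
                      cfg$melt$temp_step_c, cfg$melt$na_mM)
  tm <- vapply(amps, function(a) amplicon_melt_tm(a$sequence, mcfg$na_mM), 0)
  emit("melt_tm.tsv", function(p) write_tsv_report(data.frame(
    id = vapply(amps, `[[`, "", "id"),
    length_bp = vapply(amps, function(a) nchar(a$sequence), 0L),
    tm_predicted_c = tm), p))
  curve <- simulate_melt_curve(
    vapply(amps, `[[`, "", "sequence"), mcfg)
  emit("melt_curve.tsv", function(p) write_tsv_report(data.frame(
    temperature_c = curve$temperature, neg_dfdt = curve$dfdt), p))
}

cmd_classify <- function(cfg, out_dir, emit) {
  obs <- utils::read.csv(need_io(cfg, "qpcr_csv", "classify"),
                         stringsAsFactors = FALSE)
  ctl <- unlist(cfg$qpcr$control_tm)
  calls <- call_samples(obs, ctl, cfg$qpcr$ct_max, cfg$qpcr$tm_tol_c)
  emit("calls.tsv", function(p) write_tsv_report(calls, p))
  grp <- intersect(c("group", "crop", "timepoint_days", "assay"),
                   names(calls))
  rates <- format_detection_rates(detection_rates(calls, group_by = grp))
  emit("detection_rates.tsv", function(p) write_tsv_report(rates, p))
  if ("sample" %in% names(calls))
    emit("colonization.tsv", function(p)
      write_tsv_report(colonization_verdict(calls), p))
}

cmd_novelty <- function(cfg, out_dir, emit) {
  query <- read_fasta(need_io(cfg, "query_fasta", "novelty"), "nt")[[1]]
  ref <- read_fasta(need_io(cfg, "reference_fasta", "novelty"), "nt")[[1]]
  if (!is.null(cfg$io$annotations) && file.exists(cfg$io$annotations)) {
    feats <- read_annotations(cfg$io$annotations,
                              if (grepl("\\.gff3?$", cfg$io$annotations))
                                "gff3" else "tsv")
    query$features <- feats[[query$id]] %||% list()
  }
  ncfg <- novelty_config(cfg$novelty$seed_k, cfg$novelty$evalue_max,
                         cfg$novelty$min_region_bp, cfg$novelty$xdrop)
  regions <- find_novel_regions(query, ref, ncfg)
  summ <- summarize_novelty(regions, query$features)
  emit("novel_regions.bed", function(p) write_bed(regions, p))
  emit("novel_regions.tsv", function(p)
    write_tsv_report(as.data.frame(regions), p))
  emit("novelty_summary.tsv", function(p) write_tsv_report(data.frame(
    n_regions = summ$n_regions, total_bp = summ$total_bp,
    n_genes = summ$n_genes, n_trna = summ$n_trna), p))
}
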