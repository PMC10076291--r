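#' Run the analysis pipeline
#'
#' Orchestrates the stages over a working directory using the generator's
#' file layout (`input/hosts/*.fasta`, `input/virals.fasta`,
#' `input/mag_table.tsv`, `input/viral_table.tsv`). Stages consume their
#' predecessors' TSV/FASTA/GFF artifacts, so they can be run one at a time
#' or all at once; a rerun with the same configuration and seed reproduces
#' identical outputs.
#'
#' Stages: `simulate` (generate a synthetic community into `input/`),
#' `detect-arrays`, `match`, `network`, `interviral`, `chi`, `temporal`,
#' or `all`.
#'
#' @param stage Stage name (see above).
#' @param config A [run_config()].
#' @param synthetic A [synthetic_config()] (needed by `simulate`).
#' @param outdir Working directory (defaults to `config$output_dir`).
#' @return Invisibly, a list of artifact paths written by the stage(s).
#' @export
run_pipeline <- function(stage = "all", config = run_config(),
                         synthetic = NULL, outdir = config$output_dir) {
  stages <- c("simulate", "detect-arrays", "match", "network",
              "interviral", "chi", "temporal")
  if (!stage %in% c(stages, "all")) {
    sl_error("sl_usage_error", paste0(
      "unknown stage '", stage, "'; expected one of: ",
      paste(c(stages, "all"), collapse = ", ")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  todo <- if (stage == "all") stages else stage
  arts <- list()
  for (st in todo) {
    arts[[st]] <- switch(
      st,
      "simulate" = .stage_simulate(config, synthetic, outdir),
      "detect-arrays" = .stage_detect(config, outdir),
      "match" = .stage_match(config, outdir),
      "network" = .stage_network(config, outdir),
      "interviral" = .stage_interviral(config, outdir),
      "chi" = .stage_chi(config, outdir),
      "temporal" = .stage_temporal(config, outdir))
  }
  invisible(arts)
}

.need <- function(path, producer) {
  if (!file.exists(path)) {
    sl_error("sl_missing_artifact", paste0(
      "missing upstream artifact ", path,
      "; run the '", producer, "' stage first"))
  }
  path
}

.read_inputs <- function(config, outdir) {
  input <- file.path(outdir, "input")
  .need(file.path(input, "virals.fasta"), "simulate")
  mags <- read_mag_table(.need(file.path(input, "mag_table.tsv"), "simulate"))
  viral_meta <- read_viral_table(.need(file.path(input, "viral_table.tsv"),
                                       "simulate"))
  host_files <- list.files(file.path(input, "hosts"), full.names = TRUE,
                           pattern = "\\.fasta$")
  hs <- list()
  for (f in host_files) {
    mid <- sub("\\.fasta$", "", basename(f))
    df <- read_sequences(f, min_len = config$min_scaffold_len)
    if (nrow(df)) df$mag_id <- mid
    hs[[length(hs) + 1L]] <- df
  }
  host_scaffolds <- do.call(rbind, hs)
  virals <- read_sequences(file.path(input, "virals.fasta"),
                           min_len = config$min_scaffold_len)
  list(mags = mags, viral_meta = viral_meta,
       host_scaffolds = host_scaffolds, virals = virals)
}

.stage_simulate <- function(config, synthetic, outdir) {
  if (is.null(synthetic)) {
    sl_error("sl_usage_error",
             "the simulate stage needs a synthetic_config")
  }
  input <- file.path(outdir, "input")
  generate_community(synthetic, outdir = input)
  sl_log("info", "simulate: community written to ", input)
  input
}

.stage_detect <- function(config, outdir) {
  d <- .read_inputs(config, outdir)
  mags_q <- quality_filter_mags(d$mags, config$quality_params)
  keep <- d$host_scaffolds$mag_id %in% mags_q$mag_id
  arrays <- detect_arrays_all(d$host_scaffolds[keep, , drop = FALSE],
                              config$detect_params)
  owner_of <- stats::setNames(d$host_scaffolds$mag_id, d$host_scaffolds$id)
  spacers <- excise_spacers_all(arrays, owner_of)
  gff <- file.path(outdir, "host_arrays.gff3")
  write_arrays_gff(arrays, gff)
  sp_path <- file.path(outdir, "host_spacers.tsv")
  utils::write.table(spacers, sp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sl_log("info", "detect-arrays: ", length(arrays), " arrays, ",
         nrow(spacers), " spacers")
  c(arrays = gff, spacers = sp_path)
}

.stage_match <- function(config, outdir) {
  d <- .read_inputs(config, outdir)
  spacers <- utils::read.delim(
    .need(file.path(outdir, "host_spacers.tsv"), "detect-arrays"),
    stringsAsFactors = FALSE)
  index <- build_target_index(d$virals, k = config$match_params$index_k)
  matches <- find_protospacers(spacers, index, config$match_params)
  viral_arrays <- detect_arrays_all(d$virals, config$detect_params)
  matches <- flag_in_array(matches, viral_arrays)
  path <- file.path(outdir, "matches.tsv")
  write_matches_tsv(matches, path)
  sl_log("info", "match: ", nrow(matches), " retained matches")
  path
}

.stage_network <- function(config, outdir) {
  d <- .read_inputs(config, outdir)
  matches <- read_matches_tsv(.need(file.path(outdir, "matches.tsv"),
                                    "match"))
  mags_q <- quality_filter_mags(d$mags, config$quality_params)
  matches <- matches[matches$owner_id %in% mags_q$mag_id, , drop = FALSE]
  nets <- build_networks_by_year(matches, mags_q, d$viral_meta)
  paths <- character(0)
  for (lab in names(nets)) {
    prefix <- file.path(outdir, paste0("network_", gsub("[^A-Za-z0-9_-]", "_",
                                                        lab)))
    paths <- c(paths, write_network(nets[[lab]], prefix))
  }
  summ <- summarize_networks(nets)
  sp <- file.path(outdir, "network_summary.tsv")
  utils::write.table(summ, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  hp <- file.path(outdir, "hyper_targeted.tsv")
  hyper <- do.call(rbind, lapply(nets, function(n) {
    h <- find_hyper_targeted(n, config$hyper_threshold)
    if (nrow(h)) h$network <- n$label
    h
  }))
  utils::write.table(hyper, hp, sep = "\t", quote = FALSE, row.names = FALSE)
  sl_log("info", "network: ", nrow(summ), " networks")
  c(paths, summary = sp, hyper = hp)
}

.stage_interviral <- function(config, outdir) {
  d <- .read_inputs(config, outdir)
  va <- find_viral_arrays(d$virals, config$detect_params)
  owner_of <- stats::setNames(d$virals$id, d$virals$id)
  vsp <- excise_spacers_all(va$arrays, owner_of)
  index <- build_target_index(d$virals, k = config$match_params$index_k)
  conf <- find_conflicts(vsp, index, va$arrays, config$match_params)
  cpath <- file.path(outdir, "interviral_conflicts.tsv")
  utils::write.table(conf$conflicts, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  array_virals <- unique(vapply(va$arrays, function(a) a$scaffold_id, ""))
  pv_al <- align_viral_to_bins(
    d$virals[d$virals$id %in% array_virals, , drop = FALSE],
    d$host_scaffolds, config$provirus_params, config$match_params)
  host_lens <- stats::setNames(nchar(d$host_scaffolds$seq),
                               d$host_scaffolds$id)
  calls <- call_proviruses(pv_al, config$provirus_params, host_lens)
  ppath <- file.path(outdir, "provirus_calls.tsv")
  utils::write.table(calls, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gpath <- file.path(outdir, "provirus_calls.gff3")
  write_provirus_gff(calls, gpath)
  sl_log("info", "interviral: ", nrow(conf$conflicts), " conflicts, ",
         nrow(calls), " provirus calls")
  c(conflicts = cpath, proviruses = ppath, provirus_gff = gpath)
}

.stage_chi <- function(config, outdir) {
  d <- .read_inputs(config, outdir)
  matches <- read_matches_tsv(.need(file.path(outdir, "matches.tsv"),
                                    "match"))
  mags_q <- quality_filter_mags(d$mags, config$quality_params)
  matches <- matches[matches$owner_id %in% mags_q$mag_id, , drop = FALSE]
  nets <- build_networks_by_year(matches, mags_q, d$viral_meta)
  chi <- chi_vs_targeting(nets, d$virals, config$chi_params,
                          hyper_threshold = config$hyper_threshold,
                          seed = derive_seed(config$rng_seed, "chi"))
  path <- file.path(outdir, "chi_targeting.tsv")
  write_chi_tsv(chi, path)
  sl_log("info", "chi: ", nrow(chi$table), " targeted viral elements")
  path
}

.stage_temporal <- function(config, outdir) {
  d <- .read_inputs(config, outdir)
  cl <- cluster_viral(d$virals, config$cluster_params)
  cpath <- file.path(outdir, "viral_clusters.tsv")
  utils::write.table(cl, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mag_seqs <- split(d$host_scaffolds$seq, d$host_scaffolds$mag_id)
  pops <- dereplicate_mags(mag_seqs, config$cluster_params)
  ppath <- file.path(outdir, "mag_populations.tsv")
  utils::write.table(pops$populations, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sl_log("info", "temporal: ", length(unique(cl$cluster_id)),
         " viral populations, ",
         length(unique(pops$populations$population_id)), " MAG populations")
  c(viral_clusters = cpath, mag_populations = ppath)
}
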