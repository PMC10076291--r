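#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline into one serializable
#' object. All values default to the thresholds used throughout the
#' analysis: a 2.5 kbp scaffold floor, spacer matching at up to one
#' mismatch / >= 90% query coverage / E <= 1e-4, MAG quality gating at
#' over 70% completeness and under 10% contamination, hyper-targeting at >= 20
#' protospacers, provirus calling at bitscore >= 50 / E <= 1e-3 /
#' alignment >= 2500 bp / identity >= 70% with the 90% co-binning rule,
#' and viral population clustering at 95% global identity.
#'
#' @param min_scaffold_len Scaffold length floor in bp, applied at load.
#' @param match_params See [match_params()].
#' @param detect_params See [detect_params()].
#' @param provirus_params See [provirus_params()].
#' @param cluster_params See [cluster_params()].
#' @param quality_params See [quality_params()].
#' @param chi_params See [chi_params()].
#' @param hyper_threshold Minimum protospacer count from a single host for a
#'   viral element to count as hyper-targeted.
#' @param rng_seed Integer seed governing all randomized stages.
#' @param output_dir Directory for pipeline artifacts.
#' @return A classed list (`run_config`).
#' @export
run_config <- function(min_scaffold_len = 2500,
                       match_params = spacerlink::match_params(),
                       detect_params = spacerlink::detect_params(),
                       provirus_params = spacerlink::provirus_params(),
                       cluster_params = spacerlink::cluster_params(),
                       quality_params = spacerlink::quality_params(),
                       chi_params = spacerlink::chi_params(),
                       hyper_threshold = 20,
                       rng_seed = 1,
                       output_dir = "spacerlink_out") {
  if (is.list(match_params) && !inherits(match_params, "match_params"))
    match_params <- do.call(spacerlink::match_params, match_params)
  if (is.list(detect_params) && !inherits(detect_params, "detect_params"))
    detect_params <- do.call(spacerlink::detect_params, detect_params)
  if (is.list(provirus_params) && !inherits(provirus_params, "provirus_params"))
    provirus_params <- do.call(spacerlink::provirus_params, provirus_params)
  if (is.list(cluster_params) && !inherits(cluster_params, "cluster_params"))
    cluster_params <- do.call(spacerlink::cluster_params, cluster_params)
  if (is.list(quality_params) && !inherits(quality_params, "quality_params"))
    quality_params <- do.call(spacerlink::quality_params, quality_params)
  if (is.list(chi_params) && !inherits(chi_params, "chi_params"))
    chi_params <- do.call(spacerlink::chi_params, chi_params)
  min_scaffold_len <- as.numeric(min_scaffold_len)
  hyper_threshold <- as.numeric(hyper_threshold)
  rng_seed <- as.numeric(rng_seed)
  if (min_scaffold_len < 0) sl_error("sl_value_error", "min_scaffold_len must be >= 0")
  if (hyper_threshold < 1) sl_error("sl_value_error", "hyper_threshold must be >= 1")
  structure(list(
    min_scaffold_len = min_scaffold_len,
    match_params = match_params,
    detect_params = detect_params,
    provirus_params = provirus_params,
    cluster_params = cluster_params,
    quality_params = quality_params,
    chi_params = chi_params,
    hyper_threshold = hyper_threshold,
    rng_seed = rng_seed,
    output_dir = as.character(output_dir)
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' A configuration round-trips identically: `read_run_config(write_run_config(cfg))`
#' reconstructs `cfg` because both paths pass through the [run_config()]
#' constructor, which normalizes all numeric fields.
#'
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    sl_error("sl_schema_error",
             paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(run_config, raw)
}
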