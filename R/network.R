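#' MAG quality-gate parameters
#'
#' @param min_completeness Completeness must be strictly greater than this
#'   (default 70; 70.0 itself is dropped).
#' @param max_contamination Contamination must be strictly less than this
#'   (default 10; 10.0 itself is dropped).
#' @param hyper_threshold Hyper-targeting threshold (protospacers from one
#'   host, default 20).
#' @param min_curation_scaffold_len Flag-only floor for the length of
#'   CRISPR-array-bearing scaffolds during cross-taxon curation (default
#'   10000 bp); shorter scaffolds are flagged but never auto-failed.
#' @return A classed list (`quality_params`).
#' @export
quality_params <- function(min_completeness = 70, max_contamination = 10,
                           hyper_threshold = 20,
                           min_curation_scaffold_len = 10000) {
  stopifnot(min_completeness >= 0, max_contamination > 0,
            hyper_threshold >= 1, min_curation_scaffold_len >= 0)
  structure(list(min_completeness = as.numeric(min_completeness),
                 max_contamination = as.numeric(max_contamination),
                 hyper_threshold = as.numeric(hyper_threshold),
                 min_curation_scaffold_len = as.numeric(min_curation_scaffold_len)),
            class = "quality_params")
}

#' Filter MAGs on completeness and contamination
#'
#' Keeps genome bins that are > 70% complete with < 10% contamination
#' (medium-quality draft MAGs or better). Both inequalities are strict.
#'
#' @param mags MAG `data.frame` (see [read_mag_table()]).
#' @param params [quality_params()].
#' @return The retained rows of `mags`.
#' @export
quality_filter_mags <- function(mags, params = quality_params()) {
  keep <- mags$completeness > params$min_completeness &
    mags$contamination < params$max_contamination
  mags[keep, , drop = FALSE]
}

#' Build a virus-host interaction network
#'
#' One edge per (host MAG, viral element) pair supported by at least one
#' retained spacer-to-protospacer match. The edge weight is the number of
#' distinct protospacer loci (target, interval, strand) supporting the
#' pair: a single spacer with several matches on a viral element
#' contributes each locus. Spacer-to-spacer matches (`in_array`) are
#' excluded: lacking a protospacer-adjacent motif they confer no immunity.
#'
#' @param matches Match `data.frame` whose `owner_id` values are host MAG
#'   ids and `target_id` values viral ids; run [flag_in_array()] first if
#'   the targets carry arrays.
#' @param mags MAG `data.frame` (nodes; must cover every match owner).
#' @param virals Viral metadata `data.frame` with `viral_id`, `site`,
#'   `year` (must cover every match target).
#' @param label Network label, e.g. `"2016"` or
#'   `"2016-host-to-2017-viruses"`.
#' @return A `vh_network`: list of `hosts`, `virals`, `edges`
#'   (`host_id`, `viral_id`, `weight`, `match_ids`), `label`.
#' @export
build_network <- function(matches, mags, virals, label = "network") {
  keep <- !matches$in_array
  m <- matches[keep, , drop = FALSE]
  if (nrow(m)) {
    bad_host <- setdiff(unique(m$owner_id), mags$mag_id)
    bad_vir <- setdiff(unique(m$target_id), virals$viral_id)
    if (length(bad_host) || length(bad_vir)) {
      sl_error("sl_consistency_error", paste0(
        "matches reference unknown node(s): ",
        paste(c(bad_host, bad_vir), collapse = ", ")))
    }
  }
  if (nrow(m)) {
    loci <- unique(data.frame(host_id = m$owner_id, viral_id = m$target_id,
                              start = m$start, end = m$end,
                              strand = m$strand, stringsAsFactors = FALSE))
    agg <- stats::aggregate(cbind(weight = start) ~ host_id + viral_id,
                            data = loci, FUN = length)
    mids <- tapply(paste0(m$spacer_id, "@", m$target_id, ":", m$start, "-",
                          m$end, m$strand),
                   paste(m$owner_id, m$target_id, sep = "\r"),
                   function(x) paste(sort(unique(x)), collapse = ";"))
    agg$match_ids <- unname(mids[paste(agg$host_id, agg$viral_id,
                                       sep = "\r")])
    agg <- agg[order(agg$host_id, agg$viral_id), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(host_id = character(0), viral_id = character(0),
                      weight = integer(0), match_ids = character(0),
                      stringsAsFactors = FALSE)
  }
  hosts <- mags[mags$mag_id %in% agg$host_id, , drop = FALSE]
  vir <- virals[virals$viral_id %in% agg$viral_id, , drop = FALSE]
  structure(list(hosts = hosts, virals = vir, edges = agg, label = label),
            class = "vh_network")
}

#' Build the four temporal virus-host networks
#'
#' Builds the within-year and cross-year networks (2016 hosts to 2016
#' viruses, 2017 to 2017, 2016 hosts to 2017 viruses, 2017 hosts to 2016
#' viruses — or whatever pair of year labels the data carry).
#'
#' @param matches Combined match `data.frame`.
#' @param mags MAG table with `year`.
#' @param virals Viral table with `year`.
#' @return Named list of `vh_network` objects.
#' @export
build_networks_by_year <- function(matches, mags, virals) {
  hy <- sort(unique(mags$year))
  vy <- sort(unique(virals$year))
  out <- list()
  host_year <- stats::setNames(mags$year, mags$mag_id)
  viral_year <- stats::setNames(virals$year, virals$viral_id)
  for (a in hy) {
    for (b in vy) {
      lab <- if (a == b) as.character(a) else
        sprintf("%d-host-to-%d-viruses", a, b)
      sel <- matches$owner_id %in% mags$mag_id[mags$year == a] &
        matches$target_id %in% virals$viral_id[virals$year == b]
      out[[lab]] <- build_network(matches[sel, , drop = FALSE],
                                  mags[mags$year == a, , drop = FALSE],
                                  virals[virals$year == b, , drop = FALSE],
                                  label = lab)
    }
  }
  out
}

#' Summarize a virus-host network
#'
#' @param net A `vh_network`.
#' @return A list: `label`, `n_host_mags`, `n_viral_scaffolds`,
#'   `unique_links` (one MAG to one viral element regardless of spacer
#'   count), `pct_hosts_multi` / `pct_virals_multi` (% of hosts / viral
#'   elements with two or more partners), and the edge `weight`
#'   distribution.
#' @export
summarize_network <- function(net) {
  ed <- net$edges
  n_host <- length(unique(ed$host_id))
  n_vir <- length(unique(ed$viral_id))
  hostdeg <- table(ed$host_id)
  virdeg <- table(ed$viral_id)
  list(
    label = net$label,
    n_host_mags = n_host,
    n_viral_scaffolds = n_vir,
    unique_links = nrow(ed),
    pct_hosts_multi = if (n_host) 100 * sum(hostdeg >= 2) / n_host else 0,
    pct_virals_multi = if (n_vir) 100 * sum(virdeg >= 2) / n_vir else 0,
    weights = if (nrow(ed)) ed$weight else integer(0))
}

#' Tabulate network summaries
#'
#' @param nets List of `vh_network`.
#' @return `data.frame` mirroring a networks-summary table (`network`,
#'   `host_mags`, `viral_scaffolds`, `unique_links`).
#' @export
summarize_networks <- function(nets) {
  do.call(rbind, lapply(nets, function(n) {
    s <- summarize_network(n)
    data.frame(network = s$label, host_mags = s$n_host_mags,
               viral_scaffolds = s$n_viral_scaffolds,
               unique_links = s$unique_links, stringsAsFactors = FALSE)
  }))
}

#' Find hyper-targeted viral elements
#'
#' Hyper-targeting: at least `threshold` (default 20) distinct protospacer
#' loci on one viral element targeted by a single host's set of CRISPR
#' spacers. Edge weights already count distinct loci, so this is a simple
#' weight filter.
#'
#' @param net A `vh_network`.
#' @param threshold Minimum protospacer count (boundary inclusive).
#' @return `data.frame` (`viral_id`, `host_id`, `n_protospacers`), sorted
#'   by descending count.
#' @export
find_hyper_targeted <- function(net, threshold = 20) {
  ed <- net$edges
  sel <- ed$weight >= threshold
  out <- data.frame(viral_id = ed$viral_id[sel], host_id = ed$host_id[sel],
                    n_protospacers = ed$weight[sel], stringsAsFactors = FALSE)
  out <- out[order(-out$n_protospacers, out$viral_id, out$host_id), ]
  rownames(out) <- NULL
  out
}

#' Find viral elements predicted to infect across a taxonomic rank
#'
#' Returns viral elements whose linked hosts differ at the given rank.
#' Hosts with an empty value at that rank make a multi-host viral element
#' "unrankable" when the remaining ranked hosts do not by themselves
#' differ; unrankable records are returned flagged but are not candidates.
#'
#' @param net A `vh_network` (hosts must carry lineage rank columns).
#' @param rank `"phylum"` or `"domain"`.
#' @return `data.frame` with `viral_id`, `n_hosts`, `hosts` (";"-joined),
#'   `ranks` (";"-joined distinct values), `status`
#'   (`candidate`/`unrankable`).
#' @export
find_cross_taxon <- function(net, rank = c("phylum", "domain")) {
  rank <- match.arg(rank)
  ed <- net$edges
  hosts <- net$hosts
  rank_of <- stats::setNames(hosts[[rank]], hosts$mag_id)
  out <- list()
  for (vid in unique(ed$viral_id)) {
    hs <- unique(ed$host_id[ed$viral_id == vid])
    if (length(hs) < 2L) next
    rk <- rank_of[hs]
    known <- rk[!is.na(rk) & nzchar(rk)]
    if (length(unique(known)) >= 2L) {
      status <- "candidate"
    } else if (length(known) < length(rk)) {
      status <- "unrankable"
    } else {
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      viral_id = vid, n_hosts = length(hs),
      hosts = paste(hs, collapse = ";"),
      ranks = paste(unique(known), collapse = ";"),
      rank = rank, status = status, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(viral_id = character(0), n_hosts = integer(0),
                      hosts = character(0), ranks = character(0),
                      rank = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Curate cross-taxon infection candidates
#'
#' Applies the per-candidate checklist used before accepting a cross-phylum
#' or cross-domain call: (a) every implicated MAG passes the quality gate;
#' (b) the scaffolds carrying the targeting CRISPR arrays meet a length
#' floor (flag-only: short scaffolds are recorded, never auto-failed,
#' since no hard floor is published); (c) the implicated arrays are
#' compared — a high identical-spacer count is annotated as a possible
#' horizontal transfer of the array; (d) when per-scaffold taxonomy is
#' supplied, the array-bearing scaffold's taxon must be congruent with its
#' MAG's lineage at the tested rank. The overall verdict is `pass` only if
#' no hard check fails.
#'
#' @param candidates Output of [find_cross_taxon()] (status `candidate`).
#' @param mags Full MAG table (for the quality gate).
#' @param matches Match `data.frame` (to locate the arrays/spacers behind
#'   each candidate link).
#' @param arrays List of `crispr_array` on host scaffolds.
#' @param host_scaffolds Host scaffold `data.frame` (`id`, `seq`,
#'   `mag_id`) for scaffold lengths.
#' @param scaffold_taxonomy Optional `data.frame` (`scaffold_id`, rank
#'   columns such as `phylum`) for check (d).
#' @param params [quality_params()].
#' @param hgt_share_min Identical-spacer count at or above which the HGT
#'   annotation is attached (default 10).
#' @return `data.frame`: one row per candidate with per-check outcomes and
#'   an overall `verdict`.
#' @export
curate_cross_taxon <- function(candidates, mags, matches, arrays,
                               host_scaffolds,
                               scaffold_taxonomy = NULL,
                               params = quality_params(),
                               hgt_share_min = 10) {
  candidates <- candidates[candidates$status == "candidate", , drop = FALSE]
  if (!nrow(candidates)) {
    return(data.frame(viral_id = character(0), verdict = character(0),
                      stringsAsFactors = FALSE))
  }
  passq <- quality_filter_mags(mags, params)$mag_id
  scaf_len <- stats::setNames(nchar(host_scaffolds$seq), host_scaffolds$id)
  scaf_mag <- stats::setNames(host_scaffolds$mag_id, host_scaffolds$id)
  arr_by_id <- stats::setNames(arrays, vapply(arrays, function(a) a$array_id, ""))
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    hs <- strsplit(cd$hosts, ";", fixed = TRUE)[[1]]
    quality_ok <- all(hs %in% passq)
    # arrays whose spacers support this candidate's links
    sel <- matches$target_id == cd$viral_id & matches$owner_id %in% hs &
      !matches$in_array
    arr_ids <- unique(sub(":[0-9]+$", "", matches$spacer_id[sel]))
    arr_ids <- arr_ids[arr_ids %in% names(arr_by_id)]
    imp_arrays <- arr_by_id[arr_ids]
    scafs <- vapply(imp_arrays, function(a) a$scaffold_id, "")
    lens <- scaf_len[scafs]
    length_flag <- length(lens) > 0 &&
      any(!is.na(lens) & lens < params$min_curation_scaffold_len)
    shared <- 0L
    if (length(imp_arrays) >= 2L) {
      combs <- utils::combn(length(imp_arrays), 2L)
      for (ci in seq_len(ncol(combs))) {
        cmpv <- compare_arrays(imp_arrays[[combs[1, ci]]],
                               imp_arrays[[combs[2, ci]]])
        shared <- max(shared, cmpv$shared_spacer_count)
      }
    }
    hgt <- shared >= hgt_share_min
    tax_ok <- TRUE
    if (!is.null(scaffold_taxonomy) && nrow(candidates) &&
        cd$rank %in% names(scaffold_taxonomy)) {
      mag_rank <- stats::setNames(mags[[cd$rank]], mags$mag_id)
      st <- stats::setNames(scaffold_taxonomy[[cd$rank]],
                            scaffold_taxonomy$scaffold_id)
      for (sc in scafs) {
        if (!sc %in% names(st)) next
        expect <- mag_rank[[scaf_mag[[sc]]]]
        if (nzchar(st[[sc]]) && nzchar(expect) && st[[sc]] != expect) {
          tax_ok <- FALSE
        }
      }
    }
    verdict <- if (quality_ok && tax_ok) "pass" else "fail"
    reasons <- c(
      if (!quality_ok) "MAG quality gate failed",
      if (length_flag) "array scaffold below curation length floor (flag)",
      if (hgt) sprintf("arrays share %d identical spacers (possible HGT)",
                       shared),
      if (!tax_ok) "scaffold taxonomy incongruent with MAG lineage")
    out[[length(out) + 1L]] <- data.frame(
      viral_id = cd$viral_id, rank = cd$rank, hosts = cd$hosts,
      quality_ok = quality_ok, scaffold_length_flag = length_flag,
      shared_spacers = shared, possible_hgt = hgt,
      taxonomy_congruent = tax_ok, verdict = verdict,
      reasons = paste(reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
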