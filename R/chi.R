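#' Chi motif parameters
#'
#' The default motif is the canonical E. coli Chi octamer 5'-GCTGGTGG-3',
#' the RecBCD attenuation signal whose depletion on a viral element is
#' associated with increased spacer acquisition. The motif is counted on
#' both strands by default (the orientation convention is recorded in the
#' output), with overlapping occurrences allowed, and densities are
#' normalized per 1000 bp.
#'
#' @param motif DNA motif (length >= 4).
#' @param both_strands Count reverse-complement occurrences too.
#' @param window Normalization window in bp (density = count * window /
#'   length).
#' @return A classed list (`chi_params`).
#' @export
chi_params <- function(motif = "GCTGGTGG", both_strands = TRUE,
                       window = 1000) {
  stopifnot(nchar(motif) >= 4, grepl("^[ACGT]+$", motif), window > 0)
  structure(list(motif = motif, both_strands = isTRUE(both_strands),
                 window = as.numeric(window)),
            class = "chi_params")
}

#' Chi site count and density for one scaffold
#'
#' @param scaffold List or one-row `data.frame` with `seq` (and optionally
#'   `id`).
#' @param params [chi_params()].
#' @return List with `count` and `density` (occurrences per `window` bp).
#' @export
chi_density <- function(scaffold, params = chi_params()) {
  s <- Biostrings::DNAString(scaffold$seq[[1]])
  count <- Biostrings::countPattern(params$motif, s)
  if (params$both_strands) {
    count <- count + Biostrings::countPattern(dna_revcomp(params$motif), s)
  }
  list(count = count,
       density = count * params$window / length(s))
}

#' Relate Chi density to targeting intensity across networks
#'
#' Builds the per-virus table behind the Chi-depletion analysis: for every
#' viral element targeted in any of the supplied networks, its Chi density,
#' the total number of protospacer loci targeting it summed across
#' networks, and whether any single host hyper-targets it. Subgroup
#' summaries (mean and median density for all targeted and for
#' hyper-targeted elements, half-up rounded to 2 decimals) and a Spearman
#' rank correlation between density and targeting count with a seeded
#' permutation p-value are attached.
#'
#' @param networks List of `vh_network`.
#' @param virals `data.frame` (`id`, `seq`) covering the networks' viral
#'   nodes.
#' @param params [chi_params()].
#' @param hyper_threshold Hyper-targeting threshold (default 20).
#' @param n_perm Permutations for the p-value (default 10000).
#' @param seed Seed for the permutation stream.
#' @return List with `table` (`viral_id`, `chi_count`, `chi_density`,
#'   `times_targeted`, `hyper`, `both_strands`), `summary`, and
#'   `spearman` (`rho`, `p_value`; `rho` is `NA` with a note when ranks
#'   are degenerate).
#' @export
chi_vs_targeting <- function(networks, virals, params = chi_params(),
                             hyper_threshold = 20, n_perm = 10000,
                             seed = 1) {
  tot <- list()
  hyper <- character(0)
  for (net in networks) {
    for (i in seq_len(nrow(net$edges))) {
      vid <- net$edges$viral_id[i]
      w <- net$edges$weight[i]
      tot[[vid]] <- (if (is.null(tot[[vid]])) 0 else tot[[vid]]) + w
      if (w >= hyper_threshold) hyper <- union(hyper, vid)
    }
  }
  if (!length(tot)) {
    return(list(table = data.frame(viral_id = character(0),
                                   chi_count = integer(0),
                                   chi_density = numeric(0),
                                   times_targeted = integer(0),
                                   hyper = logical(0),
                                   both_strands = logical(0)),
                summary = NULL, spearman = NULL))
  }
  ids <- names(tot)
  seq_of <- stats::setNames(virals$seq, virals$id)
  dens <- numeric(length(ids))
  cnt <- integer(length(ids))
  for (i in seq_along(ids)) {
    if (!ids[i] %in% names(seq_of)) {
      sl_error("sl_consistency_error",
               paste0("network viral node ", ids[i], " missing from virals"))
    }
    cd <- chi_density(list(seq = seq_of[[ids[i]]]), params)
    dens[i] <- cd$density
    cnt[i] <- cd$count
  }
  tab <- data.frame(viral_id = ids, chi_count = cnt, chi_density = dens,
                    times_targeted = unlist(tot, use.names = FALSE),
                    hyper = ids %in% hyper,
                    both_strands = params$both_strands,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$times_targeted, tab$viral_id), ]
  rownames(tab) <- NULL
  summary <- list(
    mean_all = round_half_up(mean(tab$chi_density), 2),
    median_all = round_half_up(stats::median(tab$chi_density), 2),
    mean_hyper = if (any(tab$hyper))
      round_half_up(mean(tab$chi_density[tab$hyper]), 2) else NA_real_,
    median_hyper = if (any(tab$hyper))
      round_half_up(stats::median(tab$chi_density[tab$hyper]), 2) else NA_real_)
  spearman <- spearman_permutation(tab$chi_density, tab$times_targeted,
                                   n_perm = n_perm, seed = seed)
  list(table = tab, summary = summary, spearman = spearman)
}

#' Spearman correlation with a permutation p-value
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutation stream.
#' @return List with `rho`, `p_value`, `n`, and `note` when the
#'   correlation is undefined (fewer than 3 pairs or zero variance in
#'   either rank vector).
#' @export
spearman_permutation <- function(x, y, n_perm = 10000, seed = 1) {
  n <- length(x)
  if (n < 3 || stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                note = "correlation undefined (degenerate ranks)"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      stats::cor(x, sample(y), method = "spearman"), 0)
  })
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(rho = rho, p_value = p, n = n, note = NULL)
}

#' Write the per-virus Chi table as TSV
#'
#' @param chi Result of [chi_vs_targeting()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_chi_tsv <- function(chi, path) {
  utils::write.table(chi$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
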