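#' Provirus calling parameters
#'
#' Retention thresholds for calling a viral element a provirus within a
#' host genome bin: bit score >= 50, E-value <= 1e-3, alignment length of
#' at least 2500 bp, and average nucleotide identity >= 70% over the alignment
#' (gap columns count as non-matches). When 90% or more of a host-bin
#' scaffold aligns with the viral scaffold, the call is reclassified as a
#' co-binned free viral scaffold rather than an integration.
#'
#' @param min_bitscore Minimum bit score.
#' @param max_evalue Maximum E-value.
#' @param min_aln_len Minimum alignment length in columns.
#' @param min_identity Minimum average nucleotide identity (fraction).
#' @param cobin_fraction Host-scaffold aligned fraction at or above which
#'   the call is `cobinned` rather than `integrated`.
#' @param aln_match,aln_mismatch Nucleotide match/mismatch scores for the
#'   local aligner.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param anchor_k Exact word size used to prefilter scaffold pairs before
#'   alignment (pairs sharing no word are skipped).
#' @return A classed list (`provirus_params`).
#' @export
provirus_params <- function(min_bitscore = 50, max_evalue = 1e-3,
                            min_aln_len = 2500, min_identity = 0.70,
                            cobin_fraction = 0.90,
                            aln_match = 1, aln_mismatch = -2,
                            gap_open = 5, gap_extend = 2,
                            anchor_k = 16) {
  stopifnot(min_bitscore > 0, max_evalue > 0, min_aln_len > 0,
            min_identity > 0, min_identity <= 1,
            cobin_fraction > 0, cobin_fraction <= 1)
  structure(list(min_bitscore = as.numeric(min_bitscore),
                 max_evalue = as.numeric(max_evalue),
                 min_aln_len = as.numeric(min_aln_len),
                 min_identity = as.numeric(min_identity),
                 cobin_fraction = as.numeric(cobin_fraction),
                 aln_match = as.numeric(aln_match),
                 aln_mismatch = as.numeric(aln_mismatch),
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 anchor_k = as.numeric(anchor_k)),
            class = "provirus_params")
}

#' Detect CRISPR arrays on viral scaffolds
#'
#' Runs array detection over the (unclustered) viral set — clustering is
#' deferred so array variation between closely related viral elements is
#' preserved — and reports summary statistics: how many viral elements
#' encode arrays, the fraction of the set (as a percentage rounded to two
#' decimals), spacer-count range/mean, and the number of arrays with more
#' than 10 spacers.
#'
#' @param virals `data.frame` with `id` and `seq`.
#' @param params [detect_params()].
#' @return List with `arrays` (list of `crispr_array`) and `summary`.
#' @export
find_viral_arrays <- function(virals, params = detect_params()) {
  arrays <- detect_arrays_all(virals, params)
  owners <- unique(vapply(arrays, function(a) a$scaffold_id, ""))
  counts <- vapply(arrays, function(a) nrow(a$spacers), 0L)
  list(arrays = arrays, summary = list(
    n_viral = nrow(virals),
    n_with_arrays = length(owners),
    pct_with_arrays = if (nrow(virals))
      round_half_up(100 * length(owners) / nrow(virals), 2) else 0,
    n_arrays = length(arrays),
    spacer_count_min = if (length(counts)) min(counts) else NA_integer_,
    spacer_count_max = if (length(counts)) max(counts) else NA_integer_,
    spacer_count_mean = if (length(counts)) mean(counts) else NA_real_,
    n_arrays_gt10 = sum(counts > 10)))
}

#' Detect interviral conflicts
#'
#' Spacers excised from virally encoded CRISPR arrays are searched against
#' all viral scaffolds under the standard retention rules; self-hits
#' (source element = target element) are excluded. A conflict is genuine
#' only if at least one supporting match falls outside the target's own
#' CRISPR arrays: matches between spacers of two distinct viral arrays are
#' spacer-to-spacer connections, which carry no protospacer-adjacent motif
#' and are not genuine interviral conflicts.
#'
#' @param viral_spacers Spacer `data.frame` from the viral arrays
#'   (`owner_id` = source viral element).
#' @param index `seq_index` over all viral scaffolds.
#' @param viral_arrays List of `crispr_array` on the viral scaffolds (for
#'   in-array flagging).
#' @param params [match_params()].
#' @return List with `matches` (flagged match table, self-hits removed) and
#'   `conflicts`: one row per (source, target) pair with `n_matches`,
#'   `genuine`, `reason`.
#' @export
find_conflicts <- function(viral_spacers, index, viral_arrays,
                           params = match_params()) {
  matches <- find_protospacers(viral_spacers, index, params)
  if (nrow(matches)) {
    matches <- matches[matches$owner_id != matches$target_id, , drop = FALSE]
    matches <- flag_in_array(matches, viral_arrays)
  }
  if (!nrow(matches)) {
    return(list(matches = matches,
                conflicts = data.frame(source_viral_id = character(0),
                                       target_viral_id = character(0),
                                       n_matches = integer(0),
                                       genuine = logical(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)))
  }
  key <- paste(matches$owner_id, matches$target_id, sep = "\r")
  conf <- lapply(split(seq_len(nrow(matches)), key), function(ix) {
    mm <- matches[ix, ]
    genuine <- any(!mm$in_array)
    data.frame(
      source_viral_id = mm$owner_id[1], target_viral_id = mm$target_id[1],
      n_matches = nrow(mm), genuine = genuine,
      reason = if (genuine) "protospacer match outside target arrays" else
        "all matches are spacer-to-spacer (within target CRISPR arrays)",
      stringsAsFactors = FALSE)
  })
  conf <- do.call(rbind, conf)
  rownames(conf) <- NULL
  list(matches = matches,
       conflicts = conf[order(conf$source_viral_id, conf$target_viral_id), ])
}

.nuc_submat <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = params$aln_match, mismatch = params$aln_mismatch,
    baseOnly = FALSE)
}

.kmer_code_set <- function(seq, k) {
  v <- encode_kmers(seq, k)
  unique(v[!is.na(v)])
}

#' Align viral scaffolds to host-bin scaffolds
#'
#' Local (Smith-Waterman) alignment of each viral scaffold against each
#' host-bin scaffold, on both strands, with a shared-exact-word prefilter
#' (`anchor_k`) so only pairs that can plausibly align are scored. Average
#' nucleotide identity is matches over alignment columns including gaps;
#' bit scores use the ungapped Karlin-Altschul parameters of
#' [match_params()] applied to the aligner's raw score, and
#' E = m * n * 2^(-bitscore).
#'
#' @param virals `data.frame` (`id`, `seq`) of viral scaffolds.
#' @param host_scaffolds `data.frame` (`id`, `seq`, optional `mag_id`).
#' @param params [provirus_params()].
#' @param match_params [match_params()] (Karlin-Altschul constants).
#' @return `data.frame`: one row per retained pair with `viral_id`,
#'   `host_mag_id`, `host_scaffold_id`, `start`, `end` (0-based half-open
#'   on the host scaffold), `strand`, `aligned_len` (columns), `n_match`,
#'   `identity`, `score`, `bitscore`, `evalue`. Only alignments with
#'   positive score are reported; thresholding happens in
#'   [call_proviruses()].
#' @export
align_viral_to_bins <- function(virals, host_scaffolds,
                                params = provirus_params(),
                                match_params = spacerlink::match_params()) {
  submat <- .nuc_submat(params)
  k <- as.integer(params$anchor_k)
  total_host_bp <- sum(nchar(host_scaffolds$seq))
  host_codes <- lapply(host_scaffolds$seq, .kmer_code_set, k = k)
  if (is.null(host_scaffolds$mag_id)) host_scaffolds$mag_id <- NA_character_
  out <- list()
  for (vi in seq_len(nrow(virals))) {
    vseq <- virals$seq[vi]
    vcodes_f <- .kmer_code_set(vseq, k)
    vrc <- dna_revcomp(vseq)
    vcodes <- sort(unique(c(vcodes_f, .kmer_code_set(vrc, k))))
    for (hi in seq_len(nrow(host_scaffolds))) {
      if (!any(.in_sorted(vcodes, host_codes[[hi]]))) next
      hseq <- host_scaffolds$seq[hi]
      best <- NULL
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") vseq else vrc
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAString(pat),
          subject = Biostrings::DNAString(hseq),
          type = "local", substitutionMatrix = submat,
          gapOpening = params$gap_open, gapExtension = params$gap_extend)
        sc <- Biostrings::score(aln)
        if (is.null(best) || sc > best$score) {
          best <- list(aln = aln, score = sc, strand = strand)
        }
      }
      if (best$score <= 0) next
      aln <- best$aln
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      nmatch <- Biostrings::nmatch(aln)
      subj <- Biostrings::subject(aln)
      s0 <- Biostrings::start(subj@range) - 1L
      e0 <- Biostrings::end(subj@range)
      bit <- (match_params$ka_lambda * best$score - log(match_params$ka_K)) /
        log(2)
      ev <- nchar(vseq) * total_host_bp * 2^(-bit)
      out[[length(out) + 1L]] <- data.frame(
        viral_id = virals$id[vi],
        host_mag_id = host_scaffolds$mag_id[hi],
        host_scaffold_id = host_scaffolds$id[hi],
        start = s0, end = e0, strand = best$strand,
        aligned_len = cols, n_match = nmatch,
        identity = nmatch / cols, score = best$score,
        bitscore = bit, evalue = ev, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(viral_id = character(0), host_mag_id = character(0),
                      host_scaffold_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      aligned_len = integer(0), n_match = integer(0),
                      identity = numeric(0), score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify provirus calls
#'
#' Applies the four retention thresholds to viral-to-bin alignments and
#' classifies each retained call: `cobinned` when the aligned span covers
#' at least `cobin_fraction` (default 90%) of the host-bin scaffold —
#' indicating a free viral scaffold binned with the host rather than an
#' integration — else `integrated`.
#'
#' @param alignments Output of [align_viral_to_bins()].
#' @param params [provirus_params()].
#' @param host_scaffold_lengths Named vector: host scaffold id -> length.
#' @return `data.frame` of provirus calls with a `class` column.
#' @export
call_proviruses <- function(alignments, params = provirus_params(),
                            host_scaffold_lengths) {
  al <- alignments
  keep <- al$bitscore >= params$min_bitscore &
    al$evalue <= params$max_evalue &
    al$aligned_len >= params$min_aln_len &
    al$identity >= params$min_identity
  al <- al[keep, , drop = FALSE]
  if (!nrow(al)) {
    al$class <- character(0)
    al$host_aligned_fraction <- numeric(0)
    return(al)
  }
  hl <- host_scaffold_lengths[al$host_scaffold_id]
  al$host_aligned_fraction <- (al$end - al$start) / hl
  al$class <- ifelse(al$host_aligned_fraction >= params$cobin_fraction,
                     "cobinned", "integrated")
  rownames(al) <- NULL
  al
}

#' Write provirus calls as GFF3 intervals on host scaffolds
#'
#' @param calls Output of [call_proviruses()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_provirus_gff <- function(calls, path) {
  if (!nrow(calls)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$host_scaffold_id,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = calls$strand, type = "mobile_genetic_element")
  S4Vectors::mcols(gr)$ID <- sprintf("provirus_%s_%d", calls$viral_id,
                                     seq_len(nrow(calls)))
  S4Vectors::mcols(gr)$Name <- calls$viral_id
  S4Vectors::mcols(gr)$class <- calls$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Report provirus-mediated superinfection exclusion
#'
#' For each (host, targeted virus) pair supported by host spacer matches,
#' attributes each supporting match's source array to a provirus-encoded
#' array (the array interval lies inside a called provirus on the same
#' host scaffold) or a host-native array. Pairs supported only by
#' spacer-to-spacer (`in_array`) connections are flagged non-immunizing:
#' without a protospacer-adjacent motif such matches cannot direct Cas
#' cleavage.
#'
#' @param proviruses Output of [call_proviruses()].
#' @param host_arrays List of `crispr_array` on host scaffolds.
#' @param matches Match `data.frame` from host spacers against viral
#'   targets (after [flag_in_array()]).
#' @return `data.frame`: one row per (host array-owner, target virus) with
#'   `n_provirus_matches`, `n_native_matches`, `attribution`,
#'   `non_immunizing`.
#' @export
superinfection_report <- function(proviruses, host_arrays, matches) {
  if (!nrow(matches)) {
    return(data.frame(owner_id = character(0), target_id = character(0),
                      n_provirus_matches = integer(0),
                      n_native_matches = integer(0),
                      attribution = character(0),
                      non_immunizing = logical(0), stringsAsFactors = FALSE))
  }
  arr_by_id <- stats::setNames(host_arrays,
                               vapply(host_arrays, function(a) a$array_id, ""))
  in_provirus <- function(array_id) {
    a <- arr_by_id[[array_id]]
    if (is.null(a) || !nrow(proviruses)) return(FALSE)
    sel <- proviruses$host_scaffold_id == a$scaffold_id
    any(sel & proviruses$start <= a$start & proviruses$end >= a$end)
  }
  matches$array_id <- sub(":[0-9]+$", "", matches$spacer_id)
  key <- paste(matches$owner_id, matches$target_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(matches)), key), function(ix) {
    mm <- matches[ix, ]
    pv <- vapply(mm$array_id, in_provirus, TRUE)
    npv <- sum(pv)
    nnat <- sum(!pv)
    attribution <- if (npv > 0 && nnat > 0) "both" else
      if (npv > 0) "provirus-encoded" else "host-native"
    data.frame(owner_id = mm$owner_id[1], target_id = mm$target_id[1],
               n_provirus_matches = npv, n_native_matches = nnat,
               attribution = attribution,
               non_immunizing = all(mm$in_array),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$owner_id, res$target_id), ]
}
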