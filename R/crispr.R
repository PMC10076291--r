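#' CRISPR array detection parameters
#'
#' Defaults follow common CRISPR-finder conventions: direct repeats of
#' 21-48 bp, spacers of 15-70 bp, at least 2 spacers per array, repeats
#' within 20% of the array consensus, and a spacer-pair identity ceiling of
#' 0.6 that guards against plain tandem repeats being reported as arrays.
#'
#' @param repeat_len Numeric length-2 range for repeat length in bp.
#' @param spacer_len Numeric length-2 range for spacer length in bp.
#' @param min_spacers Minimum spacer count (the smallest reported arrays
#'   carry 2 spacers).
#' @param max_repeat_mismatch_frac Maximum per-column disagreement fraction
#'   tolerated while extending a candidate repeat.
#' @param max_spacer_pair_identity Any spacer pair more similar than this is
#'   taken as evidence of a tandem repeat and the candidate is rejected.
#' @param seed_k Exact seed word size for the periodic repeat finder.
#' @return A classed list (`detect_params`).
#' @export
detect_params <- function(repeat_len = c(21, 48), spacer_len = c(15, 70),
                          min_spacers = 2, max_repeat_mismatch_frac = 0.2,
                          max_spacer_pair_identity = 0.6, seed_k = 11) {
  repeat_len <- as.numeric(repeat_len)
  spacer_len <- as.numeric(spacer_len)
  stopifnot(length(repeat_len) == 2L, length(spacer_len) == 2L,
            repeat_len[1] <= repeat_len[2], spacer_len[1] <= spacer_len[2],
            min_spacers >= 1,
            max_repeat_mismatch_frac >= 0, max_repeat_mismatch_frac <= 1,
            max_spacer_pair_identity >= 0, max_spacer_pair_identity <= 1,
            seed_k >= 4, seed_k <= repeat_len[1])
  structure(list(repeat_len = repeat_len, spacer_len = spacer_len,
                 min_spacers = as.numeric(min_spacers),
                 max_repeat_mismatch_frac = as.numeric(max_repeat_mismatch_frac),
                 max_spacer_pair_identity = as.numeric(max_spacer_pair_identity),
                 seed_k = as.numeric(seed_k)),
            class = c("detect_params"))
}

# Construct a CRISPR array record. Intervals are 0-based half-open on the
# scaffold; repeats and spacers alternate (n_repeats == n_spacers + 1).
new_crispr_array <- function(array_id, scaffold_id, start0, end0,
                             repeats, spacers, consensus_repeat,
                             flank_5p = "", flank_3p = "", partial = FALSE) {
  arr <- structure(list(
    array_id = array_id, scaffold_id = scaffold_id,
    start = start0, end = end0,
    repeats = repeats,        # data.frame(start, end)
    spacers = spacers,        # data.frame(index, start, end, seq)
    consensus_repeat = consensus_repeat,
    flank_5p = flank_5p, flank_3p = flank_3p,
    partial = partial
  ), class = "crispr_array")
  validate_crispr_array(arr)
  arr
}

validate_crispr_array <- function(arr) {
  nr <- nrow(arr$repeats)
  ns <- nrow(arr$spacers)
  if (nr != ns + 1L) {
    sl_error("sl_format_error", sprintf(
      "array %s: %d repeats but %d spacers (need n_repeats == n_spacers + 1)",
      arr$array_id, nr, ns))
  }
  if (ns < 2L) {
    sl_error("sl_format_error", sprintf(
      "array %s: %d spacers (minimum is 2)", arr$array_id, ns))
  }
  units <- rbind(
    data.frame(start = arr$repeats$start, end = arr$repeats$end, kind = "repeat"),
    data.frame(start = arr$spacers$start, end = arr$spacers$end, kind = "spacer"))
  units <- units[order(units$start), ]
  if (any(utils::head(units$end, -1) > utils::tail(units$start, -1))) {
    sl_error("sl_format_error", sprintf("array %s: overlapping units", arr$array_id))
  }
  if (!all(units$kind == rep(c("repeat", "spacer"), length.out = nrow(units)))) {
    sl_error("sl_format_error", sprintf(
      "array %s: repeats and spacers do not alternate", arr$array_id))
  }
  invisible(arr)
}

#' Detect CRISPR arrays on a scaffold
#'
#' A CRT-style periodic-repeat finder: all exact `seed_k`-mers are indexed;
#' words recurring with a period compatible with one repeat plus one spacer
#' are chained; each chained occurrence set is extended left and right while
#' the per-column majority agreement stays at or above
#' `1 - max_repeat_mismatch_frac`, then trimmed back to unanimous boundary
#' columns; spacers are the inter-repeat gaps. Candidates whose repeat or
#' spacer lengths leave the configured ranges, or any of whose spacer pairs
#' exceed `max_spacer_pair_identity` (tandem-repeat guard), are rejected.
#' Maximal non-overlapping arrays are emitted leftmost-first. Deterministic.
#'
#' Arrays flush against a scaffold edge are kept and flagged `partial`
#' (one flank missing does not disqualify an array).
#'
#' @param scaffold A list or one-row `data.frame` with `id` and `seq`.
#' @param params [detect_params()].
#' @return A list of `crispr_array` objects (empty when nothing is found).
#' @export
detect_arrays <- function(scaffold, params = detect_params()) {
  id <- scaffold$id[[1]]
  s <- scaffold$seq[[1]]
  n <- nchar(s)
  k <- as.integer(params$seed_k)
  rep_rng <- params$repeat_len
  sp_rng <- params$spacer_len
  min_period <- rep_rng[1] + sp_rng[1]
  max_period <- rep_rng[2] + sp_rng[2]
  min_occ <- params$min_spacers + 1
  if (n < min_occ * rep_rng[1] + params$min_spacers * sp_rng[1]) return(list())

  codes <- encode_kmers(s, k)
  ok <- !is.na(codes)
  if (!any(ok)) return(list())
  code <- codes[ok]
  pos <- which(ok) - 1L
  o <- order(code, pos)
  code <- code[o]
  pos <- pos[o]
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$lengths >= min_occ)
  if (!length(sel)) return(list())
  pos_by_code <- lapply(sel, function(i) pos[starts[i]:ends[i]])
  # process seeds by leftmost occurrence
  ord <- order(vapply(pos_by_code, min, 0))
  pos_by_code <- pos_by_code[ord]

  candidates <- list()
  seen <- character(0)
  for (ps_all in pos_by_code) {
    # split occurrence run wherever the gap leaves the period window
    d <- diff(ps_all)
    brk <- which(d < min_period | d > max_period)
    seg_start <- c(1L, brk + 1L)
    seg_end <- c(brk, length(ps_all))
    for (sgi in seq_along(seg_start)) {
      ps <- ps_all[seg_start[sgi]:seg_end[sgi]]
      if (length(ps) < min_occ) next
      cand <- extend_repeat_set(s, n, ps, k, params)
      if (is.null(cand)) next
      key <- paste(cand$starts[1], cand$starts[length(cand$starts)],
                   cand$len)
      if (key %in% seen) next
      seen <- c(seen, key)
      arr <- finalize_array(id, s, n, cand, params, "pending")
      if (is.null(arr)) next
      candidates[[length(candidates) + 1L]] <- arr
    }
  }
  if (!length(candidates)) return(list())
  # maximal arrays win where candidates overlap (a junction-spanning seed
  # can assemble a small fragment of a larger array); then leftmost-first
  ns <- vapply(candidates, function(a) nrow(a$spacers), 0L)
  st <- vapply(candidates, function(a) a$start, 0)
  candidates <- candidates[order(-ns, st)]
  accepted <- list()
  covered <- matrix(numeric(0), ncol = 2)
  for (arr in candidates) {
    if (nrow(covered) == 0 ||
        all(arr$end <= covered[, 1] | arr$start >= covered[, 2])) {
      accepted[[length(accepted) + 1L]] <- arr
      covered <- rbind(covered, c(arr$start, arr$end))
    }
  }
  accepted <- accepted[order(vapply(accepted, function(a) a$start, 0))]
  for (i in seq_along(accepted)) {
    accepted[[i]]$array_id <- sprintf("%s_arr%d", id, i)
    sp <- accepted[[i]]$spacers
    accepted[[i]]$spacers$index <- seq_len(nrow(sp)) - 1L
  }
  accepted
}

# Extend a set of identical-seed occurrences into full repeat intervals.
# Returns list(starts, len) of repeat occurrences, or NULL.
extend_repeat_set <- function(s, n, ps, k, params) {
  r <- length(ps)
  thr <- 1 - params$max_repeat_mismatch_frac
  max_len <- params$repeat_len[2]
  chars_at <- function(off) {
    # column of characters at seed offset `off` for every occurrence
    substring(s, ps + off + 1L, ps + off + 1L)
  }
  col_agree <- function(off) {
    if (any(ps + off < 0L) || any(ps + off >= n)) return(list(a = -1, u = FALSE))
    cc <- chars_at(off)
    tab <- table(cc)
    list(a = max(tab) / r, u = length(tab) == 1L && !("N" %in% names(tab)))
  }
  left <- 0L
  while (k + left < max_len) {
    ca <- col_agree(-(left + 1L))
    if (ca$a < thr) break
    left <- left + 1L
  }
  right <- 0L
  while (k + left + right < max_len) {
    ca <- col_agree(k + right)
    if (ca$a < thr) break
    right <- right + 1L
  }
  # trim non-unanimous boundary columns so that identical planted repeats
  # recover exact boundaries (a lone coincidental majority column at a
  # boundary otherwise shifts every adjacent spacer by one base)
  while (left > 0L && !col_agree(-left)$u) left <- left - 1L
  while (right > 0L && !col_agree(k + right - 1L)$u) right <- right - 1L
  len <- k + left + right
  if (len < params$repeat_len[1] || len > params$repeat_len[2]) return(NULL)
  starts <- ps - left
  # occurrences must not overlap (period guard should ensure this)
  if (any(diff(starts) < len)) return(NULL)
  list(starts = starts, len = len)
}

finalize_array <- function(id, s, n, cand, params, array_id) {
  starts <- cand$starts
  len <- cand$len
  rep_df <- data.frame(start = starts, end = starts + len)
  gaps_start <- utils::head(rep_df$end, -1)
  gaps_end <- utils::tail(rep_df$start, -1)
  gap_len <- gaps_end - gaps_start
  # drop trailing/leading occurrences whose gap is out of spacer range by
  # keeping the longest valid consecutive stretch
  ok <- gap_len >= params$spacer_len[1] & gap_len <= params$spacer_len[2]
  if (!all(ok)) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts_r <- ends - runs$lengths + 1L
    best <- which(runs$values & runs$lengths >= params$min_spacers)
    if (!length(best)) return(NULL)
    bi <- best[which.max(runs$lengths[best])]
    sel <- starts_r[bi]:(ends[bi] + 1L)  # repeats spanning the gap run
    rep_df <- rep_df[sel, , drop = FALSE]
    gaps_start <- utils::head(rep_df$end, -1)
    gaps_end <- utils::tail(rep_df$start, -1)
  }
  ns <- nrow(rep_df) - 1L
  if (ns < params$min_spacers) return(NULL)
  spacer_seq <- substring(s, gaps_start + 1L, gaps_end)
  # tandem-repeat guard: reject if any spacer pair is too similar
  if (ns >= 2L) {
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        if (ungapped_identity(spacer_seq[i], spacer_seq[j]) >
            params$max_spacer_pair_identity) return(NULL)
      }
    }
  }
  rep_seqs <- substring(s, rep_df$start + 1L, rep_df$end)
  cons <- column_consensus(rep_seqs)$consensus
  a_start <- rep_df$start[1]
  a_end <- rep_df$end[nrow(rep_df)]
  new_crispr_array(
    array_id = array_id, scaffold_id = id, start0 = a_start, end0 = a_end,
    repeats = data.frame(start = rep_df$start, end = rep_df$end),
    spacers = data.frame(index = seq_len(ns) - 1L, start = gaps_start,
                         end = gaps_end, seq = spacer_seq,
                         stringsAsFactors = FALSE),
    consensus_repeat = cons,
    flank_5p = seq_slice(s, max(0L, a_start - 200L), a_start),
    flank_3p = seq_slice(s, a_end, min(n, a_end + 200L)),
    partial = (a_start == 0L || a_end == n))
}

#' Detect CRISPR arrays across a scaffold collection
#'
#' @param scaffolds `data.frame` with `id` and `seq` columns.
#' @param params [detect_params()].
#' @return Flat list of `crispr_array` objects.
#' @export
detect_arrays_all <- function(scaffolds, params = detect_params()) {
  out <- list()
  for (i in seq_len(nrow(scaffolds))) {
    out <- c(out, detect_arrays(scaffolds[i, ], params))
  }
  out
}

#' Excise spacers from a CRISPR array
#'
#' Returns one spacer per inter-repeat gap, ordered 5'->3' on the scaffold
#' strand, with stable ids of the form `{array_id}:{index}`.
#'
#' @param array A `crispr_array`.
#' @param owner_id Id of the owning genome bin (or viral element).
#' @return `data.frame` with columns `spacer_id`, `owner_id`, `scaffold_id`,
#'   `array_id`, `index_in_array`, `seq`.
#' @export
excise_spacers <- function(array, owner_id) {
  sp <- array$spacers
  data.frame(
    spacer_id = sprintf("%s:%d", array$array_id, sp$index),
    owner_id = owner_id,
    scaffold_id = array$scaffold_id,
    array_id = array$array_id,
    index_in_array = sp$index,
    seq = sp$seq,
    stringsAsFactors = FALSE)
}

#' Excise spacers from many arrays
#'
#' @param arrays List of `crispr_array`.
#' @param owner_of Named character vector mapping scaffold id to owner id
#'   (e.g. scaffold to MAG); scaffolds missing from the map use their own id.
#' @return Combined spacer `data.frame` (see [excise_spacers()]).
#' @export
excise_spacers_all <- function(arrays, owner_of = character(0)) {
  if (!length(arrays)) {
    return(data.frame(spacer_id = character(0), owner_id = character(0),
                      scaffold_id = character(0), array_id = character(0),
                      index_in_array = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(arrays, function(a) {
    owner <- if (a$scaffold_id %in% names(owner_of)) owner_of[[a$scaffold_id]]
             else a$scaffold_id
    excise_spacers(a, owner)
  }))
}

#' Write CRISPR arrays as GFF3
#'
#' Each array becomes a `repeat_region` feature with `direct_repeat` and
#' `spacer` children. Internal 0-based half-open intervals are emitted
#' 1-based inclusive as GFF3 mandates.
#'
#' @param arrays List of `crispr_array`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_arrays_gff <- function(arrays, path) {
  rows <- list()
  for (a in arrays) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = a$scaffold_id, type = "repeat_region",
      start = a$start + 1L, end = a$end,
      ID = a$array_id, Parent = NA_character_, stringsAsFactors = FALSE)
    rp <- a$repeats
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = a$scaffold_id, type = "direct_repeat",
      start = rp$start + 1L, end = rp$end,
      ID = sprintf("%s_r%d", a$array_id, seq_len(nrow(rp))),
      Parent = a$array_id, stringsAsFactors = FALSE)
    sp <- a$spacers
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = a$scaffold_id, type = "spacer",
      start = sp$start + 1L, end = sp$end,
      ID = sprintf("%s:%d", a$array_id, sp$index),
      Parent = a$array_id, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    type = df$type)
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load CRISPR arrays from GFF3 annotations
#'
#' Accepts externally provided array annotations (`repeat_region` features
#' with `direct_repeat`/`spacer` children), slices the corresponding
#' sequences out of the scaffolds, and enforces the structural invariants
#' (alternation, `n_repeats == n_spacers + 1`, in-bounds coordinates).
#'
#' @param path GFF3 path.
#' @param scaffolds `data.frame` with `id` and `seq` columns covering every
#'   scaffold the annotations reference.
#' @return List of `crispr_array`.
#' @export
load_arrays_gff <- function(path, scaffolds) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(as.list(df$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else "", "")
  seq_of <- stats::setNames(scaffolds$seq, scaffolds$id)
  parents <- df[df$type == "repeat_region", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(parents))) {
    pid <- parents$ID[i]
    sid <- as.character(parents$seqnames[i])
    if (!sid %in% names(seq_of)) {
      sl_error("sl_coordinate_error",
               paste0("GFF references unknown scaffold ", sid))
    }
    s <- seq_of[[sid]]
    n <- nchar(s)
    kids <- df[df$Parent == pid, , drop = FALSE]
    if (any(kids$end > n) || any(kids$start < 1)) {
      sl_error("sl_coordinate_error", paste0(
        "feature of array ", pid, " outside scaffold ", sid, " bounds"))
    }
    reps <- kids[kids$type == "direct_repeat", , drop = FALSE]
    sps <- kids[kids$type == "spacer", , drop = FALSE]
    reps <- reps[order(reps$start), , drop = FALSE]
    sps <- sps[order(sps$start), , drop = FALSE]
    ns <- nrow(sps)
    spacer_seq <- substring(s, sps$start, sps$end)
    a_start <- min(reps$start) - 1L
    a_end <- max(reps$end)
    rep_seqs <- substring(s, reps$start, reps$end)
    cons <- if (length(unique(nchar(rep_seqs))) == 1L) {
      column_consensus(rep_seqs)$consensus
    } else rep_seqs[[1]]
    out[[length(out) + 1L]] <- new_crispr_array(
      array_id = pid, scaffold_id = sid, start0 = a_start, end0 = a_end,
      repeats = data.frame(start = reps$start - 1L, end = reps$end),
      spacers = data.frame(index = seq_len(ns) - 1L, start = sps$start - 1L,
                           end = sps$end, seq = spacer_seq,
                           stringsAsFactors = FALSE),
      consensus_repeat = cons,
      flank_5p = seq_slice(s, max(0L, a_start - 200L), a_start),
      flank_3p = seq_slice(s, a_end, min(n, a_end + 200L)),
      partial = (a_start == 0L || a_end == n))
  }
  out
}
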