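#' Spacer-to-protospacer matching parameters
#'
#' Retention criteria for a spacer-protospacer hit: at most one mismatch,
#' query coverage of at least 90%, and an E-value of at most 1e-4. The
#' E-value is computed with ungapped Karlin-Altschul statistics under the
#' standard +2/-3 nucleotide scoring (lambda = 0.625, K = 0.41) over both
#' strands of the target set, so the criterion is computable without an
#' external aligner. "One mismatch" means one substitution; coverage below
#' 100% is realized only as contiguous clipping of at most
#' `floor((1 - min_query_coverage) * length)` bases from one end, the only
#' alignment shape consistent with >= 90% coverage plus <= 1 mismatch for
#' short queries.
#'
#' @param max_mismatches Maximum substitutions in the aligned core.
#' @param min_query_coverage Minimum aligned fraction of the spacer.
#' @param max_evalue E-value ceiling.
#' @param ka_lambda,ka_K Karlin-Altschul parameters.
#' @param reward,penalty Match reward and mismatch penalty.
#' @param index_k Exact word size of the target k-mer index.
#' @return A classed list (`match_params`).
#' @export
match_params <- function(max_mismatches = 1, min_query_coverage = 0.90,
                         max_evalue = 1e-4, ka_lambda = 0.625, ka_K = 0.41,
                         reward = 2, penalty = -3, index_k = 10) {
  stopifnot(max_mismatches >= 0, min_query_coverage > 0,
            min_query_coverage <= 1, max_evalue > 0, ka_lambda > 0, ka_K > 0,
            reward > 0, penalty < 0, index_k >= 4)
  structure(list(max_mismatches = as.numeric(max_mismatches),
                 min_query_coverage = as.numeric(min_query_coverage),
                 max_evalue = as.numeric(max_evalue),
                 ka_lambda = as.numeric(ka_lambda), ka_K = as.numeric(ka_K),
                 reward = as.numeric(reward), penalty = as.numeric(penalty),
                 index_k = as.numeric(index_k)),
            class = "match_params")
}

karlin_evalue <- function(score, m, n2, params) {
  params$ka_K * m * n2 * exp(-params$ka_lambda * score)
}

empty_matches <- function() {
  data.frame(spacer_id = character(0), owner_id = character(0),
             target_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), n_mismatches = integer(0),
             query_coverage = numeric(0), score = numeric(0),
             evalue = numeric(0), in_array = logical(0),
             stringsAsFactors = FALSE)
}

#' Build an exact k-mer index over target scaffolds
#'
#' Indexes every exact `k`-mer of every target on both strands (minus-strand
#' words are indexed on the reverse complement with positions in
#' reverse-complement coordinates). Words containing N are not indexed; they
#' can never form the exact anchor of an admissible hit because any column
#' involving N counts as a mismatch.
#'
#' @param targets `data.frame` with `id` and `seq` columns.
#' @param k Word size (default 10).
#' @return A `seq_index` object.
#' @export
build_target_index <- function(targets, k = 10) {
  stopifnot(nrow(targets) > 0)
  k <- as.integer(k)
  if (k > 15L) sl_error("sl_value_error", "index k must be <= 15")
  fwd <- stats::setNames(targets$seq, targets$id)
  rev <- stats::setNames(dna_revcomp(targets$seq), targets$id)
  code_l <- list()
  tidx_l <- list()
  pos_l <- list()
  str_l <- list()
  for (i in seq_len(nrow(targets))) {
    id <- targets$id[i]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd[[id]] else rev[[id]]
      codes <- encode_kmers(s, k)
      ok <- which(!is.na(codes))
      if (!length(ok)) next
      code_l[[length(code_l) + 1L]] <- as.integer(codes[ok])
      tidx_l[[length(tidx_l) + 1L]] <- rep.int(i, length(ok))
      pos_l[[length(pos_l) + 1L]] <- ok - 1L
      str_l[[length(str_l) + 1L]] <- rep.int(strand == "+", length(ok))
    }
  }
  code <- unlist(code_l)
  if (is.null(code)) code <- integer(0)
  tidx <- unlist(tidx_l)
  pos <- unlist(pos_l)
  plus <- unlist(str_l)
  # postings sorted by code; lookups are binary searches (findInterval)
  o <- order(code)
  structure(list(k = k, code = code[o],
                 target_idx = if (length(o)) tidx[o] else integer(0),
                 pos = if (length(o)) pos[o] else integer(0),
                 plus = if (length(o)) plus[o] else logical(0),
                 target_ids = targets$id,
                 fwd = fwd, rev = rev,
                 lengths = stats::setNames(nchar(targets$seq), targets$id),
                 total_bp = sum(nchar(targets$seq))),
            class = "seq_index")
}

# rows (indices into the posting vectors) holding exactly `code`
.index_lookup <- function(index, code) {
  fi <- findInterval(c(code - 1, code), index$code)
  if (fi[2] <= fi[1]) return(integer(0))
  (fi[1] + 1L):fi[2]
}

# Evaluate one candidate placement (target, strand, diagonal) of a spacer
# against an oriented target sequence and return the retained alignment
# windows. d0 is the 0-based oriented-target position aligned to spacer
# position 1. Among admissible windows on the diagonal (one-end clipping
# within the coverage budget, <= max_mismatches), only the maximal-score
# windows are reported (ties all kept), mirroring a local aligner.
evaluate_diagonal <- function(q, tseq, nt, d0, params, n2) {
  m <- length(q)
  maxclip <- floor((1 - params$min_query_coverage) * m + 1e-9)
  # mismatch profile over spacer positions; NA where target is out of bounds
  tpos <- d0 + seq_len(m) - 1L
  inb <- tpos >= 0L & tpos < nt
  mmv <- rep(NA, m)
  if (any(inb)) {
    tch <- utf8ToInt(substring(tseq, min(tpos[inb]) + 1L, max(tpos[inb]) + 1L))
    nN <- utf8ToInt("N")
    qi <- q[inb]
    mmv[inb] <- (tch != qi) | (tch == nN) | (qi == nN)
  }
  specs <- rbind(
    cbind(a = 1L + 0:maxclip, b = m),
    if (maxclip > 0) cbind(a = 1L, b = m - (1:maxclip)))
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(nrow(specs))) {
    a <- specs[r, "a"]; b <- specs[r, "b"]
    w <- mmv[a:b]
    if (anyNA(w)) next
    mm <- sum(w)
    if (mm > params$max_mismatches) next
    len <- b - a + 1L
    score <- params$reward * (len - mm) + params$penalty * mm
    if (score > best_score + 1e-9) {
      best_score <- score
      best <- list(list(a = a, b = b, mm = mm, score = score))
    } else if (abs(score - best_score) <= 1e-9 && !is.null(best)) {
      best[[length(best) + 1L]] <- list(a = a, b = b, mm = mm, score = score)
    }
  }
  if (is.null(best)) return(NULL)
  rows <- lapply(best, function(wd) {
    ev <- karlin_evalue(wd$score, m, n2, params)
    if (ev > params$max_evalue) return(NULL)
    or_start <- d0 + wd$a - 1L
    or_end <- d0 + wd$b
    data.frame(or_start = or_start, or_end = or_end,
               n_mismatches = as.integer(wd$mm),
               query_coverage = (wd$b - wd$a + 1L) / m,
               score = wd$score, evalue = ev, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  unique(do.call(rbind, rows))
}

oriented_to_original <- function(df, nt, strand) {
  if (strand == "+") {
    df$start <- df$or_start
    df$end <- df$or_end
  } else {
    df$start <- nt - df$or_end
    df$end <- nt - df$or_start
  }
  df$or_start <- NULL
  df$or_end <- NULL
  df
}

#' Find protospacer matches via the k-mer index
#'
#' Pigeonhole search: for any admissible hit (at most one substitution, at
#' most `floor(0.1 * length)` bases clipped from one end, no indels) one
#' half of the aligned core is exact and contains an exact index word at
#' the window's start or end. Candidate diagonals are collected by looking
#' up the first and last `k`-mer of every admissible clipping of the
#' spacer, then verified by direct Hamming evaluation. Duplicate candidate
#' discoveries are collapsed by (spacer, target, interval, strand).
#'
#' @param spacers Spacer `data.frame` (see [excise_spacers()]).
#' @param index A `seq_index` from [build_target_index()].
#' @param params [match_params()].
#' @return Match `data.frame` with columns `spacer_id`, `owner_id`,
#'   `target_id`, `start`, `end` (0-based half-open on the target forward
#'   strand), `strand`, `n_mismatches`, `query_coverage`, `score`,
#'   `evalue`, `in_array` (initialized `FALSE`; see [flag_in_array()]).
#' @export
find_protospacers <- function(spacers, index, params = match_params()) {
  stopifnot(inherits(index, "seq_index"))
  if (!nrow(spacers)) return(empty_matches())
  k <- index$k
  short <- nchar(spacers$seq) < 2L * k
  if (any(short)) {
    sl_error("sl_value_error", paste0(
      "spacer(s) shorter than 2*k (", 2L * k, " bp): ",
      paste(utils::head(spacers$spacer_id[short], 3), collapse = ", "),
      "; use brute_match() for such queries"))
  }
  n2 <- 2 * index$total_bp
  out <- list()
  for (si in seq_len(nrow(spacers))) {
    S <- spacers$seq[si]
    m <- nchar(S)
    q <- utf8ToInt(S)
    maxclip <- floor((1 - params$min_query_coverage) * m + 1e-9)
    specs <- rbind(cbind(a = 1L + 0:maxclip, b = m),
                   if (maxclip > 0) cbind(a = 1L, b = m - (1:maxclip)))
    c_t <- integer(0)
    c_p <- logical(0)
    c_d <- integer(0)
    for (r in seq_len(nrow(specs))) {
      a <- specs[r, "a"]; b <- specs[r, "b"]
      for (anchor in c("first", "last")) {
        if (anchor == "first") {
          code <- encode_kmers(substr(S, a, a + k - 1L), k)
          off <- a - 1L
        } else {
          code <- encode_kmers(substr(S, b - k + 1L, b), k)
          off <- b - k
        }
        if (is.na(code)) next
        rows <- .index_lookup(index, as.integer(code))
        if (!length(rows)) next
        c_t <- c(c_t, index$target_idx[rows])
        c_p <- c(c_p, index$plus[rows])
        c_d <- c(c_d, index$pos[rows] - off)
      }
    }
    if (!length(c_t)) next
    dup <- duplicated(paste(c_t, c_p, c_d))
    c_t <- c_t[!dup]; c_p <- c_p[!dup]; c_d <- c_d[!dup]
    for (ci in seq_along(c_t)) {
      tid <- index$target_ids[c_t[ci]]
      strand <- if (c_p[ci]) "+" else "-"
      nt <- index$lengths[[tid]]
      tseq <- if (c_p[ci]) index$fwd[[tid]] else index$rev[[tid]]
      ev <- evaluate_diagonal(q, tseq, nt, c_d[ci], params, n2)
      if (is.null(ev)) next
      ev <- oriented_to_original(ev, nt, strand)
      ev$spacer_id <- spacers$spacer_id[si]
      ev$owner_id <- spacers$owner_id[si]
      ev$target_id <- tid
      ev$strand <- strand
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out)) return(empty_matches())
  res <- do.call(rbind, out)
  res$in_array <- FALSE
  res <- res[, names(empty_matches())]
  res <- res[!duplicated(res[, c("spacer_id", "target_id", "start", "end",
                                 "strand")]), ]
  rownames(res) <- NULL
  res[order(res$spacer_id, res$target_id, res$start), ]
}

#' Brute-force protospacer search (oracle)
#'
#' Exhaustive sliding-window Hamming scan over both strands of every target
#' and every admissible clipping, applying the same retention rules as
#' [find_protospacers()]. Intended for desk-scale inputs and as the
#' independent reference the indexed search is checked against.
#'
#' @inheritParams find_protospacers
#' @param targets `data.frame` with `id` and `seq` columns.
#' @return Match `data.frame` in the same shape as [find_protospacers()].
#' @export
brute_match <- function(spacers, targets, params = match_params()) {
  if (!nrow(spacers) || !nrow(targets)) return(empty_matches())
  n2 <- 2 * sum(nchar(targets$seq))
  nN <- utf8ToInt("N")
  out <- list()
  for (ti in seq_len(nrow(targets))) {
    tid <- targets$id[ti]
    nt <- nchar(targets$seq[ti])
    for (strand in c("+", "-")) {
      tseq <- if (strand == "+") targets$seq[ti] else dna_revcomp(targets$seq[ti])
      tr <- utf8ToInt(tseq)
      for (si in seq_len(nrow(spacers))) {
        S <- spacers$seq[si]
        m <- nchar(S)
        q <- utf8ToInt(S)
        maxclip <- floor((1 - params$min_query_coverage) * m + 1e-9)
        cand_d0 <- integer(0)
        if (nt >= m) {
          # full-window mismatch counts for all fully in-bounds diagonals
          nd <- nt - m + 1L
          mm <- integer(nd)
          for (i in seq_len(m)) {
            tch <- tr[i:(i + nd - 1L)]
            mm <- mm + ((tch != q[i]) | (tch == nN) | (q[i] == nN))
          }
          # a diagonal can carry an admissible window only if clipping at
          # most maxclip columns can bring the count within budget
          cand_d0 <- which(mm <= params$max_mismatches + maxclip) - 1L
        }
        edge <- c(seq.int(-maxclip, -1L),
                  seq.int(nt - m + 1L, nt - m + maxclip))
        edge <- edge[edge >= -maxclip & edge <= nt - m + maxclip]
        cand_d0 <- unique(c(cand_d0, edge))
        for (d0 in cand_d0) {
          ev <- evaluate_diagonal_brute(q, tseq, nt, d0, params, n2)
          if (is.null(ev)) next
          ev <- oriented_to_original(ev, nt, strand)
          ev$spacer_id <- spacers$spacer_id[si]
          ev$owner_id <- spacers$owner_id[si]
          ev$target_id <- tid
          ev$strand <- strand
          out[[length(out) + 1L]] <- ev
        }
      }
    }
  }
  if (!length(out)) return(empty_matches())
  res <- do.call(rbind, out)
  res$in_array <- FALSE
  res <- res[, names(empty_matches())]
  res <- res[!duplicated(res[, c("spacer_id", "target_id", "start", "end",
                                 "strand")]), ]
  rownames(res) <- NULL
  res[order(res$spacer_id, res$target_id, res$start), ]
}

# Independent window enumeration for the brute-force route: walks every
# admissible (clip-left / clip-right) window explicitly and keeps the
# maximal-score ones.
evaluate_diagonal_brute <- function(q, tseq, nt, d0, params, n2) {
  m <- length(q)
  nN <- utf8ToInt("N")
  maxclip <- floor((1 - params$min_query_coverage) * m + 1e-9)
  kept <- list()
  best_score <- -Inf
  for (cl in 0:maxclip) {
    for (cr in 0:maxclip) {
      if (cl > 0 && cr > 0) next       # one-end clipping only
      if (cl + cr > maxclip) next
      a <- 1L + cl
      b <- m - cr
      ts <- d0 + a - 1L
      te <- d0 + b - 1L
      if (ts < 0L || te > nt - 1L) next
      tch <- utf8ToInt(substring(tseq, ts + 1L, te + 1L))
      qs <- q[a:b]
      mm <- sum((tch != qs) | (tch == nN) | (qs == nN))
      if (mm > params$max_mismatches) next
      len <- b - a + 1L
      score <- params$reward * (len - mm) + params$penalty * mm
      ev <- karlin_evalue(score, m, n2, params)
      if (ev > params$max_evalue) next
      if (score > best_score + 1e-9) {
        best_score <- score
        kept <- list()
      }
      if (score >= best_score - 1e-9) {
        kept[[length(kept) + 1L]] <- data.frame(
          or_start = ts, or_end = te + 1L, n_mismatches = as.integer(mm),
          query_coverage = len / m, score = score, evalue = ev,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(kept)) return(NULL)
  unique(do.call(rbind, kept))
}

#' Flag matches that fall inside a target's own CRISPR array
#'
#' A spacer hit whose interval lies (by at least 50% of its length) within
#' the repeat/spacer span of a CRISPR array on the target is a
#' spacer-to-spacer connection, not a protospacer: spacers integrated into
#' an array carry no protospacer-adjacent motif, so such matches confer no
#' immunity and are excluded from virus-host edges.
#'
#' @param matches Match `data.frame`.
#' @param target_arrays List of `crispr_array` localized on the target ids.
#' @return `matches` with `in_array` set.
#' @export
flag_in_array <- function(matches, target_arrays) {
  if (!nrow(matches)) return(matches)
  spans <- lapply(target_arrays, function(a)
    list(scaffold = a$scaffold_id, start = a$start, end = a$end))
  matches$in_array <- FALSE
  for (i in seq_len(nrow(matches))) {
    ml <- matches$end[i] - matches$start[i]
    for (sp in spans) {
      if (sp$scaffold != matches$target_id[i]) next
      ov <- overlap_len(matches$start[i], matches$end[i], sp$start, sp$end)
      if (ov >= 0.5 * ml) {
        matches$in_array[i] <- TRUE
        break
      }
    }
  }
  matches
}

#' Write matches to TSV
#'
#' @param matches Match `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read matches from TSV
#'
#' @param path TSV written by [write_matches_tsv()].
#' @return Match `data.frame`.
#' @export
read_matches_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
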