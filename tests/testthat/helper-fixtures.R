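# Shared fixture builders. Everything is generated in code at test time;
# no data files.

rnd_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitute a fixed different base at the given 1-based positions
sub_at <- function(s, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# hand-build a crispr_array without running detection
mk_array <- function(id, sid, spacer_seqs, rep_seq = strrep("ACGTTGCA", 4),
                     flank5 = "", flank3 = "", offset = 0L) {
  ns <- length(spacer_seqs)
  rl <- nchar(rep_seq)
  sl <- nchar(spacer_seqs)
  rep_starts <- cumsum(c(0L, rl + sl)) + offset
  sp_starts <- rep_starts[seq_len(ns)] + rl
  spacerlink:::new_crispr_array(
    id, sid, offset, rep_starts[ns + 1L] + rl,
    repeats = data.frame(start = rep_starts, end = rep_starts + rl),
    spacers = data.frame(index = seq_len(ns) - 1L, start = sp_starts,
                         end = sp_starts + sl, seq = spacer_seqs,
                         stringsAsFactors = FALSE),
    consensus_repeat = rep_seq, flank_5p = flank5, flank_3p = flank3)
}

# spacer table row(s) for ad-hoc matching tests
mk_spacers <- function(seqs, owner = "M1", array_id = "arr1") {
  data.frame(spacer_id = sprintf("%s:%d", array_id, seq_along(seqs) - 1L),
             owner_id = owner, scaffold_id = "s1", array_id = array_id,
             index_in_array = seq_along(seqs) - 1L, seq = seqs,
             stringsAsFactors = FALSE)
}

match_key <- function(m) {
  sort(paste(m$spacer_id, m$target_id, m$start, m$end, m$strand,
             m$n_mismatches))
}

# Independent full-DP local aligner (Gotoh affine gaps) for small
# instances; returns the optimal local score under the same convention as
# the package aligner (a gap of length L costs open + L * ext).
sw_score_ref <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                         gap_ext = 2) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in A (horizontal)
  F <- matrix(NEG, n + 1, m + 1)   # gap in B (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# small memoised community shared by a few test files
.small_comm_cache <- new.env(parent = emptyenv())
small_comm <- function() {
  if (is.null(.small_comm_cache$comm)) {
    cfg <- synthetic_config(
      n_hosts = 3, n_viruses = 5,
      scaffold_len_range = c(8000, 12000), viral_len_range = c(4000, 6000),
      arrays_per_host = c(1, 1), spacers_per_array = c(4, 4),
      planted_links = list(
        list(host = 1, virus = 1, n_protospacers = 3, mismatches = 0),
        list(host = 2, virus = 2, n_protospacers = 2, mismatches = 1),
        list(host = 3, virus = 3, n_protospacers = 2, mismatches = 2)),
      chi_spec = list(`4` = 4),
      seed = 42)
    .small_comm_cache$comm <- generate_community(cfg)
  }
  .small_comm_cache$comm
}
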