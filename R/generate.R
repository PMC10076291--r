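#' Synthetic community configuration
#'
#' Describes a synthetic landfill-like community: host MAGs carrying
#' repeat-spacer CRISPR arrays, viral scaffolds carrying planted
#' protospacers with controlled mismatch counts, virally encoded arrays
#' (optionally sharing spacers), integrated or co-binned proviruses, and
#' controlled Chi motif counts. Every planted feature is recorded in a
#' ground-truth manifest so each downstream detector has a recovery test.
#'
#' Defaults emulate the study conditions: spacers of 25-45 bp between
#' 23-40 bp direct repeats, host scaffolds of 20-40 kbp, viral elements of
#' 5-20 kbp, GC 0.5, and samples drawn from a handful of leachate-well /
#' groundwater sites.
#'
#' @param n_hosts,n_viruses Community sizes.
#' @param host_scaffolds_per_mag Scaffolds per host MAG.
#' @param scaffold_len_range Host scaffold length range (bp).
#' @param viral_len_range Viral scaffold length range (bp).
#' @param gc Background GC fraction.
#' @param arrays_per_host Range for the number of CRISPR arrays per host.
#' @param repeat_len,spacer_len Ranges for repeat and spacer lengths (bp).
#' @param spacers_per_array Range for spacers per array.
#' @param planted_links List of `list(host=, virus=, n_protospacers=,
#'   mismatches=)` entries (1-based indices).
#' @param viral_array_spec List of `list(virus=, n_spacers=, targets=)`
#'   where `targets` is a list of `list(virus=, mode=)` with mode
#'   `"protospacer"` (a genuine interviral conflict) or `"shared_spacer"`
#'   (the same spacer inside both arrays; not a genuine conflict).
#' @param provirus_spec List of `list(virus=, host=, identity=, length=,
#'   mode=)` with mode `"integrated"` or `"cobinned"`.
#' @param chi_spec Named list mapping 1-based virus index (as character) to
#'   planted Chi motif count; those viruses are scrubbed of background
#'   motif occurrences first.
#' @param duplicate_spec List of `list(virus=, identity=)`; each appends a
#'   near-duplicate viral scaffold for clustering recovery tests.
#' @param sites Character vector of sample sites (assigned round-robin).
#' @param host_year,virus_year Year labels.
#' @param seed Integer seed; generation is byte-deterministic given the
#'   seed.
#' @return A classed list (`synthetic_config`).
#' @export
synthetic_config <- function(n_hosts = 20, n_viruses = 200,
                             host_scaffolds_per_mag = 2,
                             scaffold_len_range = c(20000, 40000),
                             viral_len_range = c(5000, 20000),
                             gc = 0.5,
                             arrays_per_host = c(1, 2),
                             repeat_len = c(23, 40),
                             spacer_len = c(25, 45),
                             spacers_per_array = c(4, 8),
                             planted_links = list(),
                             viral_array_spec = list(),
                             provirus_spec = list(),
                             chi_spec = list(),
                             duplicate_spec = list(),
                             sites = c("LW1", "LW2", "LW3", "GW1", "CLC"),
                             host_year = 2016, virus_year = 2016,
                             seed = 1) {
  cfg <- structure(list(
    n_hosts = as.integer(n_hosts), n_viruses = as.integer(n_viruses),
    host_scaffolds_per_mag = as.integer(host_scaffolds_per_mag),
    scaffold_len_range = as.integer(scaffold_len_range),
    viral_len_range = as.integer(viral_len_range),
    gc = gc, arrays_per_host = as.integer(arrays_per_host),
    repeat_len = as.integer(repeat_len), spacer_len = as.integer(spacer_len),
    spacers_per_array = as.integer(spacers_per_array),
    planted_links = planted_links, viral_array_spec = viral_array_spec,
    provirus_spec = provirus_spec, chi_spec = chi_spec,
    duplicate_spec = duplicate_spec,
    sites = sites, host_year = as.integer(host_year),
    virus_year = as.integer(virus_year), seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) sl_error("sl_config_error", msg)
  chk(cfg$n_hosts >= 0 && cfg$n_viruses >= 0, "community sizes must be >= 0")
  chk(cfg$gc > 0 && cfg$gc < 1, "gc must be in (0, 1)")
  chk(cfg$spacer_len[1] >= 15, "spacers must be >= 15 bp")
  chk(cfg$spacer_len[2] <= cfg$viral_len_range[1],
      "spacer longer than shortest viral scaffold")
  for (ln in cfg$planted_links) {
    chk(ln$host >= 1 && ln$host <= cfg$n_hosts, "link host index out of range")
    chk(ln$virus >= 1 && ln$virus <= cfg$n_viruses,
        "link virus index out of range")
    chk(ln$mismatches >= 0, "link mismatches must be >= 0")
    core <- cfg$spacer_len[1] - 2 * (floor(0.1 * cfg$spacer_len[1]) + 1)
    chk(ln$mismatches <= core,
        "more substitutions requested than clip-protected spacer core positions")
  }
  for (va in cfg$viral_array_spec) {
    chk(va$virus >= 1 && va$virus <= cfg$n_viruses,
        "viral array virus index out of range")
    for (tg in if (is.null(va$targets)) list() else va$targets) {
      chk(tg$virus >= 1 && tg$virus <= cfg$n_viruses,
          "conflict target index out of range")
      chk(tg$mode %in% c("protospacer", "shared_spacer"),
          "conflict target mode must be protospacer or shared_spacer")
    }
  }
  for (pv in cfg$provirus_spec) {
    chk(pv$virus >= 1 && pv$virus <= cfg$n_viruses,
        "provirus virus index out of range")
    chk(pv$host >= 1 && pv$host <= cfg$n_hosts,
        "provirus host index out of range")
    chk(pv$identity > 0 && pv$identity <= 1, "provirus identity must be in (0,1]")
    chk(pv$mode %in% c("integrated", "cobinned"),
        "provirus mode must be integrated or cobinned")
  }
  invisible(cfg)
}

#' Introduce an exact number of substitutions into a sequence
#'
#' @param seq DNA string.
#' @param n_subs Number of substitutions; the result has Hamming distance
#'   exactly `n_subs` to the input and identical length.
#' @param seed Optional seed for a local, restored RNG stream.
#' @param positions Optional 1-based positions to draw substitution sites
#'   from (defaults to all positions).
#' @return Mutated DNA string.
#' @export
mutate_seq <- function(seq, n_subs, seed = NULL, positions = NULL) {
  m <- nchar(seq)
  if (is.null(positions)) positions <- seq_len(m)
  if (n_subs > length(positions)) {
    sl_error("sl_config_error",
             sprintf("requested %d substitutions but only %d positions available",
                     n_subs, length(positions)))
  }
  body <- function() {
    if (n_subs == 0L) return(seq)
    at <- sort(sample(positions, n_subs))
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in at) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

CHI_MOTIF_DEFAULT <- "GCTGGTGG"

# ---- internal generator machinery -------------------------------------

.count_both <- function(seq, motif) {
  s <- Biostrings::DNAString(seq)
  Biostrings::countPattern(motif, s) +
    Biostrings::countPattern(dna_revcomp(motif), s)
}

.chi_scrub <- function(seq, motif) {
  rc <- dna_revcomp(motif)
  for (iter in 1:100) {
    s <- Biostrings::DNAString(seq)
    hits <- c(Biostrings::start(Biostrings::matchPattern(motif, s)),
              Biostrings::start(Biostrings::matchPattern(rc, s)))
    if (!length(hits)) return(seq)
    p <- hits[1] + 3L  # middle of the octamer
    old <- substr(seq, p, p)
    seq <- seq_replace(seq, p - 1L, sample(setdiff(DNA_BASES, old), 1L))
  }
  sl_error("sl_config_error", "could not scrub Chi motif from background")
}

.place_free <- function(len_total, seg_len, occ, margin = 1L, tries = 400L) {
  if (seg_len > len_total) return(NULL)
  for (t in seq_len(tries)) {
    start <- sample.int(len_total - seg_len + 1L, 1L) - 1L
    end <- start + seg_len
    if (!nrow(occ) ||
        all(end + margin <= occ[, 1] | start >= occ[, 2] + margin)) {
      return(start)
    }
  }
  NULL
}

.in_sorted <- function(sorted, x) {
  if (!length(sorted)) return(rep(FALSE, length(x)))
  i <- findInterval(x, sorted)
  i > 0 & sorted[pmax(i, 1L)] == x
}

# Generator context: community-uniqueness machinery for planted spacers.
# A candidate spacer is accepted only if neither it nor its 1-mismatch
# neighborhood occurs in the viral background or in previously planted
# content (both strands, including containment between spacers of
# different lengths). A <=1-mismatch occurrence of a sequence of length
# >= 24 implies an exact shared 12-mer (one half is exact), so a sorted
# 12-mer code set serves as an exact-miss prefilter and the expensive
# direct scans only run on prefilter hits.
.make_uniq_ctx <- function(viral_seqs, motif) {
  ctx <- new.env(parent = emptyenv())
  both <- c(viral_seqs, dna_revcomp(viral_seqs))
  ctx$subject <- Biostrings::DNAString(paste(both, collapse = strrep("N", 30)))
  ctx$codes <- sort(unique(unlist(lapply(both, function(s) {
    v <- encode_kmers(s, 12L)
    v[!is.na(v)]
  }))))
  ctx$motif <- motif
  ctx$motif_rc <- dna_revcomp(motif)
  ctx$planted <- character(0)
  ctx$planted_codes <- numeric(0)
  ctx
}

.ctx_add_planted <- function(ctx, sp) {
  ctx$planted <- c(ctx$planted, sp)
  v <- c(encode_kmers(sp, 12L), encode_kmers(dna_revcomp(sp), 12L))
  ctx$planted_codes <- sort(unique(c(ctx$planted_codes, v[!is.na(v)])))
  invisible(ctx)
}

.spacer_neighborhood_free <- function(cand, ctx) {
  m <- nchar(cand)
  h <- floor(m / 2)
  rcc <- dna_revcomp(cand)
  # anchors for occurrences of `cand` elsewhere: the 12-prefix of either
  # half, on both strands
  q_half <- c(encode_kmers(substr(cand, 1L, 12L), 12L),
              encode_kmers(substr(cand, h + 1L, h + 12L), 12L),
              encode_kmers(substr(rcc, 1L, 12L), 12L),
              encode_kmers(substr(rcc, h + 1L, h + 12L), 12L))
  q_half <- q_half[!is.na(q_half)]
  if (any(.in_sorted(ctx$codes, q_half))) {
    if (Biostrings::countPattern(cand, ctx$subject, max.mismatch = 1) > 0 ||
        Biostrings::countPattern(rcc, ctx$subject, max.mismatch = 1) > 0) {
      return(FALSE)
    }
  }
  if (length(ctx$planted)) {
    # against planted content both directions (cand near a planted spacer,
    # or a shorter planted spacer contained in cand): any such event
    # implies a shared exact 12-mer with the planted code set
    q_all <- c(encode_kmers(cand, 12L), encode_kmers(rcc, 12L))
    q_all <- q_all[!is.na(q_all)]
    if (any(.in_sorted(ctx$planted_codes, q_all))) {
      text <- Biostrings::DNAString(paste(
        c(ctx$planted, dna_revcomp(ctx$planted)),
        collapse = strrep("N", 30)))
      if (Biostrings::countPattern(cand, text, max.mismatch = 1) > 0 ||
          Biostrings::countPattern(rcc, text, max.mismatch = 1) > 0) {
        return(FALSE)
      }
      cd <- Biostrings::DNAString(cand)
      for (p in ctx$planted[nchar(ctx$planted) < m]) {
        if (Biostrings::countPattern(p, cd, max.mismatch = 1) > 0 ||
            Biostrings::countPattern(dna_revcomp(p), cd,
                                     max.mismatch = 1) > 0) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

.sample_spacer <- function(len, gc, ctx, peers = character(0)) {
  for (t in 1:500) {
    cand <- random_dna(len, gc)
    if (grepl(ctx$motif, cand, fixed = TRUE) ||
        grepl(ctx$motif_rc, cand, fixed = TRUE)) next
    if (length(peers) &&
        any(vapply(peers, function(p) ungapped_identity(cand, p), 0) > 0.55)) next
    if (!.spacer_neighborhood_free(cand, ctx)) next
    return(cand)
  }
  sl_error("sl_config_error", "failed to sample a community-unique spacer")
}

.sample_repeat <- function(len, gc, ctx) {
  for (t in 1:200) {
    cand <- random_dna(len, gc)
    if (!grepl(ctx$motif, cand, fixed = TRUE) &&
        !grepl(ctx$motif_rc, cand, fixed = TRUE)) return(cand)
  }
  sl_error("sl_config_error", "failed to sample a repeat")
}

# Build one planted array description (sequence string + internal layout).
.build_array <- function(repeat_seq, spacer_seqs) {
  ns <- length(spacer_seqs)
  parts <- character(2L * ns + 1L)
  parts[seq(1L, 2L * ns + 1L, by = 2L)] <- repeat_seq
  parts[seq(2L, 2L * ns, by = 2L)] <- spacer_seqs
  seq <- paste(parts, collapse = "")
  rl <- nchar(repeat_seq)
  sl <- nchar(spacer_seqs)
  rep_starts <- integer(ns + 1L)
  sp_starts <- integer(ns)
  pos <- 0L
  for (i in seq_len(ns)) {
    rep_starts[i] <- pos
    pos <- pos + rl
    sp_starts[i] <- pos
    pos <- pos + sl[i]
  }
  rep_starts[ns + 1L] <- pos
  list(seq = seq, len = nchar(seq), repeat_len = rl,
       rep_starts = rep_starts, sp_starts = sp_starts, sp_lens = sl)
}

#' Generate a synthetic virus-host community with a truth manifest
#'
#' Backgrounds are i.i.d. nucleotides at the configured GC. Planted spacers
#' are rejection-sampled so that neither they nor their 1-mismatch
#' neighborhoods occur anywhere in the viral background (checked on both
#' strands), making link-recovery tests exact. Planted protospacers carry
#' exactly the requested number of substitutions, placed in the
#' clip-protected core of the spacer so the matcher sees the planted
#' mismatch count. Proviruses of mode `integrated` are embedded inside a
#' host scaffold (with forced junction mismatches so alignment lengths are
#' exact); mode `cobinned` emits a free host-bin scaffold about 95% covered
#' by the viral sequence. Generation is deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param outdir Optional directory; when given, the community is written as
#'   the pipeline's input formats (per-MAG multi-FASTA under `hosts/`,
#'   `virals.fasta`, `mag_table.tsv`, `viral_table.tsv`, `arrays.gff3`,
#'   `manifest.json`).
#' @return A list with `host_scaffolds`, `mags`, `virals`, `viral_meta`,
#'   `planted_arrays` (as `crispr_array` objects), and `manifest`.
#' @export
generate_community <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  res <- with_seed(cfg$seed, .generate_community_impl(cfg))
  if (!is.null(outdir)) write_community(res, outdir)
  res
}

.generate_community_impl <- function(cfg) {
  motif <- CHI_MOTIF_DEFAULT
  rng_int <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq.int(rng[1], rng[2]), 1L)

  # -- backgrounds -------------------------------------------------------
  host_ids <- sprintf("M%d", seq_len(cfg$n_hosts))
  hseqs <- list()   # scaffold id -> seq
  hocc <- list()    # scaffold id -> occupied matrix
  hmap <- list()    # mag id -> scaffold ids
  for (i in seq_len(cfg$n_hosts)) {
    sids <- sprintf("%s_s%d", host_ids[i], seq_len(cfg$host_scaffolds_per_mag))
    hmap[[host_ids[i]]] <- sids
    for (sid in sids) {
      hseqs[[sid]] <- random_dna(rng_int(cfg$scaffold_len_range), cfg$gc)
      hocc[[sid]] <- matrix(numeric(0), ncol = 2)
    }
  }
  viral_ids <- sprintf("V%d", seq_len(cfg$n_viruses))
  vseqs <- list()
  vocc <- list()
  for (j in seq_len(cfg$n_viruses)) {
    vseqs[[viral_ids[j]]] <- random_dna(rng_int(cfg$viral_len_range), cfg$gc)
    vocc[[viral_ids[j]]] <- matrix(numeric(0), ncol = 2)
  }

  # -- Chi control -------------------------------------------------------
  chi_controlled <- character(0)
  manifest_chi <- list()
  for (key in names(cfg$chi_spec)) {
    vid <- viral_ids[as.integer(key)]
    chi_controlled <- c(chi_controlled, vid)
    want <- cfg$chi_spec[[key]]
    s <- .chi_scrub(vseqs[[vid]], motif)
    planted_ok <- FALSE
    for (try in 1:20) {
      s2 <- s
      occ <- matrix(numeric(0), ncol = 2)
      ok <- TRUE
      for (c2 in seq_len(want)) {
        p <- .place_free(nchar(s2), 8L, occ, margin = 8L)
        if (is.null(p)) { ok <- FALSE; break }
        s2 <- seq_replace(s2, p, motif)
        occ <- rbind(occ, c(p, p + 8L))
      }
      if (ok && .count_both(s2, motif) == want) {
        vseqs[[vid]] <- s2
        vocc[[vid]] <- occ
        planted_ok <- TRUE
        break
      }
    }
    if (!planted_ok) sl_error("sl_config_error",
                              paste0("could not plant Chi motifs on ", vid))
    manifest_chi[[vid]] <- list(virus_id = vid, count = want,
                                length = nchar(vseqs[[vid]]),
                                density = want * 1000 / nchar(vseqs[[vid]]))
  }

  ctx <- .make_uniq_ctx(unlist(vseqs), motif)

  # -- host CRISPR arrays ------------------------------------------------
  planted_arrays <- list()
  manifest_arrays <- list()
  host_spacers <- stats::setNames(vector("list", cfg$n_hosts), host_ids)
  plant_array <- function(owner, sid, seq_env_get, seq_env_set, occ_get,
                          occ_set, n_spacers, forced_spacers = NULL) {
    rl <- rng_int(cfg$repeat_len)
    rep_seq <- .sample_repeat(rl, cfg$gc, ctx)
    sp <- character(n_spacers)
    for (t in seq_len(n_spacers)) {
      if (!is.null(forced_spacers) && t <= length(forced_spacers)) {
        sp[t] <- forced_spacers[t]
      } else {
        sp[t] <- .sample_spacer(rng_int(cfg$spacer_len), cfg$gc, ctx, peers = sp[seq_len(t - 1L)])
        ctx$planted <<- c(ctx$planted, sp[t])
      }
    }
    lay <- .build_array(rep_seq, sp)
    s <- seq_env_get(sid)
    start <- .place_free(nchar(s), lay$len, occ_get(sid), margin = 250L)
    if (is.null(start)) sl_error("sl_config_error",
                                 paste0("no room for array on ", sid))
    seq_env_set(sid, seq_replace(s, start, lay$seq))
    occ_set(sid, rbind(occ_get(sid), c(start, start + lay$len)))
    arr_id <- sprintf("%s_pl%d", sid, sum(vapply(planted_arrays, function(a)
      a$scaffold_id == sid, TRUE)) + 1L)
    ns <- length(sp)
    arr <- new_crispr_array(
      array_id = arr_id, scaffold_id = sid,
      start0 = start, end0 = start + lay$len,
      repeats = data.frame(start = start + lay$rep_starts,
                           end = start + lay$rep_starts + lay$repeat_len),
      spacers = data.frame(index = seq_len(ns) - 1L,
                           start = start + lay$sp_starts,
                           end = start + lay$sp_starts + lay$sp_lens,
                           seq = sp, stringsAsFactors = FALSE),
      consensus_repeat = rep_seq,
      flank_5p = "", flank_3p = "", partial = FALSE)
    planted_arrays[[length(planted_arrays) + 1L]] <<- arr
    manifest_arrays[[length(manifest_arrays) + 1L]] <<- list(
      owner = owner, scaffold_id = sid, array_id = arr_id,
      start = start, end = start + lay$len, repeat_consensus = rep_seq,
      spacers = data.frame(index = seq_len(ns) - 1L,
                           start = start + lay$sp_starts,
                           end = start + lay$sp_starts + lay$sp_lens,
                           seq = sp, stringsAsFactors = FALSE))
    arr
  }

  hget <- function(sid) hseqs[[sid]]
  hset <- function(sid, v) hseqs[[sid]] <<- v
  hoget <- function(sid) hocc[[sid]]
  hoset <- function(sid, v) hocc[[sid]] <<- v
  vget <- function(sid) vseqs[[sid]]
  vset <- function(sid, v) vseqs[[sid]] <<- v
  voget <- function(sid) vocc[[sid]]
  voset <- function(sid, v) vocc[[sid]] <<- v

  for (i in seq_len(cfg$n_hosts)) {
    mid <- host_ids[i]
    n_arr <- rng_int(cfg$arrays_per_host)
    for (a in seq_len(n_arr)) {
      sid <- sample(hmap[[mid]], 1L)
      arr <- plant_array(mid, sid, hget, hset, hoget, hoset,
                         rng_int(cfg$spacers_per_array))
      host_spacers[[mid]] <- rbind(host_spacers[[mid]], arr$spacers)
    }
  }

  # -- virally encoded arrays -------------------------------------------
  # first sample spacer sets so shared-spacer overlaps can be wired up
  va_spacers <- list()
  for (e in seq_along(cfg$viral_array_spec)) {
    va <- cfg$viral_array_spec[[e]]
    sp <- character(va$n_spacers)
    for (t in seq_len(va$n_spacers)) {
      sp[t] <- .sample_spacer(rng_int(cfg$spacer_len), cfg$gc, ctx,
                              peers = sp[seq_len(t - 1L)])
      ctx$planted <- c(ctx$planted, sp[t])
    }
    va_spacers[[e]] <- sp
  }
  manifest_shared <- list()
  idx_of_virus <- function(vnum) {
    w <- which(vapply(cfg$viral_array_spec, function(x) x$virus == vnum, TRUE))
    if (length(w)) w[1] else NA_integer_
  }
  for (e in seq_along(cfg$viral_array_spec)) {
    va <- cfg$viral_array_spec[[e]]
    for (tg in if (is.null(va$targets)) list() else va$targets) {
      if (tg$mode != "shared_spacer") next
      te <- idx_of_virus(tg$virus)
      if (is.na(te)) sl_error("sl_config_error",
        "shared_spacer target must itself appear in viral_array_spec")
      shared <- va_spacers[[e]][1]
      va_spacers[[te]][1] <- shared
      manifest_shared[[length(manifest_shared) + 1L]] <- list(
        source = viral_ids[va$virus], target = viral_ids[tg$virus],
        seq = shared)
    }
  }
  viral_array_of <- character(0)  # virus id -> array id
  for (e in seq_along(cfg$viral_array_spec)) {
    va <- cfg$viral_array_spec[[e]]
    vid <- viral_ids[va$virus]
    arr <- plant_array(vid, vid, vget, vset, voget, voset,
                       va$n_spacers, forced_spacers = va_spacers[[e]])
    viral_array_of[[vid]] <- arr$array_id
  }

  # -- protospacer planting ---------------------------------------------
  place_protospacer <- function(vid, spacer_seq, mismatches) {
    m <- nchar(spacer_seq)
    maxclip <- floor(0.1 * m)
    core <- seq.int(maxclip + 2L, m - maxclip - 1L)
    for (try in 1:50) {
      proto <- mutate_seq(spacer_seq, mismatches, positions = core)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") proto else dna_revcomp(proto)
      if (vid %in% chi_controlled &&
          (grepl(motif, planted, fixed = TRUE) ||
           grepl(dna_revcomp(motif), planted, fixed = TRUE))) next
      s <- vseqs[[vid]]
      p <- .place_free(nchar(s), m, vocc[[vid]], margin = 10L)
      if (is.null(p)) sl_error("sl_config_error",
                               paste0("no room for protospacer on ", vid))
      s2 <- seq_replace(s, p, planted)
      if (vid %in% chi_controlled &&
          .count_both(s2, motif) != manifest_chi[[vid]]$count) next
      vseqs[[vid]] <<- s2
      vocc[[vid]] <<- rbind(vocc[[vid]], c(p, p + m))
      return(list(start = p, end = p + m, strand = strand,
                  n_mismatches = mismatches))
    }
    sl_error("sl_config_error", "protospacer placement failed")
  }

  manifest_protos <- list()
  manifest_links <- list()
  for (ln in cfg$planted_links) {
    mid <- host_ids[ln$host]
    vid <- viral_ids[ln$virus]
    pool <- host_spacers[[mid]]
    if (is.null(pool) || !nrow(pool)) {
      sl_error("sl_config_error", paste0("host ", mid, " has no spacers"))
    }
    for (t in seq_len(ln$n_protospacers)) {
      row <- pool[((t - 1L) %% nrow(pool)) + 1L, ]
      loc <- place_protospacer(vid, row$seq, ln$mismatches)
      manifest_protos[[length(manifest_protos) + 1L]] <- list(
        host_id = mid, virus_id = vid, spacer_seq = row$seq,
        start = loc$start, end = loc$end, strand = loc$strand,
        n_mismatches = loc$n_mismatches)
    }
    manifest_links[[length(manifest_links) + 1L]] <- list(
      host_id = mid, virus_id = vid, n_protospacers = ln$n_protospacers,
      mismatches = ln$mismatches)
  }

  manifest_conflicts <- list()
  for (e in seq_along(cfg$viral_array_spec)) {
    va <- cfg$viral_array_spec[[e]]
    src <- viral_ids[va$virus]
    ti <- 0L
    for (tg in if (is.null(va$targets)) list() else va$targets) {
      if (tg$mode != "protospacer") {
        manifest_conflicts[[length(manifest_conflicts) + 1L]] <- list(
          source = src, target = viral_ids[tg$virus], mode = tg$mode,
          genuine = FALSE)
        next
      }
      ti <- ti + 1L
      # draw from the last slots first: slot 1 is reserved for
      # shared-spacer overlays, keeping the two scenarios disjoint
      ns <- length(va_spacers[[e]])
      sp_seq <- va_spacers[[e]][ns - ((ti - 1L) %% ns)]
      loc <- place_protospacer(viral_ids[tg$virus], sp_seq, 0L)
      manifest_conflicts[[length(manifest_conflicts) + 1L]] <- list(
        source = src, target = viral_ids[tg$virus], mode = tg$mode,
        genuine = TRUE, spacer_seq = sp_seq, start = loc$start,
        end = loc$end, strand = loc$strand)
    }
  }

  # -- proviruses --------------------------------------------------------
  manifest_provirus <- list()
  extra_host_scaffolds <- list()
  for (pv in cfg$provirus_spec) {
    vid <- viral_ids[pv$virus]
    mid <- host_ids[pv$host]
    vs <- vseqs[[vid]]
    li <- min(pv$length, nchar(vs))
    insert <- substr(vs, 1L, li)
    n_subs <- round((1 - pv$identity) * li)
    margin <- min(50L, floor(li / 10))
    core <- seq.int(margin + 1L, li - margin)
    insert_mut <- mutate_seq(insert, min(n_subs, length(core)), positions = core)
    if (pv$mode == "integrated") {
      cand_sids <- hmap[[mid]]
      lens <- vapply(cand_sids, function(x) nchar(hseqs[[x]]), 0)
      sid <- cand_sids[which.max(lens)]
      s <- hseqs[[sid]]
      p <- .place_free(nchar(s), li, hocc[[sid]], margin = 300L)
      if (is.null(p)) sl_error("sl_config_error",
                               paste0("no room for provirus on ", sid))
      s <- seq_replace(s, p, insert_mut)
      # force mismatching junction columns so the aligned length is exactly
      # the insert length (no chance extension past the boundary)
      for (off in 0:3) {
        hp <- p + li + off           # 0-based host position right of insert
        vch <- substr(vs, li + 1L + off, li + 1L + off)
        if (hp < nchar(s) && nzchar(vch) &&
            substr(s, hp + 1L, hp + 1L) == vch) {
          s <- seq_replace(s, hp, sample(setdiff(DNA_BASES, vch), 1L))
        }
      }
      hseqs[[sid]] <- s
      hocc[[sid]] <- rbind(hocc[[sid]], c(p, p + li))
      manifest_provirus[[length(manifest_provirus) + 1L]] <- list(
        virus_id = vid, host_id = mid, host_scaffold = sid,
        start = p, end = p + li, identity = pv$identity, length = li,
        mode = "integrated")
    } else {
      flank_total <- max(0L, round(li / 0.95) - li)
      fl <- floor(flank_total / 2)
      fr <- flank_total - fl
      sid <- sprintf("%s_cobin_%s", mid, vid)
      s <- paste0(random_dna(fl, cfg$gc), insert_mut, random_dna(fr, cfg$gc))
      hseqs[[sid]] <- s
      hocc[[sid]] <- matrix(c(fl, fl + li), ncol = 2)
      hmap[[mid]] <- c(hmap[[mid]], sid)
      extra_host_scaffolds <- c(extra_host_scaffolds, sid)
      manifest_provirus[[length(manifest_provirus) + 1L]] <- list(
        virus_id = vid, host_id = mid, host_scaffold = sid,
        start = fl, end = fl + li, identity = pv$identity, length = li,
        mode = "cobinned")
    }
  }

  # -- near-duplicate viral scaffolds (clustering ground truth) ---------
  manifest_dups <- list()
  for (dup in cfg$duplicate_spec) {
    src <- viral_ids[dup$virus]
    new_id <- sprintf("%s_dup%d", src, length(manifest_dups) + 1L)
    s <- vseqs[[src]]
    li <- nchar(s)
    n_subs <- round((1 - dup$identity) * li)
    margin <- min(50L, floor(li / 10))
    core <- seq.int(margin + 1L, li - margin)
    vseqs[[new_id]] <- mutate_seq(s, min(n_subs, length(core)), positions = core)
    vocc[[new_id]] <- matrix(numeric(0), ncol = 2)
    viral_ids <- c(viral_ids, new_id)
    manifest_dups[[length(manifest_dups) + 1L]] <- list(
      source = src, duplicate = new_id, identity = dup$identity,
      same_cluster_expected = dup$identity >= 0.95)
  }

  # -- assemble tables ---------------------------------------------------
  phyla <- c("Firmicutes", "Bacteroidota", "Proteobacteria",
             "Patescibacteria", "Actinobacteriota")
  site_of <- function(k) cfg$sites[((k - 1L) %% length(cfg$sites)) + 1L]
  mags <- data.frame(
    mag_id = host_ids,
    completeness = round(stats::runif(cfg$n_hosts, 75, 100), 2),
    contamination = round(stats::runif(cfg$n_hosts, 0, 9), 2),
    lineage = sprintf("d__Bacteria;p__%s;c__;o__;f__;g__;s__",
                      phyla[((seq_len(cfg$n_hosts) - 1L) %% length(phyla)) + 1L]),
    site = vapply(seq_len(cfg$n_hosts), site_of, ""),
    year = cfg$host_year,
    stringsAsFactors = FALSE)
  mags$scaffolds <- unname(hmap[host_ids])

  all_sids <- unlist(hmap[host_ids], use.names = FALSE)
  host_scaffolds <- data.frame(
    id = all_sids,
    seq = vapply(all_sids, function(x) hseqs[[x]], ""),
    mag_id = rep(host_ids, vapply(hmap[host_ids], length, 0L)),
    stringsAsFactors = FALSE)
  host_scaffolds$length <- nchar(host_scaffolds$seq)
  rownames(host_scaffolds) <- NULL

  provirus_virals <- unique(vapply(cfg$provirus_spec, function(p)
    viral_ids[p$virus], ""))
  virals <- data.frame(
    id = viral_ids,
    seq = vapply(viral_ids, function(x) vseqs[[x]], ""),
    stringsAsFactors = FALSE)
  virals$length <- nchar(virals$seq)
  rownames(virals) <- NULL
  viral_meta <- data.frame(
    viral_id = viral_ids,
    length = virals$length,
    site = vapply(seq_along(viral_ids), site_of, ""),
    year = cfg$virus_year,
    category = ifelse(viral_ids %in% provirus_virals, "provirus",
                      "nonintegrated"),
    dgr = FALSE,
    stringsAsFactors = FALSE)

  manifest <- list(
    seed = cfg$seed,
    arrays = manifest_arrays,
    protospacers = manifest_protos,
    links = manifest_links,
    viral_arrays = Filter(function(a) a$owner %in% viral_ids, manifest_arrays),
    shared_viral_spacers = manifest_shared,
    conflicts = manifest_conflicts,
    proviruses = manifest_provirus,
    chi = manifest_chi,
    duplicates = manifest_dups)

  list(host_scaffolds = host_scaffolds, mags = mags, virals = virals,
       viral_meta = viral_meta, planted_arrays = planted_arrays,
       manifest = manifest)
}

#' Write a generated community to disk in the pipeline's input formats
#'
#' @param community Result of [generate_community()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_community <- function(community, outdir) {
  dir.create(file.path(outdir, "hosts"), recursive = TRUE,
             showWarnings = FALSE)
  hs <- community$host_scaffolds
  for (mid in community$mags$mag_id) {
    sub <- hs[hs$mag_id == mid, ]
    write_sequences(sub, file.path(outdir, "hosts", paste0(mid, ".fasta")))
  }
  write_sequences(community$virals, file.path(outdir, "virals.fasta"))
  mt <- community$mags
  mt$scaffolds <- vapply(mt$scaffolds, paste, "", collapse = ",")
  utils::write.table(mt, file.path(outdir, "mag_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(community$viral_meta,
                     file.path(outdir, "viral_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_arrays_gff(community$planted_arrays,
                   file.path(outdir, "arrays.gff3"))
  jsonlite::write_json(community$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
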