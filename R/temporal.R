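#' Sequence clustering and dereplication parameters
#'
#' @param c Global identity threshold for viral population clustering:
#'   identical nucleotides in the best local alignment divided by the full
#'   length of the shorter sequence (default 0.95).
#' @param filter_k Exact word size for the cluster prefilter: a sequence is
#'   aligned against a representative only when a sufficient fraction of
#'   its words occur in the representative (at 95% identity about
#'   `0.95^filter_k` of words survive, so the screen keeps all plausible
#'   members while skipping unrelated pairs).
#' @param ani_threshold ANI threshold for MAG dereplication into
#'   populations (default 0.95, the conventional species-population
#'   cutoff).
#' @param sketch_size Bottom-k sketch size for ANI estimation.
#' @param sketch_k K-mer size for sketching (default 21).
#' @return A classed list (`cluster_params`).
#' @export
cluster_params <- function(c = 0.95, filter_k = 12, ani_threshold = 0.95,
                           sketch_size = 1000, sketch_k = 21) {
  stopifnot(c > 0, c <= 1, ani_threshold > 0, ani_threshold <= 1,
            filter_k >= 4, filter_k <= 26, sketch_size >= 10,
            sketch_k >= 11, sketch_k <= 26)
  structure(list(c = as.numeric(c), filter_k = as.numeric(filter_k),
                 ani_threshold = as.numeric(ani_threshold),
                 sketch_size = as.numeric(sketch_size),
                 sketch_k = as.numeric(sketch_k)),
            class = "cluster_params")
}

# Identity between two sequences in the CD-HIT-est sense: identical
# nucleotides in the best local alignment (either strand) over the length
# of the shorter sequence.
global_identity_shorter <- function(a, b, pparams = provirus_params()) {
  submat <- .nuc_submat(pparams)
  best <- 0
  for (s in list(b, dna_revcomp(b))) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(s),
      type = "local", substitutionMatrix = submat,
      gapOpening = pparams$gap_open, gapExtension = pparams$gap_extend)
    best <- max(best, Biostrings::nmatch(aln))
  }
  best / min(nchar(a), nchar(b))
}

#' Cluster viral scaffolds into populations (greedy, longest-first)
#'
#' Greedy incremental clustering in the CD-HIT-est style: sequences are
#' sorted by decreasing length (ties broken by lexicographic id); each
#' sequence joins the first existing cluster whose representative it
#' matches at global identity >= `c` (identical nucleotides in the best
#' local alignment on either strand, divided by the shorter length), else
#' it founds a new cluster. Representatives are therefore always the
#' longest member. A word-containment prefilter (`filter_k`) skips
#' representative comparisons that cannot plausibly reach the identity
#' threshold. Deterministic.
#'
#' @param seqs Named character vector (id -> sequence) or `data.frame`
#'   with `id`, `seq`.
#' @param params [cluster_params()].
#' @return `data.frame` with `member_id`, `cluster_id`,
#'   `representative_id`, `identity_to_rep` (1 for representatives).
#' @export
cluster_viral <- function(seqs, params = cluster_params()) {
  if (is.data.frame(seqs)) {
    v <- stats::setNames(seqs$seq, seqs$id)
  } else v <- seqs
  stopifnot(length(v) > 0)
  ord <- order(-nchar(v), names(v))
  v <- v[ord]
  k <- as.integer(params$filter_k)
  # containment screen: at identity c a fraction of roughly c^k of the
  # shorter sequence's words survives in the representative; demand a
  # quarter of that so borderline pairs are still aligned exactly
  min_contain <- 0.25 * params$c^k
  reps <- character(0)        # representative ids in founding order
  rep_codes <- list()
  rows <- vector("list", length(v))
  for (i in seq_along(v)) {
    id <- names(v)[i]
    s <- v[[i]]
    codes <- sort(unique(c(.kmer_code_set(s, k),
                           .kmer_code_set(dna_revcomp(s), k))))
    assigned <- FALSE
    for (ri in seq_along(reps)) {
      contain <- mean(.in_sorted(rep_codes[[ri]], codes))
      if (is.nan(contain) || contain < min_contain) next
      ident <- global_identity_shorter(s, v[[reps[ri]]])
      if (ident >= params$c) {
        rows[[i]] <- data.frame(member_id = id,
                                cluster_id = sprintf("C%d", ri),
                                representative_id = reps[ri],
                                identity_to_rep = ident,
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      rep_codes[[length(reps)]] <- sort(.kmer_code_set(s, k))
      rows[[i]] <- data.frame(member_id = id,
                              cluster_id = sprintf("C%d", length(reps)),
                              representative_id = id, identity_to_rep = 1,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Bottom-k MinHash sketch of the canonical k-mers of a sequence set.
.sketch <- function(seqs, k, size) {
  codes <- unlist(lapply(seqs, function(s) {
    v <- c(encode_kmers(s, k), encode_kmers(dna_revcomp(s), k))
    v[!is.na(v)]
  }))
  if (!length(codes)) return(numeric(0))
  # scramble with a fixed affine map modulo a Mersenne prime so sketch
  # membership is not biased by sequence composition
  p <- 2147483647
  h <- ((codes %% p) * 48271 + 11) %% p
  h <- sort(unique(h))
  h[seq_len(min(size, length(h)))]
}

# Mash-style ANI estimate from two bottom-k sketches.
.sketch_ani <- function(sa, sb, k, size) {
  if (!length(sa) || !length(sb)) return(0)
  merged <- sort(unique(c(sa, sb)))
  bottom <- merged[seq_len(min(size, length(merged)))]
  shared <- sum(bottom %in% sa & bottom %in% sb)
  j <- shared / length(bottom)
  if (j <= 0) return(0)
  d <- -(1 / k) * log(2 * j / (1 + j))
  max(0, 1 - d)
}

#' Dereplicate MAGs into populations by sketch ANI
#'
#' Estimates pairwise ANI between MAGs with bottom-k MinHash sketches
#' (k = 21 by default) and the Mash distance transform, then forms
#' populations as single-linkage components at
#' `ani >= ani_threshold` (default 0.95). Deterministic given the fixed
#' sketch hashing. MAGs with no scaffold of at least `sketch_k` bp are
#' excluded with a warning.
#'
#' @param mag_seqs Named list: MAG id -> character vector of scaffold
#'   sequences.
#' @param params [cluster_params()].
#' @return List with `populations` (`data.frame` `member_id`,
#'   `population_id`) and `ani` (pairwise estimate `data.frame`).
#' @export
dereplicate_mags <- function(mag_seqs, params = cluster_params()) {
  k <- as.integer(params$sketch_k)
  size <- as.integer(params$sketch_size)
  ok <- vapply(mag_seqs, function(x) any(nchar(x) >= k), TRUE)
  if (any(!ok)) {
    warning("excluding MAG(s) shorter than sketch k: ",
            paste(names(mag_seqs)[!ok], collapse = ", "))
  }
  mag_seqs <- mag_seqs[ok]
  ids <- names(mag_seqs)
  sketches <- lapply(mag_seqs, .sketch, k = k, size = size)
  n <- length(ids)
  pairs <- list()
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ani <- .sketch_ani(sketches[[i]], sketches[[j]], k, size)
        pairs[[length(pairs) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], ani = ani, stringsAsFactors = FALSE)
        if (ani >= params$ani_threshold) {
          edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) as.data.frame(do.call(rbind, edges)) else
      data.frame(V1 = character(0), V2 = character(0)),
    directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  pops <- data.frame(member_id = names(comp),
                     population_id = sprintf("P%d", unname(comp)),
                     stringsAsFactors = FALSE)
  list(populations = pops[order(pops$member_id), ],
       ani = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(a = character(0), b = character(0), ani = numeric(0)))
}

#' Compare two temporally separated virus-host networks
#'
#' Computes community overlap at the population level: shared viral
#' populations and shared MAG populations, both dataset-wide (all members
#' of each year) and restricted to the networks' nodes, plus shared
#' (host population, viral population) link pairs. Shared counts are
#' symmetric in the year used as reference; only the denominators differ.
#' Percentages are reported to one decimal.
#'
#' @param netA,netB `vh_network` objects (e.g. the two years).
#' @param viral_clusters Cluster assignment `data.frame` from
#'   [cluster_viral()] covering viral ids of both years.
#' @param mag_populations Population `data.frame` from
#'   [dereplicate_mags()] covering MAG ids of both years.
#' @param virals_a,virals_b Optional character vectors of all viral ids per
#'   year (dataset-wide overlap); default: the networks' viral nodes.
#' @param mags_a,mags_b Optional character vectors of all MAG ids per year.
#' @return Nested list of counts and one-decimal percentages.
#' @export
compare_networks <- function(netA, netB, viral_clusters, mag_populations,
                             virals_a = NULL, virals_b = NULL,
                             mags_a = NULL, mags_b = NULL) {
  vmap <- stats::setNames(viral_clusters$cluster_id,
                          viral_clusters$member_id)
  mmap <- stats::setNames(mag_populations$population_id,
                          mag_populations$member_id)
  net_virals <- function(net) unique(net$edges$viral_id)
  net_mags <- function(net) unique(net$edges$host_id)
  if (is.null(virals_a)) virals_a <- net_virals(netA)
  if (is.null(virals_b)) virals_b <- net_virals(netB)
  if (is.null(mags_a)) mags_a <- net_mags(netA)
  if (is.null(mags_b)) mags_b <- net_mags(netB)
  lookup <- function(map, ids, what) {
    missing <- setdiff(ids, names(map))
    if (length(missing)) {
      sl_error("sl_consistency_error", paste0(
        what, " missing from population/cluster map: ",
        paste(utils::head(missing, 5), collapse = ", ")))
    }
    unique(unname(map[ids]))
  }
  ov <- function(pa, pb) {
    shared <- length(intersect(pa, pb))
    list(shared = shared, n_a = length(pa), n_b = length(pb),
         pct_a = if (length(pa)) round_half_up(100 * shared / length(pa), 1)
                 else 0,
         pct_b = if (length(pb)) round_half_up(100 * shared / length(pb), 1)
                 else 0)
  }
  vd <- ov(lookup(vmap, virals_a, "viral id(s)"),
           lookup(vmap, virals_b, "viral id(s)"))
  vn <- ov(lookup(vmap, net_virals(netA), "viral id(s)"),
           lookup(vmap, net_virals(netB), "viral id(s)"))
  md <- ov(lookup(mmap, mags_a, "MAG id(s)"),
           lookup(mmap, mags_b, "MAG id(s)"))
  mn <- ov(lookup(mmap, net_mags(netA), "MAG id(s)"),
           lookup(mmap, net_mags(netB), "MAG id(s)"))
  pair_set <- function(net) {
    unique(paste(mmap[net$edges$host_id], vmap[net$edges$viral_id],
                 sep = "\r"))
  }
  pp <- ov(pair_set(netA), pair_set(netB))
  list(viral_dataset = vd, viral_network = vn,
       mag_dataset = md, mag_network = mn,
       link_pairs = pp)
}

#' Compare two CRISPR arrays
#'
#' Shared spacers are exact full-length sequence matches in either
#' orientation. `order_conserved` is `TRUE` when the shared spacers occur
#' in the same relative order (possibly reversed) in both arrays — i.e.
#' they form a common subsequence. Each array's 200-bp flanks are also
#' scanned for a segment at least 60% identical to the other array's
#' consensus repeat over at least half the repeat length, reported as
#' evidence of a partially degraded repeat (a shared array origin even
#' without shared spacers).
#'
#' @param arrayA,arrayB `crispr_array` objects with flanks populated.
#' @return List: `shared_spacer_count`, `total_a`, `total_b`,
#'   `order_conserved`, `flank_degraded_repeat`, `flank_location`.
#' @export
compare_arrays <- function(arrayA, arrayB) {
  canon <- function(s) pmin(s, dna_revcomp(s))
  ca <- canon(arrayA$spacers$seq)
  cb <- canon(arrayB$spacers$seq)
  shared_seqs <- intersect(ca, cb)
  shared <- length(shared_seqs)
  order_conserved <- TRUE
  if (shared >= 2L) {
    pa <- match(shared_seqs, ca)
    pb <- match(shared_seqs, cb)
    o <- order(pa)
    pb_in_a_order <- pb[o]
    order_conserved <- all(diff(pb_in_a_order) > 0) ||
      all(diff(pb_in_a_order) < 0)
  }
  deg <- .flank_degraded(arrayA, arrayB$consensus_repeat)
  if (is.na(deg)) deg <- .flank_degraded(arrayB, arrayA$consensus_repeat)
  list(shared_spacer_count = shared,
       total_a = nrow(arrayA$spacers), total_b = nrow(arrayB$spacers),
       order_conserved = order_conserved,
       flank_degraded_repeat = !is.na(deg),
       flank_location = if (!is.na(deg)) deg else NA_character_)
}

# Scan an array's flanks for a degraded copy of a repeat: any window
# matching the repeat prefix at >= 60% identity over >= 50% of the repeat
# length. Returns "5p"/"3p" or NA.
.flank_degraded <- function(array, repeat_seq, min_identity = 0.6,
                            min_frac = 0.5) {
  rl <- nchar(repeat_seq)
  min_len <- ceiling(min_frac * rl)
  for (side in c("5p", "3p")) {
    flank <- if (side == "5p") array$flank_5p else array$flank_3p
    fl <- nchar(flank)
    if (fl < min_len) next
    for (start in seq_len(fl - min_len + 1L)) {
      L <- min(rl, fl - start + 1L)
      win <- substr(flank, start, start + L - 1L)
      for (rc in c(FALSE, TRUE)) {
        w <- if (rc) dna_revcomp(win) else win
        idm <- ungapped_identity(w, repeat_seq)
        if (L >= min_len && idm >= min_identity) return(side)
      }
    }
  }
  NA_character_
}
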