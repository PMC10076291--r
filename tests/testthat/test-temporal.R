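test_that("clustering merges at 95.0% identity and splits at 94.0%", {
  withr::with_seed(91, {
    base <- rnd_dna(10000)
    # substitutions spread through the interior so the local alignment
    # spans the full sequence and identity is exact
    s95 <- sub_at(base, seq(101, by = 19, length.out = 500))
    s94 <- sub_at(base, seq(101, by = 16, length.out = 600))
    cl <- cluster_viral(c(A = base, B = s95, C = s94))
    expect_equal(cl$cluster_id[cl$member_id == "B"],
                 cl$cluster_id[cl$member_id == "A"])
    expect_equal(cl$identity_to_rep[cl$member_id == "B"], 0.95)
    expect_false(cl$cluster_id[cl$member_id == "C"] ==
                   cl$cluster_id[cl$member_id == "A"])
  })
})

test_that("identical sequences cluster with the lexicographic tie rule", {
  s <- rnd_dna(4000, seed = 92)
  cl <- cluster_viral(c(zeta = s, alpha = s))
  expect_equal(unique(cl$representative_id), "alpha")
  expect_equal(nrow(unique(cl["cluster_id"])), 1L)
})

test_that("a reverse-complemented duplicate joins its source cluster", {
  s <- rnd_dna(5000, seed = 93)
  cl <- cluster_viral(c(A = s, B = revcomp(s)))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(cl$identity_to_rep[cl$member_id == "B"], 1)
})

test_that("greedy clustering satisfies the canonical all-pairs properties", {
  withr::with_seed(94, {
    seqs <- character(0)
    for (i in 1:8) {
      b <- rnd_dna(800 + 40 * i)
      seqs[sprintf("S%02d_a", i)] <- b
      if (i <= 4) {
        # near-duplicate inside the cluster threshold
        seqs[sprintf("S%02d_b", i)] <- sub_at(b, seq(51, by = 40,
                                                     length.out = 15))
      }
    }
    cl <- cluster_viral(seqs)
    params <- cluster_params()
    reps <- cl[cl$member_id == cl$representative_id, ]
    founded <- reps$representative_id[order(reps$cluster_id)]
    for (i in seq_len(nrow(cl))) {
      row <- cl[i, ]
      ident <- spacerlink:::global_identity_shorter(
        seqs[[row$member_id]], seqs[[row$representative_id]])
      if (row$member_id != row$representative_id) {
        expect_gte(ident, params$c)
        # representative is at least as long
        expect_gte(nchar(seqs[[row$representative_id]]),
                   nchar(seqs[[row$member_id]]))
        # the member matches no EARLIER-founded representative
        ri <- match(row$representative_id, founded)
        if (ri > 1) {
          for (e in founded[seq_len(ri - 1L)]) {
            expect_lt(spacerlink:::global_identity_shorter(
              seqs[[row$member_id]], seqs[[e]]), params$c)
          }
        }
      }
    }
    # no representative reaches the threshold against an earlier one
    if (length(founded) > 1) {
      for (i in 2:length(founded)) {
        for (j in seq_len(i - 1L)) {
          expect_lt(spacerlink:::global_identity_shorter(
            seqs[[founded[i]]], seqs[[founded[j]]]), params$c)
        }
      }
    }
  })
})

test_that("MAG dereplication merges duplicates and separates unrelated genomes", {
  withr::with_seed(95, {
    m1 <- rnd_dna(80000)
    m2 <- sub_at(m1, sample(200:79800, 1600))  # ~2% divergence
    m3 <- rnd_dna(80000)
    dr <- dereplicate_mags(list(X = m1, Y = m2, Z = m3))
    pops <- stats::setNames(dr$populations$population_id,
                            dr$populations$member_id)
    expect_equal(pops[["X"]], pops[["Y"]])
    expect_false(pops[["Z"]] == pops[["X"]])
    # Mash-style ANI estimate is close to the true 98%
    ani_xy <- dr$ani$ani[dr$ani$a == "X" & dr$ani$b == "Y"]
    expect_equal(ani_xy, 0.98, tolerance = 0.01)
    # identical duplicate -> ANI 1, same population
    dr2 <- dereplicate_mags(list(A = m1, B = m1))
    expect_equal(dr2$ani$ani, 1)
    expect_equal(length(unique(dr2$populations$population_id)), 1L)
  })
})

test_that("network overlap reports shared populations with one-decimal percents", {
  mk_net <- function(hosts, virs, label) structure(list(
    hosts = NULL, virals = NULL,
    edges = data.frame(host_id = hosts, viral_id = virs, weight = 1),
    label = label), class = "vh_network")
  nA <- mk_net(c("h1", "h2"), c("va", "vb"), "2016")
  nB <- mk_net(c("h3", "h2b"), c("vc", "vb2"), "2017")
  vc <- data.frame(member_id = c("va", "vb", "vc", "vb2", "vd"),
                   cluster_id = c("C1", "C2", "C3", "C2", "C4"),
                   representative_id = NA, identity_to_rep = 1)
  mp <- data.frame(member_id = c("h1", "h2", "h3", "h2b"),
                   population_id = c("P1", "P2", "P3", "P2"))
  ov <- compare_networks(nA, nB, vc, mp,
                         virals_a = c("va", "vb", "vd"),
                         virals_b = c("vc", "vb2"))
  expect_equal(ov$viral_network$shared, 1L)
  expect_equal(ov$viral_dataset$n_a, 3L)
  expect_equal(ov$mag_network$shared, 1L)
  expect_equal(ov$link_pairs$shared, 1L)  # (P2, C2) in both
  # shared counts are symmetric in the reference year
  expect_equal(ov$viral_network$shared,
               compare_networks(nB, nA, vc, mp)$viral_network$shared)
  # identical networks overlap 100%
  same <- compare_networks(nA, nA, vc, mp)
  expect_equal(same$viral_network$pct_a, 100)
  expect_equal(same$link_pairs$pct_b, 100)
  # one-decimal formatting of the reported style: 19 of 59 -> 32.2
  expect_equal(spacerlink:::round_half_up(100 * 19 / 59, 1), 32.2)
  expect_equal(spacerlink:::round_half_up(100 * 5 / 59, 1), 8.5)
  # nodes missing from the maps are a consistency error
  expect_error(compare_networks(nA, nB, vc[-1, ], mp),
               class = "sl_consistency_error")
})

test_that("array comparison counts shared spacers and order conservation", {
  withr::with_seed(96, {
    sp <- vapply(1:6, function(i) rnd_dna(31), "")
    A <- mk_array("a", "s1", sp[1:3])
    B <- mk_array("b", "s2", sp[1:5])
    cmp <- compare_arrays(A, B)
    expect_equal(cmp$shared_spacer_count, 3L)   # subset relation
    expect_true(cmp$order_conserved)
    expect_equal(cmp$shared_spacer_count, compare_arrays(B, A)$shared_spacer_count)
    # identical array: all shared
    self <- compare_arrays(A, A)
    expect_equal(self$shared_spacer_count, 3L)
    # reverse-complemented spacers still count as shared
    C <- mk_array("c", "s3", revcomp(sp[1:3]))
    expect_equal(compare_arrays(A, C)$shared_spacer_count, 3L)
    # shuffled order is detected
    D <- mk_array("d", "s4", sp[c(2, 1, 3)])
    expect_false(compare_arrays(A, D)$order_conserved)
    # zero shared spacers but a degraded repeat copy in the flank
    rep_seq <- rnd_dna(32)
    frag <- substr(rep_seq, 1, 20)   # 20/32 of the repeat, exact
    E <- mk_array("e", "s5", vapply(1:2, function(i) rnd_dna(30), ""),
                  flank5 = paste0(rnd_dna(120), frag, rnd_dna(60)))
    F1 <- mk_array("f", "s6", vapply(1:2, function(i) rnd_dna(30), ""),
                   rep_seq = rep_seq)
    cmp2 <- compare_arrays(E, F1)
    expect_equal(cmp2$shared_spacer_count, 0L)
    expect_true(cmp2$flank_degraded_repeat)
    expect_equal(cmp2$flank_location, "5p")
  })
})
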