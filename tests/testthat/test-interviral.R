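# One community with virally encoded arrays, conflicts of both kinds, and
# planted proviruses; reused across the blocks below.
.iv_cache <- new.env(parent = emptyenv())
iv_comm <- function() {
  if (is.null(.iv_cache$comm)) {
    .iv_cache$comm <- generate_community(synthetic_config(
      n_hosts = 2, n_viruses = 6,
      scaffold_len_range = c(15000, 20000), viral_len_range = c(4000, 8000),
      arrays_per_host = c(1, 1), spacers_per_array = c(3, 3),
      viral_array_spec = list(
        list(virus = 1, n_spacers = 3,
             targets = list(list(virus = 2, mode = "protospacer"),
                            list(virus = 3, mode = "shared_spacer"))),
        list(virus = 3, n_spacers = 3, targets = list())),
      provirus_spec = list(
        list(virus = 4, host = 1, identity = 0.75, length = 4000,
             mode = "integrated"),
        list(virus = 5, host = 2, identity = 0.99, length = 2499,
             mode = "integrated"),
        list(virus = 6, host = 2, identity = 0.97, length = 3000,
             mode = "cobinned")),
      seed = 7))
  }
  .iv_cache$comm
}

test_that("virally encoded arrays are found and the summary fraction is exact", {
  comm <- iv_comm()
  va <- find_viral_arrays(comm$virals)
  expect_equal(va$summary$n_with_arrays, 2L)
  expect_equal(va$summary$pct_with_arrays,
               spacerlink:::round_half_up(100 * 2 / nrow(comm$virals), 2))
  owners <- vapply(va$arrays, function(a) a$scaffold_id, "")
  expect_setequal(owners, c("V1", "V3"))
  counts <- vapply(va$arrays, function(a) nrow(a$spacers), 0L)
  expect_true(all(counts == 3L))
  # percentage formatting matches reported style: 70 of 17057 -> 0.41
  expect_equal(spacerlink:::round_half_up(100 * 70 / 17057, 2), 0.41)
  expect_equal(spacerlink:::round_half_up(100 * 91 / 18877, 2), 0.48)
})

test_that("shared array spacers are never genuine conflicts; planted protospacers are", {
  comm <- iv_comm()
  va <- find_viral_arrays(comm$virals)
  vsp <- excise_spacers_all(va$arrays)
  idx <- build_target_index(comm$virals)
  conf <- find_conflicts(vsp, idx, va$arrays)
  cc <- conf$conflicts
  # no self conflicts
  expect_false(any(cc$source_viral_id == cc$target_viral_id))
  man <- comm$manifest$conflicts
  for (mc in man) {
    row <- cc[cc$source_viral_id == mc$source &
                cc$target_viral_id == mc$target, ]
    if (mc$mode == "protospacer") {
      expect_equal(nrow(row), 1L)
      expect_true(row$genuine)
    } else {
      # shared spacer: detected as a connection but not genuine
      expect_equal(nrow(row), 1L)
      expect_false(row$genuine)
      back <- cc[cc$source_viral_id == mc$target &
                   cc$target_viral_id == mc$source, ]
      expect_false(any(back$genuine))
    }
  }
  # every supporting match of a non-genuine conflict is in-array
  mm <- conf$matches
  for (i in which(!cc$genuine)) {
    sel <- mm$owner_id == cc$source_viral_id[i] &
      mm$target_id == cc$target_viral_id[i]
    expect_true(all(mm$in_array[sel]))
  }
})

test_that("viral-to-bin alignments match closed-form expectations", {
  comm <- iv_comm()
  al <- align_viral_to_bins(
    comm$virals[comm$virals$id %in% c("V4", "V5", "V6"), ],
    comm$host_scaffolds)
  a4 <- al[al$viral_id == "V4" & al$aligned_len >= 2500, ]
  expect_equal(nrow(a4), 1L)
  pv <- Filter(function(p) p$virus_id == "V4", comm$manifest$proviruses)[[1]]
  # planted: 4000 columns at 75% identity, no indels
  expect_equal(a4$aligned_len, 4000L)
  expect_equal(a4$identity, 0.75, tolerance = 0.002)
  expect_equal(a4$start, pv$start)
  expect_equal(a4$end, pv$end)
  n_sub <- round(0.25 * 4000)
  expect_equal(a4$score, (4000 - n_sub) * 1 + n_sub * (-2))
  # 2499-bp insert alignment cannot reach 2500 columns
  a5 <- al[al$viral_id == "V5", ]
  expect_true(all(a5$aligned_len < 2500))
})

test_that("the aligner reproduces full-DP scores on small instances", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      a <- rnd_dna(120)
      core <- substr(a, 21, 100)
      b <- paste0(rnd_dna(60), sub_at(core, sample(80, 8)), rnd_dna(60))
      # introduce an indel in one case
      if (rep > 3) b <- paste0(substr(b, 1, 90), substr(b, 94, nchar(b)))
      al <- align_viral_to_bins(data.frame(id = "q", seq = a),
                                data.frame(id = "s", seq = b))
      ref <- sw_score_ref(a, b)
      ref_rc <- sw_score_ref(revcomp(a), b)
      expect_equal(al$score, max(ref, ref_rc))
    }
  })
})

test_that("provirus calls apply all four thresholds and the co-binning rule", {
  comm <- iv_comm()
  al <- align_viral_to_bins(
    comm$virals[comm$virals$id %in% c("V4", "V5", "V6"), ],
    comm$host_scaffolds)
  host_lens <- stats::setNames(nchar(comm$host_scaffolds$seq),
                               comm$host_scaffolds$id)
  calls <- call_proviruses(al, host_scaffold_lengths = host_lens)
  expect_setequal(calls$viral_id, c("V4", "V6"))  # V5 rejected: 2499 < 2500
  expect_equal(calls$class[calls$viral_id == "V4"], "integrated")
  expect_equal(calls$class[calls$viral_id == "V6"], "cobinned")
  expect_gte(calls$host_aligned_fraction[calls$viral_id == "V6"], 0.90)
  # identity threshold: degrade V4 below 70% and it disappears
  al2 <- al
  al2$identity <- al2$identity - 0.06
  calls2 <- call_proviruses(al2, host_scaffold_lengths = host_lens)
  expect_false("V4" %in% calls2$viral_id)
  # provirus GFF export is valid and 1-based inclusive
  f <- withr::local_tempfile(fileext = ".gff3")
  write_provirus_gff(calls, f)
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), nrow(calls))
  expect_equal(GenomicRanges::start(gr), calls$start + 1L)
})

test_that("superinfection attribution separates proviral from native arrays", {
  withr::with_seed(72, {
    prov <- data.frame(viral_id = "Vp", host_mag_id = "M1",
                       host_scaffold_id = "s1", start = 1000, end = 9000,
                       class = "integrated", stringsAsFactors = FALSE)
    arr_prov <- mk_array("ap", "s1", c(rnd_dna(30), rnd_dna(31)),
                         offset = 2000L)  # inside the provirus interval
    arr_nat <- mk_array("an", "s2", c(rnd_dna(30), rnd_dna(31)))
    base <- data.frame(owner_id = "M1", target_id = "Vx", strand = "+",
                       n_mismatches = 0L, query_coverage = 1, score = 60,
                       evalue = 1e-9, stringsAsFactors = FALSE)
    m_prov <- cbind(base, spacer_id = "ap:0", start = 10, end = 40,
                    in_array = FALSE)
    m_nat <- cbind(base, spacer_id = "an:0", start = 100, end = 130,
                   in_array = FALSE)
    rep1 <- superinfection_report(prov, list(arr_prov, arr_nat), m_prov)
    expect_equal(rep1$attribution, "provirus-encoded")
    rep2 <- superinfection_report(prov, list(arr_prov, arr_nat),
                                  rbind(m_prov, m_nat))
    expect_equal(rep2$attribution, "both")
    expect_false(rep2$non_immunizing)
    # pairs supported only by in-array (spacer-to-spacer) matches are
    # flagged non-immunizing
    m_ia <- m_prov
    m_ia$in_array <- TRUE
    rep3 <- superinfection_report(prov, list(arr_prov, arr_nat), m_ia)
    expect_true(rep3$non_immunizing)
  })
})
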