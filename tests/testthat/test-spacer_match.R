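test_that("the target index posts every exact word on both strands", {
  t20 <- data.frame(id = "t", seq = rnd_dna(20, seed = 41))
  idx <- build_target_index(t20, k = 10)
  expect_equal(sum(idx$plus), 11L)    # 20 - 10 + 1 forward postings
  expect_equal(sum(!idx$plus), 11L)
  # absent word -> empty lookup
  expect_length(spacerlink:::.index_lookup(idx, 0L), 0L)
  # a palindromic word posts on both strands at the same locus
  pal <- "ACGTACGT"  # 8-mer palindrome, pad to 10 with its context
  tp <- data.frame(id = "p", seq = paste0("GG", "ACGCGCGCGT", "CC"))
  idxp <- build_target_index(tp, k = 10)
  code <- spacerlink:::encode_kmers("ACGCGCGCGT", 10)
  rows <- spacerlink:::.index_lookup(idxp, as.integer(code))
  expect_setequal(idxp$plus[rows], c(TRUE, FALSE))
})

test_that("planted protospacers are recovered at their manifest intervals", {
  comm <- small_comm()
  arrays <- detect_arrays_all(comm$host_scaffolds)
  owner_of <- stats::setNames(comm$host_scaffolds$mag_id,
                              comm$host_scaffolds$id)
  spacers <- excise_spacers_all(arrays, owner_of)
  idx <- build_target_index(comm$virals)
  m <- find_protospacers(spacers, idx)
  protos <- comm$manifest$protospacers
  exp_keys <- sort(vapply(
    Filter(function(p) p$n_mismatches <= 1, protos),
    function(p) paste(p$virus_id, p$start, p$end, p$strand, p$n_mismatches),
    ""))
  got_keys <- sort(paste(m$target_id, m$start, m$end, m$strand,
                         m$n_mismatches))
  expect_identical(got_keys, exp_keys)
  expect_true(all(m$query_coverage == 1))
  # two-substitution protospacers are never recovered
  expect_false(any(m$target_id == "V3"))
})

test_that("E-values follow the Karlin-Altschul plug-in arithmetic", {
  # 30-bp spacer, exact 30-bp hit, targets totaling 10 kb
  withr::with_seed(43, {
    sp <- rnd_dna(30)
    t1 <- paste0(rnd_dna(3000), sp, rnd_dna(1970))
    t2 <- rnd_dna(5000)
    targets <- data.frame(id = c("t1", "t2"), seq = c(t1, t2))
    idx <- build_target_index(targets)
    m <- find_protospacers(mk_spacers(sp), idx)
    m <- m[m$n_mismatches == 0 & m$query_coverage == 1, ]
    expect_equal(nrow(m), 1L)
    expect_equal(m$score, 60)
    # independently evaluated: E = K * m * n * exp(-lambda * S),
    # n = 20000 (both strands of 10 kb)
    expect_equal(m$evalue, 0.41 * 30 * 20000 * exp(-0.625 * 60),
                 tolerance = 1e-12)
    expect_equal(m$evalue, 1.27475e-11, tolerance = 1e-4)
    expect_lt(m$evalue, 1e-4)
  })
})

test_that("indexed search equals the brute-force oracle on random fixtures", {
  withr::with_seed(44, {
    for (rep in 1:4) {
      targets <- data.frame(id = sprintf("t%d", 1:4),
                            seq = vapply(1:4, function(i) rnd_dna(5000), ""))
      sp <- vapply(1:10, function(i) rnd_dna(sample(25:45, 1)), "")
      # plant some hits: exact, 1-mismatch, minus strand, 2-mismatch
      sp[1] <- substr(targets$seq[1], 101, 135)
      sp[2] <- sub_at(substr(targets$seq[2], 501, 540), 20)
      sp[3] <- revcomp(substr(targets$seq[3], 1001, 1030))
      sp[4] <- sub_at(substr(targets$seq[4], 2001, 2040), c(15, 25))
      spacers <- mk_spacers(sp)
      idx <- build_target_index(targets)
      m1 <- find_protospacers(spacers, idx)
      m2 <- brute_match(spacers, targets)
      expect_identical(match_key(m1), match_key(m2))
      expect_true(any(m1$strand == "-"))
    }
  })
})

test_that("strand symmetry: reverse-complementing targets mirrors matches", {
  withr::with_seed(45, {
    t <- rnd_dna(4000)
    sp <- substr(t, 301, 336)
    targets <- data.frame(id = "t", seq = t)
    flipped <- data.frame(id = "t", seq = revcomp(t))
    spacers <- mk_spacers(sp)
    m1 <- find_protospacers(spacers, build_target_index(targets))
    m2 <- find_protospacers(spacers, build_target_index(flipped))
    expect_equal(nrow(m1), nrow(m2))
    expect_identical(m2$strand, chartr("+-", "-+", m1$strand))
    expect_equal(m2$start, 4000 - m1$end)
    expect_equal(m2$end, 4000 - m1$start)
  })
})

test_that("coverage clipping recovers end-truncated hits but respects the budget", {
  withr::with_seed(46, {
    t <- rnd_dna(3000)
    # 36 of 40 aligned = 0.9; the 4-base tail is forced to mismatch the
    # following target bases so the clipped window is uniquely optimal
    sp40 <- paste0(substr(t, 501, 536), sub_at(substr(t, 537, 540), 1:4))
    m <- find_protospacers(mk_spacers(sp40), build_target_index(
      data.frame(id = "t", seq = t)))
    m <- m[m$target_id == "t" & m$start == 500, ]
    expect_equal(nrow(m), 1L)
    expect_equal(m$query_coverage, 0.9)
    # 5 clipped bases would undershoot 90% coverage: no full-clip hit
    sp41 <- paste0(substr(t, 1001, 1036), sub_at(substr(t, 1037, 1041), 1:5))
    m2 <- find_protospacers(mk_spacers(sp41), build_target_index(
      data.frame(id = "t", seq = t)))
    expect_false(any(m2$start == 1000 & m2$query_coverage < 0.9))
  })
})

test_that("alignment columns involving N count as mismatches", {
  core <- rnd_dna(25, seed = 52)
  t <- paste0(rnd_dna(1000, seed = 47), core, rnd_dna(1000, seed = 48))
  spN <- paste0(substr(core, 1, 12), "N", substr(core, 14, 25))
  m <- brute_match(mk_spacers(spN), data.frame(id = "t", seq = t))
  hit <- m[m$start == 1000, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_mismatches, 1L)
})

test_that("spacers shorter than twice the word size are routed to brute force", {
  idx <- build_target_index(data.frame(id = "t", seq = rnd_dna(100, seed = 49)))
  expect_error(find_protospacers(mk_spacers("ACGTACGTACGTACG"), idx),
               class = "sl_value_error")
  # brute_match handles them
  expect_s3_class(brute_match(mk_spacers("ACGTACGTACGTACG"),
                              data.frame(id = "t", seq = rnd_dna(100, seed = 50))),
                  "data.frame")
})

test_that("in-array flagging follows the 50% overlap rule", {
  arr <- mk_array("va1", "V1", c(rnd_dna(30, seed = 51),
                                 rnd_dna(30, seed = 53)),
                  offset = 1000L)   # array spans [1000, 1000+len)
  span <- c(arr$start, arr$end)
  mk_m <- function(start, end) {
    data.frame(spacer_id = "x:0", owner_id = "H", target_id = "V1",
               start = start, end = end, strand = "+", n_mismatches = 0L,
               query_coverage = 1, score = 60, evalue = 1e-9,
               in_array = FALSE)
  }
  inside <- flag_in_array(mk_m(span[1] + 5, span[1] + 35), list(arr))
  expect_true(inside$in_array)
  far <- flag_in_array(mk_m(span[2] + 10000, span[2] + 10030), list(arr))
  expect_false(far$in_array)
  # straddling the edge with 40% overlap (12 of 30 bases inside)
  strad <- flag_in_array(mk_m(span[1] - 18, span[1] + 12), list(arr))
  expect_false(strad$in_array)
  # 50% exactly is in
  half <- flag_in_array(mk_m(span[1] - 15, span[1] + 15), list(arr))
  expect_true(half$in_array)
})

test_that("match TSV round-trips", {
  comm <- small_comm()
  arrays <- detect_arrays_all(comm$host_scaffolds)
  spacers <- excise_spacers_all(
    arrays, stats::setNames(comm$host_scaffolds$mag_id,
                            comm$host_scaffolds$id))
  m <- find_protospacers(spacers, build_target_index(comm$virals))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matches_tsv(m, f)
  back <- read_matches_tsv(f)
  expect_identical(match_key(back), match_key(m))
})
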