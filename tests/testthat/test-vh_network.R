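mk_mags <- function(ids, completeness = 90, contamination = 1,
                    phylum = "Firmicutes", domain = "Bacteria",
                    site = "LW1", year = 2016) {
  df <- data.frame(mag_id = ids, completeness = completeness,
                   contamination = contamination,
                   lineage = sprintf("d__%s;p__%s", domain, phylum),
                   site = site, year = year, stringsAsFactors = FALSE)
  ranks <- spacerlink:::split_lineage(df$lineage)
  for (r in colnames(ranks)) df[[r]] <- ranks[, r]
  df
}

mk_virals <- function(ids, site = "GW1", year = 2016) {
  data.frame(viral_id = ids, site = site, year = year,
             category = "nonintegrated", dgr = FALSE,
             stringsAsFactors = FALSE)
}

mk_match <- function(owner, target, start, spacer = "a:0", mm = 0L,
                     in_array = FALSE) {
  data.frame(spacer_id = spacer, owner_id = owner, target_id = target,
             start = start, end = start + 30, strand = "+",
             n_mismatches = mm, query_coverage = 1, score = 60,
             evalue = 1e-10, in_array = in_array, stringsAsFactors = FALSE)
}

test_that("the MAG quality gate uses strict inequalities", {
  mags <- mk_mags(c("A", "B", "C", "D"),
                  completeness = c(70.13, 70.0, 90, 95),
                  contamination = c(1.8, 5, 10.0, 9.99))
  kept <- quality_filter_mags(mags)
  expect_setequal(kept$mag_id, c("A", "D"))  # 70.0 and 10.0 both fail
})

test_that("edges count distinct protospacer loci and unique links count pairs", {
  mags <- mk_mags(c("M1", "M2"))
  virals <- mk_virals(c("V1", "V2"))
  m <- rbind(mk_match("M1", "V1", 100, "a:0"),
             mk_match("M1", "V1", 200, "a:0"),   # same spacer, second locus
             mk_match("M1", "V1", 200, "a:1"),   # same locus, another spacer
             mk_match("M2", "V2", 100, "b:0"),
             mk_match("M2", "V1", 100, "b:1", in_array = TRUE))
  net <- build_network(m, mags, virals, "t")
  expect_equal(nrow(net$edges), 2L)   # in_array match contributes no edge
  w <- net$edges$weight[net$edges$host_id == "M1"]
  expect_equal(w, 2L)                 # two distinct loci
  s <- summarize_network(net)
  expect_equal(s$unique_links, 2L)
  expect_equal(s$pct_hosts_multi, 0)
  expect_equal(s$pct_virals_multi, 0)
})

test_that("a complete bipartite 2x2 network summarizes to 100% multi", {
  mags <- mk_mags(c("M1", "M2"))
  virals <- mk_virals(c("V1", "V2"))
  m <- rbind(mk_match("M1", "V1", 1), mk_match("M1", "V2", 1),
             mk_match("M2", "V1", 1), mk_match("M2", "V2", 1))
  s <- summarize_network(build_network(m, mags, virals, "t"))
  expect_equal(s$unique_links, 4L)
  expect_equal(s$pct_hosts_multi, 100)
  expect_equal(s$pct_virals_multi, 100)
})

test_that("summary agrees with a brute-force recount on random networks", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      mags <- mk_mags(sprintf("M%d", 1:6))
      virals <- mk_virals(sprintf("V%d", 1:8))
      n <- sample(5:20, 1)
      m <- do.call(rbind, lapply(seq_len(n), function(i) {
        mk_match(sample(mags$mag_id, 1), sample(virals$viral_id, 1),
                 sample(1e4, 1), sprintf("s%d:0", i))
      }))
      net <- build_network(m, mags, virals, "r")
      s <- summarize_network(net)
      pairs <- unique(m[, c("owner_id", "target_id", "start", "end",
                            "strand")])
      links <- unique(pairs[, c("owner_id", "target_id")])
      expect_equal(s$unique_links, nrow(links))
      expect_equal(sum(net$edges$weight),
                   nrow(unique(pairs)))
      deg <- table(links$owner_id)
      expect_equal(s$pct_hosts_multi,
                   100 * sum(deg >= 2) / length(unique(links$owner_id)))
    }
  })
})

test_that("matches referencing unknown nodes are a consistency error", {
  mags <- mk_mags("M1")
  virals <- mk_virals("V1")
  expect_error(build_network(mk_match("M9", "V1", 1), mags, virals),
               class = "sl_consistency_error")
  expect_error(build_network(mk_match("M1", "V9", 1), mags, virals),
               class = "sl_consistency_error")
})

test_that("four temporal networks are built from two-year data", {
  mags <- rbind(mk_mags(c("M1", "M2"), year = 2016),
                mk_mags(c("M3"), year = 2017))
  virals <- rbind(mk_virals("V1", year = 2016), mk_virals("V2", year = 2017))
  m <- rbind(mk_match("M1", "V1", 1), mk_match("M1", "V2", 1),
             mk_match("M3", "V1", 1), mk_match("M3", "V2", 1))
  nets <- build_networks_by_year(m, mags, virals)
  expect_setequal(names(nets),
                  c("2016", "2017", "2016-host-to-2017-viruses",
                    "2017-host-to-2016-viruses"))
  expect_equal(nets[["2016"]]$edges$viral_id, "V1")
  expect_equal(nets[["2016-host-to-2017-viruses"]]$edges$viral_id, "V2")
  expect_equal(nets[["2017-host-to-2016-viruses"]]$edges$host_id, "M3")
})

test_that("hyper-targeting uses an inclusive >= 20 boundary", {
  mags <- mk_mags(c("M1", "M2", "M3"))
  virals <- mk_virals(c("V1", "V2", "V3"))
  m <- do.call(rbind, c(
    lapply(1:19, function(i) mk_match("M1", "V1", i * 40, sprintf("a:%d", i))),
    lapply(1:20, function(i) mk_match("M2", "V2", i * 40, sprintf("b:%d", i))),
    lapply(1:21, function(i) mk_match("M3", "V3", i * 40, sprintf("c:%d", i)))))
  net <- build_network(m, mags, virals, "t")
  h <- find_hyper_targeted(net, 20)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$viral_id, c("V2", "V3"))
  expect_equal(h$n_protospacers, c(21L, 20L))  # sorted descending
})

test_that("cross-taxon candidates require distinct ranks; missing ranks flag unrankable", {
  mags <- rbind(mk_mags("M1", phylum = "Firmicutes"),
                mk_mags("M2", phylum = "Patescibacteria"),
                mk_mags("M3", phylum = "Muirbacteria"),
                mk_mags("M4", phylum = "Firmicutes"),
                mk_mags("M5", domain = "Archaea", phylum = "Halobacteriota"))
  mags$phylum[mags$mag_id == "M5"] <- "Halobacteriota"
  virals <- mk_virals(c("V1", "V2", "V3"))
  m <- rbind(mk_match("M1", "V1", 1), mk_match("M2", "V1", 50),
             mk_match("M3", "V1", 100),
             mk_match("M1", "V2", 1), mk_match("M4", "V2", 50),
             mk_match("M1", "V3", 1), mk_match("M5", "V3", 50))
  net <- build_network(m, mags, virals, "t")
  ph <- find_cross_taxon(net, "phylum")
  expect_setequal(ph$viral_id[ph$status == "candidate"], c("V1", "V3"))
  expect_equal(ph$ranks[ph$viral_id == "V1"],
               "Firmicutes;Patescibacteria;Muirbacteria")
  dm <- find_cross_taxon(net, "domain")
  expect_equal(dm$viral_id[dm$status == "candidate"], "V3")
  # same-phylum multi-host virus is absent entirely
  expect_false("V2" %in% ph$viral_id)
  # missing rank -> unrankable, not a candidate
  mags$phylum[mags$mag_id == "M2"] <- ""
  mags$phylum[mags$mag_id == "M3"] <- ""
  net2 <- build_network(m, mags, virals, "t")
  ph2 <- find_cross_taxon(net2, "phylum")
  expect_equal(ph2$status[ph2$viral_id == "V1"], "unrankable")
})

test_that("curation verdicts combine quality, sharing, and taxonomy checks", {
  mags <- rbind(mk_mags("M1", phylum = "Firmicutes"),
                mk_mags("M2", phylum = "Patescibacteria"),
                mk_mags("M3", phylum = "Muirbacteria",
                        completeness = 60))  # fails quality
  virals <- mk_virals(c("V1", "V2"))
  withr::with_seed(62, {
    shared <- vapply(1:56, function(i) rnd_dna(32), "")
    arr1 <- mk_array("a1", "s1", shared)
    arr2 <- mk_array("a2", "s2", c(shared[1:56], rnd_dna(33)))
    arr3 <- mk_array("a3", "s3", replicate(3, rnd_dna(30)))
  })
  scaffolds <- data.frame(id = c("s1", "s2", "s3"),
                          seq = vapply(c(15000, 9000, 12000), rnd_dna, ""),
                          mag_id = c("M1", "M2", "M3"),
                          stringsAsFactors = FALSE)
  m <- rbind(mk_match("M1", "V1", 1, "a1:0"),
             mk_match("M2", "V1", 50, "a2:0"),
             mk_match("M1", "V2", 1, "a1:1"),
             mk_match("M3", "V2", 50, "a3:0"))
  net <- build_network(m, mags, virals, "t")
  cand <- find_cross_taxon(net, "phylum")
  cur <- curate_cross_taxon(cand, mags, m, list(arr1, arr2, arr3),
                            scaffolds)
  v1 <- cur[cur$viral_id == "V1", ]
  expect_equal(v1$verdict, "pass")
  expect_equal(v1$shared_spacers, 56L)
  expect_true(v1$possible_hgt)
  expect_true(v1$scaffold_length_flag)   # s2 is below the 10 kb floor
  v2 <- cur[cur$viral_id == "V2", ]
  expect_equal(v2$verdict, "fail")       # M3 fails the quality gate
  expect_match(v2$reasons, "quality")
  # incongruent scaffold taxonomy fails an otherwise passing candidate
  tax <- data.frame(scaffold_id = "s1", phylum = "Bacteroidota",
                    stringsAsFactors = FALSE)
  cur2 <- curate_cross_taxon(cand, mags, m, list(arr1, arr2, arr3),
                             scaffolds, scaffold_taxonomy = tax)
  expect_equal(cur2$verdict[cur2$viral_id == "V1"], "fail")
  expect_false(cur2$taxonomy_congruent[cur2$viral_id == "V1"])
})
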