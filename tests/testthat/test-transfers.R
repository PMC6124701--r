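test_that("transfer classes follow the genome roles", {
  set.seed(51)
  pl <- genome("p", random_seq(2000), "circular", "plastome")
  mt <- genome("m", paste0(random_seq(500), substr(pl$seq, 101, 400),
                           random_seq(1200)), "circular", "mitogenome")
  calls <- call_transfers(pl, mt)
  expect_identical(unique(calls$klass), "MTPT")
  nuc <- genome("n", random_seq(3000), "linear", "nuclear_chromosome")
  expect_identical(nrow(call_transfers(pl, nuc)), 0L)
  expect_error(call_transfers(nuc, pl), "no transfer class")
})

test_that("no calls arise between unrelated random sequences", {
  set.seed(52)
  org <- genome("m", random_seq(50000), "circular", "mitogenome")
  for (i in 1:5) {
    host <- genome(paste0("c", i), random_seq(50000), "linear",
                   "nuclear_chromosome")
    expect_identical(nrow(call_transfers(org, host)), 0L)
  }
})

test_that("repeat-induced multiple hits collapse to the best call", {
  set.seed(53)
  rep_seq <- random_seq(800)
  org <- genome("m", paste0(random_seq(1000), rep_seq, random_seq(900),
                            rep_seq, random_seq(1100)),
                "linear", "mitogenome")
  host <- genome("c1", paste0(random_seq(1500), rep_seq, random_seq(1500)),
                 "linear", "nuclear_chromosome")
  raw <- call_transfers(org, host)
  expect_identical(nrow(raw), 2L)
  reps <- find_exact_repeats(org, 100)
  ded <- dedup_repeat_hits(raw, reps)
  expect_identical(nrow(ded), 1L)
  expect_true(ded$deduped)
  # idempotence
  expect_identical(dedup_repeat_hits(ded, reps), ded)
  # without repeats the calls pass through unchanged
  expect_identical(dedup_repeat_hits(raw, reps[0, ]), raw)
})

test_that("a three-copy family leaves one surviving call per locus", {
  set.seed(54)
  rep_seq <- random_seq(600)
  org <- genome("m", paste0(random_seq(700), rep_seq, random_seq(800),
                            rep_seq, random_seq(900), rep_seq,
                            random_seq(600)), "linear", "mitogenome")
  host <- genome("c1", paste0(random_seq(1000), rep_seq, random_seq(2000),
                              rep_seq, random_seq(800)),
                 "linear", "nuclear_chromosome")
  raw <- call_transfers(org, host)
  expect_identical(nrow(raw), 6L) # 2 nuclear loci x 3 source copies
  ded <- dedup_repeat_hits(raw, find_exact_repeats(org, 100))
  expect_identical(nrow(ded), 2L)
})

test_that("compartment attribution projects the IRs onto one copy", {
  set.seed(55)
  cfg <- sim_config(seed = 55, plastome_len = 20000, ir_len = 4000,
                    ssc_len = 2000, mito_len = 30000, repeat_spec = list(),
                    mtpt_spec = list(list(len = 1000, compartment = "IR"),
                                     list(len = 200, compartment = "SSC")))
  pl <- simulate_plastome(cfg)
  m <- simulate_mitogenome(cfg, pl)
  calls <- call_transfers(pl$genome, m$genome)
  att <- attribute_compartment(calls, pl$structure,
                               host_len = nchar(m$genome$seq))
  # the IR implant hits both IRa and IRb but is counted once
  expect_identical(unname(att$totals["IR"]), 1000)
  expect_identical(unname(att$totals["SSC"]), 200)
  expect_identical(unname(att$totals["LSC"]), 0)
  expect_identical(unname(att$totals["total"]), 1200)
  expect_identical(att$calls$compartment[att$calls$sstart >=
                                           pl$structure$ssc$start &
                                           att$calls$send <=
                                           pl$structure$ssc$end], "SSC")
  expect_warning(res <- attribute_compartment(calls, NULL), "missing")
  expect_true(all(is.na(res$totals)))
})

test_that("chromosome summaries match direct recomputation", {
  hosts <- list(genome("c1", strrep("A", 10000), role = "nuclear_chromosome"))
  calls <- data.frame(klass = "NUMT", chrom = "c1",
                      tstart = c(100L, 500L, 2000L),
                      tend = c(136L, 600L, 2300L),
                      source_id = "m", sstart = 0L, send = 1L, strand = "+",
                      length = c(36L, 100L, 300L), identity = 1,
                      evalue = 0, score = 1, deduped = FALSE,
                      compartment = NA_character_)
  s <- summarize_by_chromosome(calls, hosts, sub_threshold = 250)
  row <- s[s$chrom_id == "c1", ]
  expect_equal(unname(row$n), 3)
  expect_equal(unname(row$n_ge_threshold), 1)
  expect_equal(unname(row$median_len), 100)
  expect_equal(unname(row$cumulative_bp), 436)
  expect_equal(unname(row$pct_of_chromosome), 4.36)
  expect_equal(unname(row$min_len), 36)
  expect_equal(unname(row$max_len), 300)

  empty <- summarize_by_chromosome(calls[0, ], hosts)
  expect_equal(unname(empty$n[1]), 0)
  expect_equal(unname(empty$cumulative_bp[1]), 0)

  # 1,000 random calls against an independent pass
  set.seed(56)
  hosts2 <- list(genome("c1", strrep("A", 50000), role = "nuclear_chromosome"),
                 genome("c2", strrep("A", 50000), role = "nuclear_chromosome"))
  n <- 1000L
  st <- sample(0:49000, n, replace = TRUE)
  len <- sample(36:2000, n, replace = TRUE)
  rc <- data.frame(klass = "NUMT", chrom = sample(c("c1", "c2"), n, TRUE),
                   tstart = st, tend = pmin(st + len, 50000L),
                   source_id = "m", sstart = 0L, send = 1L, strand = "+",
                   length = NA, identity = 1, evalue = 0, score = 1,
                   deduped = FALSE, compartment = NA_character_)
  rc$length <- rc$tend - rc$tstart
  s2 <- summarize_by_chromosome(rc, hosts2, sub_threshold = 250)
  for (ch in c("c1", "c2")) {
    lens <- rc$length[rc$chrom == ch]
    row <- s2[s2$chrom_id == ch, ]
    expect_equal(unname(row$n), length(lens))
    expect_equal(unname(row$mean_len), mean(lens))
    expect_equal(unname(row$median_len), median(lens))
    expect_equal(unname(row$n_ge_threshold), sum(lens >= 250))
    expect_equal(unname(row$cumulative_bp),
                 oracle_union_length(rc$tstart[rc$chrom == ch],
                                     rc$tend[rc$chrom == ch], 50000L))
    expect_lte(row$cumulative_bp, 50000L)
  }
  roll <- s2[s2$chrom_id == "genome", ]
  expect_identical(unname(roll$cumulative_bp),
                   sum(s2$cumulative_bp[s2$chrom_id != "genome"]))
})

test_that("large-fragment clustering applies the gap and size rules", {
  mk <- function(st, en, chrom = "c1") {
    data.frame(klass = "NUMT", chrom = chrom, tstart = st, tend = en,
               source_id = "m", sstart = 0L, send = 1L, strand = "+",
               length = en - st, identity = 1, evalue = 0, score = 1,
               deduped = FALSE, compartment = NA_character_)
  }
  two <- rbind(mk(1000L, 3000L), mk(13000L, 15000L))
  cl <- cluster_large_fragments(two, min_large_len = 1000,
                                max_gap = 100000)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 2L)
  expect_identical(cl$total_bp, 4000L)
  cl2 <- cluster_large_fragments(two, min_large_len = 1000, max_gap = 5000)
  expect_identical(nrow(cl2), 0L)
  # small fragments never seed clusters
  small <- rbind(mk(1000L, 1500L), mk(1600L, 2100L))
  expect_identical(nrow(cluster_large_fragments(small, 1000)), 0L)
})

test_that("dot-matrix reports fragment structure and mosaic status", {
  set.seed(57)
  org <- genome("org", random_seq(30000), "circular", "mitogenome")
  verbatim <- genome("r1", substr(org$seq, 5001, 9000))
  d1 <- dotmatrix_report(verbatim, org)
  expect_identical(nrow(d1$fragments), 1L)
  expect_false(d1$mosaic)
  expect_identical(d1$fragments$identity_pct, 100)

  stitched <- genome("r2", paste0(substr(org$seq, 1001, 3000),
                                  substr(org$seq, 20001, 22000)))
  expect_true(dotmatrix_report(stitched, org)$mosaic)

  inv <- genome("r3", paste0(substr(org$seq, 5001, 6500),
                             revcomp(substr(org$seq, 6501, 8000)),
                             substr(org$seq, 8001, 9500)))
  d3 <- dotmatrix_report(inv, org)
  expect_identical(nrow(d3$fragments), 3L)
  expect_identical(d3$fragments$orientation, c("+", "-", "+"))
  expect_true(d3$mosaic) # mixed orientations
})
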