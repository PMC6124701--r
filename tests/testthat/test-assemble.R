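test_that("baiting keeps k-mer-sharing pairs as a unit", {
  set.seed(21)
  bait <- genome("bait", random_seq(2000), role = "mitogenome")
  hit <- substr(bait$seq, 501, 600)
  miss <- random_seq(100)
  reads <- structure(list(r1 = c(hit, miss, miss),
                          r2 = c(miss, revcomp(hit), miss),
                          origins = NULL), class = "read_set")
  kept <- bait_reads(reads, bait, assembly_params())
  # pairs 1 and 2 each share a mate with the bait; pair 3 does not
  expect_identical(length(kept$r1), 2L)
  expect_identical(kept$r1[1], hit)
  expect_identical(kept$r2[2], revcomp(hit))
  expect_error(bait_reads(reads, bait, assembly_params(bait_k = 31,
                                                       assembly_k = 63,
                                                       min_overlap = 50)),
               NA)
  short <- structure(list(r1 = "ACGTACGT", r2 = "ACGTACGT", origins = NULL),
                     class = "read_set")
  expect_error(bait_reads(short, bait), "exceeds read length")
})

test_that("contig building yields unbranched zero-mismatch unitigs", {
  set.seed(22)
  # a single read becomes a single contig
  r <- random_seq(100)
  ct <- build_contigs(r, assembly_params())
  expect_length(ct, 1)
  expect_true(ct[[1]]$seq %in% c(r, revcomp(r)))
  expect_identical(length(ct[[1]]$support), nchar(ct[[1]]$seq))
  expect_gte(min(ct[[1]]$support), 1L)

  # error-free reads tiling a linear 5 kb sequence reconstruct it
  s <- random_seq(5000)
  starts <- seq(1, 4901, by = 2)
  reads <- substring(s, starts, starts + 99)
  ct <- build_contigs(reads, assembly_params())
  expect_length(ct, 1)
  expect_true(ct[[1]]$seq %in% c(s, revcomp(s)))

  # reads from two disjoint sequences give no chimeric contig
  s2 <- random_seq(5000)
  reads2 <- substring(s2, starts, starts + 99)
  ct2 <- build_contigs(c(reads, reads2), assembly_params())
  expect_gte(length(ct2), 2)
  for (x in ct2) {
    expect_true(grepl(x$seq, s, fixed = TRUE) ||
                  grepl(revcomp(x$seq), s, fixed = TRUE) ||
                  grepl(x$seq, s2, fixed = TRUE) ||
                  grepl(revcomp(x$seq), s2, fixed = TRUE))
  }
  expect_error(build_contigs("ACGTACGT", assembly_params()),
               "smaller k")
})

test_that("iterative extension closes a gapped circle and is monotone", {
  cfg <- sim_config(seed = 23, mito_len = 12000, depth = 60,
                    repeat_spec = list(), mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  reads <- simulate_reads(m$genome, cfg)
  params <- assembly_params(min_depth_qc = 50)
  s <- m$genome$seq
  c1 <- orgEGT:::new_contig(substr(s, 1, 7000), rep(1, 7000))
  c2 <- orgEGT:::new_contig(substr(s, 7201, 12000), rep(1, 4800))
  ext <- extend_iterate(list(c1, c2), reads, params)
  expect_length(ext, 1)
  expect_gte(nchar(ext[[1]]$seq), 11800L)
  circ <- circularize(ext[[1]], params)
  expect_true(circ$closed)
  expect_identical(circ$genome$seq, canonical_rotation(s))

  # an empty read set leaves the contigs untouched
  expect_identical(extend_iterate(list(c1, c2), character(0), params),
                   list(c1, c2))
})

test_that("circularization trims a constructed terminal overlap", {
  set.seed(24)
  s <- random_seq(3000)
  contig <- orgEGT:::new_contig(paste0(s, substr(s, 1, 80)), rep(1, 3080))
  circ <- circularize(contig, assembly_params())
  expect_true(circ$closed)
  expect_identical(circ$overlap, 80L)
  expect_identical(nchar(circ$genome$seq), 3000L)
  expect_identical(circ$genome$topology, "circular")
  expect_identical(circ$genome$seq, canonical_rotation(s))

  open_contig <- orgEGT:::new_contig(random_seq(3000), rep(1, 3000))
  circ2 <- circularize(open_contig, assembly_params())
  expect_false(circ2$closed)
  expect_identical(circ2$genome$topology, "linear")
})

test_that("coverage profile flags low depth and handles empty read sets", {
  # mean depth well above the QC floor, so sampling noise cannot dip under
  cfg <- sim_config(seed = 25, mito_len = 10000, depth = 400,
                    repeat_spec = list(), mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  reads <- simulate_reads(m$genome, cfg)
  prof <- coverage_profile(m$genome, reads, assembly_params())
  expect_identical(sum(prof$flags$flag == "low"), 0L)
  expect_gt(prof$median, 200)

  expect_warning(prof0 <- coverage_profile(m$genome, character(0),
                                           assembly_params()),
                 "empty read set")
  expect_identical(prof0$flags$flag, "low")
  expect_identical(prof0$median, 0)
})

test_that("zero-mismatch mapping excludes diverged-copy reads", {
  cfg <- sim_config(seed = 26, mito_len = 8000, depth = 30,
                    repeat_spec = list(), mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  clean <- simulate_reads(m$genome, cfg)
  mut <- genome("mut", orgEGT:::mutate_fragment(m$genome$seq, 0.05)$seq)
  noisy <- simulate_reads(mut, cfg)
  mixed <- structure(list(r1 = c(clean$r1, noisy$r1),
                          r2 = c(clean$r2, noisy$r2), origins = NULL),
                     class = "read_set")
  mapped <- map_reads_exact(mixed, m$genome, assembly_params())
  n_clean <- length(clean$r1)
  expect_identical(length(mapped$r1) >= n_clean, TRUE)
  # most diverged pairs fail zero-mismatch mapping
  expect_lt(length(mapped$r1) - n_clean, 0.2 * length(noisy$r1))
})

test_that("bait-build-extend-circularize recovers a repeat-bearing circle", {
  cfg <- sim_config(seed = 27, mito_len = 30000, depth = 200,
                    repeat_spec = list(list(len = 3000, orientation = "direct",
                                            copies = 2)),
                    mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  reads <- simulate_reads(m$genome, cfg)
  asm <- assemble_genome(reads, m$genome, assembly_params())
  expect_true(asm$closed)
  expect_identical(asm$genome$seq, canonical_rotation(m$genome$seq))
  # no-mismatch guarantee: the assembled circle is read-supported everywhere
  prof <- coverage_profile(asm$genome, reads, assembly_params())
  expect_true(all(prof$depth >= 1))
})
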