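test_that("plastome geometry and determinism hold", {
  cfg <- sim_config(seed = 2, plastome_len = 15000, ir_len = 2000,
                    ssc_len = 1500)
  pl <- simulate_plastome(cfg)
  expect_identical(nchar(pl$genome$seq), 15000L)
  expect_identical(pl$structure$lsc$end - pl$structure$lsc$start, 9500L)
  ira <- substr(pl$genome$seq, pl$structure$ira$start + 1, pl$structure$ira$end)
  irb <- substr(pl$genome$seq, pl$structure$irb$start + 1, pl$structure$irb$end)
  expect_identical(revcomp(ira), irb)
  pl2 <- simulate_plastome(cfg)
  expect_identical(pl2$genome$seq, pl$genome$seq)
  expect_error(sim_config(plastome_len = 5000, ir_len = 2000, ssc_len = 1500),
               "geometry")
})

test_that("mitogenome implants are exhaustive in the event log", {
  cfg <- sim_config(seed = 3, mito_len = 20000,
                    repeat_spec = list(list(len = 800, orientation = "direct",
                                            copies = 2)),
                    mtpt_spec = list(list(len = 400, compartment = "LSC")))
  pl <- simulate_plastome(cfg)
  m <- simulate_mitogenome(cfg, pl)
  expect_identical(nchar(m$genome$seq), 20000L)
  expect_identical(nrow(m$truth), 2L)
  # conservation: every base changed from the pre-implant background lies
  # inside a logged target interval (extended by the breakpoint window)
  set.seed(cfg$seed + 102L)
  bg <- random_seq(20000, cfg$gc)
  a <- charToRaw(bg); b <- charToRaw(m$genome$seq)
  diffs <- which(a != b) - 1L
  W <- orgEGT:::BREAKPOINT_WINDOW
  allowed <- rep(FALSE, 20000)
  for (i in seq_len(nrow(m$truth))) {
    lo <- max(0L, m$truth$target_start[i] - W)
    hi <- min(20000L, m$truth$target_end[i] + W)
    allowed[(lo + 1L):hi] <- TRUE
  }
  expect_true(all(allowed[diffs + 1L]))
})

test_that("an implant-free random mitogenome carries no repeats >= 100 bp", {
  cfg <- sim_config(seed = 4, mito_len = 15000, repeat_spec = list(),
                    mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  expect_identical(nrow(find_exact_repeats(m$genome, 100)), 0L)
})

test_that("read simulation honors depth, exactness and determinism", {
  cfg <- sim_config(seed = 5, mito_len = 40000, depth = 200,
                    repeat_spec = list(), mtpt_spec = list(), error_rate = 0)
  m <- simulate_mitogenome(cfg)
  reads <- simulate_reads(m$genome, cfg)
  bases <- sum(nchar(reads$r1)) + sum(nchar(reads$r2))
  expect_lt(abs(bases - 200 * 40000) / (200 * 40000), 0.02)
  # error-free reads are exact substrings of the genome or its revcomp
  doubled <- paste0(m$genome$seq, m$genome$seq)
  idx <- sample(length(reads$r1), 200)
  for (r in c(reads$r1[idx], reads$r2[idx])) {
    expect_true(grepl(r, doubled, fixed = TRUE) ||
                  grepl(revcomp(r), doubled, fixed = TRUE))
  }
  reads2 <- simulate_reads(m$genome, cfg)
  expect_identical(reads2$r1, reads$r1)
  expect_identical(reads2$r2, reads$r2)
})

test_that("FASTQ output round-trips and is byte-stable under the seed", {
  cfg <- sim_config(seed = 6, mito_len = 5000, depth = 10,
                    repeat_spec = list(), mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  reads <- simulate_reads(m$genome, cfg)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_reads(reads, p1)
  write_reads(simulate_reads(m$genome, cfg), p2)
  expect_identical(readLines(paste0(p1, "_1.fastq")),
                   readLines(paste0(p2, "_1.fastq")))
  back <- read_reads(paste0(p1, "_1.fastq"), paste0(p1, "_2.fastq"))
  expect_identical(back$r1, reads$r1)
  expect_identical(back$r2, reads$r2)
})

test_that("plastome-weighted mixtures over-represent MTPT regions in depth", {
  cfg <- sim_config(seed = 8, depth = 100)
  pl <- simulate_plastome(cfg)
  m <- simulate_mitogenome(cfg, pl)
  qc <- simulate_reads(list(m$genome, pl$genome), cfg, weights = c(1, 10))
  prof <- coverage_profile(m$genome, qc, assembly_params(min_depth_qc = 50))
  mt <- m$truth[m$truth$class == "MTPT" &
                  (m$truth$target_end - m$truth$target_start) >= 100, ]
  in_mtpt <- unlist(lapply(seq_len(nrow(mt)), function(i) {
    (mt$target_start[i] + 1L):mt$target_end[i]
  }))
  expect_gte(mean(prof$depth[in_mtpt]), 5 * mean(prof$depth[-in_mtpt]))
})

test_that("nuclear implants at zero divergence are recovered verbatim", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_len = 30000,
                    repeat_spec = list(), mtpt_spec = list(),
                    numt_spec = list(list(len = 3000, count = 1,
                                          divergence = 0, clustered = FALSE)),
                    nupt_spec = list())
  pl <- simulate_plastome(cfg)
  m <- simulate_mitogenome(cfg, pl)
  nuc <- simulate_nuclear(cfg, m, pl)
  calls <- call_transfers(m$genome, nuc$genomes)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$length, 3000L)
  expect_identical(calls$identity, 1)
  ev <- nuc$truth[nuc$truth$class == "NUMT", ]
  expect_identical(calls$tstart, ev$target_start)
  expect_identical(calls$tend, ev$target_end)
})

test_that("clustered implant groups form a single cluster per chromosome", {
  cfg <- sim_config(seed = 10, n_chromosomes = 1, chrom_len = 80000,
                    numt_spec = list(),
                    nupt_spec = list(list(len = 1200, count = 10,
                                          divergence = 0, clustered = TRUE)))
  pl <- simulate_plastome(cfg)
  m <- simulate_mitogenome(cfg, pl)
  nuc <- simulate_nuclear(cfg, m, pl)
  calls <- call_transfers(pl$genome, nuc$genomes)
  calls <- dedup_repeat_hits(calls, find_exact_repeats(pl$genome))
  cl <- cluster_large_fragments(calls, min_large_len = 1000)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 10L)
})

test_that("divergence produces identities within the binomial band", {
  cfg <- sim_config(seed = 11, n_chromosomes = 1, chrom_len = 30000,
                    repeat_spec = list(), mtpt_spec = list(),
                    numt_spec = list(list(len = 3000, count = 3,
                                          divergence = 0.05,
                                          clustered = FALSE)),
                    nupt_spec = list())
  pl <- simulate_plastome(cfg)
  m <- simulate_mitogenome(cfg, pl)
  nuc <- simulate_nuclear(cfg, m, pl)
  calls <- call_transfers(m$genome, nuc$genomes)
  expect_gte(nrow(calls), 3L)
  big <- calls[calls$length >= 2000, ]
  expect_true(all(big$identity > 0.90 & big$identity < 0.98))
  expect_gt(mean(big$identity), 0.93)
  expect_lt(mean(big$identity), 0.97)
})
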