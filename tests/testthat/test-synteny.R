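test_that("an internal inversion yields three blocks with the middle flipped", {
  set.seed(61)
  L <- 10000
  gA <- genome("A", random_seq(L), role = "mitogenome")
  gB <- genome("B", paste0(substr(gA$seq, 1, 3500),
                           revcomp(substr(gA$seq, 3501, 6500)),
                           substr(gA$seq, 6501, L)), role = "mitogenome")
  annot <- feature_table("A", c(1000, 4500, 8000), c(1900, 5400, 8900),
                         name = c("g1", "g2", "g3"))
  bl <- find_synteny_blocks(gA, gB, annot)
  expect_identical(nrow(bl), 3L)
  expect_identical(bl$orientation, c("same", "inverted", "same"))
  expect_identical(bl$genes, c("g1", "g2", "g3"))
  # blocks are non-overlapping on gA
  expect_true(all(bl$a_start[-1] >= bl$a_end[-nrow(bl)]))

  # a genome against itself gives one whole-length block
  self <- find_synteny_blocks(gA, gA, annot)
  expect_identical(nrow(self), 1L)
  expect_identical(self$orientation, "same")
  expect_gte(self$length, L - 10L)

  # random subject gives nothing; missing annotation errors
  expect_identical(nrow(find_synteny_blocks(gA, genome("R", random_seq(L)),
                                            annot)), 0L)
  expect_error(find_synteny_blocks(gA, gB, NULL), "annotation")
})

test_that("gene and length filters prune blocks", {
  set.seed(62)
  L <- 8000
  gA <- genome("A", random_seq(L), role = "mitogenome")
  # annotation covering only the first half
  annot <- feature_table("A", 500, 1400, name = "g1")
  gB <- genome("B", paste0(substr(gA$seq, 1, 4000), random_seq(4000)),
               role = "mitogenome")
  bl <- find_synteny_blocks(gA, gB, annot)
  expect_identical(nrow(bl), 1L)
  # without the gene requirement the geneless shared block would still fail
  # only if shorter than min_block_len
  p <- synteny_params(require_gene = FALSE, min_block_len = 6000)
  expect_identical(nrow(find_synteny_blocks(gA, gB, annot, p)), 0L)
})

test_that("conserved-region classes partition each genome exactly", {
  set.seed(63)
  s <- random_seq(6000)
  three_same <- lapply(c("x", "y", "z"), function(id) {
    genome(id, s, role = "mitogenome")
  })
  cf <- conserved_fraction(three_same)
  expect_true(all(cf$with_both == 6000))
  expect_true(all(cf$unique_len == 0))

  a <- random_seq(6000)
  cf2 <- conserved_fraction(list(genome("a", a, role = "mitogenome"),
                                 genome("b", a, role = "mitogenome"),
                                 genome("c", random_seq(6000),
                                        role = "mitogenome")))
  expect_identical(cf2$with_both[1], 0L)
  expect_identical(cf2$only_with_len[1], 6000L)
  expect_identical(cf2$unique_len[3], 6000L)

  # simulated trio: classes always sum to genome length
  core <- random_seq(15000)
  trio <- list(genome("g1", paste0(core, random_seq(2000)), role = "mitogenome"),
               genome("g2", paste0(core, random_seq(2000)), role = "mitogenome"),
               genome("g3", paste0(core, random_seq(2000)), role = "mitogenome"))
  cf3 <- conserved_fraction(trio)
  expect_identical(cf3$with_both + cf3$only_with_len + cf3$only_with2_len +
                     cf3$unique_len, cf3$total_len)
  expect_true(all(abs(cf3$with_both - 15000) <= 200))
  expect_true(all(abs(cf3$unique_len - 2000) <= 200))
})

test_that("ribbon bins follow the score ratio convention", {
  set.seed(64)
  gA <- genome("A", random_seq(9000), role = "mitogenome")
  # three shared segments of very different lengths -> different ratios
  gB <- genome("B", paste0(substr(gA$seq, 1, 4000), random_seq(700),
                           substr(gA$seq, 5001, 5800), random_seq(800),
                           substr(gA$seq, 7001, 7500)),
               role = "mitogenome")
  rb <- ribbon_map(gA, gB)
  expect_identical(nrow(rb), 3L)
  expect_equal(max(rb$ratio), 1)
  expect_identical(rb$bin[which.max(rb$score)], ">0.75")
  expect_equal(rb$ratio, rb$score / max(rb$score))
  expect_identical(rb$bin[rb$ratio <= 0.25], rep("<=0.25", sum(rb$ratio <= 0.25)))
  # scores 4000, 800, 500 -> bins >0.75, <=0.25, <=0.25
  expect_identical(sort(rb$bin), c("<=0.25", "<=0.25", ">0.75"))

  empty <- ribbon_map(gA, genome("R", random_seq(9000), role = "mitogenome"))
  expect_identical(nrow(empty), 0L)
})

test_that("ORF finding matches the codon-walk oracle and the length rules", {
  # ATG + 100 sense codons + TAA = 306 bp
  set.seed(65)
  body <- paste(rep("GCT", 100), collapse = "")
  g <- genome("o", paste0(random_seq(50), "ATG", body, "TAA", random_seq(47)))
  o <- find_orfs(g, 303)
  expect_true(any(o$start == 50 & o$end == 356 & o$strand == "+"))
  expect_true(all((o$end - o$start) %% 3 == 0))

  # 300 bp total stays below the threshold
  short <- genome("o2", paste0(random_seq(50), "ATG",
                               paste(rep("GCT", 98), collapse = ""), "TAA",
                               random_seq(47)))
  expect_false(any((find_orfs(short, 303)$end -
                      find_orfs(short, 303)$start) == 300))

  # random sequences: full agreement with the brute-force oracle
  for (trial in 1:5) {
    s <- random_seq(3000)
    got <- find_orfs(genome(paste0("r", trial), s), min_len = 150)
    exp <- oracle_orfs(s, min_len = 150)
    got_kn <- got[order(got$start, got$end, got$strand),
                  c("start", "end", "strand")]
    rownames(got_kn) <- NULL
    expect_equal(got_kn, exp, ignore_attr = TRUE)
  }
})

test_that("circular ORFs wrap across the origin once", {
  set.seed(66)
  body <- paste(rep("GAT", 120), collapse = "")
  orf <- paste0("ATG", body, "TAG") # 366 bp
  s <- paste0(substr(orf, 101, 366), random_seq(600), substr(orf, 1, 100))
  g <- genome("c", s, topology = "circular")
  o <- find_orfs(g, 300)
  wrapped <- o[o$end > nchar(s), ]
  expect_true(any(wrapped$end - wrapped$start == 366L &
                    wrapped$start == nchar(s) - 100L))
})

test_that("gene presence matrix classifies copy numbers", {
  a1 <- feature_table("m1", c(0, 100, 200), c(90, 190, 290),
                      name = c("rrn5", "rrn5", "cox1"))
  a2 <- feature_table("m2", c(0, 100, 200), c(90, 190, 290),
                      kind = c("gene", "ORF", "ORF"),
                      name = c("cox1", "orf22", "orf22"))
  m <- gene_presence_matrix(list(m1 = a1, m2 = a2))
  expect_identical(m["rrn5", "m1"], "duplicated")
  expect_identical(m["rrn5", "m2"], "absent")
  expect_identical(m["cox1", "m2"], "single")
  expect_identical(m["orf22", "m2"], "duplicated")
  counts <- attr(m, "counts")
  expect_identical(counts["rrn5", "m1"], 2L)
  # duplicated ORFs are excluded from the per-genome duplicated-gene count
  dc <- attr(m, "duplicated_counts")
  expect_identical(unname(dc["m1"]), 1L)
  expect_identical(unname(dc["m2"]), 0L)
})
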