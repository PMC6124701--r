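test_that("planted repeats are found with exact coordinates", {
  set.seed(41)
  x <- random_seq(500)
  g <- genome("t", paste0(random_seq(1000), x, random_seq(800), x,
                          random_seq(700)))
  r <- find_exact_repeats(g, 100)
  expect_identical(nrow(r), 1L)
  expect_identical(r$orientation, "direct")
  expect_identical(c(r$a_start, r$a_end, r$b_start, r$b_end),
                   c(1000L, 1500L, 2300L, 2800L))

  # sentinel flanks (C/G around copy one, T/A around copy two) block any
  # chance extension so the planted length is exact
  y <- random_seq(300)
  g2 <- genome("t2", paste0(random_seq(900), "C", y, "G", random_seq(600),
                            "T", revcomp(y), "A", random_seq(500)))
  r2 <- find_exact_repeats(g2, 100)
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$orientation, "inverted")
  expect_identical(r2$length, 300L)
  expect_identical(c(r2$a_start, r2$b_start), c(901L, 1803L))

  expect_identical(nrow(find_exact_repeats(genome("r", random_seq(10000)),
                                           100)), 0L)
  expect_error(find_exact_repeats(g, 1), "min_len")
})

test_that("repeat finding matches the offset-scan oracle on planted genomes", {
  set.seed(42)
  for (trial in 1:20) {
    s <- plant_repeats(sample(800:1500, 1), n_repeats = sample(1:3, 1))
    got <- find_exact_repeats(genome("g", s), 100)
    got <- got[, c("a_start", "a_end", "b_start", "b_end", "orientation")]
    rownames(got) <- NULL
    expect_equal(got, oracle_repeats(s, 100), ignore_attr = TRUE)
  }
})

test_that("circular genomes recover planted repeats across the doubling", {
  cfg <- sim_config(seed = 43, mito_len = 20000,
                    repeat_spec = list(
                      list(len = 600, orientation = "direct", copies = 2),
                      list(len = 250, orientation = "inverted", copies = 2)),
                    mtpt_spec = list())
  m <- simulate_mitogenome(cfg)
  r <- find_exact_repeats(m$genome, 100)
  tr <- m$truth[m$truth$class == "repeat", ]
  expect_identical(nrow(r), 2L)
  for (i in seq_len(nrow(tr))) {
    members <- c(paste(r$a_start, r$a_end), paste(r$b_start, r$b_end))
    expect_true(paste(tr$source_start[i], tr$source_end[i]) %in% members)
    expect_true(paste(tr$target_start[i], tr$target_end[i]) %in% members)
  }
})

test_that("duplication statistics use interval union and pair maxima", {
  set.seed(44)
  x <- random_seq(500)
  g <- genome("t", paste0(random_seq(1000), x, random_seq(800), x,
                          random_seq(700)))
  r <- find_exact_repeats(g, 100)
  d <- duplicated_length(r, g)
  expect_identical(d$total_dup_len, 1000L)
  expect_identical(d$max_dup_len, 500L)
  expect_identical(d$sum_pair_len, 1000L)

  d0 <- duplicated_length(r[0, ], g)
  expect_identical(d0$total_dup_len, 0L)
  expect_identical(d0$max_dup_len, 0L)

  # overlapping/nested members: union equals the bit-vector oracle, and the
  # result is invariant under row order
  fake <- data.frame(seq_id = "t", a_start = c(100L, 150L, 400L),
                     a_end = c(300L, 350L, 600L),
                     b_start = c(1000L, 1100L, 2000L),
                     b_end = c(1200L, 1300L, 2200L),
                     orientation = "direct", length = c(200L, 200L, 200L))
  d1 <- duplicated_length(fake, g)
  exp_union <- oracle_union_length(c(fake$a_start, fake$b_start),
                                   c(fake$a_end, fake$b_end), nchar(g$seq))
  expect_identical(d1$total_dup_len, exp_union)
  d2 <- duplicated_length(fake[c(3, 1, 2), ], g)
  expect_identical(d1$total_dup_len, d2$total_dup_len)
})

test_that("duplication correlations reproduce the hand formula", {
  tab <- data.frame(total_len = c(10, 20, 30, 40),
                    total_dup_len = c(2, 4, 6, 9),
                    max_dup_len = c(1, 3, 2, 5))
  res <- dup_correlations(tab)
  hand_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(res$total_vs_genome$r, hand_r(tab$total_dup_len, tab$total_len))
  expect_equal(res$total_vs_max$r, hand_r(tab$total_dup_len, tab$max_dup_len))
  expect_equal(res$total_vs_genome$r_squared, res$total_vs_genome$r^2)

  exact <- data.frame(total_len = 1:5 * 2, total_dup_len = 1:5,
                      max_dup_len = c(1, 2, 3, 4, 6))
  res2 <- dup_correlations(exact)
  expect_equal(res2$total_vs_genome$r, 1)
  expect_equal(res2$total_vs_genome$r_squared, 1)

  flat <- data.frame(total_len = c(1, 2, 3), total_dup_len = c(2, 2, 2),
                     max_dup_len = c(1, 2, 3))
  expect_error(dup_correlations(flat), "zero variance")
  expect_error(dup_correlations(tab[1:2, ]), "at least 3")
})
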