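# Exact duplicated-region detection and duplication statistics.
#
# Duplicated regions are maximal exact repeated pairs (zero mismatches),
# both orientations, with a 100 bp default minimum. "Length of duplicated
# regions" is reported as the union of all repeat-member intervals (each
# genomic position counted once) -- the only convention that cannot
# double-count overlapping families; the sum of pair lengths is also
# emitted for comparison with conventions that count both copies.

#' Find maximal exact repeats within one genome
#'
#' All maximal exact repeated pairs of at least `min_len` bp, direct and
#' inverted, zero mismatches. Maximality is per relative offset: no
#' reported pair can be extended on either side. Circular genomes are
#' handled by doubling the sequence and deduplicating wrapped pairs.
#'
#' @param genome A `genome` (or DNA string, treated as linear).
#' @param min_len Minimum repeat length (>= 2).
#' @return A `data.frame` with columns `seq_id`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `orientation`, `length`; member `a` precedes
#'   member `b` in canonical order.
#' @export
find_exact_repeats <- function(genome, min_len = 100L) {
  g <- as_genome(genome)
  if (min_len < 2L) stop("min_len must be >= 2")
  n <- nchar(g$seq)
  if (n < min_len) stop("genome shorter than min_len")
  circular <- g$topology == "circular"
  s <- if (circular) paste0(g$seq, g$seq) else g$seq
  d <- cpp_exact_repeats(s, as.integer(min_len))
  if (circular && nrow(d)) {
    d <- d[d$a_start < n & (d$b_start - d$a_start) != n, , drop = FALSE]
    len <- d$a_end - d$a_start
    over <- len > n
    if (any(over)) { # repeat wraps the whole circle; cap at genome length
      d$a_end[over] <- d$a_start[over] + n
      d$b_end[over] <- d$b_start[over] + n
      len <- d$a_end - d$a_start
    }
    d$b_start <- d$b_start %% n
    d$b_end <- d$b_start + len
    swap <- (d$b_start < d$a_start) |
      (d$b_start == d$a_start & d$b_end < d$a_end)
    if (any(swap)) {
      tmp_s <- d$a_start[swap]; tmp_e <- d$a_end[swap]
      d$a_start[swap] <- d$b_start[swap]; d$a_end[swap] <- d$b_end[swap]
      d$b_start[swap] <- tmp_s; d$b_end[swap] <- tmp_e
    }
    key <- paste(d$a_start, d$b_start, d$a_end - d$a_start, d$orientation)
    d <- d[!duplicated(key), , drop = FALSE]
  }
  if (nrow(d) == 0L) {
    return(data.frame(seq_id = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), orientation = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(seq_id = g$id, a_start = d$a_start, a_end = d$a_end,
                    b_start = d$b_start, b_end = d$b_end,
                    orientation = d$orientation,
                    length = d$a_end - d$a_start, stringsAsFactors = FALSE)
  out <- out[order(out$a_start, out$b_start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Duplication statistics for one genome
#'
#' `total_dup_len` is the union length of all member intervals of all
#' pairs; `max_dup_len` the longest single pair; `sum_pair_len` the sum of
#' pair lengths (both members), for the alternative counting convention.
#'
#' @param repeat_pairs Output of [find_exact_repeats()].
#' @param genome The `genome` the pairs came from.
#' @return A one-row `data.frame` of duplication statistics.
#' @export
duplicated_length <- function(repeat_pairs, genome) {
  g <- as_genome(genome)
  n <- nchar(g$seq)
  if (nrow(repeat_pairs) == 0L) {
    return(data.frame(genome_id = g$id, total_len = n, total_dup_len = 0L,
                      max_dup_len = 0L, sum_pair_len = 0L,
                      stringsAsFactors = FALSE))
  }
  if (length(unique(repeat_pairs$seq_id)) > 1L) {
    stop("repeat pairs come from more than one genome")
  }
  # member intervals may stick past the origin of a circular genome (from
  # the doubled-sequence scan); wrap them for the union
  wrap <- function(st, en) {
    out_s <- c(); out_e <- c()
    for (i in seq_along(st)) {
      if (en[i] <= n) { out_s <- c(out_s, st[i]); out_e <- c(out_e, en[i]) }
      else {
        out_s <- c(out_s, st[i], 0L); out_e <- c(out_e, n, en[i] - n)
      }
    }
    list(s = out_s, e = out_e)
  }
  w <- wrap(c(repeat_pairs$a_start, repeat_pairs$b_start),
            c(repeat_pairs$a_end, repeat_pairs$b_end))
  ints <- data.frame(seq_id = g$id, start = w$s, end = w$e, strand = "+")
  data.frame(genome_id = g$id, total_len = n,
             total_dup_len = interval_union_length(ints),
             max_dup_len = max(repeat_pairs$length),
             sum_pair_len = 2L * sum(repeat_pairs$length),
             stringsAsFactors = FALSE)
}

#' Correlations among duplication statistics
#'
#' Pearson correlations (with two-sided p from the t transform) of total
#' duplicated length against total genome length, and of total duplicated
#' length against maximum duplicated length, with R-squared for both.
#'
#' @param dup_table A table with columns `total_len`, `total_dup_len`,
#'   `max_dup_len` (one row per genome, at least 3 rows).
#' @return A list of the two test results.
#' @export
dup_correlations <- function(dup_table) {
  if (nrow(dup_table) < 3L) stop("need at least 3 genomes")
  for (col in c("total_len", "total_dup_len", "max_dup_len")) {
    if (length(unique(dup_table[[col]])) == 1L) {
      stop("zero variance in column ", col, ": correlation undefined")
    }
  }
  t1 <- cor.test(dup_table$total_dup_len, dup_table$total_len)
  t2 <- cor.test(dup_table$total_dup_len, dup_table$max_dup_len)
  list(total_vs_genome = list(r = unname(t1$estimate), p = t1$p.value,
                              r_squared = unname(t1$estimate)^2),
       total_vs_max = list(r = unname(t2$estimate), p = t2$p.value,
                           r_squared = unname(t2$estimate)^2))
}

#' Write repeat pairs as a BED-style pair table
#'
#' @param repeat_pairs Output of [find_exact_repeats()].
#' @param path Output path.
#' @export
write_repeats <- function(repeat_pairs, path) {
  write.table(repeat_pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
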