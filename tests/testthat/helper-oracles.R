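# Independent oracles used by the tests. Each deliberately avoids the code
# path it checks: repeats by shift-diagonal run scanning, alignment scores
# by Biostrings' Smith-Waterman, interval unions by a bit vector, ORFs by a
# per-ATG codon walk.

# All maximal exact repeated pairs (both orientations) by scanning every
# relative offset for equality runs; O(n^2) but vectorized per offset.
oracle_repeats <- function(seq, min_len = 100L) {
  x <- charToRaw(seq)
  n <- length(x)
  rows <- list()
  add <- function(a0, a1, b0, b1, ori) {
    if (a0 == b0 && a1 == b1) return()
    if (b0 < a0 || (b0 == a0 && b1 < a1)) {
      t0 <- a0; t1 <- a1; a0 <- b0; a1 <- b1; b0 <- t0; b1 <- t1
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      a_start = a0, a_end = a1, b_start = b0, b_end = b1, orientation = ori,
      stringsAsFactors = FALSE)
  }
  for (d in seq_len(n - min_len)) {
    eq <- x[seq_len(n - d)] == x[(d + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      i <- starts[k]; L <- r$lengths[k]
      add(i - 1L, i - 1L + L, i - 1L + d, i - 1L + d + L, "direct")
    }
  }
  y <- charToRaw(revcomp(seq))
  for (off in (-(n - 1L)):(n - 1L)) {
    i1 <- max(1L, 1L - off); i2 <- min(n, n - off)
    if (i2 - i1 + 1L < min_len) next
    eq <- x[i1:i2] == y[(i1 + off):(i2 + off)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      i <- i1 + starts[k] - 1L; L <- r$lengths[k]; j0 <- i + off - 1L
      add(i - 1L, i - 1L + L, n - j0 - L, n - j0, "inverted")
    }
  }
  if (!length(rows)) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  d <- unique(do.call(rbind, rows))
  d <- d[order(d$a_start, d$b_start, d$orientation), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Full local (Smith-Waterman) optimum under the package's default scoring,
# via Biostrings (affine gaps: open charged once plus extend per column).
oracle_sw_score <- local({
  mat <- NULL
  function(a, b) {
    if (is.null(mat)) {
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -2,
                                                       baseOnly = TRUE)
    }
    Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                  Biostrings::DNAString(b),
                                  substitutionMatrix = mat,
                                  gapOpening = 5, gapExtension = 2,
                                  type = "local", scoreOnly = TRUE)
  }
})

# Interval union length by marking a bit vector.
oracle_union_length <- function(starts, ends, n) {
  hit <- logical(n)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) hit[(starts[i] + 1L):ends[i]] <- TRUE
  }
  sum(hit)
}

# ORFs by walking codons from every ATG to the next in-frame stop, keeping
# the longest ATG start per stop; linear sequences, forward coordinates.
oracle_orfs <- function(seq, min_len = 303L) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  out <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else revcomp(seq)
    hits <- list() # stop position -> earliest ATG
    for (a in seq_len(L - 5L)) {
      if (substr(s, a, a + 2L) != "ATG") next
      p <- a + 3L
      stop_at <- NA
      while (p + 2L <= L) {
        cod <- substr(s, p, p + 2L)
        if (cod %in% stops) { stop_at <- p; break }
        p <- p + 3L
      }
      if (is.na(stop_at)) next
      key <- as.character(stop_at)
      if (is.null(hits[[key]]) || hits[[key]] > a) hits[[key]] <- a
    }
    for (key in names(hits)) {
      a <- hits[[key]]; stop_at <- as.integer(key)
      len <- stop_at + 3L - a
      if (len < min_len) next
      if (str == "+") {
        out[[length(out) + 1L]] <- data.frame(start = a - 1L,
                                              end = a - 1L + len,
                                              strand = "+")
      } else {
        out[[length(out) + 1L]] <- data.frame(start = L - (a - 1L + len),
                                              end = L - (a - 1L),
                                              strand = "-")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  d <- unique(do.call(rbind, out))
  d <- d[order(d$start, d$end, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# random genome with planted repeats; returns sequence
plant_repeats <- function(n, n_repeats = 2L, len_range = c(100L, 300L)) {
  s <- random_seq(n)
  for (r in seq_len(n_repeats)) {
    L <- sample(len_range[1]:len_range[2], 1L)
    a <- sample(n - L, 1L)
    b <- sample(n - L, 1L)
    seg <- substr(s, a + 1L, a + L)
    if (runif(1) < 0.5) seg <- revcomp(seg)
    s <- paste0(substr(s, 1L, b), seg, substr(s, b + L + 1L, n))
  }
  s
}
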