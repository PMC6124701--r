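# Seed-and-extend local alignment (the blastn role).
#
# Exact word seeds on both strands, banded affine-gap extension with X-drop
# termination, Karlin-Altschul E-values E = K * m * n * exp(-lambda * S).
# Default scoring is blastn-like +1/-2 with gap open -5 / extend -2 (a gap
# of length g costs open + g * extend); K and lambda default to the
# published gapped nucleotide constants for that scheme (0.46, 1.28) so the
# usual e-value thresholds (1e-5, 1e-10) keep their customary meaning.
# Identity counts gap positions as alignment columns.

#' Homology search parameters
#'
#' @param word_size Exact seed length (>= 4).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; a gap of
#'   length g costs `gap_open + g * gap_extend`.
#' @param evalue_max Keep HSPs with E-value at or below this.
#' @param max_hits Truncate to this many HSPs by descending score (applied
#'   after the E-value filter, before any downstream dedup).
#' @param karlin_K,karlin_lambda Karlin-Altschul constants for the scoring
#'   scheme.
#' @param xdrop X-drop termination threshold (score units).
#' @param band Extension band half-width (diagonal drift allowance).
#' @return A `homology_params` object.
#' @export
homology_params <- function(word_size = 11L, match = 1L, mismatch = -2L,
                            gap_open = -5L, gap_extend = -2L,
                            evalue_max = 1e-5, max_hits = 50000L,
                            karlin_K = 0.46, karlin_lambda = 1.28,
                            xdrop = 20L, band = 50L) {
  stopifnot(word_size >= 4L, match > 0L, mismatch < 0L, max_hits >= 1L,
            gap_open <= 0L, gap_extend < 0L)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 evalue_max = evalue_max, max_hits = as.integer(max_hits),
                 karlin_K = karlin_K, karlin_lambda = karlin_lambda,
                 xdrop = as.integer(xdrop), band = as.integer(band)),
            class = "homology_params")
}

#' Karlin-Altschul expected hit count
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the score,
#' linear in each sequence length.
#'
#' @param score Alignment score(s).
#' @param m,n Query and subject lengths (positive).
#' @param params [homology_params()] carrying K and lambda.
#' @return E-value(s).
#' @export
evalue <- function(score, m, n, params = homology_params()) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  params$karlin_K * m * n * exp(-params$karlin_lambda * score)
}

empty_hsps <- function() {
  data.frame(qid = character(0), sid = character(0), qstart = integer(0),
             qend = integer(0), sstart = integer(0), send = integer(0),
             strand = character(0), score = numeric(0), align_len = integer(0),
             identity = numeric(0), mismatches = integer(0),
             gapopens = integer(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Find high-scoring segment pairs between two sequences
#'
#' Seeds of `word_size` exact bases on both strands are extended by banded
#' affine-gap alignment with X-drop termination. Near-duplicate alignments
#' of the same region pair (reciprocal overlap of at least 50% on both
#' sides, same strand) are merged keeping the best score. Results are
#' filtered to `evalue <= evalue_max`, truncated to `max_hits` by descending
#' score, and ordered deterministically (score desc, query start, subject
#' start). Coordinates are 0-based half-open; minus-strand hits carry the
#' query interval on the forward query.
#'
#' @param query,subject `genome` objects or DNA strings.
#' @param params [homology_params()].
#' @return An HSP table.
#' @export
find_hsps <- function(query, subject, params = homology_params()) {
  q <- as_genome(query)
  s <- as_genome(subject)
  raw <- cpp_find_hsps(q$seq, s$seq, params$word_size, params$match,
                       params$mismatch, params$gap_open, params$gap_extend,
                       params$xdrop, params$band)
  if (nrow(raw) == 0L) return(empty_hsps())
  align_len <- raw$matches + raw$mismatches + raw$gapcols
  d <- data.frame(qid = q$id, sid = s$id, qstart = raw$qstart,
                  qend = raw$qend, sstart = raw$sstart, send = raw$send,
                  strand = raw$strand, score = raw$score,
                  align_len = align_len,
                  identity = raw$matches / align_len,
                  mismatches = raw$mismatches, gapopens = raw$gapopens,
                  evalue = evalue(raw$score, nchar(q$seq), nchar(s$seq),
                                  params),
                  stringsAsFactors = FALSE)
  d <- d[d$evalue <= params$evalue_max & d$align_len >= params$word_size, ,
         drop = FALSE]
  if (nrow(d) == 0L) return(empty_hsps())
  d <- d[order(-d$score, d$qstart, d$sstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))[-1]) {
    js <- which(keep[seq_len(i - 1L)])
    if (!length(js)) next
    qo <- pmin(d$qend[js], d$qend[i]) - pmax(d$qstart[js], d$qstart[i])
    so <- pmin(d$send[js], d$send[i]) - pmax(d$sstart[js], d$sstart[i])
    qlen <- pmin(d$qend[js] - d$qstart[js], d$qend[i] - d$qstart[i])
    slen <- pmin(d$send[js] - d$sstart[js], d$send[i] - d$sstart[i])
    dup <- d$strand[js] == d$strand[i] & qo >= 0.5 * qlen & so >= 0.5 * slen
    if (any(dup)) keep[i] <- FALSE
  }
  d <- d[keep, , drop = FALSE]
  d <- utils::head(d, params$max_hits)
  rownames(d) <- NULL
  d
}

#' Union coverage of HSPs on one side
#'
#' Merged interval union (each base counted once) of the query- or
#' subject-side intervals, all of which must lie on the same sequence.
#'
#' @param hsps An HSP table.
#' @param on `"query"` or `"subject"`.
#' @return `list(intervals, total_bp)`.
#' @export
hit_coverage <- function(hsps, on = c("query", "subject")) {
  on <- match.arg(on)
  if (nrow(hsps) == 0L) {
    return(list(intervals = interval(character(0), integer(0),
                                     integer(0))[0, ], total_bp = 0L))
  }
  ids <- if (on == "query") hsps$qid else hsps$sid
  if (length(unique(ids)) > 1L) {
    stop("HSPs cover more than one ", on, " sequence")
  }
  st <- if (on == "query") hsps$qstart else hsps$sstart
  en <- if (on == "query") hsps$qend else hsps$send
  ir <- IRanges::reduce(IRanges::IRanges(start = st + 1L, end = en))
  ints <- data.frame(seq_id = ids[1], start = IRanges::start(ir) - 1L,
                     end = IRanges::end(ir), strand = "+",
                     stringsAsFactors = FALSE)
  list(intervals = ints, total_bp = sum(IRanges::width(ir)))
}

#' Write HSPs in blastn outfmt-6 style
#'
#' Columns qid, sid, pident, length, mismatches, gapopens, qstart, qend,
#' sstart, send, evalue, bitscore; 1-based inclusive coordinates with the
#' subject interval reversed for minus-strand hits. Bit score is
#' `(lambda * S - ln K) / ln 2`.
#'
#' @param hsps An HSP table.
#' @param path Output path.
#' @param params [homology_params()] (for the bit-score constants).
#' @export
write_hits_outfmt6 <- function(hsps, path, params = homology_params()) {
  minus <- hsps$strand == "-"
  ss <- ifelse(minus, hsps$send, hsps$sstart + 1L)
  se <- ifelse(minus, hsps$sstart + 1L, hsps$send)
  bits <- (params$karlin_lambda * hsps$score - log(params$karlin_K)) / log(2)
  d <- data.frame(hsps$qid, hsps$sid, sprintf("%.3f", 100 * hsps$identity),
                  hsps$align_len, hsps$mismatches, hsps$gapopens,
                  hsps$qstart + 1L, hsps$qend, ss, se,
                  format(hsps$evalue, digits = 3), sprintf("%.1f", bits))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
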