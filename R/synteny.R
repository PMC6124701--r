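# Structural comparison between mitogenomes, plus annotation utilities.
#
# Syntenic blocks chain collinear HSPs (e-value <= 1e-10) of the same
# orientation with gaps at most max_chain_gap on both genomes; blocks must
# exceed min_block_len and contain at least one annotated gene. Conserved
# fractions are computed on each genome's own coordinates (duplications
# make the shared lengths asymmetric). Ribbon bins follow the score /
# max-score ratio convention (<=0.25, <=0.50, <=0.75, >0.75); the ratio is
# scale-invariant, so raw scores and bit scores bin identically.

#' Synteny parameters
#'
#' @param min_block_len Minimum block length (bp) on the first genome.
#' @param max_chain_gap Maximum chaining gap (bp) on either genome.
#' @param require_gene Keep only blocks containing an annotated gene.
#' @param homology [homology_params()]; defaults to e-value 1e-10 as used
#'   for structural comparison.
#' @return A `synteny_params` object.
#' @export
synteny_params <- function(min_block_len = 1000L, max_chain_gap = 500L,
                           require_gene = TRUE,
                           homology = homology_params(evalue_max = 1e-10)) {
  structure(list(min_block_len = as.integer(min_block_len),
                 max_chain_gap = as.integer(max_chain_gap),
                 require_gene = require_gene, homology = homology),
            class = "synteny_params")
}

#' Find syntenic blocks between two genomes
#'
#' HSPs are chained collinearly (same orientation, bounded gaps, subject
#' coordinate advancing in the orientation's direction); chains shorter
#' than `min_block_len` on the first genome or containing no annotated
#' gene are discarded. Blocks are trimmed to be non-overlapping on the
#' first genome.
#'
#' @param gA,gB `genome` objects.
#' @param annotA Feature table for `gA` (required when `require_gene`).
#' @param params [synteny_params()].
#' @return A block table with gene lists.
#' @export
find_synteny_blocks <- function(gA, gB, annotA = NULL,
                                params = synteny_params()) {
  if (params$require_gene && is.null(annotA)) {
    stop("annotation for gA required when gene filtering is enabled")
  }
  hs <- find_hsps(gA, gB, params$homology)
  if (nrow(hs) == 0L) return(empty_blocks())
  blocks <- list()
  for (str in unique(hs$strand)) {
    h <- hs[hs$strand == str, , drop = FALSE]
    h <- h[order(h$qstart), , drop = FALSE]
    cur <- NULL
    flush <- function(b) if (!is.null(b)) blocks[[length(blocks) + 1L]] <<- b
    for (i in seq_len(nrow(h))) {
      row <- h[i, ]
      if (is.null(cur)) { cur <- row_block(row); next }
      gq <- row$qstart - cur$a_end
      gs <- if (str == "+") row$sstart - cur$b_end else cur$b_start - row$send
      collinear <- gq <= params$max_chain_gap && gq >= -200L &&
        gs <= params$max_chain_gap && gs >= -200L
      if (collinear) {
        cur$a_end <- max(cur$a_end, row$qend)
        cur$b_start <- min(cur$b_start, row$sstart)
        cur$b_end <- max(cur$b_end, row$send)
        cur$n_hsps <- cur$n_hsps + 1L
        cur$score <- cur$score + row$score
      } else {
        flush(cur)
        cur <- row_block(row)
      }
    }
    flush(cur)
  }
  d <- do.call(rbind, lapply(blocks, as.data.frame))
  d$orientation <- ifelse(d$strand == "+", "same", "inverted")
  d <- d[order(d$a_start), , drop = FALSE]
  # trim tiny overlaps on gA left by extension overshoot at breakpoints
  if (nrow(d) > 1L) {
    for (i in 2:nrow(d)) {
      if (d$a_start[i] < d$a_end[i - 1L]) d$a_start[i] <- d$a_end[i - 1L]
    }
    d <- d[d$a_end > d$a_start, , drop = FALSE]
  }
  d$length <- d$a_end - d$a_start
  d$genes <- vapply(seq_len(nrow(d)), function(i) {
    if (is.null(annotA)) return("")
    gn <- annotA$name[annotA$kind == "gene" & annotA$start < d$a_end[i] &
                        annotA$end > d$a_start[i]]
    paste(sort(unique(gn)), collapse = ",")
  }, "")
  keep <- d$length >= params$min_block_len
  if (params$require_gene) keep <- keep & nzchar(d$genes)
  d <- d[keep, , drop = FALSE]
  d$block_id <- if (nrow(d)) sprintf("block%02d", seq_len(nrow(d))) else character(0)
  rownames(d) <- NULL
  d[, c("block_id", "a_start", "a_end", "b_start", "b_end", "orientation",
        "length", "n_hsps", "score", "genes")]
}

row_block <- function(row) {
  list(a_start = row$qstart, a_end = row$qend, b_start = row$sstart,
       b_end = row$send, strand = row$strand, n_hsps = 1L, score = row$score)
}

empty_blocks <- function() {
  data.frame(block_id = character(0), a_start = integer(0),
             a_end = integer(0), b_start = integer(0), b_end = integer(0),
             orientation = character(0), length = integer(0),
             n_hsps = integer(0), score = numeric(0), genes = character(0),
             stringsAsFactors = FALSE)
}

#' Conserved-region decomposition among three genomes
#'
#' For each genome, its positions are partitioned by presence of homology
#' (e-value filtered, union of hit coverage) to each of the other two:
#' shared with both, with only one, or unique. Lengths are on each
#' genome's own coordinates and sum exactly to its length.
#'
#' @param genomes List of three `genome` objects.
#' @param params [homology_params()] (default e-value 1e-10 via
#'   [synteny_params()]).
#' @return A `data.frame`, one row per genome.
#' @export
conserved_fraction <- function(genomes, params = homology_params(evalue_max = 1e-10)) {
  genomes <- as_genome_list(genomes)
  stopifnot(length(genomes) == 3L)
  rows <- lapply(seq_along(genomes), function(i) {
    others <- setdiff(seq_along(genomes), i)
    L <- nchar(genomes[[i]]$seq)
    covs <- lapply(others, function(j) {
      hs <- find_hsps(genomes[[i]], genomes[[j]], params)
      if (nrow(hs) == 0L) return(IRanges::IRanges())
      IRanges::reduce(IRanges::IRanges(hs$qstart + 1L, hs$qend))
    })
    both <- sum(IRanges::width(IRanges::intersect(covs[[1]], covs[[2]])))
    only1 <- sum(IRanges::width(IRanges::setdiff(covs[[1]], covs[[2]])))
    only2 <- sum(IRanges::width(IRanges::setdiff(covs[[2]], covs[[1]])))
    unique_len <- L - both - only1 - only2
    data.frame(genome_id = genomes[[i]]$id, total_len = L,
               with_both = both,
               only_with = genomes[[others[1]]]$id, only_with_len = only1,
               only_with2 = genomes[[others[2]]]$id, only_with2_len = only2,
               unique_len = unique_len,
               pct_conserved = 100 * (L - unique_len) / L,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Rearrangement ribbon map between two genomes
#'
#' Every retained HSP is assigned a ratio of its score to the best score of
#' the comparison and a ribbon bin (<=0.25, <=0.50, <=0.75, >0.75), sorted
#' by position on the first genome.
#'
#' @param gA,gB `genome` objects.
#' @param params [homology_params()].
#' @return The HSP table with `ratio` and `bin` columns.
#' @export
ribbon_map <- function(gA, gB, params = homology_params(evalue_max = 1e-10)) {
  hs <- find_hsps(gA, gB, params)
  if (nrow(hs) == 0L) {
    hs$ratio <- numeric(0)
    hs$bin <- character(0)
    return(hs)
  }
  hs$ratio <- hs$score / max(hs$score)
  hs$bin <- as.character(cut(hs$ratio, c(0, 0.25, 0.5, 0.75, 1),
                             labels = c("<=0.25", "<=0.50", "<=0.75", ">0.75")))
  hs <- hs[order(hs$qstart), , drop = FALSE]
  rownames(hs) <- NULL
  hs
}

#' Find open reading frames
#'
#' All ORFs of at least `min_len` bp starting with ATG and ending at a stop
#' codon (stop included in the length), on both strands and all six frames,
#' honoring circular topology. Within one stop-bounded frame segment only
#' the longest ATG start is reported unless `longest_only = FALSE`.
#'
#' @param genome A `genome`.
#' @param min_len Minimum ORF length in bp (default 303).
#' @param longest_only Report only the longest nested ORF per stop.
#' @return A feature table of kind `ORF`; for circular genomes features may
#'   wrap (end beyond genome length, start always within).
#' @export
find_orfs <- function(genome, min_len = 303L, longest_only = TRUE) {
  g <- as_genome(genome)
  L <- nchar(g$seq)
  circular <- g$topology == "circular"
  res <- NULL
  for (str in c("+", "-")) {
    s <- if (str == "+") g$seq else revcomp(g$seq)
    scan <- if (circular) paste0(s, s) else s
    for (f in 0:2) {
      starts <- seq.int(f + 1L, nchar(scan) - 2L, by = 3L)
      codons <- substring(scan, starts, starts + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      seg <- cumsum(c(TRUE, is_stop[-length(is_stop)])) # segments ending at stop
      for (sg in split(seq_along(codons), seg)) {
        last <- sg[length(sg)]
        if (!is_stop[last]) next
        cand <- sg[-length(sg)]
        atgs <- cand[is_atg[cand]]
        if (!length(atgs)) next
        if (longest_only) atgs <- atgs[1]
        for (a in atgs) {
          len <- (last - a + 1L) * 3L
          if (len < min_len || len > L) next
          st0 <- starts[a] - 1L # 0-based on scan strand
          if (circular && st0 >= L) next # duplicate of the first copy
          en0 <- st0 + len
          if (!circular && en0 > L) next
          if (str == "+") {
            res <- rbind(res, data.frame(start = st0, end = en0, strand = "+"))
          } else {
            # map back to forward coordinates; wrapped ORFs keep end > L
            st_f <- L - (en0 %% L)
            if (st_f == L) st_f <- 0L
            res <- rbind(res, data.frame(start = st_f, end = st_f + len,
                                         strand = "-"))
          }
        }
      }
    }
  }
  if (is.null(res) || nrow(res) == 0L) {
    empty <- interval(character(0), integer(0), integer(0))
    empty$kind <- character(0)
    empty$name <- character(0)
    return(empty)
  }
  res <- unique(res)
  if (circular) res$start <- res$start %% L
  res <- unique(res[order(res$start, res$end, res$strand), , drop = FALSE])
  feature_table(g$id, res$start, res$end, strand = res$strand, kind = "ORF",
                name = sprintf("orf%04d", seq_len(nrow(res))))
}

#' Gene presence and duplication matrix
#'
#' Per gene name and genome: `absent`, `single` or `duplicated` (two or
#' more copies). The attribute `duplicated_counts` holds the number of
#' duplicated genes per genome excluding ORFs and tRNAs.
#'
#' @param annotated_genomes Named list of feature tables, one per genome.
#' @return A character matrix (gene x genome) with attributes
#'   `counts` (copy numbers) and `duplicated_counts`.
#' @export
gene_presence_matrix <- function(annotated_genomes) {
  stopifnot(is.list(annotated_genomes), !is.null(names(annotated_genomes)))
  all_genes <- sort(unique(unlist(lapply(annotated_genomes, function(a) a$name))))
  counts <- sapply(annotated_genomes, function(a) {
    tab <- table(a$name)
    out <- setNames(integer(length(all_genes)), all_genes)
    out[names(tab)] <- as.integer(tab)
    out
  })
  counts <- matrix(counts, nrow = length(all_genes),
                   dimnames = list(all_genes, names(annotated_genomes)))
  cls <- ifelse(counts == 0L, "absent", ifelse(counts == 1L, "single",
                                               "duplicated"))
  dup_counts <- vapply(names(annotated_genomes), function(g) {
    a <- annotated_genomes[[g]]
    excl <- a$name[a$kind %in% c("ORF", "tRNA")]
    sum(cls[, g] == "duplicated" & !(rownames(cls) %in% excl))
  }, 0L)
  attr(cls, "counts") <- counts
  attr(cls, "duplicated_counts") <- dup_counts
  cls
}
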