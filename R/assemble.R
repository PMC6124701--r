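# Bait-and-iterate organelle assembler.
#
# "Mapping" is operationalized as exact k-mer matching: reads are baited by
# shared bait_k-mers, contigs are maximal unbranched paths (unitigs) of the
# assembly_k de Bruijn graph of the reads (zero mismatches by construction),
# and iterative extension merges and grows contigs until the genome closes.
# Repeats longer than assembly_k collapse in the graph; they are resolved by
# coverage-multiplicity Eulerian-circuit traversal, and a sequence is
# reported only when the circuit is unique. Ambiguity is surfaced, never
# silently resolved.

#' Assembly parameters
#'
#' @param bait_k Exact k-mer size for read baiting and mapping (<= 31).
#' @param assembly_k De Bruijn graph k-mer size (odd, <= 63).
#' @param min_overlap Minimum exact end overlap for merging/circularizing.
#' @param max_iterations Cap on extension iterations.
#' @param min_depth_qc Depth below which a region is flagged low.
#' @param plastome_fold_flag Fold over median depth flagging plastome-like
#'   high-depth regions (MTPTs attract plastome-derived reads).
#' @param max_insert Upper bound on the fragment length accepted as a
#'   concordant read-pair placement during repeat resolution.
#' @return An `assembly_params` object.
#' @export
assembly_params <- function(bait_k = 31L, assembly_k = 63L, min_overlap = 50L,
                            max_iterations = 10L, min_depth_qc = 200,
                            plastome_fold_flag = 5, max_insert = 1000L) {
  stopifnot(bait_k >= 4L, bait_k <= 31L, assembly_k >= 5L, assembly_k <= 63L,
            assembly_k %% 2L == 1L, max_iterations >= 1L, min_overlap >= 10L)
  structure(list(bait_k = as.integer(bait_k), assembly_k = as.integer(assembly_k),
                 min_overlap = as.integer(min_overlap),
                 max_iterations = as.integer(max_iterations),
                 min_depth_qc = min_depth_qc,
                 plastome_fold_flag = plastome_fold_flag,
                 max_insert = as.integer(max_insert)),
            class = "assembly_params")
}

reads_vector <- function(reads) {
  if (inherits(reads, "read_set")) c(reads$r1, reads$r2)
  else as.character(reads)
}

#' Bait read pairs against reference seeds
#'
#' Keeps every pair in which at least one mate shares at least one exact
#' `bait_k`-mer (either strand) with any bait sequence; a pair is kept or
#' dropped as a unit.
#'
#' @param reads A `read_set`.
#' @param baits Bait sequences: genome(s) or character vector.
#' @param params [assembly_params()].
#' @return The baited `read_set`.
#' @export
bait_reads <- function(reads, baits, params = assembly_params()) {
  stopifnot(inherits(reads, "read_set"))
  bs <- if (is.character(baits)) baits else {
    vapply(as_genome_list(baits), `[[`, "", "seq")
  }
  if (!length(bs)) stop("baits must be non-empty")
  if (length(reads$r1) == 0L) return(reads)
  if (params$bait_k > min(nchar(c(reads$r1, reads$r2)))) {
    stop("bait_k exceeds read length")
  }
  keep <- cpp_kmer_hits(reads$r1, bs, params$bait_k) |
    cpp_kmer_hits(reads$r2, bs, params$bait_k)
  structure(list(r1 = reads$r1[keep], r2 = reads$r2[keep],
                 origins = if (is.null(reads$origins)) NULL else
                   reads$origins[keep, , drop = FALSE]),
            class = "read_set")
}

#' Keep read pairs whose mates both map with zero mismatches
#'
#' Full-length exact matching (either strand) against reference sequences,
#' anchored by shared `bait_k`-mers; a pair is kept only when both mates
#' map. This is the strict zero-mismatch read recruitment used ahead of
#' contig building: reads from diverged nuclear copies of organellar DNA
#' carry fixed mismatches and are excluded, while reads from the organelle
#' itself (error-free) always pass.
#'
#' @param reads A `read_set`.
#' @param refs Reference `genome`(s).
#' @param params [assembly_params()].
#' @return The filtered `read_set`.
#' @export
map_reads_exact <- function(reads, refs, params = assembly_params()) {
  stopifnot(inherits(reads, "read_set"))
  refs <- as_genome_list(refs)
  k1 <- rep(FALSE, length(reads$r1))
  k2 <- rep(FALSE, length(reads$r2))
  for (g in refs) {
    circ <- g$topology == "circular"
    k1 <- k1 | cpp_exact_map(g$seq, reads$r1, params$bait_k, circ)
    k2 <- k2 | cpp_exact_map(g$seq, reads$r2, params$bait_k, circ)
  }
  keep <- k1 & k2
  structure(list(r1 = reads$r1[keep], r2 = reads$r2[keep],
                 origins = if (is.null(reads$origins)) NULL else
                   reads$origins[keep, , drop = FALSE]),
            class = "read_set")
}

new_contig <- function(seq, support, circular = FALSE, iteration_born = 0L) {
  structure(list(seq = seq, support = as.integer(support),
                 circular = circular, iteration_born = as.integer(iteration_born)),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %d bp, min support %d%s\n", nchar(x$seq),
              min(x$support), if (x$circular) ", circular" else ""))
  invisible(x)
}

# expand per-k-mer coverage to per-base support (k-mer covering each base)
kmer_cov_to_support <- function(cov, k, L) {
  nk <- length(cov)
  idx <- pmin(pmax(seq_len(L) - k + 1L, 1L), nk)
  as.integer(cov[idx])
}

#' Build zero-mismatch contigs from reads
#'
#' Contigs are the maximal unbranched paths of the `assembly_k` de Bruijn
#' graph over both strands of the reads, with per-base read support.
#'
#' @param reads A `read_set` or character vector of sequences.
#' @param params [assembly_params()].
#' @param iteration Iteration label stored on the contigs.
#' @return List of `contig` objects, longest first.
#' @export
build_contigs <- function(reads, params = assembly_params(), iteration = 0L) {
  rv <- reads_vector(reads)
  if (!length(rv)) stop("no reads supplied")
  if (max(nchar(rv)) < params$assembly_k) {
    stop("all reads are shorter than assembly_k; use a smaller k")
  }
  res <- cpp_build_unitigs(rv, params$assembly_k)
  contigs <- lapply(seq_along(res$seq), function(i) {
    L <- nchar(res$seq[i])
    new_contig(res$seq[i],
               kmer_cov_to_support(res$cov[[i]], params$assembly_k, L),
               circular = res$circular[i], iteration_born = iteration)
  })
  contigs[order(-vapply(contigs, function(x) nchar(x$seq), 0L))]
}

# ---- repeat resolution on the condensed unitig graph ----
#
# Unitig copy numbers are estimated from coverage relative to the
# length-weighted median; a depth-first search enumerates closed traversals
# using each unitig (in either orientation) exactly its copy number of
# times. Because copy numbers from coverage are heuristic (shared MTPT
# sequence inflates depth without extra mitochondrial copies), candidate
# copy-number vectors are tried in order of distance from the coverage
# estimate, keeping only node-balanced vectors, and the first vector
# admitting a traversal wins; the result is used only if all its traversals
# spell the same circular sequence.

resolve_unitig_graph <- function(contigs, params, pairs = NULL,
                                 tip_rounds = 5L, max_paths = 20000L,
                                 max_distinct = 12L) {
  k <- params$assembly_k
  if (length(contigs) <= 1L) return(list(contigs = contigs, resolved = TRUE))
  seqs <- vapply(contigs, `[[`, "", "seq")
  covm <- vapply(contigs, function(ct) mean(ct$support), 0)

  # tip clipping: short unitigs with a dead end are read stubs (e.g.
  # plastome flanks crossing an MTPT boundary)
  for (round in seq_len(tip_rounds)) {
    if (length(seqs) <= 1L) break
    lens <- nchar(seqs)
    pre <- substr(seqs, 1L, k - 1L)
    suf <- substr(seqs, lens - k + 2L, lens)
    pre_rc <- revcomp(suf)
    suf_rc <- revcomp(pre)
    all_suf <- c(suf, suf_rc)
    all_pre <- c(pre, pre_rc)
    has_in <- pre %in% all_suf
    has_out <- suf %in% all_pre
    tip <- (!has_in | !has_out) & lens < 3L * k
    if (!any(tip) || all(tip)) break
    seqs <- seqs[!tip]
    covm <- covm[!tip]
    contigs <- contigs[!tip]
  }
  if (length(seqs) == 1L) return(list(contigs = contigs, resolved = TRUE))

  lens <- nchar(seqs)
  pre <- substr(seqs, 1L, k - 1L)
  suf <- substr(seqs, lens - k + 2L, lens)
  pre_rc <- revcomp(suf)
  suf_rc <- revcomp(pre)

  # length-weighted median coverage
  o <- order(covm)
  med <- covm[o][which(cumsum(lens[o]) >= sum(lens) / 2)[1]]
  if (!is.finite(med) || med <= 0) med <- 1
  raw <- covm / med
  m0 <- pmax(1L, as.integer(round(raw)))

  # candidate copy-number vectors: coverage-rounded, with 1 as the
  # alternative for any unitig called multi-copy
  opts <- lapply(seq_along(m0), function(i) unique(c(m0[i], 1L)))
  if (prod(lengths(opts)) <= 64L) {
    cands <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
    dist <- apply(cands, 1L, function(v) sum(abs(v - raw)))
    cands <- lapply(order(dist), function(i) as.integer(cands[i, ]))
  } else {
    cands <- list(m0)
  }

  node_balanced <- function(mm) {
    out <- c(tapply(mm, pre, sum), tapply(mm, pre_rc, sum))
    inn <- c(tapply(mm, suf, sum), tapply(mm, suf_rc, sum))
    out <- tapply(out, names(out), sum)
    inn <- tapply(inn, names(inn), sum)
    setequal(names(out), names(inn)) &&
      all(out[names(inn)] == inn)
  }

  start <- which.max(lens)
  build_path <- function(path) {
    # path: signed unitig indices; returns full string with terminal (k-1)
    # duplication so circularization can close it, plus per-base support
    s <- character(length(path))
    sup <- vector("list", length(path))
    for (j in seq_along(path)) {
      i <- abs(path[j])
      sq <- if (path[j] > 0) seqs[i] else revcomp(seqs[i])
      su <- contigs[[i]]$support
      if (path[j] < 0) su <- rev(su)
      if (j > 1L) {
        sq <- substr(sq, k, nchar(sq))
        su <- su[k:length(su)]
      }
      s[j] <- sq
      sup[[j]] <- su
    }
    list(seq = paste(s, collapse = ""), support = unlist(sup))
  }

  try_vector <- function(mm) {
    found <- list()
    distinct <- character(0)
    npaths <- 0L
    target <- pre[start]
    rec <- function(node, remaining, path) {
      if (npaths > max_paths || length(distinct) > max_distinct) return()
      if (all(remaining == 0L)) {
        if (node == target) {
          bp <- build_path(path)
          key <- canonical_rotation(substr(bp$seq, 1L, nchar(bp$seq) - (k - 1L)))
          if (!(key %in% distinct)) {
            distinct <<- c(distinct, key)
            found[[length(found) + 1L]] <<- bp
          }
        }
        npaths <<- npaths + 1L
        return()
      }
      for (i in seq_along(seqs)) {
        if (remaining[i] == 0L) next
        if (pre[i] == node) {
          remaining[i] <- remaining[i] - 1L
          rec(suf[i], remaining, c(path, i))
          remaining[i] <- remaining[i] + 1L
        }
        if (pre_rc[i] == node) {
          remaining[i] <- remaining[i] - 1L
          rec(suf_rc[i], remaining, c(path, -i))
          remaining[i] <- remaining[i] + 1L
        }
      }
    }
    remaining <- mm
    remaining[start] <- remaining[start] - 1L
    rec(suf[start], remaining, start)
    list(found = found, distinct = distinct)
  }

  accept <- function(bp) {
    ct <- new_contig(bp$seq, bp$support, circular = FALSE)
    list(contigs = list(ct), resolved = TRUE)
  }
  balanced <- Filter(node_balanced, cands)
  if (!length(balanced)) balanced <- cands[1]
  for (mm in balanced) {
    res <- try_vector(mm)
    nd <- length(res$distinct)
    if (nd == 1L) return(accept(res$found[[1]]))
    if (nd > 1L) {
      # repeat arrangements admitting several traversals: let paired-end
      # spanning decide; without a strict winner, surface the ambiguity
      if (!is.null(pairs) && nd <= max_distinct && length(pairs$r1)) {
        scores <- vapply(res$found, function(bp) {
          st <- substr(bp$seq, 1L, nchar(bp$seq) - (k - 1L))
          cpp_concordant_pairs(st, pairs$r1, pairs$r2, params$bait_k, 1L,
                               params$max_insert, 4000L)[1]
        }, 0L)
        w <- which(scores == max(scores))
        if (length(w) == 1L) return(accept(res$found[[w]]))
      }
      return(list(contigs = contigs, resolved = FALSE,
                  reason = "multiple Eulerian traversals"))
    }
  }
  list(contigs = contigs, resolved = FALSE, reason = "no closed traversal")
}

#' Iteratively extend and merge contigs with read support
#'
#' Each iteration recruits all reads sharing an exact `bait_k`-mer with the
#' current contigs, rebuilds the de Bruijn graph over contigs plus recruited
#' reads, merges unbranched paths, and attempts repeat resolution on the
#' condensed graph. Iteration stops when the contig set no longer improves
#' (total assembled length is never allowed to decrease) or after
#' `max_iterations`.
#'
#' @param contigs Output of [build_contigs()].
#' @param reads All candidate reads (a `read_set` or character vector); with
#'   an empty read set the input is returned unchanged.
#' @param params [assembly_params()].
#' @return List of `contig` objects.
#' @export
extend_iterate <- function(contigs, reads, params = assembly_params()) {
  rv <- reads_vector(reads)
  if (!length(rv) || !length(contigs)) return(contigs)
  pairs <- if (inherits(reads, "read_set")) reads else NULL
  total <- function(cs) sum(vapply(cs, function(x) nchar(x$seq), 0L))
  best <- contigs
  for (it in seq_len(params$max_iterations)) {
    cseqs <- vapply(best, `[[`, "", "seq")
    keep <- cpp_kmer_hits(rv, cseqs, params$bait_k)
    if (!any(keep)) break
    cand <- build_contigs(c(rv[keep], cseqs), params, iteration = it)
    rs <- resolve_unitig_graph(cand, params, pairs = pairs)
    cand <- rs$contigs
    better <- total(cand) > total(best) ||
      (total(cand) == total(best) && length(cand) < length(best))
    if (!better) break
    best <- cand
    if (isTRUE(rs$resolved) && length(best) == 1L &&
        circularize(best[[1]], params)$closed) break
  }
  best
}

#' Close a contig into a circular genome
#'
#' If the contig's two ends share an exact overlap of at least
#' `min_overlap`, one copy is trimmed and the genome is emitted circular at
#' its canonical rotation; otherwise the contig is returned linear and
#' flagged not closed. When several nested terminal overlaps exist the
#' longest is used.
#'
#' @param contig A `contig`.
#' @param params [assembly_params()].
#' @param id,role Identity of the emitted genome.
#' @return `list(genome, closed, overlap)`.
#' @export
circularize <- function(contig, params = assembly_params(), id = "assembly",
                        role = "mitogenome") {
  s <- contig$seq
  L <- nchar(s)
  mo <- params$min_overlap
  cand <- integer(0)
  if (L >= 2L * mo) {
    P <- substr(s, 1L, mo)
    hits <- gregexpr(P, s, fixed = TRUE)[[1]]
    for (p in hits[hits > 1L]) {
      ov <- L - p + 1L
      if (ov < mo || ov > L %/% 2L) next
      if (substr(s, p, L) == substr(s, 1L, ov)) cand <- c(cand, ov)
    }
  }
  if (!length(cand)) {
    return(list(genome = genome(id, s, topology = "linear", role = "contig"),
                closed = FALSE, overlap = 0L))
  }
  ov <- max(cand)
  trimmed <- substr(s, 1L, L - ov)
  list(genome = genome(id, canonical_rotation(trimmed), topology = "circular",
                       role = role),
       closed = TRUE, overlap = ov)
}

#' Per-base depth and QC flags from exact k-mer read mapping
#'
#' Reads are anchored by their first exactly matching `bait_k`-mer (either
#' strand); multi-mapping reads contribute fractional depth. Intervals below
#' `min_depth_qc` are flagged low; intervals at or above
#' `plastome_fold_flag` times the median are flagged plastome-like
#' high-depth (candidate MTPT regions attracting plastome reads).
#'
#' @param genome A `genome`.
#' @param reads A `read_set` or character vector.
#' @param params [assembly_params()].
#' @return `list(depth, flags, median)`; `flags` is a BED-like table.
#' @export
coverage_profile <- function(genome, reads, params = assembly_params()) {
  rv <- reads_vector(reads)
  L <- nchar(genome$seq)
  if (!length(rv)) {
    warning("empty read set: entire genome flagged low")
    flags <- data.frame(seq_id = genome$id, start = 0L, end = L,
                        flag = "low", stringsAsFactors = FALSE)
    return(list(depth = numeric(L), flags = flags, median = 0))
  }
  depth <- cpp_coverage_profile(genome$seq, rv, params$bait_k,
                                genome$topology == "circular")
  med <- median(depth)
  runs_to_bed <- function(mask, flag) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(seq_id = genome$id, start = starts[keep], end = ends[keep],
               flag = flag, stringsAsFactors = FALSE)
  }
  low <- runs_to_bed(depth < params$min_depth_qc, "low")
  high <- if (med > 0) {
    runs_to_bed(depth >= params$plastome_fold_flag * med,
                "plastome_like_high_depth")
  } else {
    warning("median depth is zero; skipping high-depth flags")
    NULL
  }
  flags <- rbind(low, high)
  if (is.null(flags)) {
    flags <- data.frame(seq_id = character(0), start = integer(0),
                        end = integer(0), flag = character(0),
                        stringsAsFactors = FALSE)
  }
  list(depth = depth, flags = flags, median = med)
}

#' Bait, assemble, extend and circularize in one call
#'
#' @param reads A `read_set`.
#' @param baits Bait sequences (reference seeds).
#' @param params [assembly_params()].
#' @param id,role Identity of the emitted genome.
#' @return `list(genome, closed, contigs, log)`.
#' @export
assemble_genome <- function(reads, baits, params = assembly_params(),
                            id = "assembly", role = "mitogenome") {
  baited <- bait_reads(reads, baits, params)
  if (!length(baited$r1)) stop("no reads were baited; check bait sequences")
  contigs <- build_contigs(baited, params)
  log <- data.frame(stage = "build", n_contigs = length(contigs),
                    total_bp = sum(vapply(contigs, function(x) nchar(x$seq), 0L)),
                    stringsAsFactors = FALSE)
  contigs <- extend_iterate(contigs, baited, params)
  log <- rbind(log, data.frame(stage = "extend", n_contigs = length(contigs),
                               total_bp = sum(vapply(contigs, function(x)
                                 nchar(x$seq), 0L))))
  if (length(contigs) == 1L) {
    circ <- circularize(contigs[[1]], params, id = id, role = role)
  } else {
    circ <- list(genome = NULL, closed = FALSE, overlap = 0L)
  }
  list(genome = circ$genome, closed = circ$closed, contigs = contigs,
       log = log)
}
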