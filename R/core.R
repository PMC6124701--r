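# Domain types and coordinate arithmetic.
#
# Coordinates are 0-based half-open throughout; GFF3 output converts to
# 1-based inclusive, BED stays 0-based half-open. Circular genomes are stored
# linearized; the canonical rotation (lexicographically minimal rotation of
# the smaller of sequence and reverse complement) makes assemblies comparable.

GENOME_ROLES <- c("mitogenome", "plastome", "nuclear_chromosome", "contig")
GENOME_TOPOLOGIES <- c("circular", "linear")

#' Construct a genome record
#'
#' A genome is a single DNA sequence over \{A, C, G, T, N\} with an identifier,
#' a topology (circular or linear) and a biological role. Contigs are linear
#' until circularized.
#'
#' @param id Sequence identifier (non-empty string).
#' @param seq DNA sequence; upper-cased on input.
#' @param topology `"circular"` or `"linear"`.
#' @param role One of `"mitogenome"`, `"plastome"`, `"nuclear_chromosome"`,
#'   `"contig"`.
#' @return An object of class `genome`.
#' @export
genome <- function(id, seq, topology = "linear", role = "contig") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  check_dna(seq, id)
  topology <- match.arg(topology, GENOME_TOPOLOGIES)
  role <- match.arg(role, GENOME_ROLES)
  structure(list(id = id, seq = seq, topology = topology, role = role),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s %s, %s bp\n", x$id, x$topology, x$role,
              format(nchar(x$seq), big.mark = ",")))
  invisible(x)
}

#' @export
length.genome <- function(x) nchar(x$seq)

as_genome <- function(x) {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome("seq", x))
  stop("expected a genome object or a single DNA string")
}

# Alphabet validation; reports the first offending record position (1-based).
check_dna <- function(seq, id = "sequence") {
  if (!nzchar(seq)) stop(sprintf("record '%s' is empty", id))
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("record '%s' contains invalid character '%s' at position %d",
                 id, substr(seq, bad, bad), bad))
  }
  invisible(TRUE)
}

#' Read genomes from a FASTA file
#'
#' One `genome` per record. Role and topology come from the arguments, or
#' from `role=`/`topology=` tags in the record description when present.
#' Sequences are upper-cased; `U` and any non-IUPAC character other than `N`
#' are rejected with the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param role,topology Defaults for records without header tags.
#' @return A named list of `genome` objects, in file order.
#' @export
read_fasta <- function(path, role = "contig", topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(header, "[ \t]+")[[1]]
    id <- toks[1]
    r <- sub("^role=", "", grep("^role=", toks, value = TRUE))
    t <- sub("^topology=", "", grep("^topology=", toks, value = TRUE))
    out[[i]] <- genome(id, as.character(set[[i]]),
                       topology = if (length(t)) t[1] else topology,
                       role = if (length(r)) r[1] else role)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write genomes to FASTA
#'
#' Deterministic: records are written in list order with `role=` and
#' `topology=` header tags, 70 columns per line.
#'
#' @param genomes A `genome` or list of `genome` objects.
#' @param path Output path.
#' @export
write_fasta <- function(genomes, path) {
  genomes <- as_genome_list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(seqs) <- vapply(genomes, function(g) {
    sprintf("%s role=%s topology=%s", g$id, g$role, g$topology)
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

as_genome_list <- function(x) {
  if (inherits(x, "genome")) x <- list(x)
  stopifnot(all(vapply(x, inherits, TRUE, "genome")))
  names(x) <- vapply(x, `[[`, "", "id")
  x
}

#' Reverse complement
#'
#' An involution on DNA strings; `N` maps to `N`. Vectorized over input.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Construct an interval table
#'
#' Intervals are 0-based half-open on a named sequence. A feature spanning a
#' circular origin is represented as an ordered pair of intervals, never with
#' `end < start`.
#'
#' @param seq_id Sequence identifiers.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` with columns `seq_id`, `start`, `end`, `strand`.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  n <- length(start)
  d <- data.frame(seq_id = rep_len(as.character(seq_id), n),
                  start = as.integer(start), end = as.integer(end),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  if (any(d$start < 0L) || any(d$end <= d$start)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  d
}

#' Total length covered by a set of intervals
#'
#' Overlapping bases are counted once. All intervals must lie on the same
#' sequence.
#'
#' @param intervals An interval table (see [interval()]), or any data.frame
#'   with `start`/`end` columns (0-based half-open).
#' @return Total covered length in bp.
#' @export
interval_union_length <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0L)
  if ("seq_id" %in% names(intervals) &&
      length(unique(intervals$seq_id)) > 1L) {
    stop("intervals lie on more than one sequence")
  }
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Canonical rotation of a circular sequence
#'
#' The lexicographically minimal rotation of the smaller of the sequence and
#' its reverse complement. Deterministic, so independently assembled copies
#' of the same circular molecule linearize identically.
#'
#' @param seq A DNA string.
#' @return The canonically rotated string.
#' @export
canonical_rotation <- function(seq) {
  rot <- function(s) {
    i <- cpp_min_rotation(s)
    if (i == 0L) s else paste0(substr(s, i + 1L, nchar(s)), substr(s, 1L, i))
  }
  a <- rot(seq)
  b <- rot(revcomp(seq))
  if (a <= b) a else b
}

#' Construct a feature table
#'
#' @param seq_id,start,end,strand Interval fields (0-based half-open).
#' @param kind One of `gene`, `rRNA`, `tRNA`, `ORF`, `MTPT`, `other`.
#' @param name Non-empty feature names. ORFs must have length divisible by 3.
#' @return A `data.frame` feature table.
#' @export
feature_table <- function(seq_id, start, end, strand = "+", kind = "gene",
                          name) {
  d <- interval(seq_id, start, end, strand)
  kind <- rep_len(as.character(kind), nrow(d))
  ok <- kind %in% c("gene", "rRNA", "tRNA", "ORF", "MTPT", "other")
  if (!all(ok)) stop("unknown feature kind: ", paste(unique(kind[!ok]), collapse = ", "))
  name <- rep_len(as.character(name), nrow(d))
  if (any(!nzchar(name))) stop("feature names must be non-empty")
  orf <- kind == "ORF"
  if (any(orf) && any((d$end[orf] - d$start[orf]) %% 3L != 0L)) {
    stop("ORF lengths must be divisible by 3")
  }
  d$kind <- kind
  d$name <- name
  d
}

#' Write a feature table as GFF3
#'
#' Converts internal 0-based half-open coordinates to 1-based inclusive.
#' Output ordering is by sequence, then start, then name (deterministic).
#'
#' @param features A feature table (see [feature_table()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(features, path, source = "orgEGT") {
  o <- order(features$seq_id, features$start, features$name)
  f <- features[o, , drop = FALSE]
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tName=%s", f$seq_id, source,
                     f$kind, f$start + 1L, f$end, f$strand, f$name))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' BED keeps 0-based half-open coordinates. Score is `round(1000 * score)`
#' clamped to `[0, 1000]`.
#'
#' @param intervals Interval table with optional `name` and `score` columns
#'   (score on a 0-1 scale).
#' @param path Output path.
#' @export
write_bed6 <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", n)
  score <- if ("score" %in% names(intervals)) {
    pmin(1000L, pmax(0L, as.integer(round(1000 * intervals$score))))
  } else rep(0L, n)
  o <- order(intervals$seq_id, intervals$start, intervals$end)
  d <- data.frame(intervals$seq_id, intervals$start, intervals$end, name,
                  score, intervals$strand)[o, , drop = FALSE]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Plastome quadripartite structure
#'
#' The four intervals must partition the plastome with no gaps or overlaps,
#' in the order LSC, IRa, SSC, IRb, and the IRb sequence must equal the
#' reverse complement of the IRa sequence.
#'
#' @param lsc,ira,ssc,irb Single-row interval tables on the plastome.
#' @param plastome The plastome `genome` (used to validate the partition).
#' @return A `plastome_structure` object.
#' @export
plastome_structure <- function(lsc, ira, ssc, irb, plastome = NULL) {
  parts <- list(lsc = lsc, ira = ira, ssc = ssc, irb = irb)
  stopifnot(all(vapply(parts, nrow, 0L) == 1L))
  if (!is.null(plastome)) {
    L <- nchar(plastome$seq)
    bounds <- c(lsc$start, lsc$end, ira$start, ira$end, ssc$start, ssc$end,
                irb$start, irb$end)
    if (lsc$start != 0L || irb$end != L ||
        lsc$end != ira$start || ira$end != ssc$start || ssc$end != irb$start) {
      stop("LSC, IRa, SSC, IRb must partition the plastome in order")
    }
    ira_seq <- substr(plastome$seq, ira$start + 1L, ira$end)
    irb_seq <- substr(plastome$seq, irb$start + 1L, irb$end)
    if (!identical(revcomp(ira_seq), irb_seq)) {
      stop("IRb sequence must be the reverse complement of IRa")
    }
  }
  structure(parts, class = "plastome_structure")
}
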