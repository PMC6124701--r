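# Synthetic genome, transfer-event and read generator.
#
# Defaults are a ~1/10 linear scale-down of a Solanum-like genome trio:
# quadripartite plastome, repeat-rich circular mitogenome carrying plastome
# implants (MTPTs), and nuclear chromosomes carrying scattered small and
# clustered large organellar implants (NUMTs/NUPTs) degraded by
# substitutions and indels. Every implant is logged in a ground-truth event
# table, the oracle for recovery benchmarking.
#
# Implant breakpoints are disambiguated: the host base flanking an implant
# is redrawn whenever it equals the source-genome continuation base. A
# chance-matching flank is indistinguishable from a longer transfer, so
# without this step the true transferred length is ill-defined by 1-2 bp.

#' Simulation configuration
#'
#' Lengths are in bp, depth in fold coverage, divergence as a substitution
#' fraction (indels are applied at one tenth the substitution rate).
#'
#' @param seed Integer seed; all stages derive their streams from it.
#' @param plastome_len,ir_len,ssc_len Plastome geometry; the LSC takes the
#'   remainder, so `2 * ir_len + ssc_len < plastome_len` is required.
#' @param mito_len Mitogenome length.
#' @param repeat_spec List of `list(len, orientation, copies)` exact repeat
#'   families to implant in the mitogenome.
#' @param mtpt_spec List of `list(len, compartment)` plastome segments to
#'   implant in the mitogenome (compartment one of `"LSC"`, `"SSC"`, `"IR"`).
#' @param n_chromosomes,chrom_len Nuclear chromosome count and length.
#' @param numt_spec,nupt_spec Lists of
#'   `list(len, count, divergence, clustered)` nuclear implant groups from
#'   the mitogenome / plastome.
#' @param read_len,insert_mean,insert_sd,depth,error_rate Paired-end read
#'   simulation parameters.
#' @param gc Background GC content.
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       plastome_len = 15500L, ir_len = 2550L, ssc_len = 1850L,
                       mito_len = 42400L,
                       repeat_spec = list(
                         list(len = 2000L, orientation = "direct", copies = 2L),
                         list(len = 300L, orientation = "inverted", copies = 2L),
                         list(len = 150L, orientation = "direct", copies = 2L)),
                       mtpt_spec = list(
                         list(len = 256L, compartment = "LSC"),
                         list(len = 32L, compartment = "SSC"),
                         list(len = 701L, compartment = "IR")),
                       n_chromosomes = 3L, chrom_len = 100000L,
                       numt_spec = list(
                         list(len = 150L, count = 10L, divergence = 0.02, clustered = FALSE),
                         list(len = 400L, count = 5L, divergence = 0.02, clustered = FALSE),
                         list(len = 1500L, count = 3L, divergence = 0.01, clustered = TRUE)),
                       nupt_spec = list(
                         list(len = 120L, count = 8L, divergence = 0.02, clustered = FALSE),
                         list(len = 300L, count = 4L, divergence = 0.02, clustered = FALSE),
                         list(len = 1200L, count = 3L, divergence = 0.01, clustered = TRUE)),
                       read_len = 100L, insert_mean = 400L, insert_sd = 60L,
                       depth = 200, error_rate = 0, gc = 0.45) {
  cfg <- list(seed = as.integer(seed), plastome_len = as.integer(plastome_len),
              ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
              mito_len = as.integer(mito_len), repeat_spec = repeat_spec,
              mtpt_spec = mtpt_spec, n_chromosomes = as.integer(n_chromosomes),
              chrom_len = as.integer(chrom_len), numt_spec = numt_spec,
              nupt_spec = nupt_spec, read_len = as.integer(read_len),
              insert_mean = as.integer(insert_mean),
              insert_sd = as.numeric(insert_sd), depth = as.numeric(depth),
              error_rate = as.numeric(error_rate), gc = as.numeric(gc))
  lens <- c(cfg$plastome_len, cfg$ir_len, cfg$ssc_len, cfg$mito_len,
            cfg$chrom_len, cfg$read_len, cfg$insert_mean)
  if (any(lens <= 0L)) stop("all lengths must be positive")
  if (cfg$ir_len < 1L || 2L * cfg$ir_len + cfg$ssc_len >= cfg$plastome_len) {
    stop("plastome geometry requires 2*ir_len + ssc_len < plastome_len")
  }
  if (cfg$depth < 1) stop("depth must be >= 1")
  for (sp in c(cfg$numt_spec, cfg$nupt_spec)) {
    if (sp$divergence < 0 || sp$divergence > 0.3) {
      stop("divergence must be in [0, 0.3]")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Random background DNA
#'
#' I.i.d. bases at a given GC content.
#'
#' @param n Length in bp.
#' @param gc GC fraction.
#' @return A DNA string.
#' @export
random_seq <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

empty_truth <- function() {
  data.frame(class = character(0), source_id = character(0),
             source_start = integer(0), source_end = integer(0),
             target_id = character(0), target_start = integer(0),
             target_end = integer(0), orientation = character(0),
             divergence_applied = numeric(0), indels_applied = integer(0),
             stringsAsFactors = FALSE)
}

truth_row <- function(class, source_id, s1, s2, target_id, t1, t2,
                      orientation = "direct", divergence = 0, indels = 0L) {
  data.frame(class = class, source_id = source_id, source_start = as.integer(s1),
             source_end = as.integer(s2), target_id = target_id,
             target_start = as.integer(t1), target_end = as.integer(t2),
             orientation = orientation, divergence_applied = divergence,
             indels_applied = as.integer(indels), stringsAsFactors = FALSE)
}

# Rejection-sample a free target interval of length len in [0, n), keeping a
# 1 bp margin to earlier implants so flank disambiguation never touches them.
pick_free <- function(n, len, occupied, tries = 2000L) {
  for (i in seq_len(tries)) {
    s <- sample.int(n - len - 2L, 1L)  # 1-based start > 1, end < n
    cand <- c(s - 1L, s + len + 1L)    # with margins, 1-based inclusive
    ok <- TRUE
    if (nrow(occupied)) {
      ok <- all(cand[2] <= occupied$s | cand[1] >= occupied$e)
    }
    if (ok) return(s)
  }
  stop("cannot place implant of length ", len,
       ": requested implants exceed available genome space")
}

other_base <- function(b) {
  alt <- setdiff(c("A", "C", "G", "T"), b)
  sample(alt, 1L)
}

# Overwrite host[t..t+len) (1-based t) with frag, then redraw every host
# base within the disambiguation window that equals the corresponding
# source-continuation base. left_cont/right_cont are the source bases
# immediately left/right of the copied segment, in genome order. With
# every window base mismatching, an X-drop extension (default 20, mismatch
# -2) must terminate at the true boundary, so implanted lengths are
# recovered exactly.
BREAKPOINT_WINDOW <- 12L

implant_overwrite <- function(host, t, frag, left_cont, right_cont) {
  len <- nchar(frag)
  before <- substr(host, 1L, t - 1L)
  after <- substr(host, t + len, nchar(host))
  nb <- nchar(before)
  for (i in seq_len(min(nchar(left_cont), nb))) {
    cb <- substr(left_cont, nchar(left_cont) - i + 1L, nchar(left_cont) - i + 1L)
    if (substr(before, nb - i + 1L, nb - i + 1L) == cb) {
      substr(before, nb - i + 1L, nb - i + 1L) <- other_base(cb)
    }
  }
  for (i in seq_len(min(nchar(right_cont), nchar(after)))) {
    cb <- substr(right_cont, i, i)
    if (substr(after, i, i) == cb) {
      substr(after, i, i) <- other_base(cb)
    }
  }
  paste0(before, frag, after)
}

#' Simulate a quadripartite plastome
#'
#' LSC + IRa + SSC + IRb with IRb the exact reverse complement of IRa;
#' circular topology. Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return `list(genome, structure)` with a [plastome_structure()].
#' @export
simulate_plastome <- function(cfg) {
  set.seed(cfg$seed + 101L)
  lsc_len <- cfg$plastome_len - 2L * cfg$ir_len - cfg$ssc_len
  lsc <- random_seq(lsc_len, cfg$gc)
  ira <- random_seq(cfg$ir_len, cfg$gc)
  ssc <- random_seq(cfg$ssc_len, cfg$gc)
  seq <- paste0(lsc, ira, ssc, revcomp(ira))
  g <- genome("plastome_sim", seq, topology = "circular", role = "plastome")
  st <- plastome_structure(
    lsc = interval("plastome_sim", 0L, lsc_len),
    ira = interval("plastome_sim", lsc_len, lsc_len + cfg$ir_len),
    ssc = interval("plastome_sim", lsc_len + cfg$ir_len,
                   lsc_len + cfg$ir_len + cfg$ssc_len),
    irb = interval("plastome_sim", lsc_len + cfg$ir_len + cfg$ssc_len,
                   cfg$plastome_len),
    plastome = g)
  list(genome = g, structure = st)
}

#' Simulate a repeat-rich mitogenome with plastome implants
#'
#' Exact repeat families (direct and inverted) and MTPT segments copied
#' verbatim from the plastome are implanted into random background sequence;
#' every event is logged. Implants overwrite background, so the emitted
#' genome has exactly `mito_len` bp.
#'
#' @param cfg A [sim_config()].
#' @param plastome Output of [simulate_plastome()] (required when
#'   `mtpt_spec` is non-empty).
#' @return `list(genome, truth)`.
#' @export
simulate_mitogenome <- function(cfg, plastome = NULL) {
  set.seed(cfg$seed + 102L)
  n <- cfg$mito_len
  total_implant <- sum(vapply(cfg$repeat_spec, function(r) r$len * r$copies, 0)) +
    sum(vapply(cfg$mtpt_spec, function(m) m$len, 0))
  if (total_implant > 0.8 * n) {
    stop("requested repeats and implants exceed genome length")
  }
  seq <- random_seq(n, cfg$gc)
  occupied <- data.frame(s = integer(0), e = integer(0))
  truth <- empty_truth()
  W <- BREAKPOINT_WINDOW
  occupy <- function(s, len) { # margin covers the disambiguation window
    occupied[nrow(occupied) + 1L, ] <<- c(s - 1L - W, s + len + 1L + W)
  }
  for (sp in cfg$repeat_spec) {
    len <- sp$len
    src <- pick_free(n, len, occupied)
    occupy(src, len)
    src_seq <- substr(seq, src, src + len - 1L)
    for (cp in seq_len(sp$copies - 1L)) {
      tgt <- pick_free(n, len, occupied)
      occupy(tgt, len)
      if (sp$orientation == "direct") {
        frag <- src_seq
        lc <- substr(seq, max(1L, src - W), src - 1L)
        rc <- substr(seq, src + len, min(n, src + len - 1L + W))
      } else {
        frag <- revcomp(src_seq)
        # an inverted pair extends when the target flank equals the
        # complement of the source flank on the opposite side
        lc <- revcomp(substr(seq, src + len, min(n, src + len - 1L + W)))
        rc <- revcomp(substr(seq, max(1L, src - W), src - 1L))
      }
      seq <- implant_overwrite(seq, tgt, frag, lc, rc)
      truth <- rbind(truth, truth_row("repeat", "mito_sim", src - 1L,
                                      src - 1L + len, "mito_sim", tgt - 1L,
                                      tgt - 1L + len, sp$orientation))
    }
  }
  if (length(cfg$mtpt_spec)) {
    if (is.null(plastome)) stop("plastome required when mtpt_spec is non-empty")
    pg <- plastome$genome$seq
    st <- plastome$structure
    for (sp in cfg$mtpt_spec) {
      len <- sp$len
      comp <- switch(sp$compartment, LSC = st$lsc, SSC = st$ssc, IR = st$ira,
                     stop("unknown compartment: ", sp$compartment))
      lo <- comp$start + 2L
      hi <- comp$end - len - 1L
      if (hi < lo) stop("MTPT of length ", len, " does not fit in ", sp$compartment)
      src <- sample(lo:hi, 1L) + 1L  # 1-based
      frag <- substr(pg, src, src + len - 1L)
      tgt <- pick_free(n, len, occupied)
      occupy(tgt, len)
      seq <- implant_overwrite(seq, tgt, frag,
                               substr(pg, max(1L, src - W), src - 1L),
                               substr(pg, src + len,
                                      min(nchar(pg), src + len - 1L + W)))
      truth <- rbind(truth, truth_row("MTPT", "plastome_sim", src - 1L,
                                      src - 1L + len, "mito_sim", tgt - 1L,
                                      tgt - 1L + len))
    }
  }
  g <- genome("mito_sim", seq, topology = "circular", role = "mitogenome")
  list(genome = g, truth = truth)
}

# Substitutions at rate `divergence` (uniform over the 3 alternatives) plus
# indels at divergence/10, geometric lengths capped at 10 bp.
mutate_fragment <- function(frag, divergence) {
  if (divergence <= 0) return(list(seq = frag, indels = 0L))
  b <- strsplit(frag, "")[[1]]
  n <- length(b)
  subs <- which(runif(n) < divergence)
  for (i in subs) b[i] <- other_base(b[i])
  n_indel_sites <- rbinom(1L, n, divergence / 10)
  if (n_indel_sites > 0L) {
    sites <- sort(sample.int(n, n_indel_sites), decreasing = TRUE)
    for (s in sites) {
      len <- min(rgeom(1L, 0.5) + 1L, 10L)
      if (runif(1) < 0.5) { # deletion
        keep <- setdiff(seq_along(b), s:min(n, s + len - 1L))
        b <- b[keep]
      } else { # insertion
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        b <- append(b, ins, after = s)
      }
      n <- length(b)
    }
  }
  list(seq = paste(b, collapse = ""), indels = n_indel_sites)
}

#' Simulate nuclear chromosomes with organellar implants
#'
#' Implants are drawn from the mitogenome (`numt_spec`) and plastome
#' (`nupt_spec`), mutated by their stated divergence (substitutions plus
#' indels at one tenth the rate), and placed either scattered or tightly
#' clustered (all fragments of a clustered group inside one window at most
#' 5x their total length, with spacers up to 500 bp). All events are logged.
#'
#' @param cfg A [sim_config()].
#' @param mito,plastome Outputs of the organellar simulators.
#' @return `list(genomes, truth)`.
#' @export
simulate_nuclear <- function(cfg, mito, plastome) {
  set.seed(cfg$seed + 103L)
  n <- cfg$chrom_len
  chroms <- lapply(seq_len(cfg$n_chromosomes), function(i) {
    random_seq(n, cfg$gc)
  })
  names(chroms) <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  occ <- lapply(chroms, function(x) data.frame(s = integer(0), e = integer(0)))
  truth <- empty_truth()
  cluster_chrom <- 0L

  place_group <- function(sp, klass, org_seq, org_id) {
    lens <- rep(sp$len, sp$count)
    if (any(lens >= n)) stop("implant longer than chromosome")
    if (isTRUE(sp$clustered)) {
      cluster_chrom <<- (cluster_chrom %% cfg$n_chromosomes) + 1L
      ci <- cluster_chrom
      spacers <- pmin(floor(runif(sp$count - 1L, 50, 500)), 500L)
      window <- sum(lens) + sum(spacers)
      stopifnot(window <= 5L * sum(lens))
      w0 <- pick_free(n, window, occ[[ci]])
      occ[[ci]][nrow(occ[[ci]]) + 1L, ] <<-
        c(w0 - 1L - BREAKPOINT_WINDOW, w0 + window + 1L + BREAKPOINT_WINDOW)
      pos <- w0
      for (j in seq_len(sp$count)) {
        implant_one(klass, org_seq, org_id, ci, sp$len, sp$divergence, pos)
        pos <- pos + lens[j] + if (j < sp$count) spacers[j] else 0L
      }
    } else {
      for (j in seq_len(sp$count)) {
        ci <- sample.int(cfg$n_chromosomes, 1L)
        implant_one(klass, org_seq, org_id, ci, sp$len, sp$divergence, NULL)
      }
    }
  }

  implant_one <- function(klass, org_seq, org_id, ci, len, divergence, at) {
    on <- nchar(org_seq)
    W <- BREAKPOINT_WINDOW
    src <- sample.int(on - len - 2L * W, 1L) + W # continuation windows inside
    frag <- substr(org_seq, src, src + len - 1L)
    mut <- mutate_fragment(frag, divergence)
    tlen <- nchar(mut$seq)
    tgt <- if (is.null(at)) {
      t <- pick_free(n, tlen, occ[[ci]])
      occ[[ci]][nrow(occ[[ci]]) + 1L, ] <<-
        c(t - 1L - BREAKPOINT_WINDOW, t + tlen + 1L + BREAKPOINT_WINDOW)
      t
    } else at
    chroms[[ci]] <<- implant_overwrite(chroms[[ci]], tgt, mut$seq,
                                       substr(org_seq, max(1L, src - W), src - 1L),
                                       substr(org_seq, src + len,
                                              min(on, src + len - 1L + W)))
    truth <<- rbind(truth, truth_row(klass, org_id, src - 1L, src - 1L + len,
                                     names(chroms)[ci], tgt - 1L,
                                     tgt - 1L + tlen, "direct", divergence,
                                     mut$indels))
  }

  # clustered groups need long free windows: place them before scattered
  # implants fragment the chromosomes
  specs <- c(lapply(cfg$numt_spec, function(sp) c(sp, klass = "NUMT")),
             lapply(cfg$nupt_spec, function(sp) c(sp, klass = "NUPT")))
  ord <- order(!vapply(specs, function(sp) isTRUE(sp$clustered), TRUE),
               -vapply(specs, function(sp) sp$len * sp$count, 0))
  for (sp in specs[ord]) {
    if (sp$klass == "NUMT") place_group(sp, "NUMT", mito$genome$seq, "mito_sim")
    else place_group(sp, "NUPT", plastome$genome$seq, "plastome_sim")
  }
  genomes <- mapply(function(s, id) {
    genome(id, s, topology = "linear", role = "nuclear_chromosome")
  }, chroms, names(chroms), SIMPLIFY = FALSE)
  list(genomes = genomes, truth = truth)
}

#' Simulate paired-end reads
#'
#' Insert sizes are Normal(insert_mean, insert_sd) truncated at twice the
#' read length; start positions are uniform, honoring circular topology;
#' fragments take either strand with equal probability. Mixture weights
#' scale per-genome depth, so plastome-derived reads can over-represent
#' shared MTPT regions. Per-base errors at `error_rate`; qualities are a
#' constant Q40.
#'
#' @param genomes A `genome` or list of genomes.
#' @param cfg A [sim_config()].
#' @param weights Named (or recycled) per-genome depth multipliers.
#' @return A `read_set`: `list(r1, r2, origins)`.
#' @export
simulate_reads <- function(genomes, cfg, weights = 1) {
  set.seed(cfg$seed + 104L)
  genomes <- as_genome_list(genomes)
  weights <- rep_len(weights, length(genomes))
  rl <- cfg$read_len
  r1 <- character(0); r2 <- character(0)
  origins <- NULL
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    L <- nchar(g$seq)
    if (rl > L) stop("read length exceeds genome length for ", g$id)
    npair <- round(cfg$depth * weights[gi] * L / (2 * rl))
    if (npair < 1L) next
    ins <- pmax(2L * rl, as.integer(round(rnorm(npair, cfg$insert_mean,
                                                cfg$insert_sd))))
    if (g$topology == "circular") {
      ins <- pmin(ins, L)
      starts <- sample.int(L, npair, replace = TRUE) # 1-based
      doubled <- paste0(g$seq, g$seq)
      frags <- substring(doubled, starts, starts + ins - 1L)
    } else {
      ins <- pmin(ins, L)
      starts <- floor(runif(npair, 1, L - ins + 1 + 1))
      frags <- substring(g$seq, starts, starts + ins - 1L)
    }
    flip <- runif(npair) < 0.5
    frags[flip] <- revcomp(frags[flip])
    a <- substring(frags, 1L, rl)
    b <- revcomp(substring(frags, ins - rl + 1L, ins))
    if (cfg$error_rate > 0) {
      a <- add_errors(a, cfg$error_rate)
      b <- add_errors(b, cfg$error_rate)
    }
    r1 <- c(r1, a); r2 <- c(r2, b)
    origins <- rbind(origins, data.frame(
      genome = g$id, start = starts - 1L, end = starts - 1L + ins,
      strand = ifelse(flip, "-", "+"), stringsAsFactors = FALSE))
  }
  structure(list(r1 = r1, r2 = r2, origins = origins), class = "read_set")
}

add_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    b <- strsplit(r, "")[[1]]
    hit <- which(runif(length(b)) < rate)
    for (i in hit) b[i] <- other_base(b[i])
    paste(b, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d pairs, read length %d\n", length(x$r1),
              if (length(x$r1)) nchar(x$r1[1]) else 0L))
  invisible(x)
}

#' Write a read set as a FASTQ pair
#'
#' Constant Q40 qualities; files are `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#'
#' @param reads A `read_set`.
#' @param prefix Output path prefix.
#' @export
write_reads <- function(reads, prefix) {
  ids <- sprintf("read%06d", seq_along(reads$r1))
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(if (mate == 1) reads$r1 else reads$r2)
    names(seqs) <- paste0(ids, "/", mate)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, sprintf("%s_%d.fastq", prefix, mate),
                                format = "fastq", qualities = qual)
  }
  invisible(prefix)
}

#' Read a FASTQ pair into a read set
#'
#' @param path1,path2 FASTQ paths for the two mates.
#' @return A `read_set` (without origin information).
#' @export
read_reads <- function(path1, path2) {
  r1 <- as.character(Biostrings::readDNAStringSet(path1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(path2, format = "fastq"))
  if (length(r1) != length(r2)) stop("mate files have different read counts")
  structure(list(r1 = unname(r1), r2 = unname(r2), origins = NULL),
            class = "read_set")
}

#' Derive structural variants of a genome
#'
#' Applies segment inversions and unique-segment insertions; used to emulate
#' a trio of rearranged mitogenomes that share most of their sequence. Each
#' edit is logged.
#'
#' @param g A `genome`.
#' @param n_inversions Number of random inversions.
#' @param inversion_len Length of each inverted segment.
#' @param n_insertions Number of random novel-segment insertions.
#' @param insertion_len Length of each inserted segment.
#' @param new_id Identifier of the derived genome.
#' @param seed Integer seed.
#' @return `list(genome, edits)`.
#' @export
apply_structural_variants <- function(g, n_inversions = 2L,
                                      inversion_len = 4000L,
                                      n_insertions = 1L,
                                      insertion_len = 1000L,
                                      new_id = paste0(g$id, "_var"),
                                      seed = 1L) {
  set.seed(seed)
  seq <- g$seq
  edits <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(n_inversions)) {
    L <- nchar(seq)
    s <- sample.int(L - inversion_len - 1L, 1L)
    seg <- substr(seq, s + 1L, s + inversion_len)
    seq <- paste0(substr(seq, 1L, s), revcomp(seg),
                  substr(seq, s + inversion_len + 1L, L))
    edits <- rbind(edits, data.frame(type = "inversion", start = s,
                                     end = s + inversion_len))
  }
  for (i in seq_len(n_insertions)) {
    L <- nchar(seq)
    s <- sample.int(L - 1L, 1L)
    seq <- paste0(substr(seq, 1L, s), random_seq(insertion_len),
                  substr(seq, s + 1L, L))
    edits <- rbind(edits, data.frame(type = "insertion", start = s,
                                     end = s + insertion_len))
  }
  list(genome = genome(new_id, seq, topology = g$topology, role = g$role),
       edits = edits)
}

#' Annotate random non-overlapping gene models
#'
#' A stand-in for a supplied gene annotation: gene intervals are placed
#' uniformly without overlap; a configurable number of gene names appear
#' twice (duplicated genes).
#'
#' @param g A `genome`.
#' @param n_genes Number of distinct gene names.
#' @param gene_len Length of each gene.
#' @param n_duplicated How many names get a second copy.
#' @param seed Integer seed.
#' @return A feature table.
#' @export
simulate_annotation <- function(g, n_genes = 25L, gene_len = 900L,
                                n_duplicated = 2L, seed = 1L) {
  set.seed(seed)
  L <- nchar(g$seq)
  # cap gene count so the models occupy at most ~60% of the genome
  cap <- max(1L, floor(0.6 * L / gene_len) - n_duplicated)
  n_genes <- min(n_genes, cap)
  n_duplicated <- min(n_duplicated, n_genes)
  total <- n_genes + n_duplicated
  occupied <- data.frame(s = integer(0), e = integer(0))
  starts <- integer(total)
  for (i in seq_len(total)) {
    s <- pick_free(L, gene_len, occupied)
    occupied[nrow(occupied) + 1L, ] <- c(s - 1L, s + gene_len + 1L)
    starts[i] <- s - 1L
  }
  nm <- c(sprintf("gene%02d", seq_len(n_genes)),
          sprintf("gene%02d", seq_len(n_duplicated)))
  feature_table(g$id, starts, starts + gene_len,
                strand = sample(c("+", "-"), total, replace = TRUE),
                kind = "gene", name = nm)
}

#' Write a ground-truth event table as JSON
#'
#' @param truth Event table from the simulators.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", digits = NA)
  invisible(path)
}
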