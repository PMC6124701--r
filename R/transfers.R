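# Intracellular transfer calling and summarization.
#
# Classes follow the genome roles: plastome -> mitogenome hits are MTPTs,
# mitogenome -> nucleus NUMTs, plastome -> nucleus NUPTs. Direction of
# mito/nuclear sharing is not inferred: every shared segment is a NUMT.
# Multiple hits at one host locus caused by duplicated regions of the
# organellar query are eliminated (best score kept) to avoid
# overestimating transfer; hits to the two plastome IR copies are
# projected onto one IR before compartment totals are taken.

transfer_class <- function(org_role, host_role) {
  if (org_role == "plastome" && host_role == "mitogenome") return("MTPT")
  if (org_role == "mitogenome" && host_role == "nuclear_chromosome") return("NUMT")
  if (org_role == "plastome" && host_role == "nuclear_chromosome") return("NUPT")
  stop("no transfer class for ", org_role, " -> ", host_role)
}

empty_calls <- function() {
  data.frame(klass = character(0), chrom = character(0), tstart = integer(0),
             tend = integer(0), source_id = character(0), sstart = integer(0),
             send = integer(0), strand = character(0), length = integer(0),
             identity = numeric(0), evalue = numeric(0), score = numeric(0),
             deduped = logical(0), compartment = character(0),
             stringsAsFactors = FALSE)
}

#' Call organellar-DNA transfers into a host genome
#'
#' Runs the homology search with the organelle as query against each host
#' sequence and emits one transfer call per retained HSP. The call's target
#' is the host-side interval, its source the organellar counterpart; length
#' is the host-side length.
#'
#' @param organelle The organellar `genome` (query).
#' @param hosts A host `genome` or list of host genomes.
#' @param params [homology_params()] (word size 11, e-value 1e-5 and 50,000
#'   max hits by default).
#' @return A transfer-call table.
#' @export
call_transfers <- function(organelle, hosts, params = homology_params()) {
  hosts <- as_genome_list(hosts)
  out <- empty_calls()
  for (h in hosts) {
    kl <- transfer_class(organelle$role, h$role)
    hs <- find_hsps(organelle, h, params)
    if (nrow(hs) == 0L) next
    out <- rbind(out, data.frame(
      klass = kl, chrom = h$id, tstart = hs$sstart, tend = hs$send,
      source_id = organelle$id, sstart = hs$qstart, send = hs$qend,
      strand = hs$strand, length = hs$send - hs$sstart,
      identity = hs$identity, evalue = hs$evalue, score = hs$score,
      deduped = FALSE, compartment = NA_character_,
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$tstart, out$tend), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Eliminate repeat-induced multiple hits
#'
#' Organellar duplicated regions make one host locus match several source
#' copies. Among calls whose target intervals overlap reciprocally by at
#' least 50% and whose source intervals lie in members of the same exact
#' repeat family, only the best-scoring call is kept (marked `deduped`);
#' calls not implicated by any repeat pass through unchanged. Idempotent.
#'
#' @param calls A transfer-call table.
#' @param organelle_repeats Output of [find_exact_repeats()] on the source
#'   genome.
#' @return The deduplicated call table.
#' @export
dedup_repeat_hits <- function(calls, organelle_repeats) {
  if (nrow(calls) == 0L || nrow(organelle_repeats) == 0L) return(calls)
  # repeat members; family = connected component linking pair members and
  # overlapping members
  mem <- data.frame(
    start = c(organelle_repeats$a_start, organelle_repeats$b_start),
    end = c(organelle_repeats$a_end, organelle_repeats$b_end),
    pair = rep(seq_len(nrow(organelle_repeats)), 2L))
  parent <- seq_len(nrow(mem))
  link <- function(i, j) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  np <- nrow(organelle_repeats)
  for (p in seq_len(np)) link(p, p + np)
  ir <- IRanges::IRanges(mem$start + 1L, mem$end)
  ov <- IRanges::findOverlaps(ir, ir)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(ir[qh], ir[sh]))
  ok <- qh < sh & w >= 0.5 * pmin(IRanges::width(ir)[qh], IRanges::width(ir)[sh])
  for (x in which(ok)) link(qh[x], sh[x])
  fam <- vapply(seq_len(nrow(mem)), function(i) uf_find(parent, i), 0L)

  # implicate calls: source interval overlapping a member by >= 50% of the
  # call's source length
  cir <- IRanges::IRanges(calls$sstart + 1L, calls$send)
  ov <- IRanges::findOverlaps(cir, ir)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(cir[qh], ir[sh]))
  good <- w >= 0.5 * IRanges::width(cir)[qh]
  call_fam <- rep(NA_integer_, nrow(calls))
  for (x in which(good)) {
    i <- qh[x]
    if (is.na(call_fam[i])) call_fam[i] <- fam[sh[x]]
  }

  drop <- rep(FALSE, nrow(calls))
  idx <- which(!is.na(call_fam))
  if (length(idx) > 1L) {
    for (ch in unique(calls$chrom[idx])) {
      ii <- idx[calls$chrom[idx] == ch]
      for (f in unique(call_fam[ii])) {
        jj <- ii[call_fam[ii] == f]
        if (length(jj) < 2L) next
        # group by reciprocal >= 50% target overlap (connected components)
        tp <- seq_along(jj)
        for (a in seq_along(jj)) for (b in seq_along(jj)) {
          if (a >= b) next
          ia <- jj[a]; ib <- jj[b]
          o <- min(calls$tend[ia], calls$tend[ib]) -
            max(calls$tstart[ia], calls$tstart[ib])
          la <- calls$tend[ia] - calls$tstart[ia]
          lb <- calls$tend[ib] - calls$tstart[ib]
          if (o >= 0.5 * la && o >= 0.5 * lb) {
            ra <- uf_find(tp, a); rb <- uf_find(tp, b)
            tp[max(ra, rb)] <- min(ra, rb)
          }
        }
        groups <- vapply(seq_along(jj), function(i) uf_find(tp, i), 0L)
        for (grp in unique(groups)) {
          kk <- jj[groups == grp]
          if (length(kk) < 2L) next
          best <- kk[which.max(calls$score[kk])]
          calls$deduped[best] <- TRUE
          drop[setdiff(kk, best)] <- TRUE
        }
      }
    }
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

project_ir <- function(st, en, ira, irb) {
  # map an interval inside IRb onto IRa coordinates (reverse complement
  # position mapping)
  ns <- ira$start + (irb$end - en)
  ne <- ira$start + (irb$end - st)
  c(ns, ne)
}

#' Attribute plastome-sourced calls to LSC/SSC/IR and total by compartment
#'
#' Each call's source interval is intersected with the plastome
#' compartments; the call is labeled with the compartment holding the
#' majority of its source. Per-compartment totals are union lengths of the
#' source-side coverage with hits to IRb projected onto IRa first, so the
#' two IR copies are counted once. Also emits the host-side union total and
#' its percentage of the host genome.
#'
#' @param calls Plastome-sourced transfer calls (MTPT or NUPT).
#' @param structure A [plastome_structure()]; if `NULL`, compartments stay
#'   `NA` with a warning.
#' @param host_len Host genome length for the percentage (optional).
#' @return `list(calls, totals)` where `totals` has LSC/SSC/IR/total bp on
#'   the plastome side, plus `host_bp` and `host_pct`.
#' @export
attribute_compartment <- function(calls, structure, host_len = NA_real_) {
  if (is.null(structure)) {
    warning("plastome structure missing: compartments set to NA")
    return(list(calls = calls,
                totals = c(LSC = NA_real_, SSC = NA_real_, IR = NA_real_,
                           total = NA_real_, host_bp = NA_real_,
                           host_pct = NA_real_)))
  }
  comp_of <- function(st, en) {
    ov <- function(iv) max(0L, min(en, iv$end) - max(st, iv$start))
    o <- c(LSC = ov(structure$lsc), SSC = ov(structure$ssc),
           IR = ov(structure$ira) + ov(structure$irb))
    names(o)[which.max(o)]
  }
  if (nrow(calls)) {
    calls$compartment <- vapply(seq_len(nrow(calls)), function(i) {
      comp_of(calls$sstart[i], calls$send[i])
    }, "")
  }
  # source-side coverage with IRb projected onto IRa
  st <- calls$sstart; en <- calls$send
  pieces_s <- integer(0); pieces_e <- integer(0)
  for (i in seq_along(st)) {
    segs <- list(c(st[i], en[i]))
    for (seg in segs) {
      a <- seg[1]; b <- seg[2]
      # split against IRb, project that part
      ib_s <- max(a, structure$irb$start); ib_e <- min(b, structure$irb$end)
      if (ib_s < ib_e) {
        pr <- project_ir(ib_s, ib_e, structure$ira, structure$irb)
        pieces_s <- c(pieces_s, pr[1]); pieces_e <- c(pieces_e, pr[2])
      }
      if (a < structure$irb$start) {
        pieces_s <- c(pieces_s, a)
        pieces_e <- c(pieces_e, min(b, structure$irb$start))
      }
      if (b > structure$irb$end) {
        pieces_s <- c(pieces_s, max(a, structure$irb$end))
        pieces_e <- c(pieces_e, b)
      }
    }
  }
  totals <- c(LSC = 0, SSC = 0, IR = 0)
  if (length(pieces_s)) {
    ir <- IRanges::reduce(IRanges::IRanges(pieces_s + 1L, pieces_e))
    for (nm in c("LSC", "SSC", "IR")) {
      comp <- switch(nm, LSC = structure$lsc, SSC = structure$ssc,
                     IR = structure$ira)
      cr <- IRanges::IRanges(comp$start + 1L, comp$end)
      totals[nm] <- sum(IRanges::width(IRanges::intersect(ir, cr)))
    }
  }
  host_bp <- if (nrow(calls)) {
    interval_union_length(data.frame(seq_id = "host", start = calls$tstart,
                                     end = calls$tend, strand = "+"))
  } else 0L
  list(calls = calls,
       totals = c(totals, total = sum(totals), host_bp = host_bp,
                  host_pct = if (is.na(host_len)) NA_real_ else
                    100 * host_bp / host_len))
}

#' Per-chromosome transfer summaries
#'
#' For each host chromosome: call count, mean/median/max/min call length,
#' the same restricted to calls of at least `sub_threshold` bp, cumulative
#' union bp and its percentage of the chromosome; plus a genome-level
#' rollup row.
#'
#' @param calls A transfer-call table.
#' @param host_genomes List of host `genome`s (defines the chromosome set).
#' @param sub_threshold Length floor for the parenthetical sub-statistics.
#' @return A `data.frame`, one row per chromosome plus a `genome` rollup.
#' @export
summarize_by_chromosome <- function(calls, host_genomes, sub_threshold = 250L) {
  host_genomes <- as_genome_list(host_genomes)
  stat <- function(x) {
    if (!length(x)) c(n = 0L, mean = 0, median = 0, max = 0, min = 0)
    else c(n = length(x), mean = mean(x), median = median(x), max = max(x),
           min = min(x))
  }
  rows <- lapply(host_genomes, function(g) {
    cc <- calls[calls$chrom == g$id, , drop = FALSE]
    len <- cc$tend - cc$tstart
    s1 <- stat(len)
    s2 <- stat(len[len >= sub_threshold])
    cum <- if (nrow(cc)) {
      interval_union_length(data.frame(seq_id = g$id, start = cc$tstart,
                                       end = cc$tend, strand = "+"))
    } else 0L
    data.frame(chrom_id = g$id, n = s1["n"], mean_len = s1["mean"],
               median_len = s1["median"], max_len = s1["max"],
               min_len = s1["min"], n_ge_threshold = s2["n"],
               mean_len_ge = s2["mean"], median_len_ge = s2["median"],
               max_len_ge = s2["max"], min_len_ge = s2["min"],
               cumulative_bp = cum,
               pct_of_chromosome = 100 * cum / nchar(g$seq),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  total_len <- sum(vapply(host_genomes, function(g) nchar(g$seq), 0L))
  len <- calls$tend - calls$tstart
  s1 <- stat(len)
  s2 <- stat(len[len >= sub_threshold])
  roll <- data.frame(chrom_id = "genome", n = s1["n"], mean_len = s1["mean"],
                     median_len = s1["median"], max_len = s1["max"],
                     min_len = s1["min"], n_ge_threshold = s2["n"],
                     mean_len_ge = s2["mean"], median_len_ge = s2["median"],
                     max_len_ge = s2["max"], min_len_ge = s2["min"],
                     cumulative_bp = sum(d$cumulative_bp),
                     pct_of_chromosome = 100 * sum(d$cumulative_bp) / total_len,
                     stringsAsFactors = FALSE)
  out <- rbind(d, roll)
  rownames(out) <- NULL
  out
}

#' Cluster large transfer fragments along chromosomes
#'
#' Single-linkage clustering of calls of at least `min_large_len` bp with
#' inter-member gap at most `max_gap`; only clusters with two or more
#' members are reported, sorted by total (union) bp, largest first.
#'
#' @param calls A transfer-call table.
#' @param min_large_len Member length floor.
#' @param max_gap Maximum gap between consecutive members.
#' @return A `data.frame` of clusters with a `members` list-column of row
#'   indices into the filtered large-call table (attribute `large_calls`).
#' @export
cluster_large_fragments <- function(calls, min_large_len = 1000L,
                                    max_gap = 100000L) {
  big <- calls[(calls$tend - calls$tstart) >= min_large_len, , drop = FALSE]
  rownames(big) <- NULL
  out <- data.frame(chrom_id = character(0), window_start = integer(0),
                    window_end = integer(0), n_members = integer(0),
                    total_bp = integer(0), stringsAsFactors = FALSE)
  members <- list()
  if (nrow(big)) {
    for (ch in unique(big$chrom)) {
      idx <- which(big$chrom == ch)
      idx <- idx[order(big$tstart[idx])]
      gap_open <- c(TRUE, big$tstart[idx][-1] - big$tend[idx][-length(idx)] >
                      max_gap)
      cl <- cumsum(gap_open)
      for (g in unique(cl)) {
        kk <- idx[cl == g]
        if (length(kk) < 2L) next
        tot <- interval_union_length(data.frame(
          seq_id = ch, start = big$tstart[kk], end = big$tend[kk],
          strand = "+"))
        out[nrow(out) + 1L, c("chrom_id", "window_start", "window_end",
                              "n_members", "total_bp")] <-
          list(ch, min(big$tstart[kk]), max(big$tend[kk]), length(kk), tot)
        members[[length(members) + 1L]] <- kk
      }
    }
  }
  o <- order(-out$total_bp, out$chrom_id, out$window_start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members[o]
  attr(out, "large_calls") <- big
  out
}

#' Dot-matrix style fragment report for a nuclear region
#'
#' Lists every HSP of at least `min_large_len` bp between a nuclear region
#' and an organellar genome (nuclear interval, organellar interval,
#' orientation, identity %), and flags the region as mosaic when its
#' fragments derive from organellar loci more than 10 kb apart or carry
#' mixed orientations.
#'
#' @param nuclear_region A `genome` slice of the nuclear chromosome.
#' @param organelle The organellar `genome`.
#' @param params [homology_params()].
#' @param min_large_len Fragment length floor.
#' @return `list(fragments, mosaic)`.
#' @export
dotmatrix_report <- function(nuclear_region, organelle,
                             params = homology_params(),
                             min_large_len = 1000L) {
  hs <- find_hsps(nuclear_region, organelle, params)
  hs <- hs[(hs$qend - hs$qstart) >= min_large_len, , drop = FALSE]
  frags <- data.frame(nuc_start = hs$qstart, nuc_end = hs$qend,
                      org_start = hs$sstart, org_end = hs$send,
                      orientation = hs$strand,
                      identity_pct = 100 * hs$identity,
                      stringsAsFactors = FALSE)
  frags <- frags[order(frags$nuc_start), , drop = FALSE]
  rownames(frags) <- NULL
  mosaic <- FALSE
  if (nrow(frags) >= 2L) {
    if (length(unique(frags$orientation)) > 1L) mosaic <- TRUE
    o <- order(frags$org_start)
    gaps <- frags$org_start[o][-1] - frags$org_end[o][-nrow(frags)]
    if (any(gaps > 10000L)) mosaic <- TRUE
  }
  list(fragments = frags, mosaic = mosaic)
}

#' Write transfer calls as BED6
#'
#' Name is `klass:source_id:sstart-send`; score is identity on a 0-1000
#' scale.
#'
#' @param calls A transfer-call table.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  d <- data.frame(seq_id = calls$chrom, start = calls$tstart,
                  end = calls$tend,
                  name = sprintf("%s:%s:%d-%d", calls$klass, calls$source_id,
                                 calls$sstart, calls$send),
                  score = calls$identity, strand = calls$strand,
                  stringsAsFactors = FALSE)
  write_bed6(d, path)
}
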