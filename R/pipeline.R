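# End-to-end orchestration over the synthetic study conditions.
#
# One global seed drives per-stage derived streams; every threshold the
# analysis depends on (repeat 100 bp, ORF 303 bp, block 1 kb, sub-count
# 250 bp, word size 11, e-values 1e-5 / 1e-10, 50,000 max hits, depth QC
# 200x) is echoed into the run report for provenance.

#' Pipeline run configuration
#'
#' @param seed Global seed; stages derive their own streams from it.
#' @param outdir Output directory for all artifacts.
#' @param stages Character vector of enabled stages, in fixed order
#'   `simulate`, `assemble`, `repeats`, `transfers`, `synteny`.
#' @param sim [sim_config()] (seed is overridden by `seed`).
#' @param assembly [assembly_params()].
#' @param homology [homology_params()] for transfer calling.
#' @param synteny [synteny_params()] for structural comparison.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("egt_run_"),
                       stages = c("simulate", "assemble", "repeats",
                                  "transfers", "synteny"),
                       sim = sim_config(seed = seed),
                       assembly = assembly_params(),
                       homology = homology_params(),
                       synteny = synteny_params()) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 sim = sim, assembly = assembly, homology = homology,
                 synteny = synteny),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing standard-format artifacts
#' (FASTA, FASTQ, GFF3, BED, TSV, JSON) under `config$outdir`, and returns
#' (and writes) a run report. When the truth manifest exists, transfer
#' calls are validated against it (precision, recall, breakpoint error).
#'
#' @param config A [run_config()].
#' @return The run report (a list), invisibly written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    stages = config$stages,
    thresholds = list(repeat_min_len = 100, orf_min_len = 303,
                      block_min_len = 1000, sub_threshold = 250,
                      word_size = config$homology$word_size,
                      evalue_transfers = config$homology$evalue_max,
                      evalue_structure = config$synteny$homology$evalue_max,
                      max_hits = config$homology$max_hits,
                      min_depth_qc = config$assembly$min_depth_qc))
  state <- new.env()
  for (stage in c("simulate", "assemble", "repeats", "transfers", "synteny")) {
    if (!(stage %in% config$stages)) next
    report[[stage]] <- switch(stage,
      simulate = stage_simulate(config, state),
      assemble = stage_assemble(config, state),
      repeats = stage_repeats(config, state),
      transfers = stage_transfers(config, state),
      synteny = stage_synteny(config, state))
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

stage_simulate <- function(config, state) {
  cfg <- config$sim
  state$plastome <- simulate_plastome(cfg)
  state$mito <- simulate_mitogenome(cfg, state$plastome)
  state$nuclear <- simulate_nuclear(cfg, state$mito, state$plastome)
  state$annot <- simulate_annotation(state$mito$genome, seed = cfg$seed + 7L)
  vb <- apply_structural_variants(state$mito$genome, new_id = "mito_sim_b",
                                  seed = cfg$seed + 11L)
  vc <- apply_structural_variants(state$mito$genome, new_id = "mito_sim_c",
                                  seed = cfg$seed + 12L)
  state$trio <- list(state$mito$genome, vb$genome, vc$genome)
  state$truth <- rbind(state$mito$truth, state$nuclear$truth)
  out <- config$outdir
  write_fasta(state$plastome$genome, file.path(out, "plastome.fasta"))
  write_fasta(state$mito$genome, file.path(out, "mitogenome.fasta"))
  write_fasta(state$nuclear$genomes, file.path(out, "nuclear.fasta"))
  write_fasta(state$trio, file.path(out, "mito_trio.fasta"))
  write_gff3(state$annot, file.path(out, "mito_genes.gff3"))
  write_truth(state$truth, file.path(out, "truth.json"))
  list(plastome_len = nchar(state$plastome$genome$seq),
       mito_len = nchar(state$mito$genome$seq),
       n_chromosomes = length(state$nuclear$genomes),
       n_truth_events = nrow(state$truth))
}

stage_assemble <- function(config, state) {
  cfg <- config$sim
  pool_genomes <- c(list(state$mito$genome, state$plastome$genome),
                    state$nuclear$genomes)
  # nuclear depth reduced to keep the desk-scale pool small; mito and
  # plastome at full configured depth
  weights <- c(1, 1, rep(0.25, length(state$nuclear$genomes)))
  reads <- simulate_reads(pool_genomes, cfg, weights = weights)
  write_reads(reads, file.path(config$outdir, "reads"))
  # zero-mismatch full-read recruitment against the reference seed before
  # contig building; diverged nuclear-copy reads are excluded here
  mapped <- map_reads_exact(reads, state$mito$genome, config$assembly)
  asm <- assemble_genome(mapped, state$mito$genome, config$assembly,
                         id = "mito_assembly")
  exact <- !is.null(asm$genome) && asm$closed &&
    identical(asm$genome$seq, canonical_rotation(state$mito$genome$seq))
  if (!is.null(asm$genome)) {
    write_fasta(asm$genome, file.path(config$outdir, "assembly.fasta"))
  }
  # depth QC on a verification pool with plastome over-representation
  # (emulates organellar copy-number imbalance producing MTPT peaks)
  qc_reads <- simulate_reads(list(state$mito$genome, state$plastome$genome),
                             cfg, weights = c(1, 10))
  prof <- coverage_profile(state$mito$genome, qc_reads, config$assembly)
  write.table(data.frame(pos = seq_along(prof$depth) - 1L,
                         depth = prof$depth),
              file.path(config$outdir, "depth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(prof$flags)) {
    write.table(prof$flags, file.path(config$outdir, "depth_flags.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  state$assembly <- asm
  list(n_read_pairs = length(reads$r1), closed = asm$closed,
       assembly_len = if (is.null(asm$genome)) 0L else nchar(asm$genome$seq),
       identical_to_truth = exact,
       n_contigs = length(asm$contigs),
       median_depth = prof$median,
       n_high_depth_flags = sum(prof$flags$flag == "plastome_like_high_depth"))
}

stage_repeats <- function(config, state) {
  reps <- lapply(state$trio, find_exact_repeats)
  dup <- do.call(rbind, mapply(duplicated_length, reps, state$trio,
                               SIMPLIFY = FALSE))
  write_repeats(reps[[1]], file.path(config$outdir, "repeats_mito.tsv"))
  write.table(dup, file.path(config$outdir, "dup_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  state$repeats <- reps
  state$dup <- dup
  corr <- tryCatch(dup_correlations(dup), error = function(e) NULL)
  list(dup_stats = dup,
       correlations = if (is.null(corr)) "undefined (too few genomes)" else corr)
}

stage_transfers <- function(config, state) {
  out <- config$outdir
  mtpt <- call_transfers(state$plastome$genome, state$mito$genome,
                         config$homology)
  mtpt <- dedup_repeat_hits(mtpt, find_exact_repeats(state$plastome$genome))
  att <- attribute_compartment(mtpt, state$plastome$structure,
                               host_len = nchar(state$mito$genome$seq))
  mtpt <- att$calls
  numt <- call_transfers(state$mito$genome, state$nuclear$genomes,
                         config$homology)
  numt <- dedup_repeat_hits(numt, state$repeats[[1]])
  nupt <- call_transfers(state$plastome$genome, state$nuclear$genomes,
                         config$homology)
  nupt <- dedup_repeat_hits(nupt, find_exact_repeats(state$plastome$genome))
  numt_sum <- summarize_by_chromosome(numt, state$nuclear$genomes)
  nupt_sum <- summarize_by_chromosome(nupt, state$nuclear$genomes)
  clusters <- cluster_large_fragments(numt, min_large_len = 1000L)
  write_calls_bed(rbind(mtpt, numt, nupt), file.path(out, "transfers.bed"))
  write.table(numt_sum, file.path(out, "numt_by_chromosome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(nupt_sum, file.path(out, "nupt_by_chromosome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(clusters, file.path(out, "numt_clusters.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  safe_validate <- function(calls, klass) {
    tr <- state$truth[state$truth$class == klass, ]
    if (nrow(tr) == 0L) return(NULL)
    validate_against_truth(calls, tr)
  }
  validation <- Filter(Negate(is.null),
                       list(NUMT = safe_validate(numt, "NUMT"),
                            NUPT = safe_validate(nupt, "NUPT"),
                            MTPT = safe_validate(mtpt, "MTPT")))
  state$calls <- list(mtpt = mtpt, numt = numt, nupt = nupt)
  list(mtpt_compartment_totals = as.list(att$totals),
       n_numt = nrow(numt), n_nupt = nrow(nupt), n_mtpt = nrow(mtpt),
       numt_summary = numt_sum, nupt_summary = nupt_sum,
       n_numt_clusters = nrow(clusters), validation = validation)
}

stage_synteny <- function(config, state) {
  out <- config$outdir
  blocks <- find_synteny_blocks(state$trio[[1]], state$trio[[2]],
                                state$annot, config$synteny)
  write.table(blocks, file.path(out, "synteny_blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cons <- conserved_fraction(state$trio, config$synteny$homology)
  write.table(cons, file.path(out, "conserved_fractions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ribbon <- ribbon_map(state$trio[[1]], state$trio[[2]],
                       config$synteny$homology)
  write.table(ribbon, file.path(out, "ribbon_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  orfs <- find_orfs(state$trio[[1]])
  write_gff3(orfs, file.path(out, "orfs.gff3"))
  list(n_blocks = nrow(blocks),
       longest_block = if (nrow(blocks)) max(blocks$length) else 0L,
       conserved = cons, n_orfs = nrow(orfs),
       n_ribbon_hsps = nrow(ribbon))
}

#' Validate calls against the ground-truth event log
#'
#' A call matches a truth event of the same chromosome when their target
#' intervals overlap reciprocally by at least 50%. Breakpoint error is the
#' mean absolute endpoint offset over matched pairs.
#'
#' @param calls A transfer-call table (or any table with `chrom`,
#'   `tstart`, `tend`).
#' @param truth Truth event rows (with `target_id`, `target_start`,
#'   `target_end`).
#' @return `list(precision, recall, breakpoint_error_bp, n_calls,
#'   n_events)`.
#' @export
validate_against_truth <- function(calls, truth) {
  if (nrow(truth) == 0L) stop("empty truth manifest")
  matched_call <- rep(FALSE, nrow(calls))
  matched_event <- rep(FALSE, nrow(truth))
  offs <- numeric(0)
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      if (calls$chrom[i] != truth$target_id[j]) next
      o <- min(calls$tend[i], truth$target_end[j]) -
        max(calls$tstart[i], truth$target_start[j])
      lc <- calls$tend[i] - calls$tstart[i]
      le <- truth$target_end[j] - truth$target_start[j]
      if (o >= 0.5 * lc && o >= 0.5 * le) {
        if (!matched_call[i]) {
          offs <- c(offs, abs(calls$tstart[i] - truth$target_start[j]),
                    abs(calls$tend[i] - truth$target_end[j]))
        }
        matched_call[i] <- TRUE
        matched_event[j] <- TRUE
      }
    }
  }
  list(precision = if (nrow(calls)) mean(matched_call) else NA_real_,
       recall = mean(matched_event),
       breakpoint_error_bp = if (length(offs)) mean(offs) else NA_real_,
       n_calls = nrow(calls), n_events = nrow(truth))
}
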