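#!/usr/bin/env Rscript

# Generate the synthetic study system: a quadripartite plastome, a
# repeat-rich circular mitogenome carrying plastome implants (MTPTs),
# three nuclear chromosomes with scattered and clustered organellar
# implants (NUMTs/NUPTs), a trio of structurally rearranged mitogenome
# variants, gene annotations, and a 200x paired-end read pool.
# All outputs land under results/sim/ together with the ground-truth
# event log that later steps validate against.

suppressPackageStartupMessages(library(orgEGT))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

out <- "results/sim"
cfg <- run_config(seed = seed, outdir = out, stages = "simulate")
rep <- run_pipeline(cfg)

cat(sprintf("plastome: %d bp, mitogenome: %d bp, %d chromosomes\n",
            rep$simulate$plastome_len, rep$simulate$mito_len,
            rep$simulate$n_chromosomes))
cat(sprintf("%d ground-truth events logged to %s/truth.json\n",
            rep$simulate$n_truth_events, out))
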