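#!/usr/bin/env Rscript
# Simulate the study conditions: a skewed reference genome (polyT tracts
# placed on the non-template strand of their host gene with probability
# q = 0.6, mirroring the reference-genome polyT skew), an indel cohort with
# a planted non-template excess that is stronger for insertions than for
# deletions, half the samples MMR-deficient, plus a coupled expression
# table and a sawtooth replication-timing track. Everything is written
# under results/sim/ as standard FASTA/BED/VCF/TSV/bedGraph plus a JSON
# ground-truth manifest.

suppressMessages(library(indelstrand))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  seed = 20260926L,
  genome_length = 4e6, n_chroms = 4L,
  n_genes = 800L, gene_length = 2000L,
  tracts_per_gene = 4L, tract_units = "T",
  q = 0.6,
  n_samples = 24L, indels_per_sample = 300,
  insertion_fraction = 0.36,            # deletions outnumber insertions
  beta_ins = 0.62, beta_del = 0.55,     # insertions carry the larger excess
  length_slope = 1.3,                   # longer tracts are more mutable
  msi_fraction = 0.5, msi_multiplier = 3,
  background_indel_rate = 0.3,
  del_max_units = 4L,                   # deletions get a broader size spectrum
  cohort_name = "simulated")

ref <- generate_reference(cfg)
expr <- generate_expression(cfg, ref)
coh <- generate_cohort(cfg, ref, expression = expr)
rs <- generate_repliseq(cfg, ref)

write_reference(ref, out)
write_cohort(coh, ref, out)
write.table(as.data.frame(expr$rpkm), file.path(out, "expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_signal_track(rs$track, file.path(out, "repliseq.bedGraph"))
jsonlite::write_json(rs$truth, file.path(out, "repliseq_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("genome: %d chromosomes, %.1f Mb total\n",
            length(genome_lengths(ref$genome)),
            sum(genome_lengths(ref$genome)) / 1e6))
cat(sprintf("genes: %d (%.0f%% on +)\n", nrow(ref$genes),
            100 * mean(ref$genes$strand == "+")))
cat(sprintf("planted tracts: %d (non-template share %.3f, target q = %.2f)\n",
            nrow(ref$tracts),
            mean(ref$tracts$reading == "non_template"), cfg$q))
cat(sprintf("cohort: %d samples (%d MSI), %d indels (%.0f%% insertions)\n",
            nrow(coh$samples), sum(coh$samples$msi), nrow(coh$indels),
            100 * mean(coh$indels$kind == "insertion")))
cat("written to", out, "\n")
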