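#!/usr/bin/env Rscript
# Stratified analyses on the simulated cohort: strand bias by gene
# expression tier (33rd/66th RPKM percentiles), replication-timing
# quantiles, and leading/lagging replication orientation — the controls
# that separate a transcription-coupled signal from replication-coupled
# alternatives. Reads the files written by 01_simulate.R.

suppressMessages(library(indelstrand))

sim <- "results/sim"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome(file.path(sim, "genome.fa"))
genes <- read_gene_table(file.path(sim, "genes.bed"), coords = "bed")
samples <- dplyr::as_tibble(read.table(file.path(sim, "samples.tsv"),
                                       header = TRUE, sep = "\t"))
indels <- dplyr::bind_rows(lapply(samples$sample_id, function(sid)
  read_indel_vcf(file.path(sim, paste0(sid, ".vcf")), sid, genome = genome)))
rpkm <- dplyr::as_tibble(read.table(file.path(sim, "expression.tsv"),
                                    header = TRUE, sep = "\t"))

tracts <- find_homopolymer_tracts(genome)
oriented <- orient_tracts(tracts[tracts$length >= 3, ], genes)
hits <- assign_hits(indels, oriented, target_unit = "T")

# expression tiers
tiers <- expression_tiers(rpkm)
by_tier <- stratified_bias(hits, oriented, "T", tiers = tiers,
                           stratify_by = "expression")
write_report_tsv(by_tier, file.path(out, "bias_polyT_by_expression.tsv"))
cat("strand bias by expression tier:\n")
print(as.data.frame(by_tier[, c("tier", "nt_indels", "t_indels", "bias")]))

# replication annotation from the Repli-seq track
track <- read_signal_track(file.path(sim, "repliseq.bedGraph"))
ann <- replication_annotation(track, smoothing_bp = 3e4)
cat(sprintf("replication annotation: %.0f%% of bins in firm orientation\n",
            100 * mean(ann$orientation != "transition")))

ob <- orientation_controlled_bias(hits, oriented, ann, "T")
write_report_tsv(ob, file.path(out, "bias_polyT_by_replication.tsv"))
cat("transcriptional bias within replication-orientation partitions:\n")
print(as.data.frame(ob))

tq <- timing_quantile_bias(hits, oriented, genes, ann, "T", n_quantiles = 5)
write_report_tsv(tq$per_quantile, file.path(out, "bias_polyT_by_timing.tsv"))
cat("strand bias across replication-timing quantiles:\n")
print(as.data.frame(tq$per_quantile[, c("quantile_bin", "bias")]))
cat("tables written to", out, "\n")
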