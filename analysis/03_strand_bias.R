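#!/usr/bin/env Rscript
# Cohort-level strand-asymmetry analysis: per-sample indel summaries,
# background-corrected polyT strand bias with gene bootstrap and binomial
# test, tract-length stratification, the insertion/deletion split, and the
# MSI vs MSS comparison. Reads the simulation written by 01_simulate.R.

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

cs <- cohort_summary(indels, callable_bp = sum(genome_lengths(genome)))
write_report_tsv(cs$per_sample, file.path(out, "cohort_summary.tsv"))
cat(sprintf("cohort: median %.1f deletions vs %.1f insertions per sample (size-variance p = %.2g)\n",
            cs$median_deletions, cs$median_insertions, cs$size_variance_p))

tracts <- find_homopolymer_tracts(genome)
oriented <- orient_tracts(tracts[tracts$length >= 3, ], genes)
hits <- assign_hits(indels, oriented, target_unit = "T")
write_hits_tsv(hits, file.path(out, "hits_polyT.tsv"))

sc <- counts_from_hits(hits, oriented, "T")
est <- strand_bias(sc)
bt <- bootstrap_bias(sc, n_boot = 1000L, seed = 2L)
pv <- binomial_strand_test(sc)
cat(sprintf("polyT strand bias %.4f (bootstrap sd %.4f), NT excess %.1f%%, binomial p = %.2g\n",
            est$bias, bt$boot_sd, est$excess_pct, pv))
write_report_tsv(
  tibble::tibble(unit = "T", nt_indels = sc$nt_indels, t_indels = sc$t_indels,
                 nt_motifs = sc$nt_motifs, t_motifs = sc$t_motifs,
                 bias = est$bias, excess_pct = est$excess_pct,
                 boot_sd = bt$boot_sd, p_binomial = pv),
  file.path(out, "bias_polyT_overall.tsv"))

by_len <- stratified_bias(hits, oriented, "T", stratify_by = "tract_length")
write_report_tsv(by_len, file.path(out, "bias_polyT_by_length.tsv"))

by_kind <- dplyr::bind_rows(lapply(c("insertion", "deletion"), function(k) {
  e <- strand_bias(counts_from_hits(hits, oriented, "T", kind = k))
  tibble::tibble(kind = k, bias = e$bias, excess_pct = e$excess_pct)
}))
write_report_tsv(by_kind, file.path(out, "bias_polyT_by_kind.tsv"))
cat(sprintf("insertion bias %.3f vs deletion bias %.3f\n",
            by_kind$bias[1], by_kind$bias[2]))

# MSI vs MSS: per-sample biases, rank-sum test, enrichment ratio
per_sample <- dplyr::bind_rows(lapply(samples$sample_id, function(sid) {
  e <- strand_bias(counts_from_hits(hits[hits$sample_id == sid, ],
                                    oriented, "T"))
  tibble::tibble(sample_id = sid, bias = e$bias)
}))
per_sample <- dplyr::left_join(per_sample, samples, by = "sample_id")
cmp <- group_comparison(per_sample$bias, ifelse(per_sample$msi, "MSI", "MSS"),
                        test = "rank_sum")
enr <- msi_enrichment_ratio(indels, hits, samples, min_tract_length = 3L)
write_report_tsv(per_sample, file.path(out, "bias_polyT_per_sample.tsv"))
cat(sprintf("MSI median bias %.3f vs MSS %.3f (rank-sum p = %.2g); enrichment ratio %.2f\n",
            median(per_sample$bias[per_sample$msi]),
            median(per_sample$bias[!per_sample$msi]), cmp$p_raw, enr$ratio))

resp <- msi_length_response(hits, oriented, samples)
write_report_tsv(resp, file.path(out, "indel_frequency_by_length_msi.tsv"))
cat("tables written to", out, "\n")
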