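# End-to-end orchestration: atlas -> hits -> bias tables -> stratified
# tables -> report directory, from a single configuration.

#' Build a run configuration
#'
#' All downstream stages read their settings from this object; it is
#' serialized into the output directory for reproducibility. Inputs can be
#' file paths (read through the package's readers) or in-memory objects
#' (a `"genome"`, gene/indel/sample tibbles, a `"signal_track"`).
#'
#' @param genome Path to FASTA or a `"genome"` object.
#' @param genes Path to a BED6 gene table or a gene tibble.
#' @param indels Named character vector of per-sample VCF paths, or an
#'   indel tibble covering all samples.
#' @param samples Sample metadata: path to TSV (`sample_id`, `cohort`,
#'   `msi`) or tibble.
#' @param expression Optional RPKM table: path to TSV (`gene_id`, `rpkm`)
#'   or tibble.
#' @param repliseq Optional replication timing: bedGraph path or
#'   `"signal_track"`.
#' @param target_units Homopolymer units analysed (non-template reading).
#' @param strata Length strata (bp) used for the headline bias tables.
#' @param dinucleotides Also compute the dinucleotide asymmetry matrix.
#' @param split_ins_del Compute insertion/deletion split tables.
#' @param msi_comparison Compare MSI vs MSS samples (needs `msi` labels).
#' @param n_boot Bootstrap iterations for bias dispersion.
#' @param seed Seed for all stochastic steps.
#' @param null_mode Binomial null: `"motif_share"` or `"half"`.
#' @param bonferroni_family Explicit family size for adjusted p-values.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(genome, genes, indels, samples,
                       expression = NULL, repliseq = NULL,
                       target_units = c("T", "G"),
                       strata = as.character(2:10),
                       dinucleotides = FALSE,
                       split_ins_del = TRUE,
                       msi_comparison = FALSE,
                       n_boot = 1000L, seed = 1L,
                       null_mode = c("motif_share", "half"),
                       bonferroni_family = 1L) {
  cfg <- as.list(environment())
  cfg$null_mode <- match.arg(null_mode)
  class(cfg) <- "run_config"
  cfg
}

.load_inputs <- function(config) {
  genome <- if (inherits(config$genome, "genome")) config$genome else
    read_genome(config$genome)
  genes <- if (is.data.frame(config$genes)) config$genes else
    read_gene_table(config$genes, coords = "bed")
  samples <- if (is.data.frame(config$samples)) config$samples else
    as_tibble(read.table(config$samples, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE))
  indels <- if (is.data.frame(config$indels)) config$indels else
    bind_rows(lapply(names(config$indels), function(sid)
      read_indel_vcf(config$indels[[sid]], sid, genome = genome)))
  expression <- NULL
  if (!is.null(config$expression)) {
    expression <- if (is.data.frame(config$expression)) config$expression else
      as_tibble(read.table(config$expression, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE))
  }
  repliseq <- NULL
  if (!is.null(config$repliseq)) {
    repliseq <- if (inherits(config$repliseq, "signal_track"))
      config$repliseq else read_signal_track(config$repliseq)
  }
  list(genome = genome, genes = genes, samples = samples, indels = indels,
       expression = expression, repliseq = repliseq)
}

#' Run the full strand-asymmetry analysis
#'
#' Executes atlas construction, orientation, hit assignment, per-cohort
#' bias estimation (overall, by tract length, split by indel kind, MSI vs
#' MSS, expression tiers, replication strata when inputs allow) and writes
#' all tables plus a log into `out_dir`. Any stage failure aborts with the
#' stage name.
#'
#' @param config A `"run_config"`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with all computed tables (also written as
#'   TSVs).
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    logf("stage ", name, " start")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logf("stage ", name, " done")
    res
  }
  cat("", file = log_path)
  logf("seed=", config$seed, " n_boot=", config$n_boot,
       " null=", config$null_mode)

  inp <- stage("load", .load_inputs(config))
  results <- list(config = config)

  atlas <- stage("atlas", {
    homo <- find_homopolymer_tracts(inp$genome)
    oriented <- orient_tracts(homo, inp$genes)
    logf("tracts=", nrow(homo), " oriented pairs=", nrow(oriented))
    list(tracts = homo, oriented = oriented)
  })
  write_tract_bed(atlas$tracts, file.path(out_dir, "atlas.bed"))

  bias_tables <- stage("bias", {
    rows <- list(); hit_store <- list()
    for (u in config$target_units) {
      hits <- assign_hits(inp$indels, atlas$oriented, target_unit = u)
      hit_store[[u]] <- hits
      sc <- counts_from_hits(hits, atlas$oriented, u, strata = config$strata)
      est <- strand_bias(sc)
      bt <- if (sc$nt_indels + sc$t_indels >= 1)
        binomial_strand_test(sc, null = config$null_mode) else NA_real_
      boot <- if (!is.null(sc$per_gene) && nrow(sc$per_gene) >= 2 &&
                  sc$nt_indels + sc$t_indels > 0)
        bootstrap_bias(sc, n_boot = config$n_boot, seed = config$seed)
      else list(boot_mean = NA_real_, boot_sd = NA_real_)
      rows[[u]] <- tibble(
        unit = u, nt_indels = sc$nt_indels, t_indels = sc$t_indels,
        nt_motifs = sc$nt_motifs, t_motifs = sc$t_motifs,
        A = est$A, B = est$B, bias = est$bias, excess_pct = est$excess_pct,
        boot_mean = boot$boot_mean, boot_sd = boot$boot_sd,
        p_raw = bt, p_adj = pmin(1, bt * config$bonferroni_family))
    }
    list(table = bind_rows(rows), hits = hit_store)
  })
  results$bias <- bias_tables$table
  write_report_tsv(bias_tables$table, file.path(out_dir, "bias_overall.tsv"))

  results$by_length <- stage("by_length", {
    out <- bind_rows(lapply(config$target_units, function(u) {
      tb <- stratified_bias(bias_tables$hits[[u]], atlas$oriented, u,
                            stratify_by = "tract_length")
      tb$unit <- u
      tb
    }))
    write_report_tsv(out, file.path(out_dir, "bias_by_length.tsv"))
    out
  })

  if (config$split_ins_del) {
    results$by_kind <- stage("ins_del_split", {
      out <- bind_rows(lapply(config$target_units, function(u) {
        bind_rows(lapply(c("insertion", "deletion"), function(k) {
          sc <- counts_from_hits(bias_tables$hits[[u]], atlas$oriented, u,
                                 strata = config$strata, kind = k)
          est <- strand_bias(sc)
          tibble(unit = u, kind = k, nt_indels = sc$nt_indels,
                 t_indels = sc$t_indels, nt_motifs = sc$nt_motifs,
                 t_motifs = sc$t_motifs, bias = est$bias,
                 excess_pct = est$excess_pct)
        }))
      }))
      write_report_tsv(out, file.path(out_dir, "bias_by_kind.tsv"))
      out
    })
  }

  if (config$msi_comparison && "msi" %in% names(inp$samples)) {
    results$msi <- stage("msi", {
      u <- config$target_units[1]
      hits <- bias_tables$hits[[u]]
      per_sample <- bind_rows(lapply(inp$samples$sample_id, function(sid) {
        sc <- counts_from_hits(hits[hits$sample_id == sid, ],
                               atlas$oriented, u, strata = config$strata)
        tibble(sample_id = sid, bias = strand_bias(sc)$bias)
      }))
      per_sample <- left_join(per_sample,
                              inp$samples[, c("sample_id", "msi")],
                              by = "sample_id")
      cmp <- tryCatch(
        group_comparison(per_sample$bias,
                         ifelse(per_sample$msi, "MSI", "MSS"),
                         test = "rank_sum",
                         family_size = config$bonferroni_family),
        error = function(e) NULL)
      enr <- tryCatch(
        msi_enrichment_ratio(inp$indels, hits, inp$samples,
                             min_tract_length = 3L),
        error = function(e) NULL)
      out <- list(per_sample = per_sample, comparison = cmp,
                  enrichment = enr)
      write_report_tsv(per_sample, file.path(out_dir, "bias_per_sample_msi.tsv"))
      out
    })
  }

  if (!is.null(inp$expression)) {
    results$expression <- stage("expression", {
      tiers <- expression_tiers(inp$expression)
      out <- bind_rows(lapply(config$target_units, function(u) {
        tb <- stratified_bias(bias_tables$hits[[u]], atlas$oriented, u,
                              tiers = tiers, stratify_by = "expression")
        tb$unit <- u
        tb
      }))
      write_report_tsv(out, file.path(out_dir, "bias_by_expression.tsv"))
      out
    })
  }

  if (!is.null(inp$repliseq)) {
    results$replication <- stage("replication", {
      ann <- replication_annotation(inp$repliseq)
      out <- bind_rows(lapply(config$target_units, function(u) {
        tb <- orientation_controlled_bias(bias_tables$hits[[u]],
                                          atlas$oriented, ann, u)
        tb$unit <- u
        tb
      }))
      write_report_tsv(out, file.path(out_dir, "bias_by_replication.tsv"))
      out
    })
  }

  if (config$dinucleotides) {
    results$dinucleotide <- stage("dinucleotide_matrix", {
      di <- find_dinucleotide_tracts(inp$genome)
      odi <- orient_tracts(di, inp$genes)
      am <- asymmetry_matrix(inp$indels, odi, inp$samples)
      write_report_tsv(am$long, file.path(out_dir, "asymmetry_matrix.tsv"))
      am
    })
  }

  cfg <- config
  class(cfg) <- NULL
  is_path <- function(x) is.character(x) && is.null(attr(x, "class")) &&
    length(x) >= 1L && all(nchar(x) < 4096)
  for (f in c("genome", "genes", "indels", "samples", "expression",
              "repliseq")) {
    if (!is.null(cfg[[f]]) && !is_path(cfg[[f]])) cfg[[f]] <- "<in-memory>"
  }
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("run complete")
  invisible(results)
}

#' Write a result table as TSV with a stable schema
#'
#' Fixed column order as computed, missing values written as `"NA"`.
#' Zero-row tables produce a headers-only file.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
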