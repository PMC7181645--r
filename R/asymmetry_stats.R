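# Background-corrected strand-bias statistics: point estimate, gene-level
# bootstrap, binomial and rank tests, MSI enrichment, down-sampling z-score.
#
# The central statistic corrects indel counts for the skewed background
# distribution of repeat tracts between strands:
#   A = (indels overlapping motif on non-template) / (motif occurrences on non-template)
#   B = (indels overlapping motif on template)     / (motif occurrences on template)
#   strand bias = A / (A + B)        (0.5 = no asymmetry)

#' Construct strand counts
#'
#' The four counts feeding the strand-bias statistic, optionally with a
#' per-gene breakdown for gene-level bootstrapping.
#'
#' @param nt_indels,t_indels Indel-tract hit counts on the non-template and
#'   template strands.
#' @param nt_motifs,t_motifs Oriented tract occurrence counts on each strand.
#' @param per_gene Optional tibble with columns `gene_id`, `nt_indels`,
#'   `t_indels`, `nt_motifs`, `t_motifs`; must sum to the totals.
#' @return List of class `"strand_counts"`.
#' @export
strand_counts <- function(nt_indels, t_indels, nt_motifs, t_motifs,
                          per_gene = NULL) {
  stopifnot(nt_indels >= 0, t_indels >= 0, nt_motifs >= 0, t_motifs >= 0)
  if (!is.null(per_gene)) {
    need <- c("gene_id", "nt_indels", "t_indels", "nt_motifs", "t_motifs")
    stopifnot(all(need %in% names(per_gene)))
    sums <- colSums(per_gene[, need[-1]])
    if (!isTRUE(all.equal(unname(sums),
                          c(nt_indels, t_indels, nt_motifs, t_motifs)))) {
      stop("per-gene counts do not sum to the totals")
    }
  }
  structure(list(nt_indels = nt_indels, t_indels = t_indels,
                 nt_motifs = nt_motifs, t_motifs = t_motifs,
                 per_gene = per_gene),
            class = "strand_counts")
}

#' Assemble strand counts from hits and oriented tracts
#'
#' Builds the four counts (and the per-gene breakdown) for a target unit:
#' motif denominators are oriented tract occurrences reading the unit on
#' each strand, numerators are indel-tract hits labelled by strand class.
#'
#' @param hits Hit tibble from [assign_hits()] for the same `target_unit`.
#' @param oriented Oriented tract tibble (the denominator atlas).
#' @param target_unit Unit read on the non-template strand.
#' @param strata Optional character vector of length strata to restrict both
#'   numerators and denominators to (labels as in [length_stratum()]).
#' @param kind Optional `"insertion"`/`"deletion"` restriction of numerators.
#' @return A `"strand_counts"` object.
#' @export
counts_from_hits <- function(hits, oriented, target_unit, strata = NULL,
                             kind = NULL) {
  cu <- revcomp(target_unit)
  mot <- oriented[oriented$nt_unit %in% c(target_unit, cu), ]
  mot$stratum <- length_stratum(mot$length, mot$over_max)
  hits$stratum <- length_stratum(hits$tract_length, hits$over_max)
  if (!is.null(strata)) {
    mot <- mot[mot$stratum %in% strata, ]
    hits <- hits[hits$stratum %in% strata, ]
  }
  if (!is.null(kind)) hits <- hits[hits$kind == kind, ]
  if (is.null(hits$strand_class) || all(is.na(hits$strand_class))) {
    hits$strand_class <- ifelse(hits$nt_unit == target_unit,
                                "non_template", "template")
  }
  hits <- hits[hits$nt_unit %in% c(target_unit, cu), ]

  genes <- sort(unique(c(mot$gene_id, hits$gene_id)))
  per <- tibble(
    gene_id = genes,
    nt_indels = as.integer(table(factor(hits$gene_id[hits$strand_class == "non_template"], genes))),
    t_indels = as.integer(table(factor(hits$gene_id[hits$strand_class == "template"], genes))),
    nt_motifs = as.integer(table(factor(mot$gene_id[mot$nt_unit == target_unit], genes))),
    t_motifs = as.integer(table(factor(mot$gene_id[mot$nt_unit == cu], genes))))
  strand_counts(sum(per$nt_indels), sum(per$t_indels),
                sum(per$nt_motifs), sum(per$t_motifs), per_gene = per)
}

.bias_from_counts <- function(nt_i, t_i, nt_m, t_m) {
  A <- nt_i / nt_m
  B <- t_i / t_m
  ifelse(nt_m > 0 & t_m > 0 & (A + B) > 0, A / (A + B), NA_real_)
}

#' Strand-bias point estimate
#'
#' Computes the background-corrected per-strand mutational densities
#' `A` and `B`, the bias `A/(A+B)` and the percentage excess
#' `(A/B - 1) * 100`. Undefined when either motif count is zero or when no
#' indels hit either strand (`defined = FALSE`).
#'
#' @param counts A `"strand_counts"` object.
#' @return List of class `"bias_estimate"`: `A`, `B`, `bias`, `excess_pct`,
#'   `defined`, plus the input counts.
#' @export
strand_bias <- function(counts) {
  stopifnot(inherits(counts, "strand_counts"))
  defined <- counts$nt_motifs > 0 && counts$t_motifs > 0
  A <- if (counts$nt_motifs > 0) counts$nt_indels / counts$nt_motifs else NA_real_
  B <- if (counts$t_motifs > 0) counts$t_indels / counts$t_motifs else NA_real_
  defined <- defined && isTRUE((A + B) > 0)
  structure(list(
    A = A, B = B,
    bias = if (defined) A / (A + B) else NA_real_,
    excess_pct = if (defined && B > 0) (A / B - 1) * 100 else NA_real_,
    defined = defined, counts = counts),
    class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat("Strand bias estimate\n")
  cat(sprintf("  A (non-template density): %.4g   B (template density): %.4g\n",
              x$A, x$B))
  cat(sprintf("  bias A/(A+B): %.4f   excess (A/B - 1): %.1f%%\n",
              x$bias, x$excess_pct))
  if (!is.null(x$boot_sd)) {
    cat(sprintf("  bootstrap: mean %.4f, sd %.4f (%d iterations)\n",
                x$boot_mean, x$boot_sd, x$n_boot))
  }
  invisible(x)
}

#' Gene-level bootstrap of the strand bias
#'
#' Resamples genes with replacement, sums the four per-gene counts over each
#' resample, and recomputes the bias. Iterations where the bias is undefined
#' (zero motifs or zero total density in the resample) are redrawn and
#' counted; a warning is raised when more than 1% of iterations had to be
#' redrawn.
#'
#' @param counts A `"strand_counts"` object carrying `per_gene`.
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return List: `boot_mean`, `boot_sd`, `ci` (2.5/97.5 percentiles),
#'   `n_boot`, `n_redrawn`, `seed`, `values`.
#' @export
bootstrap_bias <- function(counts, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(counts, "strand_counts"))
  pg <- counts$per_gene
  if (is.null(pg) || nrow(pg) < 2L) stop("per-gene counts with >= 2 genes required")
  if (counts$nt_indels + counts$t_indels == 0L) stop("no indel hits to bootstrap")
  C <- as.matrix(pg[, c("nt_indels", "t_indels", "nt_motifs", "t_motifs")])
  G <- nrow(C)
  withr::with_seed(seed, {
    vals <- numeric(n_boot)
    need <- seq_len(n_boot)
    n_redrawn <- 0L
    while (length(need) > 0L) {
      B <- length(need)
      idx <- matrix(sample.int(G, G * B, replace = TRUE), nrow = G)
      cnt <- apply(idx, 2, tabulate, nbins = G)      # G x B multiplicities
      sums <- crossprod(C, cnt)                      # 4 x B
      b <- .bias_from_counts(sums[1, ], sums[2, ], sums[3, ], sums[4, ])
      ok <- !is.na(b)
      vals[need[ok]] <- b[ok]
      n_redrawn <- n_redrawn + sum(!ok)
      need <- need[!ok]
    }
    if (n_redrawn > 0.01 * n_boot) {
      warning(n_redrawn, " undefined bootstrap iteration(s) redrawn (> 1%)")
    }
    list(boot_mean = mean(vals), boot_sd = sd(vals),
         ci = unname(quantile(vals, c(0.025, 0.975))),
         n_boot = n_boot, n_redrawn = n_redrawn, seed = seed, values = vals)
  })
}

#' Exact binomial test of strand asymmetry
#'
#' Tests the non-template hit count against the background-corrected null:
#' under no asymmetry, each hit falls on the non-template strand with
#' probability equal to the non-template share of motif occurrences
#' (`null = "motif_share"`). `null = "half"` tests against 0.5 instead
#' (uncorrected).
#'
#' @param counts A `"strand_counts"` object.
#' @param two_sided Two-sided (default) or greater-than alternative.
#' @param null `"motif_share"` or `"half"`.
#' @return p-value.
#' @export
binomial_strand_test <- function(counts, two_sided = TRUE,
                                 null = c("motif_share", "half")) {
  stopifnot(inherits(counts, "strand_counts"))
  null <- match.arg(null)
  n <- counts$nt_indels + counts$t_indels
  stopifnot(n >= 1L)
  p0 <- if (null == "motif_share") {
    counts$nt_motifs / (counts$nt_motifs + counts$t_motifs)
  } else 0.5
  binom.test(counts$nt_indels, n, p = p0,
             alternative = if (two_sided) "two.sided" else "greater")$p.value
}

#' MSI over MSS enrichment ratio of tract-overlapping indels
#'
#' Ratio of the pooled within-group proportions of indels that overlap
#' polyA/polyT tracts (or any supplied tract set): (proportion in MSI
#' samples) / (proportion in MSS samples).
#'
#' @param indels Indel tibble (all indels, all samples).
#' @param hits Hit tibble from [assign_hits()] (the tract-overlapping
#'   subset; any tract set, e.g. polyA/T).
#' @param samples Tibble with `sample_id` and logical `msi`.
#' @param min_tract_length Count only hits on tracts of at least this length
#'   (bp).
#' @return List: `ratio`, `prop_msi`, `prop_mss`, `n_msi`, `n_mss`,
#'   `low_n` flag (either group has a single sample).
#' @export
msi_enrichment_ratio <- function(indels, hits, samples, min_tract_length = 1L) {
  stopifnot(all(c("sample_id", "msi") %in% names(samples)))
  msi_ids <- samples$sample_id[samples$msi]
  mss_ids <- samples$sample_id[!samples$msi]
  if (length(msi_ids) == 0L || length(mss_ids) == 0L) {
    stop("both MSI and MSS groups must be non-empty")
  }
  hits <- hits[hits$tract_length >= min_tract_length, ]
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$kind, d$seq, sep = "\r")
  hit_keys <- unique(key(hits))
  overl <- key(indels) %in% hit_keys
  in_msi <- indels$sample_id %in% msi_ids
  in_mss <- indels$sample_id %in% mss_ids
  prop_msi <- sum(overl & in_msi) / sum(in_msi)
  prop_mss <- sum(overl & in_mss) / sum(in_mss)
  if (prop_mss == 0) {
    return(list(ratio = NA_real_, prop_msi = prop_msi, prop_mss = prop_mss,
                n_msi = sum(in_msi), n_mss = sum(in_mss),
                low_n = length(msi_ids) < 2L || length(mss_ids) < 2L))
  }
  list(ratio = prop_msi / prop_mss, prop_msi = prop_msi, prop_mss = prop_mss,
       n_msi = sum(in_msi), n_mss = sum(in_mss),
       low_n = length(msi_ids) < 2L || length(mss_ids) < 2L)
}

#' Rank tests comparing per-sample biases between groups
#'
#' Mann--Whitney rank-sum between two groups, Kruskal--Wallis across several,
#' or Wilcoxon signed-rank for paired vectors, with explicit Bonferroni
#' family size. Groups with fewer than 2 samples are excluded with a message.
#'
#' @param x Numeric vector of per-sample bias values (or first member of the
#'   pair for `signed_rank`).
#' @param g Group labels (ignored for `signed_rank`).
#' @param y Second paired vector for `signed_rank`.
#' @param test `"rank_sum"`, `"kruskal"` or `"signed_rank"`.
#' @param family_size Bonferroni multiplier (explicit; default 1).
#' @return List: `test`, `statistic`, `p_raw`, `p_adj`, `family_size`,
#'   `groups_used`.
#' @export
group_comparison <- function(x, g = NULL, y = NULL,
                             test = c("rank_sum", "kruskal", "signed_rank"),
                             family_size = 1L) {
  test <- match.arg(test)
  if (test == "signed_rank") {
    stopifnot(!is.null(y), length(x) == length(y))
    keep <- complete.cases(x, y)
    ht <- suppressWarnings(wilcox.test(x[keep], y[keep], paired = TRUE))
    groups <- NULL
  } else {
    stopifnot(!is.null(g), length(x) == length(g))
    keep <- !is.na(x)
    x <- x[keep]; g <- as.character(g[keep])
    sizes <- table(g)
    small <- names(sizes)[sizes < 2L]
    if (length(small) > 0L) {
      message("group(s) with < 2 samples excluded: ",
              paste(small, collapse = ", "))
      sel <- !(g %in% small)
      x <- x[sel]; g <- g[sel]
    }
    groups <- unique(g)
    if (length(groups) < 2L) stop("need >= 2 groups with >= 2 samples")
    ht <- if (test == "rank_sum") {
      stopifnot(length(groups) == 2L)
      suppressWarnings(wilcox.test(x[g == groups[1]], x[g == groups[2]]))
    } else {
      kruskal.test(x, factor(g))
    }
  }
  p_adj <- min(1, ht$p.value * family_size)
  list(test = test, statistic = unname(ht$statistic), p_raw = ht$p.value,
       p_adj = p_adj, family_size = family_size, groups_used = groups)
}

#' Down-sampling z-score against reference cohorts
#'
#' Compares a focal sample's strand bias with a reference cohort at the
#' focal sample's (small) hit count: `n_boot` draws of the focal number of
#' hits are sampled with replacement from the cohort's pooled hit set
#' (preserving the cohort's non-template proportion), the bias is recomputed
#' per draw with the cohort's motif denominators, and the focal bias is
#' placed on that distribution: `z = (bias_focal - mean)/sd`, with the
#' empirical two-sided tail fraction as p-value. Insertions and deletions
#' are assessed separately.
#'
#' @param focal_hits Hit tibble (with `strand_class`) for the focal sample.
#' @param cohort_hits Pooled hit tibble for the reference cohort.
#' @param nt_motifs,t_motifs Motif occurrence denominators (shared atlas).
#' @param n_boot Draws (default 10000).
#' @param seed RNG seed.
#' @param kinds Indel kinds to assess.
#' @return Tibble: `kind`, `n_focal`, `bias_focal`, `mean_draw`, `sd_draw`,
#'   `z`, `p_empirical` (NA rows where the focal sample has no hits of the
#'   kind).
#' @export
downsample_zscore <- function(focal_hits, cohort_hits, nt_motifs, t_motifs,
                              n_boot = 10000L, seed = 1L,
                              kinds = c("insertion", "deletion")) {
  stopifnot(nt_motifs > 0, t_motifs > 0)
  res <- lapply(kinds, function(k) {
    f <- focal_hits[focal_hits$kind == k, ]
    pool <- cohort_hits$strand_class[cohort_hits$kind == k]
    n <- nrow(f)
    if (n == 0L || length(pool) == 0L) {
      return(tibble(kind = k, n_focal = n, bias_focal = NA_real_,
                    mean_draw = NA_real_, sd_draw = NA_real_, z = NA_real_,
                    p_empirical = NA_real_))
    }
    p_nt <- mean(pool == "non_template")
    bias_f <- .bias_from_counts(sum(f$strand_class == "non_template"),
                                sum(f$strand_class == "template"),
                                nt_motifs, t_motifs)
    draws <- withr::with_seed(seed, rbinom(n_boot, n, p_nt))
    bias_d <- .bias_from_counts(draws, n - draws, nt_motifs, t_motifs)
    bias_d <- bias_d[!is.na(bias_d)]
    m <- mean(bias_d); s <- sd(bias_d)
    z <- if (s > 0) (bias_f - m) / s else NA_real_
    p_emp <- mean(abs(bias_d - m) >= abs(bias_f - m))
    tibble(kind = k, n_focal = n, bias_focal = bias_f, mean_draw = m,
           sd_draw = s, z = z, p_empirical = p_emp)
  })
  bind_rows(res)
}

#' Transcriptional orientation of base substitutions
#'
#' For a target change `X>Y`, a substitution inside a gene is assigned to
#' the non-template strand when the reference base read on the non-template
#' strand is `X` with alternate `Y`, and to the template strand when the
#' non-template reading is the complementary change. Substitutions with
#' reference base N or outside genes are skipped; a substitution inside two
#' overlapping genes is counted once per gene.
#'
#' @param subs Tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param genes Gene tibble.
#' @param target_change Change string like `"C>A"`.
#' @param oriented Optional oriented tract tibble: restrict to substitutions
#'   lying inside or immediately adjacent to those tracts.
#' @return List: `nt`, `t`, `per_gene` tibble of the two counts.
#' @export
substitution_orientation <- function(subs, genes, target_change = "C>A",
                                     oriented = NULL) {
  parts <- strsplit(target_change, ">", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2L)
  X <- toupper(parts[1]); Y <- toupper(parts[2])
  cmp <- c(A = "T", C = "G", G = "C", T = "A")
  subs <- subs[subs$ref %in% names(cmp), ]
  if (!is.null(oriented) && nrow(subs) > 0L) {
    sp <- GenomicRanges::GRanges(subs$chrom,
                                 IRanges::IRanges(subs$pos + 1L, subs$pos + 1L))
    tr <- GenomicRanges::GRanges(oriented$chrom,
                                 IRanges::IRanges(oriented$start, oriented$end + 1L))
    keep <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(sp, tr)))
    subs <- subs[sort(keep), ]
  }
  if (nrow(subs) == 0L || nrow(genes) == 0L) {
    return(list(nt = 0L, t = 0L,
                per_gene = tibble(gene_id = character(), nt = integer(),
                                  t = integer())))
  }
  sp <- GenomicRanges::GRanges(subs$chrom,
                               IRanges::IRanges(subs$pos + 1L, subs$pos + 1L))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(sp, gn)
  si <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  plus <- genes$strand[gi] == "+"
  ref_nt <- ifelse(plus, subs$ref[si], unname(cmp[subs$ref[si]]))
  alt_nt <- ifelse(plus, subs$alt[si], unname(cmp[subs$alt[si]]))
  is_nt <- ref_nt == X & alt_nt == Y
  is_t <- ref_nt == cmp[X] & alt_nt == cmp[Y]
  per <- tibble(gene_id = genes$gene_id[gi], nt = as.integer(is_nt),
                t = as.integer(is_t)) %>%
    group_by(gene_id) %>%
    summarise(nt = sum(nt), t = sum(t), .groups = "drop")
  list(nt = sum(is_nt), t = sum(is_t), per_gene = per)
}

#' Cohort-by-stratum dinucleotide asymmetry matrix
#'
#' Computes the strand bias for every (cohort, unit, unit-count) cell over
#' the eight orientable dinucleotide units, suitable for downstream
#' clustering. Cells whose stratum has no motifs or no hits are `NA`.
#'
#' @param indels Indel tibble for all samples.
#' @param oriented Oriented dinucleotide tract tibble.
#' @param samples Tibble with `sample_id` and `cohort`.
#' @param units Units to include (non-template reading).
#' @param max_units Unit-count strata 1..`max_units`.
#' @return List: `long` tibble (cohort, unit, n_units, four counts, bias)
#'   and `matrix` (cohorts x unit:n_units columns).
#' @export
asymmetry_matrix <- function(indels, oriented, samples, units = DINUC_UNITS,
                             max_units = 5L) {
  stopifnot(all(c("sample_id", "cohort") %in% names(samples)))
  indels <- left_join(indels, samples[, c("sample_id", "cohort")],
                      by = "sample_id")
  cohorts <- sort(unique(samples$cohort))
  rows <- list()
  for (u in units) {
    hits_u <- assign_hits(indels, oriented, target_unit = u)
    hits_u <- left_join(hits_u, samples[, c("sample_id", "cohort")],
                        by = "sample_id")
    cu <- revcomp(u)
    for (k in seq_len(max_units)) {
      mot <- oriented[oriented$nt_unit %in% c(u, cu) &
                        oriented$n_units == k & !oriented$over_max, ]
      nt_m <- sum(mot$nt_unit == u); t_m <- sum(mot$nt_unit == cu)
      hk <- hits_u[hits_u$n_units == k & !hits_u$over_max, ]
      for (co in cohorts) {
        hc <- hk[hk$cohort == co, ]
        nt_i <- sum(hc$strand_class == "non_template")
        t_i <- sum(hc$strand_class == "template")
        rows[[length(rows) + 1L]] <- tibble(
          cohort = co, unit = u, n_units = k,
          nt_indels = nt_i, t_indels = t_i, nt_motifs = nt_m, t_motifs = t_m,
          bias = .bias_from_counts(nt_i, t_i, nt_m, t_m))
      }
    }
  }
  long <- bind_rows(rows)
  wide <- tidyr::pivot_wider(
    long %>% mutate(colname = paste0(unit, ":", n_units)) %>%
      select(cohort, colname, bias),
    names_from = "colname", values_from = "bias")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$cohort
  list(long = long, matrix = mat)
}
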