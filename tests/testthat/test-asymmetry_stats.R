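# Strand-bias arithmetic, bootstrap behaviour, binomial tests, MSI
# enrichment, rank tests, down-sampling z, substitution orientation,
# dinucleotide matrix.

test_that("strand bias arithmetic on fixed counts", {
  est <- strand_bias(sc_of(20, 10, 100, 100))
  expect_equal(est$A, 0.2)
  expect_equal(est$B, 0.1)
  expect_equal(est$bias, 2 / 3)
  expect_equal(est$excess_pct, 100)

  # equal densities: bias exactly 0.5, excess 0
  eq <- strand_bias(sc_of(15, 15, 100, 100))
  expect_equal(eq$bias, 0.5)
  expect_equal(eq$excess_pct, 0)

  # background correction removes reference skew
  sk <- strand_bias(sc_of(30, 25, 120, 100))
  expect_equal(sk$bias, 0.5)

  # scaling the non-template pair leaves the bias unchanged
  a <- strand_bias(sc_of(20, 10, 100, 100))
  b <- strand_bias(sc_of(60, 10, 300, 100))
  expect_equal(a$bias, b$bias)

  # undefined cases are flagged
  expect_false(strand_bias(sc_of(5, 5, 0, 100))$defined)
  expect_false(strand_bias(sc_of(0, 0, 100, 100))$defined)
})

test_that("gene bootstrap: degenerate spread, planted recovery, sqrt(n) law", {
  # all genes identical -> every resample identical -> sd 0
  pg <- tibble::tibble(gene_id = paste0("g", 1:20),
                       nt_indels = 3L, t_indels = 2L,
                       nt_motifs = 10L, t_motifs = 10L)
  sc <- strand_counts(60, 40, 200, 200, per_gene = pg)
  b <- bootstrap_bias(sc, n_boot = 200, seed = 5)
  expect_equal(b$boot_sd, 0)
  expect_equal(b$boot_mean, 0.6)

  # bootstrap is reproducible under the seed
  withr::with_seed(31, {
    G <- 300L
    pg2 <- tibble::tibble(
      gene_id = paste0("g", seq_len(G)),
      nt_indels = rbinom(G, 10, 0.6), t_indels = rbinom(G, 10, 0.4),
      nt_motifs = 5L + rbinom(G, 5, 0.5), t_motifs = 5L + rbinom(G, 5, 0.5))
    sc2 <- strand_counts(sum(pg2$nt_indels), sum(pg2$t_indels),
                         sum(pg2$nt_motifs), sum(pg2$t_motifs), per_gene = pg2)
    b1 <- bootstrap_bias(sc2, n_boot = 300, seed = 9)
    b2 <- bootstrap_bias(sc2, n_boot = 300, seed = 9)
    expect_identical(b1$values, b2$values)

    # doubling the gene count shrinks boot_sd by ~ sqrt(2)
    pg4 <- dplyr::bind_rows(pg2, dplyr::mutate(pg2, gene_id = paste0(gene_id, "b")))
    sc4 <- strand_counts(2 * sum(pg2$nt_indels), 2 * sum(pg2$t_indels),
                         2 * sum(pg2$nt_motifs), 2 * sum(pg2$t_motifs),
                         per_gene = pg4)
    b4 <- bootstrap_bias(sc4, n_boot = 600, seed = 11)
    expect_equal(b1$boot_sd / b4$boot_sd, sqrt(2), tolerance = 0.25)
  })

  expect_error(bootstrap_bias(strand_counts(0, 0, 10, 10,
    per_gene = tibble::tibble(gene_id = c("a", "b"), nt_indels = 0L,
                              t_indels = 0L, nt_motifs = 5L, t_motifs = 5L))),
    "no indel hits")
})

test_that("binomial strand test: identities and published counts", {
  # symmetric counts give p ~ 1
  expect_gt(binomial_strand_test(sc_of(10, 10, 50, 50)), 0.99)

  # the PAH-exposure polyG counts: 77 non-template vs 39 template
  p <- binomial_strand_test(sc_of(77, 39, 100, 100))
  expect_lt(p, 0.001)
  expect_equal(p, binom.test(77, 116, 0.5)$p.value)

  # motif-share null: a skewed background is not significant by itself
  p_bg <- binomial_strand_test(sc_of(60, 40, 600, 400))
  expect_gt(p_bg, 0.9)
  # but is highly significant against the uncorrected null
  expect_lt(binomial_strand_test(sc_of(600, 400, 600, 400), null = "half"),
            1e-5)
})

test_that("binomial test is calibrated under the motif-share null", {
  withr::with_seed(41, {
    n_sim <- 1000L
    nt_m <- 600L; t_m <- 400L
    p0 <- nt_m / (nt_m + t_m)
    n <- 150L
    nt <- rbinom(n_sim, n, p0)
    pv <- vapply(nt, function(k)
      binomial_strand_test(sc_of(k, n - k, nt_m, t_m)), numeric(1))
    rate <- mean(pv < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
  })
})

test_that("MSI enrichment ratio recovers the planted proportion ratio", {
  cfg <- sim_config(seed = 37, beta = 0.5, n_genes = 400, genome_length = 2e6,
                    n_samples = 20, indels_per_sample = 200,
                    msi_fraction = 0.5, msi_multiplier = 3,
                    background_indel_rate = 0.5)
  ref <- generate_reference(cfg)
  coh <- generate_cohort(cfg, ref)
  tr <- find_homopolymer_tracts(ref$genome)
  ori <- orient_tracts(tr[tr$length >= 3, ], ref$genes)
  hits <- assign_hits(coh$indels, ori, target_unit = "T")
  enr <- msi_enrichment_ratio(coh$indels, hits, coh$samples,
                              min_tract_length = 3L)
  # closed form: p_msi = 3/(3+0.5), p_mss = 1/1.5 -> ratio = 1.2857
  expected <- (3 / 3.5) / (1 / 1.5)
  expect_equal(enr$ratio, expected, tolerance = 0.08)

  # identical groups give ratio 1 by symmetry of the generator labels
  coh$samples$msi <- rep(c(TRUE, FALSE), 10)   # relabel arbitrarily
  cfg0 <- sim_config(seed = 38, beta = 0.5, n_genes = 300, genome_length = 1.5e6,
                     n_samples = 10, indels_per_sample = 200,
                     background_indel_rate = 0.5)
  ref0 <- generate_reference(cfg0)
  coh0 <- generate_cohort(cfg0, ref0)
  tr0 <- find_homopolymer_tracts(ref0$genome)
  ori0 <- orient_tracts(tr0[tr0$length >= 3, ], ref0$genes)
  hits0 <- assign_hits(coh0$indels, ori0, target_unit = "T")
  s0 <- dplyr::mutate(coh0$samples, msi = sample_id %in% sample_id[1:5])
  enr0 <- msi_enrichment_ratio(coh0$indels, hits0, s0, min_tract_length = 3L)
  expect_equal(enr0$ratio, 1, tolerance = 0.12)

  # single-sample group computes but is flagged
  s1 <- dplyr::mutate(coh0$samples, msi = sample_id == sample_id[1])
  enr1 <- msi_enrichment_ratio(coh0$indels, hits0, s1, min_tract_length = 3L)
  expect_true(enr1$low_n)
  expect_false(is.na(enr1$ratio))
})

test_that("group comparisons: identities, power, Bonferroni", {
  withr::with_seed(53, {
    # identical group distributions: p well above significance
    v <- c(0.5, 0.52, 0.54, 0.56, 0.58, 0.6, 0.62, 0.64, 0.66, 0.68)
    g <- rep(c("a", "b"), each = 10)
    res <- group_comparison(c(v, v), g, test = "rank_sum")
    expect_gt(res$p_raw, 0.9)

    # family size 1 leaves p unchanged; larger families multiply
    expect_equal(res$p_adj, res$p_raw)
    res5 <- group_comparison(c(v, v), g, test = "rank_sum",
                             family_size = 5)
    expect_equal(res5$p_adj, min(1, res5$p_raw * 5))

    # planted MSI/MSS difference detected by rank-sum in most replicates
    hitrate <- mean(replicate(60, {
      msi <- rnorm(30, 0.62, 0.03)
      mss <- rnorm(30, 0.55, 0.03)
      group_comparison(c(msi, mss), rep(c("MSI", "MSS"), each = 30),
                       test = "rank_sum")$p_raw < 0.01
    }))
    expect_gte(hitrate, 0.9)

    # kruskal and signed rank run and agree on null-ish data
    k <- group_comparison(rnorm(60), rep(c("a", "b", "c"), 20),
                          test = "kruskal")
    expect_gt(k$p_raw, 0.001)
    sr <- group_comparison(rnorm(30), y = rnorm(30), test = "signed_rank")
    expect_gt(sr$p_raw, 0.001)

    # groups with < 2 samples are excluded with a message
    expect_message(
      group_comparison(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c"),
                       test = "rank_sum"), "excluded")
  })
})

test_that("down-sampling z: direction, calibration, normal approximation", {
  withr::with_seed(59, {
    mk_hits <- function(n, p_nt, kind = "insertion") {
      nt <- rbinom(1, n, p_nt)
      tibble::tibble(kind = kind,
                     strand_class = rep(c("non_template", "template"),
                                        c(nt, n - nt)))
    }
    cohort <- mk_hits(4000, 0.65)
    # focal sample with bias at 0.50 against a 0.65 cohort: z < 0
    focal_low <- tibble::tibble(
      kind = "insertion",
      strand_class = rep(c("non_template", "template"), c(25, 25)))
    z <- downsample_zscore(focal_low, cohort, 100, 100, n_boot = 4000,
                           seed = 3, kinds = "insertion")
    expect_lt(z$z, -1)

    # self-draws are calibrated: |z| < 2 in ~95% of repetitions
    inside <- replicate(150, {
      f <- cohort[sample.int(nrow(cohort), 50), ]
      zz <- downsample_zscore(f, cohort, 100, 100, n_boot = 1000,
                              seed = sample.int(1e6, 1), kinds = "insertion")
      abs(zz$z) < 2
    })
    expect_gt(mean(inside), 0.88)
    expect_lt(mean(inside), 1.0)

    # empirical p close to the normal approximation at n = 200
    f200 <- mk_hits(200, 0.62)
    zz <- downsample_zscore(f200, cohort, 100, 100, n_boot = 20000, seed = 8,
                            kinds = "insertion")
    p_norm <- 2 * stats::pnorm(-abs(zz$z))
    expect_lt(abs(zz$p_empirical - p_norm), 0.02)

    # zero focal insertions: flagged undefined
    z0 <- downsample_zscore(focal_low[0, ], cohort, 100, 100, n_boot = 100,
                            seed = 1, kinds = "insertion")
    expect_true(is.na(z0$z))
  })
})

test_that("substitution orientation follows gene strand", {
  genes <- tibble::tibble(gene_id = c("p", "m"), chrom = "c1",
                          start = c(0L, 200L), end = c(100L, 300L),
                          strand = c("+", "-"), biotype = "protein_coding")
  subs <- tibble::tibble(chrom = "c1",
                         pos = c(10L, 20L, 210L, 220L, 500L),
                         ref = c("C", "G", "C", "G", "C"),
                         alt = c("A", "T", "A", "T", "A"))
  res <- substitution_orientation(subs, genes, "C>A")
  # + gene: C>A at ref C -> non-template; G>T at ref G -> template C>A
  # - gene: the two swap
  expect_equal(res$nt, 2L)
  expect_equal(res$t, 2L)

  # strand swap exchanges the counts
  flipped <- genes
  flipped$strand <- c("-", "+")
  res_f <- substitution_orientation(subs, flipped, "C>A")
  expect_equal(res_f$nt, res$t)
  expect_equal(res_f$t, res$nt)
})

test_that("dinucleotide asymmetry matrix: complementarity and planted excess", {
  cfg <- sim_config(seed = 61, q = 0.5, beta = 0.7, n_genes = 300,
                    genome_length = 1.5e6, tract_units = "TG",
                    tract_length_range = c(4L, 10L),
                    n_samples = 8, indels_per_sample = 250)
  ref <- generate_reference(cfg)
  coh <- generate_cohort(cfg, ref)
  di <- find_dinucleotide_tracts(ref$genome)
  ori <- orient_tracts(di, ref$genes)
  am <- asymmetry_matrix(coh$indels, ori, coh$samples, max_units = 5L)
  long <- am$long

  # complementarity: bias(TG) = 1 - bias(CA) cell by cell
  tg <- long[long$unit == "TG", ]
  ca <- long[long$unit == "CA", ]
  ok <- !is.na(tg$bias) & !is.na(ca$bias)
  expect_true(any(ok))
  expect_equal(tg$bias[ok], 1 - ca$bias[ok], tolerance = 1e-12)

  # planted TG excess appears in TG cells (pooled over unit counts)
  tg_tot <- sum(tg$nt_indels) / sum(tg$nt_motifs)
  tg_t <- sum(tg$t_indels) / sum(tg$t_motifs)
  expect_gt(tg_tot / (tg_tot + tg_t), 0.6)

  # unplanted units carry no hits at all (background rate is zero)
  other <- long[!long$unit %in% c("TG", "CA"), ]
  expect_true(all(other$nt_indels + other$t_indels == 0))
})
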