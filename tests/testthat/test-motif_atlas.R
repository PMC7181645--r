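# Tract scanners against independent oracles; orientation algebra;
# reference asymmetry; metagene binning; TSS/TES profiles; skew.

test_that("homopolymer scanner handles forced examples", {
  g <- genome_from_seqs(c(c1 = "GAAAT"))
  tr <- find_homopolymer_tracts(g)
  expect_equal(tr$unit, c("G", "A", "T"))
  expect_equal(tr$start, c(0L, 1L, 4L))
  expect_equal(tr$end, c(1L, 4L, 5L))
  expect_equal(tr$length, c(1L, 3L, 1L))
  expect_false(any(tr$over_max))

  g12 <- genome_from_seqs(c(c1 = strrep("A", 12)))
  tr12 <- find_homopolymer_tracts(g12, max_len = 10)
  expect_equal(nrow(tr12), 1L)
  expect_equal(tr12$length, 12L)
  expect_true(tr12$over_max)

  gn <- genome_from_seqs(c(c1 = "AANAA"))
  trn <- find_homopolymer_tracts(gn)
  expect_equal(nrow(trn), 2L)   # N breaks the run
  expect_equal(trn$start, c(0L, 3L))
})

test_that("homopolymer scanner equals the regex oracle on random sequences", {
  withr::with_seed(101, {
    for (i in 1:60) {
      s <- random_seq(600, with_n = i %% 3 == 0)
      got <- find_homopolymer_tracts(genome_from_seqs(c(c1 = s)))
      want <- oracle_homopolymers(s)
      want <- want[want$unit %in% c("A", "C", "G", "T"), ]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$unit, want$unit)
    }
  })
})

test_that("dinucleotide scanner handles forced examples", {
  g <- genome_from_seqs(c(c1 = "TGTGT"))
  tr <- find_dinucleotide_tracts(g)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, "TG")
  expect_equal(tr$n_units, 2L)
  expect_equal(c(tr$start, tr$end), c(0L, 4L))

  # palindromic units cannot be oriented and are never emitted
  expect_equal(nrow(find_dinucleotide_tracts(genome_from_seqs(c(c1 = "ATATAT")))), 0L)
  expect_equal(nrow(find_dinucleotide_tracts(genome_from_seqs(c(c1 = "GCGCGC")))), 0L)
  # identical-base units belong to the homopolymer class
  expect_equal(nrow(find_dinucleotide_tracts(genome_from_seqs(c(c1 = "AAAA")))), 0L)
})

test_that("dinucleotide scanner equals the brute-force greedy oracle", {
  withr::with_seed(202, {
    for (i in 1:60) {
      s <- random_seq(600, with_n = i %% 4 == 0)
      got <- find_dinucleotide_tracts(genome_from_seqs(c(c1 = s)),
                                      min_units = 1L)
      want <- oracle_dinucs(s, min_units = 1L)
      expect_equal(got$start, want$start)
      expect_equal(got$unit, want$unit)
      expect_equal(got$n_units, want$n_units)
    }
  })
})

test_that("tracts orient by host gene strand", {
  ref <- tiny_reference()
  # chr1: polyT [10,15) inside gp(+) and polyA [44,48)... outside genes;
  # use explicit tract rows to pin the semantics
  tracts <- tibble::tibble(
    chrom = "chr1", start = c(10L, 30L), end = c(15L, 33L),
    unit = c("T", "G"), n_units = c(5L, 3L), length = c(5L, 3L),
    over_max = FALSE)
  ori <- orient_tracts(tracts, ref$genes)
  # polyT inside + gene reads T on non-template
  expect_equal(ori$nt_unit[ori$start == 10], "T")
  # polyG inside - gene reads C on non-template
  expect_equal(ori$nt_unit[ori$start == 30], "C")

  # a tract under two overlapping genes on opposite strands gets
  # complementary readings
  genes2 <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "chr1", start = c(0L, 5L),
    end = c(40L, 45L), strand = c("+", "-"), biotype = "protein_coding")
  ori2 <- orient_tracts(tracts[1, ], genes2)
  expect_setequal(ori2$nt_unit, c("T", "A"))

  # tracts straddling a gene boundary are dropped
  straddle <- tibble::tibble(chrom = "chr1", start = 23L, end = 27L,
                             unit = "T", n_units = 4L, length = 4L,
                             over_max = FALSE)
  expect_equal(nrow(orient_tracts(straddle, ref$genes)), 0L)
})

test_that("reference asymmetry counts, conservation and strand swap", {
  withr::with_seed(7, {
    n <- 400
    ori <- tibble::tibble(
      chrom = "c1", start = seq_len(n) * 10L, end = seq_len(n) * 10L + 4L,
      unit = "T", n_units = 4L, length = 4L, over_max = FALSE,
      gene_id = paste0("g", seq_len(n)),
      gene_strand = sample(c("+", "-"), n, replace = TRUE))
    ori$nt_unit <- ifelse(ori$gene_strand == "+", "T", "A")
    ra <- reference_asymmetry(ori, "T")
    # conservation: NT + T equals the number of pairs
    expect_equal(ra$nt + ra$t, n)
    # strand swap inverts the ratio
    flip <- ori
    flip$gene_strand <- ifelse(ori$gene_strand == "+", "-", "+")
    flip$nt_unit <- ifelse(flip$gene_strand == "+", "T", "A")
    ra_f <- reference_asymmetry(flip, "T")
    expect_equal(ra_f$nt, ra$t)
    expect_equal(ra_f$t, ra$nt)
    expect_equal(ra_f$ratio, 1 / ra$ratio, tolerance = 1e-12)
  })
})

test_that("planted reference skew q is recovered as ratio q/(1-q)", {
  cfg <- sim_config(seed = 31, q = 0.6, n_genes = 500, genome_length = 2e6,
                    tracts_per_gene = 4)
  ref <- generate_reference(cfg)
  tr <- find_homopolymer_tracts(ref$genome)
  ori <- orient_tracts(tr[tr$length >= 3, ], ref$genes)
  ra <- reference_asymmetry(ori, "T")
  n <- ra$nt + ra$t
  phat <- ra$nt / n
  # within 3 binomial standard errors of q
  expect_lt(abs(phat - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  # and the manifest agrees exactly
  expect_equal(ra$nt, sum(ref$tracts$reading == "non_template"))
  expect_equal(ra$t, sum(ref$tracts$reading == "template"))
})

test_that("bin enrichment: planted concentration and normalization identity", {
  withr::with_seed(5, {
    n_g <- 20L
    gl <- 10000L
    # genes far enough apart that 10 kb flank bins never overlap neighbours
    starts <- seq(21000L, by = 60000L, length.out = n_g)
    L <- max(starts) + gl + 21000L
    g <- genome_from_seqs(c(c1 = random_seq(L)))
    genes <- tibble::tibble(
      gene_id = paste0("g", seq_len(n_g)), chrom = "c1",
      start = starts, end = starts + gl,
      strand = rep(c("+", "-"), length.out = n_g),
      biotype = "protein_coding")
    # place every tract at the centre of bin 3 = the first body bin in
    # transcription order (bins 1-2 are the upstream flanks)
    bin3_start <- ifelse(genes$strand == "+",
                         genes$start + 500L,
                         genes$end - (gl %/% 10L) + 500L)
    tracts <- tibble::tibble(
      chrom = "c1", start = as.integer(bin3_start),
      end = as.integer(bin3_start + 4L), unit = "T", n_units = 4L,
      length = 4L, over_max = FALSE)
    prof <- gene_bin_enrichment(tracts, genes, g)$profile
    expect_equal(prof$n_tracts[prof$bin == 3], n_g)
    expect_equal(sum(prof$n_tracts), n_g)
    # base-weighted mean enrichment is exactly 1
    expect_equal(sum(prof$enrichment * prof$bases) / sum(prof$bases), 1,
                 tolerance = 1e-12)
    # flank bins are 10 kb each
    expect_equal(prof$bases[prof$bin == 1], 10000 * n_g)
  })
})

test_that("bin enrichment is ~1 everywhere for uniform random tracts", {
  withr::with_seed(6, {
    L <- 500000L
    g <- genome_from_seqs(c(c1 = random_seq(L)))
    genes <- tibble::tibble(
      gene_id = paste0("g", 1:10), chrom = "c1",
      start = seq(25000L, by = 45000L, length.out = 10),
      end = seq(25000L, by = 45000L, length.out = 10) + 20000L,
      strand = rep(c("+", "-"), 5), biotype = "protein_coding")
    pos <- sample.int(L - 10L, 6000L)
    tracts <- tibble::tibble(chrom = "c1", start = pos, end = pos + 2L,
                             unit = "T", n_units = 2L, length = 2L,
                             over_max = FALSE)
    prof <- gene_bin_enrichment(tracts, genes, g)$profile
    expect_true(all(abs(prof$enrichment - 1) < 0.35))
    expect_error(
      gene_bin_enrichment(tracts, genes[0, ], g), "no genes")
  })
})

test_that("TSS profile recovers a planted density step on both strands", {
  withr::with_seed(9, {
    L <- 300000L
    g <- genome_from_seqs(c(c1 = random_seq(L)))
    n_g <- 40L
    starts <- seq(6000L, by = 7000L, length.out = n_g)
    genes <- tibble::tibble(
      gene_id = paste0("g", seq_len(n_g)), chrom = "c1",
      start = starts, end = starts + 4000L,
      strand = rep(c("+", "-"), length.out = n_g),
      biotype = "protein_coding")
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    # plant polyG reading G on the non-template strand, 2x density in
    # [TSS, TSS+500): 4 tracts inside the window, 2 in [500,1000)
    mk <- function(rel) {
      gpos <- ifelse(genes$strand == "+", tss + rel, tss - rel - 3L)
      tibble::tibble(chrom = "c1", start = as.integer(gpos),
                     end = as.integer(gpos + 3L),
                     unit = ifelse(genes$strand == "+", "G", "C"),
                     n_units = 3L, length = 3L, over_max = FALSE)
    }
    tracts <- dplyr::bind_rows(lapply(c(50, 150, 250, 350, 550, 750), mk))
    prof <- positional_density_profile(tracts, genes, anchor = "TSS",
                                       window_bp = 1000L, interval = 100L,
                                       n_boot = 200L, seed = 4L)
    gprof <- prof[prof$nt_unit == "G", ]
    near <- sum(gprof$n[gprof$offset >= 0 & gprof$offset < 500])
    far <- sum(gprof$n[gprof$offset >= 500 & gprof$offset < 1000])
    expect_equal(near, 4L * n_g)
    expect_equal(far, 2L * n_g)
    # everything planted reads G on non-template; no C signal
    expect_true(all(prof$n[prof$nt_unit == "C"] == 0))
  })
})

test_that("bootstrap SE of the profile shrinks like 1/sqrt(n_genes)", {
  withr::with_seed(10, {
    build <- function(n_g) {
      starts <- seq(4000L, by = 5000L, length.out = n_g)
      genes <- tibble::tibble(
        gene_id = paste0("g", seq_len(n_g)), chrom = "c1",
        start = starts, end = starts + 3000L, strand = "+",
        biotype = "protein_coding")
      # Poisson-like random tract counts near the TSS
      rel <- sample.int(1000L, n_g * 3L, replace = TRUE)
      gidx <- sample.int(n_g, n_g * 3L, replace = TRUE)
      tibble::tibble(chrom = "c1",
                     start = as.integer(genes$start[gidx] + rel),
                     end = as.integer(genes$start[gidx] + rel + 3L),
                     unit = "T", n_units = 3L, length = 3L,
                     over_max = FALSE) -> tracts
      list(genes = genes, tracts = tracts)
    }
    a <- build(50L)
    b <- build(200L)
    pa <- positional_density_profile(a$tracts, a$genes, "TSS", 1000L, 100L,
                                     n_boot = 400L, seed = 2L)
    pb <- positional_density_profile(b$tracts, b$genes, "TSS", 1000L, 100L,
                                     n_boot = 400L, seed = 2L)
    ra <- mean(pa$se[pa$offset >= 0], na.rm = TRUE)
    rb <- mean(pb$se[pb$offset >= 0], na.rm = TRUE)
    expect_equal(ra / rb, 2, tolerance = 0.35)   # sqrt(200/50) = 2
  })
})

test_that("GC skew closed forms and reverse-complement invariance", {
  g <- genome_from_seqs(c(c1 = paste0(strrep("G", 200), strrep("C", 200),
                                      strrep("A", 100), strrep("T", 100))))
  genes <- tibble::tibble(gene_id = "g1", chrom = "c1", start = 100L,
                          end = 500L, strand = "+",
                          biotype = "protein_coding")
  sk <- sequence_skew(g, genes, anchor = "TSS", window_bp = 100L,
                      interval = 100L, kind = "GC")
  # window [100,200) is all G -> +1; [0,100) all G -> +1
  expect_equal(sk$skew, c(1, 1))

  eq <- genome_from_seqs(c(c1 = strrep("GC", 300)))
  sk_eq <- sequence_skew(eq, genes, "TSS", 100L, 100L, "GC")
  expect_equal(sk_eq$skew, c(0, 0))

  # reverse-complementing the genome and flipping strands leaves skew alone
  withr::with_seed(12, {
    s <- random_seq(4000)
    g1 <- genome_from_seqs(c(c1 = s))
    g2 <- genome_from_seqs(c(c1 = revcomp(s)))
    genes1 <- tibble::tibble(gene_id = "a", chrom = "c1", start = 1000L,
                             end = 3000L, strand = "+",
                             biotype = "protein_coding")
    genes2 <- genes1
    genes2$start <- 4000L - 3000L
    genes2$end <- 4000L - 1000L
    genes2$strand <- "-"
    for (kind in c("GC", "AT")) {
      s1 <- sequence_skew(g1, genes1, "TSS", 400L, 100L, kind)
      s2 <- sequence_skew(g2, genes2, "TSS", 400L, 100L, kind)
      expect_equal(s1$skew, s2$skew, tolerance = 1e-12)
    }
  })
})

test_that("skew windows with zero denominator are excluded", {
  g <- genome_from_seqs(c(c1 = paste0(strrep("A", 300), strrep("G", 300))))
  genes <- tibble::tibble(gene_id = "g", chrom = "c1", start = 100L,
                          end = 500L, strand = "+",
                          biotype = "protein_coding")
  sk <- sequence_skew(g, genes, "TSS", 100L, 100L, "GC")
  expect_equal(sk$n_genes, c(0L, 0L))   # both windows all-A
  expect_true(all(is.na(sk$skew)))
})
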