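# Synthetic genomes, gene annotations, expression tables, replication
# timing tracks and indel cohorts with planted, manifest-recorded
# parameters. Every pipeline stage can be tested against the closed-form
# expectations implied by the configuration.
#
# RNG discipline: each generator derives its stream from `config$seed` plus
# a fixed per-stage offset (reference +0, expression +1, repli-seq +2,
# cohort +3), so stages are individually reproducible and jointly
# deterministic.

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic run. Key planted parameters:
#' `q` is the probability that a planted tract reads its unit on the
#' non-template strand of its host gene (reference-strand placement skew;
#' the expected reference NT/T occurrence ratio is `q/(1-q)`). `beta` is the
#' target non-template share of indel density after motif correction (0.5 =
#' no asymmetry); per-kind (`beta_ins`/`beta_del`) and per-expression-tier
#' (`beta_tiers`) values override it. `msi_multiplier` scales the
#' tract-associated indel rate of MSI samples; `background_indel_rate` is
#' the rate of indels placed outside planted tracts relative to the
#' tract-associated rate (0 = every indel comes from a planted tract).
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param genome_length Total genome size in bp (split over `n_chroms`).
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of non-overlapping genes (random strands).
#' @param gene_length Gene length in bp.
#' @param tracts_per_gene Planted tracts per gene.
#' @param tract_units Repeat units to plant, as read on the tract's assigned
#'   strand (1 bp homopolymer or 2 bp dinucleotide units).
#' @param tract_length_range Planted tract length range in bp.
#' @param tract_length_geom_p Success probability of the truncated geometric
#'   tract length distribution over that range.
#' @param q Reference-strand placement skew (see above).
#' @param n_samples Samples in the cohort.
#' @param indels_per_sample Expected tract-associated indels per sample
#'   (Poisson; scaled by `msi_multiplier` for MSI samples).
#' @param insertion_fraction Probability an indel is an insertion.
#' @param beta,beta_ins,beta_del Planted strand bias (scalar, or named
#'   vector over tiers low/medium/high).
#' @param beta_tiers Optional named vector of per-tier biases overriding
#'   `beta` for both kinds.
#' @param length_slope Multiplicative increase of the per-tract indel rate
#'   per extra bp of tract length.
#' @param tier_multipliers Named per-tier multipliers of the per-tract rate.
#' @param msi_fraction Fraction of samples labelled MSI.
#' @param msi_multiplier Tract-rate multiplier for MSI samples.
#' @param background_indel_rate See above.
#' @param del_max_units Maximum repeat units removed by one deletion
#'   (default 1; larger values draw a truncated-geometric unit count for
#'   size-spectrum analyses).
#' @param rep_beta If non-`NULL`, replication-driven placement: probability
#'   an indel lands on a tract whose unit reads on the lagging strand
#'   (replaces transcription-driven `beta`).
#' @param rep_period_bp,rep_amplitude,rep_phase,rep_bin_size Sawtooth
#'   replication-timing track parameters.
#' @param cohort_name Cohort label for the sample table.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 4e6, n_chroms = 4L,
                       n_genes = 1000L, gene_length = 2000L,
                       tracts_per_gene = 4L, tract_units = "T",
                       tract_length_range = c(3L, 10L),
                       tract_length_geom_p = 0.35,
                       q = 0.5,
                       n_samples = 20L, indels_per_sample = 250,
                       insertion_fraction = 0.36,
                       beta = 0.5, beta_ins = NULL, beta_del = NULL,
                       beta_tiers = NULL,
                       length_slope = 1.0,
                       tier_multipliers = c(low = 1, medium = 1, high = 1),
                       msi_fraction = 0, msi_multiplier = 1,
                       background_indel_rate = 0,
                       del_max_units = 1L,
                       rep_beta = NULL,
                       rep_period_bp = 5e5, rep_amplitude = 1,
                       rep_phase = 0, rep_bin_size = 1e4,
                       cohort_name = "synthetic") {
  cfg <- as.list(environment())
  probs <- c(q, insertion_fraction, msi_fraction,
             unlist(cfg[c("beta", "beta_ins", "beta_del", "beta_tiers")]),
             rep_beta)
  stopifnot(all(probs >= 0 & probs <= 1),
            length_slope > 0, msi_multiplier >= 0,
            background_indel_rate >= 0,
            tract_length_range[1] >= 1L,
            tract_length_range[2] >= tract_length_range[1])
  class(cfg) <- "sim_config"
  cfg
}

# run-suppressed i.i.d. background: no run of one base longer than 2, so
# planted tracts are the only tracts of length >= 3
.background_raw <- function(len) {
  bases <- charToRaw("ACGT")
  x <- sample(bases, len, replace = TRUE)
  for (pass in 1:100) {
    bad <- which(x[-c(1L, 2L)] == x[-c(1L, len)] &
                   x[-c(1L, 2L)] == x[-c(len - 1L, len)]) + 2L
    if (length(bad) == 0L) break
    repl <- sample(bases, length(bad), replace = TRUE)
    clash <- repl == x[bad - 1L]
    while (any(clash)) {
      repl[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- repl == x[bad - 1L]
    }
    x[bad] <- repl
  }
  x
}

.truncgeom <- function(n, range, p) {
  lo <- range[1]; hi <- range[2]
  if (lo == hi) return(rep(lo, n))
  k <- hi - lo
  u <- runif(n)
  # inverse CDF of geometric truncated to 0..k
  cdf_max <- 1 - (1 - p)^(k + 1)
  lo + pmin(k, floor(log1p(-u * cdf_max) / log1p(-p)))
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Generate a synthetic reference: genome, genes and planted tracts
#'
#' Builds an i.i.d. background genome in which native runs longer than 2 bp
#' are suppressed, places non-overlapping genes of equal length on random
#' strands, and plants repeat tracts inside gene bodies. Each tract's unit
#' is read on the host gene's non-template strand with probability `q`
#' (else on the template strand); flanking bases are set so planted tracts
#' stay maximal. The manifest records every planted tract with its strand
#' reading.
#'
#' @param config A `"sim_config"`.
#' @return List of class `"sim_reference"`: `genome` (a `"genome"`),
#'   `genes` (gene tibble), `tracts` (manifest tibble with `chrom`,
#'   `start`, `end`, `unit` (reference reading), `planted_unit` (assigned
#'   reading), `length`, `gene_id`, `gene_strand`, `reading`
#'   (`"non_template"`/`"template"`)), `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_chroms <- config$n_chroms
    clen <- rep(floor(config$genome_length / n_chroms), n_chroms)
    chroms <- paste0("chr", seq_len(n_chroms))
    # gene packing
    per <- rep(floor(config$n_genes / n_chroms), n_chroms)
    extra <- config$n_genes - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    margin <- 100L
    raws <- list(); genes <- list()
    for (ci in seq_len(n_chroms)) {
      L <- clen[ci]
      ng <- per[ci]
      gap <- (L - 2L * margin - ng * config$gene_length) / (ng + 1L)
      if (gap < 10) stop("infeasible gene packing: genome too small")
      starts <- margin + round(seq_len(ng) * gap + (seq_len(ng) - 1L) * config$gene_length) +
        sample.int(max(1L, floor(gap / 2)), ng, replace = TRUE) - 1L
      raws[[ci]] <- .background_raw(L)
      genes[[ci]] <- tibble(
        gene_id = sprintf("g_%s_%04d", chroms[ci], seq_len(ng)),
        chrom = chroms[ci], start = as.integer(starts),
        end = as.integer(starts + config$gene_length),
        strand = sample(c("+", "-"), ng, replace = TRUE),
        biotype = "protein_coding")
    }
    genes <- bind_rows(genes)

    # plant tracts inside gene bodies, one per equal-width slot
    tpg <- config$tracts_per_gene
    n_tracts <- nrow(genes) * tpg
    units <- sample(config$tract_units, n_tracts, replace = TRUE)
    ul <- nchar(units)
    bp <- .truncgeom(n_tracts, config$tract_length_range,
                     config$tract_length_geom_p)
    lens_units <- pmax(1L, as.integer(bp %/% ul))
    tract_bp <- lens_units * ul
    read_nt <- runif(n_tracts) < config$q
    gidx <- rep(seq_len(nrow(genes)), each = tpg)
    slot <- rep(seq_len(tpg), times = nrow(genes))
    slot_w <- (config$gene_length - 20L) %/% tpg
    max_bp <- max(config$tract_length_range)
    if (slot_w < max_bp + 8L) stop("genes too short for requested tract planting")
    off <- sample.int(slot_w - max_bp - 6L, n_tracts, replace = TRUE)
    tstart <- genes$start[gidx] + 10L + (slot - 1L) * slot_w + off + 2L
    tend <- tstart + tract_bp

    gene_strand <- genes$strand[gidx]
    # reference reading: the assigned unit if it reads on +, else revcomp
    on_plus <- (read_nt & gene_strand == "+") | (!read_nt & gene_strand == "-")
    ref_unit <- ifelse(on_plus, units, revcomp(units))

    tracts <- tibble(
      chrom = genes$chrom[gidx], start = as.integer(tstart),
      end = as.integer(tend), unit = ref_unit, planted_unit = units,
      n_units = as.integer(lens_units), length = as.integer(tract_bp),
      gene_id = genes$gene_id[gidx], gene_strand = gene_strand,
      reading = ifelse(read_nt, "non_template", "template"))

    # write tracts into the raw genome with maximality-preserving flanks
    for (ci in seq_len(n_chroms)) {
      sel <- which(tracts$chrom == chroms[ci])
      if (length(sel) == 0L) next
      x <- raws[[ci]]
      for (i in sel) {
        s <- tracts$start[i]; e <- tracts$end[i]
        u <- charToRaw(tracts$unit[i])
        x[(s + 1L):e] <- rep(u, length.out = e - s)
        first <- u[1]; last <- u[length(u)]
        # left flank: must not extend the run nor (for dinucs) seed a
        # phase-shifting unit; a copy of the first base is safe for dinucs,
        # any differing base for homopolymers
        acgt <- as.integer(charToRaw("ACGT"))
        if (length(u) == 1L) {
          cand <- setdiff(acgt, as.integer(c(first, x[s - 1L])))
          x[s] <- as.raw(cand[1])
        } else {
          x[s] <- first
          if (x[s - 1L] == first) {
            x[s - 1L] <- as.raw(setdiff(acgt, as.integer(c(first, x[s - 2L])))[1])
          }
        }
        # right flank: break the run
        nxt <- if (e + 2L <= length(x)) x[e + 2L] else raw(0)
        cand <- setdiff(acgt, as.integer(c(last, nxt)))
        x[e + 1L] <- as.raw(cand[1])
      }
      raws[[ci]] <- x
    }
    seqs <- vapply(raws, rawToChar, character(1))
    names(seqs) <- chroms
    structure(list(genome = genome_from_seqs(seqs), genes = genes,
                   tracts = tracts, config = config),
              class = "sim_reference")
  })
}

#' Generate a gene expression table coupled to the manifest
#'
#' Draws log-normal RPKM per gene and records the implied low/medium/high
#' tier (33rd/66th percentile split, ties to the lower tier) in the result;
#' [generate_cohort()] uses these tiers for tier-dependent rates and biases.
#'
#' @param config A `"sim_config"`.
#' @param reference A `"sim_reference"`.
#' @param meanlog,sdlog Log-normal parameters of RPKM.
#' @return List: `rpkm` (tibble `gene_id`, `rpkm`), `tiers` (tibble
#'   `gene_id`, `tier`), `degenerate` flag.
#' @export
generate_expression <- function(config, reference, meanlog = 1, sdlog = 1.5) {
  withr::with_seed(config$seed + 1L, {
    genes <- reference$genes
    rpkm <- tibble(gene_id = genes$gene_id,
                   rpkm = rlnorm(nrow(genes), meanlog, sdlog))
    q <- quantile(rpkm$rpkm, c(1 / 3, 2 / 3), names = FALSE)
    tier <- ifelse(rpkm$rpkm <= q[1], "low",
                   ifelse(rpkm$rpkm <= q[2], "medium", "high"))
    list(rpkm = rpkm, tiers = tibble(gene_id = genes$gene_id, tier = tier),
         degenerate = length(unique(tier)) == 1L)
  })
}

#' Generate a sawtooth replication-timing track with orientation truth
#'
#' Produces a triangular (sawtooth) timing signal of configured period,
#' amplitude and phase, binned at `rep_bin_size`, plus the true per-bin
#' left/right replication orientation (sign of the slope; `transition`
#' where the amplitude is zero or at the teeth).
#'
#' @param config A `"sim_config"`.
#' @param reference A `"sim_reference"`.
#' @return List: `track` (a `"signal_track"` tibble), `truth` (tibble
#'   `chrom`, `start`, `end`, `orientation`).
#' @export
generate_repliseq <- function(config, reference) {
  bs <- as.integer(config$rep_bin_size)
  period <- config$rep_period_bp
  if (period < 2 * bs) stop("rep_period_bp must be at least 2 bins")
  lens <- genome_lengths(reference$genome)
  out <- lapply(names(lens), function(ch) {
    n <- lens[[ch]] %/% bs
    start <- (seq_len(n) - 1L) * bs
    mid <- start + bs / 2
    ph <- ((mid / period + config$rep_phase) %% 1)
    tri <- ifelse(ph < 0.5, 2 * ph, 2 * (1 - ph))       # rising then falling
    value <- config$rep_amplitude * tri
    orientation <- if (config$rep_amplitude == 0) {
      rep("transition", n)
    } else {
      ifelse(ph < 0.5, "right_replicating", "left_replicating")
    }
    list(track = tibble(chrom = ch, start = start, end = start + bs,
                        value = value),
         truth = tibble(chrom = ch, start = start, end = start + bs,
                        orientation = orientation))
  })
  track <- bind_rows(lapply(out, `[[`, "track"))
  attr(track, "bin_size") <- bs
  class(track) <- c("signal_track", class(track))
  list(track = track, truth = bind_rows(lapply(out, `[[`, "truth")))
}

# resolve the planted bias for given kind and tiers (vectorised over tiers)
.beta_for <- function(config, kind, tier) {
  pick <- function(b) {
    if (is.null(b)) return(NULL)
    if (length(b) == 1L && is.null(names(b))) return(rep(b, length(tier)))
    unname(b[tier])
  }
  b <- pick(if (kind == "insertion") config$beta_ins else config$beta_del)
  if (is.null(b)) b <- pick(config$beta_tiers)
  if (is.null(b)) b <- pick(config$beta)
  b
}

#' Generate an indel cohort with planted strand bias
#'
#' For each sample, tract-associated indel counts are Poisson with mean
#' `indels_per_sample` (times `msi_multiplier` for MSI samples) and
#' background counts Poisson with mean `indels_per_sample *
#' background_indel_rate`. Each tract-associated indel selects a planted
#' tract with probability proportional to
#' `length_slope^(length-1) * tier_multiplier * s(beta)`, where `s(beta)`
#' is `beta` for tracts reading their unit on the non-template strand and
#' `1 - beta` otherwise — so the planted value of `beta` is exactly the
#' expected motif-corrected non-template share of indel density. Deletions
#' remove one repeat unit at a uniform in-tract offset; insertions add one
#' unit at a uniform interior insertion point. Background indels are 1 bp
#' deletions at uniform positions outside planted tracts.
#'
#' @param config A `"sim_config"`.
#' @param reference A `"sim_reference"`.
#' @param expression Optional result of [generate_expression()] (required
#'   when tier multipliers or per-tier biases are configured).
#' @param rep_truth Optional truth tibble from [generate_repliseq()]
#'   (required when `rep_beta` is set).
#' @return List of class `"sim_cohort"`: `indels` (indel tibble),
#'   `samples` (tibble `sample_id`, `cohort`, `msi`), `manifest` (indel
#'   tibble plus `source_tract`, `planted_class`), `config`.
#' @export
generate_cohort <- function(config, reference, expression = NULL,
                            rep_truth = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  tracts <- reference$tracts
  if (nrow(tracts) == 0L) stop("no planted tracts available for indels")
  withr::with_seed(config$seed + 3L, {
    tier <- rep("medium", nrow(tracts))
    if (!is.null(expression)) {
      tier <- expression$tiers$tier[match(tracts$gene_id,
                                          expression$tiers$gene_id)]
    }
    tier_mult <- unname(config$tier_multipliers[tier])
    tier_mult[is.na(tier_mult)] <- 1
    base_w <- config$length_slope^(tracts$length - 1) * tier_mult

    nt_read <- tracts$reading == "non_template"
    if (!is.null(config$rep_beta)) {
      if (is.null(rep_truth)) stop("rep_beta requires rep_truth")
      # strand the unit reads on: reference + iff (NT reading & + gene) or
      # (T reading & - gene)
      on_plus <- (nt_read & tracts$gene_strand == "+") |
        (!nt_read & tracts$gene_strand == "-")
      tb <- GenomicRanges::GRanges(rep_truth$chrom,
                                   IRanges::IRanges(rep_truth$start + 1L,
                                                    rep_truth$end))
      tp <- GenomicRanges::GRanges(tracts$chrom,
                                   IRanges::IRanges(tracts$start + 1L,
                                                    tracts$start + 1L))
      hit <- GenomicRanges::findOverlaps(tp, tb, select = "first")
      orient <- rep_truth$orientation[hit]
      # right_lagging_plus convention: + strand lagging in right-replicating
      lagging_strand <- ifelse(orient == "right_replicating", "+", "-")
      reads_lagging <- ifelse(is.na(orient) | orient == "transition", NA,
                              (on_plus & lagging_strand == "+") |
                                (!on_plus & lagging_strand == "-"))
      class_w_ins <- class_w_del <-
        ifelse(is.na(reads_lagging), 0.5,
               ifelse(reads_lagging, config$rep_beta, 1 - config$rep_beta))
    } else {
      b_ins <- .beta_for(config, "insertion", tier)
      b_del <- .beta_for(config, "deletion", tier)
      class_w_ins <- ifelse(nt_read, b_ins, 1 - b_ins)
      class_w_del <- ifelse(nt_read, b_del, 1 - b_del)
    }
    w_ins <- base_w * class_w_ins
    w_del <- base_w * class_w_del

    n_s <- config$n_samples
    msi <- seq_len(n_s) <= round(config$msi_fraction * n_s)
    samples <- tibble(
      sample_id = sprintf("s%03d", seq_len(n_s)),
      cohort = config$cohort_name,
      msi = msi)

    lens <- genome_lengths(reference$genome)
    all_ind <- list(); all_man <- list()
    for (si in seq_len(n_s)) {
      m_s <- if (msi[si]) config$msi_multiplier else 1
      n_tr <- stats::rpois(1, config$indels_per_sample * m_s)
      n_bg <- stats::rpois(1, config$indels_per_sample *
                             config$background_indel_rate)
      n_ins <- rbinom(1, n_tr, config$insertion_fraction)
      n_del <- n_tr - n_ins

      draw <- function(n, w, kind) {
        if (n == 0L) return(NULL)
        ti <- sample.int(nrow(tracts), n, replace = TRUE, prob = w)
        tr <- tracts[ti, ]
        ulen <- nchar(tr$unit)
        if (kind == "deletion") {
          # remove m consecutive units starting at a uniform unit offset
          m <- if (config$del_max_units > 1L) {
            pmin(tr$n_units,
                 pmin(1L + stats::rgeom(n, 0.5), config$del_max_units))
          } else rep(1L, n)
          k <- floor(runif(n) * (tr$n_units - m + 1L))
          pos <- tr$start + as.integer(k) * ulen
          # units removed at a unit boundary: the deleted sequence is the
          # unit repeated, as written on the reference strand
          seqv <- strrep(tr$unit, m)
        } else {
          # interior insertion point (falls back to any in-tract point for
          # single-unit tracts)
          lo <- pmin(tr$start + 1L, tr$end)
          hi <- pmax(tr$end - 1L, lo)
          pos <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
          seqv <- tr$unit
        }
        tibble(sample_id = samples$sample_id[si], chrom = tr$chrom,
               pos = as.integer(pos), kind = kind, seq = seqv,
               length = nchar(seqv),
               source_tract = ti, planted_class = tr$reading)
      }
      ins <- draw(n_ins, w_ins, "insertion")
      del <- draw(n_del, w_del, "deletion")

      bg <- NULL
      if (n_bg > 0L) {
        # 1 bp deletions at uniform positions outside planted tracts
        pos <- integer(0); chr <- character(0)
        occupied <- GenomicRanges::GRanges(
          tracts$chrom, IRanges::IRanges(tracts$start, tracts$end + 1L))
        while (length(pos) < n_bg) {
          need <- n_bg - length(pos)
          ci <- sample(names(lens), need, replace = TRUE)
          pp <- as.integer(floor(runif(need) * (lens[ci] - 2L))) + 1L
          cand <- GenomicRanges::GRanges(ci, IRanges::IRanges(pp + 1L, pp + 1L))
          bad <- unique(S4Vectors::queryHits(
            GenomicRanges::findOverlaps(cand, occupied)))
          keep <- setdiff(seq_len(need), bad)
          pos <- c(pos, pp[keep]); chr <- c(chr, ci[keep])
        }
        seqv <- vapply(seq_len(n_bg), function(j)
          genome_subseq(reference$genome, chr[j], pos[j], pos[j] + 1L),
          character(1))
        bg <- tibble(sample_id = samples$sample_id[si], chrom = chr,
                     pos = pos, kind = "deletion", seq = seqv, length = 1L,
                     source_tract = NA_integer_,
                     planted_class = NA_character_)
      }
      man <- bind_rows(ins, del, bg)
      all_man[[si]] <- man
    }
    manifest <- bind_rows(all_man)
    manifest <- manifest[order(manifest$sample_id, manifest$chrom,
                               manifest$pos), ]
    indels <- manifest[, c("sample_id", "chrom", "pos", "kind", "seq",
                           "length")]
    structure(list(indels = indels, samples = samples, manifest = manifest,
                   config = config),
              class = "sim_cohort")
  })
}

#' Write a synthetic reference to disk
#'
#' Emits FASTA, a BED6+biotype gene table and a JSON manifest of planted
#' tracts and configuration.
#'
#' @param reference A `"sim_reference"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(reference$genome, file.path(dir, "genome.fa"))
  write_gene_table(reference$genes, file.path(dir, "genes.bed"))
  cfg <- reference$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg, tracts = reference$tracts),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a synthetic cohort to disk
#'
#' Emits one VCF per sample, a sample metadata TSV and a JSON indel
#' manifest.
#'
#' @param cohort A `"sim_cohort"`.
#' @param reference The `"sim_reference"` it was generated from.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in cohort$samples$sample_id) {
    write_indel_vcf(cohort$indels[cohort$indels$sample_id == sid, ],
                    reference$genome, file.path(dir, paste0(sid, ".vcf")))
  }
  write.table(as.data.frame(cohort$samples),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "indel_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
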