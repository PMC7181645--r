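# Stratified strand-bias analyses: gene-expression tiers, tract length,
# replication timing quantiles, leading/lagging replication orientation.

#' Assign genes to expression tiers
#'
#' Splits genes into `low`, `medium` and `high` tiers at the 33rd and 66th
#' percentiles of RPKM. Zero-RPKM ("not expressed") genes fall into `low`;
#' ties at a threshold go to the lower tier. With `zero_tier = TRUE`,
#' zero-RPKM genes form a separate `zero` tier and the percentiles are
#' computed on the remaining genes.
#'
#' @param rpkm Tibble with columns `gene_id`, `rpkm` (RPKM >= 0).
#' @param zero_tier Keep zero-RPKM genes as their own tier (default FALSE).
#' @return List of class `"expression_tiers"`: `tiers` (tibble `gene_id`,
#'   `tier`), `thresholds` (33rd/66th percentile RPKM), `degenerate` flag
#'   (all genes in one tier).
#' @export
expression_tiers <- function(rpkm, zero_tier = FALSE) {
  stopifnot(all(c("gene_id", "rpkm") %in% names(rpkm)))
  if (nrow(rpkm) == 0L) stop("empty expression table")
  if (any(rpkm$rpkm < 0)) stop("RPKM values must be >= 0")
  if (anyDuplicated(rpkm$gene_id)) stop("duplicate gene_id in expression table")
  x <- rpkm$rpkm
  base <- if (zero_tier) x[x > 0] else x
  if (length(base) == 0L) base <- x
  q <- quantile(base, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  tier <- ifelse(x <= q[1], "low", ifelse(x <= q[2], "medium", "high"))
  if (zero_tier) tier[x == 0] <- "zero"
  degenerate <- length(unique(tier)) == 1L
  structure(list(
    tiers = tibble(gene_id = rpkm$gene_id, tier = tier),
    thresholds = c(p33 = q[1], p66 = q[2]),
    degenerate = degenerate),
    class = "expression_tiers")
}

#' Strand bias per stratum
#'
#' Assembles strand counts within each stratum (motif denominators
#' restricted to the stratum's genes or tract lengths) and applies
#' [strand_bias()]. Strata can be an expression-tier assignment
#' (`stratify_by = "expression"`), tract length (`"tract_length"`), or their
#' cross (`"both"`).
#'
#' @param hits Hit tibble from [assign_hits()] for `target_unit`.
#' @param oriented Oriented tract tibble (denominators).
#' @param target_unit Unit read on the non-template strand.
#' @param tiers An `"expression_tiers"` object (required unless
#'   `stratify_by = "tract_length"`).
#' @param stratify_by `"expression"`, `"tract_length"` or `"both"`.
#' @return Tibble: stratum columns (`tier` and/or `stratum`), the four
#'   counts, `bias`, `excess_pct` (`NA` where undefined).
#' @export
stratified_bias <- function(hits, oriented, target_unit,
                            tiers = NULL,
                            stratify_by = c("expression", "tract_length", "both")) {
  stratify_by <- match.arg(stratify_by)
  cu <- revcomp(target_unit)
  mot <- oriented[oriented$nt_unit %in% c(target_unit, cu), ]
  hits <- hits[hits$nt_unit %in% c(target_unit, cu), ]
  if (is.null(hits$strand_class) || all(is.na(hits$strand_class))) {
    hits$strand_class <- ifelse(hits$nt_unit == target_unit,
                                "non_template", "template")
  }
  mot$stratum <- length_stratum(mot$length, mot$over_max)
  hits$stratum <- length_stratum(hits$tract_length, hits$over_max)
  if (stratify_by %in% c("expression", "both")) {
    stopifnot(inherits(tiers, "expression_tiers"))
    mot <- left_join(mot, tiers$tiers, by = "gene_id")
    hits <- left_join(hits, tiers$tiers, by = "gene_id")
    mot <- mot[!is.na(mot$tier), ]
    hits <- hits[!is.na(hits$tier), ]
  }
  keys <- switch(stratify_by,
                 expression = "tier",
                 tract_length = "stratum",
                 both = c("tier", "stratum"))
  mot_g <- mot %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(nt_motifs = sum(nt_unit == target_unit),
              t_motifs = sum(nt_unit == cu), .groups = "drop")
  hit_g <- hits %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(nt_indels = sum(strand_class == "non_template"),
              t_indels = sum(strand_class == "template"), .groups = "drop")
  out <- mot_g %>%
    left_join(hit_g, by = keys) %>%
    mutate(nt_indels = ifelse(is.na(nt_indels), 0L, nt_indels),
           t_indels = ifelse(is.na(t_indels), 0L, t_indels),
           bias = .bias_from_counts(nt_indels, t_indels, nt_motifs, t_motifs),
           excess_pct = ifelse(!is.na(bias) & t_indels > 0 & nt_motifs > 0,
                               ((nt_indels / nt_motifs) / (t_indels / t_motifs) - 1) * 100,
                               NA_real_))
  out
}

#' Annotate a replication timing track
#'
#' Smooths the signal with a centred moving average, takes the central first
#' difference as replication direction (positive slope = `right_replicating`,
#' negative = `left_replicating`, |slope| below `derivative_threshold` =
#' `transition`), and the second difference to flag initiation/termination
#' zones. Under the convention `rep_convention = "right_lagging_plus"`
#' (default), the reference `+` strand is the lagging-strand template in
#' right-replicating bins and leading in left-replicating bins; the
#' alternative convention inverts this. The convention is configurable
#' because it is not identifiable from the signal alone; analyses downstream
#' should test convention-independent properties.
#'
#' @param track A `"signal_track"` tibble.
#' @param smoothing_bp Moving-average window in bp (default 50000).
#' @param derivative_threshold Absolute slope (per bin) below which a bin is
#'   a transition; default the 5th percentile of |slope|.
#' @param rep_convention `"right_lagging_plus"` or `"right_leading_plus"`.
#' @return Tibble of class `"replication_annotation"`: `chrom`, `start`,
#'   `end`, `timing` (smoothed), `slope`, `curvature`, `orientation`,
#'   `plus_strand` (`"leading"`/`"lagging"`/`NA` in transitions), plus
#'   attributes `bin_size` and `rep_convention`.
#' @export
replication_annotation <- function(track, smoothing_bp = 50000L,
                                   derivative_threshold = NULL,
                                   rep_convention = c("right_lagging_plus",
                                                      "right_leading_plus")) {
  rep_convention <- match.arg(rep_convention)
  bin_size <- attr(track, "bin_size")
  if (is.null(bin_size)) bin_size <- unique(track$end - track$start)[1]
  w <- max(1L, round(smoothing_bp / bin_size))
  if (w %% 2L == 0L) w <- w + 1L
  out <- lapply(split(as.data.frame(track), track$chrom), function(sub) {
    sub <- sub[order(sub$start), ]
    n <- nrow(sub)
    if (n < w + 2L) stop("signal track shorter than smoothing window on ",
                         sub$chrom[1])
    sm <- as.numeric(stats::filter(sub$value, rep(1 / w, w), sides = 2))
    # pad smoothed ends with raw values so every bin keeps an annotation
    sm[is.na(sm)] <- sub$value[is.na(sm)]
    slope <- c(sm[2] - sm[1],
               (sm[3:n] - sm[1:(n - 2)]) / 2,
               sm[n] - sm[n - 1])
    curv <- c(0, sm[3:n] - 2 * sm[2:(n - 1)] + sm[1:(n - 2)], 0)
    tibble(chrom = sub$chrom, start = sub$start, end = sub$end,
           timing = sm, slope = slope, curvature = curv)
  })
  out <- bind_rows(out)
  thr <- if (is.null(derivative_threshold)) {
    as.numeric(quantile(abs(out$slope), 0.05))
  } else derivative_threshold
  out$orientation <- ifelse(abs(out$slope) <= thr, "transition",
                            ifelse(out$slope > 0, "right_replicating",
                                   "left_replicating"))
  right_plus <- if (rep_convention == "right_lagging_plus") "lagging" else "leading"
  left_plus <- if (right_plus == "lagging") "leading" else "lagging"
  out$plus_strand <- ifelse(out$orientation == "right_replicating", right_plus,
                            ifelse(out$orientation == "left_replicating",
                                   left_plus, NA_character_))
  attr(out, "bin_size") <- bin_size
  attr(out, "rep_convention") <- rep_convention
  attr(out, "derivative_threshold") <- thr
  class(out) <- c("replication_annotation", class(out))
  out
}

# replication class ("leading"/"lagging") of the strand a target unit is
# read on, at each tract's start bin. The reference strand shows the unit
# exactly when the tract's reference reading equals the target unit, so the
# unit-bearing strand is + iff unit == target_unit. NA in transition bins or
# outside the annotation.
.tract_replication_class <- function(chrom, start, unit_on_plus, annotation) {
  ab <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start + 1L,
                                                annotation$end))
  tp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, start + 1L))
  # disjoint chromosome sets are a valid (all-NA) outcome, not a user error
  ov <- suppressWarnings(GenomicRanges::findOverlaps(tp, ab, select = "first"))
  plus_role <- annotation$plus_strand[ov]            # NA where unmatched/transition
  ifelse(is.na(plus_role), NA_character_,
         ifelse(unit_on_plus, plus_role,
                ifelse(plus_role == "leading", "lagging", "leading")))
}

#' Strand bias controlled for replication orientation
#'
#' Partitions oriented tracts (and their hits) by the replication role of
#' the strand the target unit is read on — a motif "occurs in the leading
#' orientation" when its unit-bearing strand is the leading-strand template
#' under the annotation's convention; transition bins are dropped — and
#' computes the transcriptional strand bias within each partition. A purely
#' replication-coupled process biases the two partitions' indel totals but
#' leaves the within-partition transcriptional bias at 0.5, and a purely
#' transcription-coupled process gives equal bias in both partitions.
#'
#' @param hits Hit tibble from [assign_hits()] for `target_unit`.
#' @param oriented Oriented tract tibble.
#' @param annotation A `"replication_annotation"`.
#' @param target_unit Unit read on the non-template strand.
#' @return Tibble: `replication_class`, four counts, `bias`.
#' @export
orientation_controlled_bias <- function(hits, oriented, annotation,
                                        target_unit) {
  cu <- revcomp(target_unit)
  mot <- oriented[oriented$nt_unit %in% c(target_unit, cu), ]
  hits <- hits[hits$nt_unit %in% c(target_unit, cu), ]
  if (nrow(mot) == 0L) {
    return(tibble(replication_class = character(), nt_indels = integer(),
                  t_indels = integer(), nt_motifs = integer(),
                  t_motifs = integer(), bias = numeric()))
  }
  mot$replication_class <- .tract_replication_class(
    mot$chrom, mot$start, mot$unit == target_unit, annotation)
  if (nrow(hits) > 0L) {
    hits$replication_class <- .tract_replication_class(
      hits$chrom, hits$tract_start, hits$unit == target_unit, annotation)
    if (is.null(hits$strand_class) || all(is.na(hits$strand_class))) {
      hits$strand_class <- ifelse(hits$nt_unit == target_unit,
                                  "non_template", "template")
    }
  } else {
    hits$replication_class <- character(0)
  }
  classes <- c("leading", "lagging")
  rows <- lapply(classes, function(cl) {
    m <- mot[!is.na(mot$replication_class) & mot$replication_class == cl, ]
    h <- hits[!is.na(hits$replication_class) & hits$replication_class == cl, ]
    nt_m <- sum(m$nt_unit == target_unit); t_m <- sum(m$nt_unit == cu)
    nt_i <- sum(h$strand_class == "non_template")
    t_i <- sum(h$strand_class == "template")
    tibble(replication_class = cl, nt_indels = nt_i, t_indels = t_i,
           nt_motifs = nt_m, t_motifs = t_m,
           bias = .bias_from_counts(nt_i, t_i, nt_m, t_m))
  })
  bind_rows(rows)
}

#' Strand bias per replication timing quantile
#'
#' Assigns each gene the length-weighted mean timing of its overlapping
#' bins, splits genes into `n_quantiles` near-equal groups (quantile 1 =
#' lowest timing values), and computes the strand bias within each group.
#'
#' @param hits Hit tibble from [assign_hits()] for `target_unit`.
#' @param oriented Oriented tract tibble.
#' @param genes Gene tibble.
#' @param annotation A `"replication_annotation"` (or any constant-width
#'   signal tibble with `timing`).
#' @param target_unit Unit read on the non-template strand.
#' @param n_quantiles Number of timing groups (default 5).
#' @return List: `per_quantile` tibble (`quantile_bin`, counts, `bias`),
#'   `gene_timing` tibble (`gene_id`, `timing`, `quantile_bin`).
#' @export
timing_quantile_bias <- function(hits, oriented, genes, annotation,
                                 target_unit, n_quantiles = 5L) {
  if (nrow(genes) < n_quantiles) stop("need at least ", n_quantiles, " genes")
  gb <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  ab <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start + 1L,
                                                annotation$end))
  ov <- GenomicRanges::findOverlaps(gb, ab)
  gi <- S4Vectors::queryHits(ov); bi <- S4Vectors::subjectHits(ov)
  wdt <- GenomicRanges::width(GenomicRanges::pintersect(gb[gi], ab[bi]))
  tim <- tibble(gene_id = genes$gene_id[gi], w = wdt,
                t = annotation$timing[bi]) %>%
    group_by(gene_id) %>%
    summarise(timing = sum(w * t) / sum(w), .groups = "drop")
  # near-equal groups by rank; ties broken by order
  rk <- rank(tim$timing, ties.method = "first")
  tim$quantile_bin <- as.integer(ceiling(rk * n_quantiles / nrow(tim)))
  cu <- revcomp(target_unit)
  mot <- oriented[oriented$nt_unit %in% c(target_unit, cu), ] %>%
    left_join(tim[, c("gene_id", "quantile_bin")], by = "gene_id")
  hits <- hits[hits$nt_unit %in% c(target_unit, cu), ] %>%
    left_join(tim[, c("gene_id", "quantile_bin")], by = "gene_id")
  if (is.null(hits$strand_class) || all(is.na(hits$strand_class))) {
    hits$strand_class <- ifelse(hits$nt_unit == target_unit,
                                "non_template", "template")
  }
  per <- lapply(seq_len(n_quantiles), function(q) {
    m <- mot[!is.na(mot$quantile_bin) & mot$quantile_bin == q, ]
    h <- hits[!is.na(hits$quantile_bin) & hits$quantile_bin == q, ]
    nt_m <- sum(m$nt_unit == target_unit); t_m <- sum(m$nt_unit == cu)
    nt_i <- sum(h$strand_class == "non_template")
    t_i <- sum(h$strand_class == "template")
    tibble(quantile_bin = q, nt_indels = nt_i, t_indels = t_i,
           nt_motifs = nt_m, t_motifs = t_m,
           bias = .bias_from_counts(nt_i, t_i, nt_m, t_m))
  })
  list(per_quantile = bind_rows(per), gene_timing = tim)
}
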