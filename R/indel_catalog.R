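# Indel classification, indel-tract intersection under the positional
# overlap rule, and cohort summary statistics.

#' Positional overlap between indels and tracts
#'
#' A deletion overlaps a tract when the deleted interval `[pos, pos+length)`
#' intersects the tract interval `[start, end)`. An insertion overlaps when
#' its insertion point `p` lies inside the tract or immediately at either
#' boundary, i.e. `start <= p <= end`. Overlap is purely positional: the
#' inserted/deleted sequence is not required to match the tract unit (see
#' `require_base_match` in [assign_hits()] for the stricter mode).
#'
#' @param indels Indel tibble (parallel vectors are recycled per row).
#' @param tracts Tract tibble of the same length (row-wise comparison).
#' @return Logical vector.
#' @export
indel_tract_overlaps <- function(indels, tracts) {
  same <- indels$chrom == tracts$chrom
  del <- indels$kind == "deletion"
  ov_del <- indels$pos < tracts$end & (indels$pos + indels$length) > tracts$start
  ov_ins <- indels$pos >= tracts$start & indels$pos <= tracts$end
  same & ifelse(del, ov_del, ov_ins)
}

# 1-based closed ranges that encode the overlap predicate for IRanges:
# deletions [pos+1, pos+len]; insertions as the 2 bp window [p, p+1]
# (so p == tract.end still touches the tract range [start+1, end]).
.indel_ranges <- function(indels) {
  del <- indels$kind == "deletion"
  s <- ifelse(del, indels$pos + 1L, indels$pos)
  e <- ifelse(del, indels$pos + indels$length, indels$pos + 1L)
  GenomicRanges::GRanges(indels$chrom, IRanges::IRanges(s, e))
}

#' Intersect indels with oriented tracts for a target unit
#'
#' For a target unit U read on the non-template strand, hits on tracts with
#' `nt_unit == U` are labelled `non_template` and hits on tracts reading U on
#' the template strand (`nt_unit == revcomp(U)`) are labelled `template`.
#' An indel hitting several tracts or a tract inside several genes yields one
#' hit per (indel, tract, gene) triple. With `target_unit = NULL` all
#' oriented tracts are used and `strand_class` is left `NA` (label against a
#' unit later).
#'
#' @param indels Indel tibble.
#' @param oriented Oriented tract tibble from [orient_tracts()].
#' @param target_unit Unit read on the non-template strand (e.g. `"T"`).
#' @param require_base_match If `TRUE`, additionally require the
#'   inserted/deleted sequence to consist of the tract's reference-strand
#'   unit (sensitivity mode; default `FALSE`, the positional rule).
#' @return Tibble of hits: indel columns, tract columns prefixed `tract_`,
#'   `unit`, `n_units`, `tract_length`, `over_max`, `gene_id`,
#'   `gene_strand`, `nt_unit`, `strand_class`.
#' @export
assign_hits <- function(indels, oriented, target_unit = NULL,
                        require_base_match = FALSE) {
  if (!is.null(target_unit)) {
    keep <- oriented$nt_unit %in% c(target_unit, revcomp(target_unit))
    oriented <- oriented[keep, ]
  }
  empty <- tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    kind = character(), seq = character(), length = integer(),
    tract_start = integer(), tract_end = integer(), unit = character(),
    n_units = integer(), tract_length = integer(), over_max = logical(),
    gene_id = character(), gene_strand = character(), nt_unit = character(),
    strand_class = character())
  if (nrow(indels) == 0L || nrow(oriented) == 0L) return(empty)

  ir <- .indel_ranges(indels)
  tr <- GenomicRanges::GRanges(oriented$chrom,
                               IRanges::IRanges(oriented$start + 1L, oriented$end))
  ov <- GenomicRanges::findOverlaps(ir, tr)
  ii <- S4Vectors::queryHits(ov); ki <- S4Vectors::subjectHits(ov)
  if (length(ii) == 0L) return(empty)

  hits <- tibble(
    sample_id = indels$sample_id[ii], chrom = indels$chrom[ii],
    pos = indels$pos[ii], kind = indels$kind[ii], seq = indels$seq[ii],
    length = indels$length[ii],
    tract_start = oriented$start[ki], tract_end = oriented$end[ki],
    unit = oriented$unit[ki], n_units = oriented$n_units[ki],
    tract_length = oriented$length[ki], over_max = oriented$over_max[ki],
    gene_id = oriented$gene_id[ki], gene_strand = oriented$gene_strand[ki],
    nt_unit = oriented$nt_unit[ki],
    strand_class = if (is.null(target_unit)) NA_character_ else
      ifelse(oriented$nt_unit[ki] == target_unit, "non_template", "template"))
  if (require_base_match) {
    # the affected sequence must be a run of the tract's unit (any phase)
    ok <- mapply(function(s, u) {
      grepl(s, strrep(u, nchar(s) %/% nchar(u) + 2L), fixed = TRUE)
    }, hits$seq, hits$unit)
    hits <- hits[ok, ]
  }
  hits
}

#' Per-sample and cohort indel summary
#'
#' Per sample: insertion/deletion counts, deletion:insertion ratio, indel
#' density per Mb of callable genome. Cohort level: medians, a rank-sum test
#' comparing per-sample insertion and deletion counts, and a Brown--Forsythe
#' (median-centred Levene) test comparing insertion and deletion size
#' distributions.
#'
#' @param indels Indel tibble covering one or more samples.
#' @param callable_bp Callable genome size in bp used for density.
#' @return List with `per_sample` tibble (`sample_id`, `n_insertions`,
#'   `n_deletions`, `del_ins_ratio`, `density_per_mb`), `median_insertions`,
#'   `median_deletions`, `count_ranksum_p`, `size_variance_p`.
#' @export
cohort_summary <- function(indels, callable_bp) {
  stopifnot(nrow(indels) >= 1L, callable_bp > 0)
  per <- indels %>%
    group_by(sample_id) %>%
    summarise(n_insertions = sum(kind == "insertion"),
              n_deletions = sum(kind == "deletion"), .groups = "drop") %>%
    mutate(del_ins_ratio = ifelse(n_insertions > 0,
                                  n_deletions / n_insertions, NA_real_),
           density_per_mb = (n_insertions + n_deletions) / (callable_bp / 1e6))
  count_p <- if (nrow(per) >= 2L) {
    suppressWarnings(wilcox.test(per$n_deletions, per$n_insertions,
                                 paired = TRUE)$p.value)
  } else NA_real_
  sizes <- indels$length
  grp <- factor(indels$kind)
  var_p <- if (nlevels(grp) == 2L && all(table(grp) >= 2L) &&
               stats::var(sizes) > 0) {
    car::leveneTest(sizes ~ grp, center = median)[1, "Pr(>F)"]
  } else NA_real_
  list(per_sample = per,
       median_insertions = median(per$n_insertions),
       median_deletions = median(per$n_deletions),
       count_ranksum_p = count_p,
       size_variance_p = var_p)
}

#' Distances between consecutive indels of one sample
#'
#' Indels are sorted by position within each chromosome; distances between
#' consecutive starts are returned. Pairs spanning different chromosomes are
#' excluded.
#'
#' @param indels Indel tibble (one sample).
#' @param kind Optional restriction to `"insertion"` or `"deletion"`.
#' @return Integer vector of distances (possibly empty).
#' @export
inter_indel_distances <- function(indels, kind = NULL) {
  if (!is.null(kind)) indels <- indels[indels$kind == kind, ]
  if (nrow(indels) < 2L) return(integer(0))
  unlist(lapply(split(indels$pos, indels$chrom), function(p) {
    if (length(p) < 2L) return(integer(0))
    diff(sort(p))
  }), use.names = FALSE)
}

#' Indel frequency per tract length stratum, by MSI status
#'
#' Frequency is the number of indel-tract hits divided by the number of
#' oriented tract occurrences in the stratum, computed separately for MSI
#' and MSS sample groups (per-group numerators over a shared denominator).
#'
#' @param hits Hit tibble from [assign_hits()].
#' @param oriented Oriented tract tibble (denominators).
#' @param samples Tibble with `sample_id` and logical `msi`.
#' @return Tibble: `stratum`, `group` ("MSI"/"MSS"), `n_hits`, `n_tracts`,
#'   `frequency` (NA where the stratum has no tracts, flagged by
#'   `n_tracts == 0`).
#' @export
msi_length_response <- function(hits, oriented, samples) {
  stopifnot(all(c("sample_id", "msi") %in% names(samples)))
  hits <- left_join(hits, samples[, c("sample_id", "msi")], by = "sample_id")
  hits$group <- ifelse(hits$msi, "MSI", "MSS")
  hits$stratum <- length_stratum(hits$tract_length, hits$over_max)
  den <- oriented %>%
    mutate(stratum = length_stratum(length, over_max)) %>%
    count(stratum, name = "n_tracts")
  strata <- unique(den$stratum)
  grid <- tidyr::expand_grid(stratum = strata, group = c("MSI", "MSS"))
  num <- hits %>% count(stratum, group, name = "n_hits")
  num$stratum <- as.character(num$stratum)     # keep types stable when empty
  num$group <- as.character(num$group)
  out <- grid %>%
    left_join(num, by = c("stratum", "group")) %>%
    left_join(den, by = "stratum") %>%
    mutate(n_hits = ifelse(is.na(n_hits), 0L, n_hits),
           frequency = ifelse(n_tracts > 0, n_hits / n_tracts, NA_real_))
  ord <- suppressWarnings(as.integer(out$stratum))
  out[order(is.na(ord), ord, out$stratum, out$group), ]
}

#' Write hits as TSV
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  hits$stratum <- length_stratum(hits$tract_length, hits$over_max)
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
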