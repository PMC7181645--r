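# Repeat-tract atlas: tract discovery, transcriptional orientation, and
# reference-genome asymmetry/profile summaries.

BASES <- c("A", "C", "G", "T")
DINUC_UNITS <- c("GT", "TG", "AC", "CA", "CT", "TC", "AG", "GA")

#' Find homopolymer (polyN) repeat tracts
#'
#' Scans every chromosome for maximal runs of a single base. Runs with length
#' in `[min_len, max_len]` are emitted as tracts; longer runs are emitted
#' with their true length and flagged `over_max` (downstream length-stratified
#' analyses pool them into a single "over" stratum). N bases break runs and
#' are never part of a tract.
#'
#' @param genome A `"genome"` object.
#' @param min_len,max_len Tract length bounds in bp (defaults 1 and 10).
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `unit` (single base, reference strand), `n_units`, `length`, `over_max`.
#' @export
find_homopolymer_tracts <- function(genome, min_len = 1L, max_len = 10L) {
  out <- lapply(names(genome), function(ch) {
    raw <- charToRaw(unclass(genome)[[ch]])
    r <- rle(as.integer(raw))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    base <- rawToChar(as.raw(r$values), multiple = TRUE)
    keep <- base %in% BASES & r$lengths >= min_len
    tibble(chrom = ch, start = starts[keep], end = ends[keep],
           unit = base[keep], n_units = r$lengths[keep],
           length = r$lengths[keep], over_max = r$lengths[keep] > max_len)
  })
  bind_rows(out)
}

#' Find dinucleotide repeat tracts
#'
#' Greedy leftmost-longest scan for runs of the eight orientable dinucleotide
#' units (GT/TG/AC/CA/CT/TC/AG/GA). At each position the longest tract
#' starting there is taken and the scan skips past it, so emitted tracts
#' never overlap. Units with two identical bases are covered by the
#' homopolymer scan instead, and palindromic units (AT/TA/GC/CG) are excluded
#' because they read identically on both strands and cannot be oriented.
#' Tracts span complete units only; runs of more than `max_units` units are
#' emitted with their true length and flagged `over_max`.
#'
#' @param genome A `"genome"` object.
#' @param min_units,max_units Unit-count bounds (defaults 1 and 5, i.e.
#'   2--10 bp).
#' @return Tibble as in [find_homopolymer_tracts()] with 2-bp `unit`s.
#' @export
find_dinucleotide_tracts <- function(genome, min_units = 1L, max_units = 5L) {
  out <- lapply(names(genome), function(ch) {
    df <- .dinuc_scan(unclass(genome)[[ch]], as.integer(min_units))
    tibble(chrom = ch, start = df$start, end = df$start + 2L * df$n_units,
           unit = df$unit, n_units = df$n_units, length = 2L * df$n_units,
           over_max = df$n_units > max_units)
  })
  bind_rows(out)
}

#' Orient tracts relative to overlapping genes
#'
#' Pairs every tract with every gene that fully contains it and records the
#' repeat unit as read 5'->3' on the gene's non-template (coding) strand:
#' the reference-strand unit for genes on `+`, its reverse complement for
#' genes on `-`. A tract inside two overlapping genes yields one row per
#' gene; tracts straddling a gene boundary or outside genes are dropped.
#'
#' @param tracts Tract tibble from [find_homopolymer_tracts()] or
#'   [find_dinucleotide_tracts()].
#' @param genes Gene tibble from [read_gene_table()].
#' @return Tibble of oriented tracts: tract columns plus `gene_id`,
#'   `gene_strand`, `nt_unit`.
#' @export
orient_tracts <- function(tracts, genes) {
  if (nrow(tracts) == 0L || nrow(genes) == 0L) {
    return(dplyr::mutate(tracts[0, ], gene_id = character(),
                         gene_strand = character(), nt_unit = character()))
  }
  tr <- GenomicRanges::GRanges(tracts$chrom,
                               IRanges::IRanges(tracts$start + 1L, tracts$end))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(tr, gn, type = "within")
  ti <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  out <- tracts[ti, ]
  out$gene_id <- genes$gene_id[gi]
  out$gene_strand <- genes$strand[gi]
  out$nt_unit <- ifelse(out$gene_strand == "+", out$unit, revcomp(out$unit))
  out
}

#' Length stratum labels for tracts
#'
#' Lengths within the scanner's cap keep their bp length as the stratum;
#' over-cap tracts are pooled into a single `"over"` stratum.
#' @param length Tract lengths (bp).
#' @param over_max Logical over-cap flags.
#' @return Character vector of stratum labels.
#' @export
length_stratum <- function(length, over_max) {
  ifelse(over_max, "over", as.character(length))
}

#' Reference-genome strand asymmetry of a repeat unit
#'
#' For a target unit U (as read on the non-template strand), counts oriented
#' tracts reading U on the non-template strand (`nt_unit == U`) and on the
#' template strand (`nt_unit == revcomp(U)`), overall and per length
#' stratum, and reports the non-template/template occurrence ratio together
#' with the occurrence-weighted average ratio across length strata.
#'
#' @param oriented Oriented tract tibble from [orient_tracts()].
#' @param unit Target unit read on the non-template strand (e.g. `"T"`,
#'   `"TG"`).
#' @param by_length Include the per-length-stratum breakdown.
#' @return List of class `"ref_asymmetry"`: `unit`, `nt`, `t`, `ratio`
#'   (NA when the template count is 0), `weighted_ratio`, and (when
#'   `by_length`) tibble `per_length` with per-stratum counts and ratios.
#' @export
reference_asymmetry <- function(oriented, unit, by_length = TRUE) {
  stopifnot(nrow(oriented) >= 1L)
  cu <- revcomp(unit)
  sub <- oriented[oriented$nt_unit %in% c(unit, cu), ]
  nt <- sum(sub$nt_unit == unit)
  tt <- sum(sub$nt_unit == cu)
  res <- list(unit = unit, nt = nt, t = tt,
              ratio = if (tt > 0) nt / tt else NA_real_)
  if (by_length) {
    sub$stratum <- length_stratum(sub$length, sub$over_max)
    sub$is_nt <- sub$nt_unit == unit
    per <- sub %>%
      group_by(stratum) %>%
      summarise(nt = sum(is_nt), t = sum(!is_nt), .groups = "drop") %>%
      mutate(ratio = ifelse(t > 0, nt / t, NA_real_),
             weight = nt + t)
    ok <- !is.na(per$ratio)
    res$per_length <- per
    res$weighted_ratio <- if (any(ok)) {
      sum(per$ratio[ok] * per$weight[ok]) / sum(per$weight[ok])
    } else NA_real_
  }
  class(res) <- "ref_asymmetry"
  res
}

#' @export
print.ref_asymmetry <- function(x, ...) {
  cat("Reference strand asymmetry for unit", x$unit, "\n")
  cat("  non-template:", x$nt, " template:", x$t,
      " NT/T ratio:", format(x$ratio, digits = 4), "\n")
  if (!is.null(x$weighted_ratio)) {
    cat("  occurrence-weighted average ratio across lengths:",
        format(x$weighted_ratio, digits = 4), "\n")
  }
  invisible(x)
}

# per-chromosome cumulative count of a set of bytes; cum[i+1]-cum[j+1] style
.cum_base_count <- function(chromseq, bases) {
  raw <- charToRaw(chromseq)
  hit <- raw %in% charToRaw(paste0(bases, collapse = ""))
  c(0L, cumsum(hit))
}

#' Metagene bin enrichment of repeat tracts
#'
#' Divides every gene into `n_body_bins` equal body bins plus `flank_bins`
#' upstream and downstream flank bins of `flank_bp` each (14 bins with the
#' defaults), oriented in the direction of transcription (bin 1 is the
#' 5'-most upstream flank). A tract is assigned to the bin containing its
#' start. Bin density is the aggregated tract count divided by aggregated
#' non-N bases; enrichment is bin density over the all-bin density, so the
#' base-weighted mean enrichment is exactly 1.
#'
#' @param tracts Tract tibble (filter by `unit` upstream for per-class
#'   profiles, or use `unit`).
#' @param genes Gene tibble.
#' @param genome A `"genome"` object (for chromosome bounds and N content).
#' @param n_body_bins,flank_bp,flank_bins Binning scheme.
#' @param unit Optional unit filter applied to `tracts` (reference-strand
#'   reading together with its reverse complement).
#' @return List with `profile` (tibble: `bin`, `n_tracts`, `bases`,
#'   `density`, `enrichment`) and `n_genes_used`/`n_genes_excluded`.
#' @export
gene_bin_enrichment <- function(tracts, genes, genome, n_body_bins = 10L,
                                flank_bp = 10000L, flank_bins = 2L,
                                unit = NULL) {
  if (!is.null(unit)) {
    tracts <- tracts[tracts$unit %in% c(unit, revcomp(unit)), ]
  }
  lens <- genome_lengths(genome)
  short <- (genes$end - genes$start) < n_body_bins
  if (any(short)) {
    message(sum(short), " gene(s) shorter than ", n_body_bins, " bp excluded")
  }
  genes <- genes[!short, ]
  if (nrow(genes) == 0L) stop("no genes long enough to bin")
  n_bins <- n_body_bins + 2L * flank_bins

  # per-gene bin intervals in genome coordinates, bin index in transcription order
  bins <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]; e <- genes$end[i]
    body <- s + round((0:n_body_bins) * (e - s) / n_body_bins)
    up <- s - rev(seq_len(flank_bins)) * flank_bp     # upstream boundaries
    dn <- e + seq_len(flank_bins) * flank_bp
    bounds <- c(up, body, dn)                          # length n_bins + 1, left to right
    idx <- if (genes$strand[i] == "+") seq_len(n_bins) else rev(seq_len(n_bins))
    tibble(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
           bstart = bounds[-length(bounds)], bend = bounds[-1], bin = idx)
  })
  bins <- bind_rows(bins)
  # clip to chromosome bounds
  bins$bstart <- pmax(bins$bstart, 0L)
  bins$bend <- pmin(bins$bend, lens[bins$chrom])
  bins <- bins[bins$bend > bins$bstart, ]

  # non-N bases per bin via cumulative counts
  bins$bases <- 0
  for (ch in unique(bins$chrom)) {
    cumN <- .cum_base_count(unclass(genome)[[ch]], "N")
    sel <- bins$chrom == ch
    w <- bins$bend[sel] - bins$bstart[sel]
    nN <- cumN[bins$bend[sel] + 1L] - cumN[bins$bstart[sel] + 1L]
    bins$bases[sel] <- w - nN
  }

  # tract start -> bin assignment
  if (nrow(tracts) > 0L) {
    tp <- GenomicRanges::GRanges(tracts$chrom,
                                 IRanges::IRanges(tracts$start + 1L, tracts$start + 1L))
    bg <- GenomicRanges::GRanges(bins$chrom,
                                 IRanges::IRanges(bins$bstart + 1L, bins$bend))
    ov <- GenomicRanges::findOverlaps(tp, bg)
    counts <- tabulate(bins$bin[S4Vectors::subjectHits(ov)], nbins = n_bins)
  } else {
    counts <- integer(n_bins)
  }
  bases <- vapply(seq_len(n_bins), function(b) sum(bins$bases[bins$bin == b]),
                  numeric(1))
  dens <- counts / bases
  overall <- sum(counts) / sum(bases)
  profile <- tibble(bin = seq_len(n_bins), n_tracts = counts, bases = bases,
                    density = dens, enrichment = dens / overall)
  list(profile = profile, n_genes_used = nrow(genes),
       n_genes_excluded = sum(short))
}

#' Tract density profile around the TSS or TES
#'
#' Measures, in fixed intervals along the direction of transcription, the
#' density of tract occurrences around an anchor (TSS or TES), split by the
#' unit read on the non-template strand, with a gene-level bootstrap standard
#' error. Tracts are assigned by their 5'-most position in the direction of
#' transcription; orientation comes from the anchoring gene's strand, so
#' tracts in the flanks (outside the gene body) are included.
#'
#' @param tracts Tract tibble (typically filtered to one unit class, e.g.
#'   polyT/polyA).
#' @param genes Gene tibble.
#' @param anchor `"TSS"` or `"TES"`.
#' @param window_bp Half-window around the anchor; multiple of `interval`.
#' @param interval Interval width in bp (default 100).
#' @param n_boot Bootstrap iterations over genes (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Tibble: `offset` (interval start relative to anchor, transcription
#'   direction), `nt_unit`, `density` (occurrences per bp per gene), `se`
#'   (bootstrap), `n` (occurrences).
#' @export
positional_density_profile <- function(tracts, genes, anchor = c("TSS", "TES"),
                                       window_bp = 2000L, interval = 100L,
                                       n_boot = 1000L, seed = 1L) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) stop("no genes supplied")
  if (window_bp %% interval != 0L) stop("window_bp must be a multiple of interval")
  K <- 2L * window_bp %/% interval
  offsets <- seq(-window_bp, window_bp - interval, by = interval)

  acoord <- if (anchor == "TSS") {
    ifelse(genes$strand == "+", genes$start, genes$end)
  } else {
    ifelse(genes$strand == "+", genes$end, genes$start)
  }
  # pair genes' windows with tract 5' positions
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(acoord - window_bp, 0L) + 1L, acoord + window_bp))
  tr <- GenomicRanges::GRanges(tracts$chrom,
                               IRanges::IRanges(tracts$start + 1L, tracts$end))
  ov <- GenomicRanges::findOverlaps(tr, win)
  ti <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  plus <- genes$strand[gi] == "+"
  rel <- ifelse(plus, tracts$start[ti] - acoord[gi], acoord[gi] - tracts$end[ti])
  keep <- rel >= -window_bp & rel < window_bp
  ti <- ti[keep]; gi <- gi[keep]; rel <- rel[keep]
  nt_unit <- ifelse(genes$strand[gi] == "+", tracts$unit[ti],
                    revcomp(tracts$unit[ti]))
  kbin <- (rel + window_bp) %/% interval + 1L

  units <- sort(unique(nt_unit))
  if (length(units) == 0L) units <- character(0)
  G <- nrow(genes)
  # per-gene occurrence matrix, columns = (interval, unit)
  ncol_m <- K * max(length(units), 1L)
  M <- matrix(0L, nrow = G, ncol = ncol_m)
  if (length(units) > 0L && length(ti) > 0L) {
    uidx <- match(nt_unit, units)
    col <- (uidx - 1L) * K + kbin
    M <- matrix(tabulate((col - 1L) * G + gi, nbins = G * ncol_m), nrow = G)
  }
  dens <- colSums(M) / (G * interval)
  # gene bootstrap
  se <- rep(NA_real_, ncol_m)
  if (n_boot > 0L && G >= 2L) {
    se <- withr::with_seed(seed, {
      smp <- matrix(sample.int(G, G * n_boot, replace = TRUE), nrow = G)
      cnt <- apply(smp, 2, tabulate, nbins = G)
      boot_sums <- crossprod(M, cnt) / (G * interval)   # ncol_m x n_boot
      apply(boot_sums, 1, sd)
    })
  }
  if (length(units) == 0L) {
    return(tibble(offset = integer(), nt_unit = character(),
                  density = numeric(), se = numeric(), n = integer()))
  }
  tibble(
    offset = rep(offsets, times = length(units)),
    nt_unit = rep(units, each = K),
    density = dens, se = se,
    n = as.integer(colSums(M))
  )
}

#' GC or AT skew around the TSS or TES
#'
#' Computes (G - C)/(G + C) (or (A - T)/(A + T)) in fixed windows around the
#' anchor, read on the non-template strand of each gene (reverse complement
#' orientation for genes on `-`), and averages over genes. Windows that run
#' off a chromosome and windows with a zero denominator are excluded.
#'
#' @param genome A `"genome"` object.
#' @param genes Gene tibble.
#' @param anchor `"TSS"` or `"TES"`.
#' @param window_bp Half-window; multiple of `interval`.
#' @param interval Window width in bp (default 100).
#' @param kind `"GC"` or `"AT"`.
#' @return Tibble: `offset`, `skew` (mean over genes), `n_genes`.
#' @export
sequence_skew <- function(genome, genes, anchor = c("TSS", "TES"),
                          window_bp = 2000L, interval = 100L,
                          kind = c("GC", "AT")) {
  anchor <- match.arg(anchor)
  kind <- match.arg(kind)
  if (window_bp %% interval != 0L) stop("window_bp must be a multiple of interval")
  b1 <- substr(kind, 1, 1); b2 <- substr(kind, 2, 2)   # skew = (b1 - b2)/(b1 + b2) on NT strand
  lens <- genome_lengths(genome)
  offsets <- seq(-window_bp, window_bp - interval, by = interval)
  K <- length(offsets)

  acoord <- if (anchor == "TSS") {
    ifelse(genes$strand == "+", genes$start, genes$end)
  } else {
    ifelse(genes$strand == "+", genes$end, genes$start)
  }
  sums <- numeric(K); ns <- integer(K)
  for (ch in unique(genes$chrom)) {
    cseq <- unclass(genome)[[ch]]
    cum1 <- .cum_base_count(cseq, b1)
    cum2 <- .cum_base_count(cseq, b2)
    sel <- which(genes$chrom == ch)
    for (i in sel) {
      a <- acoord[i]
      if (genes$strand[i] == "+") {
        ws <- a + offsets
      } else {
        ws <- a - offsets - interval
      }
      we <- ws + interval
      ok <- ws >= 0L & we <= lens[[ch]]
      if (!any(ok)) next
      c1 <- cum1[we[ok] + 1L] - cum1[ws[ok] + 1L]
      c2 <- cum2[we[ok] + 1L] - cum2[ws[ok] + 1L]
      if (genes$strand[i] == "-") { tmp <- c1; c1 <- c2; c2 <- tmp }  # NT reading
      den <- c1 + c2
      good <- den > 0L
      kk <- which(ok)[good]
      sums[kk] <- sums[kk] + (c1[good] - c2[good]) / den[good]
      ns[kk] <- ns[kk] + 1L
    }
  }
  tibble(offset = offsets, skew = ifelse(ns > 0, sums / ns, NA_real_),
         n_genes = ns)
}

#' Write a tract atlas as BED6+
#'
#' Columns: chrom, start, end, name (`unit:n_units`), score (length bp),
#' strand (`.`), over_max.
#' @param tracts Tract tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tract_bed <- function(tracts, path) {
  out <- data.frame(tracts$chrom, tracts$start, tracts$end,
                    paste0(tracts$unit, ":", tracts$n_units),
                    tracts$length, ".",
                    ifelse(tracts$over_max, "over_max", "."))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
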