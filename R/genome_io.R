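# Genome, gene-table, VCF and signal-track input/output.
#
# Coordinate convention used everywhere inside the package: 0-based,
# half-open [start, end), as in BED. VCF (1-based, anchor-base indel style)
# is converted at the read/write boundary and nowhere else.

#' Read a reference genome from FASTA
#'
#' Loads all records of a FASTA file into an in-memory genome: a named
#' character vector of upper-case sequences (one element per chromosome),
#' with class `"genome"`. Multi-line records are concatenated and lower-case
#' input is upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `"genome"`; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file ", path, " contains no records")
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(Biostrings::width(set) < 1L)) {
    stop("empty FASTA record(s): ", paste(nm[Biostrings::width(set) < 1L], collapse = ", "))
  }
  g <- toupper(as.character(set))
  names(g) <- nm
  class(g) <- "genome"
  g
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of A/C/G/T/N sequences (any case).
#' @return A `"genome"` object (upper-cased).
#' @export
genome_from_seqs <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names")
  if (any(nchar(seqs) < 1L)) stop("every chromosome must have length >= 1")
  g <- toupper(seqs)
  class(g) <- "genome"
  g
}

#' Chromosome lengths of a genome
#' @param genome A `"genome"` object.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Extract a genome subsequence (0-based half-open)
#'
#' @param genome A `"genome"` object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; must satisfy
#'   `0 <= start < end <= length(chrom)`.
#' @return Character scalar.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    stop("subsequence [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", len, ")")
  }
  substr(unclass(genome)[[chrom]], start + 1L, end)
}

#' Reverse complement of a DNA string
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a genome to FASTA
#' @param genome A `"genome"` object.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene tables

#' Read a gene table (BED6 or 1-based TSV)
#'
#' BED input is 0-based half-open with columns chrom/start/end/name/score/
#' strand and an optional seventh biotype column. TSV input has a header with
#' columns `gene_id`, `chrom`, `start`, `end`, `strand` and optionally
#' `biotype`, with 1-based inclusive coordinates (Ensembl "Gene start"/"Gene
#' end" style) that are converted to 0-based half-open on read.
#'
#' @param path Input file.
#' @param coords `"bed"` (0-based half-open) or `"one-based"` (1-based
#'   inclusive TSV with header).
#' @param biotype_filter If non-`NULL`, keep only genes with this biotype.
#' @param known_chroms Optional character vector; genes on other chromosomes
#'   are dropped with a message stating the count.
#' @param chrom_style `NULL` to keep names as-is, `"chr"` to force a "chr"
#'   prefix, `"plain"` to strip it.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (0-based half-open).
#' @export
read_gene_table <- function(path, coords = c("bed", "one-based"),
                            biotype_filter = NULL, known_chroms = NULL,
                            chrom_style = NULL) {
  coords <- match.arg(coords)
  if (coords == "bed") {
    df <- read.table(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 6L) stop("BED gene table needs >= 6 columns (strand in column 6)")
    genes <- tibble(
      gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
      strand = as.character(df[[6]]),
      biotype = if (ncol(df) >= 7L) as.character(df[[7]]) else NA_character_
    )
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(df))) {
      stop("TSV gene table missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    genes <- tibble(
      gene_id = as.character(df$gene_id), chrom = as.character(df$chrom),
      start = as.integer(df$start) - 1L, end = as.integer(df$end),
      strand = as.character(df$strand),
      biotype = if ("biotype" %in% names(df)) as.character(df$biotype) else NA_character_
    )
  }
  # numeric strand dialects (Ensembl 1/-1)
  genes$strand[genes$strand %in% c("1")] <- "+"
  genes$strand[genes$strand %in% c("-1")] <- "-"
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be one of +/- (or 1/-1); offending values: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  if (!is.null(chrom_style)) genes$chrom <- restyle_chrom(genes$chrom, chrom_style)
  if (!is.null(biotype_filter)) {
    genes <- genes[!is.na(genes$biotype) & genes$biotype == biotype_filter, ]
  }
  if (!is.null(known_chroms)) {
    drop <- !(genes$chrom %in% known_chroms)
    if (any(drop)) {
      message(sum(drop), " gene(s) on unknown chromosomes dropped")
      genes <- genes[!drop, ]
    }
  }
  genes
}

#' Write a gene table as BED6(+1)
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand,
                    ifelse(is.na(genes$biotype), ".", genes$biotype))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

restyle_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", x)
  if (style == "chr") paste0("chr", bare) else bare
}

# ---------------------------------------------------------------------------
# Indels

#' Read somatic indels from a VCF file
#'
#' Accepts VCF 4.x with anchor-base indel representation (exactly one of
#' REF/ALT has length 1 after splitting multi-allelic rows). Substitutions
#' and complex MNVs are skipped with a message stating the count. The anchor
#' base is stripped: a deletion `REF=AT ALT=A` at POS gives a deletion of "T"
#' over the 0-based interval `[POS, POS+1)`; an insertion `REF=A ALT=AT` at
#' POS gives insertion point `p = POS` (between 0-based offsets POS-1 and
#' POS). When `genome` is supplied, records are left-aligned before return.
#'
#' @param path VCF file.
#' @param sample_id Sample identifier attached to every record.
#' @param genome Optional `"genome"` object used for left alignment.
#' @param normalize Left-align indels against `genome` (default `TRUE` when a
#'   genome is given).
#' @param chrom_style Optional chromosome-name restyling (see
#'   [read_gene_table()]).
#' @return Tibble with columns `sample_id`, `chrom`, `pos` (0-based; first
#'   deleted base for deletions, insertion point for insertions), `kind`
#'   (`"insertion"`/`"deletion"`), `seq`, `length`.
#' @export
read_indel_vcf <- function(path, sample_id, genome = NULL,
                           normalize = !is.null(genome), chrom_style = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)       # single-row VCFs drop to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), kind = character(), seq = character(),
                  length = integer()))
  }
  # split multi-allelic rows into one record per ALT
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  chrom <- fix$CHROM[idx]
  pos1 <- as.integer(fix$POS)[idx]
  ref <- toupper(fix$REF[idx])
  alt <- toupper(unlist(alts))

  # trim shared trailing bases (left-over from multi-allelic encoding) so the
  # anchor-base rule applies
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 1L, nr[can] - 1L)
    alt[can] <- substr(alt[can], 1L, na[can] - 1L)
  }

  nr <- nchar(ref); na <- nchar(alt)
  is_del <- nr > 1L & na == 1L
  is_ins <- nr == 1L & na > 1L
  skipped <- sum(!(is_del | is_ins))
  if (skipped > 0L) {
    message(skipped, " non-indel/complex record(s) skipped in ", basename(path))
  }
  keep_del <- which(is_del & substr(ref, 1L, 1L) == alt)
  keep_ins <- which(is_ins & substr(alt, 1L, 1L) == ref)
  bad <- sum(is_del | is_ins) - length(keep_del) - length(keep_ins)
  if (bad > 0L) message(bad, " indel record(s) without matching anchor base skipped")

  rec <- tibble(
    sample_id = sample_id,
    chrom = c(chrom[keep_del], chrom[keep_ins]),
    pos = c(pos1[keep_del], pos1[keep_ins]),   # 0-based: first deleted base / insertion point
    kind = rep(c("deletion", "insertion"), c(length(keep_del), length(keep_ins))),
    seq = c(substr(ref[keep_del], 2L, nchar(ref[keep_del])),
            substr(alt[keep_ins], 2L, nchar(alt[keep_ins])))
  )
  rec$length <- nchar(rec$seq)
  if (!is.null(chrom_style)) rec$chrom <- restyle_chrom(rec$chrom, chrom_style)
  rec <- rec[order(rec$chrom, rec$pos), ]
  if (normalize) {
    if (is.null(genome)) stop("normalize = TRUE requires a genome")
    rec <- left_align_indels(rec, genome)
  }
  rec
}

#' Left-align indel records against a genome
#'
#' Shifts every indel to its lowest-coordinate equivalent placement: a
#' deletion `[pos, pos+len)` moves one base left while the base preceding it
#' equals the last deleted base; an insertion moves left while the base
#' preceding the insertion point equals the last inserted base. Kind, length
#' and the multiset of affected bases are preserved; the operation is
#' idempotent.
#'
#' @param indels Indel tibble (see [read_indel_vcf()]).
#' @param genome A `"genome"` object.
#' @return The tibble with `pos` and `seq` normalized.
#' @export
left_align_indels <- function(indels, genome) {
  if (nrow(indels) == 0L) return(indels)
  pos <- indels$pos
  seqs <- indels$seq
  for (i in seq_len(nrow(indels))) {
    chromseq <- unclass(genome)[[indels$chrom[i]]]
    p <- pos[i]; s <- seqs[i]; len <- nchar(s)
    if (indels$kind[i] == "deletion") {
      # sanity: the record must match the reference
      if (substr(chromseq, p + 1L, p + len) != s) {
        stop("deletion at ", indels$chrom[i], ":", p,
             " does not match reference sequence")
      }
      while (p > 0L && substr(chromseq, p, p) == substr(s, len, len)) {
        s <- paste0(substr(chromseq, p, p), substr(s, 1L, len - 1L))
        p <- p - 1L
      }
    } else {
      while (p > 0L && substr(chromseq, p, p) == substr(s, len, len)) {
        s <- paste0(substr(chromseq, p, p), substr(s, 1L, len - 1L))
        p <- p - 1L
      }
    }
    pos[i] <- p; seqs[i] <- s
  }
  indels$pos <- pos
  indels$seq <- seqs
  indels
}

#' Write indel records as a minimal VCF 4.2 file
#'
#' Emits anchor-base style rows (inverse of [read_indel_vcf()]); requires the
#' genome to recover anchor bases. Indels with `pos == 0` (no anchor base
#' available) are rejected.
#'
#' @param indels Indel tibble.
#' @param genome A `"genome"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(indels, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=indelstrand"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(indels) > 0L && any(indels$pos == 0L)) {
    stop("cannot write VCF for indel at position 0 (no anchor base)")
  }
  indels <- indels[order(indels$chrom, indels$pos), ]
  rows <- character(nrow(indels))
  for (i in seq_len(nrow(indels))) {
    anchor <- genome_subseq(genome, indels$chrom[i], indels$pos[i] - 1L, indels$pos[i])
    if (indels$kind[i] == "deletion") {
      ref <- paste0(anchor, indels$seq[i]); alt <- anchor
    } else {
      ref <- anchor; alt <- paste0(anchor, indels$seq[i])
    }
    rows[i] <- paste(indels$chrom[i], indels$pos[i], ".", ref, alt, ".", ".", ".",
                     sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Signal tracks (Repli-seq)

#' Read a bedGraph signal track, re-binned to constant width
#'
#' Input intervals must be sorted and non-overlapping per chromosome. The
#' signal is re-binned to `bin_size` by length-weighted averaging of
#' overlapping input values; bins with no covering input are dropped.
#'
#' @param path bedGraph file.
#' @param bin_size Output bin width in bp; `NULL` keeps the input binning
#'   (which must then already be of constant width).
#' @param chrom_style Optional chromosome-name restyling.
#' @return Tibble of class `"signal_track"` with columns `chrom`, `start`,
#'   `end`, `value` (constant width), plus attribute `bin_size`.
#' @export
read_signal_track <- function(path, bin_size = NULL, chrom_style = NULL) {
  if (file.exists(path) && file.size(path) == 0L) {
    out <- tibble(chrom = character(), start = integer(),
                  end = integer(), value = numeric())
    attr(out, "bin_size") <- bin_size
    class(out) <- c("signal_track", class(out))
    return(out)
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
  if (!is.null(chrom_style)) df$chrom <- restyle_chrom(df$chrom, chrom_style)
  if (any(!is.finite(df$value))) stop("non-finite values in signal track")
  df <- df[order(df$chrom, df$start), ]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping intervals in signal track on ", ch)
    }
  }
  if (is.null(bin_size)) {
    w <- df$end - df$start
    if (length(unique(w)) != 1L) {
      stop("input bins have unequal widths; supply bin_size to re-bin")
    }
    out <- df
    attr(out, "bin_size") <- unique(w)
    class(out) <- c("signal_track", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(lapply(split(df, df$chrom), function(sub) {
    lo <- (min(sub$start) %/% bin_size) * bin_size
    hi <- ceiling(max(sub$end) / bin_size) * bin_size
    bs <- seq(lo, hi - bin_size, by = bin_size)
    num <- numeric(length(bs)); den <- numeric(length(bs))
    for (i in seq_len(nrow(sub))) {
      j1 <- (sub$start[i] - lo) %/% bin_size + 1L
      j2 <- (sub$end[i] - 1L - lo) %/% bin_size + 1L
      for (j in j1:j2) {
        ov <- min(sub$end[i], lo + j * bin_size) - max(sub$start[i], lo + (j - 1L) * bin_size)
        num[j] <- num[j] + ov * sub$value[i]
        den[j] <- den[j] + ov
      }
    }
    keep <- den > 0
    tibble(chrom = sub$chrom[1], start = as.integer(bs[keep]),
           end = as.integer(bs[keep] + bin_size), value = num[keep] / den[keep])
  }))
  attr(out, "bin_size") <- bin_size
  class(out) <- c("signal_track", class(out))
  out
}

#' Write a signal track as bedGraph
#' @param track A `"signal_track"` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  write.table(as.data.frame(track)[, c("chrom", "start", "end", "value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
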