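# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package code
# (regex / shifted-equality run lengths / all-pairs loops).

random_seq <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

# maximal single-base runs via regex alternation
oracle_homopolymers <- function(seq) {
  m <- gregexpr("A+|C+|G+|T+", seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), length = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
             unit = substr(rep(seq, length(m)), m, m), length = len)
}

# greedy leftmost-longest dinucleotide tracts via vectorised run lengths
oracle_dinucs <- function(seq, min_units = 1L) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  empty <- data.frame(start = integer(), unit = character(),
                      n_units = integer())
  if (n < 2L) return(empty)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- s %in% names(comp)
  if (n >= 3L) {
    tt <- s[1:(n - 2L)] == s[3:n] & ok[1:(n - 2L)] & ok[3:n]
    r <- rle(tt)
    K <- sequence(r$lengths,
                  from = ifelse(r$values, r$lengths, 0L),
                  by = ifelse(r$values, -1L, 0L))
    K <- c(K, 0L)
  } else {
    K <- 0L
  }
  nu <- 1L + K %/% 2L
  valid <- ok[1:(n - 1L)] & ok[2:n] & s[1:(n - 1L)] != s[2:n] &
    s[2:n] != unname(comp[s[1:(n - 1L)]])
  valid[is.na(valid)] <- FALSE
  starts <- integer(n); counts <- integer(n); k <- 0L
  i <- 1L
  while (i <= n - 1L) {
    if (valid[i] && nu[i] >= min_units) {
      k <- k + 1L
      starts[k] <- i - 1L
      counts[k] <- nu[i]
      i <- i + 2L * nu[i]
    } else {
      i <- i + 1L
    }
  }
  if (k == 0L) return(empty)
  data.frame(start = starts[seq_len(k)],
             unit = paste0(s[starts[seq_len(k)] + 1L],
                           s[starts[seq_len(k)] + 2L]),
             n_units = counts[seq_len(k)])
}

# all-pairs indel/tract intersection under the positional overlap rule
oracle_hits <- function(indels, tracts) {
  out <- list()
  for (ch in unique(indels$chrom)) {
    ii <- which(indels$chrom == ch)
    tt <- which(tracts$chrom == ch)
    if (length(ii) == 0L || length(tt) == 0L) next
    I <- rep(ii, each = length(tt))
    T_ <- rep(tt, times = length(ii))
    del <- indels$kind[I] == "deletion"
    hit <- ifelse(del,
                  indels$pos[I] < tracts$end[T_] &
                    indels$pos[I] + indels$length[I] > tracts$start[T_],
                  indels$pos[I] >= tracts$start[T_] &
                    indels$pos[I] <= tracts$end[T_])
    out[[ch]] <- data.frame(indel = I[hit], tract = T_[hit])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(indel = integer(), tract = integer())
  res[order(res$indel, res$tract), , drop = FALSE]
}

# enumerate every placement of an indel equivalent under sequence identity
# (used to check left alignment); returns the minimum equivalent start
oracle_leftmost_indel <- function(chromseq, pos, kind, seq) {
  len <- nchar(seq)
  n <- nchar(chromseq)
  del_at <- function(p) paste0(substr(chromseq, 1, p),
                               substr(chromseq, p + len + 1L, n))
  ins_at <- function(p, s) paste0(substr(chromseq, 1, p), s,
                                  substr(chromseq, p + 1L, n))
  target <- if (kind == "deletion") del_at(pos) else ins_at(pos, seq)
  for (p in 0:pos) {
    if (kind == "deletion") {
      if (del_at(p) == target) return(p)
    } else {
      # the inserted string at p is forced by the target sequence
      s <- substr(target, p + 1L, p + len)
      if (ins_at(p, s) == target) return(p)
    }
  }
  pos
}

# tiny deterministic fixture: two chromosomes, genes on both strands
tiny_reference <- function() {
  genome <- genome_from_seqs(c(
    chr1 = paste0("ACGTACGTAC", "TTTTT", "GACGT", "GGG", "ACGTACGTAC",
                  "AAAA", "CGTACGTACG"),
    chr2 = paste0("GTCAGTCAGT", "CCCC", "ATGCATGCAT")))
  genes <- tibble::tibble(
    gene_id = c("gp", "gm", "g2"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(5L, 28L, 5L),
    end = c(25L, 44L, 20L),
    strand = c("+", "-", "+"),
    biotype = "protein_coding")
  list(genome = genome, genes = genes)
}

# quick strand_counts builder
sc_of <- function(nt_i, t_i, nt_m, t_m) {
  strand_counts(nt_i, t_i, nt_m, t_m)
}
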