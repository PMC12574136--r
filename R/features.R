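#' Extract strand-aware break dinucleotides from filtered reads
#'
#' The 5'-end of every mapped read marks the site where the DNA backbone was
#' hydrolysed during library preparation. The break dinucleotide is the pair
#' (upstream neighbour, read first base), written 5'->3' on the read's
#' strand:
#' * forward read at 1-based position p: break position p-1 (0-based),
#'   dinucleotide = reference bases at 0-based p-2 and p-1;
#' * reverse read with 1-based alignment end e: break position e-1
#'   (0-based), dinucleotide = reverse complement of the reference bases at
#'   0-based e-1 and e.
#'
#' Reads whose required neighbour falls off the chromosome, whose
#' dinucleotide contains N, or whose 5'-end is soft/hard-clipped (unless
#' `include_clipped = TRUE`) yield no event.
#'
#' @param reads Tibble from [stream_filtered_reads()] (columns `chrom`,
#'   `start`, `end`, `strand`, and optionally `five_prime_clipped`).
#' @param genome An `fm_genome`.
#' @param include_clipped Keep reads with a 5'-clipped alignment (default
#'   FALSE: the mapped start of a clipped read is not the molecule end).
#' @return Tibble of break events: `chrom`, `break_pos` (0-based), `strand`,
#'   `dinuc`.
#' @export
break_events <- function(reads, genome, include_clipped = FALSE) {
  stopifnot(inherits(genome, "fm_genome"))
  miss <- setdiff(unique(reads$chrom), names(genome$seq))
  if (length(miss))
    stop("chromosome absent from genome: ", paste(miss, collapse = ", "))
  if (!include_clipped && "five_prime_clipped" %in% names(reads))
    reads <- reads[!reads$five_prime_clipped, , drop = FALSE]
  if (nrow(reads) == 0)
    return(tibble(chrom = character(), break_pos = integer(),
                  strand = character(), dinuc = character()))
  len <- unname(genome$lengths[reads$chrom])
  fwd <- reads$strand == "+"
  # 1-based substring bounds of the two reference bases under the dinucleotide
  lo1 <- ifelse(fwd, reads$start - 1L, reads$end)
  hi1 <- lo1 + 1L
  ok <- lo1 >= 1L & hi1 <= len
  ref_dinuc <- rep(NA_character_, nrow(reads))
  ref_dinuc[ok] <- substring(genome$seq[reads$chrom[ok]], lo1[ok], hi1[ok])
  dinuc <- ref_dinuc
  rev_ok <- ok & !fwd
  dinuc[rev_ok] <- revcomp_chr(ref_dinuc[rev_ok])
  keep <- ok & !is.na(dinuc) & dinuc %in% dinucleotides()
  tibble(
    chrom = reads$chrom[keep],
    break_pos = as.integer(ifelse(fwd, reads$start - 1L, reads$end - 1L))[keep],
    strand = reads$strand[keep],
    dinuc = dinuc[keep]
  )
}

#' Count overlapping dinucleotides in a sequence
#'
#' Counts all L-1 overlapping windows; windows containing N (or any
#' non-ACGT letter) are excluded.
#'
#' @param sequence Nucleotide string, length >= 2.
#' @return Named integer vector over [dinucleotides()].
#' @export
count_island_dinucleotides <- function(sequence) {
  if (nchar(sequence) < 2) stop("sequence must contain at least one dinucleotide")
  cnt <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(sequence))
  cnt[dinucleotides()]
}

# dinucleotide composition matrix (islands x 16) from island sequences
island_dinuc_matrix <- function(islands) {
  if (any(islands$length < 2)) stop("island shorter than 2 bp")
  m <- Biostrings::dinucleotideFrequency(Biostrings::DNAStringSet(islands$sequence))
  m <- m[, dinucleotides(), drop = FALSE]
  rownames(m) <- islands$island_id
  m
}

#' Attribute break events to islands and accumulate sufficient statistics
#'
#' An event is attributed to an island when both bases of its break
#' dinucleotide lie within the island's \[start, end) interval, so that the
#' event numerator and the sequence-composition denominator of the odds
#' ratio range over the same L-1 dinucleotide positions. Overlapping
#' islands each receive the event independently.
#'
#' @param islands Island tibble from [load_islands()].
#' @param events Break-event tibble from [break_events()].
#' @return An `fm_counts` object: island table plus matrices `n` (events per
#'   dinucleotide), `m` (sequence composition), vectors `N` (total events)
#'   and `L` (island length).
#' @export
island_counts <- function(islands, events) {
  dn <- dinucleotides()
  n <- matrix(0L, nrow = nrow(islands), ncol = 16,
              dimnames = list(islands$island_id, dn))
  if (nrow(events) > 0) {
    # 0-based leftmost base of the break dinucleotide footprint
    lo <- ifelse(events$strand == "+", events$break_pos - 1L, events$break_pos)
    for (ch in unique(islands$chrom)) {
      isl_i <- which(islands$chrom == ch)
      ev_i <- which(events$chrom == ch)
      if (!length(ev_i)) next
      ev_r <- IRanges::IRanges(start = lo[ev_i] + 1L, width = 2L)
      isl_r <- IRanges::IRanges(start = islands$start[isl_i] + 1L,
                                end = islands$end[isl_i])
      hits <- IRanges::findOverlaps(ev_r, isl_r, type = "within")
      if (!length(hits)) next
      tab <- table(
        factor(isl_i[S4Vectors::subjectHits(hits)], levels = seq_len(nrow(islands))),
        factor(events$dinuc[ev_i[S4Vectors::queryHits(hits)]], levels = dn)
      )
      n <- n + unclass(tab)
    }
  }
  structure(
    list(
      islands = dplyr::select(islands, "island_id", "chrom", "start", "end", "length"),
      n = n,
      m = island_dinuc_matrix(islands),
      N = rowSums(n),
      L = setNames(islands$length, islands$island_id)
    ),
    class = "fm_counts"
  )
}

#' @export
print.fm_counts <- function(x, ...) {
  cat("<fm_counts> ", nrow(x$islands), " island(s), ",
      format(sum(x$N), big.mark = ","), " attributed event(s), ",
      sum(x$N == 0), " uncovered\n", sep = "")
  invisible(x)
}

#' Compute per-island dinucleotide fragmentation odds ratios
#'
#' For island i and dinucleotide XY,
#' rho_XY = (n_XY / N) / (m_XY / (L - 1)):
#' the fraction of break events at XY relative to the fraction of island
#' dinucleotide positions that are XY. Under uniform fragmentation every
#' rho is ~1. By convention rho_XY = 0 when the island has no XY
#' dinucleotide or no XY event; an island with no events at all gets an
#' all-zero vector and is flagged uncovered.
#'
#' @param counts An `fm_counts` object from [island_counts()].
#' @return Tibble with `island_id`, `chrom`, `start`, `end`, `N`,
#'   `uncovered`, and the 16 `rho_AA` ... `rho_TT` columns in canonical
#'   order.
#' @export
compute_rho <- function(counts) {
  stopifnot(inherits(counts, "fm_counts"))
  N <- counts$N
  L <- counts$L
  frac_n <- counts$n / ifelse(N > 0, N, 1)
  frac_m <- counts$m / (L - 1)
  rho <- ifelse(counts$n > 0 & counts$m > 0, frac_n / frac_m, 0)
  rho[N == 0, ] <- 0
  colnames(rho) <- rho_cols()
  dplyr::bind_cols(
    counts$islands[, c("island_id", "chrom", "start", "end")],
    tibble(N = as.integer(N), uncovered = N == 0),
    as_tibble(rho)
  )
}

#' Featurize an alignment file into per-island rho vectors
#'
#' Runs the full extraction path: filtered read loading, break-dinucleotide
#' extraction, island attribution and odds-ratio computation.
#'
#' @param alignment_path Coordinate-sorted indexed BAM (or SAM) path.
#' @param genome An `fm_genome`.
#' @param islands Island tibble from [load_islands()].
#' @param mapq_min Minimum mapping quality (default 0).
#' @param include_clipped Keep 5'-clipped reads (default FALSE).
#' @return Rho tibble as from [compute_rho()].
#' @export
featurize <- function(alignment_path, genome, islands, mapq_min = 0,
                      include_clipped = FALSE) {
  reads <- stream_filtered_reads(alignment_path, mapq_min = mapq_min)
  events <- break_events(reads, genome, include_clipped = include_clipped)
  counts <- island_counts(islands, events)
  message("featurize: ", nrow(events), " break event(s), ",
          sum(counts$N), " attributed to islands, ",
          sum(counts$N == 0), " island(s) uncovered")
  compute_rho(counts)
}

#' Featurize an in-memory break-event table
#'
#' Same computation as [featurize()] but starting from events already in
#' memory (e.g. from the simulator), bypassing alignment parsing.
#'
#' @param events Break-event tibble.
#' @param islands Island tibble.
#' @return Rho tibble as from [compute_rho()].
#' @export
featurize_events <- function(events, islands) {
  compute_rho(island_counts(islands, events))
}
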