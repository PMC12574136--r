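# shared fixtures: tiny genomes, hand-built SAM files, and naive oracle
# implementations kept deliberately independent of the package internals

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(purrr::map2(names(seqs), seqs, ~c(paste0(">", .x), .y))),
             path)
  path
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  path
}

# minimal SAM writer for arbitrary flag/mapq/cigar records
write_test_sam <- function(records, chrom_lengths,
                           path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(chrom_lengths), "\tLN:",
                     unname(chrom_lengths)))
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  lines <- sprintf("r%03d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   seq_len(nrow(records)), records$flag, records$chrom,
                   records$pos, records$mapq, records$cigar)
  writeLines(c(header, lines), path)
  path
}

toy_islands <- function(genome, chrom, start, end, id = NULL) {
  id <- id %||% paste0(chrom, ":", start, "-", end)
  tibble::tibble(
    island_id = id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), length = as.integer(end - start),
    sequence = unname(fragmeth::genome_slice(genome, chrom, start, end))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive dinucleotide counter: plain substr loop
naive_dinuc_counts <- function(sequence) {
  dn <- fragmeth::dinucleotides()
  out <- setNames(integer(16), dn)
  for (i in seq_len(nchar(sequence) - 1)) {
    d <- substr(sequence, i, i + 1)
    if (d %in% dn) out[d] <- out[d] + 1L
  }
  out
}

# naive per-island rho: one island at a time, attribution and odds ratio
# recomputed from first principles (no interval-tree machinery)
naive_rho <- function(islands, events) {
  dn <- fragmeth::dinucleotides()
  res <- matrix(0, nrow(islands), 16, dimnames = list(islands$island_id, dn))
  lo <- ifelse(events$strand == "+", events$break_pos - 1L, events$break_pos)
  for (i in seq_len(nrow(islands))) {
    m <- naive_dinuc_counts(islands$sequence[i])
    L <- islands$length[i]
    sel <- events$chrom == islands$chrom[i] &
      lo >= islands$start[i] & lo + 1L <= islands$end[i] - 1L
    n <- table(factor(events$dinuc[sel], levels = dn))
    N <- sum(n)
    if (N > 0)
      for (d in dn)
        if (n[d] > 0 && m[d] > 0)
          res[i, d] <- (n[d] / N) / (m[d] / (L - 1))
  }
  res
}

# naive break-dinucleotide extraction from a read table, character by
# character (preallocated accumulators; still one read at a time)
naive_break_events <- function(reads, genome_seqs) {
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nrow(reads)
  chrom <- character(n); bp <- integer(n); strand <- character(n)
  dinuc <- character(n); k <- 0L
  for (j in seq_len(n)) {
    s <- genome_seqs[[reads$chrom[j]]]
    if (reads$strand[j] == "+") {
      p <- reads$start[j]
      if (p < 2) next
      d <- paste0(substr(s, p - 1, p - 1), substr(s, p, p))
      b <- p - 1L
    } else {
      e <- reads$end[j]
      if (e + 1 > nchar(s)) next
      b1 <- substr(s, e, e); b2 <- substr(s, e + 1, e + 1)
      if (!(b1 %in% names(rc)) || !(b2 %in% names(rc))) next
      d <- paste0(rc[[b2]], rc[[b1]])
      b <- e - 1L
    }
    if (!grepl("^[ACGT]{2}$", d)) next
    k <- k + 1L
    chrom[k] <- reads$chrom[j]; bp[k] <- b
    strand[k] <- reads$strand[j]; dinuc[k] <- d
  }
  tibble::tibble(chrom = chrom[seq_len(k)], break_pos = bp[seq_len(k)],
                 strand = strand[seq_len(k)], dinuc = dinuc[seq_len(k)])
}

# small labeled feature table with a separable rho_CG signal
separable_dataset <- function(n_per_class = 40, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  rho <- matrix(runif(n * 16, 0.5, 1.5), n, 16,
                dimnames = list(NULL, paste0("rho_", fragmeth::dinucleotides())))
  label <- rep(c(1L, 0L), each = n_per_class)
  rho[, "rho_CG"] <- ifelse(label == 1L, 2 + runif(n, -0.1, 0.1),
                            0.5 + runif(n, -0.1, 0.1))
  dplyr::bind_cols(
    tibble::tibble(island_id = sprintf("i%03d", seq_len(n)),
                   chrom = "c1", start = seq_len(n) * 100L,
                   end = seq_len(n) * 100L + 50L, label = label),
    tibble::as_tibble(rho)
  )
}
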