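#' Construct a genome object from in-memory sequences
#'
#' A genome is a named set of chromosome sequences over the alphabet
#' {A,C,G,T,N}. Lowercase (soft-masked) bases are uppercased; IUPAC
#' ambiguity codes other than N are converted to N.
#'
#' @param sequences Named character vector of nucleotide strings.
#' @return An object of class `fm_genome` with elements `seq` (named
#'   uppercase character vector) and `lengths` (named integer vector).
#' @export
fm_genome <- function(sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome name: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  seqs <- toupper(sequences)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  structure(
    list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
    class = "fm_genome"
  )
}

#' @export
print.fm_genome <- function(x, ...) {
  cat("<fm_genome> ", length(x$seq), " sequence(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Load a reference genome from FASTA
#'
#' Sequence names are taken as the first whitespace-delimited token of each
#' FASTA header. Soft-masked (lowercase) bases are treated as ordinary
#' nucleotides.
#'
#' @param fasta_path Path to a FASTA file (optionally with a .fai index).
#' @return An `fm_genome` object.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- setNames(as.character(dss), nm)
  fm_genome(seqs)
}

#' Extract a genome slice (0-based half-open coordinates)
#'
#' @param genome An `fm_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Nucleotide string of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "fm_genome"))
  if (!all(chrom %in% names(genome$seq)))
    stop("chromosome absent from genome: ",
         paste(setdiff(chrom, names(genome$seq)), collapse = ", "))
  substring(genome$seq[chrom], start + 1L, end)
}

#' Load CpG islands from BED and attach their sequences
#'
#' Reads BED3/BED4 (0-based half-open). Islands are sorted by (chrom, start)
#' and given stable ids `chrom:start-end` when the BED name column is
#' absent. Intervals on chromosomes missing from the genome, empty or
#' reversed intervals, intervals shorter than 2 bp and intervals running off
#' the chromosome end are dropped with a warning.
#'
#' @param bed_path Path to a BED file.
#' @param genome An `fm_genome`.
#' @return A tibble with columns `island_id`, `chrom`, `start`, `end`,
#'   `length`, `sequence`.
#' @export
load_islands <- function(bed_path, genome) {
  stopifnot(inherits(genome, "fm_genome"))
  raw <- readr::read_tsv(bed_path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3) stop("BED file must have at least 3 columns: ", bed_path)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinates in BED file '", bed_path, "' (line ",
         which(is.na(start) | is.na(end))[1], ")")
  tbl <- tibble(
    chrom = raw[[1]],
    start = as.integer(start),
    end = as.integer(end),
    island_id = if (ncol(raw) >= 4) raw[[4]] else NA_character_
  )
  tbl$island_id <- ifelse(is.na(tbl$island_id) | tbl$island_id == "" | tbl$island_id == ".",
                          paste0(tbl$chrom, ":", tbl$start, "-", tbl$end),
                          tbl$island_id)

  bad_interval <- tbl$start >= tbl$end | (tbl$end - tbl$start) < 2L
  if (any(bad_interval))
    warning(sum(bad_interval), " interval(s) rejected (empty, reversed or < 2 bp)")
  off_chrom <- !(tbl$chrom %in% names(genome$seq))
  if (any(off_chrom & !bad_interval))
    warning(sum(off_chrom & !bad_interval),
            " interval(s) dropped: chromosome absent from genome")
  keep <- !bad_interval & !off_chrom
  over_end <- keep & tbl$end > genome$lengths[tbl$chrom]
  over_end[is.na(over_end)] <- FALSE
  if (any(over_end))
    warning(sum(over_end), " interval(s) dropped: end beyond chromosome length")
  tbl <- tbl[keep & !over_end, , drop = FALSE]
  tbl <- dplyr::arrange(tbl, .data$chrom, .data$start, .data$end)
  tbl$length <- tbl$end - tbl$start
  tbl$sequence <- unname(genome_slice(genome, tbl$chrom, tbl$start, tbl$end))
  dplyr::select(tbl, "island_id", "chrom", "start", "end", "length", "sequence")
}

#' Write islands back to BED4
#'
#' @param islands Island tibble as returned by [load_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  readr::write_tsv(
    dplyr::select(islands, "chrom", "start", "end", "island_id"),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Load filtered aligned reads from BAM/SAM
#'
#' Applies the read-level filtering contract: only mapped, properly paired,
#' primary (not secondary, not supplementary/chimeric), non-duplicate,
#' QC-passing records with mapping quality >= `mapq_min` are returned. Both
#' mates of a proper pair are returned, since each read 5'-end is an
#' independent break observation.
#'
#' A `.sam` input is converted to a sorted, indexed BAM in a temporary
#' directory. A `.bam` input must be coordinate-sorted and indexed.
#'
#' @param alignment_path Path to a coordinate-sorted BAM (indexed) or a SAM.
#' @param mapq_min Minimum mapping quality (default 0: flag filters only).
#' @return Tibble with columns `chrom`, `start` (1-based leftmost),
#'   `end` (1-based inclusive), `strand`, `mapq`, `five_prime_clipped`.
#' @export
stream_filtered_reads <- function(alignment_path, mapq_min = 0) {
  if (!file.exists(alignment_path)) stop("alignment file not found: ", alignment_path)
  bam <- alignment_path
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(alignment_path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("BAM index not found for '", bam,
           "'; index it first (samtools index / Rsamtools::indexBam)")
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  so <- unname(sub(".*SO:", "", grep("SO:", unlist(hdr$text["@HD"]), value = TRUE)))
  if (length(so) == 1 && so != "coordinate")
    stop("alignment file is not coordinate-sorted (SO:", so, ")")

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isProperPair = TRUE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE, isNotPassingQualityControls = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq_min,
                                   what = c("mapq", "cigar"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  n_total <- Rsamtools::countBam(bam)$records
  md <- S4Vectors::mcols(ga)
  strand <- as.character(GenomicAlignments::strand(ga))
  cig <- md$cigar
  clipped5 <- ifelse(strand == "+",
                     grepl("^[0-9]+[SH]", cig),
                     grepl("[0-9]+[SH]$", cig))
  out <- tibble(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = strand,
    mapq = md$mapq,
    five_prime_clipped = clipped5
  )
  message("stream_filtered_reads: ", nrow(out), " record(s) accepted, ",
          n_total - nrow(out), " rejected by filters")
  out
}

#' Load a WGBS methylome (bedMethyl or Bismark coverage)
#'
#' Positions are normalised to the 0-based coordinate of the CpG cytosine on
#' the forward strand; methylation fractions are normalised to \[0,1\]. In
#' the bedMethyl dialect, minus-strand records (the G of the CpG) are
#' shifted one base left to the forward-strand C. The Bismark coverage
#' dialect (1-based positions, percent, methylated count, unmethylated
#' count) recomputes the fraction from the two counts. With
#' `merge_strands = TRUE`, records sharing one normalised position are
#' merged by summing coverage and coverage-weighting the fraction.
#'
#' @param path Path to the methylome file.
#' @param dialect `"auto"` (detect by column count), `"bedMethyl"` or
#'   `"bismark_cov"`.
#' @param merge_strands Merge records mapping to the same CpG (default
#'   FALSE: records are kept as reported).
#' @return Tibble with columns `chrom`, `pos` (0-based forward-strand C),
#'   `coverage`, `meth_fraction`.
#' @export
load_methylome <- function(path, dialect = c("auto", "bedMethyl", "bismark_cov"),
                           merge_strands = FALSE) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (dialect == "auto") {
    dialect <- if (ncol(raw) >= 10) "bedMethyl"
    else if (ncol(raw) == 6) "bismark_cov"
    else stop("cannot auto-detect methylome dialect from ", ncol(raw),
              " columns in ", path)
  }
  if (dialect == "bedMethyl") {
    if (ncol(raw) < 11) stop("bedMethyl requires 11 columns, got ", ncol(raw))
    cov <- suppressWarnings(as.numeric(raw[[10]]))
    pct <- suppressWarnings(as.numeric(raw[[11]]))
    pos <- suppressWarnings(as.integer(raw[[2]]))
    strand <- raw[[6]]
    if (anyNA(cov) || anyNA(pct) || anyNA(pos))
      stop("non-numeric field in bedMethyl file ", path)
    if (any(pct < 0 | pct > 100))
      stop("bedMethyl percent column outside [0,100] in ", path)
    tbl <- tibble(
      chrom = raw[[1]],
      pos = ifelse(strand == "-", pos - 1L, pos),
      coverage = cov,
      meth_fraction = pct / 100
    )
  } else {
    if (ncol(raw) != 6) stop("Bismark coverage requires 6 columns, got ", ncol(raw))
    n_meth <- suppressWarnings(as.numeric(raw[[5]]))
    n_unmeth <- suppressWarnings(as.numeric(raw[[6]]))
    pos1 <- suppressWarnings(as.integer(raw[[2]]))
    if (anyNA(n_meth) || anyNA(n_unmeth) || anyNA(pos1))
      stop("non-numeric field in Bismark coverage file ", path)
    tbl <- tibble(
      chrom = raw[[1]],
      pos = pos1 - 1L,
      coverage = n_meth + n_unmeth,
      meth_fraction = ifelse(n_meth + n_unmeth > 0,
                             n_meth / (n_meth + n_unmeth), 0)
    )
    bad <- n_meth < 0 | n_unmeth < 0
    if (any(bad)) {
      warning(sum(bad), " record(s) rejected: negative counts")
      tbl <- tbl[!bad, , drop = FALSE]
    }
  }
  neg <- tbl$coverage < 0
  if (any(neg)) {
    warning(sum(neg), " record(s) rejected: negative coverage")
    tbl <- tbl[!neg, , drop = FALSE]
  }
  if (merge_strands) {
    tbl <- tbl |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(
        meth_fraction = if (sum(.data$coverage) > 0)
          sum(.data$meth_fraction * .data$coverage) / sum(.data$coverage) else 0,
        coverage = sum(.data$coverage),
        .groups = "drop"
      ) |>
      dplyr::select("chrom", "pos", "coverage", "meth_fraction")
  }
  dplyr::arrange(tbl, .data$chrom, .data$pos)
}
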