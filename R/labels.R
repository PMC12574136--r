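#' Call per-CpG methylation status from WGBS records
#'
#' A CpG is called methylated when more than 90% of its reads support
#' methylation and it is covered by more than 10 reads; unmethylated when
#' more than 90% support the unmethylated state under the same coverage
#' rule; otherwise unknown. All bounds are strict: fraction > 0.9 (or
#' < 0.1) and coverage >= 11.
#'
#' @param methylome Tibble from [load_methylome()] (`chrom`, `pos`,
#'   `coverage`, `meth_fraction`).
#' @return The input with an added `status` column in
#'   {"methylated","unmethylated","unknown"}.
#' @export
call_cpg_status <- function(methylome) {
  deep <- methylome$coverage > 10
  status <- dplyr::case_when(
    deep & methylome$meth_fraction > 0.9 ~ "methylated",
    deep & methylome$meth_fraction < 0.1 ~ "unmethylated",
    TRUE ~ "unknown"
  )
  dplyr::mutate(methylome, status = status)
}

#' Enumerate CpG positions within islands
#'
#' CpGs are the forward-strand "CG" occurrences in the island reference
#' sequence; the reported position is the 0-based genome coordinate of the
#' C.
#'
#' @param islands Island tibble.
#' @return Tibble `island_id`, `chrom`, `pos`.
#' @export
island_cpg_positions <- function(islands) {
  hits <- stringr::str_locate_all(islands$sequence, "CG")
  purrr::map2_dfr(seq_len(nrow(islands)), hits, function(i, h) {
    if (nrow(h) == 0) return(NULL)
    tibble(island_id = islands$island_id[i],
           chrom = islands$chrom[i],
           pos = islands$start[i] + h[, 1] - 1L)
  })
}

#' Label islands from per-CpG methylation calls
#'
#' Methylome records are matched to the reference CpG positions of each
#' island (records not coinciding with a reference CG are ignored with a
#' warning). An island is methylated (y = 1) when its methylated CpG calls
#' outnumber the unmethylated ones, unmethylated (y = 0) in the opposite
#' case, and excluded as unknown when no CpG received a definite call
#' (`no_assigned_cpg`) or the two tallies are equal (`tie`).
#'
#' @param islands Island tibble.
#' @param methylome Methylome tibble from [load_methylome()].
#' @return Tibble `island_id`, `chrom`, `start`, `end`, `label` (integer 0/1
#'   or NA), `n_meth`, `n_unmeth`, `excluded_reason`.
#' @export
label_islands <- function(islands, methylome) {
  calls <- call_cpg_status(methylome)
  cpgs <- island_cpg_positions(islands)
  matched <- dplyr::inner_join(cpgs, calls, by = c("chrom", "pos"))
  n_in_span <- sum(
    purrr::map_int(seq_len(nrow(islands)), function(i) {
      sum(methylome$chrom == islands$chrom[i] &
            methylome$pos >= islands$start[i] &
            methylome$pos < islands$end[i])
    })
  )
  n_unmatched <- n_in_span - nrow(matched)
  if (n_unmatched > 0)
    warning(n_unmatched,
            " methylome record(s) inside islands do not match a reference CG; ignored")
  tallies <- matched |>
    dplyr::group_by(.data$island_id) |>
    dplyr::summarise(
      n_meth = sum(.data$status == "methylated"),
      n_unmeth = sum(.data$status == "unmethylated"),
      .groups = "drop"
    )
  out <- islands |>
    dplyr::select("island_id", "chrom", "start", "end") |>
    dplyr::left_join(tallies, by = "island_id") |>
    dplyr::mutate(
      n_meth = dplyr::coalesce(.data$n_meth, 0L),
      n_unmeth = dplyr::coalesce(.data$n_unmeth, 0L),
      label = dplyr::case_when(
        .data$n_meth > .data$n_unmeth ~ 1L,
        .data$n_unmeth > .data$n_meth ~ 0L,
        TRUE ~ NA_integer_
      ),
      excluded_reason = dplyr::case_when(
        !is.na(.data$label) ~ NA_character_,
        .data$n_meth + .data$n_unmeth == 0 ~ "no_assigned_cpg",
        TRUE ~ "tie"
      )
    ) |>
    dplyr::select("island_id", "chrom", "start", "end",
                  "label", "n_meth", "n_unmeth", "excluded_reason")
  message("label_islands: ", sum(out$label == 1, na.rm = TRUE), " methylated, ",
          sum(out$label == 0, na.rm = TRUE), " unmethylated, ",
          sum(is.na(out$label)), " unknown")
  out
}

#' Exclude islands overlapping segmental duplications
#'
#' Any island overlapping an exclusion interval by at least one base
#' (half-open interval arithmetic; abutting intervals do not overlap) has
#' its label set to unknown with reason `segdup_overlap`.
#'
#' @param labels Label tibble from [label_islands()].
#' @param segdups Tibble of exclusion intervals with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. BED loaded via readr or [load_islands()].
#' @return The label tibble with overlapping islands excluded.
#' @export
exclude_segdup_overlaps <- function(labels, segdups) {
  if (is.null(segdups) || nrow(segdups) == 0) return(labels)
  hit <- rep(FALSE, nrow(labels))
  for (ch in unique(labels$chrom)) {
    li <- which(labels$chrom == ch)
    si <- which(segdups$chrom == ch)
    if (!length(si)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(start = labels$start[li] + 1L, end = labels$end[li]),
      IRanges::IRanges(start = segdups$start[si] + 1L, end = segdups$end[si])
    )
    hit[li] <- ov
  }
  labels$label[hit] <- NA_integer_
  labels$excluded_reason[hit] <- "segdup_overlap"
  if (any(hit)) message("exclude_segdup_overlaps: ", sum(hit), " island(s) excluded")
  labels
}

#' Fraction of labeled islands that are methylated
#'
#' Estimates the expected genome-wide methylated fraction r from a labeled
#' training set: the count of y = 1 islands over all islands with a definite
#' label.
#'
#' @param labels Label tibble.
#' @return A single number in \[0,1\].
#' @export
labeled_fraction <- function(labels) {
  lab <- labels$label[!is.na(labels$label)]
  if (!length(lab)) stop("no labeled islands: cannot infer r")
  mean(lab == 1L)
}
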