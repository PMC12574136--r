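test_that("break dinucleotide is the 5'-end base with its upstream neighbor", {
  # a read starting 5'-ACCGG aligned where T precedes it: hydrolysis at TA
  g <- fm_genome(c(c1 = "GGTACCGGTT"))
  reads <- tibble::tibble(chrom = "c1", start = 4L, end = 8L, strand = "+",
                          five_prime_clipped = FALSE)
  ev <- break_events(reads, g)
  expect_equal(ev$dinuc, "TA")
  expect_equal(ev$break_pos, 3L)

  # forward read mapped at position 1: no upstream base, no event
  reads1 <- tibble::tibble(chrom = "c1", start = 1L, end = 5L, strand = "+",
                           five_prime_clipped = FALSE)
  expect_equal(nrow(break_events(reads1, g)), 0L)

  # reverse read ending where the reference reads CA: reverse complement TG
  g2 <- fm_genome(c(c1 = "AACATT"))
  reads2 <- tibble::tibble(chrom = "c1", start = 1L, end = 3L, strand = "-",
                           five_prime_clipped = FALSE)
  ev2 <- break_events(reads2, g2)
  expect_equal(ev2$dinuc, "TG")
  expect_equal(ev2$break_pos, 2L)

  # reverse read ending at the last base: no downstream neighbor
  reads3 <- tibble::tibble(chrom = "c1", start = 3L, end = 6L, strand = "-",
                           five_prime_clipped = FALSE)
  expect_equal(nrow(break_events(reads3, g2)), 0L)
})

test_that("events over N and clipped 5' ends are discarded", {
  g <- fm_genome(c(c1 = "AANCGT"))
  reads <- tibble::tibble(chrom = "c1", start = c(4L, 5L), end = c(6L, 6L),
                          strand = "+", five_prime_clipped = c(FALSE, FALSE))
  ev <- break_events(reads, g)   # N upstream of position 4 is dropped
  expect_equal(ev$dinuc, "CG")

  g2 <- fm_genome(c(c1 = "AATCGT"))
  reads2 <- tibble::tibble(chrom = "c1", start = c(4L, 5L), end = c(6L, 6L),
                           strand = "+", five_prime_clipped = c(TRUE, FALSE))
  expect_equal(break_events(reads2, g2)$dinuc, "CG")
  expect_equal(break_events(reads2, g2, include_clipped = TRUE)$dinuc,
               c("TC", "CG"))

  expect_error(
    break_events(tibble::tibble(chrom = "cX", start = 3L, end = 4L,
                                strand = "+", five_prime_clipped = FALSE), g),
    "absent")
})

test_that("break extraction matches a character-by-character oracle", {
  set.seed(31)
  seqs <- list(c1 = paste(sample(c("A", "C", "G", "T", "N"), 300, TRUE,
                                 prob = c(.24, .24, .24, .24, .04)),
                          collapse = ""))
  g <- fm_genome(c(c1 = seqs$c1))
  reads <- tibble::tibble(
    chrom = "c1",
    start = sample(1:290, 120, TRUE),
    strand = sample(c("+", "-"), 120, TRUE),
    five_prime_clipped = FALSE)
  reads$end <- pmin(300L, reads$start + 9L)
  got <- break_events(reads, g)
  want <- naive_break_events(reads, list(c1 = toupper(seqs$c1)))
  expect_equal(nrow(got), nrow(want))
  expect_equal(dplyr::arrange(got, break_pos, strand, dinuc),
               dplyr::arrange(want, break_pos, strand, dinuc))
})

test_that("dinucleotide counting covers all windows and skips N", {
  c1 <- count_island_dinucleotides("ACGTA")
  expect_equal(sum(c1), 4L)
  expect_equal(unname(c1[c("AC", "CG", "GT", "TA")]), rep(1L, 4))
  expect_equal(unname(count_island_dinucleotides("AAAA")["AA"]), 3L)
  c3 <- count_island_dinucleotides("ACNGA")
  expect_equal(sum(c3), 2L)
  expect_equal(unname(c3[c("AC", "GA")]), c(1L, 1L))
  expect_error(count_island_dinucleotides("A"), "at least one dinucleotide")

  # random-sequence oracle
  set.seed(5)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                      prob = c(.23, .23, .23, .23, .08)), collapse = "")
    expect_equal(count_island_dinucleotides(s), naive_dinuc_counts(s))
  }
})

test_that("attribution requires the whole break dinucleotide inside the island", {
  g <- fm_genome(c(c1 = strrep("ACGT", 10)))
  isl <- toy_islands(g, "c1", 10, 20)
  mk <- function(pos, strand) {
    d <- if (strand == "+")
      substr(g$seq[["c1"]], pos, pos + 1)
    else as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(g$seq[["c1"]], pos + 1, pos + 2))))
    tibble::tibble(chrom = "c1", break_pos = as.integer(pos), strand = strand,
                   dinuc = d)
  }
  # forward event at break_pos 10: upstream base at 9 is outside -> dropped
  expect_equal(sum(island_counts(isl, mk(10, "+"))$N), 0)
  # forward break_pos 11..19 are in; 20 is out
  expect_equal(sum(island_counts(isl, mk(11, "+"))$N), 1)
  expect_equal(sum(island_counts(isl, mk(19, "+"))$N), 1)
  expect_equal(sum(island_counts(isl, mk(20, "+"))$N), 0)
  # reverse events span [break_pos, break_pos+1]: 10..18 in, 19 out
  expect_equal(sum(island_counts(isl, mk(10, "-"))$N), 1)
  expect_equal(sum(island_counts(isl, mk(18, "-"))$N), 1)
  expect_equal(sum(island_counts(isl, mk(19, "-"))$N), 0)
  # empty stream: all-zero counts
  empty <- island_counts(isl, mk(10, "+")[0, ])
  expect_equal(unname(empty$N), 0)
  expect_true(all(empty$n == 0))
})

test_that("overlapping islands each count the event independently", {
  g <- fm_genome(c(c1 = strrep("ACGT", 10)))
  isl <- dplyr::bind_rows(toy_islands(g, "c1", 8, 20, "a"),
                          toy_islands(g, "c1", 12, 24, "b"))
  ev <- tibble::tibble(chrom = "c1", break_pos = 15L, strand = "+",
                       dinuc = substr(g$seq[["c1"]], 15, 16))
  cnt <- island_counts(isl, ev)
  expect_equal(unname(cnt$N), c(1, 1))
})

test_that("rho follows the odds-ratio formula and the zero conventions", {
  g <- fm_genome(c(c1 = paste0(strrep("T", 10), "ACGTA", strrep("T", 10))))
  isl <- toy_islands(g, "c1", 10, 15)
  # one break at each of AC, CG, GT, TA (forward break_pos 11..14)
  ev <- tibble::tibble(chrom = "c1", break_pos = 11:14, strand = "+",
                       dinuc = c("AC", "CG", "GT", "TA"))
  rho <- compute_rho(island_counts(isl, ev))
  vals <- unlist(rho[1, rho_cols <- paste0("rho_", dinucleotides())])
  expect_equal(unname(vals[paste0("rho_", c("AC", "CG", "GT", "TA"))]),
               rep(1, 4))
  expect_equal(sum(vals), 4)

  # "ACGCG": m AC=1 CG=2 GC=1, L-1 = 4; events 2x CG + 1x AC
  g2 <- fm_genome(c(c1 = paste0(strrep("T", 10), "ACGCG", strrep("T", 10))))
  isl2 <- toy_islands(g2, "c1", 10, 15)
  ev2 <- tibble::tibble(chrom = "c1", break_pos = c(12L, 12L, 11L),
                        strand = "+", dinuc = c("CG", "CG", "AC"))
  rho2 <- compute_rho(island_counts(isl2, ev2))
  expect_equal(rho2$rho_CG, (2 / 3) / (2 / 4))
  expect_equal(rho2$rho_AC, (1 / 3) / (1 / 4))
  expect_equal(rho2$rho_GC, 0)   # present in sequence, zero events
  expect_equal(rho2$N, 3L)

  # dinucleotide absent from the sequence stays 0 regardless of events
  g3 <- fm_genome(c(c1 = strrep("A", 100)))
  isl3 <- toy_islands(g3, "c1", 0, 100)
  ev3 <- tibble::tibble(chrom = "c1", break_pos = c(10L, 11L), strand = "+",
                        dinuc = "AA")
  rho3 <- compute_rho(island_counts(isl3, ev3))
  expect_identical(rho3$rho_CG, 0)
  expect_gt(rho3$rho_AA, 0)

  # uncovered island: all-zero vector, flagged
  rho0 <- compute_rho(island_counts(isl3, ev3[0, ]))
  expect_true(rho0$uncovered)
  expect_true(all(unlist(rho0[, rho_cols]) == 0))
})

test_that("rho is invariant to duplicating the event stream", {
  set.seed(13)
  g <- fm_genome(c(c1 = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                              collapse = "")))
  isl <- toy_islands(g, "c1", 50, 350)
  b <- sample(51:349, 200, TRUE)
  ev <- tibble::tibble(chrom = "c1", break_pos = as.integer(b), strand = "+",
                       dinuc = substring(g$seq[["c1"]], b, b + 1))
  r1 <- featurize_events(ev, isl)
  r2 <- featurize_events(dplyr::bind_rows(ev, ev), isl)
  expect_equal(r2[, paste0("rho_", dinucleotides())],
               r1[, paste0("rho_", dinucleotides())])
  expect_equal(r2$N, 2L * r1$N)
})

test_that("featurized vectors match the naive oracle on random islands", {
  set.seed(17)
  seqc <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g <- fm_genome(c(c1 = seqc))
  starts <- seq(10, 2800, by = 180)
  isl <- dplyr::bind_rows(purrr::map(seq_along(starts), function(i) {
    toy_islands(g, "c1", starts[i], starts[i] + sample(10:50, 1),
                sprintf("isl%02d", i))
  }))
  b <- sample(1:2998, 400, TRUE)
  strand <- sample(c("+", "-"), 400, TRUE)
  dinuc <- ifelse(strand == "+", substring(seqc, b, b + 1),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(substring(seqc, b + 1, b + 2)))))
  ev <- tibble::tibble(chrom = "c1", break_pos = as.integer(b),
                       strand = strand, dinuc = dinuc)
  got <- featurize_events(ev, isl)
  want <- naive_rho(isl, ev)
  expect_equal(unname(as.matrix(got[, paste0("rho_", dinucleotides())])),
               unname(want), tolerance = 1e-12)
})

test_that("complementary dinucleotides are tracked separately", {
  g <- fm_genome(c(c1 = paste0(strrep("T", 10), "CACACATG", strrep("T", 10))))
  isl <- toy_islands(g, "c1", 10, 18)
  # forward events at CA only
  ev <- tibble::tibble(chrom = "c1", break_pos = c(12L, 14L), strand = "+",
                       dinuc = "CA")
  rho <- compute_rho(island_counts(isl, ev))
  expect_gt(rho$rho_CA, 0)
  expect_identical(rho$rho_TG, 0)
  expect_equal(length(grep("^rho_", names(rho))), 16L)
})
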