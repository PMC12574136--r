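#' Dinucleotide fragility model
#'
#' Relative propensities of the DNA backbone to hydrolyse at each
#' dinucleotide under mechanical shearing, plus the extra fragility of
#' methylated CpGs. Defaults follow the mechanochemical literature the
#' method builds on: CpG dinucleotides break about 1.5 times more often
#' than other dinucleotides, and methylation of a CpG raises its
#' fragmentation rate by about a further 30%.
#'
#' @param weights Named positive vector over [dinucleotides()] (unnamed
#'   scalar entries recycled); default all 1 with CG = 1.5.
#' @param meth_cpg_multiplier Positive multiplier applied to CG positions in
#'   methylated islands (default 1.3).
#' @return An `fm_fragility` list.
#' @export
fragility_model <- function(weights = NULL, meth_cpg_multiplier = 1.3) {
  w <- setNames(rep(1, 16), dinucleotides())
  w["CG"] <- 1.5
  if (!is.null(weights)) {
    if (is.null(names(weights))) stop("weights must be named by dinucleotide")
    bad <- setdiff(names(weights), dinucleotides())
    if (length(bad)) stop("unknown dinucleotide(s): ", paste(bad, collapse = ", "))
    w[names(weights)] <- weights
  }
  if (any(w <= 0)) stop("all fragility weights must be positive")
  if (meth_cpg_multiplier <= 0) stop("meth_cpg_multiplier must be positive")
  structure(list(weights = w, meth_cpg_multiplier = meth_cpg_multiplier),
            class = "fm_fragility")
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a small diploid-agnostic genome
#' with non-overlapping CpG islands of typical length 500-2000 bp, a true
#' methylated island fraction matching the ~19% observed for human CGIs,
#' dinucleotide-biased break events, and a mock WGBS methylome for
#' ground-truth labeling.
#'
#' @param genome_length Total genome size in bp (split over `n_chrom`
#'   chromosomes).
#' @param n_chrom Number of chromosomes.
#' @param n_islands Number of CpG islands.
#' @param island_length Length range (bp), uniform draw.
#' @param island_gc G+C fraction of island sequence (background is A/T
#'   rich).
#' @param island_cpg_rate Probability of planting a CpG token per island
#'   sequence token; controls CpG enrichment.
#' @param r_star True methylated fraction: exactly `round(r_star *
#'   n_islands)` islands are methylated.
#' @param mean_events Expected break events per (unmethylated, average)
#'   island.
#' @param background_events Expected break events outside islands, per
#'   genome.
#' @param read_length Read length for the optional alignment writer.
#' @param wgbs_mean_coverage Mean per-CpG WGBS coverage (Poisson).
#' @param wgbs_error Per-read bisulfite miscall probability, in \[0, 0.5).
#' @param mosaic_fraction Probability a CpG's state disagrees with its
#'   island (robustness knob; default 0: islands are all-or-none).
#' @param fragility An [fragility_model()].
#' @param seed Integer seed; every simulator artifact is deterministic
#'   given it.
#' @return An `fm_sim_config` list.
#' @export
sim_config <- function(genome_length = 1.2e6, n_chrom = 2, n_islands = 150,
                       island_length = c(500, 2000), island_gc = 0.55,
                       island_cpg_rate = 0.04, r_star = 0.2,
                       mean_events = 1000, background_events = 2000,
                       read_length = 100, wgbs_mean_coverage = 30,
                       wgbs_error = 0.02, mosaic_fraction = 0,
                       fragility = fragility_model(), seed = 1) {
  stopifnot(genome_length > 0, n_chrom >= 1, n_islands >= 1,
            length(island_length) == 2, island_length[1] >= 2,
            island_length[1] <= island_length[2],
            island_gc > 0, island_gc < 1,
            island_cpg_rate >= 0, island_cpg_rate < 1,
            r_star >= 0, r_star <= 1,
            mean_events > 0, background_events >= 0,
            wgbs_mean_coverage > 0, wgbs_error >= 0, wgbs_error < 0.5,
            mosaic_fraction >= 0, mosaic_fraction <= 1,
            inherits(fragility, "fm_fragility"))
  structure(as.list(environment()), class = "fm_sim_config")
}

# CpG-enriched island sequence: tokens are either a planted "CG" (prob
# cpg_rate) or a single GC-rich base
gen_island_seq <- function(len, cpg_rate, gc) {
  p1 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  n_tok <- len + 8L
  is_cg <- runif(n_tok) < cpg_rate
  tok <- character(n_tok)
  tok[is_cg] <- "CG"
  tok[!is_cg] <- sample(names(p1), sum(!is_cg), replace = TRUE, prob = p1)
  s <- paste(tok, collapse = "")
  while (nchar(s) < len) s <- paste0(s, gen_island_seq(len - nchar(s), cpg_rate, gc))
  substr(s, 1, len)
}

#' Simulate a genome with CpG islands of known methylation state
#'
#' Background sequence is drawn from an A/T-rich low-CpG nucleotide model;
#' island segments have elevated G+C and planted CpGs. Islands are
#' non-overlapping, separated by at least 200 bp of background, and exactly
#' `round(r_star * n_islands)` of them (a random subset) are methylated.
#'
#' @param config An [sim_config()].
#' @return An `fm_sim` list: `genome` (fm_genome), `islands` (island
#'   tibble), `truth` (tibble `island_id`, `methylated`), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "fm_sim_config"))
  with_seed(config$seed, {
    chrom_names <- paste0("sim", seq_len(config$n_chrom))
    chrom_len <- rep(floor(config$genome_length / config$n_chrom), config$n_chrom)
    isl_chrom <- sort(rep_len(seq_len(config$n_chrom), config$n_islands))
    p_bg <- c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)
    min_gap <- 200L

    seqs <- character(config$n_chrom)
    islands <- vector("list", config$n_chrom)
    for (ci in seq_len(config$n_chrom)) {
      n_i <- sum(isl_chrom == ci)
      lens <- floor(runif(n_i, config$island_length[1], config$island_length[2] + 1))
      extra <- chrom_len[ci] - sum(lens) - (n_i + 1L) * min_gap
      if (extra < 0)
        stop("islands cannot fit in genome length; increase genome_length")
      wgap <- stats::rexp(n_i + 1L)
      gaps <- min_gap + floor(extra * wgap / sum(wgap))
      segs <- character(2L * n_i + 1L)
      starts <- integer(n_i)
      pos <- 0L
      for (j in seq_len(n_i)) {
        segs[2L * j - 1L] <- paste(
          sample(names(p_bg), gaps[j], replace = TRUE, prob = p_bg),
          collapse = "")
        pos <- pos + gaps[j]
        starts[j] <- pos
        segs[2L * j] <- gen_island_seq(lens[j], config$island_cpg_rate,
                                       config$island_gc)
        pos <- pos + lens[j]
      }
      tail_len <- chrom_len[ci] - pos
      segs[2L * n_i + 1L] <- paste(
        sample(names(p_bg), tail_len, replace = TRUE, prob = p_bg),
        collapse = "")
      seqs[ci] <- paste(segs, collapse = "")
      islands[[ci]] <- tibble(chrom = chrom_names[ci], start = starts,
                              end = starts + lens)
    }
    isl <- dplyr::bind_rows(islands)
    isl$island_id <- sprintf("cgi_%04d", seq_len(nrow(isl)))
    genome <- fm_genome(setNames(seqs, chrom_names))
    isl$length <- isl$end - isl$start
    isl$sequence <- unname(genome_slice(genome, isl$chrom, isl$start, isl$end))
    isl <- dplyr::select(isl, "island_id", "chrom", "start", "end",
                         "length", "sequence")
    n_meth <- round(config$r_star * nrow(isl))
    meth_idx <- sample(nrow(isl), n_meth)
    truth <- tibble(island_id = isl$island_id,
                    methylated = seq_len(nrow(isl)) %in% meth_idx)
    structure(list(genome = genome, islands = isl, truth = truth,
                   config = config),
              class = "fm_sim")
  })
}

#' @export
print.fm_sim <- function(x, ...) {
  cat("<fm_sim> ", length(x$genome$seq), " chromosome(s), ",
      nrow(x$islands), " island(s), ",
      sum(x$truth$methylated), " methylated (r* = ",
      signif(mean(x$truth$methylated), 3), ")\n", sep = "")
  invisible(x)
}

# per-boundary fragility weights for one sequence string
boundary_weights <- function(sequence, fragility, methylated) {
  l <- nchar(sequence)
  dn <- substring(sequence, seq_len(l - 1L), seq_len(l - 1L) + 1L)
  w <- unname(fragility$weights[dn])
  w[is.na(w)] <- 0
  if (methylated) w[dn == "CG"] <- w[dn == "CG"] * fragility$meth_cpg_multiplier
  list(dinuc = dn, w = w)
}

# sample n_frag fragments at boundaries b (0-based coordinate of the
# boundary's second base); each fragment contributes one forward and one
# reverse break observation
sample_fragment_events <- function(chrom, offset0, dinuc, w, n_frag, frag_id0) {
  if (n_frag == 0 || sum(w) == 0)
    return(tibble(chrom = character(), break_pos = integer(),
                  strand = character(), dinuc = character(), frag = integer()))
  idx_f <- sample.int(length(w), n_frag, replace = TRUE, prob = w)
  idx_r <- sample.int(length(w), n_frag, replace = TRUE, prob = w)
  b_f <- offset0 + idx_f        # 0-based second base of boundary
  b_r <- offset0 + idx_r
  dplyr::bind_rows(
    tibble(chrom = chrom, break_pos = as.integer(b_f), strand = "+",
           dinuc = dinuc[idx_f], frag = frag_id0 + seq_len(n_frag)),
    tibble(chrom = chrom, break_pos = as.integer(b_r - 1L), strand = "-",
           dinuc = revcomp_chr(dinuc[idx_r]), frag = frag_id0 + seq_len(n_frag))
  )
}

#' Simulate dinucleotide-biased break events
#'
#' Every dinucleotide boundary is a candidate hydrolysis site with
#' probability proportional to its fragility weight; CG boundaries in
#' methylated islands are further multiplied by `meth_cpg_multiplier`.
#' Events come in fragment pairs: each fragment contributes one
#' forward-strand and one reverse-strand break observation, following the
#' strand-aware dinucleotide convention of [break_events()]. Islands whose
#' total fragility is higher therefore receive proportionally more events
#' (the per-island expected count is `mean_events` for an island of average
#' unboosted fragility).
#'
#' @param sim An `fm_sim` from [simulate_genome()].
#' @param mean_events Expected events per average unmethylated island
#'   (default from the config).
#' @param background_events Expected events outside islands (default from
#'   the config).
#' @param fragility Fragility model (default from the config).
#' @param seed Seed (default config seed + 1).
#' @return Tibble of events: `chrom`, `break_pos` (0-based), `strand`,
#'   `dinuc`, `frag` (fragment pair id), `island_id` (NA for background).
#' @export
simulate_breaks <- function(sim, mean_events = NULL, background_events = NULL,
                            fragility = NULL, seed = NULL) {
  stopifnot(inherits(sim, "fm_sim"))
  cfg <- sim$config
  mean_events <- mean_events %||% cfg$mean_events
  background_events <- background_events %||% cfg$background_events
  fragility <- fragility %||% cfg$fragility
  seed <- seed %||% (cfg$seed + 1L)
  isl <- dplyr::left_join(sim$islands, sim$truth, by = "island_id")
  with_seed(seed, {
    bw <- purrr::map2(isl$sequence, isl$methylated,
                      ~boundary_weights(.x, fragility, .y))
    w0_sum <- purrr::map2_dbl(isl$sequence, FALSE,
                              ~sum(boundary_weights(.x, fragility, .y)$w))
    w_bar <- mean(w0_sum)
    ev <- vector("list", nrow(isl) + length(sim$genome$seq))
    frag0 <- 0L
    for (i in seq_len(nrow(isl))) {
      lambda <- mean_events / 2 * sum(bw[[i]]$w) / w_bar
      n_frag <- rpois(1, lambda)
      e <- sample_fragment_events(isl$chrom[i], isl$start[i], bw[[i]]$dinuc,
                                  bw[[i]]$w, n_frag, frag0)
      if (nrow(e)) e$island_id <- isl$island_id[i]
      ev[[i]] <- e
      frag0 <- frag0 + n_frag
    }
    # background: weighted draws over non-island boundaries of each chromosome
    if (background_events > 0) {
      isl_by_chrom <- split(isl, isl$chrom)
      chrom_names <- names(sim$genome$seq)
      bg_frags <- rpois(length(chrom_names),
                        background_events / 2 / length(chrom_names))
      for (ci in seq_along(chrom_names)) {
        ch <- chrom_names[ci]
        bwc <- boundary_weights(sim$genome$seq[[ch]], fragility, FALSE)
        # zero out island-internal boundaries so islands only receive the
        # events simulated above
        if (ch %in% names(isl_by_chrom)) {
          ii <- isl_by_chrom[[ch]]
          for (j in seq_len(nrow(ii))) {
            rng <- seq.int(ii$start[j] + 1L, ii$end[j] - 1L)
            bwc$w[rng] <- 0
          }
        }
        e <- sample_fragment_events(ch, 0L, bwc$dinuc, bwc$w, bg_frags[ci], frag0)
        if (nrow(e)) e$island_id <- NA_character_
        ev[[nrow(isl) + ci]] <- e
        frag0 <- frag0 + bg_frags[ci]
      }
    }
    out <- dplyr::bind_rows(ev)
    dplyr::arrange(out, .data$chrom, .data$break_pos, .data$strand, .data$frag)
  })
}

#' Write simulated break events as a minimal paired-end SAM/BAM
#'
#' Each fragment pair becomes a properly paired read pair: the forward
#' break is read 1 (flag 99) starting at the break, the reverse break is
#' read 2 (flag 147) ending at the break. Output is coordinate-sorted and,
#' for BAM, indexed, so it passes the package's own read-filtering
#' contract.
#'
#' @param events Event tibble from [simulate_breaks()] (needs `frag`).
#' @param genome The `fm_genome` the events were simulated on.
#' @param path Output path; `.bam` writes a sorted indexed BAM, `.sam` a
#'   sorted SAM.
#' @param read_length Read length (default 100).
#' @return The output path, invisibly.
#' @export
write_events_sam <- function(events, genome, path, read_length = 100) {
  fwd <- dplyr::filter(events, .data$strand == "+")
  rev <- dplyr::filter(events, .data$strand == "-")
  both <- intersect(fwd$frag, rev$frag)
  fwd <- fwd[match(both, fwd$frag), , drop = FALSE]
  rev <- rev[match(both, rev$frag), , drop = FALSE]
  clen <- genome$lengths
  # read 1: forward, 5' end at the break
  p1 <- fwd$break_pos + 1L
  l1 <- pmin(read_length, clen[fwd$chrom] - p1 + 1L)
  # read 2: reverse, 5' end (alignment end) at the break
  e2 <- rev$break_pos + 1L
  p2 <- pmax(1L, e2 - read_length + 1L)
  l2 <- e2 - p2 + 1L
  seq1 <- substring(genome$seq[fwd$chrom], p1, p1 + l1 - 1L)
  seq2 <- revcomp_chr(substring(genome$seq[rev$chrom], p2, e2))
  rec <- function(qname, flag, chrom, pos, cigar, mpos, seq) {
    paste(qname, flag, chrom, pos, 60L, cigar, "=", mpos, 0L, seq, "*",
          sep = "\t")
  }
  qn <- paste0("frag", both)
  lines <- c(
    rec(qn, 99L, fwd$chrom, p1, paste0(l1, "M"), p2, seq1),
    rec(qn, 147L, rev$chrom, p2, paste0(l2, "M"), p1, seq2)
  )
  ord <- order(c(fwd$chrom, rev$chrom), c(p1, p2))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(clen), "\tLN:", unname(clen)))
  sam_tmp <- tempfile(fileext = ".sam")
  writeLines(c(header, lines[ord]), sam_tmp)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
    bam <- Rsamtools::asBam(sam_tmp, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam_tmp)
    return(invisible(bam))
  }
  file.copy(sam_tmp, path, overwrite = TRUE)
  unlink(sam_tmp)
  invisible(path)
}

#' Simulate a WGBS methylome for the islands
#'
#' Per CpG of every island, coverage is Poisson with the configured mean
#' and the methylated-read count is binomial with success probability
#' (1 - error) in methylated islands and (error) in unmethylated ones.
#' With a nonzero `mosaic_fraction`, each CpG independently disagrees with
#' its island state with that probability.
#'
#' @param sim An `fm_sim`.
#' @param mean_coverage,error_rate,mosaic,seed Override the config values.
#' @return Methylome tibble: `chrom`, `pos` (0-based C), `coverage`,
#'   `n_meth`, `n_unmeth`, `meth_fraction`.
#' @export
simulate_wgbs <- function(sim, mean_coverage = NULL, error_rate = NULL,
                          mosaic = NULL, seed = NULL) {
  stopifnot(inherits(sim, "fm_sim"))
  cfg <- sim$config
  mean_coverage <- mean_coverage %||% cfg$wgbs_mean_coverage
  error_rate <- error_rate %||% cfg$wgbs_error
  mosaic <- mosaic %||% cfg$mosaic_fraction
  seed <- seed %||% (cfg$seed + 2L)
  cpgs <- island_cpg_positions(sim$islands) |>
    dplyr::left_join(sim$truth, by = "island_id")
  with_seed(seed, {
    flip <- runif(nrow(cpgs)) < mosaic
    meth <- xor(cpgs$methylated, flip)
    coverage <- rpois(nrow(cpgs), mean_coverage)
    n_meth <- rbinom(nrow(cpgs), coverage,
                     ifelse(meth, 1 - error_rate, error_rate))
    tibble(
      chrom = cpgs$chrom, pos = cpgs$pos,
      coverage = coverage, n_meth = n_meth, n_unmeth = coverage - n_meth,
      meth_fraction = ifelse(coverage > 0, n_meth / coverage, 0)
    )
  })
}

#' Write a methylome tibble in Bismark coverage format
#'
#' @param wgbs Methylome tibble from [simulate_wgbs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(wgbs, path) {
  readr::write_tsv(
    tibble(chrom = wgbs$chrom, start = wgbs$pos + 1L, end = wgbs$pos + 1L,
           percent = round(wgbs$meth_fraction * 100, 6),
           n_meth = wgbs$n_meth, n_unmeth = wgbs$n_unmeth),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Run the full pipeline on simulated data
#'
#' Simulates a genome, break events and a WGBS methylome; featurizes;
#' labels islands; assembles the dataset; and cross-validates the
#' classifier. The desk-scale twin of the paper-scale train/evaluate
#' workflow.
#'
#' @param config An [sim_config()].
#' @param use_sam Route events through the SAM/BAM writer and the alignment
#'   reader instead of the in-memory path (default FALSE).
#' @param k Cross-validation folds (default 10).
#' @param num_trees Forest size (default 500).
#' @return An `fm_run` list: `sim`, `events`, `rho`, `labels`, `dataset`,
#'   `cv`, `r_hat`.
#' @export
sim_pipeline <- function(config, use_sam = FALSE, k = 10, num_trees = 500) {
  sim <- simulate_genome(config)
  events <- simulate_breaks(sim)
  if (use_sam) {
    bam <- file.path(tempdir(), paste0("fragmeth_sim_", config$seed, ".bam"))
    write_events_sam(events, sim$genome, bam, read_length = config$read_length)
    rho <- featurize(bam, sim$genome, sim$islands)
  } else {
    rho <- featurize_events(events, sim$islands)
  }
  wgbs <- simulate_wgbs(sim)
  labels <- suppressWarnings(label_islands(sim$islands, wgbs))
  dataset <- make_dataset(rho, labels, sample_name = "simulation")
  cv <- cross_validate(dataset, k = k, seed = config$seed + 3L,
                       num_trees = num_trees)
  structure(
    list(sim = sim, events = events, rho = rho, labels = labels,
         dataset = dataset, cv = cv, r_hat = labeled_fraction(labels)),
    class = "fm_run"
  )
}

#' @export
print.fm_run <- function(x, ...) {
  cat("<fm_run> ", nrow(x$dataset), " labeled island(s), r_hat = ",
      signif(x$r_hat, 3), "\n", sep = "")
  print(x$cv$summary)
  invisible(x)
}

#' Held-out AUC over an event-coverage ladder
#'
#' For each seed, one genome and methylome are simulated and labeled once;
#' break events are then simulated at `mean_events * level` for every
#' ladder level and the cross-validated held-out AUC is recorded. Mirrors
#' the observation that accuracy grows with genomic read coverage.
#'
#' @param config An [sim_config()].
#' @param levels Coverage multipliers (default 1, 5, 10, 20).
#' @param seeds Seeds (one genome per seed; default 1:5).
#' @param k CV folds (default 5).
#' @param num_trees Forest size (default 200).
#' @return Tibble `seed`, `level`, `auc`.
#' @export
coverage_ladder <- function(config, levels = c(1, 5, 10, 20), seeds = 1:5,
                            k = 5, num_trees = 200) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- simulate_genome(cfg)
    wgbs <- simulate_wgbs(sim)
    labels <- suppressWarnings(label_islands(sim$islands, wgbs))
    purrr::map_dfr(levels, function(lv) {
      events <- simulate_breaks(sim, mean_events = cfg$mean_events * lv,
                                background_events = 0,
                                seed = cfg$seed + 10L * lv)
      rho <- featurize_events(events, sim$islands)
      ds <- make_dataset(rho, labels)
      cv <- cross_validate(ds, k = k, seed = cfg$seed + 3L,
                           num_trees = num_trees)
      tibble(seed = s, level = lv, auc = cv$summary$auc_roc)
    })
  })
}

#' Macro accuracy as a function of the assumed methylated fraction r
#'
#' Simulates one dataset, splits islands into stratified train/test halves,
#' trains a balanced forest on the training half and evaluates the top-r
#' rule on the (naturally distributed) test half for each candidate r.
#' The accuracy is expected to peak where r matches the true methylated
#' fraction.
#'
#' @param config An [sim_config()].
#' @param r_values Candidate r values (default r* + c(-0.2, -0.1, 0, 0.1,
#'   0.2), clamped to \[0,1\]).
#' @param num_trees Forest size (default 300).
#' @return Tibble `r`, `macro_accuracy`, `auc` plus attribute `r_test`
#'   (realized test-set methylated fraction).
#' @export
r_sweep <- function(config, r_values = NULL, num_trees = 300) {
  r_values <- r_values %||% pmin(1, pmax(0, config$r_star + seq(-0.2, 0.2, 0.1)))
  sim <- simulate_genome(config)
  events <- simulate_breaks(sim)
  rho <- featurize_events(events, sim$islands)
  wgbs <- simulate_wgbs(sim)
  labels <- suppressWarnings(label_islands(sim$islands, wgbs))
  ds <- make_dataset(rho, labels)
  half <- stratified_folds(ds$label, 2, seed = config$seed + 7L)
  train <- ds[half == 1, , drop = FALSE]
  test <- ds[half == 2, , drop = FALSE]
  model <- train_forest(balance_by_undersampling(train, seed = config$seed + 8L),
                        num_trees = num_trees, seed = config$seed + 9L)
  post <- predict_posteriors(model, test)
  out <- purrr::map_dfr(r_values, function(r) {
    ev <- evaluate_predictions(dplyr::select(test, "island_id", "label"),
                               apply_top_r(post, r))
    tibble(r = r, macro_accuracy = ev$macro_accuracy, auc = ev$auc_roc)
  })
  attr(out, "r_test") <- mean(test$label == 1L)
  out
}
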