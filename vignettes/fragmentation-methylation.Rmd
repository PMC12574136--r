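---
title: "Calling CpG-island methylation from WGS fragmentation bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CpG-island methylation from WGS fragmentation bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(fragmeth)
library(dplyr)
```

## The idea

Standard short-read WGS libraries are made by mechanically shearing genomic
DNA. Hydrolysis of the sugar-phosphate backbone under mechanical stress is a
mechanochemical reaction whose rate depends on the local sequence: CpG
dinucleotides break roughly 1.5x more often than other dinucleotides, and
methylation of the CpG cytosine raises the rate by roughly a further 30%.
Every read 5'-end marks one such break, so the genome-wide distribution of
read start coordinates carries an epigenetic signal that is normally
discarded.

`fragmeth` turns that signal into a methylation call for CpG islands
(CGIs) — CpG-rich segments of typically 500–2000 bp that behave as discrete
regulatory units and are, in the large majority of cases, either fully
methylated or fully unmethylated.

## The fragmentation odds ratio

For island $i$ and dinucleotide $XY$ the package computes

$$\rho^i_{XY} \;=\; \frac{n^i_{XY}/N^i}{\,m^i_{XY}/(L^i-1)\,}$$

where $n^i_{XY}$ counts break events at $XY$ positions inside the island,
$N^i$ is the island's total event count, $m^i_{XY}$ the number of $XY$
dinucleotides in the island sequence and $L^i$ its length. Under uniform
fragmentation every $\rho \approx 1$; $\rho_{XY} > 1$ means preferential
breakage at $XY$. When a dinucleotide is absent from the island or received
no events, its $\rho$ is set to 0 by convention; an island with no events
at all gets an all-zero vector and is flagged `uncovered`.

A break event is extracted from each filtered read as the *(upstream
neighbour, first aligned base)* pair, read 5'→3' on the read's strand; on
the reverse strand this is the reverse complement of the two reference
bases at the alignment end. Complementary dinucleotides are deliberately
kept separate ($\rho_{CA}$ and $\rho_{TG}$ are different features), since
measured fragmentation rates of complementary dinucleotides differ.

Two conventions are worth spelling out:

* **Attribution boundary.** An event is attributed to an island only when
  *both* bases of its break dinucleotide lie inside `[start, end)`. The
  numerator then ranges over exactly the same $L-1$ dinucleotide positions
  as the denominator, which is what makes uniform placement give
  $\rho = 1$ exactly rather than approximately. Overlapping islands each
  count the event independently.
* **Read filtering.** Only mapped, properly paired, primary,
  non-supplementary (non-chimeric), non-duplicate, QC-passing records are
  used; both mates count, each contributing one break observation. The
  default MAPQ threshold is 0 — the contract is defined by flags, and a
  stricter `mapq_min` is a user choice. Reads whose 5' end is soft- or
  hard-clipped are dropped by default, because their mapped start is not
  the molecule end.

```{r rho-demo}
island <- tibble::tibble(island_id = "demo", chrom = "chr1", start = 10L,
                         end = 15L, length = 5L, sequence = "ACGCG")
events <- tibble::tibble(chrom = "chr1", break_pos = c(12L, 12L, 11L),
                         strand = "+", dinuc = c("CG", "CG", "AC"))
featurize_events(events, island) |> select(island_id, N, rho_AC, rho_CG, rho_GC)
```

## Ground truth from WGBS

Labels come from bisulfite methylomes (bedMethyl or Bismark coverage
dialects). A CpG is called methylated (unmethylated) when more than 90% of
its reads agree *and* it is covered by more than 10 reads — both bounds
strict, so coverage 10 or a fraction of exactly 0.9 is `unknown`. An island
is labeled by strict majority of its definite CpG calls; islands with no
definite CpG, tied tallies, or any overlap with a segmental-duplication
exclusion interval are excluded. Ties are excluded (rather than broken
arbitrarily) to mirror the conservative spirit of the other filters.
Whether WGBS strands should be merged per CpG before filtering is left to
the user (`merge_strands`, default off, i.e. records are used as reported).

## The classifier and the top-r rule

Each labeled island contributes one row
$y^i \sim [\rho^i_{AA}\,\ldots\,\rho^i_{TT}]_{1\times16}$ to a two-class
random forest. Because most CGIs are unmethylated, the training set is
balanced by undersampling the majority class, which makes the implied
class priors 0.5/0.5. The forest reports a posterior per island — the
fraction of trees voting "methylated" — and hard calls are made by
*ranking*: given the expected genome-wide methylated fraction $r$, the top
$\mathrm{round}(r \cdot K)$ islands by posterior are called methylated and
the rest unmethylated. $r$ can be supplied explicitly or inferred from the
labeled training data. Posterior ties are broken by genomic coordinate so
the rule is deterministic; `round` (not `floor`) is the package's choice
for the cutoff count.

Defaults: 500 trees, `mtry = 4` ($\sqrt{16}$), minimum node size 1, with
an optional small grid search (trees 100/500, node size 1/5) scored by
internal cross-validation on the training split only. Evaluation reports
macro-averaged accuracy (the unweighted mean of per-class accuracies), ROC
AUC, average precision and the confusion matrix; cross-validation is
stratified by class, applies undersampling inside each training split
only, and leaves test folds at their natural class distribution. In
cross-sample use (train on one sample, predict another) no per-sample
renormalisation is performed. Feature importance is mean decrease in
impurity, normalised to sum to 1; $\rho_{CG}$ dominates whenever a
methylation signal is present.

## What the simulator emulates

All of the above is testable without external data through the built-in
generator:

* **Genome.** An A/T-rich, CpG-poor background (A,T 33%, C,G 17% each)
  with non-overlapping islands of length uniform in 500–2000 bp, G+C 55%,
  and planted CpGs giving a CpG density around 0.10 per dinucleotide
  position — the density regime of real CGIs. Exactly
  `round(r_star * n_islands)` islands are methylated; the default
  `r_star = 0.2` matches the ~19% methylated fraction typical of human
  CGI annotations.
* **Breaks.** Every dinucleotide boundary is a candidate hydrolysis site
  with weight 1, except CG at 1.5, times 1.3 at methylated-island CGs
  (both from the mechanochemical literature; fully configurable). Events
  are drawn as independent fragment ends — one forward and one reverse
  observation per fragment — with per-island totals Poisson around
  `mean_events` scaled by the island's total fragility, so more fragile
  (methylated) islands receive proportionally more reads. No
  fragment-length model is imposed, since only 5'-end positions enter the
  method. Background (non-island) CpGs are simulated unboosted; they never
  enter the feature computation.
* **WGBS.** Per-CpG coverage is Poisson (default mean 30); methylated-read
  counts are binomial with a symmetric miscall rate (default 0.02).
  Islands are all-or-none by default, with a `mosaic_fraction` knob as a
  robustness device only.
* **Alignment writer.** Fragment pairs become properly paired SAM/BAM
  records (flags 99/147, MAPQ 60), coordinate-sorted and indexed, so the
  whole BAM ingestion path is exercised; it round-trips to exactly the
  in-memory event counts.

What the simulator does *not* emulate: mapping ambiguity, PCR-amplification
bias, sequencing errors, partially methylated domains, chromosome-scale
composition structure, or the nuclease-driven end motifs of cfDNA (a
different fragmentation process). Passing tests therefore demonstrate the
correctness and internal calibration of the method, not its accuracy on
real libraries, which depends on those unmodelled effects.

```{r pipeline, message = FALSE, warning = FALSE}
cfg <- sim_config(n_islands = 60, genome_length = 5e5, mean_events = 500,
                  seed = 7)
run <- sim_pipeline(cfg, k = 5, num_trees = 200)
run$cv$summary
```

## Numerical and design choices

* Coordinates are 0-based half-open internally; SAM's 1-based positions
  are converted on ingest; bedMethyl minus-strand records are shifted to
  the forward-strand C.
* N-containing dinucleotides are excluded symmetrically from event counts
  and sequence composition; soft-masked bases are ordinary nucleotides.
* Degenerate inputs map to defined results rather than errors wherever the
  statistic has a natural convention ($\rho = 0$ cases, empty event
  streams); genuinely inconsistent inputs (chromosome absent from the
  genome, unindexed BAM) raise errors.
* Chromosome-name mismatches (`chr1` vs `1`) are not auto-healed.
* Every stochastic step takes an explicit seed, and simulator outputs are
  byte-identical across runs with the same seed.

**A known estimator property.** The odds ratio is internally normalised by
the island's total event count, so boosting CG breakage also inflates the
denominator: the expected ratio of mean $\rho_{CG}$ between methylated and
unmethylated islands is $w/(1 + (w-1)\varphi)$, not $w$, where $w$ is the
methylated-CpG rate multiplier and $\varphi$ the CG share of total island
fragility (~0.1–0.15 at CGI-typical CpG density). At $w = 1.3$ the
attenuation is a few percent; genome-wide, where the CG share is ~1%, it is
negligible. This is a property of the statistic itself, not of the
implementation — the package's tests verify that the debiased estimate
recovers $w$ exactly within Monte-Carlo error, and classification is
unaffected because the attenuated ratio remains monotone in $w$.

Problem sizes used throughout the test suite (hundreds of islands, $10^2$
to $10^4$ events per island, forests of 100–500 trees) were chosen as the
smallest scales at which the statistical properties under test are stable;
they are desk-scale stand-ins for the genome-scale datasets the method is
meant for.

## Limitations

* Accuracy on real data is bounded by coverage: the per-island $\rho$
  vector at typical 30x coverage is noisy, and published applications of
  this family of methods report macro accuracies around 0.7 on single
  high-coverage samples, improving substantially when reads are pooled.
* The method classifies whole islands into two states; partially
  methylated islands and per-CpG resolution are out of scope.
* The model assumes the library was mechanically sheared; enzymatic
  fragmentation or cfDNA libraries violate the fragility model.
```
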