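---
title: "Screening for metastable epialleles and quantifying read-level methylation homogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for metastable epialleles and quantifying read-level methylation homogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mescan)
```

## The problem

DNA methylation at most genomic loci is either developmentally programmed
(consistent across individuals) or tissue-specific. Metastable epialleles
(MEs) are the exception: loci where *individuals* differ substantially but
each individual's *tissues* agree. Because the three germ layers separate
at gastrulation, cross-tissue agreement implies the variable state was
established earlier, in the pre-gastrulation embryo — exactly the window
in which periconceptional environment (e.g. maternal nutrition) can leave
lasting marks. `mescan` implements the computational machinery for finding
such regions in whole-genome bisulfite sequencing (WGBS) cohorts,
following their methylation through early-embryo developmental series
(RRBS), asking whether their intermediate methylation is molecule-specific
or mosaic at the read level, and testing what genomic company they keep.

## The screen and its assumptions

Per CpG dyad (both strands merged, total depth ≥ `min_depth = 10` in every
sample of a dataset) the screen computes

* `d_inter`: the maximum absolute difference between individuals'
  tissue-averaged methylation fractions, and
* `d_intra`: the maximum within-individual between-tissue difference,

and calls the CpG an ME-CpG when `d_inter ≥ 0.15` and
`d_intra ≤ d_inter / 3`. Both constants are screen parameters
(`inter_threshold`, `intra_ratio`); the defaults are the published ones.
With more than two individuals or tissues the maxima over pairs are used,
which reduces to the plain differences in the original 2 × 2 design. Three
further choices deserve note:

* **SNP masking.** Any CpG within 60 bp (inclusive) of a SNP is excluded
  *in the dataset containing the SNP*, guarding against allele-specific
  methylation masquerading as metastability. We read "within 60 bp"
  inclusively; the boundary is configurable (`snp_window`).
* **Cross-dataset combination.** The criteria are assessed separately per
  dataset. How the per-dataset passing sets were combined in the original
  screen is not stated; we default to **intersection** (a locus must show
  systemic variation in every cohort), which matches the idea of
  replicated systemic variation and empirically keeps the false-discovery
  proportion near zero. `combine_mode = "union"` is available.
* **Purity denominator.** Clusters (single-linkage, gap ≤ 300 bp, ≥ 4
  ME-CpGs) must contain at least twice as many ME-CpGs as non-ME-CpGs. The
  set of "non-ME-CpGs" is not defined in the source; we count CpGs covered
  in every sample of at least one dataset that did not qualify — including
  CpGs removed by the SNP mask, which is the conservative reading.

Control regions are sampled from the clustered whole-genome background
(same clustering parameters, no metastability filter, ME-overlapping
candidates removed), stratified to match the ME joint distribution of
(span, CpG count). The matching procedure is unspecified in the source; we
use 5 × 5 quantile bins with largest-remainder allocation and proportional
reallocation when a bin's candidate pool runs dry (`n_bins` configurable).
Sampling is deterministic given `seed`.

## Stage dynamics

`stage_summary()` counts every covered CpG once per replicate (so
replicate occurrences are separate observations), reports the mean, a
10-bin histogram on [0, 1] (last bin right-closed) and the fraction of
sites with **intermediate methylation**, defined as a methylation fraction
in the closed interval [0.10, 0.90] ("10 to 90%" read inclusively;
`lo`/`hi` configurable). The > 200× depth cap is applied in read-level
work only and is off by default for stage summaries, mirroring the source
analysis, which states it only in the read-level context.

`stratified_transition()` implements the pre/post-gastrulation analysis:
every (pre-replicate, post-replicate) pair contributes one observation per
CpG covered in both, observations are stratified by pre-stage methylation
(default quartile bins; the published stratum edges are shown graphically
only, so bins are configuration, not constants), and each stratum's
post-stage median gets a 95% percentile bootstrap CI from 1000 resamples.

## The read homogeneity index

Intermediate methylation in a pooled sample can mean two things: every
molecule is partially methylated (mosaic), or molecules are each fully
methylated or unmethylated in differing proportions (molecule-specific,
i.e. variegation). The RHI distinguishes them using only the reads
overlapping a cluster, tolerating uncalled cytosines and reads that clip
the cluster edge:

1. count observed **transitions** — adjacent *called* CpGs on the same
   read with different calls; missing calls are skipped, not breaking the
   read (the statistic exists precisely because reads contain uncalled
   sites);
2. permute the multiset of all called values across all called positions
   cluster-wide, preserving read locations and missing positions — every
   permutation therefore carries exactly the observed number of methylated
   calls — and recount; repeat `n_rand = 1000` times;
3. `RHI = median(randomized counts) / observed count`.

We use the **lower median** for even `n_rand` so the ratio of two integers
is reproducible. An observed count of zero (perfectly homogeneous reads)
leaves the index undefined; such clusters are reported as `NA` and
excluded from comparisons, not coerced to a large value. Permutation is
cluster-wide rather than within-read: the worked illustration in the
source resamples calls across the whole region while "preserving the
location of the reads", and within-read permutation would leave fully
covered single-CpG reads invariant.

Two filters intentionally differ: read-level methylation *distributions*
exclude reads with < 4 called CpGs, but the RHI keeps short reads (the
source's illustration includes reads overlapping only one or two CpGs).
Eligibility for RHI comparisons defaults to clusters with pooled mean
methylation in [0.1, 0.9] and ≥ 5 reads; the read minimum is not stated in
the source and is logged as our own threshold.

`compare_rhi()` is a two-sided Mann–Whitney test. Because RHI sets are
small and tied in some designs, we enumerate the exact rank-sum
permutation distribution when `choose(n1 + n2, n1)` is small (≤ 10 000)
and fall back to the tie-corrected normal approximation otherwise;
`stats::wilcox.test` refuses exactness under ties, which is why the exact
route is implemented here.

## Enrichment statistics

All enrichment tests reduce to `fisher_exact()`, computed from the
conditional hypergeometric distribution with the usual "at least as
extreme up to a 1e-7 relative tolerance" two-sided rule. The odds ratio is
the sample OR `ad/bc` (reported `Inf`/`0` at zero cells), *not* the
conditional MLE that `stats::fisher.test` reports — the source quotes
sample ORs. The genome is tiled into 1-kb half-open tiles (final partial
tile kept); a tile's feature status is crossed with whether it lies within
10 kb of a region. The garbled published sentence defining this table is
interpreted as that 2 × 2 over tiles — the only reading consistent with
reporting an OR from a Fisher test. An optional CpG-count weighting (each
tile contributes its CpG count) approximates conditioning on the genomic
distribution of CpG dinucleotides; it is off by default because the method
text describes only the unweighted tile test.

Distances in `proximity_profile()` are interval gaps (0 means actual
overlap; adjacency counts at any positive threshold), thresholds
inclusive, computed on full intervals rather than midpoints. The chromHMM
15 → 8 collapse is a configurable map; the default grouping
(TSS, Enhancer, Transcription, ZNF, Heterochromatin, Bivalent,
Repressed-Polycomb, Quiescent) follows the named groups, since the exact
mapping is not published.

## What the synthetic generator emulates — and what it does not

`sim_config()` describes a stated world; its defaults are fixed and are
not tuned per analysis:

* **Cohort**: two datasets (2 and 3 individuals, two tissues each),
  Poisson depth with mean 30, background CpGs every ~150 bp, 50 planted ME
  regions of 14 CpGs at ~50 bp spacing (CpG-dense, island-like).
* **Planted MEs** follow a switch-like bimodal epigenotype model: each
  individual is latently hypomethylated (level ~ U(0.02, 0.12)) or
  hypermethylated (U(0.80, 0.95)), the same level in all of its tissues,
  with at least one individual per group in every dataset. This mirrors
  the near-extreme interindividual contrasts real MEs display and implies
  an interindividual spread ≥ ~0.6, comfortably above the 0.2 minimum the
  recovery claims assume. We deliberately did not center planted levels at
  intermediate values: at 30× depth the binomial noise of an
  intermediately methylated sample (SD ≈ 0.09) makes the `d_inter/3`
  concordance criterion intrinsically unstable, which is a property of the
  screen, not of the implementation.
* **Background** methylation is a two-component extreme-Beta mixture
  (shapes (0.8, 16) and mirror), identical across individuals — so any
  background CpG passing the screen is a pure false positive.
* **Stage series**: nine stages whose means trace demethylation to the
  blastocyst and remethylation after gastrulation; per-site levels come
  from an extreme-Beta mixture whose *mixing weight* matches the stage
  mean, making stage methylomes bimodal with a small intrinsic
  intermediate tail, plus a planted uniform-[0.1, 0.9] component
  (fraction 0.5) in ME regions post-gastrulation.
* **Reads**: molecules are homogeneous with probability `p_homog`
  (all-M with probability equal to the cluster mean, else all-U) and
  mosaic otherwise (independent Bernoulli calls); 5% of calls are
  uncalled.

Not emulated: sequence context, bisulfite conversion errors, mapping
artifacts, copy-number and repeat structure, linked genetic effects on
methylation (SNPs are placed independently of planted levels), and
correlated methylation between neighboring background CpGs. A green
recovery test therefore establishes that the screen's logic recovers
systemic variation under honest sequencing noise — not that it is robust
to alignment artifacts or to metastability-mimicking genetic effects.

## Numerical conventions

* Coordinates are 0-based half-open everywhere internally; a CpG dyad is
  addressed by its plus-strand C. Bismark rows shift by 1 (plus) or 2
  (minus) on read; both-strand merging precedes depth filtering.
* One master seed; every stochastic component draws a child seed through a
  fixed affine rule (`child_seed()`), so components are independently
  reproducible and all seeds stay below 2^31.
* Lower medians for even-length permutation counts; closed intervals for
  the intermediate band; left-closed histogram and stratum bins with a
  closed final bin.
* Degenerate inputs error loudly: all-zero contingency tables, clusters
  with no adjacent called CpGs, empty stages, unmapped chromatin states.

## Known limitations

* With more than two individuals the pairwise-maximum reading of the
  interindividual difference is one of several defensible
  generalizations; it reduces to the original two-individual design and is
  monotone in the threshold, but a rank-based alternative could behave
  differently at the margins.
* The intersection combination rule makes the screen conservative; the
  published region count cannot adjudicate it (the original combination
  rule is unstated), so it is exposed as configuration.
* Bootstrap CIs are percentile CIs; no BCa correction.
* The RHI null treats calls as exchangeable across the cluster; strong
  position-specific methylation gradients within a cluster would inflate
  RHI even under mosaic methylation.
* Recomputing the published numbers (687 MEs, the 52.3%/20.1%/26.6%
  intermediate proportions, OR 6.2 mQTL enrichment, ZFP57 proximity
  percentages) requires the external WGBS/RRBS accessions and annotation
  downloads; the manifest path (`?read_manifest`) is the documented route
  once those files are on disk.
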