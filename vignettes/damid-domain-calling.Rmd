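---
title: "Calling and analyzing protein-bound chromatin domains from DamID-seq bin counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analyzing protein-bound chromatin domains from DamID-seq bin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damidomains)
```

## The measurement and the model

DamID maps protein-genome contacts by expressing a Dam methyltransferase
fused to a protein of interest (POI) — here B-type lamin (Lam),
heterochromatin protein 1a (HP1a), or Polycomb (Pc). Sequenced methylated
fragments are counted in fixed 1-kb genomic bins for two samples: the
Dam-POI fusion and a Dam-only control that absorbs accessibility and
amplification biases. The quantity the whole pipeline revolves around is
the per-bin log ratio

$$ r_i = \log_2 \frac{\mathrm{RPM}^{POI}_i + \varepsilon}
                      {\mathrm{RPM}^{Dam}_i + \varepsilon}, $$

where counts are first summed over replicates, each merged sample is scaled
to reads per million (RPM), and $\varepsilon$ is the RPM equivalent of a
one-read pseudocount. Contiguous runs of elevated $r_i$ are the footprint
of protein-bound chromatin domains: lamina-associated domains (LADs) for
Lam, HP1a domains, Pc domains.

### Missing bins

Bins whose merged Dam-only count is zero carry no usable signal and are
masked *on the Dam sample only*: a zero Dam-POI count over a covered Dam
bin is a legitimate strong-negative observation, not a gap. The pseudocount
keeps such bins finite. This asymmetric rule matters downstream: the
segmentation never interpolates across masked bins, so a domain can never
bridge a coverage hole, and reported domain sizes are accordingly
conservative.

### Cross-tissue quantile normalization

Profiles of one POI measured in different organs or cell types can differ
markedly in dynamic range for purely technical reasons (different induction
systems), so cross-tissue comparisons use quantile normalization: each
profile's non-missing values are replaced by the mean of the per-profile
order statistics at the same rank (ties averaged, interpolation when
profiles have unequal numbers of non-missing bins). This is delegated to
`limma::normalizeQuantiles()`, whose reference is exactly that
mean-of-sorted-vectors construction. Rank order within a profile is
preserved by construction. Metagene profiles (below) deliberately use the
*raw*, non-quantile-normalized profiles, because quantile normalization
reshapes the local value scale around features.

## Segmentation: a Gaussian hidden Markov model

Domains are called with a hidden Markov model on the per-bin log2 ratios.
Emissions are univariate Gaussians per state — the standard choice for
approximately continuous, roughly symmetric log-ratio data. Two states
(unbound / bound) are used for Lam and HP1a; three states are available for
Pc, where a two-state fit absorbs too much intermediate signal into the
bound state; with three states only the highest-mean state is reported as
domain.

Design choices a user should know:

* **Observation segments.** Each chromosome arm is split at masked bins
  into maximal runs of consecutive observed bins. All segments share one
  parameter set during fitting (each segment restarts the chain from the
  initial distribution), and decoding is per segment, so domains respect
  both arm boundaries and coverage gaps. Length-1 segments participate.
* **Deterministic initialization.** State means start at the 25th/75th
  value percentiles (10th/50th/90th for three states), variances at the
  global variance, self-transitions at 0.99, uniform initial distribution.
  Baum-Welch EM from a fixed starting point makes domain calls exactly
  reproducible — rerunning a fit is bit-identical. A log2-ratio profile
  with real signal is strongly bimodal, so percentile initialization
  starts near the basin of attraction of the intended optimum; random
  multi-restart buys little and costs reproducibility.
* **Convergence.** EM stops when the log-likelihood gain per observation
  falls below `tol` (default 1e-6) or after `max_iter` (default 500)
  iterations. The per-iteration log-likelihood is non-decreasing (an EM
  guarantee that the test suite checks explicitly).
* **Variance floor.** State variances are floored at 1e-3 (log2 units
  squared) to prevent emission collapse onto constant runs.
* **No minimum domain length.** Any run of bound-state bins, including a
  single bin, is a domain. Filtering by length is left to the user.
* **Decoding.** Viterbi, per segment. The implementation is checked
  against exhaustive enumeration of all state paths on short segments.

## Domain statistics

Interval arithmetic (intersection, union, complement, coverage fractions)
is exact base-pair set algebra, implemented on GenomicRanges and verified
against a per-base boolean oracle. Two features overlap when they share at
least 1 bp; a promoter (the distal transcription start site, i.e. the TSS
farthest from the gene's 3' end) is assigned by its single base pair under
half-open containment. Conserved domains across cell types are the strict
intersection of all per-cell-type domain sets (a k-of-n relaxation exists
but is off by default); conserved inter-domains are the bases outside
every set.

### Permutation nulls

Enrichment of overlap between two interval sets is judged against a null
in which each element of the query set is independently re-placed
uniformly within its own chromosome arm's analysis region, preserving its
length; shuffled elements may overlap one another. The empirical p-value
uses the add-one estimator $p = (1 + \#\{S_{null} \ge S_{obs}\})/(1 +
n_{perm})$, which is never zero and is bounded below by $1/(n_{perm}+1)$.
Uniform independent placement is the simplest defensible null when the
only constraints are arm identity and element length; the test suite
verifies that under a true null the p-values are Uniform(0,1).

Chromosome-level comparisons (e.g. whether HP1a signal on the X is shifted
relative to autosomes) use two-sided Mann-Whitney U tests with normal
approximation and tie correction; the 4th chromosome is excluded from the
autosome pool by default because its domain organization differs
qualitatively from the major arms.

### TE proximity

Transposable-element insertions are extended by 0.5 kb on each side and
counted as (TE, domain) overlapping pairs against HP1a-bound versus
HP1a-free LADs. Because the two classes have different total lengths,
events are normalized per Mb of class length ("occupancy") before forming
the bound/free ratio; the permutation null re-places TEs uniformly within
the analysis windows of their own arms.

## Expression integration

Gene expression enters as TPM tables (replicates averaged arithmetically).
Genes with TPM ≥ 1 count as expressed; expression strata are silent
(TPM 0–1), low (1–10), medium (10–44), high (> 44), with a data-driven
mode that re-derives the two upper boundaries so the three expressed
strata hold equal gene counts. Ubiquitously expressed genes are defined
from microarray present calls: a transcript qualifies with ≥ 3 of 4
present calls in every one of 15 tissues, and a gene qualifies through any
transcript. Tissue-specific genes are the expressed genes minus the
ubiquitous list.

The metagene profile takes, for each qualifying gene, the seven 1-kb bins
centered on the bin containing its distal TSS, read in the gene's 5'→3'
orientation (mirror-reversed on the minus strand). A gene qualifies only
if its body overlaps the relevant domain type; upstream bins that touch
another gene are dropped (they would import that gene's promoter signal),
and downstream bins must still lie over the gene's own body. Per-offset
medians are taken over genes, skipping masked bins.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.
Its defaults define the package's reference conditions:

* **Toy genome:** two 5-Mb euchromatic arms plus one 500-kb
  pericentromeric (CHet) arm, 1-kb bins — large enough for stable
  statistics, fast enough for test suites.
* **Domain architecture:** LAD coverage 0.40 of the analysis windows with
  geometric domain lengths of mean 50 bins; HP1a coverage 0.15, mean 10
  bins, with 80% of HP1a length planted inside LADs; Pc coverage 0.15
  placed independently. Placement is sequential packing: lengths are drawn
  until the coverage target is met (the last draw trimmed), positions are
  uniform over the remaining free space, so realized coverage matches the
  target to within one domain and planted domains never merge away.
  HP1a host LADs are drawn uniformly per LAD from a random subset holding
  half the LAD length, which leaves a substantial HP1a-free LAD class of
  comparable length distribution — mirroring real cell types, where most
  HP1a lies in LADs while only part of total LAD length carries HP1a.
* **Counts:** negative binomial per bin (not Poisson — DamID bin counts
  are overdispersed), size parameter 5, expected depth 10^6 reads per
  replicate, two replicates. Dam-POI means are multiplied by $2^\delta$
  ($\delta = 1.5$ by default) inside planted domains. A 5% dropout
  fraction of bins is forced to zero Dam counts to exercise the
  missing-bin path end to end.
* **Expression:** log2 TPM is Gaussian with mean 4 outside and 1 inside
  domains (a 3-log2 planted repression), sd 1.5.
* **TEs:** 3000 insertions of 500 bp placed with twofold density inside
  and within 0.5 kb of HP1a-bound LADs relative to background.

Everything is a pure function of configuration and a mandatory seed.

What the generator does *not* emulate: GATC-fragment structure and
mappability, bin-to-bin autocorrelation of technical noise, copy-number
variation, replicate-specific biases, the empirical length distribution of
real LADs, or TE family structure. Passing recovery tests on synthetic
data therefore demonstrates the *correctness of the algorithms under the
generative assumptions*, not performance on any particular real library.

One quantitative consequence of the overdispersion default is worth
stating: with NB size 5 the between-replicate correlation of single-
replicate log-ratio profiles is limited to roughly
$\sigma^2_{signal}/(\sigma^2_{signal} + \sigma^2_{noise}) \approx 0.4$ at
$\delta = 1.5$, however deep the sequencing, because the dispersion term
$2/\mathrm{size}$ dominates the noise. Strong replicate correlations like
those seen in real experiments correspond to low-overdispersion regimes
(size on the order of 10^2), and the test suite checks exactly this
decomposition rather than a blanket correlation threshold.

## Problem sizes and numerical notes

The bundled analyses run on the toy genome (10,500 bins) with EM
converging in well under 100 iterations; the Viterbi-versus-enumeration
check uses 500 random segments of length ≤ 12; permutation calibration
uses 200 trials of 500 permutations; interval-algebra verification uses
1000 random cases on 10-kb arms. These sizes were chosen so the entire
verification cycle completes in a few minutes on a laptop while keeping
Monte-Carlo error well inside the asserted tolerances. Degenerate inputs
fail loudly rather than silently: constant observation vectors, all-zero
Dam samples, empty regions, elements longer than any window on their arm,
and genes on unknown arms are all explicit error or warning paths.

## Known limitations

* Domain calls are bin-resolution; boundary uncertainty below the bin
  width is invisible.
* The HMM assumes Gaussian emissions; profiles with heavy tails (e.g.
  unmasked copy-number artifacts) can inflate state variances.
* The permutation null ignores interval-interval spacing constraints;
  for highly clustered query sets it is slightly liberal.
* Quantile normalization across cell types assumes the *shape* difference
  between profiles is technical; genuine global biological differences
  are normalized away by construction.
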