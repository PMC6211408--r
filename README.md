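# damidomains

Downstream analysis of DamID-seq experiments that map protein–genome
contacts in *Drosophila*-style genomes: nuclear lamin (Lam), HP1a and
Polycomb (Pc). The package is aimed at analysts who already have per-bin
read counts (1-kb bins by default) for Dam-only and Dam-POI samples and
want reproducible domain calls and the statistics built on them.

The pipeline:

1. **Normalize** — merge replicates, scale each merged sample to reads per
   million, and form the per-bin profile
   `r_i = log2((RPM_POI_i + ε)/(RPM_Dam_i + ε))`, masking bins with no Dam
   coverage. Optional quantile normalization aligns profiles of one POI
   across cell types.
2. **Segment** — a two- or three-state Gaussian hidden Markov model
   (Baum–Welch + Viterbi, deterministic initialization) labels each bin;
   runs of the highest-mean state are the protein-bound domains
   (lamina-associated domains for Lam). Segmentation never bridges bins
   lacking Dam coverage.
3. **Quantify** — exact base-pair interval algebra for coverage, pairwise
   overlap and cross-cell-type conservation; permutation tests that
   re-place elements uniformly within their chromosome arm (length
   preserved); X-versus-autosome value shifts (Mann–Whitney U);
   promoter/body classification of genes against domains, expression
   strata, TSS metagene profiles; transposable-element occupancy near
   HP1a-bound versus HP1a-free LADs.
4. **Simulate** — a synthetic-data generator plants domain architectures,
   negative-binomial counts, expression tables and TE insertions with
   known truth, so every stage is testable without sequencing data.

## Worked example

Simulate a two-arm toy genome with planted LADs, run the pipeline, and
score the calls against the planted truth:

```r
library(damidomains)

truth <- generate_truth(seed = 42)                  # planted domains + genes
sim   <- simulate_damid_counts(truth, poi = "Lam", seed = 43)
prof  <- merge_and_normalize(sim$dam, sim$poi, poi = "Lam", cell_type = "toy")
res   <- call_domains(prof, n_states = 2)
res$model
#> HmmModel: 2 states; 6 EM iterations; logLik -11100.21
#>   means: -0.8350,  0.6675
#>   sds:   0.6777, 0.6788
res$domains
#> DomainSet [Lam/toy]: 235 intervals, 3,793,000 bp

st <- domain_recovery_stats(res$domains, truth$domains$Lam, truth$grid)
#> F1 = 0.964, median boundary error = 0 bp
```

The fitted unbound/bound emission means (−0.84 / +0.67 log2 units) bracket
the planted 1.5-log2 enrichment; 96% of bins are labelled correctly
(F1 = 0.964) and the typical called boundary sits on the true one.

Domain-overlap enrichment against a permutation null:

```r
win <- cha_windows(truth$assembly)
permutation_overlap_test(res$domains, truth$domains$HP1a, win,
                         n_perm = 1000, seed = 44)
#> Permutation test (overlap-length, greater): observed 1.151e+06,
#>   null mean 5.826e+05, enrichment 1.98, p = 0.000999 (n_perm = 1000)
```

The called LADs overlap the planted HP1a domains about twice as much as
arm-shuffled intervals of the same lengths would (the generator plants 80%
of HP1a length inside LADs), with the p-value at the floor of the add-one
estimator.

A command-line wrapper over the same functions is installed at
`inst/scripts/damid_pipeline.R` (subcommands `simulate`, `normalize`,
`call-domains`, `overlap`, `permtest`, `chrom-shift`, `te-enrich`;
YAML config; exit codes 0/2/3 for success/config error/data error).

## Vignette

`vignettes/damid-domain-calling.Rmd` documents the model, the missing-bin
policy, the HMM design choices (initialization, tolerance, variance
floor), the permutation nulls, what the synthetic generator does and does
not emulate, and known limitations.
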