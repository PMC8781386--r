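# tandemshm

Tandem substitution analysis for somatic hypermutation (SHM) in B-cell
receptor repertoires.

## The problem

During affinity maturation, activation-induced cytosine deaminase (AID)
triggers somatic hypermutation of immunoglobulin V regions. Most resulting
mutations are single nucleotide substitutions (SNS), but a fraction are
*tandem* substitutions: two or more contiguous bases replaced in a single
damage/repair event (tandem dinucleotide substitutions, TDNS, for k = 2).
In a sequenced repertoire a true tandem is indistinguishable from two
independent SNS that happen to land on adjacent positions, so the observed
count of contiguous substitutions overstates the true tandem rate —
especially around AID hotspots, where mutations cluster.

`tandemshm` is a tested pipeline for this analysis:

* **Selection** — collapse clonal expansions (same V/D/J gene, same CDR3
  length, ≥ 95% CDR3 nucleotide identity, single linkage) to the least
  mutated member; exclude unmutated sequences and those with > 5%
  V-region mutations; optional binning of the hypermutated remainder.
* **Calling** — maximal runs of adjacent mutated positions against the
  germline V allele, with 1-nt flanks; indels and `N` are disregarded and
  split runs; transitions/transversions (Ts/Tv).
* **Monte-Carlo null** — per-position SNS frequencies `f(p)` and target
  distributions `g(p, b)` drive an in-silico re-mutation of the germline:
  each sequence receives its in-vivo mutation load, placed independently.
  Clusters arising in `R` replicates are "false" tandems; observed counts
  are corrected by the simulated mean, with z-scores
  `z_k = (O_k − μ_k)/σ_k` and corrected incidences
  `C_k / (S′ + Σ C_k)` where `S′ = O_1 + Σ k·μ_k` re-counts each false
  cluster as `k` SNS.
* **Classification** — TDNS geometry: *inversion* (`XY → YX`),
  *juxtalocation* of the 5′ or 3′ base (one germline base re-appears
  shifted one position), or *other*; expected fractions under a uniform
  outcome null are 1/9, 4/9 and 4/9. Codon slot, amino-acid effect
  (including slot-3 double-codon calls), germline-context containment,
  and AID motif annotation (WRCY/WA/RCG, both strands, hotspot-anchored).
* **Signatures** — 144-cell dinucleotide substitution tables, collapse to
  the 78-class COSMIC-style doublet (DBS-78) catalog, cosine similarity
  against supplied signature catalogs.
* **Selection scoring** — per-codon mutational resistance score
  `S_q = s_q/n_q − E_q` (observed minus expected synonymous proportion,
  nonsense substitutions disregarded on both sides) and quasi-Poisson
  regression of per-position TDNS counts on the score.
* **Synthetic data** — a generator with known ground truth: hotspot-biased
  SNS, an injected true-tandem process with controllable rate θ and a
  juxtalocation-biased outcome model, clonal expansion, and regeneration
  of sequences acquiring stop codons.

## Worked example

```r
library(tandemshm)
cfg <- synthetic_config(n_sequences = 300, theta = 0.05, seed = 7)
res <- run_synthetic_analysis(cfg, reps = 2000)
res$report
```

```
collapse: 300 -> 300 records
filter: kept 300 (unmutated 0, hypermutated 0)
call: 1932 events from 300 records
<tdns_report> schema 1.0
  records: 300 in -> 300 analysed; 1932 events
  corrected cumulative tandem incidence: 0.0512
  TDNS categories: inversion 0.118, juxtalocation 0.412, other 0.471
  Ts/Tv: 1.062 (ok)
```

The generator injected true tandems at rate θ = 0.05; after subtracting
the simulated false-tandem mean the pipeline reports a corrected
cumulative tandem incidence of 0.0512. The k = 2 z-score in the same run
is 13.3 — the observed tandem count is far above what independent SNS
placement explains — while run lengths ≥ 3 sit near their null mean.
Ts/Tv ≈ 1.06 reflects the generator's transition weighting, matching the
roughly balanced pattern seen in SHM data.

A CLI mirroring the pipeline stages ships in `inst/cli/tandemshm.R`:

```sh
Rscript inst/cli/tandemshm.R synth --theta 0.05 --n 500 --seed 1 --out-dir out/
Rscript inst/cli/tandemshm.R run --germlines out/alleles.fasta \
    --rearrangements out/records.tsv --reps 1000 --seed 1 --out-dir out/
```

## Documentation

The methods vignette (`vignettes/tandem-substitutions.Rmd`) describes the
model, the null simulation and its assumptions, the synthetic-data world,
numerical choices and known limitations. Function-level documentation is
in the roxygen comments in `R/`.
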