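---
title: "Quantifying tandem substitutions in somatic hypermutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tandem substitutions in somatic hypermutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemshm)
```

## The model

Somatic hypermutation deposits point mutations across immunoglobulin V
regions at rates of a few percent per base, concentrated around AID
hotspot motifs (WRCY, WA, RCG and their reverse complements). A *tandem*
substitution is a run of k ≥ 2 adjacent substituted bases created by one
damage/repair event. The central inference problem is that a sequenced
repertoire only shows *runs*: a run of length 2 may be one tandem event or
two independent single nucleotide substitutions (SNS) that landed next to
each other. Because SHM clusters mutations, the coincidence rate is far
from negligible and must be estimated, not assumed.

`tandemshm` estimates it with a profile-driven Monte-Carlo null. For each
V allele we tabulate, from k = 1 events only,

* `f(p)` — SNS count at ungapped position `p` divided by the number of
  sequences with a readable base there, and
* `g(p, b)` — the empirical distribution of the three non-germline target
  bases at `p`.

Each replicate re-mutates the germline: every sequence receives exactly
its observed number of substituted bases, placed at distinct positions
drawn with probability proportional to `f` (without replacement — a
position mutates at most once per sequence), and runs are counted with
the same scanner used on the real data. Replicates yield the null mean
`μ_k` and spread `σ_k` of run counts; the observed count `O_k` is
compared by `z_k = (O_k − μ_k)/σ_k` and corrected as `C_k = O_k − μ_k`.
Re-counting each expected false cluster as `k` single substitutions gives
an adjusted SNS total `S′ = O_1 + Σ_{k≥2} k·μ_k`, so the corrected
incidence of length-k events is `C_k / (S′ + Σ_{k≥2} C_k)`.

Two modelling choices deserve emphasis:

* **The profile uses SNS only.** Bases inside observed runs do not
  contribute to `f`. Including them would contaminate the null with the
  very signal under test; the cost is a slight under-weighting of
  genuinely hot positions that happen to sit inside tandems.
* **Loads are matched per sequence, not per repertoire.** A sequence with
  10 substituted bases is re-mutated with exactly 10. This preserves the
  quadratic dependence of coincidence rates on per-sequence load, which a
  pooled-load model would miss.

The simulation restricts to the most abundant alleles (default 20, the
`top_alleles` argument) so that each profile is estimated from enough
sequences; an extrapolation factor (total events / modelled events) is
reported for whole-dataset arithmetic. Negative corrected counts are
reported as-is with a flag, never clipped.

## Tandem geometry

For a reference dinucleotide `XY` mutated to `X′Y′` with both bases
substituted, the classifier distinguishes

* **inversion**: `X′ = Y` and `Y′ = X` (the dinucleotide reversed),
* **juxtalocation of the 5′ base**: `Y′ = X`, i.e. the germline 5′ base
  re-appears one slot downstream (sequence shifted up by one),
* **juxtalocation of the 3′ base**: `X′ = Y` (the mirror case),
* **other**: neither equality.

Inversion takes precedence because it satisfies both equalities. Under a
uniform distribution over the 9 legal outcomes of a heterodimer
reference, enumeration gives 1/9 inversions, 4/9 pooled juxtalocations,
4/9 other — the yardstick against which observed category fractions are
tested (a one-sample z-test on the proportion; the underlying test
construction for fractions was not fully specified upstream, so the
normal-approximation proportion test is used and documented here as that
stand-in). For homodimer references no legal outcome can satisfy either
equality, so only *other* is possible; geometry is therefore only
assessable on heterodimer references.

Which equality is called "5′" versus "3′" juxtalocation is a labelling
convention: the source figure names the classes without writing the
equalities. The convention above (5′ base re-appearing downstream =
juxtalocation of the 5′ base) is fixed and documented; either choice
leaves every aggregate count unchanged.

## Amino-acid effects, motifs, context

Events are placed in codon slots by the allele's reading frame: slot 1
covers codon bases 1–2, slot 2 bases 2–3, slot 3 spans base 3 plus base 1
of the next codon. Effects are computed with the standard genetic code;
a slot-3 tandem touching two codons can be `double_synonymous`,
`double_replacement`, or `nonsynonymous` for the mixed case, and any
codon turning into a stop is `nonsense`. Events overlapping an incomplete
trailing codon are skipped with a recorded reason and retained for all
non-effect analyses.

AID motif annotation is *hotspot-anchored*: a flag is set only when an
occurrence of WRCY/WA/RCG (forward, or the reverse-complement image
RGYW/TW/CGY searched on the coding strand) has its mutable hotspot base —
the C of WRCY/RCG, the A of WA, or the complementary base for
reverse-complement occurrences — exactly at the event's 5′-most or
3′-most position. This is the strictest reading of "motif at the 5′/3′
position of the tandem"; window-overlap annotation would flag more events
but blurs the strand asymmetry the analysis looks for. The orientation
convention for the non-canonical RCG motif is unstated upstream; it is
searched forward plus reverse-complement, symmetrically with the other
two motifs.

Germline-context containment asks whether the *observed* dinucleotide
already exists immediately around the site (offset −1 or +1 windows),
the signature of a one-position juxtalocation; boundary windows never
match.

## Signatures

k = 2 events accumulate in a 144-cell table (16 references × 9 legal
outcomes). The table collapses onto the 78 canonical COSMIC-style doublet
classes by reverse-complementing any (reference, alternate) pair whose
label is not canonical. The collapse conserves total mass and maps a
table and its strand-wise reverse complement to the identical catalog;
both properties are asserted in tests. Comparison against supplied
catalogs uses cosine similarity on the 78-vector. No signature fitting or
decomposition is attempted.

## Mutational resistance score

For each sense codon the 9 single-base substitutions partition into
synonymous / non-synonymous / nonsense. Nonsense substitutions are
disregarded (a receptor with a stop codon is deleted from the repertoire
and cannot be observed), giving `P_syn = n_syn / (n_syn + n_nonsyn)`.
Weighted by germline codon usage at each position (repertoire-frequency
weights by default, allele-uniform available) this yields the expected
synonymous proportion `E_q`; the observed proportion among SNS (nonsense
excluded symmetrically) minus `E_q` is the mutational resistance score
`S_q ∈ [−1, 1]`. High scores mark positions where replacement mutations
are purged — candidates for purifying selection. Per-position TDNS counts
(attributed to the codon containing the event's 5′ base, a deterministic
convention) are regressed on `S_q` with a quasi-Poisson GLM
(log link, IRLS, Pearson dispersion, t-based p on N − 2 df). The
quasi-Poisson point estimates equal plain-Poisson estimates; only the
standard errors scale by √φ — asserted in tests.

## The synthetic world

The generator states one fixed world; its defaults were chosen once and
are not tuned against test outcomes:

* V alleles: 5 random in-frame, stop-free 300-nt sequences containing at
  least one WRCY and one WA occurrence (`generate_toy_alleles`).
* Per-sequence load: uniform 1–12 mutation *events*, so total mutated
  bases stay within the analysis' 0–5% window at the tandem rates used.
* Hotspot bias: positions inside WRCY/WA footprints (either strand) carry
  a 3-fold placement weight — mid-range for reported hotspot
  enrichments and strong enough that coincidental adjacency is a real
  effect to correct.
* SNS targets: the transition weighted 2:1 over each transversion,
  giving Ts/Tv ≈ 1, the balanced pattern characteristic of SHM.
* True tandems: with probability θ an event is an adjacent pair; under
  the juxtalocation-biased model (default) the outcome is a ±1-shifted
  germline dinucleotide with probability 0.8 when a legal shift exists,
  else uniform over the 9 legal outcomes.
* Selection proxy: sequences whose mutated V region contains a stop codon
  are regenerated (bounded retries), emulating the depletion of nonsense
  variants without modelling selection explicitly.
* Clonal structure: `expand_clones` adds 1..factor copies with extra SNS,
  so the original is always the least mutated member and clonal collapse
  is exactly invertible.

What a green test does establish: the caller recovers planted events
exactly; the null model's corrected incidence is centred on 0 when θ = 0
and covers θ at the rates tested; classification, effect and signature
arithmetic agree with independent enumeration oracles. What it does not:
real repertoires have indels, sequencing error, allele mis-assignment,
lineage structure and selection acting during (not after) mutation
accumulation — none of which are simulated — so green tests validate the
*method*, not cohort-level biological claims.

A known small bias is visible in parameter recovery: observed loads
include tandem bases, so the null (which places every base independently)
slightly *over*-estimates the coincidence rate, depressing the corrected
incidence by a few tenths of a percentage point at θ = 0.05 under the
default loads. The acceptance check absorbs this within its combined
binomial + Monte-Carlo error band; at repertoire scale the same bias
affects the original method and is one reason corrected incidences are
conservative.

## Numerical choices

* Coordinates are 0-based, half-open, in ungapped germline space; IMGT
  `'.'` columns are dropped before any position is numbered.
* A run interrupted by `N` or a gap is split; the flank facing the
  unreadable base is recorded as `'N'`, boundary flanks as `'-'`
  (sentinels never match any context window).
* The Monte-Carlo kernel is compiled (Rcpp) and draws weighted samples
  without replacement via exponential keys, distributionally identical to
  R's sequential `sample(prob = )`; the pure-R `simulate_replicate` is
  the readable reference implementation and the two are cross-checked.
  Replicate r's RNG stream depends only on (seed, r), so results are
  reproducible and independent of execution order.
* Replicates default to 1000 in the API (the reference scale is 100000);
  tests and the acceptance suite use 2000 to stay within desk-scale CPU
  budgets. The estimator is unbiased in the number of replicates; only
  Monte-Carlo error shrinks.
* Ties in clonal collapse (equal mutation counts) resolve to the
  lexicographically smallest sequence id; single linkage is used for the
  ≥ 95% CDR3 clusters (the linkage criterion was unstated upstream and is
  documented here as a package choice).
* Mutation-load bins are left-open/right-closed — `(0.05, 0.10]`,
  `(0.10, 0.20]`, `(0.20, 1]` — so a sequence at exactly 5% belongs to
  the main analysis set and no sequence is double-counted.

## Limitations

* Insertions and deletions are ignored throughout; a run abutting an
  indel is kept but split, which may undercount longer tandems in
  indel-rich data.
* Region/frame metadata must be supplied (a toy set ships in
  `inst/extdata/`); the package does not re-derive IMGT numbering.
* The proportion z-test on category fractions is approximate for small
  tandem counts.
* Cosine similarity compares catalogs; it does not decompose a catalog
  into signature mixtures.
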