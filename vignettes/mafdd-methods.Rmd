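---
title: "Pooled F1 mapping with MAFD and AFDDD: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled F1 mapping with MAFD and AFDDD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafdd)
```

## The genetic model

The package targets a specific and common situation in out-crossing woody
species: a dominant trait segregating in a small F1 population whose two
parents are both highly heterozygous. One parent (the *seed parent*)
carries a single copy of the dominant causal allele $W$; the other parent is
$ww$. Progeny are therefore expected to split 1:1 between carriers
(mutant phenotype) and non-carriers, which `chi_square_ratio()` tests.

DNA of the progeny is not sequenced individually. Instead, two bulks are
formed — a mutant pool and a wildtype pool — and sequenced as single
libraries. A variant's pooled allele frequency then estimates its frequency
among the $2n$ chromosomes of the pool, and linkage to $W$ distorts that
frequency in opposite directions in the two pools.

For a biallelic variant the parents' allele configuration is one of the
pseudo-testcross segregation types. Writing the seed parent's causal-phase
allele first, the three *informative* types and their expected variant
allele frequencies at full linkage are:

* type I `<lm×mm>` — heterozygous in the seed parent only: (50%, 0%);
* type II `<lm×ll>` — seed parent heterozygous, other parent homozygous for
  the variant: (100%, 50%);
* type III `<hk×hk>` — both parents heterozygous for the same two alleles:
  (75%, 25%).

`expected_pool_frequency()` generalises these to any recombination fraction
$r \in [0, 0.5]$ by exact enumeration of the seed parent's four ordered
gamete classes (causal allele × variant-locus allele, weights $(1-r)/2$ and
$r/2$), conditioned on the pool (carriers vs non-carriers), plus the other
parent's unconditioned transmission. At $r = 0.5$ the pools coincide at the
unlinked expectations (25%, 75% and 50%). The enumeration is closed-form
and shares no code with the simulator, so agreement between the two
(tested) is a genuine cross-validation.

Because all three informative types show the same +50-percentage-point
excess in the mutant pool, the *allele frequency directional difference*

$$\mathrm{AFDD} = f_\text{mutant} - f_\text{wildtype}$$

is the shared, measurable signature of linkage. It is signed on purpose:
the reciprocal contrast (wildtype-specific or wildtype-enriched variants)
serves as a negative control, available via `afddd_map(..., reverse = TRUE)`.

## The two scans

Both mapping functions combine a frequency-signal profile with a variant
*density* scan, because pooling concentrates trait-linked variants in the
causal region while the selection band thins them out everywhere else.

**MAFD** (`mafd_map()`) uses the mutant-pool-specific variants (type I at
full linkage is invisible in the wildtype pool because its expected
frequency there is 0). The profile is the moving-window mean frequency of
*all* mutant-specific variants; the density track counts only variants with
frequency inside the band (default 40–60%, inclusive) around the type I
expectation of 50%.

**AFDDD** (`afddd_map()`) uses the pool-common variants. Variants with
AFDD ≥ 30 points (inclusive) are selected; the profile is their
moving-window mean AFDD and the density track their per-Mb counts. The
threshold sits well below the 50-point optimum: pools of 17 and 16 progeny
plus 25× binomial read sampling give the AFDD of a fully linked variant a
standard deviation around 15 points, and 30 keeps roughly 90% of truly
linked variants while admitting only ~2% of unlinked ones.

Significance is assessed per 1-Mb bin with the standard score
$z = (X - \mu)/\sigma$, where $X$ is the bin's density (variants/Mb) and
$\mu, \sigma$ are the mean and population standard deviation (divisor $N$)
over **all** bins genome-wide, empty bins included. Bins with $z \ge 2.6$
(inclusive) are significant — two-tailed normal $P \approx 0.01$, computed
exactly as $2(1 - \Phi(|z|))$ by `z_to_p()` and reported to two significant
figures. Maximal runs of contiguous significant bins are merged into
regions, with no gap bridging; the region's peak $z$ is its score in the
BED export (×100, clamped to [0, 1000]).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| heterozygous band | 15–80 (inclusive), >80 homozygous | % | at 25× coverage a true 50% heterozygote rarely reads below 15% or above 80%; the asymmetry reflects that homozygotes can only read downwards |
| low-frequency class | <15 | % | excluded from genotype groups, counted separately — such calls are rare after the read-count filters |
| MAFD band | 40–60 | % | symmetric around the type I expectation of 50% |
| AFDD threshold | ≥30 | points | inclusive; see above |
| moving window | 20 | variants | fixed-count windows adapt their genomic span to local variant density |
| bin size | 1 Mb | bp | density is defined per Mb; bins anchored at position 1, final partial bin length-scaled |
| z cutoff | 2.6 | — | two-tailed $P \approx 0.01$ |
| primary filter | coverage ≥10, variant reads ≥2 | reads | permissive capture stage |
| confidence filter | coverage ≥20, balance 0.25–0.5, unique starts ≥5 | — | pre-mapping false-positive control |

Two filter definitions are not fixed by any published description of the
upstream callers and are therefore explicit, configurable choices here:
*hyperallelic* means ≥3 distinct alternate alleles at one position
(`hyperallelic_min_alts`), and the homopolymer filter removes indels whose
site sits inside a reference run of ≥4 identical bases
(`homopolymer_min_run`), skipping with a warning when no reference context
is supplied. Strand *balance* is defined on variant-supporting reads as
$\min(f, r)/(f + r)$, so 0.5 is perfect balance — the only reading under
which an upper bound of 0.5 is meaningful.

## Genotype groups and candidate types

Pool-common variants are cross-classified by zygosity in each pool into G1
(het/het), G2 (hom/het), G3 (het/hom), G4 (hom/hom) and G5 ("complex", ≥3
distinct bases at the site across pools). `infer_candidate_types()` maps
each group back to the segregation types that could produce it; the map
covers the six base types in both phases and is our reconstruction — with
coupling/repulsion phase resolved, G2 is essentially diagnostic for type II,
while G1 mixes type III with non-informative configurations, which is why
AFDDD selection (not group membership alone) is the operative filter.
`<lm×mm>` appears among the G3 candidates because at incomplete linkage its
wildtype-pool frequency $100 \cdot r/2$ can clear the calling threshold.

## The simulator, and what it does and does not emulate

`simulate_cross()` is the package's test harness. Defaults describe the
study design the method addresses: pools of 17 and 16 progeny, 25× mean
coverage, and a five-chromosome 30-Mb genome that keeps full-genome tests
fast while leaving a real genome-wide background (150 bins). Variants are
placed uniformly at 40/Mb for each of type I, II, III and the
non-informative classes (an equal mix of `<nn×np>` and `<qq×qq>`) —
comparable to the pool-specific variant density seen in real heterozygous
tree crosses — with random phase (`coupling_fraction = 0.5`). Linkage uses
Haldane's map function $r = (1 - e^{-2d/100})/2$ at 2 cM/Mb, applied
between each variant and the causal locus only (no multi-locus
interference). Read sampling is Poisson coverage (minimum 1), binomial
variant reads at the true pooled fraction, binomial strand split, and a
capped-Poisson model (mean 10) for unique read start positions. Calls with
zero variant reads are suppressed, which is what makes membership
(pool-specific vs common) emerge naturally. Phenotype misclassification
(default 0) flips a progeny's pool assignment with a fixed probability, a
deliberately crude stand-in for incomplete penetrance and intermediate
phenotypes. All randomness flows from one integer seed; identical configs
are byte-identical.

The simulator does **not** emulate: read-level errors and mapping bias,
uneven coverage between pools (a known source of false pool-specific
calls), linkage disequilibrium among variants beyond their common linkage
to the causal locus, multi-allelic sites, or structural variation. Passing
tests therefore demonstrate the statistical machinery under clean Mendelian
sampling, not robustness to alignment artefacts.

## Resolution: why simulated peaks are broad

A point worth understanding before interpreting simulated scans: at
2 cM/Mb, the expected AFDD of a linked variant, $50(1 - 2r(d))$, stays
above the 30-point selection threshold out to roughly 13 Mb from the causal
locus. On a 30-Mb chromosome this means the *entire* causal chromosome
becomes an elevated, nearly flat plateau of selected-variant density rather
than a sharp peak. Two consequences, both visible in the test suite:

* the genome-wide maximum-z bin reliably falls on the causal chromosome,
  but its exact position wanders across the plateau from seed to seed, so
  single-bin localisation is not a meaningful claim at this genome scale;
* with 20% of all bins elevated, the genome-wide $\sigma$ is inflated and
  plateau z-scores sit only modestly above the cutoff (≈2–3.5).

On a realistic genome where the causal chromosome is a few percent of the
total (e.g. 17 chromosomes totalling >500 Mb), both effects shrink and the
method localises to a sub-chromosomal region. The density z-test itself is
scale-invariant in variant density, so raising simulated densities does not
sharpen the peak — only a larger genome or tighter linkage decay does.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive internally (VCF convention); only the
  BED writer converts to 0-based half-open.
* Multi-allelic records are split into biallelic calls before anything
  else; the cross-pool join is on the exact key (chromosome, position,
  class, ref, alt), so the same position with different alternate alleles
  yields two pool-specific records. Matching on allele identity rather than
  position alone is a deliberate choice: a shared position with discordant
  alleles is evidence of two different variants, not one common one.
* Declared frequencies in tabular input are cross-checked against
  count/coverage; discrepancies beyond 0.5 points warn and the recomputed
  value wins.
* `z_test()` with identical densities ($\sigma = 0$) sets all z to 0 with a
  warning; fewer than 2 bins is an error. Empty band or AFDD selections
  warn and return empty density tracks rather than failing.
* The Yates continuity term is capped at $|O - E|$ so the corrected
  chi-square statistic can never go negative. Both corrected and
  uncorrected statistics are always computed and carried in the result,
  because published segregation tables mix the two conventions; the choice
  is the caller's and the printout shows both.
* Filter cascade order is fixed and each removed record is attributed to
  the first failing filter, making report counts conserve exactly
  (input = removed + surviving).

## Problem sizes used by the test suite

The suite simulates full crosses at the default 5 × 30 Mb scale
(~24 000 variants, seconds per replicate) for mapping tests and 20-replicate
recovery studies, and ~1000-variant single-chromosome crosses at 1000×
coverage for the segregation-type frequency checks, where pool-sampling
noise alone sets the ±2-point tolerance. These sizes were chosen to make
every stochastic assertion comfortably stable under its fixed seed.

## Known limitations

* Causal variants themselves are only discoverable in the mutant-specific
  (MAFD) track; AFDDD's common variants cannot contain a dominant causal
  mutation's private allele.
* Segregation types with more than two alleles (`<ab×cd>`, `<ef×eg>`) are
  recognised as G5 but not modelled quantitatively.
* No multiple-testing correction is applied beyond the plain z cutoff; the
  scan is a screening tool, and downstream confirmation (markers,
  co-segregation) is expected.
* Intermediate phenotypes are modelled only as symmetric misclassification;
  a second modifier locus is outside the default model.
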