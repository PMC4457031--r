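---
title: "Methods: recessive-trait mapping and digital expression in an F2 intercross"
author: "f2map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive-trait mapping and digital expression in an F2 intercross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f2map)
```

This vignette documents the models, assumptions, parameter choices and
numerical conventions behind each stage of the pipeline, in the order a
study would run them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Study design and what the simulator emulates

The setting is a single three-generation family: two founders from
divergent lines, two F1 full sibs, and their F2 offspring segregating a
fully penetrant autosomal-recessive disorder (expected 3:1
unaffected:affected). `simulate_f2_cross()` emulates this design with:

* **Inbred-line founders.** Each founder is drawn as a line-representative
  homozygote: per marker, the line-B allele frequency either mirrors line
  A's (probability `founder_divergence`, default 0.7) or equals it. This is
  the classical fixed-line intercross model. It is a deliberate
  idealization: a heterozygous founder dam would hand different haplotypes
  to the two F1s over half the genome, and a clean shared-homozygosity
  segment around the causal locus would exist only where both F1 line-B
  chromosomes happen to descend from the same founder haplotype — the
  single-family design of the emulated study worked because that was the
  case. Residual within-line polymorphism is therefore *not* simulated, and
  passing tests say nothing about populations where the disease haplotype
  is not unique in the founder line.
* **Haldane crossovers.** Per gamete, crossovers are a Poisson process at
  1 cM/Mb (configurable), no interference. At the ~100-Mb scale of one
  chromosome, interference would change segment-length variance slightly
  but not the operating characteristics tested here.
* **Planted truth.** An F2 is affected if and only if both its gametes
  carry founder-B origin at `causal_bp` (default mid-chromosome at 50 Mb on
  a 100-Mb chromosome): full penetrance, no phenocopies. Genotyping error
  flips a dosage to one of the other two values at rate 0.002; missingness
  is 0.02 — values a 60K-chip study would consider typical after sample QC.
  Defaults of 75 F2s and 1,000 markers reflect the emulated family size and
  a realistic informative-marker density for desk-scale validation.

All generators are pure functions of `(seed, parameters)` and serialize
enough truth (origins per gamete and marker, carrier dosages, crossover
positions) to score every downstream stage without re-simulation.

## Marker QC and segregation

`qc_filter_markers()` removes markers with call rate < 0.90, minor allele
frequency < 0.05, Hardy–Weinberg equilibrium p < 10⁻⁶ (Pearson χ², 1 df, no
continuity correction), or unknown position. Boundary semantics are
literal: a value exactly at a threshold is kept. HWE is computed over *all*
genotyped individuals, the default of standard GWAS toolchains; an F2 of a
full-sib mating deviates from HWE by design, but the 10⁻⁶ threshold is
lenient enough that only genotyping artifacts (e.g. (25, 0, 22) genotype
counts with no hets at all) are removed. The choice of cohort for the HWE
test is exposed to the caller via subsetting the genotype matrix.

`segregation_test()` is the Pearson goodness-of-fit of (unaffected,
affected) F2 counts against 3:1, again without continuity correction so the
statistic reproduces the textbook closed form.
`differential_missingness_test()` runs a per-marker Fisher exact test on
the missing × phenotype 2×2 table (via `stats::fisher.test`); its p-values
are discrete and conservative, so calibration checks assert bounded
rejection rates rather than uniformity.

## Founder-origin inference

Origins are inferred in two passes:

1. **Trio-logic phasing of each F1.** At each marker the founder genotypes
   determine, where possible, which allele the F1 inherited from which
   line, yielding P(B allele | line-A origin) and P(B | line-B origin) per
   F1 parent. Unresolvable sites (both founders heterozygous or missing)
   fall back to founder allele frequencies, and conflicts fall back to 0.5.
2. **Viterbi smoothing per F2.** The hidden state is the ordered origin
   pair of the two gametes (4 states). Transitions between adjacent markers
   use Haldane recombination fractions; emissions convolve the two gametes'
   allele probabilities and pass them through a symmetric genotyping-error
   kernel (default assumed error 0.005 — deliberately slightly above the
   generator's 0.002 so the smoother is mildly conservative). Missing
   genotypes emit nothing. Ties in the Viterbi argmax break toward the
   first state index, making the output deterministic.

If a chromosome carries no informative marker, or an individual has no
genotypes on it, origins are labelled `unknown`. Because both F1 parents of
a full-sib mating have identical founder-labelled structure, the two states
with origin dosage 1 (AB and BA) have identical emissions; the paternal /
maternal attribution within dosage-1 segments is therefore arbitrary, and
accuracy is assessed (and used downstream) at the level of origin *dosage*.

The association scan regresses phenotype on line-B origin dosage and
reports the OLS slope *t* (equivalently the trend test); a Welch two-group
variant (homozygous-A vs homozygous-B origin classes) is available because
the grouping of the haplotype-based test this replaces is ambiguous.
Markers with unknown origins in more than half the F2s, or with constant
dosage, are skipped and excluded from the Bonferroni count N; the
genome-wide threshold is exactly α/N.

## IBD scan and breakpoint refinement

`shared_homozygosity_scan()` finds maximal runs of markers at which every
affected is homozygous for one identical allele. Missing genotypes are
compatible (a strict mode exists because chip studies differ on this);
`max_discordant` allows a stated number of deviating animals per marker.
The package default for the *operation* is 0 (exact sharing); the pipeline
wrapper uses 1, a decision made from the error model before any end-to-end
run: with genotyping error rate e and n affected animals, a fraction
≈ n·e of markers inside the true IBD segment (~3.5% at e = 0.002, n = 18)
shows one discordant animal by error alone, which would fragment the
segment roughly every 28 markers; two simultaneous errors at one marker
(~6×10⁻⁴) are rare enough to break runs only where real recombination
does. Tie-breaking is explicit: intervals sort by marker count, and
downstream takes the longest in bp, then the lowest coordinate.

Refinement excludes subintervals that cannot contain the locus and returns
the maximal remaining run, with boundaries at the outermost *kept* markers
(the conservative inner-bound convention, since true breakpoints fall
between markers). Two evidence rules are implemented:

* **Confirmed carriers** (the operation's default): a known heterozygous
  carrier shows zero copies of the disease haplotype exactly where its
  disease-line chromosome is recombinant, excluding that subinterval. This
  rule is *only* sound for animals whose carrier status is externally
  established — for an unconfirmed unaffected animal, a homozygous-normal
  segment is equally consistent with simply not carrying the disease
  allele, and excluding on it can discard the true locus.
* **Phenotype contradiction** (used by `map_recessive_locus()` over all
  unaffected F2s): an unaffected animal homozygous for the disease-line
  *origin* over a subinterval would be affected if the locus were there.
  This needs no carrier knowledge. Because a recombination breakpoint is
  localized only to the gap between informative markers, the outermost
  markers of an inferred homozygous-origin block may belong to the
  neighbouring state, so only the block *interior* is excluded.

Both rules require `min_confirm` consecutive exclusion markers per animal
(pipeline default 2) so that an isolated miscalled genotype — expected
roughly twice per interval at the study's error rate — cannot truncate the
interval. `min_confirm = 1` reproduces the literal marker-by-marker rule.

## Variant-site QC and the exclusion cascade

`variant_site_qc()` applies, in order: depth within [6, 70] (inclusive),
spacing ≥ 5 bp to the immediately preceding variant in the sorted input
(whether or not that variant itself survived), and quality ≥ 20. The
simulator draws site depths Poisson(35): this is the post-deduplication
unique-read depth the site filters see, chosen so that the depth window —
which tops out at 70 — retains typical sites; raw sequencing coverage of a
capture experiment is several-fold higher but is not the quantity being
filtered.

`mendelian_recessive_filter()` implements the four-step cascade. Step 2
removes variants homozygous-*alt* in a parent (an unaffected obligate
carrier cannot be a mutant homozygote); step 3 then enforces the recessive
model (affected homozygous-alt, alt present in both parents), which also
catches homozygous-*ref* parents of a homozygous-alt child. Splitting the
two parental-homozygote cases this way gives each step a distinct role
while producing exactly the same survivor set as reading step 2 as "either
allele"; survivors are always homozygous-alt in the affected,
heterozygous in both parents, and protein-altering. A genotype that is
missing at the step that needs it removes the variant at that step —
conservative and logged, never a silent pass. Functional class is taken
from the input annotation (`INFO CLASS`); effect prediction engines are out
of scope.

`population_screen()` removes variants whose alt allele segregates in the
panel at frequency > 0.1; frequencies in (0, 0.1] are retained but flagged
ambiguous, since a rare panel allele neither clears nor condemns a
candidate. The cascade order (site QC → Mendelian → panel) is the pipeline
default; the screen is an independent operation and can be applied at any
point.

`insilico_rflp()` cuts at every site occurrence on either strand at the
enzyme's offset; a palindromic site matches both strands at the same start,
which is a single binding event and a single fragment boundary. Fragment
lengths always sum to the sequence length. `predict_truncation()` applies a
delins edit in CDS coordinates and translates (standard code) to the first
stop; the termination residue is the codon index of that stop.

## Digital expression

RPKM uses the constant 10⁹ (reads per *kilobase* per *million*). The
equal-expression test is the exact Poisson two-library law

p(y|x) = (N₂/N₁)ʸ (x+y)! / (x!·y!·(1+N₂/N₁)^(x+y+1)),

computed in log space via `lgamma` (overflow is a defect, not an error
path). The two-sided p doubles the smaller of P(Y ≤ y|x) and P(Y ≥ y|x),
both summed over the same law; a "minlike" convention (sum of all outcomes
no more likely than the observed) is config-exposed because the two-sided
convention of the original formulation is undocumented. Note that the test
*conditions on the first sample's count*: swapping the samples conditions
on the other margin and yields a different, equally valid p-value — they
coincide only for equal library totals at symmetric counts, so no exact
swap-symmetry is asserted.

DEG calls require q ≤ 0.001 (Benjamini–Hochberg, via `stats::p.adjust`)
*and* |log₂(RPKM_wt/RPKM_mut)| ≥ 1, both boundaries inclusive. Genes with
zero counts in both libraries are excluded before testing (no evidence
either way); a zero in exactly one library gives an infinite log2 ratio
that passes the fold criterion by convention — the p-value still decides
significance. Direction labels are relative to the mutant sample. The
simulator's defaults (2,000 genes, two libraries of 10⁶ reads, lognormal
expression, lengths 200–10,000 bp) keep the acceptance suite inside its
runtime budget while giving median per-gene counts in the hundreds —
"adequate depth" for the planted |log₂fc| = 2 sensitivity check. Counts are
Poisson because that is the distributional assumption of the test itself;
a negative-binomial option exists solely for misspecification experiments,
and passing Poisson-based tests says nothing about biological-replicate
overdispersion (which this two-pool design cannot estimate).

## Prioritization and the human variant filter

`top_fraction_consensus()` takes the top ⌈fraction·n⌉ of each list
(per-list length, since external prioritizers rank different subsets) and
intersects. Ceiling is used so that no floor/ceiling convention would
include a gene this one excludes. Ranked lists sort by score with a stable
radix sort, so tied scores keep their input order — reproducible and
documented rather than arbitrary.

`human_variant_filter()` retains variants with damaging score ≥ 0.85 (the
conventional "probably damaging" band of the scoring tool, exposed because
only the category, not the cutoff, is standard), conservation fraction ≥ 1
("fully conserved", with a relaxed option), and absence from every required
population database. Scores and database flags are inputs; querying live
services is out of scope.

## Numerical and interface conventions

* Coordinates are 1-based and closed everywhere; BED export converts to
  0-based half-open on write. Interval length is (end − start + 1)/10⁶ Mb,
  so a single base spans 10⁻⁶ Mb.
* Genotypes are B-allele dosages in {0, 1, 2} with NA for missing; allele B
  is the alphabetically later allele, making the coding independent of file
  order. PED "0 0" (and half-missing pairs) read as missing.
* Filter traces conserve counts (in = removed + out) at every step, and
  every simulator and every pipeline stage is deterministic given its seed
  and inputs.
* Problem sizes used by the validation suite: 25 crosses of 75 F2 × 1,000
  markers for locus recovery, 25 trio simulations of ~300 background
  variants for the cascade, 20 null and 5 planted count simulations of
  2,000 genes for the DEG characteristics. These sizes were chosen as the
  smallest at which the binomial noise of the pass criteria (e.g. ≥ 24/25
  recovery) is comfortably resolved.

## Known limitations

* Founder lines are fully inbred in simulation; founder heterozygosity and
  within-line disease-haplotype diversity are not modelled.
* Origin inference assumes a single F1×F1 full-sib mating; multi-family
  designs and kinship corrections are out of scope.
* The expression stage models Poisson sampling of two pooled libraries —
  no replicate-level dispersion estimation.
* The human variant filter consumes externally computed damaging scores and
  database flags; it does not compute them.
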