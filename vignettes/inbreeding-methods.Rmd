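---
title: "Estimating and comparing pedigree and genomic inbreeding with autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing pedigree and genomic inbreeding with autozyg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The problem

In small closed populations — rare horse breeds are the canonical case —
inbreeding must be monitored from whatever data exist: studbook pedigrees
of uneven depth, and SNP-array genotypes for a subset of animals. The
pedigree coefficient F_PED is an *expectation* over the recorded ancestry;
genomic coefficients measure *realised* autozygosity, and segment-based
ones additionally date it, because identity-by-descent tracts are broken
by recombination at roughly one crossover per Morgan per meiosis, so a
tract inherited from a common ancestor g generations back has expected
length about 1/(2g) Morgan. `autozyg` implements the five coefficients
such comparisons use, the quality control around them, the comparison
statistics, and a simulator that knows the truth.

## Models and procedures

### Pedigree: validation, tracing, A-matrix, F_PED

`validate_pedigree()` applies the usual studbook checks (duplicate ids,
invalid sex codes, self-parentage, identical sire and dam, parental-sex
mismatch, implausible parental age, unrealistic or missing birth dates),
severing offending parent links rather than deleting animals, and logging
every action. Parental-sex mismatches are flagged but the link kept: the
record is internally consistent and the error may lie in the sex field.
The plausible parental-age window defaults to 2–30 years (configurable),
a horse-breeding convention. Any remaining cycle is broken at the cycle
member appearing last in the input, input order standing in for recency
when birth dates are absent.

`trace_ancestors()` bounds the pedigree at a five-generation horizon
before the A-matrix is built. The horizon is applied by tracing, not by
post-hoc filtering, so F_PED values are comparable across animals; the
matching completeness filter in `f_ped()` reports animals with fewer than
five *complete* generations as missing rather than biasing them toward
zero. The A-matrix uses the tabular recursion with unknown parents as
unrelated, non-inbred founders; this is exact, so tests can compare it to
Monte-Carlo gene dropping.

### Genotype QC

`qc_cascade()` applies, in one documented pass: autosomes only → SNP call
rate ≥ 0.90 → HWE exact p ≥ 1e-6 → individual missingness ≤ 0.10 → MAF ≥
0.01. The order follows the sentence order in which such filters are
conventionally reported; per-SNP statistics are not recomputed after
individual removal, so the cascade is idempotent and auditable. The HWE
test is the exact conditional test (enumeration of heterozygote counts
given allele counts), not the chi-square approximation, and not mid-p.
The duplicate/relative screen (`ibs_screen()`) uses the method-of-moments
IBS decomposition with falling-factorial allele-count corrections —
without them PI_HAT is visibly biased in cohorts of tens of animals — and
both it and the heterozygosity-outlier screen are report-only: the
analyst, not the package, decides about exclusions.

### Frequency-based estimators

F_HOM is `(O_HOM − E_HOM)/(m − E_HOM)` with the expectation summed over
each individual's non-missing loci. The denominator's published form is
ambiguous in places; this reading is the standard method-of-moments
estimator and is what the usual tooling computes. F_GRM is `G_ii − 1` on
the VanRaden method-I GRM; missing genotypes are set to their frequency
expectation (zero after centring). Both can legitimately be negative —
they measure deviation from the allele frequencies used, which by default
are in-sample. Supplying founder/base-population frequencies (as the
simulator's truth makes possible) removes that reference-point effect;
this matters for unbiasedness tests but is not available for real data.
The GRM deliberately shares the one QC-filtered marker set with all other
estimators — no extra MAF filter — so differences between coefficients
reflect the estimators, not their inputs.

### ROH scan

The scan mirrors the sliding-window convention of SNP-array tooling:
50-SNP windows, at most 1 heterozygous and 5 missing calls per window,
per-SNP hit rate ≥ 5%, segments kept if ≥ 1 Mb, ≥ 15 SNPs and ≤ 200 kb per
SNP, split at gaps > 1 Mb. Only fully contained windows are formed, and
the hit-rate denominator is the number of windows actually covering a SNP
(SNPs near chromosome ends are covered by fewer). Segment span is
`end − start + 1` over the bounding SNPs; at exact class-boundary ties the
segment goes to the upper class, matching the half-open printed notation
(2 Mb exactly is "2–<4 Mb"). There is no segment-level heterozygote cap
beyond what window flags admit. All eight constants are fields of
`roh_params()`; F_ROH divides by an autosomal genome length of 2410 Mb by
default (the equine assembly), which simulations override with their true
genome size.

### HBD hidden Markov model

`hbd_model()` defines K = 10 classes with rates R_k = 2^k, k = 1..10;
classes R2..R512 are HBD and the R1024 class is non-HBD. The literature
this mirrors is internally inconsistent about whether the last HBD class
is R512 or R1024 and about the age grouping, so both groupings ship as
presets (`"methods"`: very recent R2–R8, recent R16–R64, intermediate
R128–R256, ancient R512; `"results"`: very recent R2–R4, intermediate
R8–R32, ancient R64+), and the class structure is configurable. Between
adjacent markers at genetic distance d the chain stays in class k with
probability exp(−R_k d); otherwise the segment ends and the next class is
drawn from the mixing weights (self-transitions allowed). HBD classes emit
a copied allele read twice with error ε: P(hom-ref) = p(1−ε) + p²ε,
P(het) = 2pqε; the non-HBD class emits Hardy–Weinberg probabilities;
missing genotypes emit 1 in every state. ε defaults to 0.001. Genetic
distances come from physical positions at 1 cM/Mb unless a genetic map is
supplied. EM estimates the mixing weights only (rates are the fixed class
definitions); the pipeline fits per individual, the standard usage. F_HBD
is the marker-averaged posterior over HBD classes — not Viterbi coverage —
with Viterbi reserved for segment tables, mirroring the two purposes'
usual split. The forward–backward and Viterbi cores are in C++; the
transition structure admits O(K) per-locus updates.

### Comparison layer

`describe()`, `shapiro_wilk()`, `spearman()` and `regress_fped()` wrap the
base-R routines with the reporting conventions fixed: sample SD,
pairwise-complete observations, average ranks with the t-approximation
p-value, OLS with slope p-values, residual/fitted vectors exported for
visual diagnostics. No multiple-testing correction is applied — the
comparison layer reports, it does not gatekeep. Class contributions are
per-individual shares of each class in the total coefficient, averaged
over individuals; individuals with zero total are excluded (and counted)
rather than contributing 0/0.

## The simulator and what passing tests mean

`simulate_pedigree()` + `gene_drop()` create genotypes whose autozygosity
is known exactly: founder haplotypes carry unique labels, meioses place
crossovers as a Poisson process (Haldane, no interference), and a tract is
autozygous when both haplotypes carry the same founder label — so
IBS-by-chance is excluded from truth by construction, which is exactly the
quantity the estimators target. Genotyping error (one allele flipped with
rate ε) and missingness are applied after truth is recorded. Each tract's
generations-to-coalescence g is found by climbing both haplotype
transmission paths to their first shared haplotype, averaging the two path
lengths; it is evaluated at the tract midpoint (within a tract the
coalescence depth can in principle change while the founder label does
not — a rare event at these pedigree depths that we accept for summary
purposes).

The default study cohort — chosen once as the validation condition — has
200 genotyped individuals: 50 outbred founder-pair offspring, 75 offspring
of planted full-sib matings bred from fresh unrelated founders (so their
expected autozygosity is exactly 0.25, coalescing two generations back),
and 75 individuals from a 10-generation closed line of 10 founders and 20
animals per generation, whose autozygosity is older and spread over
depths. The genome is 10 chromosomes × 1 Morgan (100 Mb) × 2,000 SNPs on a
regular 50 kb grid; founder reference-allele frequencies are uniform on
[0.05, 0.5]; ε = 0.001 and 0.5% missingness. Unit and acceptance tests use
smaller versions of the same designs (fewer chromosomes, hundreds of SNPs)
to keep the default suite fast.

What the simulator does *not* emulate: linkage-disequilibrium structure in
founders (founder alleles are drawn independently per locus), realistic
equine recombination maps (constant 1 cM/Mb), selection, mutation, array
ascertainment bias, and clustered genotyping error. Tests passing on these
data show the estimators recover autozygosity generated by recombination
and finite pedigrees; they do not certify behaviour under founder LD or
map heterogeneity, where window and rate parameters interact with local
SNP density.

## Numerical choices

Scaled forward–backward recursions guard against underflow, and posteriors
are renormalised per locus; EM stops when the log-likelihood gain drops
below 1e-6 (default) or at the iteration cap, and a mixing weight
collapsing to zero is floored at 1e-12 and renormalised — with
per-individual fits on ~20K markers several empty classes are the norm,
so `run_hbd()` treats the floor as routine. The HWE test sums enumerated
probabilities with a 1 + 1e-12 relative tie tolerance so ties at the
observed configuration's probability are included deterministically. The
pipeline writes numeric tables through a fixed 10-significant-digit
formatter, which is what makes rerun outputs byte-identical. Degenerate
inputs error early and descriptively: empty marker sets after QC,
non-topologically-ordered pedigrees, zero GRM denominators, frequencies
at 0 or 1 reaching the HBD emissions.

## Orchestration

`run_pipeline()` drives simulate-or-read → pedigree QC → genotype QC →
the five estimators → the comparison tables, from a `run_config()` (or a
YAML file via `read_run_config()`), writes every table plus a
resolved-config snapshot beside the outputs, and draws all randomness from
the single seed. Stage failures abort with the stage name and the
artifacts already written. The package deliberately exposes this as R
functions plus config rather than a shell entry point: its users script in
R, as the surrounding analysis ecosystem does.

## Known limitations

F_PED inherits every limitation of the recorded pedigree; the
five-generation horizon is a comparability device, not a claim that deeper
ancestry is irrelevant. The ROH scan's parameters are tuned to
medium-density arrays (~1 SNP / 50 kb); at much sparser spacing the
density cap suppresses detection entirely. Per-individual EM with 10
classes on desk-scale genomes is weakly identified — class-wise F_HBD is
more stable than the fitted weights themselves. The IBS screen assumes
approximately unrelated cohort frequencies; in a deeply inbred cohort
PI_HAT is a screening statistic, not an estimate of kinship. And the
comparison layer's regressions are descriptive concordance measures, not
causal models.
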