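---
title: "Forensic matching and compliance auditing for skeleton export quotas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic matching and compliance auditing for skeleton export quotas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonematch)
library(dplyr)
```

## The problem

Quota-regulated exports of captive-bred lion skeletons are monitored by a
mixed-methods compliance procedure: every skeleton is tagged and sampled at
its source farm, and a fraction of every consignment is re-sampled and
re-weighed at the port of exit. Three questions must be answered for each
spot-checked skeleton:

1. **Is it a lion?** Tigers and lion–tiger hybrids may not enter the trade.
2. **Is it the same individual that was tagged at the farm?** A port sample
   whose DNA profile does not match its tag indicates pooled skeletons
   (bone mixing, "Type I") or mislabelling / tag-swapping ("Type II").
3. **Does its weight profile behave?** A port weight more than 0.6 kg above
   the farm weight triggers investigation.

`bonematch` implements this full analysis chain — species assignment from
diagnostic mtDNA SNPs with a supervised nuclear admixture estimator,
microsatellite marker validation, Queller–Goodnight relatedness matching
with generalized-ESD significance, duplicate detection, weight audits and
consignment regressions — together with a synthetic cohort generator that
emulates the study conditions, because the underlying casework genotypes
and weights are confidential and not deposited. All validation is therefore
property-based: exact algebraic identities, independent oracles, and exact
recovery of planted anomalies.

## The synthetic cohort generator

`make_species_panels()` builds one allele-frequency table per species over
a shared locus set (default 18 loci, 5–11 alleles per locus, the dimensions
of the validated marker panel). Frequencies are symmetric Dirichlet(1, …)
draws. The `divergence` parameter sets the fraction of each locus's alleles
private to each species; its default 0.35 is calibrated so that roughly
70% of the union of alleles is species-private, matching the observed
ratio in lion/tiger reference panels (108 private alleles of 149). With
`divergence = 0` both species share one identical table — a degenerate
no-information case used to test that the admixture estimator flags flat
likelihoods.

`simulate_cohort()` draws an annual quota (default 800 skeletons across
10 farms, 7 traders, consignments of 30–60) under Hardy–Weinberg
proportions, spot-checks `ceiling(0.125 × size)` skeletons per consignment
(at least one per batch), and plants the requested anomalies after truth
assignment:

- `non_target_species` — a tiger genotype and tiger mtDNA alleles under a
  farm tag; withheld from port sampling, emulating interception;
- `reassigned_tag` — a port sample carrying the declared tag but the
  genotype of a different (clean, same-facility) farm individual;
- `pooled_no_match` — a port genotype from an individual absent from all
  farm samples;
- `duplicate_individual` — two farm tags sharing one genotype.

Genotyping error (per-allele-copy dropout, per-locus false alleles) is
applied last and defaults to zero so that matching on clean cohorts is
exact. The generator is seeded and byte-reproducible.

`simulate_weights()` gives each skeleton a truncated-normal farm weight
(mean 16.6 kg, SD 5.5 kg — the 2018 farm inspection profile — floored at
5 kg, just under the lightest observed skeleton), multiplies by a
desiccation factor (default 0.88; skeletons are cleaned and dry out between
inspections, and the reported reduction is on the order of 12%, while the
published paired means imply closer to 15% — the factor is deliberately a
parameter, not a constant) and adds packaging (default 1.1 kg, the
published single-trader mean). What the generator does **not** emulate:
relatives in the cohort (no pedigree structure — the analysis only needs
self vs unrelated), null alleles, inter-laboratory scoring differences, and
scale miscalibration. Passing tests therefore demonstrate correctness of
the algorithms under the stated statistical model, not robustness to every
artefact of real casework data.

## Species assignment

The first pass is a consensus over three diagnostic mtDNA loci (control
region, 12S, 16S) carrying fixed differences between lion and tiger:
unanimity among determined loci gives a species call, any disagreement is
`INCONCLUSIVE` and triggers nuclear follow-up.

The nuclear estimator replaces an unsupervised MCMC clustering with a
supervised maximum-likelihood admixture fit: with reference panels for both
species available by construction (20 individuals each, as in the
casework), each allele copy's frequency is modelled as
$q\,p_{\mathrm{lion}} + (1-q)\,p_{\mathrm{tiger}}$ and the multilocus
log-likelihood is maximized over a grid $q \in [0,1]$ with step 0.001 —
deterministic, desk-scale, and exactly symmetric under swapping the panels
($q \mapsto 1-q$). Frequencies of alleles unseen in a panel are floored at
$\varepsilon = 1/(2n_{\mathrm{ref}}+1)$, which avoids degenerate
log-likelihoods while still penalizing foreign alleles; the mixture is not
renormalized after flooring, a deliberate simplification that is
conservative for both species symmetrically.

Final calls combine the evidence: the mtDNA call stands when the nuclear
genome agrees; a sample carrying private alleles of both species, a
membership estimate inside the hybrid band $[0.05, 0.95]$, or a
nuclear–mtDNA conflict (mtDNA is maternal only) escalates to
`HYBRID_SUSPECT` — an investigation trigger, not a definitive call. At the
default study conditions roughly 0.5% of pure individuals escalate this
way; none are assigned the wrong species in 2,000 simulated pures, and F1
hybrids sit at $q \approx 0.5$ and are flagged reliably.

## Marker validation

Per-locus statistics follow the standard definitions over allele
frequencies $p_i$ (with $S_k = \sum_i p_i^k$): $A_e = 1/S_2$,
$H_E = 1 - S_2$, $\mathrm{PIC} = 1 - S_2 - (S_2^2 - S_4)$, and the
probability of identity $\mathrm{PID} = 2S_2^2 - S_4$, multiplying across
independent loci. $H_E$ is deliberately uncorrected so the identity
$\mathrm{PIC} \le H_E$ holds exactly; the $2n/(2n-1)$ unbiased form is an
option. The null-allele estimate is the Chakraborty heterozygote-deficit
form $(H_E - H_O)/(H_E + H_O)$, chosen because the casework software's
estimator is not reproducible from its published description.

Exclusion probabilities Pe1 (one parent known) and Pe2 (both parents
known) are computed by exact enumeration over parent–offspring genotype
configurations at the given frequencies, rather than from any of the
several non-equivalent textbook closed forms; the test suite checks the
enumeration against an independent brute-force oracle to $10^{-12}$.

The Hardy–Weinberg test is the exact conditional test: the probability,
under the Levene distribution of genotype tables given allele counts, of
tables no more probable than the observed one. Tables are enumerated
exhaustively below a bound of $10^6$ tables (with a closed biallelic
branch); larger problems fall back to seeded Monte-Carlo pairing of allele
copies with $10^5$ replicates by default. Linkage disequilibrium uses a
G-statistic on the two-locus genotype table with a permutation null.
Genotype accumulation curves resample locus subsets and count distinct
multilocus profiles, treating missing loci as wildcards (merged by
single-linkage, since wildcard indistinguishability is not transitive).

## Matching

Pairwise relatedness is the Queller–Goodnight estimator in its
ratio-of-sums multilocus form, symmetrized over the two directions. The
ratio of sums (rather than a mean of per-locus ratios) avoids the
degenerate zero denominator of a heterozygote whose two alleles exhaust
the locus's frequency mass; loci where both directional denominators
vanish are skipped. For locus-identical genotypes the numerator equals the
denominator algebraically, so identity pairs score exactly 1 under any
frequency table — the anchor property of the whole matching procedure.
Reference frequencies come from the full farm cohort of the year, without
dyad exclusion: stable at n ≈ 800 and standard practice.

Each port sample's relatedness to every farm sample of its year forms the
null set for a generalized ESD (Rosner) outlier test at α = 0.05 with
`k_max = 5` — a port sample can have at most a handful of near-identical
relatives in a captive cohort. The ESD test is two-sided, but only flags
above the cohort mean can be matches; a flagged same-tag sample attaining
the maximum relatedness is a `MATCH`, another flagged sample with
r ≥ 0.9 (`r_identity_floor`, separating "same individual" from full sibs
near r = 0.5) is a reassignment (same-farm or cross-farm, with the matched
facility recorded), anything else is `NO_MATCH`. The null-set composition,
`k_max` and the floor are not fixed by any published description of the
procedure; all three are explicit, configurable parameters, and the
alternative pooled-null design is noted as such.

Duplicate farm tags are found by exact profile hashing (tolerance 0) or a
pairwise scan allowing a configurable number of disagreeing loci to absorb
dropout; the panel's cumulative PID (order $10^{-12}$ at 18 loci)
quantifies how unlikely a chance collision is (n² · PID ≪ 1 at n = 800).
Detected anomalies map onto the compliance taxonomy: no-match port samples
and duplicate farm tags are pooling candidates (Type I), reassignments are
mislabelling candidates (Type II), and non-target species are counted
separately; one sample can carry several applicable classes, and the
ledger records all of them rather than guessing a priority.

## Weight audit

The paired audit flags `port nett − farm > 0.6 kg` with packaging
subtracted where recorded and a configured trader mean otherwise; the
threshold applies to nett weight (the published rule does not say
nett or gross — this is a declared choice). No multiple-testing correction
is applied: a flag triggers investigation, not a statistical claim.
Consignment regressions fit skeleton count on nett consignment weight by
OLS per year group, with prediction intervals for auditing unopened
consignments and an interaction test for slope drift across years; count
is the response (matching how the relationship is used), and a numerical
note: because consignment weight is the noisy variable, the fitted slope
carries a small attenuation (≈1.4% at the default weight profile) relative
to 1/mean-skeleton-weight, well inside a single fit's standard error.
Cross-year estimation warns, since slopes steepen as mean skeleton weight
rises year on year.

## Numerical and design notes

- All tie comparisons in the exact HWE test use a relative tolerance of
  1e-9 on log-probabilities; permutation p-values use the add-one form
  `(1 + hits)/(reps + 1)` and are never exactly zero.
- The admixture grid step (0.001) bounds the q resolution; the grid is
  symmetric so panel-swap symmetry is exact, and flat curves (identical
  panels) are flagged rather than returning an arbitrary argmax.
- Monomorphic loci report PID = 1, PIC = 0, undefined null-allele
  frequency as 0 with a flag, and no HWE p-value.
- Sample sizes in the test suite (cohorts of 120–800, 500-seed
  calibrations, 1,000-replicate assignment panels) were chosen as the
  smallest sizes at which the tested properties are statistically stable;
  the end-to-end recovery checks run the full 800-skeleton quota.
- Reports are rendered to JSON with fixed numeric precision and no
  timestamps, so a rerun on identical inputs and seed is byte-identical;
  file checksums (SHA-256) tie a report to its evidence files.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config_2018(seed = 1)
panels <- make_species_panels(seed = 1)
sim <- simulate_cohort(cfg, panels)
sim$lion_reference <- simulate_reference_genotypes(panels$lion, seed = 2)
sim$tiger_reference <- simulate_reference_genotypes(panels$tiger, seed = 3)
sim$weights <- simulate_weights(sim$consignments, port_tags = sim$port$tag, seed = 4)

report <- run_pipeline(sim, seed = 1)
report$ledger$summary
```

The ledger reproduces the planted truth: 3 farm anomalies of 800 (one
tiger, one duplicated pair) and 5 port anomalies of the ~104 spot-checked
samples (one reassigned tag, four pooled profiles).

## Known limitations

- Supervised assignment assumes the two reference panels bracket the
  ancestry space; backcross generations (F2, B1) are not discriminated
  from F1, only flagged as suspects.
- The ESD null set is each port sample's own relatedness distribution;
  with very small cohorts (tens of skeletons) the t-based critical values
  are conservative.
- Marker statistics assume locus independence for cumulative PID; linked
  loci would make the cumulative value optimistic, which is why the LD
  screen is part of panel validation.
- The weight model is multiplicative-desiccation plus additive packaging;
  real consignments also vary with processing style and storage time,
  which the generator does not model.
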