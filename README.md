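# bonematch

Forensic genotype matching and compliance auditing for quota-regulated
wildlife skeleton exports.

## The problem

Under a CITES Appendix II quota, captive-bred lion (*Panthera leo*)
skeletons may be exported only if each skeleton is the tagged, lion,
single individual it claims to be. Compliance is checked twice: every
skeleton is DNA-sampled and weighed at its source farm, and a random
12.5% of every consignment is re-sampled and re-weighed at the port of
exit. Three failure modes must be detected:

- **non-target species** — a tiger or hybrid skeleton entering under a
  lion tag;
- **pooled skeletons (Type I irregularity)** — a port bone whose DNA
  profile matches no farm skeleton, or two farm tags on one individual;
- **mislabelling / tag-swapping (Type II)** — a port profile matching a
  different tag's skeleton.

`bonematch` implements the complete analysis chain used for this kind of
audit, for forensic-genetics and compliance practitioners:

- **Species assignment**: consensus calls at three diagnostic mtDNA SNP
  loci (control region, 12S, 16S rRNA), species-private allele screening,
  and a supervised two-species admixture estimator — the multilocus
  genotype likelihood with per-allele frequency
  *q·p*<sub>lion</sub> + (1−*q*)·*p*<sub>tiger</sub>, maximized over a
  grid *q* ∈ [0,1] — with a hybrid band [0.05, 0.95] that escalates
  rather than calls.
- **Marker validation**: per-locus *A*<sub>n</sub>, *A*<sub>e</sub>,
  *H*<sub>O</sub>, *H*<sub>E</sub>, PIC, probability of identity
  PID = 2*S*₂² − *S*₄ (multiplied across loci), exclusion probabilities
  Pe1/Pe2 by exact enumeration, Chakraborty null-allele estimates, an
  exact conditional Hardy–Weinberg test (full table enumeration with a
  Monte-Carlo fallback), G-statistic LD permutation tests, and genotype
  accumulation curves.
- **Individual matching**: Queller–Goodnight pairwise relatedness
  (ratio-of-sums, symmetrized; identical profiles score exactly 1), with
  farm–port tag matches declared significant by a generalized extreme
  studentized deviate (Rosner) test on each port sample's relatedness
  distribution; duplicate-tag detection by profile hashing with a
  configurable mismatch tolerance.
- **Weight audit**: the paired >0.6 kg port-gain rule with packaging
  correction, paired t-tests, per-trader ANOVA, and year-stratified
  consignment regressions (count on nett weight) with prediction
  intervals.
- **Synthetic cohorts**: a seeded generator for reference panels, an
  800-skeleton quota with per-consignment spot-checks, planted anomalies
  of every class, genotyping error, and paired weight manifests with a
  ground-truth table — the validation substrate for the whole pipeline,
  since real casework genotypes are confidential.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for the main result types.

## Worked example

```r
library(bonematch)

cfg    <- cohort_config_2018(seed = 1)      # 800 skeletons, 12.5% spot-check,
                                            # 1 tiger + 1 reassigned + 4 pooled
                                            # + 1 duplicate pair planted
panels <- make_species_panels(seed = 1)     # 18 STR loci, 3 diagnostic SNPs
sim    <- simulate_cohort(cfg, panels)
sim$lion_reference  <- simulate_reference_genotypes(panels$lion,  seed = 2)
sim$tiger_reference <- simulate_reference_genotypes(panels$tiger, seed = 3)
sim$weights <- simulate_weights(sim$consignments,
                                port_tags = sim$port$tag, seed = 4)

report <- run_pipeline(sim, seed = 1)
report$ledger$summary
#> # A tibble: 2 × 6
#>   site   year n_anomalies n_total proportion label
#>   <chr> <int>       <int>   <int>      <dbl> <chr>
#> 1 FARM   2018           3     800    0.00375 3/800 (0.4%)
#> 2 PORT   2018           5     111    0.0450  5/111 (4.5%)
```

The ledger reads: 3 of 800 farm samples were anomalous (one tiger
skeleton, intercepted before export, and one pair of tags on a single
individual) and 5 of the 111 spot-checked port samples (one matching a
different same-farm tag — a mislabelling candidate — and four matching no
farm skeleton — pooling candidates). `render_report(report, "json")`
serializes the full audit; reruns on the same seed are byte-identical.

Individual pieces work standalone on your own tables:

```r
geno  <- read_genotype_table("farm_genotypes.csv")
stats <- marker_stats(geno)                  # per-locus validation TSV-ready
cumulative_pid(stats)                        # panel-wide PID
r     <- qg_matrix(port_geno, geno, allele_frequencies(geno))
esd_outliers(r[1, ], k_max = 5, alpha = 0.05)
```

A thin CLI wrapping the same functions lives at
`inst/scripts/bonematch` (subcommands `simulate`, `qc`, `assign`,
`match`, `audit`, `report`, `run-all`; exit status 2 signals detected
anomalies, for scripted enforcement).

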