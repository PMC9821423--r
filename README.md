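# tcrcohort

Cohort-level analysis of bulk CDR3β T-cell receptor repertoires with
prognosis association. The motivating problem: in cancers where malignant
effusions are routinely sampled (the package was built around ovarian
cancer ascites), does the T-cell repertoire — its diversity, the antigens
it recognizes, and the specificity groups its clones form — separate
patients who will respond durably to therapy from those who will not?

The package is written for computational immunologists and biostatisticians
and covers the full analysis path:

* **Repertoire metrics** — parse immunoSEQ-style clonotype TSVs; per-sample
  productive entropy $H = -\sum_i f_i \log_2 f_i$, clonality
  $1 - H/\log_2 R$, and max/top-10/top-100 productive frequencies.
* **Antigen annotation** — fuzzy (Levenshtein ≤ 1) and exact CDR3β matching
  against a McPAS/VDJdb-style reference table; chi-square goodness-of-fit
  category enrichment against the catalog background (pathogens 68%,
  cancer 16%, autoimmune 13%, allergy 2.7%, other 0.3%); per-condition
  Kruskal–Wallis + Dunn prognosis tests; per-group match frequencies;
  epitope-gene matrices; V/J usage.
* **Specificity groups** — GLIPH-style clustering: enriched interior k-mers
  (k ∈ {3,4}, fold ≥ 10, resampled p ≤ 0.001, min depth 3) plus
  equal-length Hamming-1 similarity; wildcard consensus patterns such as
  `CA%SL%NTEAFF`; ≥4-subject 2×2 chi-square cluster–prognosis association;
  neighbor-joining trees and position-frequency matrices per cluster.
* **Association networks** — patient similarity over shared
  prognosis-associated clusters at Pearson r ≥ 0.60, with label
  assortativity to quantify prognosis separation.
* **Survival** — Kaplan–Meier, log-rank, maximally-selected optimal
  cutpoints with permutation p-values, Cox PH (Breslow ties) with
  covariate adjustment.
* **Flow-marker clustering** — log2 / z-score normalization, average-linkage
  clustering on 1 − Pearson distance, gap-statistic model selection,
  CD8/Treg ratio.
* **Synthetic cohorts** — a fully seeded 47-patient generator (groups
  4/16/13/14) with planted motif clusters, planted database matches,
  group-dependent clone-frequency laws, flow shifts and survival hazards,
  plus a `truth_report()` scoring recovery against the planted truth.

## Worked example

```r
library(tcrcohort)

cohort <- generate_cohort(cohort_config(seed = 1))
stats  <- cohort_stats_table(cohort$repertoires)
head(stats[, c("patient_id", "productive_rearrangements",
               "productive_entropy_bits", "productive_clonality")], 4)
#>   patient_id productive_rearrangements productive_entropy_bits productive_clonality
#> 1        P01                        97                    4.75                0.281
#> 2        P02                        85                    4.31                0.328
#> 3        P03                        90                    4.49                0.309
#> 4        P04                        87                    4.35                0.325

lab <- cohort$labels$label[match(stats$patient_id, cohort$labels$patient_id)]
round(tapply(stats$productive_entropy_bits, lab, mean), 2)
#>     worst      poor      good excellent
#>      4.47      4.91      5.77      6.23
```

Repertoire diversity rises with prognosis: unfavorable groups are more
oligoclonal (steeper clone-frequency law), favorable groups more diverse.
Exact annotation against the bundled reference shows cancer-matched
peptides concentrated in the excellent group (frequency = distinct matched
occurrences per patient in the group):

```r
exact <- annotate_cohort(cohort$repertoires, cohort$reference_db, mode = "exact")
cancer_match_group_frequency(exact, cohort$labels)
#>       label n_patients n_matches frequency
#> 1     worst          4        12         3
#> 2      poor         16        48         3
#> 3      good         13        39         3
#> 4 excellent         14        84         6
```

Specificity-group clustering recovers the planted motif clusters with
wildcard patterns and prognosis associations:

```r
members  <- clustering_input(cohort$repertoires)
ref      <- generate_reference_repertoire(10000, seed = 101,
              exclude_motifs = cohort_config()$planted_motifs$motif)
clusters <- build_specificity_clusters(members,
              enriched_motifs(members$cdr3_aa, ref, seed = 101))
assoc    <- associate_clusters(clusters, cohort$labels, members)
subset(assoc, associated_with != "none",
       c(pattern, subjects, excellent_p, poorworst_p, associated_with))
#>             pattern subjects excellent_p poorworst_p associated_with
#> 5  CAS%%QWDH%%%EQFF       16    0.000393    2.73e-02       excellent
#> 10 CAS%%RMGY%%%EQFF       16    0.001582    4.71e-09      poor/worst
#> 11 CAS%%KYRT%%%EQFF       11    0.000025    2.30e-02       excellent
#> ...
```

Survival separates the prognosis sides as planted:

```r
clin <- cohort$clinical
fit <- cox_ph_fit(data.frame(time = clin$os_months, event = clin$os_event,
                             unfavorable = as.integer(lab %in% c("worst", "poor"))),
                  "unfavorable")
#> HR: 3.24   95% CI: 1.63 - 6.46   LR p: 0.00079
```

The whole analysis runs as one pipeline (stage outputs + a JSON report in
`outdir`), or from the command line via `inst/cli/tcrcohort.R` with
subcommands `simulate`, `run`, `report`:

```r
report <- run_pipeline(pipeline_config(synthetic = cohort_config(seed = 1),
                                       outdir = "run1", seed = 1))
```

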