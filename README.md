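# cnvconcord

Quality assessment and validation analysis for SNP-array derived copy
number variant (CNV) calls in case-control cohorts.

Array-based CNV calls are unreliable in ways that can manufacture
case-control association signals: reliability depends on the number of
supporting array markers, the segment size and the CNV type (deletions are
recovered far better than duplications), and batch effects between groups
of conjointly processed arrays confound frequencies. `cnvconcord` is for
statistical geneticists who need to interrogate an array-based CNV
association before believing it: it implements call filtering with an
"unfiltered" re-analysis mode, allelic association statistics, an
array-versus-MLPA match-score concordance framework, call-reliability
curves, and LD-region overlap screening — plus a fully seeded synthetic
cohort generator so the whole pipeline is testable without raw array data.

## The statistics at the core

For a 2x2 allele table (a, b; c, d) — risk / non-risk alleles in cases and
controls, each diploid individual contributing two alleles:

- allelic odds ratio θ̂ = ad/bc with the Woolf 95% interval
  exp(ln θ̂ ± 1.96 √(1/a + 1/b + 1/c + 1/d));
- Pearson χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)) on 1 df (uncorrected
  by default, Yates available);
- a two-sided exact test by full hypergeometric enumeration
  (minimum-likelihood convention).

CNV allele dosage is 2 − CN for deletions and min(CN − 2, 2) for
duplications. Cross-platform agreement uses the 0/1/2 **match score**
(2 = same type and copy number, 1 = same type only, 0 = otherwise), with
per-locus mean scores, discordance rates, a deletion-vs-duplication
Mann-Whitney comparison, and the cumulative mean-of-mean-scores reliability
curve over median segment size or marker count, summarised by Spearman's ρ.
LD regions around lead SNPs use EM-estimated r² from unphased genotypes
(threshold r² > 0.1).

## Worked example

The package ships the published cohort-level count tables of a psoriatic
arthritis CNV study (478 cases / 3798 controls) as a fixture;
`run_paper_fixture()` recomputes every statistic derivable from them:

```r
library(cnvconcord)
cat(run_paper_fixture()$rendered, sep = "\n")
#> == Frequent CNV association ==
#> UXS1  discovery            freq 90.1%/79.3%  OR 2.36 [1.90-2.94]  p 2.8e-15
#> UXS1  unfiltered discovery freq 66.4%/67.7%  OR 0.94 [0.82-1.09]  p 0.41
#> UXS1  replication          freq 66.5%/66.0%  OR 1.02 [0.81-1.29]  p 0.86
#> TRB   discovery            freq 81.2%/69.6%  OR 1.88 [1.59-2.23]  p 1.2e-13
#> TRB   replication          freq 51.1%/52.8%  OR 0.94 [0.82-1.07]  p 0.34
#> == Validated low-frequency CNVs (exact test) ==
#> CSMD1  deletion    1 vs 7 alleles  p 1.0
#> IL12B  duplication 2 vs 3 alleles  p 0.1
#> RYR2   deletion    2 vs 12 alleles  p 0.7
#> == Validation by CNV type ==
#> deletion    8 of 11 validated (73%)
#> duplication 2 of 17 validated (12%)
#> == Array-vs-MLPA discordance ==
#> UXS1  MLPA subset  50 of 135 (37.0%)
#> TRB   MLPA subset  48 of 135 (35.6%)
#> TRB   full cohort  157 of 446 (35.2%)
```

Reading this: the UXS1 deletion looks strongly associated in the filtered
discovery analysis (OR 2.36), but once sub-threshold calls are re-admitted
("unfiltered discovery") the case frequency drops from 90.1% to 66.4% and
the signal vanishes — the association was an artefact of the size filter
interacting with fragmented calls. A third of array genotypes disagree
with MLPA at both frequent loci, and deletions validate at 73% versus 12%
for duplications.

Simulated cohorts run the same stages end to end:

```r
loci <- list(locus_spec("DEL_A", "deletion", q_control = 0.3,
                        odds_ratio = 2, marker_mean = 20))
res <- run_pipeline(loci, n_case = 150, n_control = 300, seed = 11)
res$association
res$concordance
```

See `vignettes/cnv-concordance-methods.Rmd` for the model, its assumptions
and the design choices.

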