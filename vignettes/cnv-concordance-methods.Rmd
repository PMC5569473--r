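---
title: "Methods: CNV association, cross-platform concordance and call reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV association, cross-platform concordance and call reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconcord)
```

## The problem

SNP-array based copy number variant (CNV) calling is error-prone: segmental
calls depend on the number of supporting array markers, the segment size,
the CNV type (deletions are recovered more reliably than duplications), and
on systematic differences between groups of conjointly processed arrays
(batch effects). A case-control association signal at a CNV can therefore
be a genotyping artefact rather than biology. `cnvconcord` implements the
quality-assessment workflow used to interrogate such signals:

1. **Call filtering** — retain calls supported by at least 5 markers and
   spanning at least 5000 bp (both thresholds inclusive and configurable),
   with an "unfiltered" mode that re-admits sub-threshold calls to test
   whether a filter-induced ascertainment distortion created the signal.
2. **Allelic association** — odds ratio with Woolf confidence interval,
   Pearson chi-squared, and an exact hypergeometric test on 2x2 allele
   tables.
3. **Cross-platform concordance** — a per-individual 0/1/2 match score
   between array-derived and MLPA-derived copy numbers, aggregated into
   per-locus mean scores, discordance rates and validation calls.
4. **Reliability curves** — the cumulative mean-of-mean-match-scores as a
   function of median segment size or median marker count, summarised by a
   Spearman rank correlation.
5. **LD-region screening** — r² based regions around lead associated SNPs,
   screened for overlapping CNVs.

A seeded synthetic-cohort generator stands in for raw array data, which are
typically not shareable.

## Copy-number model and allele dosage

A locus is either a deletion locus (copy numbers 0, 1, 2) or a duplication
locus (2, 3, 4; a biallelic duplication-allele model — states above CN 4
are clamped to dosage 2 with a warning). The CNV **allele dosage** of an
individual is `2 - CN` for deletions and `min(CN - 2, 2)` for duplications,
so each diploid individual contributes two alleles and a group of n
individuals contributes 2n. Individuals absent from a locus's genotype map
are reference (CN 2): segmentation algorithms only emit non-reference
segments, so cohort denominators always come from the sample sheet, never
from the call file.

All intervals are stored 0-based half-open; converters to and from the
1-based inclusive convention used in print are provided
(`onebased_to_halfopen()`).

## Association statistics

For an allele table (a, b; c, d) — risk/non-risk alleles in cases and
controls — the package computes:

* **Odds ratio** \(\hat\theta = ad/bc\) with the Woolf interval
  \(\exp(\ln\hat\theta \pm z\sqrt{1/a + 1/b + 1/c + 1/d})\). Zero cells
  leave the estimate undefined by default; the Haldane–Anscombe +0.5 rule
  is available for the estimate and interval only, never for tests.
* **Pearson chi-squared** \(N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))\)
  on 1 df, uncorrected by default. Uncorrected Pearson reproduces the
  published discovery-stage p-values of the cohorts this workflow was
  developed on (2.84e-15 and 1.22e-13) while the Yates-corrected variant
  does not; the Yates flag is provided because one published
  replication-stage p-value (0.44) is only reproduced by the corrected
  variant, and one (0.94) by neither — the variant used for those rows was
  not recorded at source, so both are reported side by side by
  `fixture_association_results()` rather than resolved.
* **Exact test** by full enumeration of the hypergeometric support, summing
  the probabilities of all tables no more probable than the observed one
  (minimum-likelihood convention, relative tolerance 1e-7). Tables with a
  zero margin have p = 1.

```{r association}
fixture_association_results()[, c("locus", "analysis", "or", "ci_low",
                                  "ci_high", "chi2_p")]
```

## Match score and validation

The match score compares an array-derived and an MLPA-derived copy number
for one individual: **2** if identical; **1** if both are non-reference of
the same type (deletion or duplication) but differ in copy number; **0**
otherwise. Two design points deserve note:

* Reference-vs-reference (2, 2) scores 2. The score is defined for CNV
  genotypes, and extending "same type and copy number" to the reference
  state is the only completion consistent with counting confirmed
  wild-type states as concordant.
* A locus is **validated** when MLPA confirms at least one non-reference
  genotype of the locus's type (`min_confirmed` is configurable); MLPA
  finding only reference states at a called CNV locus means no copy-number
  variability could be confirmed.

The deletion-vs-duplication comparison uses a two-sided Mann-Whitney
rank-sum test on the per-locus mean match scores. Scores live on {0, 1, 2},
so ties are guaranteed: the default is the tie-corrected normal
approximation (no continuity correction); when both groups have at most 12
loci the exact permutation distribution over the observed values is
enumerated instead, which handles ties exactly and reduces to the classical
exact distribution when tie-free. A pooled per-individual mode is provided
because it is genuinely ambiguous whether per-locus means or pooled scores
are the better unit; per-locus means are the default since the summary of
interest is locus-level validation.

## Reliability curve

For each locus the median segment size and median marker count of its calls
are computed (average-of-middle-two for even counts; the convention is
stated because it is not standardised). With per-locus mean scores
\(m_i\) and ordering key \(k_i\), the curve value is
\(c_i = \mathrm{mean}\{m_j : k_j \ge k_i\}\) — inclusive of the index locus
and of all key ties, so the smallest key carries the grand mean and tied
keys share one value. The inclusive reading is adopted deliberately: the
exclusive variant ("strictly larger only") leaves the largest locus
undefined. Spearman's rho between key and curve summarises the trend;
a constant vector makes rho undefined and is reported as NA.

## LD regions and CNV screening

r² between unphased SNPs is estimated by the standard
expectation-maximization over the double-heterozygote phase ambiguity
(every other genotype pair resolves to haplotypes unambiguously), with
missing genotypes dropped pairwise, convergence at a maximum
haplotype-frequency change below 1e-10, and a 1000-iteration cap. A region
around a lead SNP collects all panel SNPs with r² strictly above the
threshold (default 0.1) and takes their bounding half-open interval; the
bounding-interval construction is our choice, as is the strict inequality.
CNV loci are screened for any 1-bp overlap with these regions, with
per-group allele frequencies attached and CNVs below 5% pooled frequency
flagged as rare.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs.

* **Truth genotypes**: Hardy-Weinberg proportions q², 2q(1-q), (1-q)² at
  each locus — the minimal neutral model, chosen because no genotype model
  is implied by the workflow itself. Case frequencies derive from the
  configured allelic odds ratio via `case_allele_freq()`, which inverts the
  odds-ratio definition exactly.
* **Array miscall process**: an individual's true state is replaced with
  probability `plogis(alpha_type - beta * log(markers) + batch_shift)` by a
  uniformly chosen different admissible state. The logistic form is an
  assumption — the empirical findings it emulates (deletions validated at
  73% vs duplications at 12%; recovery rising with marker count) are
  outcome rates, not a mechanism — and uniform replacement keeps the
  oracle analytic. Marker counts are drawn as
  `1 + NB(mu = marker_mean - 1, size = dispersion)` so counts are at least
  1 with the configured mean; spans are `markers * spacing`.
* **MLPA**: truth with probability 1 - epsilon, else a uniform different
  admissible state; MLPA is modelled as near-truth because it is the
  orthogonal reference assay.
* **Batches**: additive shifts on the miscall log-odds per batch label,
  assigned round-robin.
* **Determinism**: every stage draws from a named substream derived from
  the master seed, so identical configurations produce byte-identical
  output files and adding a locus never perturbs the draws of another.

What the generator does *not* emulate: probe intensities, B-allele
frequencies, segmentation boundary noise, correlated miscalls within
batches beyond the mean shift, and CNVs above copy number 4. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean generative model, not robustness to every artefact of real array
data.

## Batch heterogeneity screen

Batch effects are screened per locus with an uncorrected Pearson
chi-squared test of carrier/non-carrier counts across batches, with a
configurable flagging threshold (default 0.05). This is a transparent
heterogeneity screen, intentionally simpler than a mixed-model batch
correction: it flags loci for inspection rather than adjusting estimates.
A single batch makes the screen inapplicable.

## Numerical choices and problem sizes

* Exact-test enumeration uses `dhyper` over the full support; the test
  suite checks it against an independent factorial enumeration for all
  table totals up to 200 and against the standard reference implementation.
* The EM r² is verified against a likelihood grid search: any EM stationary
  point has allele frequencies equal to the sample frequencies, so the grid
  runs over the single free haplotype frequency at resolution 1e-4 with
  local refinement.
* Simulation-based checks use 10,000-20,000 individuals for rate recovery
  (3 binomial SEs), 100 replicates of 5,000 cases / 5,000 controls for
  odds-ratio interval coverage (expected at least 90% empirical coverage),
  and 25 replicates of 20 loci x 200 individuals for the sign of the
  reliability correlation; these sizes give comfortable statistical margins
  while keeping the whole suite fast.

## Worked example

```{r pipeline}
loci <- list(
  locus_spec("DEL_A", "deletion", q_control = 0.3, odds_ratio = 2,
             chrom = "chr1", marker_mean = 20),
  locus_spec("DUP_B", "duplication", q_control = 0.15, odds_ratio = 1,
             chrom = "chr2", marker_mean = 20))
res <- run_pipeline(loci, n_case = 150, n_control = 300,
                    model = error_model(alpha_del = -2, alpha_dup = 0,
                                        beta = 1, mlpa_error = 0.01),
                    seed = 11)
res$association[, c("locus_id", "or", "ci_low", "ci_high", "chi2_p")]
res$concordance
```

## Known limitations

* The linear mixed-model batch correction used in large array studies is
  out of scope; the chi-squared screen only detects, it does not correct.
* Genotypic (2x3) tests, trend tests and covariate-adjusted regression are
  not provided; the association layer is strictly allelic.
* Call-to-locus matching uses a 50% reciprocal-overlap rule; fragmented or
  partially overlapping calls near that boundary are sensitive to it. The
  rule is configurable because no standard exists.
* The canonical locus list for susceptibility screening must come from
  configuration; the package ships only the count-table fixture.
```
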