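---
title: "Rare-variant discovery and candidate-gene triage: methods and design"
author: "crcburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant discovery and candidate-gene triage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcburden)
```

## The problem

Early-onset colorectal cancer (CRC) that is mismatch-repair proficient and
unexplained by the known Mendelian syndromes is a natural place to look for
moderately penetrant germline risk factors. The strategy implemented here
searches case exomes for genes recurrently hit by rare, potentially damaging
variants, removes genes that accumulate comparable variants in matched
controls, and then triages the survivors through ordered external-evidence
lists. The package provides every stage of that analysis as composable,
tested functions over plain variant tables, together with a synthetic cohort
generator so the whole pipeline can be exercised and calibrated without any
protected data.

The intended user is an analyst with per-sample annotated germline variant
calls (VCF or the package's TSV dialect), cohort manifests, and plain-text
gene lists. The package does not call, annotate or score variants: read
depth, consequence, PhyloP conservation and the in-silico predictor labels
are consumed as inputs.

## The filter cascade

A call-level cascade is applied identically to the case and control
cohorts, in a fixed order chosen for log readability (the gates are
conjunctive predicates, so order does not change the result):

1. **Read-level quality.** A call needs at least 10 reads, 5 variant reads,
   5 unique read start positions, and 28% variant reads. All comparisons
   are inclusive. Unique starts cannot be counted per allele for
   insertions/deletions, so that rule is skipped when the field is absent —
   an absent optional field is `NA`, never zero.
2. **Population frequency.** A variant is kept only if its minor allele
   frequency (allele count over twice the panel size) is at most 0.001 in
   *every* enforced reference panel (default: an in-house panel and the
   EVS panel). A per-config cutoff of 0 reproduces the stricter
   "absent from the panel" reading; we chose one uniform MAF mechanism with
   the cutoff as a parameter rather than a special-cased membership rule,
   since the strict reading is the cutoff's limit.
3. **LoF-tolerant genes.** Genes known to tolerate loss-of-function
   variation in healthy populations are dropped entirely. The reader
   refuses an empty tolerant list, because an empty list would silently
   disable the gate.
4. **Impact class.** Nonsense, frameshift and canonical splice-site (±1/2)
   changes are *protein-truncating* regardless of conservation; missense
   changes are kept as *conserved missense* only with PhyloP ≥ 3.0
   (inclusive — a splice variant with PhyloP 2.427 is retained, a missense
   at 2.99 is not). Synonymous and other consequences are never retained.
   A missense record with missing PhyloP is excluded with a warning.

Every threshold lives in `filter_config()`, and `filter_fingerprint()`
serializes the whole configuration. The burden screen refuses to compare
cohorts whose fingerprints differ: a control cohort filtered under even a
slightly different configuration produces incomparable burdens, which is
the single easiest way to manufacture false enrichment.

## Biallelic and recurrent genes

Homozygosity is called from the variant-read fraction alone (≥ 95% on an
autosome); there is no genotype-likelihood model, and high-fraction calls
on sex chromosomes are deliberately left heterozygous because hemizygosity
confounds the fraction. A gene is a biallelic candidate in a sample with a
homozygous qualifying variant or two *distinct* heterozygous ones; without
phasing the compound heterozygote is labelled putative.

A gene is *recurrent* when qualifying variants occur in at least two
distinct families. We read "two variants in unrelated individuals" as two
unrelated carrier individuals — the within-person case is exactly what the
biallelic analysis handles separately — but `require_unrelated = FALSE`
gives the looser reading. An identical shared allele in two unrelated
carriers counts: recurrence of the variant is evidence, not duplication.
Family granularity is delegated entirely to the manifest.

## The burden screen

For each recurrent gene the qualifying-variant count in cases is compared
with controls by a chi-square goodness-of-fit test with expected counts
proportional to cohort sizes, 1 degree of freedom and no continuity
correction. Counts of *variants* (sample–variant observations) are the
default unit because the screen asks about frequencies of variants;
carrier counts are available as an option and are the unit of the exact
Fisher stage, which is framed as a 2×2 carrier table. Benjamini–Hochberg
critical values and adjusted p-values are reported over the number of
recurrent genes by default. Retention uses the raw p ≤ 0.05 rule with the
BH flags alongside: in a small discovery cohort nothing typically survives
FDR correction, and making the fallback explicit is more honest than
hiding it.

The Fisher p-value is computed by exhaustive hypergeometric enumeration
under the minimum-likelihood two-sided convention (ties guarded by a
1 + 1e-7 relative tolerance), with the sample cross-product odds ratio —
infinite when an off-diagonal zero makes it unbounded. The test suite
cross-checks the chi-square stage against `chisq.test()` and the Fisher
stage against both direct enumeration and `fisher.test()`.

## Triage

Burden survivors pass through four ordered evidence steps, and a gene is
reported at the first that matches: (1) all qualifying variants in the
gene are truncating, with truncating variants in at least two unrelated
carriers; (2) membership in a CRC driver-gene list; (3) membership in a
mouse transposon CRC-screen list *and* a cancer-related KEGG pathway;
(4) membership in a CRC GWAS list. All matching steps are also emitted, so
first-match assignment loses no information. Hits in known predisposition
genes are annotations carrying a "requires functional follow-up" note,
never pathogenicity verdicts — demoting or promoting them requires tumor
and functional data outside this analysis.

The bundled gene-list packs are illustrative reconstructions: they contain
the genes the logic must recognize plus field-standard members, but
pathway and driver catalogs drift between releases and the packs are not
pinned to any snapshot. Real analyses should supply their own packs
directory (`manifest.tsv` plus one plain-text list per pack).

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the analysis assumes: 55
case and 164 control exomes by default, per-gene per-individual Poisson
variant counts (rate `background_rate / n_case`, identical in controls),
spiked genes multiplying the case rate by a relative risk, a truncating
fraction of 0.15 (the truncating share of qualifying calls in an
early-onset CRC exome screen), PhyloP drawn from a transparent
two-component uniform mixture on [0, 3) and [3, 7] so the conservation
threshold is exercised on both sides, panel allele counts drawn on either
side of the MAF 0.001 boundary, and a configurable fraction of calls
constructed to violate exactly one quality rule. Every variant carries its
construction truth, and a property test asserts that the filter cascade
recovers that truth exactly at default thresholds.

What the generator does *not* emulate: linkage and haplotype structure
(never used by the analysis), platform batch effects, shared variants
between individuals beyond what recurrence tests inject explicitly, and
realistic per-gene mutation-rate variation — background rates are uniform
across genes and chosen for test power, not biological realism. Passing
tests therefore validate the pipeline's logic and the screen's statistical
behavior, not performance on real exomes.

## Calibration, honestly

`estimate_calibration()` reports the burden screen's empirical
conditional type-I rate and power. The conditioning matters: a gene only
reaches the test after being recurrent in the *case* cohort, which selects
for case enrichment, so the conditional type-I rate sits well above the
nominal level (around 0.22 at α = 0.05 under the default null
configuration) — an inherent property of the screen-then-test design, not
a bug. The rate is therefore reported with its Monte-Carlo standard error
and a flag when it exceeds α by more than three standard errors, rather
than asserted to be near α. Downstream stages (FDR correction, the exact
Fisher confirmation against an independent control panel, and the
evidence triage) exist precisely because the screen alone is permissive.
Power is estimated the same way over spiked genes; replicate seeds derive
from the configuration seed, so configurations differing only in relative
risk share common random numbers and power comparisons across relative
risks are paired.

Problem sizes used by the shipped checks — 500 replicates at 60 genes for
the null rate and 150 replicates at 40 genes per relative-risk point (100
each in the acceptance script) — were chosen to hold the Monte-Carlo
standard error of the reported rates below about 0.01–0.05, which is tight
enough to order power across relative risks 1, 3 and 10.

## Numerical and degenerate-input choices

* MAF uses the chromosome-count denominator 2N; cohort tables that print
  heterozygous carrier counts use the carrier count as the allele count.
* A pooled count of zero makes the chi-square test undefined and is an
  error, not a p-value of 1.
* Fisher tie comparison uses the 1 + 1e-7 relative guard standard in exact
  two-sided implementations; without it floating-point noise makes equal
  probability outcomes drop out of the tail sum.
* Empty cohorts, empty recurrence tables and empty triage inputs all flow
  through and produce structurally complete, deterministic reports.
* Reports are ordered by gene then position, making regeneration
  byte-identical.

## Known limitations

Phasing, pedigree inference, population-stratification correction,
variance-component burden tests and any re-annotation are out of scope.
The chi-square screen with expected counts below ~5 is approximate by
construction; its role is cheap triage between the recurrence filter and
the exact confirmation stages. Gene symbols are upper-cased at ingest but
not alias-resolved, so mismatched aliases between variant tables and gene
packs are the user's responsibility.
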