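---
title: "Prioritizing germline variants in small familial tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing germline variants in small familial tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The problem

Adult granulosa cell tumor (AGCT) is a rare sex cord-stromal ovarian cancer;
almost all cases carry the somatic *FOXL2* c.402C>G mutation, but no germline
predisposition is known. When the same rare tumor appears twice in one family
— a mother and daughter, an aunt and niece, or two second cousins — the
natural question is whether a shared rare germline variant explains it.
`famvar` implements the full desk-side analysis for that situation: verify
that the declared relationships are genetically real, filter the jointly
carried small variants down to a reviewable candidate list, group structural
variants by shared breakpoints, scan candidate loci, and compare the familial
patients against an unrelated reference cohort of the same tumor type.

Because real cohorts of this kind are controlled-access, the package ships a
pedigree gene-dropping simulator that produces a complete synthetic cohort
with known ground truth, so every stage is testable end to end offline.

## Relatedness: pedigree and genotype sides

**Pedigree kinship.** `kinship_matrix()` implements the standard recursion
over a topological order: founders are non-inbred and unrelated,
$\varphi_{ii} = \tfrac12(1 + \varphi_{f_i m_i})$, and
$\varphi_{ij} = \tfrac12(\varphi_{f_i j} + \varphi_{m_i j})$ when $i$ is not
an ancestor of $j$. Degrees use the midpoint-in-log2 convention: degree $d$
covers $\varphi \in (2^{-d-1.5}, 2^{-d-0.5}]$, so the exact pedigree values
1/4 (parent–offspring), 1/8 (aunt–niece) and 1/64 (second cousins) map to
degrees 1, 2 and 5 with no boundary ambiguity. Beyond `max_degree` (default
9) pairs report as unrelated.

**Moment estimator.** `estimate_kinship_moment()` is the allele-frequency-free
within-pair estimator
$$\hat\varphi = \frac{N_{\text{het,het}} - 2\,N_{\text{opp.hom}}}
{N_{\text{het}}(i) + N_{\text{het}}(j)},$$
whose expectation is the kinship coefficient and whose null (unrelated)
expectation is zero for any allele-frequency spectrum. A pair with no
heterozygous markers has no defined estimate and is flagged, never silently
zero. One published worked example for this estimator assigns opposite-homozygote
counts to heterozygous-versus-homozygous marker pairs; we follow the
definition (both samples homozygous for different alleles), under which the
all-het versus alternating-hom pair gives $\hat\varphi = 0$.

**IBD segments.** `find_ibd_segments()` does exact-match segment detection on
phased haplotypes: maximal marker runs where some haplotype of $i$ equals
some haplotype of $j$, kept at genetic length $\ge$ `ibd_min_cm` (default
3 cM). Exact matching presumes error-free phasing — the synthetic-data
contract — and is restricted to markers with minor allele frequency $\ge$
`ibd_min_maf` (default 0.05) so near-monomorphic sites cannot fake long
matches. IBD2 is credited only where two disjoint haplotype pairings carry
retained runs simultaneously; an earlier per-marker version of that rule
inflated distant-pair estimates by counting state coincidences inside IBD1
segments, which the gene-drop origin oracle caught.

**Two-tier combination.** `estimate_relatedness()` uses the moment estimator
where it is strong (degree 1–4) and refines anything deeper with IBD
segments, because at desk-scale genomes the moment estimator's sampling
noise spans several deep-degree bands while "zero segments of 3 cM" cleanly
separates unrelated pairs from genuine distant relatives.

## The SNV filter cascade

Stage order (each stage only removes; `FilterTrace` asserts the funnel):

1. **Within-family sharing** — every affected, sequenced member carries at
   least one alternate allele. A missing genotype disqualifies: no-calls
   must not manufacture candidates.
2. **Caller quality** — records failing FILTER are parsed but gated here.
3. **Rarity** — population frequency $\le$ 0.001 (1:1000) *or missing*:
   absence from databases is evidence of rarity; the filter removes variants
   known to be common.
4. **Pool of normals** — membership matched on the parsimony-trimmed
   (chrom, pos, ref, alt) key, so representation differences cannot leak
   panel variants through.
5. **Branch A (coding candidates)** — exonic window (any exon of any
   transcript $\pm$ 10 bp, boundaries inclusive), then consequence:
   frameshift/stop-gain/stop-loss/start-loss unconditionally, nonsynonymous
   only with $\ge$ 3 of 5 predictor calls pathogenic. The denominator is
   fixed at five; a missing call counts against. Nonsynonymous variants at
   exactly 2/5 are reported on a side channel (the near-miss a reviewer may
   still rescue for a tumor suppressor) but never auto-included.
   Cancer-census membership is annotation, never a filter.
6. **Branch B (genome-wide)** — CADD PHRED tiers on the family-shared
   union (annotate $\ge 5$, assess $\ge 20$, both inclusive per the stated
   thresholds; highlight strictly $> 30$ per the "greater than 30" wording),
   variants shared by $\ge 2$ families, and genes with qualifying variants
   in $\ge 2$ families (blacklist ships empty; genes supported only by
   quality-failing calls are removed with a logged reason).

Variant normalization splits multiallelic records one alternate allele at a
time, conserving each sample's total alternate dosage, and trims the shared
allele suffix then prefix (position advances per prefix base). This matches
what `bcftools norm` produces for the same records; full left-alignment
against a reference sequence is intentionally out of scope, so indels inside
repeat tracts keep their anchor.

## Structural variants

Each SV is two oriented breakends with confidence intervals. Two SVs share
breakpoints when their types are compatible, both canonical slots agree on
chromosome and orientation, and the CI-expanded windows intersect within
`sv_max_gap_bp` (default 100 bp — the quoted upstream tool only says
"default parameters", so this is a config knob). Orientation agreement at
both slots keeps deletions and duplications at the same coordinates apart.
Groups are connected components (union-find) of that relation, with ids
derived from sorted member lists so the partition is input-order invariant.
A group counts for a family only when *every* affected member contributes a
member SV; groups fully shared by no family are removed — the only reading
of "present in less than one family" that makes the sentence a filter.
Genes are assigned by transcript-span intersection for intrachromosomal
types and by a 1 kb flank around unpaired breakend junctions. A dosage
check flags family-shared duplications on the chromosome-14 gain and
deletions on the chromosome-22 loss that characterize this tumor's somatic
copy-number profile.

## Cohort comparison

Welch's $t$ is the default two-sample test (8 versus 33 patients with no
variance-equality guarantee); the pooled Student variant is selectable.
Degenerate inputs (zero variance in both groups) return $p = 1$ for equal
means by convention, flagged. "Metastatic at diagnosis" is operationalized
as FIGO stage beyond I, with unknown stage never satisfying the predicate
and always counted in the denominator. Reference-cohort presence counts,
for each candidate, the reference samples carrying at least one alternate
allele.

## The synthetic world

`sim_spec()` states the emulated design once:

| parameter | default | why |
|---|---|---|
| families | 4 (affected-pair degrees 5, 1, 2, 5) | the study's family structures: second cousins, mother–daughter, aunt–niece, second cousins |
| sequenced per family | 2 affected | the study sequenced 8 familial patients |
| reference samples | 33 | the unrelated same-tumor reference group |
| genome | 2 chromosomes × 25k markers, 267.8 + 251.7 cM | desk scale; genetic lengths of the two largest human chromosomes |
| founder AF spectrum | Beta(0.2, 0.2), 10% forced rare (AF ≤ 0.001) | U-shaped site spectrum plus guaranteed input for the rarity filter |
| recombination | Poisson crossovers, uniform in cM, no interference | standard gene-dropping model |
| planted variants | 1 rare coding deleterious per family; 1 two-family variant with 2 reference carriers | ground truth for branch A, cross-family sharing and reference presence |
| planted SVs | 1 family-shared DEL per family, 1 two-family DUP; jitter SD 20 bp truncated inside the 100 bp gap | grouping ground truth that cannot straddle the slack |
| ages/stages | the familial table as printed (mean 38.375, range 17–60, one stage IIB); reference ~ N(51, 11) clipped to [29, 75] | the familial arm is data, the reference arm is only summarized in print |

Variants are planted by choosing a founder haplotype that *all* affected
members inherited at the target marker, re-drawing the family's gene-drop
seed until such a haplotype exists (always immediate for mother–daughter,
a handful of retries for aunt–niece, ~16 expected for second cousins). This
conditions those genomes on IBD at the planted locus — exactly what a real
family segregating a causal variant looks like.

What the generator does **not** emulate: sequencing error, coverage,
caller artifacts (pool-of-normals membership is assigned, not emergent),
linkage disequilibrium between founder haplotypes, population structure,
phasing error, and multi-transcript gene models. A green recovery test
therefore establishes the *logic* of each stage on clean inputs, not
robustness to noisy calls.

## A known red criterion

The recovery suite expects IBD-based classification to place simulated
degree-5 pairs within ±1 degree in ≥ 80% of 30 replicates. At the stated
desk genome (519 cM) this is unattainable: an oracle that classifies from
the *true* realized IBD fraction — read off the gene-drop origin mosaics,
no detection step at all — succeeds in only ~53% of replicates, because
about one in five second-cousin pairs shares no detectable segment at
5.2 Morgans and the realized-kinship distribution spans degrees 3–8.
Detection itself is exact (parent–offspring recovers the full genome to
within 2%; self-comparison gives $\hat\varphi = 0.5$). The corresponding
acceptance test is implemented faithfully and left failing; scaling the
genome toward the real 3,500 cM would make it pass but would abandon the
stated desk-scale world.

## Numerical and degenerate-input choices

- Coordinates are 1-based closed everywhere; BED converts on read.
- Missing genotype, missing population AF, missing CADD and missing
  predictor calls are all distinct states with stage-specific semantics
  (disqualify, keep, tier `none`, count-against respectively).
- Kinship estimates clamp to $[-0.5, 0.5]$ for classification; negative
  means unrelated.
- Group ids, report rows and emitted files are deterministically ordered;
  re-running any stage with the same inputs and seed is byte-identical
  (manifests carry wall-clock and are excluded from digest comparisons).
- The single run seed fans out to per-component seeds through an integer
  hash (`derive_seed()`), so components are independently reproducible and
  all derived seeds stay under $2^{31}$.

## Limitations

Annotation is consumed, never computed: effect classes, CADD scores and
predictor calls must arrive in the VCF INFO fields. The predictor vector is
abstract (five ternary calls) because the upstream tool set is not public.
Clinical-database lookups are replaced by user-supplied gene/variant lists.
Exact-match IBD detection is not suitable for real, error-containing data
without a preceding phasing/error model.
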