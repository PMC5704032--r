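---
title: "Discordance analysis of monozygotic twin quad genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discordance analysis of monozygotic twin quad genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinquad)
```

## The question and the model

Monozygotic twins discordant for a disease are a natural experiment: both
carry the same inherited genome, so differences between them are dominated
by post-zygotic (somatic) mutation. Under a liability-threshold model,
inherited variation supplies a family-specific predisposition that both
twins share, and the affected twin's additional post-zygotic load is what
crossed the disease threshold. twinquad operationalizes this in two moves:

* **Variant-level classification.** In a family quad, a twin's variant is
  *shared* when the co-twin carries a call with the same canonical key,
  and an unshared variant is *inherited* when at least one parent carries
  it, otherwise *de novo* (a post-zygotic candidate). Without parental
  genomes the inherited/de novo split is impossible and unshared variants
  are labeled *provisional de novo*. Presence is compared as set
  membership of canonical keys — zygosity is deliberately ignored, since
  the design contrasts presence/absence between near-identical genomes.

* **Pathway-level comparison (GP/GPD).** Each individual's genes hit by
  unique (de novo or provisional de novo) variants of any class are tested
  for pathway over-representation, and the top 20 pathways per individual
  are compared as name sets. Pathways present in both co-twins are
  *genetic predisposition* (GP); pathways unique to the affected twin are
  candidate *disease* pathways (GPD). Across families,
  `final_gpd = (intersection of affected top-20 lists) minus (union of
  unaffected top-20 lists)`. Membership in the top-k list is the only
  criterion — no p-value cutoff is applied — because rank membership is
  what makes profiles of individuals with very different query sizes
  comparable.

## Thresholds and their defaults

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 50 reads | high-confidence floor on per-call read depth |
| `min_quality` | 100 (phred-like) | high-confidence floor on call quality |
| `overlap_threshold` | 0.5 | reciprocal-overlap fraction for CNV/SV identity |
| `junction_dist` | 500 bp | strict bound on inter-chromosomal junction distance |
| `top_k` | 20 | pathway-profile length in the GP/GPD comparison |
| `promoter_bp` | 2000 bp | promoter window upstream of the transcript start |
| `splice_bp` | 2 bp | intronic splice-site flank |

Numerical conventions worth stating explicitly:

* **Boundary inclusivity.** The depth/quality filter and the overlap rule
  are met *at* equality (depth 50 passes; exactly 50% reciprocal overlap
  matches; an inversion with exactly 50% overlap and the same direction is
  shared). The junction rule is strict (`< 500 bp`), and both junctions
  must satisfy it.
* **Coordinates.** Small variants use 1-based VCF positions; CNV/SV
  intervals are 0-based half-open, so an event's length is exactly
  `end - start` — this is the convention under which every bundled
  published CNV row reproduces its printed size.
* **Normalization.** Indels are trimmed of shared flanks (keeping the VCF
  anchor base) and left-aligned against the reference, so all spellings of
  one indel share a key. "Call quality" is mapped to the VCF `QUAL`
  column.
* **Grouping.** The ≥50% reciprocal-overlap relation is not transitive, so
  merged event groups are defined as connected components of the pairwise
  match graph; a chain A~B~C forms one group even where A and C do not
  match directly. Cross-category matches are never attempted and CNV
  copy direction (amp vs del) must agree for a match.
* **Inversion identity** is implemented as reciprocal *positional* overlap
  plus equal orientation. Sequence-level identity would be an alternative
  reading; it is not mixed in because no other matching step compares
  sequence.
* **Tie-breaks.** Enrichment rows are ranked by p-value with ties broken
  by canonicalized set name, making top-k lists deterministic.
* **Parental presence checks** use unfiltered parental call sets by
  default: a true parental variant that merely failed the depth filter
  should not manufacture a false de novo. The subject twin's calls are
  always filtered. Both choices are configurable, and summary tables
  report filtered and total counts so either reading of a published
  "high-confidence unshared" column can be reproduced.
* **Site-level quality.** The quality threshold is applied per call
  (site), not per allele.

## Over-representation statistic

The original analysis style in this field uses commercial knowledge-base
tooling whose statistic and background are proprietary. twinquad uses the
standard right-tail hypergeometric test against the gene-set collection's
own universe (union of member genes) or a user-supplied background:

$$p = \sum_{j=k}^{\min(K,n)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}$$

evaluated through the numerically stable log-space tail. Published
knowledge-base p-values are therefore context, not reproduction targets;
the GP/GPD comparison depends only on rank membership, which is why the
bundled worked example reproduces the published pathway sets exactly even
though the statistic differs. Because the universe a proprietary tool used
is unknowable, both background modes are provided and neither is claimed
to match it. A flat gene-to-tag table stands in for knowledge-base
"direct connection" phenotype filters (`phenotype_tag_filter()`).

## What the simulator emulates

`simulate_quad()` plants, on a synthetic genome with multi-exon genes on
both strands and a disjoint pathway collection:

* two parental pools of inherited variants (each present in its parent and
  in both twins; a small fraction, 5%, in both parents), with SNV
  transitions drawn at Ti/Tv = 2.1;
* germline de novo variants (both twins, neither parent);
* post-zygotic variants per twin, each with a mosaic cell fraction drawn
  from a Beta(2, 4) model (mean 1/3) by default — the field reports
  post-zygotic variants at widely varying cell fractions but no canonical
  distribution, so this right-skewed choice is a modeling decision, made
  once, favouring partial mosaicism; a fixed-fraction model is available
  for controlled experiments;
* shared and twin-unique CNVs (copy states {0,1,3,4}) and SVs in five
  categories, with twin-unique events split inherited : de novo ≈ 30 : 70,
  echoing the published 2-of-7 inherited unique CNVs;
* optional low-quality decoys (quality 50), inherited-but-discordant
  variants, and "spiked" post-zygotic variants placed in the coding
  sequence of named gene sets to plant pathway signal.

Default counts are desk-scaled to roughly 1/1000 of real per-genome
totals (≈3.6 k inherited SNVs, ≈400 indels, ≈75 block substitutions across
the two parental pools), while CNV (≈150) and SV (≈100) counts stay near
their real magnitudes since they are already small. Planted calls carry
quality 200 and, in the default noiseless mode, a constant read depth of
50 — so every planted call deterministically meets the high-confidence
floor and classification accuracy can be measured against ground truth
without detection noise. A Poisson depth model is available when filter
attrition itself is under study.

Mosaic detection loss is modeled separately and explicitly:
`apply_mosaic_dropout()` draws supporting reads Binomial(depth, f/2) for a
variant at cell fraction `f` (heterozygous in carrier cells) and drops
calls with fewer than 3 supporting reads. Retention therefore follows the
exact binomial tail (`retention_probability()`), reaching >0.999 at f = 1
and depth 50 and decaying to zero with f, which is what produces the
monotone recall degradation the tests assert.

The simulator does **not** emulate: read-level data (FASTQ), GC bias or
read-depth HMM behavior of upstream CNV callers, linkage disequilibrium or
realistic allele-frequency spectra, sequencing error (false positive
calls), or genotype dosage. Passing tests show the *classification logic*
is exact under the stated presence/absence model; they do not certify
performance against caller artifacts in real data.

Determinism: each simulation stage seeds R's RNG once from the config seed
(reference at `seed`, quad at `seed + 1`, dropout at `seed + 2`), and all
writers emit no timestamps, so a config reproduces its output directory
byte for byte.

## Problem sizes in the test suite

Unit and property tests run on quads of a few hundred to a few thousand
small variants and tens of events — large enough that every class of
planted origin is exercised, small enough that the full suite runs in
about two minutes. The enrichment null-calibration uses a 30,000-gene
universe with ten sets of 1,200–3,000 genes and 1,000 random queries of
3,000 genes: at these sizes the discrete hypergeometric tail is nearly
continuous, so the empirical type-I error at 0.05 is a meaningful
calibration check (the exact null rejection rate of this design is 0.047).

## Known limitations

* Presence/absence comparison cannot distinguish genotype changes (e.g. a
  loss of heterozygosity event looks identical to the shared variant).
* Parent-of-origin and germline-vs-early-embryonic timing are out of
  scope; "inherited" means present in at least one parent.
* Impact annotation picks the first overlapping transcript per gene (the
  synthetic models have one transcript per gene); isoform-aware
  annotation is not attempted.
* With declared no-call regions absent, a variant missing from a sample is
  treated as absent, mirroring near-complete genome callability; partial
  callability would require per-sample coverage masks.
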