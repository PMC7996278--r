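---
title: "Selecting tagging SNPs in candidate gene regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting tagging SNPs in candidate gene regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagsel)
```

## Scope and model

`tagsel` selects tagging SNPs (tagSNPs) for case–control studies of
ischemic-stroke outcome, starting from candidate genes identified in a rat
brain-ischemia model and mapped to their human orthologues. The statistical
object at the centre is the pairwise linkage-disequilibrium matrix of
squared allele correlations,

$$ r^2_{ij} = \frac{(p_{ij} - p_i p_j)^2}{p_i(1-p_i)\,p_j(1-p_j)}, $$

with $p_i$, $p_j$ the alternate-allele frequencies and $p_{ij}$ the
frequency of the haplotype carrying both alternate alleles. A tag *captures*
a SNP when $r^2 \ge$ a threshold; genotyping only the tags then preserves,
to fidelity $r^2$, the association information of the full SNP set.

## Pipeline stages and the parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `flank` | 5000 | bp | symmetric 5'/3' regulatory neighbourhood around each gene |
| `maf_threshold` | 0.10 | frequency | common variants only; strictly greater than ("higher than" the cutoff) |
| `r2_threshold` | 0.8 | $r^2$ | conventional high-LD capture threshold |
| `tissue_keywords` | Brain, Artery, Nerve, Blood, Heart | — | stroke-relevant tissue groups for eQTL filtering |
| `te_convention` | captured_per_tag | — | see below |

Coordinates are 1-based inclusive throughout (the VCF convention); only the
BED writer converts to 0-based half-open. Flanked regions clamp at position
1. Multiallelic VCF records and indels are dropped and counted, never split:
the downstream genotyping application (single-probe real-time PCR assays)
presumes biallelic markers. Missing genotypes are kept as missing and all LD
computations use pairwise-complete observations, the behaviour of the
standard interactive LD tools; no Hardy–Weinberg or missingness filters are
applied by default because the pipeline specifies only the MAF filter (both
are easy to add upstream, and their silent application by GUI tools is a
known source of SNP-count discrepancies between implementations).

## LD estimation

On phased haplotypes, $r^2$ is computed by direct haplotype counting over
the haplotypes non-missing at both sites. On unphased genotypes two
estimators are provided:

- **EM (default):** two-locus maximum-likelihood haplotype frequencies.
  Only double heterozygotes are phase-ambiguous; the EM splits them between
  *cis* and *trans* configurations. Initialization is at linkage
  equilibrium, convergence is $|\Delta\,\log L| < 10^{-8}$ with a
  1000-iteration cap, and non-convergence falls back to the composite
  estimator with a warning. These are conventional two-locus EM settings;
  the estimate is exact (equals the phased count) whenever the data contain
  no double heterozygotes.
- **Composite:** squared Pearson correlation of the dosage vectors — robust
  and assumption-light, but it mixes within- and between-haplotype
  covariance, so it matches the haplotype estimator only in expectation,
  not sample-by-sample.

SNPs with zero variance have undefined LD; `ld_matrix()` excludes them with
a warning and records their ids, and the workflow logs each exclusion.

## Tagging algorithms

**Greedy set cover** (the pairwise mode of Tagger-style tagging):
iteratively select the SNP covering the largest number of yet-uncovered
SNPs at $r^2 \ge$ threshold. The multimarker/haplotype-aggressive mode of
the original tool is deliberately out of scope. **Complete-linkage minimax
clustering** (CLUSTAG-style): cluster on distance $1 - r^2$, cut at
$1 -$ threshold so every within-cluster pair meets the threshold, and tag
each cluster by its minimax member. Clustering yields a partition; greedy
yields a cover in which a SNP capturable by several tags is assigned to the
tag with the highest $r^2$ (ties to the earlier-chosen tag), which makes the
mean capture $r^2$ of a run well defined.

Determinism was a design goal: all ties — equal cover counts, equal minimax
radii — are broken by higher MAF, then lower genomic position, then
lexicographic id, so identical inputs give byte-identical outputs. Capture
comparisons use a $10^{-9}$ tolerance on $r^2 \ge$ threshold: an exactly
rational $r^2$ (e.g. $1/2$) can be stored a few ulp below the cutoff, and
the tolerance keeps the three routes (greedy cover, clustering cut,
exhaustive oracle) mutually consistent. It is far below any scientifically
meaningful LD difference.

**Tagging effectiveness.** The pipeline's efficiency metric relates the tag
count to the number of SNPs tagged. Its two possible orientations conflict
in the source material (the verbal definition reads tags ÷ tagged, while
the method comparison treats larger TE as better and prefers the method
with fewer tags); `tagsel` defaults to captured-per-tag (higher = more
economical) and labels the convention in every summary, with the literal
inverse available as `te_convention = "tags_per_captured"`.

**Oracle.** `brute_force_min_tags()` searches all subsets (cap 20 SNPs) for
the minimum cover. The greedy heuristic carries the classical set-cover
$H_k$ guarantee; on the random test battery it is asserted to be within 2
tags of the optimum. One caution found during development: the greedy tag
*count* is not guaranteed monotone in the threshold (rare random instances
decrease coverage yet re-tile more efficiently); the exhaustive minimum is
monotone, and that is the invariant the tests assert.

## eQTL annotation and ranking

Tags are intersected with significant single-tissue eQTL records. Tissue
filtering is case-insensitive substring matching with underscores treated
as spaces, so the keyword *Blood* reaches *Whole_Blood* and *Brain* reaches
every brain sub-tissue — the keyword list names tissue groups, not exact
labels. Variant matching prefers identical ids and falls back to
(chromosome, position, allele-pair) comparison, allele-order-insensitive,
because population-panel ids are typically rsIDs while eQTL exports use
positional ids. Only *cis* records (matching gene id) are considered.

Ranking is a total order: candidates with any brain-tissue eQTL come first,
then candidates with other-tissue evidence ordered by descending largest
|NES| and ascending smallest p-value (the rule that promotes a single
strongest non-brain marker), then candidates with no eQTL. The final manual
curation step of a real study cannot be reproduced algorithmically; the
ranking formalizes its stated criteria.

By default the workflow annotates the assignment with the larger mean
capture $r^2$ (ties to greedy); `method_selection = "greedy"` forces the
greedy result regardless, matching a protocol that fixes the Tagger output
for annotation.

## The synthetic-data generator

`simulate_block_haplotypes()` is a founder-resampling model, not a
coalescent simulator: per block, founder haplotypes are drawn with per-SNP
founder-level MAF above a floor; each panel haplotype copies one founder
per block, re-drawing the founder at block boundaries with the
recombination probability; alleles then flip with the mutation rate.
Defaults — 99 individuals (the CEU reference sample size), four blocks of
ten SNPs with four founders each, boundary switch probability 0.1, flip
rate 0.01, MAF floor 0.1 — emulate a gene-sized region of a European
reference panel with realistic block structure. Positions are laid out at
1 kb spacing from 10 000; spacing is arbitrary and irrelevant to LD.

The generator gives *assertable* structure: two complementary founders make
a block rank-1 ($r^2 = 1$ within), independent founder choice makes blocks
independent ($E[r^2] \approx 1/(2N)$ across), and the truth attribute
records block memberships for ground-truth recovery tests. What it does not
emulate: recombination gradients within blocks, allele-frequency spectra
from demography, genotyping error correlation — so passing tests show the
algorithms are correct on block-structured input, not that real 1000
Genomes regions will decompose as cleanly.

## Problem sizes in the test suite

The packaged checks run at desk scale: 200 random LD matrices of 4–12 SNPs
against the exhaustive oracle, 1000 random two-SNP panels against the
correlation oracle, EM accuracy at n = 100 individuals (median absolute
error < 0.05), block recovery for 1–5 blocks at n = 100, and a 20-replicate
TE benchmark at the generator defaults — sizes chosen so the whole suite
completes in well under a minute per property while keeping Monte Carlo
noise far from the asserted margins. The headline counts of a real
application (the number of final markers from 1000 Genomes CEU and GTEx V8)
depend on those external releases and are not recomputed here; the
package's integration surface (`run_workflow()` on real VCF + eQTL exports)
is exercised end-to-end on synthetic bundles with known truth instead.

## Known limitations

- Pairwise tagging only: no multi-marker haplotype tagging, no
  haplotype-block definitions (confidence-interval or graph methods), no
  force-include lists.
- No D′, no multi-population LD, no trans-eQTLs, no liftover: orthologue
  coordinates are stored verbatim and never cross-checked against VCF
  contigs (the table and panel may legitimately come from different
  assembly eras).
- The EM estimator assumes Hardy–Weinberg genotype proportions within the
  two-locus system, as all two-locus EMs do.
- The brute-force oracle is exponential and refuses above 20 SNPs by
  design.
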