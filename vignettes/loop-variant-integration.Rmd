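---
title: "Integrating chromatin-loop topology with GWAS variants and differential expression"
author: "loopvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating chromatin-loop topology with GWAS variants and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopvar)
library(data.table)
```

## The problem

Most trait-associated variants from GWAS of bone mineral density and related
skeletal phenotypes sit in non-coding sequence, where they are presumed to
perturb enhancers and repressors rather than protein products. Chromatin
conformation assays (Hi-C and its nucleosome-resolution refinement, Micro-C)
reveal which distal regions a locus physically contacts, so a natural triage
for candidate regulatory variants is: does the variant fall inside a loop
*contact region* (anchor) of the disease-relevant cell type — here an
osteoclast-like state versus its precursor state — and does that loop exist
in only one of the two states (a *differential loop locus*, DLL)?

`loopvar` implements that integration as a chain of testable set operations
over called loops, variant tables, gene models and differential-expression
(DEG) tables:

1. **Loop classification.** Two loop sets are compared; each loop is
   `shared_loop` (both anchors match a loop of the other state),
   `shared_single_anchor` (exactly one anchor matches: one end keeps its
   contact, the other moves), or `unique` (a DLL).
2. **Variant selection and mapping.** Candidates are sentinels with
   association p strictly below 1e-5 plus LD proxies with r² strictly above
   0.6 whose sentinel survives; candidates are intersected with contact
   regions, counting unique SNPs and unique contacts.
3. **Positional clustering.** Candidates within 5 kb of one another are
   chained (single-linkage, bedtools-merge semantics); chains with fewer
   than 10 members are discarded; the span is last − first.
4. **Concordance.** Cluster/DEG overlap and windowed variant/DEG and
   DEG/DLL-contact co-location at ±0, 50, 200 and 1000 kb.
5. **Loop-anchored enrichment.** Each loop is assigned the gene with the
   closest promoter (±1 kb around a strand-aware TSS); the one state's
   loop-gene list is tested for term over-representation against the
   loop-gene universe with hypergeometric upper-tail p-values and
   Benjamini–Hochberg correction at adjusted p ≤ 0.05.

## Coordinate and matching conventions

All intervals are 0-based half-open internally (BED-native); variant
positions arriving 1-based can be converted on read
(`read_variant_table(..., one_based = TRUE)`). Chromosome names are
normalised to `chrN`. Overlap always means ≥ 1 bp of intersection of
half-open intervals; a variant hits a contact `[start, end)` when
`start ≤ pos < end`.

Loop callers do not define when two independently called loops are "the
same". We treat two anchors as matching when their intervals overlap after
widening each side by `slack_bins × min(resolution)`; the default
`slack_bins = 0` requires raw overlap. Anchor pairing is
orientation-agnostic (a left anchor may match a right anchor), and a fully
shared loop records the partner with maximal summed anchor overlap, ties
broken by smallest (chrom, start). Exact-coordinate equality would be too
brittle across the 1/4/16 kb call scales; the slack knob makes the
trade-off explicit. When one loop of a set duplicates or overlaps another
loop of the *same* set, the number of fully matched loops counted from each
side can legitimately differ (two near-copies in A can both match one loop
in B), so count symmetry is asserted only where sets contain
non-overlapping loops, as the synthetic generator guarantees.

Loops called at several scales are combined with
`combine_resolutions()`, collapsing identical-coordinate duplicates to the
smallest-resolution record — the choice that preserves the most precise
anchors; the reduction rule is not dictated by any upstream convention and
is therefore a documented package decision.

## Statistical choices

* **Regional loop-count comparison** (`region_loop_count_test`): an exact
  two-sided binomial test with success probability 0.5 on
  `count_A + count_B` trials, doubling the smaller tail and capping at 1.
  For counts (22, 7) this gives p = 0.00813, matching reported regional
  contrasts of that size; for (6, 3) it gives 0.508, which does **not**
  match every published regional p-value — the upstream test was never
  named, so the binomial is the default and a chi-square goodness-of-fit
  alternative is provided. `stats::binom.test` is *not* used because it
  defines two-sidedness by minimum likelihood rather than the doubled
  smaller tail.
* **Trait-versus-control contact enrichment**: two-sided Fisher's exact
  test on the 2×2 in-contact × trait table; the odds ratio is the sample
  cross-product (infinite on a zero denominator), not the conditional MLE.
* **Term over-representation**: upper-tail hypergeometric
  `P(X ≥ k)` via `stats::phyper` (an exact, log-space-stable tail sum),
  BH-corrected with `stats::p.adjust`. Terms with no universe overlap are
  untestable and omitted. BH output is monotone over the sorted raw
  p-values and never smaller than the raw value, but applying BH to its own
  output is *not* an identity in general (raw p = (0.25, 0.6) adjusts to
  (0.5, 0.6), which re-adjusts to (0.6, 0.6)), so idempotence is
  deliberately not asserted anywhere.
* **Strict thresholds**: p < 1e-5 and r² > 0.6 are strict inequalities;
  a sentinel at exactly 1e-5 and a proxy at exactly 0.6 are excluded.

The variant table carries an explicit `sentinel_rsid` column linking each
proxy to its sentinel: proxy retention is defined through the sentinel's
own survival, which is impossible to evaluate from r² alone, and a proxy
referencing an absent sentinel is an input error reported by rsID.

## What the synthetic generator emulates

Real loop calls and GWAS snapshots for this design are not redistributable,
so every stage is exercised on synthetic data with planted, recorded truth
(`generate_synthetic_study()`):

* **Slot layout.** Chromosomes are divided into exclusive slots of the
  largest anchor resolution (16 kb). Loop anchors, variant groups and gene
  bodies each occupy their own slots, so planted relationships are the
  *only* relationships: fully shared loops have identical coordinates,
  single-anchor pairs share exactly one anchor, and nothing else overlaps.
* **Class fractions** are realised exactly by largest-remainder
  apportionment (ties to the larger fractional part first), so requested
  fractions are met without drift at any n.
* **Variant structure.** Each sentinel carries `proxies_per_sentinel`
  proxies with r² uniform on bounds straddling 0.6 (default 0.4–1.0), so
  the strict threshold filter is always exercised. A configurable fraction
  of trait sentinels is planted inside cell-A anchors; a disjoint control
  trait has a lower in-anchor rate. Dense ("cluster") sentinel clouds are
  confined to ±2 kb so any surviving subset chains into one cluster; sparse
  clouds spread over ±50 kb. All groups are kept > 5 kb apart, so expected
  cluster memberships are derivable from the group construction alone, and
  the test suite re-derives them with an all-pairs union-find oracle.
* **Genes and DEGs.** Strand is uniform; the DEG count is exact by
  largest-remainder; one DEG body is planted over each expected cluster (up
  to the DEG budget) and recorded as a truth pair. TSS convention: plus
  strand TSS = start, minus strand TSS = end − 1 on half-open bodies.
* **Gene sets.** Planted enriched terms draw ≥ 80% of members from the
  DEG (foreground) list, with term sizes clamped so that guarantee is
  attainable; background terms draw uniformly from the gene universe.

Defaults (4 chromosomes × 10 Mb, 300 loops per state with 10% fully shared
and 5% single-anchor, 40 sentinels × 12 proxies, 20 control sentinels, 300
genes with 25% DEG, 40 terms with 4 planted) mirror the *shape* of a
differentiated-versus-precursor comparison — a large unique-loop majority
and roughly ten candidates per sentinel — at a size where every brute-force
oracle stays exhaustive. What the generator does **not** emulate: contact
matrices and loop-calling noise, LD estimated from genotypes (r² values are
assigned), overlapping gene models, and genome-scale loop counts. Passing
tests therefore demonstrate correctness of the set algebra and statistics
under planted truth, not loop-caller robustness on real data.

One seed drives every draw; regeneration under the same configuration is
byte-identical, which the suite asserts file by file.

## Numerical and degenerate-input choices

* Empty loop files, empty contact lists and empty candidate sets flow
  through every stage producing zero counts rather than errors.
* Window-extended gene starts are floored at 0; windows are half-open on
  the right like every other interval.
* Ties in loop-gene assignment (two promoters equidistant from a loop) go
  to the lexicographically smaller `gene_id`; ties in loop matching to the
  smallest (chrom, start). All outputs are sorted, making every table
  deterministic.
* `fraction_in_contacts` reports both the raw percentage and the nearest
  integer; 12,588 of 117,835 gives 10.68%, i.e. "approximately 11%".

## Problem sizes

The test suite runs the oracle-equivalence comparisons on 100 random
instances per operation (≤ ~200 entities each, where the brute force is
O(n·m)), planted-truth recovery on 20 seeds of a reduced configuration
(2 chromosomes × 4 Mb, 60 loops, 12 sentinels), and null calibration of the
enrichment stage over 20 seeds; the full default configuration is exercised
end-to-end by the analysis drivers and the acceptance script. These sizes
keep the whole suite under a minute while leaving every oracle exhaustive.

## Known limitations

* DLL status is presence/absence of a matching loop, not a statistical
  differential-contact test on matrices; loop calling itself is upstream.
* The windowed "x of y DEGs" summary uses a fixed DEG denominator; a
  window-dependent universe cannot be reconstructed from a fixed DEG list
  and is not modelled.
* The enrichment universe is the loop-gene union of both states; whether a
  background should instead be all annotated genes is configuration, not
  inference.
* No ontology-graph propagation: terms are flat gene sets (GMT).
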