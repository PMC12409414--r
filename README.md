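# loopvar

Integration of chromatin-loop topology with GWAS variants and differential
expression.

Most variants associated with bone mineral density and other skeletal traits
are non-coding, and a standing question is which of them sit in regulatory
sequence that is active in the disease-effector cell. Given loop calls from
a chromatin-conformation assay (Micro-C/Hi-C) for two cell states — e.g. an
osteoclast-like state and its precursor — `loopvar` answers, with exact set
operations and exact tests:

* which loops are **shared**, share a **single anchor**, or are **unique**
  to one state (differential loop loci, DLLs) — anchors match when their
  intervals overlap, optionally widened by `slack_bins × min(resolution)`;
* which **candidate variants** (sentinels at p < 1e-5 plus LD proxies at
  r² > 0.6) fall inside loop **contact regions**, with unique-SNP /
  unique-contact counting and a Fisher trait-versus-control 2×2 test;
* how candidates **cluster** positionally (single-linkage chaining at 5 kb,
  clusters under 10 SNPs discarded) and how clusters, DEGs and DLL contacts
  co-locate at ±0/50/200/1000 kb windows;
* which gene-set terms are over-represented in one state's **loop-gene
  list** (gene of the closest promoter, ±1 kb around the strand-aware TSS)
  against the loop-gene universe, by hypergeometric upper tail
  P(X ≥ k) with Benjamini–Hochberg correction at p_adj ≤ 0.05.

Because the raw data behind such studies are access-restricted, the package
ships a seeded synthetic-data generator (`generate_synthetic_study()`) that
plants loops, variants, genes, DEGs and enriched terms with a recorded
ground-truth manifest; every downstream stage is tested against that truth
and against brute-force oracles.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (seed 1) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_loop_topology.R
Rscript analysis/03_snp_mapping.R
Rscript analysis/04_concordance.R
Rscript analysis/05_enrichment.R
```

Stage 3 prints, for example:

```
trait candidates: 380 (40 sentinels); control candidates: 171
41 unique candidate SNPs in 16 unique contacts (10.79%, ~11%)
24 unique candidate SNPs within 13 unique differential-loop contacts
trait vs control in-contact: OR = 1.26, Fisher p = 0.543
```

i.e. of 380 candidate variants (40 sentinels surviving p < 1e-5 plus their
r² > 0.6 proxies), 41 distinct SNPs fall inside 16 distinct cell-A contact
regions — 10.79% of candidates, about 11% — and 24 of them are inside
contacts of loops unique to cell A. Stage 4 then reports the positional
clusters and their DEG overlaps:

```
7 retained clusters (median span 3291 bp, 75 clustered SNPs)
7 unique clusters overlapped 7 unique DEGs
```

which matches the generator's truth manifest exactly (the planted dense
sentinel clouds whose surviving proxies number at least 10, each with a DEG
body planted over it).

The same computation is available as a single call:

```r
library(loopvar)
rep <- run_pipeline(pipeline_config(out_dir = "results/pipeline",
                                    synthetic = synthetic_config(seed = 1),
                                    seed = 1))
rep$snp_mapping$percent_in_contacts
#> [1] 10.78947
```

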