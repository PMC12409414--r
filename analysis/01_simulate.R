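#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-cell-state study (loops, variants,
# genes, DEGs, gene sets) with a recorded ground-truth manifest.
# Writes results/data/; all later stages read from there.

suppressMessages(library(loopvar))

seed <- 1L
out <- "results/data"
cfg <- synthetic_config(seed = seed)
syn <- generate_synthetic_study(cfg, out)

cat(sprintf("genome: %d chromosomes x %.1f Mb\n",
            nrow(syn$genome), cfg$chrom_length_bp / 1e6))
cat(sprintf("loops: %d per cell state (%d fully shared, %d single-anchor planted)\n",
            cfg$n_loops_per_cell,
            sum(syn$loops$truth$class == "shared_loop" & syn$loops$truth$cell_label == "A"),
            sum(syn$loops$truth$class == "shared_single_anchor" & syn$loops$truth$cell_label == "A")))
cat(sprintf("variants: %d (%d trait sentinels x %d proxies + controls)\n",
            nrow(syn$variants$variants), cfg$n_sentinels, cfg$proxies_per_sentinel))
cat(sprintf("genes: %d (%d DEG); terms: %d (%d planted enriched)\n",
            nrow(syn$genes_deg$genes), nrow(syn$genes_deg$deg),
            cfg$n_terms, cfg$planted_enriched_terms))
cat("expected retained SNP clusters:", length(syn$variants$expected_clusters), "\n")
cat("wrote", out, "\n")
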