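#!/usr/bin/env Rscript
# Stage 4: cluster candidate variants (5 kb single-linkage chains, >= 10
# members), overlap clusters with DEG bodies, and summarise variant/DEG and
# DEG/differential-contact concordance at 0/50/200/1000 kb windows.
# Writes results/snp_clusters.tsv, results/cluster_deg_pairs.tsv,
# results/concordance_windows.tsv.

suppressMessages({ library(loopvar); library(data.table) })

variants <- read_variant_table("results/data/variants.tsv")
genes <- read_gene_table("results/data/genes.tsv")
deg <- read_deg_table("results/data/deg.tsv")
dll_contacts <- read_bed3("results/dll_contacts.bed")
deg_genes <- genes[gene_id %in% deg$gene_id]

sel <- select_candidates(variants[trait == "bone"])
cl <- cluster_variants(sel$candidates, gap_bp = 5000L, min_size = 10L)
fwrite(cl$clusters, "results/snp_clusters.tsv", sep = "\t")
cat(sprintf("%d retained clusters (median span %.0f bp, %d clustered SNPs)\n",
            nrow(cl$clusters), stats::median(cl$clusters$span_bp), nrow(cl$members)))

ov <- overlap_clusters_degs(cl$clusters, deg_genes)
fwrite(ov$pairs, "results/cluster_deg_pairs.tsv", sep = "\t")
cat(sprintf("%d unique clusters overlapped %d unique DEGs\n",
            ov$unique_cluster_count, ov$unique_deg_count))

windows <- c(0L, 50000L, 200000L, 1000000L)
vng <- variants_near_genes(sel$candidates, deg_genes, windows)
gnc <- genes_near_contacts(deg_genes, dll_contacts, windows)
summ <- merge(vng, gnc, by = "window_bp")
fwrite(summ, "results/concordance_windows.tsv", sep = "\t")
for (i in seq_len(nrow(summ))) {
  cat(sprintf("+-%d kb: %d unique SNPs near %d unique DEGs; %d of %d DEGs near a DLL contact\n",
              summ$window_bp[i] / 1000, summ$unique_snp_count[i],
              summ$unique_deg_count[i], summ$x[i], summ$y[i]))
}
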