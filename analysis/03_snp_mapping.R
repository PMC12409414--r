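#!/usr/bin/env Rscript
# Stage 3: select candidate variants (sentinels at p < 1e-5 plus LD proxies
# at r2 > 0.6), map them into cell-A contact regions, and test the trait
# against the control trait. Writes results/contact_hits.tsv.

suppressMessages({ library(loopvar); library(data.table) })

variants <- read_variant_table("results/data/variants.tsv")
contacts <- read_bed3("results/contacts_A.bed")
dll_contacts <- read_bed3("results/dll_contacts.bed")

sel <- select_candidates(variants[trait == "bone"])
sel_ctrl <- select_candidates(variants[trait == "control"])
cat(sprintf("trait candidates: %d (%d sentinels); control candidates: %d\n",
            sel$candidate_count, sel$sentinel_count, sel_ctrl$candidate_count))

mp <- map_variants_to_contacts(sel$candidates, contacts, "A")
fwrite(mp$hits, "results/contact_hits.tsv", sep = "\t")
frac <- fraction_in_contacts(mp$unique_snp_count, sel$candidate_count)
cat(sprintf("%d unique candidate SNPs in %d unique contacts (%.2f%%, ~%d%%)\n",
            mp$unique_snp_count, mp$unique_contact_count,
            frac$percent, frac$percent_rounded))

mp_dll <- map_variants_to_contacts(sel$candidates, dll_contacts, "A")
cat(sprintf("%d unique candidate SNPs within %d unique differential-loop contacts\n",
            mp_dll$unique_snp_count, mp_dll$unique_contact_count))

mp_ctrl <- map_variants_to_contacts(sel_ctrl$candidates, contacts, "A")
enr <- trait_enrichment_test(mp$unique_snp_count, sel$candidate_count,
                             mp_ctrl$unique_snp_count, sel_ctrl$candidate_count)
cat(sprintf("trait vs control in-contact: OR = %.2f, Fisher p = %.3g\n",
            enr$odds_ratio, enr$p_value))
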