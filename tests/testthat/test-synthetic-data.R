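test_that("genome generation echoes the configuration", {
  cfg <- tiny_config(1)
  g <- generate_genome(cfg)
  expect_equal(nrow(g), 2L)
  expect_true(all(g$length_bp == cfg$chrom_length_bp))
  cfg0 <- tiny_config(1, n_chromosomes = 0L)
  expect_equal(nrow(generate_genome(cfg0)), 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(1, frac_shared_loops = 0.8, frac_shared_single_anchor = 0.4),
               "frac_shared_loops")
  expect_error(tiny_config(1, frac_deg = 1.2), "proportions")
  expect_error(tiny_config(1, anchor_resolutions_bp = c(1000L, 1000L)), "distinct")
  expect_error(tiny_config(1, n_genes = -1L), "counts")
  expect_error(tiny_config(1, proxy_window_bp = 5000000L), "proxy_window")
})

test_that("planted loop class fractions are realised exactly", {
  cfg <- tiny_config(3, n_loops_per_cell = 10L, frac_shared_loops = 0.5,
                     frac_shared_single_anchor = 0)
  set.seed(cfg$seed)
  loops <- generate_loop_sets(cfg, generate_genome(cfg))
  tr <- loops$truth
  expect_equal(sum(tr$cell_label == "A" & tr$class == "shared_loop"), 5L)
  expect_equal(sum(tr$cell_label == "A" & tr$class == "unique"), 5L)

  # frac_shared_single_anchor = 0.3, n = 10 -> exactly 3, verified brute force
  cfg2 <- tiny_config(4, n_loops_per_cell = 10L, frac_shared_loops = 0,
                      frac_shared_single_anchor = 0.3)
  set.seed(cfg2$seed)
  loops2 <- generate_loop_sets(cfg2, generate_genome(cfg2))
  cls <- brute_classify(loops2$set_a, loops2$set_b)
  expect_equal(sum(cls == "shared_single_anchor"), 3L)

  # fully shared sets leave nothing unique in either direction
  cfg3 <- tiny_config(5, n_loops_per_cell = 8L, frac_shared_loops = 1,
                      frac_shared_single_anchor = 0)
  set.seed(cfg3$seed)
  loops3 <- generate_loop_sets(cfg3, generate_genome(cfg3))
  res <- match_loops(loops3$set_a, loops3$set_b)
  expect_equal(sum(res$a$match_class == "unique"), 0L)
  expect_equal(sum(res$b$match_class == "unique"), 0L)

  expect_error({
    cfg4 <- tiny_config(6, n_loops_per_cell = 100000L)
    set.seed(cfg4$seed)
    generate_loop_sets(cfg4, generate_genome(cfg4))
  }, "binding constraint")
})

test_that("largest-remainder apportionment preserves exact totals", {
  lr <- loopvar:::largest_remainder
  expect_equal(lr(10, c(0.5, 0)), c(5L, 0L))
  expect_equal(lr(10, 0.3), 3L)
  expect_equal(sum(lr(7, c(1 / 3, 1 / 3, 1 / 3))), 7L)
  expect_equal(lr(100, c(0.104, 0.896)), c(10L, 90L))
})

test_that("in-contact truth equals a brute-force point-in-anchor check", {
  for (seed in c(11, 12)) {
    cfg <- tiny_config(seed)
    syn <- generate_synthetic_study(cfg, withr::local_tempdir())
    v <- syn$variants$variants
    truth <- syn$variants$truth
    for (set_name in c("set_a", "set_b")) {
      cc <- contact_regions(syn$loops[[set_name]])
      want <- vapply(seq_len(nrow(v)), function(i) {
        any(v$chrom[i] == cc$chrom & v$pos[i] >= cc$start & v$pos[i] < cc$end)
      }, TRUE)
      col <- if (set_name == "set_a") "in_contact_A" else "in_contact_B"
      expect_equal(truth[[col]][match(v$rsid, truth$rsid)], want)
    }
  }
})

test_that("each sentinel carries the configured number of proxies within the window", {
  cfg <- tiny_config(19)
  syn <- generate_synthetic_study(cfg, withr::local_tempdir())
  v <- syn$variants$variants
  prox <- v[is_sentinel == FALSE]
  tab <- table(prox$sentinel_rsid)
  expect_true(all(tab == cfg$proxies_per_sentinel))
  sent_pos <- v$pos[match(prox$sentinel_rsid, v$rsid)]
  expect_true(all(abs(prox$pos - sent_pos) <= cfg$proxy_window_bp))
  expect_false(any(duplicated(v[, list(chrom, pos)])))
})

test_that("regeneration under the same seed is byte-identical", {
  cfg <- tiny_config(13)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic_study(cfg, d1)
  generate_synthetic_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("DEG planting is exact and planted bodies overlap their clusters", {
  cfg <- tiny_config(14, n_genes = 8L, frac_deg = 0.25)
  set.seed(cfg$seed)
  genome <- generate_genome(cfg)
  loops <- generate_loop_sets(cfg, genome)
  vars <- generate_variants(cfg, genome, loops)
  gd <- generate_genes_and_deg(cfg, genome, loops, vars)
  expect_equal(nrow(gd$deg), 2L)
  expect_true(all(gd$deg$p_adj < 0.05))
  expect_true(all(gd$deg$log_fc != 0))

  cfg2 <- tiny_config(15)
  syn2 <- generate_synthetic_study(cfg2, withr::local_tempdir())
  pairs <- syn2$genes_deg$planted_overlap_pairs
  chains <- syn2$variants$expected_clusters
  genes <- syn2$genes_deg$genes
  for (i in seq_len(nrow(pairs))) {
    ch <- chains[[pairs$cluster_index[i]]]
    g <- genes[gene_id == pairs$gene_id[i]]
    expect_true(g$chrom == ch$chrom && g$start < ch$last_pos + 1L &&
                  ch$first_pos < g$end)
  }
})

test_that("term sets plant foreground-heavy enriched terms deterministically", {
  cfg <- tiny_config(16)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_synthetic_study(cfg, d1)
  s2 <- generate_synthetic_study(cfg, d2)
  expect_identical(readLines(file.path(d1, "terms.gmt")),
                   readLines(file.path(d2, "terms.gmt")))
  fg <- s1$genes_deg$deg$gene_id
  for (tid in s1$terms$enriched_term_ids) {
    members <- s1$terms$term_sets[[tid]]
    expect_gte(mean(members %in% fg), 0.8 - 1e-9)
  }
})
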