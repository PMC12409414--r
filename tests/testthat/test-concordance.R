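vt <- function(pos, chrom = "chr1") {
  data.table(rsid = sprintf("rs%04d", seq_along(pos)), chrom = chrom, pos = as.integer(pos))
}

test_that("cluster_variants chains within the gap and filters by size", {
  # chains {100,4000,8000} and {20000}; both below 10 members -> none retained
  cl <- cluster_variants(vt(c(100, 4000, 8000, 20000)))
  expect_equal(nrow(cl$clusters), 0L)
  # with a lenient size threshold the chain structure is visible
  cl2 <- cluster_variants(vt(c(100, 4000, 8000, 20000)), min_size = 1L)
  expect_equal(cl2$clusters$n_snps, c(3L, 1L))

  # 10 variants spaced 1000 bp from 0: one cluster, span 9000
  cl3 <- cluster_variants(vt(seq(0, 9000, by = 1000)[1:10]))
  expect_equal(nrow(cl3$clusters), 1L)
  expect_equal(cl3$clusters$span_bp, 9000L)
  expect_equal(cl3$clusters$n_snps, 10L)

  expect_error(cluster_variants(vt(1), gap_bp = -1), "gap_bp")
})

test_that("single-linkage chaining equals union-find closure on random positions", {
  set.seed(17)
  for (rep in 1:10) {
    v <- unique(vt(sample.int(200000L, 300)), by = "pos")
    v$rsid <- sprintf("rs%04d", seq_len(nrow(v)))
    cl <- cluster_variants(v, gap_bp = 1000L, min_size = 3L)
    got <- lapply(split(cl$members$rsid, cl$members$cluster_id), sort)
    names(got) <- NULL
    oracle <- brute_cluster(v$chrom, v$pos, 1000L, 3L)
    want <- lapply(oracle, function(ix) sort(v$rsid[ix]))
    expect_setequal(got, want)
  }
})

test_that("clustering is order-invariant and idempotent", {
  set.seed(23)
  v <- unique(vt(sample.int(50000L, 120)), by = "pos")
  v$rsid <- sprintf("rs%04d", seq_len(nrow(v)))
  a <- cluster_variants(v, gap_bp = 2000L, min_size = 2L)
  b <- cluster_variants(v[sample.int(nrow(v))], gap_bp = 2000L, min_size = 2L)
  expect_equal(a$clusters, b$clusters)
  # re-clustering one cluster's members reproduces that cluster
  m1 <- a$members[cluster_id == a$clusters$cluster_id[1]]
  re <- cluster_variants(m1[, list(rsid, chrom, pos)], gap_bp = 2000L, min_size = 2L)
  expect_equal(nrow(re$clusters), 1L)
  expect_equal(re$clusters$first_pos, a$clusters$first_pos[1])
  expect_equal(re$clusters$last_pos, a$clusters$last_pos[1])
})

test_that("cluster-DEG overlap counts match constructed and brute-force cases", {
  clus <- data.table(cluster_id = "C0001", chrom = "chr1",
                     first_pos = 11000L, last_pos = 15000L)
  deg <- data.table(gene_id = "G1", chrom = "chr1", start = 10000L, end = 20000L)
  expect_equal(overlap_clusters_degs(clus, deg)$pairs,
               data.table(cluster_id = "C0001", gene_id = "G1"))
  clus2 <- data.table(cluster_id = "C0001", chrom = "chr1",
                      first_pos = 0L, last_pos = 100L)
  deg2 <- data.table(gene_id = "G1", chrom = "chr1", start = 200L, end = 300L)
  expect_equal(nrow(overlap_clusters_degs(clus2, deg2)$pairs), 0L)
  # inclusive cluster endpoint: last_pos touching gene start still overlaps
  clus3 <- data.table(cluster_id = "C0001", chrom = "chr1",
                      first_pos = 0L, last_pos = 200L)
  expect_equal(nrow(overlap_clusters_degs(clus3, deg2)$pairs), 1L)

  set.seed(41)
  for (rep in 1:10) {
    s <- sample.int(100000L, 100) - 1L
    cl <- data.table(cluster_id = sprintf("C%04d", 1:100),
                     chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                     first_pos = s, last_pos = s + sample.int(8000L, 100))
    g <- rand_genes(50)
    got <- overlap_clusters_degs(cl, g)
    want <- brute_cluster_deg_pairs(cl, g)
    setkeyv(want, c("cluster_id", "gene_id"))
    expect_equal(setkeyv(got$pairs, c("cluster_id", "gene_id")), want)
    expect_equal(got$unique_cluster_count, length(unique(want$cluster_id)))
    expect_equal(got$unique_deg_count, length(unique(want$gene_id)))
  }
})

test_that("variants_near_genes applies floored half-open windows", {
  g <- data.table(gene_id = "G1", chrom = "chr1", start = 10000L, end = 20000L)
  near <- function(p, w) {
    variants_near_genes(data.table(rsid = "rs1", chrom = "chr1", pos = p),
                        g, windows_bp = w)$unique_snp_count
  }
  expect_equal(near(65000L, 50000L), 1L)  # [0, 70000): counted, start floored
  expect_equal(near(70000L, 50000L), 0L)  # half-open right edge
  expect_equal(near(9999L, 0L), 0L)
  expect_equal(near(10000L, 0L), 1L)
})

test_that("window proximity counts equal brute force and are monotone", {
  set.seed(53)
  windows <- c(0L, 5000L, 20000L, 100000L)
  for (rep in 1:10) {
    v <- rand_variants(150)
    g <- rand_genes(40)
    res <- variants_near_genes(v, g, windows)
    for (i in seq_along(windows)) {
      want <- brute_near_counts(v, g, windows[i])
      expect_equal(res$unique_snp_count[i], want$n_snp)
      expect_equal(res$unique_deg_count[i], want$n_deg)
    }
    expect_true(all(diff(res$unique_snp_count) >= 0))
    expect_true(all(diff(res$unique_deg_count) >= 0))
  }
})

test_that("genes_near_contacts counts x of y with a fixed denominator", {
  g <- data.table(gene_id = "G1", chrom = "chr1", start = 10000L, end = 20000L,
                  strand = "+")
  cc <- data.table(chrom = "chr1", start = 25000L, end = 26000L)
  res <- genes_near_contacts(g, cc, windows_bp = c(0L, 50000L))
  expect_equal(res$x, c(0L, 1L))
  expect_equal(res$y, c(1L, 1L))
  # empty contact list: x = 0 everywhere
  res2 <- genes_near_contacts(g, cc[0], windows_bp = c(0L, 50000L))
  expect_equal(res2$x, c(0L, 0L))
  # random instance vs brute force, monotone in window
  set.seed(61)
  gg <- rand_genes(60); cx <- rand_intervals(30)
  windows <- c(0L, 2000L, 10000L, 50000L)
  res3 <- genes_near_contacts(gg, cx, windows)
  for (i in seq_along(windows)) {
    w <- windows[i]
    want <- sum(vapply(seq_len(nrow(gg)), function(k) {
      any(gg$chrom[k] == cx$chrom & gg$start[k] < cx$end + w &
            pmax(0L, cx$start - w) < gg$end[k])
    }, TRUE))
    expect_equal(res3$x[i], want)
  }
  expect_true(all(diff(res3$x) >= 0))
})
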