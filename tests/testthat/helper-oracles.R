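# Brute-force oracles and random-instance generators. Every oracle is a
# deliberately naive O(n*m) (or exhaustive) computation kept independent of
# the package's sweep-line / findOverlaps code paths.

library(data.table)

ov1 <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2 # >=1 bp overlap, half-open

# all-pairs loop classification; anchors orientation-agnostic, widened by
# `widen` bp on each side
brute_classify <- function(set_x, set_y, widen = 0L) {
  x <- as.data.frame(set_x); y <- as.data.frame(set_y)
  cls <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    anyA <- FALSE; full <- FALSE
    ax <- list(c(x$start1[i] - widen, x$end1[i] + widen),
               c(x$start2[i] - widen, x$end2[i] + widen))
    for (j in seq_len(nrow(y))) {
      if (x$chrom[i] != y$chrom[j]) next
      ay <- list(c(y$start1[j] - widen, y$end1[j] + widen),
                 c(y$start2[j] - widen, y$end2[j] + widen))
      m <- matrix(FALSE, 2, 2)
      for (p in 1:2) for (q in 1:2) {
        m[p, q] <- ov1(ax[[p]][1], ax[[p]][2], ay[[q]][1], ay[[q]][2])
      }
      if ((m[1, 1] && m[2, 2]) || (m[1, 2] && m[2, 1])) full <- TRUE
      if (any(m)) anyA <- TRUE
    }
    cls[i] <- if (full) "shared_loop" else if (anyA) "shared_single_anchor" else "unique"
  }
  cls
}

# all-pairs point-in-interval hit set
brute_map <- function(variants, contacts) {
  v <- as.data.frame(variants); cc <- as.data.frame(contacts)
  out <- list()
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(cc))) {
    if (v$chrom[i] == cc$chrom[j] && v$pos[i] >= cc$start[j] && v$pos[i] < cc$end[j]) {
      out[[length(out) + 1L]] <- data.table(rsid = v$rsid[i], chrom = cc$chrom[j],
                                            start = cc$start[j], end = cc$end[j])
    }
  }
  if (length(out)) unique(rbindlist(out)) else
    data.table(rsid = character(), chrom = character(), start = integer(), end = integer())
}

# union-find closure over all variant pairs within gap_bp on one chromosome
brute_cluster <- function(chrom, pos, gap_bp, min_size) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= gap_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  # path-compress fully
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  groups[vapply(groups, length, 0L) >= min_size]
}

# all-pairs cluster-gene overlap; cluster interval [first, last+1)
brute_cluster_deg_pairs <- function(clusters, genes) {
  out <- list()
  cl <- as.data.frame(clusters); g <- as.data.frame(genes)
  for (i in seq_len(nrow(cl))) for (j in seq_len(nrow(g))) {
    if (cl$chrom[i] == g$chrom[j] &&
        ov1(cl$first_pos[i], cl$last_pos[i] + 1L, g$start[j], g$end[j])) {
      out[[length(out) + 1L]] <- data.table(cluster_id = cl$cluster_id[i],
                                            gene_id = g$gene_id[j])
    }
  }
  if (length(out)) unique(rbindlist(out)) else
    data.table(cluster_id = character(), gene_id = character())
}

# all-pairs windowed variant/gene proximity counts
brute_near_counts <- function(variants, genes, w) {
  v <- as.data.frame(variants); g <- as.data.frame(genes)
  snps <- character(); degs <- character()
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(g))) {
    lo <- max(0L, g$start[j] - w); hi <- g$end[j] + w
    if (v$chrom[i] == g$chrom[j] && v$pos[i] >= lo && v$pos[i] < hi) {
      snps <- c(snps, v$rsid[i]); degs <- c(degs, g$gene_id[j])
    }
  }
  list(n_snp = length(unique(snps)), n_deg = length(unique(degs)))
}

# exhaustive hypergeometric upper tail by enumerating all draws (N <= 25)
enum_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K) # first K elements are the term
  hits <- apply(draws, 2, function(d) sum(d %in% in_term))
  mean(hits >= k)
}

# random instance generators --------------------------------------------

rand_loop_set <- function(n, label, chroms = c("chr1", "chr2"), max_pos = 200000L,
                          res = 1000L) {
  chrom <- sample(chroms, n, replace = TRUE)
  s1 <- sample.int(max_pos, n, replace = TRUE)
  s2 <- sample.int(max_pos, n, replace = TRUE)
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  hi[hi == lo] <- hi[hi == lo] + res
  dt <- data.table(loop_id = sprintf("%s%04d", label, seq_len(n)), chrom = chrom,
                   start1 = lo, end1 = lo + res, start2 = hi, end2 = hi + res,
                   resolution_bp = res, score = NA_real_, cell_label = label)
  loopvar:::as_loop_set(dt, label)
}

rand_variants <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L) {
  data.table(rsid = sprintf("rs%05d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(max_pos, n, replace = TRUE) - 1L)
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L,
                           max_len = 3000L) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(max_len, n, replace = TRUE))
}

rand_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.table(gene_id = sprintf("G%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(5000L, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE))
}

tiny_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L, chrom_length_bp = 4000000L,
                   n_loops_per_cell = 60L, n_sentinels = 12L,
                   n_control_sentinels = 6L, n_genes = 80L, n_terms = 15L,
                   planted_enriched_terms = 2L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
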