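#' Cluster candidate variants by single-linkage chaining
#'
#' Variants on the same chromosome are chained while the gap between
#' consecutive sorted positions is at most `gap_bp` (bedtools-merge
#' semantics); a gap above the threshold starts a new cluster. Clusters
#' with fewer than `min_size` members are discarded. The retained cluster
#' span is `last_pos - first_pos` (inclusive endpoints); for overlap tests
#' the cluster interval is `[first_pos, last_pos + 1)` in half-open
#' coordinates.
#'
#' @param candidates variant data.table (`rsid`, `chrom`, `pos`).
#' @param gap_bp maximum inter-variant gap within a cluster (default 5000).
#' @param min_size minimum members for a cluster to be retained (default 10).
#' @return list with `clusters` (cluster_id, chrom, first_pos, last_pos,
#'   span_bp, n_snps) and `members` (cluster_id, rsid, pos).
#' @export
cluster_variants <- function(candidates, gap_bp = 5000L, min_size = 10L) {
  if (gap_bp < 0 || min_size < 0) stop("gap_bp and min_size must be >= 0", call. = FALSE)
  dt <- as.data.table(candidates)[, list(rsid, chrom, pos)]
  setorder(dt, chrom, pos, rsid)
  if (nrow(dt)) {
    dt[, prov := paste0(chrom, "_", cumsum(c(TRUE, diff(pos) > gap_bp))), by = chrom]
  } else {
    dt[, prov := character()]
  }
  clus <- dt[, list(chrom = chrom[1], first_pos = min(pos), last_pos = max(pos),
                    n_snps = .N), by = prov]
  clus <- clus[n_snps >= min_size]
  setorder(clus, chrom, first_pos)
  clus[, cluster_id := if (.N) sprintf("C%04d", seq_len(.N)) else character(0)]
  clus[, span_bp := last_pos - first_pos]
  members <- merge(dt, clus[, list(prov, cluster_id)], by = "prov")
  members <- members[, list(cluster_id, rsid, chrom, pos)]
  setorder(members, cluster_id, pos, rsid)
  list(clusters = clus[, list(cluster_id, chrom, first_pos, last_pos, span_bp, n_snps)],
       members = members[])
}

#' Overlap retained variant clusters with differentially expressed genes
#'
#' A (cluster, gene) pair is counted when the cluster interval
#' `[first_pos, last_pos + 1)` intersects the gene body `[start, end)` by
#' at least one bp.
#'
#' @param clusters retained cluster table from [cluster_variants()].
#' @param deg_genes gene table restricted to DEGs (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @return list with `pairs` (cluster_id, gene_id), `unique_cluster_count`,
#'   `unique_deg_count`.
#' @export
overlap_clusters_degs <- function(clusters, deg_genes) {
  clus <- as.data.table(clusters); genes <- as.data.table(deg_genes)
  pairs <- vector("list", 0L)
  for (ch in intersect(unique(clus$chrom), unique(genes$chrom))) {
    cl <- clus[chrom == ch]; g <- genes[chrom == ch]
    ir_c <- IRanges::IRanges(cl$first_pos + 1L, cl$last_pos + 1L) # [first, last+1)
    ir_g <- IRanges::IRanges(g$start + 1L, g$end)
    h <- IRanges::findOverlaps(ir_c, ir_g, minoverlap = 1L)
    if (!length(h)) next
    pairs[[length(pairs) + 1L]] <- data.table(
      cluster_id = cl$cluster_id[S4Vectors::queryHits(h)],
      gene_id = g$gene_id[S4Vectors::subjectHits(h)]
    )
  }
  pairs <- if (length(pairs)) unique(rbindlist(pairs)) else
    data.table(cluster_id = character(), gene_id = character())
  setorder(pairs, cluster_id, gene_id)
  list(pairs = pairs[],
       unique_cluster_count = length(unique(pairs$cluster_id)),
       unique_deg_count = length(unique(pairs$gene_id)))
}

#' Count candidate variants within windows of differentially expressed genes
#'
#' For each window `w`, a variant is counted when its position falls in
#' `[gene.start - w, gene.end + w)` for at least one DEG, with the extended
#' start floored at zero. Window 0 means inside the gene body.
#'
#' @param candidates variant data.table (`rsid`, `chrom`, `pos`).
#' @param deg_genes gene table restricted to DEGs.
#' @param windows_bp non-negative windows in bp (default 0, 50 kb, 200 kb,
#'   1 Mb).
#' @return data.table with one row per window: `window_bp`,
#'   `unique_snp_count`, `unique_deg_count`.
#' @export
variants_near_genes <- function(candidates, deg_genes,
                                windows_bp = c(0L, 50000L, 200000L, 1000000L)) {
  if (any(windows_bp < 0)) stop("windows must be >= 0", call. = FALSE)
  genes <- as.data.table(deg_genes)
  out <- lapply(windows_bp, function(w) {
    ext <- genes[, list(gene_id, chrom,
                        start = pmax(0L, start - as.integer(w)),
                        end = end + as.integer(w))]
    mp <- map_variants_to_contacts(candidates, ext[, list(chrom, start, end)])
    # recover gene ids per hit interval for unique DEG counting
    hits <- merge(mp$hits, ext, by = c("chrom", "start", "end"),
                  allow.cartesian = TRUE)
    data.table(window_bp = as.integer(w),
               unique_snp_count = length(unique(hits$rsid)),
               unique_deg_count = length(unique(hits$gene_id)))
  })
  rbindlist(out)
}

#' Count DEGs within windows of differential-loop contacts
#'
#' For each window `w`, `x` is the number of distinct DEGs whose gene body
#' intersects some contact interval widened by `w` bp on each side (start
#' floored at zero). The denominator `y` is by default the fixed total
#' number of DEGs supplied; alternatively a window-dependent universe
#' (all supplied genes with a body within `w` of any contact, intersected
#' with the DEG list denominator semantics) can be selected.
#'
#' @param deg_genes gene table restricted to DEGs.
#' @param dll_contacts contact intervals of differential loops.
#' @param windows_bp windows in bp.
#' @param denominator `"fixed"` (default): y = number of DEGs supplied.
#' @return data.table with `window_bp`, `x` (DEGs near a contact), `y`
#'   (denominator).
#' @export
genes_near_contacts <- function(deg_genes, dll_contacts,
                                windows_bp = c(0L, 50000L, 200000L, 1000000L),
                                denominator = c("fixed")) {
  denominator <- match.arg(denominator)
  genes <- as.data.table(deg_genes)
  cont <- as.data.table(dll_contacts)
  y <- length(unique(genes$gene_id))
  out <- lapply(windows_bp, function(w) {
    x <- 0L
    if (nrow(cont) && nrow(genes)) {
      near <- logical(nrow(genes))
      for (ch in intersect(unique(genes$chrom), unique(cont$chrom))) {
        gi <- which(genes$chrom == ch)
        cc <- cont[chrom == ch]
        ir_g <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
        ir_c <- IRanges::IRanges(pmax(0L, cc$start - as.integer(w)) + 1L,
                                 cc$end + as.integer(w))
        near[gi] <- IRanges::overlapsAny(ir_g, ir_c, minoverlap = 1L)
      }
      x <- length(unique(genes$gene_id[near]))
    }
    data.table(window_bp = as.integer(w), x = x, y = y)
  })
  rbindlist(out)
}
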