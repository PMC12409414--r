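#' Strand-aware transcription start site of half-open gene bodies
#'
#' Plus strand: TSS = start; minus strand: TSS = end - 1 (the last base of
#' the 0-based half-open body).
#'
#' @param genes validated gene table.
#' @return integer vector of TSS positions, one per gene.
#' @export
gene_tss <- function(genes) {
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}

#' Assign the gene with the closest promoter to each loop
#'
#' The promoter window of a gene is `[TSS - flank, TSS + flank + 1)` in
#' half-open coordinates, with a strand-aware TSS (plus strand: gene start;
#' minus strand: `end - 1`). The distance from a loop to a gene is the
#' minimum over both anchors of the gap to the promoter window (0 when an
#' anchor intersects it). Each loop is assigned the single gene with
#' minimal distance; ties break to the lexicographically smallest
#' `gene_id`. Loops on chromosomes with no genes are unassigned.
#'
#' @param loops a `loop_set`.
#' @param genes validated gene table.
#' @param promoter_flank_bp promoter half-width around the TSS (default
#'   1000).
#' @return data.table with one row per assigned loop: `loop_id`,
#'   `gene_id`, `distance_bp`.
#' @export
assign_genes_to_loops <- function(loops, genes, promoter_flank_bp = 1000L) {
  dt <- as.data.table(loops)
  g <- as.data.table(genes)
  g[, tss := gene_tss(g)]
  g[, `:=`(pstart = pmax(0L, tss - as.integer(promoter_flank_bp)),
           pend = tss + as.integer(promoter_flank_bp) + 1L)]
  out <- vector("list", 0L)
  for (ch in unique(dt$chrom)) {
    gl <- g[chrom == ch]
    if (!nrow(gl)) next
    ll <- dt[chrom == ch]
    # distance matrix loop x gene: min over the two anchors of the gap to
    # the promoter window; scales fine at loop-call sizes
    for (i in seq_len(nrow(ll))) {
      d1 <- interval_gap(ll$start1[i], ll$end1[i], gl$pstart, gl$pend)
      d2 <- interval_gap(ll$start2[i], ll$end2[i], gl$pstart, gl$pend)
      d <- pmin(d1, d2)
      j <- order(d, gl$gene_id)[1]
      out[[length(out) + 1L]] <- data.table(loop_id = ll$loop_id[i],
                                            gene_id = gl$gene_id[j],
                                            distance_bp = d[j])
    }
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(loop_id = character(), gene_id = character(), distance_bp = integer())
  setorder(res, loop_id)
  res[]
}

#' Upper-tail hypergeometric p-value P(X >= k)
#'
#' Probability of drawing at least `k` genes of a term of size `K` when
#' sampling `n` genes from a universe of `N`, computed as an exact tail sum
#' in log space (via [stats::phyper]).
#'
#' @param k overlap observed; `K` term size; `n` foreground size; `N`
#'   universe size.
#' @param K,n,N see above.
#' @return upper-tail probability.
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric parameters", call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!(p > 0 & p <= 1))) stop("p-values must lie in (0,1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Term over-representation of a foreground gene list
#'
#' One hypergeometric upper-tail test per term of the foreground list
#' against the universe, BH-corrected; terms with zero universe overlap
#' (K = 0) are untestable and omitted. Results are sorted by adjusted then
#' raw p then term id, with a significance flag at `p_adj <= alpha`.
#'
#' @param foreground character vector of foreground gene ids (must be a
#'   subset of the universe).
#' @param universe character vector of universe gene ids.
#' @param term_sets named list of character vectors (e.g. from
#'   [read_gmt()]); member lists are intersected with the universe before
#'   testing.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.table with `term_id`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
enrich_terms <- function(foreground, universe, term_sets, alpha = 0.05) {
  foreground <- unique(foreground); universe <- unique(universe)
  extra <- setdiff(foreground, universe)
  if (length(extra)) {
    stop("foreground genes absent from universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  n <- length(foreground); N <- length(universe)
  rows <- lapply(names(term_sets), function(tid) {
    tg <- intersect(unique(term_sets[[tid]]), universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, foreground))
    data.table(term_id = tid, k = k, K = K, n = n, N = N,
               p_raw = hypergeometric_pvalue(k, K, n, N))
  })
  res <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (!nrow(res)) {
    return(data.table(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical()))
  }
  res[, p_adj := bh_adjust(p_raw)]
  res[, significant := p_adj <= alpha]
  setorder(res, p_adj, p_raw, term_id)
  res[]
}
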