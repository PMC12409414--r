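# Internal helpers shared across modules. All genomic intervals in memory are
# 0-based half-open [start, end); chromosome names are normalised to "chrN".

#' @importFrom data.table data.table as.data.table setorder setorderv := .N .SD fread fwrite rbindlist
#' @importFrom stats phyper pbinom p.adjust fisher.test chisq.test runif
#' @importFrom S4Vectors queryHits subjectHits
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "start", "end", "pos", "rsid", "gene_id", "loop_id",
  "chrom1", "start1", "end1", "chrom2", "start2", "end2",
  "is_sentinel", "ld_r2", "assoc_p", "sentinel_rsid", "trait",
  "cluster_id", "first_pos", "last_pos", "n_snps", "span_bp",
  "match_class", "matched_loop_id", "cell_label", "resolution_bp",
  "score", "strand", "log_fc", "p_adj", "is_deg", "term_id", "p_raw",
  "distance_bp", "n_members", "contact_id", "N", "prov", "tss",
  "pstart", "pend", "nfree", "slot_start", "idx_a", "idx_b", "zlo",
  "zhi", "significant", "a_loop", "b_loop", "a_side", "b_side",
  "overlap", "shared", "total_overlap", "b_chrom", "b_start", "side",
  "length_bp", "window_bp", "unique_snp_count", "unique_deg_count"
))

norm_chrom <- function(x) {
  x <- as.character(x)
  if (any(!nzchar(x))) stop("empty chromosome name", call. = FALSE)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

check_intervals <- function(chrom, start, end, what = "interval") {
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("%s %d violates 0 <= start < end (start=%s, end=%s)",
                 what, bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# gap in bp between half-open [a1,a2) and [b1,b2); 0 if they overlap or abut?
# No: abutting intervals ([0,5) and [5,9)) have gap 0 but do not overlap;
# overlap tests elsewhere require >= 1 bp intersection.
interval_gap <- function(a1, a2, b1, b2) {
  pmax(0L, pmax(b1 - a2, a1 - b2))
}

# >= 1 bp intersection between half-open intervals
intervals_overlap <- function(a1, a2, b1, b2) {
  a1 < b2 & b1 < a2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
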