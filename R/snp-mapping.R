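#' Select candidate variants by association and LD thresholds
#'
#' Sentinels are kept iff their association p-value is strictly below
#' `assoc_p_threshold`; LD proxies are kept iff their sentinel survives and
#' their r-squared to it is strictly above `ld_r2_threshold`. Both
#' inequalities are strict, matching the usual "p < 1e-5" / "r2 > 0.6"
#' candidate definitions.
#'
#' @param variants validated variant table (see [read_variant_table()]);
#'   proxies must carry `sentinel_rsid`.
#' @param assoc_p_threshold sentinel association threshold (default 1e-5).
#' @param ld_r2_threshold LD threshold for proxies (default 0.6).
#' @return list with `candidates` (data.table of retained variants),
#'   `sentinel_count` and `candidate_count`.
#' @export
select_candidates <- function(variants, assoc_p_threshold = 1e-5, ld_r2_threshold = 0.6) {
  dt <- as.data.table(variants)
  sent <- dt[is_sentinel == TRUE]
  prox <- dt[is_sentinel == FALSE]
  if (nrow(prox)) {
    missing_ref <- prox$rsid[is.na(prox$sentinel_rsid) |
                             !(prox$sentinel_rsid %in% sent$rsid)]
    if (length(missing_ref)) {
      stop("proxy references a missing sentinel: ", missing_ref[1], call. = FALSE)
    }
  }
  sent_keep <- sent[assoc_p < assoc_p_threshold]
  prox_keep <- prox[ld_r2 > ld_r2_threshold & sentinel_rsid %in% sent_keep$rsid]
  cand <- rbindlist(list(sent_keep, prox_keep), use.names = TRUE)
  setorder(cand, chrom, pos, rsid)
  list(candidates = cand[],
       sentinel_count = nrow(sent_keep),
       candidate_count = nrow(cand))
}

#' Map variants into loop contact regions (sweep line)
#'
#' Produces one hit for every (variant, contact) pair with the variant
#' position inside the half-open contact interval `[start, end)`. Uses a
#' per-chromosome binary-search sweep over sorted positions, so runtime is
#' O((n+m) log(n+m)) rather than all-pairs. A variant inside two
#' overlapping contacts yields two hits but one unique rsID.
#'
#' @param candidates variant data.table (needs `rsid`, `chrom`, `pos`).
#' @param contacts contact intervals (`chrom`, `start`, `end`).
#' @param cell_label label recorded on every hit.
#' @return list with `hits` (rsid, chrom, start, end, cell_label),
#'   `unique_snp_count`, `unique_contact_count`.
#' @export
map_variants_to_contacts <- function(candidates, contacts, cell_label = "A") {
  cand <- as.data.table(candidates)
  cont <- as.data.table(contacts)
  check_intervals(cont$chrom, cont$start, cont$end, "contact")
  hits <- vector("list", 0L)
  for (ch in intersect(unique(cand$chrom), unique(cont$chrom))) {
    v <- cand[chrom == ch][order(pos)]
    cc <- cont[chrom == ch]
    p <- v$pos
    # indices of sorted positions falling in [start, end): binary search on
    # both interval ends
    lo <- findInterval(cc$start - 0.5, p) + 1L
    hi <- findInterval(cc$end - 0.5, p)
    keep <- which(lo <= hi)
    if (!length(keep)) next
    idx <- sequence(hi[keep] - lo[keep] + 1L, from = lo[keep])
    ci <- rep(keep, hi[keep] - lo[keep] + 1L)
    hits[[length(hits) + 1L]] <- data.table(
      rsid = v$rsid[idx], chrom = ch,
      start = cc$start[ci], end = cc$end[ci], cell_label = cell_label
    )
  }
  hits <- if (length(hits)) rbindlist(hits) else
    data.table(rsid = character(), chrom = character(), start = integer(),
               end = integer(), cell_label = character())
  hits <- unique(hits)
  setorder(hits, chrom, start, end, rsid)
  list(hits = hits[],
       unique_snp_count = length(unique(hits$rsid)),
       unique_contact_count = nrow(unique(hits[, list(chrom, start, end)])))
}

#' Trait-versus-control contact enrichment (Fisher's exact test)
#'
#' Two-sided Fisher's exact test on the 2x2 table of in-contact /
#' not-in-contact counts for a trait of interest against a control trait.
#' The odds ratio is the sample cross-product (infinite on a zero
#' denominator), not the conditional MLE.
#'
#' @param hits_trait,total_trait in-contact and total variant counts for
#'   the trait of interest.
#' @param hits_control,total_control same for the control trait.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return list with `table_2x2`, `odds_ratio`, `p_value`, `method`.
#' @export
trait_enrichment_test <- function(hits_trait, total_trait, hits_control, total_control,
                                  method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (hits_trait > total_trait || hits_control > total_control) {
    stop("hits exceed totals", call. = FALSE)
  }
  if (total_trait <= 0 || total_control <= 0) stop("totals must be > 0", call. = FALSE)
  tab <- matrix(c(hits_trait, total_trait - hits_trait,
                  hits_control, total_control - hits_control),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("trait", "control"), c("in_contact", "not_in_contact")))
  p <- if (method == "fisher") {
    fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(table_2x2 = tab, odds_ratio = or, p_value = p, method = method)
}

#' Percentage of candidate variants falling in loop contacts
#'
#' @param unique_snp_hits distinct candidate variants with at least one
#'   contact hit.
#' @param total_candidates total distinct candidate variants.
#' @return list with `percent` (raw) and `percent_rounded` (nearest integer).
#' @export
fraction_in_contacts <- function(unique_snp_hits, total_candidates) {
  if (total_candidates <= 0) stop("total_candidates must be > 0", call. = FALSE)
  if (unique_snp_hits < 0 || unique_snp_hits > total_candidates) {
    stop("hits must lie in [0, total]", call. = FALSE)
  }
  pct <- 100 * unique_snp_hits / total_candidates
  list(percent = pct, percent_rounded = round(pct))
}
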