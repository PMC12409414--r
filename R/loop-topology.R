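#' Combine loop calls from several detection scales into one set
#'
#' Loop callers run at several resolutions (e.g. 1, 4 and 16 kb) can report
#' the same loop more than once. Loops with identical anchor coordinates are
#' collapsed to the record called at the smallest resolution, which carries
#' the most precise anchors.
#'
#' @param loop_sets list of `loop_set` objects for one cell state at
#'   different resolutions.
#' @param cell_label label for the combined set.
#' @return a single `loop_set` with unique anchor-coordinate loops.
#' @export
combine_resolutions <- function(loop_sets, cell_label = "A") {
  all <- rbindlist(lapply(loop_sets, as.data.table), use.names = TRUE, fill = TRUE)
  setorder(all, chrom, start1, end1, start2, end2, resolution_bp)
  out <- all[, .SD[1], by = list(chrom, start1, end1, start2, end2)]
  setorder(out, chrom, start1, end1, start2, end2)
  out[, loop_id := sprintf("L%05d", seq_len(.N))]
  out[, cell_label := cell_label]
  as_loop_set(out, cell_label)
}

# long table of anchors: one row per (loop, side), side in {"L","R"}
anchor_table <- function(loops) {
  dt <- as.data.table(loops)
  rbindlist(list(
    dt[, list(loop_id, chrom, start = start1, end = end1, side = "L")],
    dt[, list(loop_id, chrom, start = start2, end = end2, side = "R")]
  ))
}

# all (a_loop, b_loop) anchor overlaps between two anchor tables after
# widening each anchor by `widen` bp on each side; returns per-pair overlap
# flags for the four side pairings plus summed raw overlap width
anchor_overlap_pairs <- function(anch_a, anch_b, widen = 0L) {
  out <- vector("list", 0L)
  for (ch in intersect(unique(anch_a$chrom), unique(anch_b$chrom))) {
    a <- anch_a[chrom == ch]
    b <- anch_b[chrom == ch]
    # IRanges is 1-based closed; [start, end) widened by `widen` maps to
    # [start - widen + 1, end + widen]
    ir_a <- IRanges::IRanges(a$start - widen + 1L, a$end + widen)
    ir_b <- IRanges::IRanges(b$start - widen + 1L, b$end + widen)
    hits <- IRanges::findOverlaps(ir_a, ir_b, minoverlap = 1L)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(a$end[qi] + widen, b$end[si] + widen) -
      pmax(a$start[qi] - widen, b$start[si] - widen)
    out[[length(out) + 1L]] <- data.table(
      a_loop = a$loop_id[qi], a_side = a$side[qi],
      b_loop = b$loop_id[si], b_side = b$side[si],
      b_chrom = ch, b_start = b$start[si], overlap = ov
    )
  }
  if (!length(out)) {
    return(data.table(a_loop = character(), a_side = character(),
                      b_loop = character(), b_side = character(),
                      b_chrom = character(), b_start = integer(),
                      overlap = integer()))
  }
  rbindlist(out)
}

# classify the loops of `set_x` against `set_y` given the long pair table
# (columns a_* refer to set_x). Returns one DLL record per loop of set_x.
classify_one_side <- function(set_x, pairs, label) {
  dt <- as.data.table(set_x)
  rec <- data.table(loop_id = dt$loop_id, cell_label = label,
                    match_class = "unique", matched_loop_id = NA_character_)
  if (nrow(pairs)) {
    per <- pairs[, {
      ll <- any(a_side == "L" & b_side == "L"); rr <- any(a_side == "R" & b_side == "R")
      lr <- any(a_side == "L" & b_side == "R"); rl <- any(a_side == "R" & b_side == "L")
      list(shared = (ll && rr) || (lr && rl),
           total_overlap = sum(overlap),
           b_chrom = b_chrom[1], b_start = min(b_start))
    }, by = list(a_loop, b_loop)]
    shared <- per[shared == TRUE]
    if (nrow(shared)) {
      # best partner: maximal summed anchor overlap, ties to smallest (chrom, start)
      setorder(shared, a_loop, -total_overlap, b_chrom, b_start, b_loop)
      best <- shared[, .SD[1], by = a_loop]
      rec[match(best$a_loop, rec$loop_id),
          `:=`(match_class = "shared_loop", matched_loop_id = best$b_loop)]
    }
    partial <- setdiff(unique(per$a_loop), unique(per[shared == TRUE]$a_loop))
    if (length(partial)) {
      rec[match(partial, rec$loop_id), match_class := "shared_single_anchor"]
    }
  }
  rec[]
}

#' Classify loops of two cell states into shared / single-anchor / unique
#'
#' A loop in one set is `shared_loop` if some loop in the other set matches
#' on both anchors, `shared_single_anchor` if it is not fully shared but at
#' least one anchor matches an anchor of some loop in the other set, and
#' `unique` otherwise (a differential loop locus, DLL). Two anchors match
#' when their intervals overlap by at least one bp after widening each by
#' `slack_bins` times the smallest resolution present in either set
#' (`slack_bins = 0` requires raw >= 1 bp overlap). Anchor pairings are
#' orientation-agnostic: a left anchor may match a right anchor. A fully
#' shared loop records its best partner — the match with maximal summed
#' anchor overlap, ties broken by smallest (chrom, start).
#'
#' @param set_a,set_b canonicalised `loop_set` objects.
#' @param slack_bins non-negative integer widening factor.
#' @return list with elements `a` and `b`: one DLL record per loop
#'   (`loop_id`, `cell_label`, `match_class`, `matched_loop_id`), plus a
#'   `summary` data.table of per-class counts for each set.
#' @export
match_loops <- function(set_a, set_b, slack_bins = 0L) {
  if (slack_bins < 0) stop("slack_bins must be >= 0", call. = FALSE)
  dt_a <- as.data.table(set_a); dt_b <- as.data.table(set_b)
  if (any(dt_a$start1 > dt_a$start2) || any(dt_b$start1 > dt_b$start2)) {
    stop("loop sets must be canonicalized (left anchor start <= right anchor start)",
         call. = FALSE)
  }
  res_all <- c(dt_a$resolution_bp, dt_b$resolution_bp)
  widen <- if (length(res_all)) {
    as.integer(slack_bins) * as.integer(min(res_all, na.rm = TRUE))
  } else 0L
  lab_a <- attr(set_a, "cell_label") %||% "A"
  lab_b <- attr(set_b, "cell_label") %||% "B"

  pairs_ab <- anchor_overlap_pairs(anchor_table(dt_a), anchor_table(dt_b), widen)
  rec_a <- classify_one_side(dt_a, pairs_ab, lab_a)
  pairs_ba <- pairs_ab[, list(a_loop = b_loop, a_side = b_side,
                              b_loop = a_loop, b_side = a_side, overlap)]
  # (chrom, start) of set A loops for tie-breaking from the B side
  key_a <- dt_a[, list(b_loop = loop_id, b_chrom = chrom, b_start = start1)]
  pairs_ba <- merge(pairs_ba, key_a, by = "b_loop", sort = FALSE)
  rec_b <- classify_one_side(dt_b, pairs_ba, lab_b)

  summ <- rbindlist(list(
    rec_a[, list(n = .N), by = list(cell_label, match_class)],
    rec_b[, list(n = .N), by = list(cell_label, match_class)]
  ))
  list(a = rec_a, b = rec_b, summary = summ)
}

#' Extract unique contact regions (loop anchors) from a loop set
#'
#' The multiset of all anchors reduced to unique intervals by exact
#' coordinates, sorted by position.
#'
#' @param loops a `loop_set`.
#' @return data.table with columns `chrom`, `start`, `end`.
#' @export
contact_regions <- function(loops) {
  anch <- anchor_table(as.data.table(loops))
  out <- unique(anch[, list(chrom, start, end)])
  setorder(out, chrom, start, end)
  out[]
}

#' Fraction of contact regions overlapping an annotation track
#'
#' @param contacts data.frame of intervals (`chrom`, `start`, `end`).
#' @param annotation data.frame of annotation intervals (e.g. ChromHMM
#'   enhancer states).
#' @return proportion of contacts overlapping at least one annotation
#'   interval by >= 1 bp.
#' @export
contact_annotation_fraction <- function(contacts, annotation) {
  contacts <- as.data.table(contacts); annotation <- as.data.table(annotation)
  if (nrow(contacts) == 0L) return(NaN)
  if (nrow(annotation) == 0L) return(0)
  hit <- logical(nrow(contacts))
  for (ch in unique(contacts$chrom)) {
    ci <- which(contacts$chrom == ch)
    ann <- annotation[chrom == ch]
    if (!nrow(ann)) next
    ir_c <- IRanges::IRanges(contacts$start[ci] + 1L, contacts$end[ci])
    ir_a <- IRanges::IRanges(ann$start + 1L, ann$end)
    hit[ci] <- IRanges::overlapsAny(ir_c, ir_a, minoverlap = 1L)
  }
  mean(hit)
}

#' Compare regional loop counts between two cell states
#'
#' Tests whether the number of loops (or contact regions) observed in a
#' genomic region differs between two cell states, treating each observed
#' loop as a Bernoulli draw between the states. The default is an exact
#' two-sided binomial test with success probability 0.5 on
#' `count_a + count_b` trials, two-sided p computed as twice the smaller
#' tail, capped at 1. A chi-square goodness-of-fit test against equal
#' expectation is available as an alternative.
#'
#' @param count_a,count_b non-negative loop counts, not both zero.
#' @param method `"binomial"` (default) or `"chisq"`.
#' @return two-sided p-value.
#' @export
region_loop_count_test <- function(count_a, count_b, method = c("binomial", "chisq")) {
  method <- match.arg(method)
  if (count_a < 0 || count_b < 0) stop("counts must be >= 0", call. = FALSE)
  n <- count_a + count_b
  if (n == 0) stop("both counts zero: test undefined", call. = FALSE)
  if (method == "binomial") {
    k <- min(count_a, count_b)
    min(1, 2 * pbinom(k, n, 0.5))
  } else {
    suppressWarnings(chisq.test(c(count_a, count_b), p = c(0.5, 0.5))$p.value)
  }
}
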