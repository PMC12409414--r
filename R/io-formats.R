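#' Read chromatin loops from a BEDPE file
#'
#' Reads a 6+ column BEDPE file of intra-chromosomal loop calls. All
#' coordinates are taken as 0-based half-open, BED-native. Anchors are
#' canonicalised so that the left anchor starts at or before the right
#' anchor; exact duplicate rows (after canonicalisation) are collapsed and
#' the number of collapsed duplicates is recorded in the
#' `"duplicates_collapsed"` attribute of the result.
#'
#' @param path path to a BEDPE file (tab- or space-separated, no header).
#' @param resolution_bp loop-call resolution in bp recorded on every loop.
#' @param cell_label label for the cell state the calls come from.
#' @return a `loop_set`: a data.table with columns `loop_id`, `chrom`,
#'   `start1`, `end1`, `start2`, `end2`, `resolution_bp`, `score`,
#'   `cell_label`, one row per unique loop.
#' @export
read_loops <- function(path, resolution_bp, cell_label = "A") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    empty <- data.table(loop_id = character(), chrom = character(),
                        start1 = integer(), end1 = integer(),
                        start2 = integer(), end2 = integer(),
                        resolution_bp = integer(), score = numeric(),
                        cell_label = character())
    res <- as_loop_set(empty, cell_label)
    attr(res, "duplicates_collapsed") <- 0L
    return(res)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 6L) stop("BEDPE needs >= 6 columns, got ", ncol(dt), call. = FALSE)
  loops <- data.table(
    chrom1 = norm_chrom(dt[[1]]), start1 = as.integer(dt[[2]]), end1 = as.integer(dt[[3]]),
    chrom2 = norm_chrom(dt[[4]]), start2 = as.integer(dt[[5]]), end2 = as.integer(dt[[6]]),
    score  = if (ncol(dt) >= 7L) suppressWarnings(as.numeric(dt[[7]])) else NA_real_
  )
  bad <- which(is.na(loops$start1) | is.na(loops$end1) | is.na(loops$start2) | is.na(loops$end2))
  if (length(bad)) stop("malformed BEDPE row at line ", bad[1], call. = FALSE)
  bad <- which(loops$start1 >= loops$end1 | loops$start2 >= loops$end2)
  if (length(bad)) stop("start >= end in BEDPE row at line ", bad[1], call. = FALSE)
  bad <- which(loops$chrom1 != loops$chrom2)
  if (length(bad)) {
    stop("inter-chromosomal loop at line ", bad[1],
         " (", loops$chrom1[bad[1]], " vs ", loops$chrom2[bad[1]], "); only cis loops are supported",
         call. = FALSE)
  }
  # canonical anchor order: left anchor start <= right anchor start
  swap <- loops$start1 > loops$start2
  if (any(swap)) {
    tmp_s <- loops$start1[swap]; tmp_e <- loops$end1[swap]
    loops$start1[swap] <- loops$start2[swap]; loops$end1[swap] <- loops$end2[swap]
    loops$start2[swap] <- tmp_s; loops$end2[swap] <- tmp_e
  }
  out <- loops[, list(score = score[1]), by = list(chrom = chrom1, start1, end1, start2, end2)]
  ndup <- nrow(loops) - nrow(out)
  setorder(out, chrom, start1, end1, start2, end2)
  out[, loop_id := sprintf("L%05d", seq_len(.N))]
  out[, resolution_bp := as.integer(resolution_bp)]
  out[, cell_label := cell_label]
  data.table::setcolorder(out, c("loop_id", "chrom", "start1", "end1", "start2", "end2",
                                 "resolution_bp", "score", "cell_label"))
  res <- as_loop_set(out, cell_label)
  attr(res, "duplicates_collapsed") <- ndup
  res
}

#' Write a loop set to BEDPE
#'
#' @param loops a `loop_set` (see [read_loops()]).
#' @param path output path.
#' @export
write_loops <- function(loops, path) {
  stopifnot(is.data.frame(loops))
  out <- data.table(
    chrom1 = loops$chrom, start1 = loops$start1, end1 = loops$end1,
    chrom2 = loops$chrom, start2 = loops$start2, end2 = loops$end2,
    score = ifelse(is.na(loops$score), ".", as.character(loops$score))
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

as_loop_set <- function(dt, cell_label) {
  dt <- as.data.table(dt)
  if (anyDuplicated(dt$loop_id)) stop("duplicate loop_id within a loop set", call. = FALSE)
  check_intervals(dt$chrom, dt$start1, dt$end1, "left anchor of loop")
  check_intervals(dt$chrom, dt$start2, dt$end2, "right anchor of loop")
  if (any(dt$start1 > dt$start2)) stop("loop set not canonicalized: left anchor after right", call. = FALSE)
  cl <- class(dt)
  if (!"loop_set" %in% cl) class(dt) <- c("loop_set", cl)
  attr(dt, "cell_label") <- cell_label
  dt
}

#' Read a variant table
#'
#' Reads a TSV with header columns `rsid`, `chrom`, `pos`, `trait`,
#' `is_sentinel`, `assoc_p`, `ld_r2` and (optional but required for candidate
#' selection) `sentinel_rsid` linking each LD proxy to its sentinel.
#' Positions are 0-based by default; set `one_based = TRUE` for
#' dbSNP-style 1-based input, which is converted on read.
#'
#' @param path path to the TSV.
#' @param one_based logical; if `TRUE`, input positions are 1-based and are
#'   shifted down by one on read.
#' @return data.table of validated variant records sorted by (chrom, pos).
#' @export
read_variant_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  validate_variants(dt, one_based = one_based)
}

validate_variants <- function(dt, one_based = FALSE) {
  dt <- as.data.table(dt)
  need <- c("rsid", "chrom", "pos", "trait", "is_sentinel", "assoc_p", "ld_r2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"sentinel_rsid" %in% names(dt)) dt[, sentinel_rsid := NA_character_]
  dt[, chrom := norm_chrom(chrom)]
  dt[, pos := as.integer(pos)]
  if (one_based) dt[, pos := pos - 1L]
  dt[, is_sentinel := as.logical(is_sentinel)]
  if (anyDuplicated(dt$rsid)) {
    stop("duplicate rsID in variant table: ", dt$rsid[duplicated(dt$rsid)][1], call. = FALSE)
  }
  bad <- which(dt$ld_r2 < 0 | dt$ld_r2 > 1)
  if (length(bad)) stop("ld_r2 outside [0,1] for ", dt$rsid[bad[1]], call. = FALSE)
  bad <- which(!(dt$assoc_p > 0 & dt$assoc_p <= 1))
  if (length(bad)) stop("assoc_p outside (0,1] for ", dt$rsid[bad[1]], call. = FALSE)
  bad <- which(dt$is_sentinel & dt$ld_r2 != 1)
  if (length(bad)) stop("sentinel with ld_r2 != 1: ", dt$rsid[bad[1]], call. = FALSE)
  if (any(dt$pos < 0)) stop("negative variant position", call. = FALSE)
  setorder(dt, chrom, pos, rsid)
  dt[]
}

#' Write a variant table as TSV (0-based positions)
#' @param variants validated variant data.table.
#' @param path output path.
#' @export
write_variant_table <- function(variants, path) {
  data.table::fwrite(as.data.table(variants), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' TSV with header columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open gene bodies; strand `+` or `-`).
#' @param path path to the TSV.
#' @return validated data.table sorted by (chrom, start).
#' @export
read_gene_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  validate_genes(dt)
}

validate_genes <- function(dt) {
  dt <- as.data.table(dt)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dt[, chrom := norm_chrom(chrom)]
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  check_intervals(dt$chrom, dt$start, dt$end, "gene body")
  if (!all(dt$strand %in% c("+", "-"))) stop("invalid strand value in gene table", call. = FALSE)
  if (anyDuplicated(dt$gene_id)) stop("duplicate gene_id in gene table", call. = FALSE)
  setorder(dt, chrom, start, gene_id)
  dt[]
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log_fc`, `p_adj`.
#' @param path path to the TSV.
#' @return validated data.table.
#' @export
read_deg_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "log_fc", "p_adj")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("DEG table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(dt$p_adj > 0 & dt$p_adj <= 1)) stop("p_adj outside (0,1] in DEG table", call. = FALSE)
  dt[]
}

#' Read gene sets in GMT format
#'
#' One tab-separated line per set: name, description, then member gene ids.
#' @param path path to the GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields", call. = FALSE)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a chrom.sizes file
#' @param path two-column chromosome/length text file.
#' @return data.table with columns `chrom`, `length_bp`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  out <- data.table(chrom = norm_chrom(dt[[1]]), length_bp = as.integer(dt[[2]]))
  if (any(out$length_bp <= 0)) stop("non-positive chromosome length", call. = FALSE)
  out
}

#' @rdname read_chrom_sizes
#' @param genome data.table with columns `chrom`, `length_bp`.
#' @export
write_chrom_sizes <- function(genome, path) {
  data.table::fwrite(genome[, c("chrom", "length_bp")], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write intervals as BED3
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed3 <- function(intervals, path) {
  check_intervals(intervals$chrom, intervals$start, intervals$end, "BED interval")
  data.table::fwrite(as.data.table(intervals)[, list(chrom, start, end)], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read BED3 intervals
#' @param path path to a 3+ column BED file.
#' @return data.table with columns `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  out <- data.table(chrom = norm_chrom(dt[[1]]), start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]))
  check_intervals(out$chrom, out$start, out$end, "BED interval")
  setorder(out, chrom, start, end)
  out
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write the pipeline report as JSON
#'
#' Serialises a named list of per-stage counts and statistics to a single
#' schema-versioned JSON document. Round-trips losslessly through
#' [read_report()].
#'
#' @param results named list keyed by stage.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  stopifnot(is.list(results))
  check_ser <- function(x, key) {
    if (is.list(x)) {
      for (nm in names(x)) check_ser(x[[nm]], paste(key, nm, sep = "."))
    } else if (!(is.numeric(x) || is.character(x) || is.logical(x) || is.null(x))) {
      stop("unserializable value at key: ", key, call. = FALSE)
    }
  }
  for (nm in names(results)) check_ser(results[[nm]], nm)
  doc <- c(list(schema_version = REPORT_SCHEMA_VERSION), results)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
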