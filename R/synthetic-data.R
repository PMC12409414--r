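# Seeded synthetic study generator. Entities are laid out on an exclusive
# slot grid (slot width = the largest anchor resolution) so that planted
# relationships -- loop sharing, variant-in-anchor status, cluster
# membership, cluster-DEG overlap -- are exact by construction and recorded
# in a truth manifest that downstream stages must reproduce.

#' Build a validated synthetic-study configuration
#'
#' Defaults emulate a two-cell-state loop study at desk scale: loop calls at
#' 1/4/16 kb with a small shared fraction (most loops unique to one state,
#' as in differentiated-versus-precursor comparisons), sentinel variants
#' with LD-proxy clouds whose r-squared straddles the 0.6 candidate
#' threshold, a control trait with a lower in-anchor rate, gene bodies with
#' strand-aware TSSs, a DEG subset, and gene sets with a few planted
#' enriched terms.
#'
#' @param seed integer RNG seed; all draws flow from this single seed.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param anchor_resolutions_bp distinct positive loop-call resolutions.
#' @param n_loops_per_cell loops per cell state.
#' @param frac_shared_loops fraction of loops fully shared between states.
#' @param frac_shared_single_anchor fraction sharing exactly one anchor.
#' @param n_sentinels,proxies_per_sentinel trait-variant structure.
#' @param frac_cluster_sentinels fraction of sentinels whose proxy cloud is
#'   packed within +-2 kb (dense, clusterable); the rest spread over
#'   `proxy_window_bp`.
#' @param ld_r2_distribution uniform bounds for proxy r-squared; should
#'   straddle 0.6 so the strict threshold is exercised.
#' @param proxy_window_bp half-width of the sparse proxy window.
#' @param frac_sentinel_in_anchor fraction of trait sentinels planted inside
#'   a loop anchor of cell state A.
#' @param n_control_sentinels,frac_control_in_anchor disjoint control-trait
#'   sentinels with a (lower) planted in-anchor rate.
#' @param n_genes,frac_deg gene universe size and DEG fraction.
#' @param n_terms,planted_enriched_terms gene-set structure; planted terms
#'   draw >= 80 percent of members from the foreground (DEG) list.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 4L,
                             chrom_length_bp = 10000000L,
                             anchor_resolutions_bp = c(1000L, 4000L, 16000L),
                             n_loops_per_cell = 300L,
                             frac_shared_loops = 0.10,
                             frac_shared_single_anchor = 0.05,
                             n_sentinels = 40L,
                             proxies_per_sentinel = 12L,
                             frac_cluster_sentinels = 0.4,
                             ld_r2_distribution = c(0.4, 1.0),
                             proxy_window_bp = 50000L,
                             frac_sentinel_in_anchor = 0.2,
                             n_control_sentinels = 20L,
                             frac_control_in_anchor = 0.05,
                             n_genes = 300L,
                             frac_deg = 0.25,
                             n_terms = 40L,
                             planted_enriched_terms = 4L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              anchor_resolutions_bp = as.integer(anchor_resolutions_bp),
              n_loops_per_cell = as.integer(n_loops_per_cell),
              frac_shared_loops = frac_shared_loops,
              frac_shared_single_anchor = frac_shared_single_anchor,
              n_sentinels = as.integer(n_sentinels),
              proxies_per_sentinel = as.integer(proxies_per_sentinel),
              frac_cluster_sentinels = frac_cluster_sentinels,
              ld_r2_distribution = ld_r2_distribution,
              proxy_window_bp = as.integer(proxy_window_bp),
              frac_sentinel_in_anchor = frac_sentinel_in_anchor,
              n_control_sentinels = as.integer(n_control_sentinels),
              frac_control_in_anchor = frac_control_in_anchor,
              n_genes = as.integer(n_genes), frac_deg = frac_deg,
              n_terms = as.integer(n_terms),
              planted_enriched_terms = as.integer(planted_enriched_terms))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  fracs <- c(cfg$frac_shared_loops, cfg$frac_shared_single_anchor,
             cfg$frac_cluster_sentinels, cfg$frac_sentinel_in_anchor,
             cfg$frac_control_in_anchor, cfg$frac_deg)
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: all proportions must lie in [0,1]", call. = FALSE)
  }
  if (cfg$frac_shared_loops + cfg$frac_shared_single_anchor > 1) {
    stop("configuration error: frac_shared_loops + frac_shared_single_anchor > 1",
         call. = FALSE)
  }
  counts <- c(cfg$n_chromosomes, cfg$n_loops_per_cell, cfg$n_sentinels,
              cfg$proxies_per_sentinel, cfg$n_control_sentinels, cfg$n_genes,
              cfg$n_terms, cfg$planted_enriched_terms)
  if (any(counts < 0)) stop("configuration error: counts must be >= 0", call. = FALSE)
  res <- cfg$anchor_resolutions_bp
  if (any(res <= 0) || anyDuplicated(res)) {
    stop("configuration error: resolutions must be positive and distinct", call. = FALSE)
  }
  if (cfg$n_chromosomes > 0 && cfg$chrom_length_bp <= 0) {
    stop("configuration error: non-positive chromosome length", call. = FALSE)
  }
  if (cfg$n_terms < cfg$planted_enriched_terms) {
    stop("configuration error: n_terms < planted_enriched_terms", call. = FALSE)
  }
  if (length(cfg$ld_r2_distribution) != 2 ||
      any(cfg$ld_r2_distribution < 0 | cfg$ld_r2_distribution > 1) ||
      cfg$ld_r2_distribution[1] > cfg$ld_r2_distribution[2]) {
    stop("configuration error: ld_r2_distribution must be bounds within [0,1]",
         call. = FALSE)
  }
  if (cfg$proxy_window_bp >= cfg$chrom_length_bp) {
    stop("configuration error: proxy_window_bp must be smaller than the chromosome",
         call. = FALSE)
  }
  invisible(cfg)
}

# integer apportionment: exact totals, no drift
largest_remainder <- function(n, fracs) {
  exact <- n * fracs
  base <- floor(exact)
  rem <- round(n * sum(fracs)) - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate the synthetic genome (chromosome sizes)
#'
#' @param config a `synthetic_config`.
#' @return data.table with columns `chrom`, `length_bp`.
#' @export
generate_genome <- function(config) {
  validate_synthetic_config(config)
  if (config$n_chromosomes == 0L) {
    return(data.table(chrom = character(), length_bp = integer()))
  }
  data.table(chrom = paste0("chr", seq_len(config$n_chromosomes)),
             length_bp = rep(config$chrom_length_bp, config$n_chromosomes))
}

# shuffled registry of exclusive slots (slot width = max resolution)
make_slot_registry <- function(config, genome) {
  slot <- max(config$anchor_resolutions_bp)
  reg <- rbindlist(lapply(seq_len(nrow(genome)), function(i) {
    n_slots <- genome$length_bp[i] %/% slot
    data.table(chrom = genome$chrom[i],
               slot_start = as.integer((seq_len(n_slots) - 1L) * slot))
  }))
  reg[sample.int(nrow(reg))]
}

pop_slots <- function(state, ch, k) {
  idx <- which(state$free$chrom == ch)[seq_len(k)]
  if (anyNA(idx)) stop("internal: slot underflow on ", ch, call. = FALSE)
  out <- state$free[idx]
  state$free <- state$free[-idx]
  list(slots = out, state = state)
}

#' Generate the two loop sets with planted sharing structure
#'
#' Class counts (fully shared / single-shared-anchor / unique per set) are
#' realised exactly by largest-remainder apportionment. Anchors are aligned
#' to a per-loop resolution drawn from the configured scales and placed in
#' exclusive grid slots, so fully shared loops have identical coordinates,
#' single-anchor pairs share exactly one anchor, and no other anchors
#' overlap.
#'
#' @param config a `synthetic_config`.
#' @param genome output of [generate_genome()].
#' @return list with `set_a`, `set_b` (`loop_set` objects), `truth`
#'   (per-loop class table) and the remaining free-slot registry in
#'   `free_slots`.
#' @export
generate_loop_sets <- function(config, genome) {
  validate_synthetic_config(config)
  n <- config$n_loops_per_cell
  counts <- largest_remainder(n, c(config$frac_shared_loops,
                                   config$frac_shared_single_anchor))
  n_shared <- counts[1]; n_single <- counts[2]
  n_unique <- n - n_shared - n_single
  slot <- max(config$anchor_resolutions_bp)
  state <- list(free = make_slot_registry(config, genome))
  slots_needed <- 2L * n_shared + 3L * n_single + 2L * 2L * n_unique
  if (slots_needed > nrow(state$free)) {
    stop(sprintf(paste0("generation error: %d loops need %d anchor slots but the ",
                        "genome provides %d (binding constraint: chromosome length / ",
                        "max resolution)"),
                 n, slots_needed, nrow(state$free)), call. = FALSE)
  }

  res_of <- function(k) sample(config$anchor_resolutions_bp, k, replace = TRUE)
  pick_chrom <- function(k) {
    tab <- state$free[, list(nfree = .N), by = chrom][nfree >= k]
    if (!nrow(tab)) stop("generation error: no chromosome has ", k,
                         " free anchor slots left", call. = FALSE)
    tab$chrom[sample.int(nrow(tab), 1L)]
  }
  mk_anchor <- function(slots, res) {
    data.table(chrom = slots$chrom, start = slots$slot_start,
               end = slots$slot_start + as.integer(res))
  }
  rows_a <- list(); rows_b <- list(); truth <- list()
  add_loop <- function(lst, ch, a1, a2, res) {
    # canonical order by anchor start
    if (a1$start > a2$start) { tmp <- a1; a1 <- a2; a2 <- tmp }
    c(lst, list(data.table(chrom = ch, start1 = a1$start, end1 = a1$end,
                           start2 = a2$start, end2 = a2$end,
                           resolution_bp = as.integer(res))))
  }

  for (i in seq_len(n_shared)) {
    ch <- pick_chrom(2L); pk <- pop_slots(state, ch, 2L); state <- pk$state
    res <- res_of(1L)
    a <- mk_anchor(pk$slots[1], res); b <- mk_anchor(pk$slots[2], res)
    rows_a <- add_loop(rows_a, ch, a, b, res)
    rows_b <- add_loop(rows_b, ch, a, b, res)
    truth <- c(truth, list(data.table(idx_a = length(rows_a), idx_b = length(rows_b),
                                      class = "shared_loop")))
  }
  for (i in seq_len(n_single)) {
    ch <- pick_chrom(3L); pk <- pop_slots(state, ch, 3L); state <- pk$state
    res <- res_of(1L)
    shared_anchor <- mk_anchor(pk$slots[1], res)
    other_a <- mk_anchor(pk$slots[2], res_of(1L))
    other_b <- mk_anchor(pk$slots[3], res_of(1L))
    rows_a <- add_loop(rows_a, ch, shared_anchor, other_a, res)
    rows_b <- add_loop(rows_b, ch, shared_anchor, other_b, res)
    truth <- c(truth, list(data.table(idx_a = length(rows_a), idx_b = length(rows_b),
                                      class = "shared_single_anchor")))
  }
  for (i in seq_len(n_unique)) {
    ch <- pick_chrom(2L); pk <- pop_slots(state, ch, 2L); state <- pk$state
    res <- res_of(1L)
    rows_a <- add_loop(rows_a, ch, mk_anchor(pk$slots[1], res),
                       mk_anchor(pk$slots[2], res), res)
    truth <- c(truth, list(data.table(idx_a = length(rows_a), idx_b = NA_integer_,
                                      class = "unique_A")))
  }
  for (i in seq_len(n_unique)) {
    ch <- pick_chrom(2L); pk <- pop_slots(state, ch, 2L); state <- pk$state
    res <- res_of(1L)
    rows_b <- add_loop(rows_b, ch, mk_anchor(pk$slots[1], res),
                       mk_anchor(pk$slots[2], res), res)
    truth <- c(truth, list(data.table(idx_a = NA_integer_, idx_b = length(rows_b),
                                      class = "unique_B")))
  }

  finish <- function(rows, label) {
    dt <- if (length(rows)) rbindlist(rows) else
      data.table(chrom = character(), start1 = integer(), end1 = integer(),
                 start2 = integer(), end2 = integer(), resolution_bp = integer())
    dt[, loop_id := sprintf("%s_L%04d", label, seq_len(.N))]
    dt[, score := NA_real_]
    dt[, cell_label := label]
    data.table::setcolorder(dt, c("loop_id", "chrom", "start1", "end1",
                                  "start2", "end2", "resolution_bp", "score",
                                  "cell_label"))
    as_loop_set(dt, label)
  }
  set_a <- finish(rows_a, "A"); set_b <- finish(rows_b, "B")
  tr <- rbindlist(truth)
  class_tbl <- rbindlist(list(
    tr[!is.na(idx_a), list(cell_label = "A", loop_id = set_a$loop_id[idx_a], class)],
    tr[!is.na(idx_b), list(cell_label = "B", loop_id = set_b$loop_id[idx_b],
                           class = sub("unique_B", "unique", sub("unique_A", "unique", class)))]
  ))
  class_tbl[cell_label == "A", class := sub("unique_A", "unique", class)]
  list(set_a = set_a, set_b = set_b,
       truth = class_tbl[], free_slots = state$free)
}

# place a sentinel group; returns positions (sentinel first) or NULL if it
# collides with an existing exclusion zone
place_group <- function(center, dense, n_proxies, proxy_window_bp, chrom_len, zones, ch) {
  half <- if (dense) 2000L else proxy_window_bp
  lo <- max(0L, center - half); hi <- min(chrom_len - 1L, center + half)
  avail <- setdiff(lo:hi, center)
  if (length(avail) < n_proxies) return(NULL)
  prox <- sort(sample(avail, n_proxies))
  pos <- c(center, prox)
  zlo <- min(pos) - 5000L; zhi <- max(pos) + 5000L
  zch <- zones[zones$chrom == ch, ]
  if (nrow(zch) && any(zch$zlo <= zhi & zlo <= zch$zhi)) return(NULL)
  pos
}

#' Generate sentinel and proxy variants with planted contact status
#'
#' Each sentinel receives `proxies_per_sentinel` proxies with r-squared
#' drawn uniformly from the configured bounds. A configurable fraction of
#' trait sentinels is placed inside loop anchors of cell state A; a
#' disjoint control-trait set is generated with its own (lower) in-anchor
#' rate. Dense ("cluster") sentinel clouds are packed within +-2 kb;
#' sparse clouds spread over the proxy window. All sentinel groups are kept
#' more than 5 kb apart so positional clusters never bridge groups.
#'
#' @param config a `synthetic_config`.
#' @param genome output of [generate_genome()].
#' @param loop_sets output of [generate_loop_sets()].
#' @return list with `variants` (validated table), `truth` (per-variant
#'   in-contact status and candidacy), `expected_clusters` (list of rsID
#'   vectors for retained clusters at the default thresholds, sorted by
#'   position).
#' @export
generate_variants <- function(config, genome, loop_sets) {
  validate_synthetic_config(config)
  contacts_a <- contact_regions(loop_sets$set_a)
  contacts_b <- contact_regions(loop_sets$set_b)
  chrom_len <- config$chrom_length_bp
  slot_bp <- max(config$anchor_resolutions_bp)
  zones <- data.table(chrom = character(), zlo = integer(), zhi = integer())
  free <- loop_sets$free_slots

  plant_set <- function(n_sent, frac_in_anchor, frac_dense, trait, id_prefix) {
    n_in <- largest_remainder(n_sent, frac_in_anchor)
    n_dense <- largest_remainder(n_sent, frac_dense)
    in_anchor <- sample(rep(c(TRUE, FALSE), c(n_in, n_sent - n_in)))
    dense <- sample(rep(c(TRUE, FALSE), c(n_dense, n_sent - n_dense)))
    rows <- list()
    for (i in seq_len(n_sent)) {
      placed <- NULL
      for (try in seq_len(200L)) {
        if (in_anchor[i]) {
          if (nrow(contacts_a) == 0L) {
            stop("generation error: in-anchor sentinels requested but set A has no anchors",
                 call. = FALSE)
          }
          j <- sample.int(nrow(contacts_a), 1L)
          ch <- contacts_a$chrom[j]
          center <- contacts_a$start[j] +
            sample.int(contacts_a$end[j] - contacts_a$start[j], 1L) - 1L
        } else {
          j <- sample.int(nrow(free), 1L)
          ch <- free$chrom[j]
          # mid-slot so the sentinel itself cannot touch any anchor
          center <- free$slot_start[j] + slot_bp %/% 2L
        }
        placed <- place_group(center, dense[i], config$proxies_per_sentinel,
                              config$proxy_window_bp, chrom_len, zones, ch)
        if (!is.null(placed)) break
      }
      if (is.null(placed)) {
        stop("generation error: could not place sentinel group without ",
             "duplicate positions or zone collisions; window too small or ",
             "genome too crowded", call. = FALSE)
      }
      zones <<- rbind(zones, data.table(chrom = ch, zlo = min(placed) - 5000L,
                                        zhi = max(placed) + 5000L))
      sid <- sprintf("%s%04d", id_prefix, i)
      n_p <- config$proxies_per_sentinel
      rows[[length(rows) + 1L]] <- data.table(
        rsid = c(sid, sprintf("%s_p%02d", sid, seq_len(n_p))),
        chrom = ch, pos = as.integer(placed), trait = trait,
        is_sentinel = c(TRUE, rep(FALSE, n_p)),
        assoc_p = c(10^-runif(1, 6, 12), 10^-runif(n_p, 1, 8)),
        ld_r2 = c(1, runif(n_p, config$ld_r2_distribution[1],
                           config$ld_r2_distribution[2])),
        sentinel_rsid = c(NA_character_, rep(sid, n_p))
      )
    }
    if (length(rows)) rbindlist(rows) else
      data.table(rsid = character(), chrom = character(), pos = integer(),
                 trait = character(), is_sentinel = logical(),
                 assoc_p = numeric(), ld_r2 = numeric(),
                 sentinel_rsid = character())
  }

  trait_v <- plant_set(config$n_sentinels, config$frac_sentinel_in_anchor,
                       config$frac_cluster_sentinels, "bone", "rsB")
  ctrl_v <- plant_set(config$n_control_sentinels, config$frac_control_in_anchor,
                      0, "control", "rsC")
  variants <- validate_variants(rbindlist(list(trait_v, ctrl_v)))

  in_any <- function(v, contacts) {
    out <- logical(nrow(v))
    for (ch in unique(v$chrom)) {
      vi <- which(v$chrom == ch)
      cc <- contacts[contacts$chrom == ch, ]
      if (!nrow(cc)) next
      out[vi] <- vapply(v$pos[vi], function(p) any(p >= cc$start & p < cc$end), TRUE)
    }
    out
  }
  truth <- data.table(
    rsid = variants$rsid, trait = variants$trait,
    in_contact_A = in_any(variants, contacts_a),
    in_contact_B = in_any(variants, contacts_b),
    is_candidate = variants$is_sentinel | variants$ld_r2 > 0.6
  )

  # expected retained clusters at the default thresholds, derived from the
  # planted group structure: groups are > 5 kb apart, so chaining happens
  # only within a group
  cand <- variants[truth$is_candidate[match(variants$rsid, truth$rsid)] &
                   variants$trait == "bone"]
  grp <- ifelse(cand$is_sentinel, cand$rsid, cand$sentinel_rsid)
  chains <- list()
  for (g in unique(grp)) {
    sub <- cand[grp == g][order(pos)]
    brk <- cumsum(c(TRUE, diff(sub$pos) > 5000L))
    for (s in split(seq_len(nrow(sub)), brk)) {
      if (length(s) >= 10L) {
        chains[[length(chains) + 1L]] <- list(
          chrom = sub$chrom[1], first_pos = min(sub$pos[s]),
          last_pos = max(sub$pos[s]), members = sort(sub$rsid[s]))
      }
    }
  }
  if (length(chains)) {
    ord <- order(vapply(chains, `[[`, "", "chrom"),
                 vapply(chains, `[[`, 0L, "first_pos"))
    chains <- chains[ord]
  }
  list(variants = variants, truth = truth, expected_clusters = chains,
       zones = zones)
}

#' Generate gene bodies and a DEG table with planted cluster overlaps
#'
#' Genes are strand-assigned uniformly and placed in exclusive grid slots;
#' for each expected retained variant cluster (up to the DEG budget) one
#' DEG body is planted over the cluster interval. Exactly
#' `round-by-largest-remainder(frac_deg * n_genes)` genes are flagged DEG,
#' with nonzero logFC and adjusted p below 0.05.
#'
#' @param config a `synthetic_config`.
#' @param genome output of [generate_genome()].
#' @param loop_sets output of [generate_loop_sets()] (for the free-slot
#'   registry).
#' @param variant_truth output of [generate_variants()] (for planted
#'   cluster-DEG overlaps); may be NULL to skip planting.
#' @return list with `genes`, `deg` (tables), `planted_overlap_pairs`
#'   (cluster index into `expected_clusters` -> gene_id).
#' @export
generate_genes_and_deg <- function(config, genome, loop_sets, variant_truth = NULL) {
  validate_synthetic_config(config)
  n <- config$n_genes
  n_deg <- largest_remainder(n, config$frac_deg)
  free <- loop_sets$free_slots
  zones <- if (!is.null(variant_truth)) variant_truth$zones else
    data.table(chrom = character(), zlo = integer(), zhi = integer())
  # genes avoid variant exclusion zones so only planted bodies touch clusters
  slot_bp <- max(config$anchor_resolutions_bp)
  if (nrow(zones)) {
    keep <- rep(TRUE, nrow(free))
    for (i in seq_len(nrow(free))) {
      z <- zones[zones$chrom == free$chrom[i], ]
      if (nrow(z) && any(z$zlo <= free$slot_start[i] + slot_bp &
                         free$slot_start[i] <= z$zhi)) keep[i] <- FALSE
    }
    free <- free[keep]
  }
  chains <- if (!is.null(variant_truth)) variant_truth$expected_clusters else list()
  n_planted <- min(length(chains), n_deg, n)
  if (n - n_planted > nrow(free)) {
    stop("generation error: n_genes exceeds placeable capacity (",
         nrow(free), " free slots)", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(n_planted)) {
    ch <- chains[[i]]
    rows[[length(rows) + 1L]] <- data.table(
      chrom = ch$chrom,
      start = max(0L, ch$first_pos - 500L),
      end = ch$last_pos + 501L)
  }
  n_rest <- n - n_planted
  if (n_rest > 0) {
    idx <- seq_len(n_rest)
    len_max <- max(2000L, as.integer(slot_bp * 0.75))
    len <- sample(2000:len_max, n_rest, replace = TRUE)
    off <- vapply(slot_bp - len, function(m) sample.int(m, 1L) - 1L, 0L)
    rows[[length(rows) + 1L]] <- data.table(
      chrom = free$chrom[idx],
      start = free$slot_start[idx] + off,
      end = free$slot_start[idx] + off + len)
  }
  genes <- rbindlist(rows)
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  genes[, gene_id := sprintf("G%04d", seq_len(.N))]
  planted_ids <- if (n_planted) genes$gene_id[seq_len(n_planted)] else character()

  # DEG flags: planted-overlap genes first, remainder drawn at random
  deg_ids <- planted_ids
  pool <- setdiff(genes$gene_id, planted_ids)
  extra <- n_deg - length(deg_ids)
  if (extra > 0) deg_ids <- c(deg_ids, sample(pool, extra))
  deg <- data.table(gene_id = sort(deg_ids))
  lfc <- numeric(nrow(deg))
  if (nrow(deg)) {
    lfc <- stats::rnorm(nrow(deg), 0, 2)
    lfc[lfc == 0] <- 0.1
  }
  deg[, `:=`(log_fc = lfc, p_adj = runif(.N, 1e-8, 0.049))]
  genes <- validate_genes(genes)
  pairs <- if (n_planted) {
    data.table(cluster_index = seq_len(n_planted), gene_id = planted_ids)
  } else data.table(cluster_index = integer(), gene_id = character())
  list(genes = genes, deg = deg[], planted_overlap_pairs = pairs)
}

#' Generate gene sets in GMT form with planted enrichment
#'
#' Planted enriched terms draw at least 80 percent of their members from
#' the foreground list (the DEG genes); background terms draw uniformly
#' from the universe.
#'
#' @param config a `synthetic_config`.
#' @param genes gene table (the universe).
#' @param foreground character vector of foreground gene ids.
#' @return list with `term_sets` (named list), `enriched_term_ids`.
#' @export
generate_term_sets <- function(config, genes, foreground) {
  validate_synthetic_config(config)
  universe <- genes$gene_id
  n_terms <- config$n_terms; n_plant <- config$planted_enriched_terms
  sets <- vector("list", n_terms)
  names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
  for (i in seq_len(n_terms)) {
    size <- sample(10:30, 1L)
    if (size > length(universe)) {
      stop("generation error: term size exceeds gene universe", call. = FALSE)
    }
    if (i <= n_plant) {
      # clamp so >= 80 percent of members can come from the foreground
      size <- max(2L, min(size, floor(length(foreground) / 0.8)))
      n_fg <- ceiling(0.8 * size)
      bg_pool <- setdiff(universe, foreground)
      n_bg <- min(size - n_fg, length(bg_pool))
      sets[[i]] <- sort(c(sample(foreground, n_fg), sample(bg_pool, n_bg)))
    } else {
      sets[[i]] <- sort(sample(universe, size))
    }
  }
  list(term_sets = sets,
       enriched_term_ids = names(sets)[seq_len(n_plant)])
}

#' Generate a full synthetic study and write every file plus the truth manifest
#'
#' Runs all generator stages under one seed and writes: `chrom.sizes`,
#' `loops_A.bedpe` / `loops_B.bedpe`, `variants.tsv`, `genes.tsv`,
#' `deg.tsv`, `terms.gmt` and `truth.json`. Regenerating with the same
#' configuration yields byte-identical files.
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all in-memory objects and the truth
#'   manifest.
#' @export
generate_synthetic_study <- function(config, out_dir) {
  validate_synthetic_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  genome <- generate_genome(config)
  loops <- generate_loop_sets(config, genome)
  vars <- generate_variants(config, genome, loops)
  gd <- generate_genes_and_deg(config, genome, loops, vars)
  terms <- generate_term_sets(config, gd$genes, gd$deg$gene_id)

  write_chrom_sizes(genome, file.path(out_dir, "chrom.sizes"))
  write_loops(loops$set_a, file.path(out_dir, "loops_A.bedpe"))
  write_loops(loops$set_b, file.path(out_dir, "loops_B.bedpe"))
  write_variant_table(vars$variants, file.path(out_dir, "variants.tsv"))
  data.table::fwrite(gd$genes, file.path(out_dir, "genes.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(gd$deg, file.path(out_dir, "deg.tsv"), sep = "\t", quote = FALSE)
  write_gmt(terms$term_sets, file.path(out_dir, "terms.gmt"))

  manifest <- list(
    seed = config$seed,
    loop_classes = loops$truth,
    snp_in_contact = vars$truth,
    expected_clusters = lapply(vars$expected_clusters, function(ch) {
      list(chrom = ch$chrom, first_pos = ch$first_pos, last_pos = ch$last_pos,
           members = ch$members)
    }),
    planted_cluster_deg_pairs = gd$planted_overlap_pairs,
    enriched_term_ids = terms$enriched_term_ids,
    foreground_genes = gd$deg$gene_id
  )
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(config = config, genome = genome, loops = loops,
                 variants = vars, genes_deg = gd, terms = terms,
                 manifest = manifest))
}
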