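#' Build a validated pipeline configuration
#'
#' Either `synthetic` is a [synthetic_config()] (inputs are generated under
#' `out_dir/synthetic`) or all five input paths are supplied. Thresholds
#' default to the study's printed parameters: 5000 bp cluster gap, minimum
#' 10 SNPs per cluster, r-squared > 0.6, p < 1e-5, concordance windows
#' 0/50/200/1000 kb, +-1 kb promoter flank, adjusted-p significance 0.05.
#'
#' @param out_dir output directory for stage tables and the JSON report.
#' @param synthetic optional [synthetic_config()].
#' @param loops_a,loops_b,variants,genes,deg,gmt input paths (ignored when
#'   `synthetic` is given).
#' @param resolution_bp loop-call resolution recorded on loops read from
#'   file.
#' @param trait,control_trait trait labels selecting the variant subsets.
#' @param gap_bp,min_cluster_size,ld_r2_threshold,assoc_p_threshold,windows_bp,promoter_flank_bp,slack_bins,alpha
#'   analysis thresholds.
#' @param seed RNG seed for the synthetic branch.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = NULL,
                            loops_a = NULL, loops_b = NULL, variants = NULL,
                            genes = NULL, deg = NULL, gmt = NULL,
                            resolution_bp = 1000L,
                            trait = "bone", control_trait = "control",
                            gap_bp = 5000L, min_cluster_size = 10L,
                            ld_r2_threshold = 0.6, assoc_p_threshold = 1e-5,
                            windows_bp = c(0L, 50000L, 200000L, 1000000L),
                            promoter_flank_bp = 1000L, slack_bins = 0L,
                            alpha = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  if (is.unsorted(windows_bp)) stop("windows must be sorted ascending", call. = FALSE)
  if (any(windows_bp < 0)) stop("windows must be >= 0", call. = FALSE)
  if (gap_bp < 0 || min_cluster_size < 0 || promoter_flank_bp < 0 || slack_bins < 0) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (is.null(synthetic)) {
    paths <- c(loops_a = loops_a, loops_b = loops_b, variants = variants,
               genes = genes, deg = deg, gmt = gmt)
    if (length(paths) < 6L) {
      stop("either `synthetic` or all six input paths must be given", call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full loop/variant/expression integration pipeline
#'
#' Stages run in dependency order: loop reading and cross-state
#' classification, differential-loop (DLL) contact extraction, candidate
#' selection, variant-to-contact mapping with trait-versus-control
#' enrichment, positional clustering, cluster/variant/gene concordance at
#' each window, and loop-anchored term over-representation. Every stage's
#' counts are collected into a single schema-versioned JSON report;
#' per-stage tables are written as TSV under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report list (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (!is.null(config$synthetic)) {
    syn_dir <- file.path(config$out_dir, "synthetic")
    syn <- generate_synthetic_study(config$synthetic, syn_dir)
    set_a <- syn$loops$set_a; set_b <- syn$loops$set_b
    variants <- syn$variants$variants
    genes <- syn$genes_deg$genes; deg <- syn$genes_deg$deg
    term_sets <- syn$terms$term_sets
  } else {
    set_a <- read_loops(config$loops_a, config$resolution_bp, "A")
    set_b <- read_loops(config$loops_b, config$resolution_bp, "B")
    variants <- read_variant_table(config$variants)
    genes <- read_gene_table(config$genes)
    deg <- read_deg_table(config$deg)
    term_sets <- read_gmt(config$gmt)
  }

  # -- loop topology ---------------------------------------------------
  dll <- match_loops(set_a, set_b, slack_bins = config$slack_bins)
  contacts_a <- contact_regions(set_a)
  contacts_b <- contact_regions(set_b)
  uniq_a <- as.data.table(set_a)[loop_id %in% dll$a[match_class == "unique"]$loop_id]
  dll_contacts <- if (nrow(uniq_a)) contact_regions(as_loop_set(uniq_a, "A")) else
    data.table(chrom = character(), start = integer(), end = integer())

  # -- candidate selection and contact mapping -------------------------
  sel_trait <- select_candidates(variants[trait == config$trait],
                                 config$assoc_p_threshold, config$ld_r2_threshold)
  sel_ctrl <- select_candidates(variants[trait == config$control_trait],
                                config$assoc_p_threshold, config$ld_r2_threshold)
  map_trait <- map_variants_to_contacts(sel_trait$candidates, contacts_a, "A")
  map_ctrl <- map_variants_to_contacts(sel_ctrl$candidates, contacts_a, "A")
  map_dll <- map_variants_to_contacts(sel_trait$candidates, dll_contacts, "A")
  frac <- if (sel_trait$candidate_count > 0) {
    fraction_in_contacts(map_trait$unique_snp_count, sel_trait$candidate_count)
  } else list(percent = NA_real_, percent_rounded = NA_real_)
  enr <- if (sel_trait$candidate_count > 0 && sel_ctrl$candidate_count > 0) {
    trait_enrichment_test(map_trait$unique_snp_count, sel_trait$candidate_count,
                          map_ctrl$unique_snp_count, sel_ctrl$candidate_count)
  } else NULL

  # -- clustering and concordance --------------------------------------
  cl <- cluster_variants(sel_trait$candidates, config$gap_bp, config$min_cluster_size)
  deg_genes <- genes[gene_id %in% deg$gene_id]
  ov <- overlap_clusters_degs(cl$clusters, deg_genes)
  vng <- variants_near_genes(sel_trait$candidates, deg_genes, config$windows_bp)
  gnc <- genes_near_contacts(deg_genes, dll_contacts, config$windows_bp)

  # -- loop-anchored enrichment ----------------------------------------
  assign_a <- assign_genes_to_loops(set_a, genes, config$promoter_flank_bp)
  assign_b <- assign_genes_to_loops(set_b, genes, config$promoter_flank_bp)
  universe <- union(assign_a$gene_id, assign_b$gene_id)
  foreground <- unique(assign_a$gene_id)
  enrich <- if (length(universe)) {
    enrich_terms(foreground, universe, term_sets, config$alpha)
  } else NULL

  # -- stage tables ----------------------------------------------------
  fw <- function(x, f) data.table::fwrite(x, file.path(config$out_dir, f),
                                          sep = "\t", quote = FALSE)
  fw(rbindlist(list(dll$a, dll$b)), "dll_records.tsv")
  write_bed3(dll_contacts, file.path(config$out_dir, "dll_contacts.bed"))
  fw(map_trait$hits, "contact_hits.tsv")
  fw(cl$clusters, "snp_clusters.tsv")
  fw(ov$pairs, "cluster_deg_pairs.tsv")
  if (!is.null(enrich)) fw(enrich, "term_enrichment.tsv")

  class_count <- function(rec, cls) sum(rec$match_class == cls)
  report <- list(
    seed = config$seed,
    loops = list(
      n_loops_a = nrow(set_a), n_loops_b = nrow(set_b),
      shared_loop_a = class_count(dll$a, "shared_loop"),
      shared_single_anchor_a = class_count(dll$a, "shared_single_anchor"),
      unique_a = class_count(dll$a, "unique"),
      shared_loop_b = class_count(dll$b, "shared_loop"),
      shared_single_anchor_b = class_count(dll$b, "shared_single_anchor"),
      unique_b = class_count(dll$b, "unique"),
      n_contacts_a = nrow(contacts_a), n_contacts_b = nrow(contacts_b),
      n_dll_contacts = nrow(dll_contacts)
    ),
    snp_mapping = list(
      sentinel_count = sel_trait$sentinel_count,
      candidate_count = sel_trait$candidate_count,
      unique_snps_in_contacts = map_trait$unique_snp_count,
      unique_contacts_with_snp = map_trait$unique_contact_count,
      unique_snps_in_dll_contacts = map_dll$unique_snp_count,
      unique_dll_contacts_with_snp = map_dll$unique_contact_count,
      percent_in_contacts = frac$percent,
      percent_in_contacts_rounded = frac$percent_rounded,
      control_candidate_count = sel_ctrl$candidate_count,
      control_unique_snps_in_contacts = map_ctrl$unique_snp_count,
      enrichment_odds_ratio = if (!is.null(enr)) enr$odds_ratio else NA,
      enrichment_p = if (!is.null(enr)) enr$p_value else NA
    ),
    clustering = list(
      n_clusters = nrow(cl$clusters),
      n_clustered_snps = nrow(cl$members),
      clusters_overlapping_deg = ov$unique_cluster_count,
      degs_overlapping_cluster = ov$unique_deg_count
    ),
    concordance = list(
      variants_near_degs = lapply(seq_len(nrow(vng)), function(i) as.list(vng[i])),
      degs_near_dll_contacts = lapply(seq_len(nrow(gnc)), function(i) as.list(gnc[i]))
    ),
    enrichment = list(
      n_terms_tested = if (!is.null(enrich)) nrow(enrich) else 0L,
      n_significant = if (!is.null(enrich)) sum(enrich$significant) else 0L,
      foreground_size = length(foreground),
      universe_size = length(universe)
    )
  )
  write_report(report, file.path(config$out_dir, "report.json"))
  invisible(report)
}
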