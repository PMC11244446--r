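## End-to-end orchestration: context statistics -> island detection ->
## viral classification -> silencing/reactivation analysis, on an input
## bundle (typically a simulated one; any bundle-shaped list of parsed
## inputs works).

#' Default pipeline parameters
#'
#' @param window_size_bp Window width for the non-CGC/GCG track.
#' @param theta Island-calling threshold.
#' @param max_gap_windows Bridgeable gap while merging flagged windows.
#' @param min_island_bp Minimum island length.
#' @param min_sites_per_window Window support floor.
#' @param subwindow_bp Boundary-refinement step.
#' @param promoter_bp Promoter length upstream of the TSS.
#' @param min_promoter_sites Promoter site floor for decile scoring.
#' @param fdr,lfc_min Differential-expression thresholds.
#' @param tpm_threshold Expression threshold for reactivation categories.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(window_size_bp = 10000L, theta = 0.4,
                            max_gap_windows = 1L, min_island_bp = 10000L,
                            min_sites_per_window = 10L, subwindow_bp = 1000L,
                            promoter_bp = 1000L, min_promoter_sites = 5L,
                            fdr = 0.01, lfc_min = 0, tpm_threshold = 1) {
  as.list(environment())
}

#' Run the full methylome-to-reactivation pipeline
#'
#' Steps: merge and classify the control methylome; spike-in conversion QC;
#' per-context weighted methylation and per-replicate treatment comparison;
#' windowed non-CGC/GCG track, island calling, boundary refinement and TE
#' annotation; island classification and contribution statistics; promoter
#' methylation deciles versus the differential-expression table;
#' reactivation categories and per-class summary; Fisher domain enrichment
#' of GEVE-island genes.
#'
#' @param bundle A `sim_bundle` (or an equally shaped list of parsed
#'   inputs; see [simulate_methylome()] for the components).
#' @param params See [pipeline_params()].
#' @return Named list of results tables.
#' @export
run_geve_pipeline <- function(bundle, params = pipeline_params()) {
  genome <- bundle$genome
  analysis <- genome[bundle$analysis_chroms]

  control_names <- names(bundle$meth_conditions)[
    bundle$meth_conditions == "control"]
  control <- merge_replicates(bundle$methylomes[control_names])
  control <- classify_sites(genome, control)

  qc <- conversion_qc(
    control[control$chrom == bundle$spike_unmethylated, , drop = FALSE],
    control[control$chrom == bundle$spike_methylated, , drop = FALSE])

  main <- control[control$chrom %in% bundle$analysis_chroms, , drop = FALSE]
  context_summary <- weighted_methylation(main)

  levels_by_cond <- split(
    vapply(names(bundle$methylomes), function(cond) {
      s <- bundle$methylomes[[cond]]
      s <- s[s$chrom %in% bundle$analysis_chroms, , drop = FALSE]
      global_cg_level(classify_sites(genome, s))
    }, numeric(1)),
    unname(bundle$meth_conditions))
  treatment_table <- compare_treatments(levels_by_cond)

  track <- window_track(main, analysis,
                        window_size_bp = params$window_size_bp,
                        min_sites_per_window = params$min_sites_per_window)
  islands <- call_islands(track, theta = params$theta,
                          max_gap_windows = params$max_gap_windows,
                          min_island_bp = params$min_island_bp)
  islands <- refine_boundaries(islands, main, analysis,
                               theta = params$theta,
                               subwindow_bp = params$subwindow_bp,
                               window_size_bp = params$window_size_bp,
                               min_island_bp = params$min_island_bp)
  islands <- annotate_secondary_te(islands, bundle$tes)

  features <- island_gene_features(islands, bundle$models, bundle$domains,
                                   bundle$catalog)
  classification <- classify_island(features, bundle$catalog)
  islands$class <- as.character(
    classification$class[match(islands$island_id,
                               classification$island_id)])
  contribution <- contribution_stats(classification, islands, analysis,
                                     bundle$models)
  census <- insertion_census(islands, bundle$placed_chroms,
                             bundle$unplaced_chroms)

  chrom_lengths <- nchar(analysis)
  promoters <- promoter_methylation(bundle$models, main,
                                    promoter_bp = params$promoter_bp,
                                    min_promoter_sites =
                                      params$min_promoter_sites,
                                    chrom_lengths = chrom_lengths)
  decile_table <- decile_response_table(promoters, bundle$de,
                                        fdr = params$fdr,
                                        lfc_min = params$lfc_min)

  categories <- reactivation_categories(bundle$expr, bundle$expr_groups,
                                        tpm_threshold =
                                          params$tpm_threshold)
  gene_classes <- .pipeline_gene_classes(islands, bundle$models, bundle$tes)
  reactivation <- reactivation_summary(categories, gene_classes)

  geve_ids <- gene_classes$gene_id[gene_classes$class == "GEVE"]
  island_gene_ids <- unique(
    genes_in_islands(islands, bundle$models)$gene_id)
  background <- union(geve_ids,
                      setdiff(bundle$models$genes$gene_id, island_gene_ids))
  enrichment <- fisher_domain_enrichment(bundle$domains, geve_ids,
                                         background)

  list(conversion_qc = qc,
       context_summary = context_summary,
       treatment_table = treatment_table,
       track = track,
       islands = islands,
       features = features,
       classification = classification,
       contribution = contribution,
       census = census,
       promoters = promoters,
       decile_table = decile_table,
       categories = categories,
       gene_classes = gene_classes,
       reactivation = reactivation,
       enrichment = enrichment,
       params = params)
}

## gene classification used for the reactivation summary: island class for
## genes inside detected islands, "TE_ORF" for genes contained in TE copies
.pipeline_gene_classes <- function(islands, models, tes) {
  assign <- genes_in_islands(islands, models)
  cls <- data.frame(gene_id = assign$gene_id,
                    class = islands$class[match(assign$island_id,
                                                islands$island_id)],
                    stringsAsFactors = FALSE)
  g <- models$genes
  outside <- g[!g$gene_id %in% cls$gene_id, , drop = FALSE]
  if (nrow(outside) > 0L && nrow(tes) > 0L) {
    ggr <- GenomicRanges::GRanges(outside$chrom,
                                  IRanges::IRanges(outside$start + 1L,
                                                   outside$end))
    tgr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1L, tes$end))
    hits <- GenomicRanges::findOverlaps(ggr, tgr, type = "within")
    te_genes <- unique(outside$gene_id[S4Vectors::queryHits(hits)])
    if (length(te_genes) > 0L) {
      cls <- rbind(cls, data.frame(gene_id = te_genes, class = "TE_ORF",
                                   stringsAsFactors = FALSE))
    }
  }
  cls[order(cls$gene_id), , drop = FALSE]
}

#' Evaluate pipeline results against simulation ground truth
#'
#' Base-level island precision, recall and Jaccard (over the analysis
#' contigs), island class accuracy (each truth island judged by its
#' maximum-overlap detected island), reactivation-category accuracy, and
#' whether the up-regulated fraction increases strictly over the top five
#' promoter-methylation deciles.
#'
#' @param results Output of [run_geve_pipeline()].
#' @param truth The `truth` component of a `sim_bundle`.
#' @return Named list of metrics.
#' @export
truth_eval <- function(results, truth) {
  det <- results$islands
  tru <- truth$islands
  dgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    det$chrom, IRanges::IRanges(det$start + 1L, det$end)))
  tgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tru$chrom, IRanges::IRanges(tru$start + 1L, tru$end)))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(dgr, tgr)))
  d_bp <- sum(GenomicRanges::width(dgr))
  t_bp <- sum(GenomicRanges::width(tgr))
  precision <- if (d_bp > 0) inter / d_bp else NA_real_
  recall <- if (t_bp > 0) inter / t_bp else 0
  jaccard <- if (d_bp + t_bp - inter > 0) {
    inter / (d_bp + t_bp - inter)
  } else NA_real_

  ## class accuracy over truth islands
  class_ok <- logical(nrow(tru))
  for (k in seq_len(nrow(tru))) {
    same <- det[det$chrom == tru$chrom[k], , drop = FALSE]
    if (nrow(same) == 0L) next
    ov <- pmin(same$end, tru$end[k]) - pmax(same$start, tru$start[k])
    if (max(ov) <= 0L) next
    class_ok[k] <- same$class[which.max(ov)] == tru$class[k]
  }
  class_accuracy <- mean(class_ok)

  m <- match(results$categories$gene_id, truth$genes$gene_id)
  if (anyNA(m)) stop("gene id mismatch between results and ground truth")
  category_accuracy <- mean(as.character(results$categories$category) ==
                              truth$genes$category[m])

  dt <- results$decile_table
  up_frac <- dt$up / pmax(1L, dt$up + dt$down + dt$not_de)
  top5_increasing <- all(diff(up_frac[6:10]) > 0)

  list(island_precision = precision, island_recall = recall,
       island_jaccard = jaccard, class_accuracy = class_accuracy,
       category_accuracy = category_accuracy,
       decile_up_fraction = up_frac,
       top5_increasing = top5_increasing)
}
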