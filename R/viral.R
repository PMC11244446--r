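## Classification of hypermethylated islands into GEVE / adintovirus /
## Plavaka / TE-rich / unclassified, from gene-architecture features and
## marker-gene evidence, plus genome/proteome contribution accounting.

ISLAND_CLASSES <- c("GEVE", "adintovirus", "plavaka", "te_rich",
                    "unclassified")

#' Default island classification thresholds
#'
#' Declared approximations, not recovered literature parameters:
#' endogenized giant-virus genes are intron-poor (`geve_max_mean_exons`),
#' complete adintovirus insertions are compact (`adinto_max_bp`; intact
#' copies run around 30 kb), and islands that are mostly TE bases without
#' viral markers are TE-rich (`te_rich_min_fraction`).
#'
#' @param geve_max_mean_exons Maximum mean exons/gene for the GEVE rule.
#' @param adinto_max_bp Maximum island length for the adintovirus rule.
#' @param te_rich_min_fraction Minimum TE base fraction for the TE-rich rule.
#' @return Named list of thresholds.
#' @export
classification_rules <- function(geve_max_mean_exons = 2,
                                 adinto_max_bp = 60000L,
                                 te_rich_min_fraction = 0.6) {
  list(geve_max_mean_exons = geve_max_mean_exons,
       adinto_max_bp = as.integer(adinto_max_bp),
       te_rich_min_fraction = te_rich_min_fraction)
}

#' Assign genes to islands
#'
#' A gene belongs to an island iff at least half of its span (`>= 50%`,
#' inclusive) overlaps the island.
#'
#' @param islands Island data.frame.
#' @param models A `gene_models` object.
#' @param min_overlap_fraction Overlap fraction threshold (default 0.5).
#' @return `data.frame` with `gene_id`, `island_id`.
#' @export
genes_in_islands <- function(islands, models, min_overlap_fraction = 0.5) {
  g <- models$genes
  if (nrow(islands) == 0L || nrow(g) == 0L) {
    return(data.frame(gene_id = character(0), island_id = character(0),
                      stringsAsFactors = FALSE))
  }
  ggr <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(g$start + 1L, g$end))
  igr <- GenomicRanges::GRanges(islands$chrom,
                                IRanges::IRanges(islands$start + 1L,
                                                 islands$end))
  hits <- GenomicRanges::findOverlaps(ggr, igr)
  if (length(hits) == 0L) {
    return(data.frame(gene_id = character(0), island_id = character(0),
                      stringsAsFactors = FALSE))
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ggr[qi], igr[si]))
  frac <- ov / GenomicRanges::width(ggr)[qi]
  keep <- frac >= min_overlap_fraction
  data.frame(gene_id = g$gene_id[qi][keep],
             island_id = islands$island_id[si][keep],
             stringsAsFactors = FALSE)
}

#' Gene-architecture and marker features per island
#'
#' Computes, per island: length, number of assigned genes, gene density per
#' 10 kb, mean exons per gene (`NA` and flagged when an island holds no
#' gene), the TE base fraction, and marker-gene hits per supported class
#' (the intersection of the domain-hit table with the marker catalog over
#' the island's genes).
#'
#' @param islands Island data.frame (with `te_fraction` when available).
#' @param models A `gene_models` object.
#' @param domains Domain-hits table.
#' @param catalog Marker catalog (see [read_marker_catalog()]).
#' @param min_overlap_fraction Gene-assignment threshold (default 0.5).
#' @return `data.frame`, one row per island: `island_id`, `length_bp`,
#'   `n_genes`, `gene_density_10kb`, `mean_exons_per_gene`, `te_fraction`,
#'   `marker_<class>` (hits on `required-any` catalog rows),
#'   `supporting_<class>` (hits on `supporting` rows), and a `genes_inside`
#'   list-column of gene ids.
#' @export
island_gene_features <- function(islands, models, domains, catalog,
                                 min_overlap_fraction = 0.5) {
  assign <- genes_in_islands(islands, models, min_overlap_fraction)
  g <- models$genes
  marker_hits <- merge(domains, catalog, by = "domain_accession")
  feats <- data.frame(island_id = islands$island_id,
                      length_bp = islands$end - islands$start,
                      stringsAsFactors = FALSE)
  feats$n_genes <- 0L
  feats$mean_exons_per_gene <- NA_real_
  feats$te_fraction <- if ("te_fraction" %in% names(islands)) {
    islands$te_fraction
  } else 0
  for (cl in c("GEVE", "adintovirus", "plavaka")) {
    feats[[paste0("marker_", cl)]] <- 0L
    feats[[paste0("supporting_", cl)]] <- 0L
  }
  feats$genes_inside <- vector("list", nrow(feats))
  for (k in seq_len(nrow(feats))) {
    gid <- assign$gene_id[assign$island_id == feats$island_id[k]]
    feats$genes_inside[[k]] <- gid
    feats$n_genes[k] <- length(gid)
    if (length(gid) > 0L) {
      feats$mean_exons_per_gene[k] <-
        mean(g$n_exons[match(gid, g$gene_id)])
    }
    mk <- marker_hits[marker_hits$gene_id %in% gid, , drop = FALSE]
    for (cl in c("GEVE", "adintovirus", "plavaka")) {
      feats[[paste0("marker_", cl)]][k] <-
        sum(mk$class == cl & mk$weight == "required-any")
      feats[[paste0("supporting_", cl)]][k] <-
        sum(mk$class == cl & mk$weight == "supporting")
    }
  }
  feats$gene_density_10kb <- feats$n_genes / (feats$length_bp / 1e4)
  feats
}

#' Classify islands
#'
#' First-match decision list, every evaluated rule logged:
#' \enumerate{
#'   \item any GEVE marker hit and `mean_exons_per_gene <=
#'     geve_max_mean_exons` -> `GEVE`;
#'   \item any adintovirus marker hit (DNA polymerase B / capsid set) and
#'     `length_bp <= adinto_max_bp` -> `adintovirus`;
#'   \item any Plavaka / tyrosine-recombinase marker hit -> `plavaka`;
#'   \item `te_fraction >= te_rich_min_fraction` with no viral marker ->
#'     `te_rich`;
#'   \item otherwise `unclassified`.
#' }
#'
#' @param features Output of [island_gene_features()].
#' @param catalog Marker catalog (must be non-empty).
#' @param rules See [classification_rules()].
#' @return `data.frame`: `island_id`, `class`, plus an `evidence` attribute
#'   (named list of per-island rule-evaluation logs).
#' @export
classify_island <- function(features, catalog,
                            rules = classification_rules()) {
  if (nrow(catalog) == 0L) stop("empty marker catalog")
  classes <- character(nrow(features))
  evidence <- vector("list", nrow(features))
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    log <- character(0)
    r1 <- !is.na(f$mean_exons_per_gene) && f$marker_GEVE > 0L &&
      f$mean_exons_per_gene <= rules$geve_max_mean_exons
    log <- c(log, sprintf(
      "rule1 GEVE: markers=%d mean_exons=%s -> %s", f$marker_GEVE,
      format(f$mean_exons_per_gene), r1))
    r2 <- f$marker_adintovirus > 0L && f$length_bp <= rules$adinto_max_bp
    log <- c(log, sprintf("rule2 adintovirus: markers=%d length=%d -> %s",
                          f$marker_adintovirus, f$length_bp, r2))
    r3 <- f$marker_plavaka > 0L
    log <- c(log, sprintf("rule3 plavaka: markers=%d -> %s",
                          f$marker_plavaka, r3))
    no_viral <- f$marker_GEVE == 0L && f$marker_adintovirus == 0L &&
      f$marker_plavaka == 0L && f$supporting_GEVE == 0L &&
      f$supporting_adintovirus == 0L && f$supporting_plavaka == 0L
    r4 <- no_viral && f$te_fraction >= rules$te_rich_min_fraction
    log <- c(log, sprintf("rule4 te_rich: te_fraction=%.3f no_viral=%s -> %s",
                          f$te_fraction, no_viral, r4))
    classes[k] <- if (r1) "GEVE" else if (r2) "adintovirus" else
      if (r3) "plavaka" else if (r4) "te_rich" else "unclassified"
    evidence[[k]] <- log
  }
  out <- data.frame(island_id = features$island_id,
                    class = factor(classes, levels = ISLAND_CLASSES),
                    stringsAsFactors = FALSE)
  names(evidence) <- features$island_id
  attr(out, "evidence") <- evidence
  out
}

#' Genome and proteome contribution of classified islands
#'
#' Per class and overall: island count, total bases, fraction of the
#' assembly, genes inside, fraction of all genes, and the insertion-size
#' median and interquartile range.
#'
#' @param classification Output of [classify_island()].
#' @param islands Island data.frame.
#' @param genome Named character vector (assembly to measure against; pass
#'   only the analysis contigs, e.g. without spike-in controls).
#' @param models A `gene_models` object.
#' @param min_overlap_fraction Gene-assignment threshold.
#' @return `data.frame` with one row per class plus `"all"`.
#' @export
contribution_stats <- function(classification, islands, genome, models,
                               min_overlap_fraction = 0.5) {
  genome_bp <- sum(nchar(genome))
  n_genes_total <- nrow(models$genes)
  assign <- genes_in_islands(islands, models, min_overlap_fraction)
  cls <- as.character(classification$class[
    match(islands$island_id, classification$island_id)])
  sizes <- islands$end - islands$start
  one_row <- function(label, sel) {
    n_genes <- length(unique(
      assign$gene_id[assign$island_id %in% islands$island_id[sel]]))
    data.frame(class = label,
               n_islands = sum(sel),
               total_bp = sum(sizes[sel]),
               pct_of_assembly = 100 * sum(sizes[sel]) / genome_bp,
               n_genes = n_genes,
               pct_of_genes = 100 * n_genes / n_genes_total,
               median_size_bp = if (any(sel)) stats::median(sizes[sel])
                                else NA_real_,
               iqr_size_bp = if (any(sel)) stats::IQR(sizes[sel])
                             else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(ISLAND_CLASSES, function(cl) one_row(cl, cls == cl))
  rows[[length(rows) + 1L]] <- one_row("all", rep(TRUE, nrow(islands)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Census of insertions by chromosome placement
#'
#' @param islands Island data.frame.
#' @param placed_chroms Ids of placed chromosomes.
#' @param unplaced_chroms Ids of unplaced contigs/scaffolds.
#' @return Named list `n_chromosomal`, `n_unplaced`.
#' @export
insertion_census <- function(islands, placed_chroms, unplaced_chroms) {
  unknown <- setdiff(unique(islands$chrom),
                     c(placed_chroms, unplaced_chroms))
  if (length(unknown) > 0L) {
    stop("island on sequence of unknown placement: ",
         paste(unknown, collapse = ", "))
  }
  list(n_chromosomal = sum(islands$chrom %in% placed_chroms),
       n_unplaced = sum(islands$chrom %in% unplaced_chroms))
}
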