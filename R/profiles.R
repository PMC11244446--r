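## Expression-stratified metagene profiles and TE methylation profiles.
## A profile bins each feature into fixed-bp flank bins and
## length-normalised body bins, oriented 5'->3' on the feature strand, and
## pools weighted methylation per bin across features.

#' Default metagene layout
#'
#' 2,000-bp flanks split into 20 bins each, 20 body bins. Chosen for stable
#' per-bin site counts on desk-scale genomes; every element is configurable.
#'
#' @param upstream_bp,downstream_bp Flank lengths in bp.
#' @param n_flank_bins Bins per flank.
#' @param n_body_bins Bins across the scaled feature body.
#' @return Named list with the four layout fields.
#' @export
profile_layout <- function(upstream_bp = 2000L, n_flank_bins = 20L,
                           n_body_bins = 20L, downstream_bp = 2000L) {
  stopifnot(upstream_bp > 0L, downstream_bp > 0L, n_flank_bins > 0L,
            n_body_bins > 0L)
  list(upstream_bp = as.integer(upstream_bp),
       n_flank_bins = as.integer(n_flank_bins),
       n_body_bins = as.integer(n_body_bins),
       downstream_bp = as.integer(downstream_bp))
}

#' Stratify genes by expression level
#'
#' Genes below `tpm_threshold` (strict `<`) form the `"not_expressed"`
#' stratum; the remaining genes are sorted by TPM (ties broken by gene id)
#' and split into `n_strata` equal-rank groups, ascending
#' (`expr_q1` lowest ... `expr_qK` highest).
#'
#' @param expr Expression table (`gene_id` + condition columns).
#' @param condition Condition column to stratify on.
#' @param n_strata Number of quantile strata for expressed genes (default
#'   terciles).
#' @param tpm_threshold Not-expressed cutoff (default 1 TPM, strict).
#' @return Named list of gene-id character vectors.
#' @export
stratify_genes_by_expression <- function(expr, condition, n_strata = 3L,
                                         tpm_threshold = 1) {
  if (nrow(expr) == 0L) stop("empty expression table")
  if (!condition %in% names(expr)) stop("unknown condition: ", condition)
  tpm <- expr[[condition]]
  out <- list(not_expressed = sort(expr$gene_id[tpm < tpm_threshold]))
  idx <- which(tpm >= tpm_threshold)
  o <- idx[order(tpm[idx], expr$gene_id[idx])]
  m <- length(o)
  for (k in seq_len(n_strata)) out[[paste0("expr_q", k)]] <- character(0)
  if (m > 0L) {
    stratum <- ceiling(seq_len(m) * n_strata / m)
    for (k in seq_len(n_strata)) {
      out[[paste0("expr_q", k)]] <- expr$gene_id[o[stratum == k]]
    }
  }
  out
}

## Per-feature bin assignment. d = signed distance from the feature 5' end
## along its orientation. Returns the 0-based bin index or NA.
.assign_bins <- function(d, len, layout) {
  up <- layout$upstream_bp; down <- layout$downstream_bp
  nf <- layout$n_flank_bins; nb <- layout$n_body_bins
  bin <- rep(NA_integer_, length(d))
  f <- d < 0 & d >= -up
  bin[f] <- floor((d[f] + up) * nf / up)
  b <- d >= 0 & d < len
  bin[b] <- nf + floor(d[b] * nb / len)
  g <- d >= len & d < len + down
  bin[g] <- nf + nb + floor((d[g] - len) * nf / down)
  bin
}

.profile_bin_labels <- function(layout) {
  nf <- layout$n_flank_bins; nb <- layout$n_body_bins
  c(paste0("up_", seq_len(nf)),
    paste0("body_", seq_len(nb)),
    paste0("down_", seq_len(nf)))
}

## Core pooled-binning engine shared by gene and TE profiles.
## features: data.frame(chrom, start, end, strand); "." strands profile as "+".
.pooled_profile <- function(features, sites, layout, context_filter,
                            stratum = "all") {
  nbins <- 2L * layout$n_flank_bins + layout$n_body_bins
  sum_meth <- numeric(nbins); sum_total <- numeric(nbins)
  n_sites <- integer(nbins)
  use <- !is.na(sites$context) & sites$context %in% context_filter
  s <- sites[use, , drop = FALSE]
  split_sites <- split(seq_len(nrow(s)), s$chrom)
  n_skipped <- 0L
  for (k in seq_len(nrow(features))) {
    chrom <- features$chrom[k]
    start <- features$start[k]; end <- features$end[k]
    len <- end - start
    if (len < layout$n_body_bins) {
      n_skipped <- n_skipped + 1L
      next
    }
    idx <- split_sites[[chrom]]
    if (is.null(idx)) next
    pos <- s$pos[idx]
    lo <- start - layout$upstream_bp - layout$downstream_bp
    hi <- end + layout$upstream_bp + layout$downstream_bp
    idx <- idx[pos >= lo & pos < hi]
    if (length(idx) == 0L) next
    pos <- s$pos[idx]
    d <- if (identical(features$strand[k], "-")) (end - 1L) - pos
         else pos - start
    bin <- .assign_bins(d, len, layout)
    ok <- !is.na(bin)
    if (!any(ok)) next
    bf <- factor(bin[ok], levels = 0:(nbins - 1L))
    sum_meth <- sum_meth + as.numeric(tapply(s$n_meth[idx][ok], bf, sum,
                                             default = 0))
    sum_total <- sum_total + as.numeric(tapply(s$n_total[idx][ok], bf, sum,
                                               default = 0))
    n_sites <- n_sites + as.integer(tapply(rep(1L, sum(ok)), bf, sum,
                                           default = 0L))
  }
  if (n_skipped > 0L) {
    message(n_skipped, " feature(s) shorter than n_body_bins skipped")
  }
  out <- data.frame(bin_index = seq_len(nbins),
                    bin_label = .profile_bin_labels(layout),
                    level = ifelse(sum_total > 0, sum_meth / sum_total,
                                   NA_real_),
                    n_sites = n_sites,
                    sum_meth = sum_meth,
                    sum_total = sum_total,
                    stringsAsFactors = FALSE)
  attr(out, "layout") <- layout
  attr(out, "stratum") <- stratum
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Metagene methylation profile
#'
#' Pools weighted methylation over all genes into a fixed layout: fixed-bp
#' flank bins around the TSS and TES and length-normalised body bins, with
#' minus-strand genes mirrored so the first bins are always the 5' end. Each
#' site lands in exactly one bin (half-open bin edges on the site's cytosine
#' position). Genes shorter than `n_body_bins` bp are skipped with a message.
#'
#' @param models A `gene_models` object.
#' @param sites Classified methylation sites.
#' @param layout See [profile_layout()].
#' @param context_filter Context classes pooled (default both CG classes).
#' @param gene_ids Optional subset of gene ids (e.g. one expression stratum).
#' @param stratum Label stored on the profile.
#' @return A `metagene_profile` data.frame: `bin_index`, `bin_label`,
#'   `level`, `n_sites`, `sum_meth`, `sum_total`.
#' @export
metagene_profile <- function(models, sites, layout = profile_layout(),
                             context_filter = c("CG_sym", "CG_other"),
                             gene_ids = NULL, stratum = "all") {
  g <- models$genes
  if (!is.null(gene_ids)) g <- g[g$gene_id %in% gene_ids, , drop = FALSE]
  .pooled_profile(g, sites, layout, context_filter, stratum)
}

#' TE methylation profile
#'
#' Same binning as [metagene_profile()] applied to TE copies, pooling both
#' strands and all families, after filtering to copies spanning at least
#' `min_span_fraction` of their consensus model.
#'
#' @param tes TE table (needs `consensus_span_fraction` unless the filter is
#'   disabled with `min_span_fraction = NULL`).
#' @param sites Classified methylation sites.
#' @param layout See [profile_layout()].
#' @param min_span_fraction Span-fraction floor, inclusive (default 0.7);
#'   `NULL` disables the filter.
#' @param context_filter Context classes pooled.
#' @return A `metagene_profile` data.frame.
#' @export
te_profile <- function(tes, sites, layout = profile_layout(),
                       min_span_fraction = 0.7,
                       context_filter = c("CG_sym", "CG_other")) {
  if (!is.null(min_span_fraction)) {
    if (any(is.na(tes$consensus_span_fraction))) {
      stop("consensus_span_fraction missing; cannot apply span filter")
    }
    tes <- tes[tes$consensus_span_fraction >= min_span_fraction, ,
               drop = FALSE]
    if (nrow(tes) == 0L) {
      stop("no TE copy passes the span filter (>= ", min_span_fraction, ")")
    }
  }
  tes$strand[!tes$strand %in% c("+", "-")] <- "+"
  .pooled_profile(tes, sites, layout, context_filter, stratum = "TE")
}

#' TE methylation versus sequence divergence
#'
#' Pools the CG weighted level over the sites inside TE copies of each
#' divergence bin; young (low-divergence) insertions are expected to be the
#' most methylated. Bins with fewer than `min_sites` contributing sites are
#' flagged (`low_support = TRUE`) and their level reported as computed.
#'
#' @param tes TE table with a `divergence` column.
#' @param sites Classified methylation sites.
#' @param divergence_breaks Numeric break vector for `cut()` (left-closed).
#' @param context_filter Context classes pooled.
#' @param min_sites Support flag threshold (default 50).
#' @return `data.frame`: `bin`, `n_tes`, `n_sites`, `level`, `low_support`.
#' @export
methylation_vs_divergence <- function(tes, sites,
                                      divergence_breaks = seq(0, 30, by = 5),
                                      context_filter = c("CG_sym",
                                                         "CG_other"),
                                      min_sites = 50L) {
  if (any(is.na(tes$divergence))) stop("TE divergence missing")
  bins <- cut(tes$divergence, divergence_breaks, right = FALSE,
              include.lowest = TRUE)
  use <- !is.na(sites$context) & sites$context %in% context_filter
  s <- sites[use, , drop = FALSE]
  sgr <- GenomicRanges::GRanges(s$chrom,
                                IRanges::IRanges(s$pos + 1L, width = 1L))
  tgr <- GenomicRanges::GRanges(tes$chrom,
                                IRanges::IRanges(tes$start + 1L, tes$end))
  hits <- GenomicRanges::findOverlaps(sgr, tgr)
  si <- S4Vectors::queryHits(hits)
  bi <- bins[S4Vectors::subjectHits(hits)]
  out <- data.frame(bin = levels(bins),
                    n_tes = as.integer(table(bins)),
                    n_sites = as.integer(tapply(rep(1L, length(si)), bi, sum,
                                                default = 0L)),
                    stringsAsFactors = FALSE)
  sm <- as.numeric(tapply(s$n_meth[si], bi, sum, default = 0))
  st <- as.numeric(tapply(s$n_total[si], bi, sum, default = 0))
  out$level <- ifelse(st > 0, sm / st, NA_real_)
  out$low_support <- out$n_sites < min_sites
  rownames(out) <- NULL
  out
}
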