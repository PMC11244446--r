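## Extended-context classification of cytosines and weighted methylation
## statistics. The context of a cytosine is read on its own strand from the
## flanking bases (up, C, d1, d2) = positions -1, 0, +1, +2 relative to the
## cytosine; minus-strand sites are read on the reverse complement.
##
##   CG  iff d1 == G;  CHG iff d1 != G and d2 == G;  CHH otherwise.
##   Within CG: CG_sym iff d2 == C (mCGC) or up == G (GmCG); CG_other else.
##   ambiguous when an N / out-of-range flank leaves the class undecidable.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.chrom_chars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  strsplit(genome[[chrom]], "", fixed = TRUE)[[1L]]
}

## flanks for a vector of sites on one chromosome; out-of-range bases are "N"
.site_flanks <- function(chars, pos, strand) {
  L <- length(chars)
  at <- function(i) {
    b <- rep("N", length(i))
    ok <- i >= 1L & i <= L
    b[ok] <- chars[i[ok]]
    b[!b %in% c("A", "C", "G", "T")] <- "N"
    b
  }
  i <- pos + 1L  # 1-based index of the Watson base
  plus <- strand == "+"
  ref <- at(i)
  base <- ifelse(plus, ref, unname(.COMP[ref]))
  up <- ifelse(plus, at(i - 1L), unname(.COMP[at(i + 1L)]))
  d1 <- ifelse(plus, at(i + 1L), unname(.COMP[at(i - 1L)]))
  d2 <- ifelse(plus, at(i + 2L), unname(.COMP[at(i - 2L)]))
  list(base = base, up = up, d1 = d1, d2 = d2)
}

#' Classify cytosine contexts against the genome
#'
#' Assigns each site one of `CG_sym`, `CG_other`, `CHG`, `CHH` or
#' `ambiguous`. The symmetric family `CG_sym` covers the mCGC (downstream C)
#' and GmCG (upstream G) trinucleotides; all other fully resolved CG sites
#' are `CG_other` (the island-detection signal is their methylation). A site
#' is `ambiguous` only when an `N` or chromosome-edge flank leaves the class
#' undecidable. A site whose base is not a cytosine on its own strand is a
#' hard error (corrupt calls).
#'
#' @param genome Named character vector of sequences.
#' @param sites Methylation-site `data.frame`.
#' @return `sites` with the `context` column filled.
#' @export
classify_sites <- function(genome, sites) {
  ctx <- character(nrow(sites))
  for (chr in unique(sites$chrom)) {
    sel <- which(sites$chrom == chr)
    chars <- .chrom_chars(genome, chr)
    if (any(sites$pos[sel] < 0L | sites$pos[sel] >= length(chars))) {
      stop("site position out of chromosome bounds on ", chr)
    }
    fl <- .site_flanks(chars, sites$pos[sel], sites$strand[sel])
    if (any(fl$base != "C" & fl$base != "N")) {
      stop("methylation call at a non-cytosine base on ", chr,
           "; calls do not match the genome")
    }
    ctx_chr <- .classify_flanks(fl$up, fl$d1, fl$d2)
    ctx_chr[fl$base == "N"] <- "ambiguous"  # unverifiable reference base
    ctx[sel] <- ctx_chr
  }
  sites$context <- ctx
  sites
}

.classify_flanks <- function(up, d1, d2) {
  n <- length(d1)
  out <- rep("ambiguous", n)
  cg <- d1 == "G"
  sym <- cg & (d2 == "C" | up == "G")
  other <- cg & !sym & d2 != "N" & up != "N"
  out[sym] <- "CG_sym"
  out[other] <- "CG_other"
  chg <- d1 != "G" & d1 != "N" & d2 == "G"
  chh <- d1 != "G" & d1 != "N" & d2 != "G" & d2 != "N"
  out[chg] <- "CHG"
  out[chh] <- "CHH"
  out
}

#' Classify a single cytosine
#'
#' Convenience scalar wrapper around [classify_sites()].
#'
#' @param genome Named character vector.
#' @param chrom,pos,strand Site coordinates (0-based Watson position).
#' @return The context class as a string.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  s <- methylation_sites(chrom, pos, strand, 0L, 1L)
  classify_sites(genome, s)$context
}

#' Pooled (weighted) methylation level
#'
#' The field-standard weighted level: pooled methylated reads over pooled
#' total reads, robust to per-site coverage variation.
#'
#' @param n_meth,n_total Read-count vectors.
#' @return `sum(n_meth) / sum(n_total)`, or `NA` when no reads.
#' @export
pooled_level <- function(n_meth, n_total) {
  tot <- sum(as.numeric(n_total))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(n_meth)) / tot
}

#' Weighted methylation summary per context class
#'
#' @param sites Classified methylation sites.
#' @param min_coverage Minimum per-site total reads for a site to contribute
#'   (default 1, i.e. no floor for pooled levels).
#' @return `data.frame` with one row per context class present (plus any
#'   level of `context` seen): `context`, `n_sites`, `sum_meth`, `sum_total`,
#'   `weighted_level` (`NA` and flagged via `n_sites = 0` when no site
#'   contributes).
#' @export
weighted_methylation <- function(sites, min_coverage = 1L) {
  if (min_coverage < 1L) stop("min_coverage must be >= 1")
  keep <- sites$n_total >= min_coverage
  ctx <- factor(sites$context[keep], levels = CONTEXT_LEVELS)
  out <- data.frame(
    context = CONTEXT_LEVELS,
    n_sites = as.integer(tapply(rep(1L, sum(keep)), ctx, sum,
                                default = 0L)),
    sum_meth = as.numeric(tapply(sites$n_meth[keep], ctx, sum, default = 0)),
    sum_total = as.numeric(tapply(sites$n_total[keep], ctx, sum,
                                  default = 0)),
    stringsAsFactors = FALSE)
  out$weighted_level <- ifelse(out$sum_total > 0,
                               out$sum_meth / out$sum_total, NA_real_)
  rownames(out) <- NULL
  out
}

#' Global CG weighted methylation level
#'
#' Pools `CG_sym` and `CG_other` sites.
#'
#' @param sites Classified methylation sites.
#' @param min_coverage Per-site coverage floor (default 1).
#' @return A single level in \[0, 1\] (or `NA`).
#' @export
global_cg_level <- function(sites, min_coverage = 1L) {
  keep <- sites$context %in% c("CG_sym", "CG_other") &
    sites$n_total >= min_coverage
  pooled_level(sites$n_meth[keep], sites$n_total[keep])
}

#' Merge replicate methylomes by summing read counts
#'
#' Pools per-cytosine counts across replicate call sets (same coordinate
#' space); the merged site keeps the union of positions.
#'
#' @param site_list List of methylation-site data.frames.
#' @return A single methylation-site data.frame, sorted by (chrom, pos,
#'   strand), context reset to unclassified.
#' @export
merge_replicates <- function(site_list) {
  all <- do.call(rbind, site_list)
  key <- paste(all$chrom, all$pos, all$strand, sep = "\r")
  nm <- rowsum(all$n_meth, key)
  nt <- rowsum(all$n_total, key)
  parts <- strsplit(rownames(nm), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
                    strand = vapply(parts, `[[`, character(1), 3L),
                    context = NA_character_,
                    n_meth = as.integer(nm[, 1L]),
                    n_total = as.integer(nt[, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spike-in conversion QC
#'
#' Estimates enzymatic/bisulfite conversion from control molecules of known
#' methylation state: an unmethylated spike (e.g. phage lambda) and a fully
#' methylated spike (e.g. CpG-methylated pUC19).
#' `conversion_efficiency = 1 - level(unmethylated)`;
#' `overconversion = 1 - level(methylated)`. A warning fires when conversion
#' efficiency falls below 0.98.
#'
#' @param spike_unmethylated,spike_methylated Methylation-site data.frames
#'   restricted to the respective control contigs.
#' @return Named list with `conversion_efficiency` and `overconversion`.
#' @export
conversion_qc <- function(spike_unmethylated, spike_methylated) {
  if (nrow(spike_unmethylated) == 0L || nrow(spike_methylated) == 0L) {
    stop("missing spike-in control sites")
  }
  conv <- 1 - pooled_level(spike_unmethylated$n_meth,
                           spike_unmethylated$n_total)
  over <- 1 - pooled_level(spike_methylated$n_meth,
                           spike_methylated$n_total)
  if (is.na(conv) || is.na(over)) stop("spike-in controls without coverage")
  if (conv < 0.98) {
    warning(sprintf("conversion efficiency %.4f below 0.98", conv))
  }
  list(conversion_efficiency = conv, overconversion = over)
}

#' Compare global methylation across treatment conditions
#'
#' Summarises replicate-level global CG methylation per condition, as in a
#' demethylating-drug experiment (control vs 5-azacytidine and friends).
#'
#' @param replicate_levels Named list: condition -> numeric vector of
#'   replicate global CG weighted levels.
#' @return `data.frame` sorted by condition: `condition`, `n_replicates`,
#'   `mean_level`, `min_level`, `max_level`, `range`.
#' @export
compare_treatments <- function(replicate_levels) {
  if (length(replicate_levels) < 2L) {
    stop("need at least two conditions to compare")
  }
  if (any(vapply(replicate_levels, length, integer(1)) == 0L)) {
    stop("condition with zero replicates")
  }
  out <- data.frame(
    condition = names(replicate_levels),
    n_replicates = vapply(replicate_levels, length, integer(1)),
    mean_level = vapply(replicate_levels, mean, numeric(1)),
    min_level = vapply(replicate_levels, min, numeric(1)),
    max_level = vapply(replicate_levels, max, numeric(1)),
    stringsAsFactors = FALSE)
  out$range <- out$max_level - out$min_level
  out <- out[order(out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
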