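## Hypermethylation-island detection from the windowed non-CGC/GCG signal.
## The genome is tiled with fixed windows; windows are scored with the
## pooled weighted level of the selected context class(es); runs of windows
## above a threshold are merged into islands and their edges refined at
## sub-window resolution. All steps are deterministic and order-invariant.

#' Windowed methylation track
#'
#' Tiles every chromosome with non-overlapping windows of `window_size_bp`
#' (the terminal window is shorter) and scores each window with the pooled
#' weighted level of the sites whose context is in `context_filter`.
#' Windows supported by fewer than `min_sites_per_window` sites are marked
#' `missing`: they never seed an island but can be bridged while merging.
#'
#' @param sites Classified methylation sites.
#' @param genome Named character vector (provides chromosome lengths and
#'   order).
#' @param window_size_bp Window width (default 10,000; minimum 100).
#' @param context_filter Context classes scored (default `CG_other`, the
#'   non-CGC/GCG silencing signal).
#' @param min_sites_per_window Support floor below which a window is
#'   `missing` (default 10).
#' @return A `window_track` data.frame: `chrom`, `start`, `end`, `n_sites`,
#'   `sum_meth`, `sum_total`, `level`, `missing`. Window size and filter are
#'   stored as attributes.
#' @export
window_track <- function(sites, genome, window_size_bp = 10000L,
                         context_filter = "CG_other",
                         min_sites_per_window = 10L) {
  if (window_size_bp < 100L) stop("window_size_bp must be >= 100")
  use <- !is.na(sites$context) & sites$context %in% context_filter
  s <- sites[use, , drop = FALSE]
  per_chrom <- split(s, s$chrom)
  out <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    chrom <- names(genome)[k]
    L <- nchar(genome[[k]])
    starts <- seq.int(0L, max(0L, L - 1L), by = window_size_bp)
    ends <- pmin(starts + window_size_bp, L)
    n <- length(starts)
    sm <- numeric(n); st <- numeric(n); ns <- integer(n)
    sc <- per_chrom[[chrom]]
    if (!is.null(sc) && nrow(sc) > 0L) {
      w <- findInterval(sc$pos, starts)
      wf <- factor(w, levels = seq_len(n))
      sm <- as.numeric(tapply(sc$n_meth, wf, sum, default = 0))
      st <- as.numeric(tapply(sc$n_total, wf, sum, default = 0))
      ns <- as.integer(tapply(rep(1L, nrow(sc)), wf, sum, default = 0L))
    }
    out[[k]] <- data.frame(chrom = chrom, start = starts, end = ends,
                           n_sites = ns, sum_meth = sm, sum_total = st,
                           level = ifelse(st > 0, sm / st, NA_real_),
                           missing = ns < min_sites_per_window,
                           stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "window_size_bp") <- as.integer(window_size_bp)
  attr(track, "context_filter") <- context_filter
  class(track) <- c("window_track", "data.frame")
  track
}

#' Call hypermethylated islands from a window track
#'
#' Windows with `level >= theta` (and not `missing`) are flagged; runs of
#' flagged windows on a chromosome are merged when separated by at most
#' `max_gap_windows` unflagged-or-missing windows; merged spans shorter than
#' `min_island_bp` are discarded. Island coordinates run from the start of
#' the first flagged window to the end of the last; the island mean level is
#' the pooled level over all windows in the span (gaps included).
#'
#' @param track A `window_track`.
#' @param theta Hypermethylation threshold in (0, 1) (default 0.4, the
#'   midpoint between the ~0.2 background and the hypermethylated mode).
#' @param max_gap_windows Bridgeable gap length in windows (default 1).
#' @param min_island_bp Minimum merged-span length (default 10,000).
#' @return `data.frame` of islands: `island_id`, `chrom`, `start`, `end`,
#'   `n_windows` (flagged windows), `mean_level`, `supporting_sites`,
#'   `refined` (`FALSE` here).
#' @export
call_islands <- function(track, theta = 0.4, max_gap_windows = 1L,
                         min_island_bp = 10000L) {
  if (!(theta > 0 && theta < 1)) stop("theta must be in (0, 1)")
  res <- list()
  for (chrom in unique(track$chrom)) {
    tw <- track[track$chrom == chrom, , drop = FALSE]
    flagged <- which(!tw$missing & !is.na(tw$level) & tw$level >= theta)
    if (length(flagged) == 0L) next
    grp <- cumsum(c(1L, diff(flagged) > max_gap_windows + 1L))
    for (g in unique(grp)) {
      idx <- flagged[grp == g]
      span <- seq.int(min(idx), max(idx))
      start <- tw$start[span[1L]]
      end <- tw$end[span[length(span)]]
      if (end - start < min_island_bp) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end,
        n_windows = length(idx),
        mean_level = pooled_level(tw$sum_meth[span], tw$sum_total[span]),
        supporting_sites = sum(tw$n_sites[span]),
        refined = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    out <- data.frame(island_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_windows = integer(0), mean_level = numeric(0),
                      supporting_sites = integer(0), refined = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, unique(track$chrom)), out$start), ,
             drop = FALSE]
  out <- cbind(island_id = sprintf("island_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## pooled level + site count of one sub-window [start, end) on one chromosome
.subwindow_stats <- function(pos, n_meth, n_total, start, end) {
  sel <- pos >= start & pos < end
  list(n = sum(sel),
       level = pooled_level(n_meth[sel], n_total[sel]))
}

#' Refine island boundaries at sub-window resolution
#'
#' Replays the visual block demarcation as a deterministic greedy rule: from
#' each island edge, the boundary extends outward in `subwindow_bp` steps
#' while the adjacent sub-window's pooled level stays at or above `theta`
#' (and has at least one site); then edge sub-windows with level below
#' `theta_site` (or with no sites) are trimmed inward. Refinement is
#' idempotent. Refined islands shorter than `min_island_bp` are dropped;
#' trimming never empties an interval (at least one sub-window remains).
#'
#' @param islands Output of [call_islands()].
#' @param sites Classified methylation sites.
#' @param genome Named character vector (chromosome bounds).
#' @param theta Extension threshold (default 0.4).
#' @param theta_site Trimming threshold (default `theta`).
#' @param subwindow_bp Refinement step, must be smaller than the window size
#'   used for calling (default 1,000).
#' @param window_size_bp Window size the islands were called with (used only
#'   to validate `subwindow_bp`).
#' @param context_filter Context classes scored; must match the track.
#' @param min_island_bp Minimum refined length (default 10,000).
#' @return Islands with updated coordinates, `mean_level`,
#'   `supporting_sites`, and `refined = TRUE`.
#' @export
refine_boundaries <- function(islands, sites, genome, theta = 0.4,
                              theta_site = theta, subwindow_bp = 1000L,
                              window_size_bp = 10000L,
                              context_filter = "CG_other",
                              min_island_bp = 10000L) {
  if (subwindow_bp >= window_size_bp) {
    stop("subwindow_bp must be smaller than window_size_bp")
  }
  use <- !is.na(sites$context) & sites$context %in% context_filter
  s <- sites[use, , drop = FALSE]
  per_chrom <- split(s, s$chrom)
  keep <- logical(nrow(islands))
  for (k in seq_len(nrow(islands))) {
    chrom <- islands$chrom[k]
    L <- nchar(genome[[chrom]])
    sc <- per_chrom[[chrom]]
    pos <- if (is.null(sc)) integer(0) else sc$pos
    nm <- if (is.null(sc)) integer(0) else sc$n_meth
    nt <- if (is.null(sc)) integer(0) else sc$n_total
    left <- islands$start[k]; right <- islands$end[k]

    ## outward extension
    repeat {
      if (left - subwindow_bp < 0L) break
      st <- .subwindow_stats(pos, nm, nt, left - subwindow_bp, left)
      if (st$n == 0L || is.na(st$level) || st$level < theta) break
      left <- left - subwindow_bp
    }
    repeat {
      if (right + subwindow_bp > L) break
      st <- .subwindow_stats(pos, nm, nt, right, right + subwindow_bp)
      if (st$n == 0L || is.na(st$level) || st$level < theta) break
      right <- right + subwindow_bp
    }

    ## inward trimming
    repeat {
      if (right - left <= subwindow_bp) break
      st <- .subwindow_stats(pos, nm, nt, left, left + subwindow_bp)
      if (st$n > 0L && !is.na(st$level) && st$level >= theta_site) break
      left <- left + subwindow_bp
    }
    repeat {
      if (right - left <= subwindow_bp) break
      st <- .subwindow_stats(pos, nm, nt, right - subwindow_bp, right)
      if (st$n > 0L && !is.na(st$level) && st$level >= theta_site) break
      right <- right - subwindow_bp
    }

    sel <- pos >= left & pos < right
    islands$start[k] <- left
    islands$end[k] <- right
    islands$mean_level[k] <- pooled_level(nm[sel], nt[sel])
    islands$supporting_sites[k] <- sum(sel)
    islands$refined[k] <- TRUE
    keep[k] <- (right - left) >= min_island_bp
  }
  out <- islands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate islands with their TE base fraction
#'
#' Records, per island, the fraction of island bases covered by the union of
#' TE intervals (nested/overlapping copies counted once).
#'
#' @param islands Island data.frame.
#' @param tes TE table.
#' @return Islands with a `te_fraction` column.
#' @export
annotate_secondary_te <- function(islands, tes) {
  islands$te_fraction <- 0
  if (nrow(islands) == 0L) return(islands)
  if (nrow(tes) > 0L) {
    tgr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(tes$chrom,
                             IRanges::IRanges(tes$start + 1L, tes$end)))
    igr <- GenomicRanges::GRanges(islands$chrom,
                                  IRanges::IRanges(islands$start + 1L,
                                                   islands$end))
    cov <- GenomicRanges::intersect(igr, tgr, ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(cov, igr)
    covered <- tapply(
      GenomicRanges::width(cov)[S4Vectors::queryHits(hits)],
      factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(islands))),
      sum, default = 0)
    islands$te_fraction <- as.numeric(covered) / (islands$end - islands$start)
  }
  islands
}

#' Write islands as BED6+
#'
#' Name = island id (or class when present), score = `floor(1000 *
#' mean_level)`, extra columns `n_windows` and `te_fraction`.
#'
#' @param islands Island data.frame.
#' @param path Output path.
#' @export
write_islands_bed <- function(islands, path) {
  name <- if ("class" %in% names(islands)) {
    paste(islands$island_id, islands$class, sep = "|")
  } else islands$island_id
  lines <- paste(islands$chrom, islands$start, islands$end, name,
                 floor(1000 * islands$mean_level), ".",
                 islands$n_windows,
                 if ("te_fraction" %in% names(islands)) {
                   sprintf("%.4f", islands$te_fraction)
                 } else "NA",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a window track as bedGraph
#'
#' @param track A `window_track`.
#' @param path Output path.
#' @export
write_track_bedgraph <- function(track, path) {
  keep <- !is.na(track$level)
  lines <- paste(track$chrom[keep], track$start[keep], track$end[keep],
                 sprintf("%.4f", track$level[keep]), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
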