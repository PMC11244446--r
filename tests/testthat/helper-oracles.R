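# Independent brute-force oracles. Each one re-derives the quantity with
# the most literal implementation available (per-element loops, explicit
# reverse-complement strings, exhaustive enumeration) and stays independent
# of the package's code paths.

# context class via an explicit reverse-complement scan of the strand string
oracle_context <- function(genome, chrom, pos, strand) {
  s <- genome[[chrom]]
  L <- nchar(s)
  j <- if (strand == "-") {
    s <- revcomp_str(s)
    L - 1L - pos
  } else pos
  at <- function(k) {
    if (k < 0L || k >= L) return("N")
    b <- substr(s, k + 1L, k + 1L)
    if (b %in% c("A", "C", "G", "T")) b else "N"
  }
  c0 <- at(j); up <- at(j - 1L); d1 <- at(j + 1L); d2 <- at(j + 2L)
  if (c0 == "N") return("ambiguous")
  stopifnot(c0 == "C")
  if (d1 == "N") return("ambiguous")
  if (d1 == "G") {
    if (d2 == "C" || up == "G") return("CG_sym")
    if (d2 == "N" || up == "N") return("ambiguous")
    return("CG_other")
  }
  if (d2 == "N") return("ambiguous")
  if (d2 == "G") return("CHG")
  "CHH"
}

# weighted level by a plain loop
oracle_weighted_level <- function(n_meth, n_total, min_coverage = 1L) {
  sm <- 0; st <- 0
  for (i in seq_along(n_meth)) {
    if (n_total[i] >= min_coverage) {
      sm <- sm + n_meth[i]
      st <- st + n_total[i]
    }
  }
  if (st == 0) NA_real_ else sm / st
}

# per-window pooled levels by a double loop
oracle_window_track <- function(sites, genome, ws, context = "CG_other",
                                min_sites = 10L) {
  rows <- list()
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    starts <- seq(0L, max(0L, L - 1L), by = ws)
    for (s0 in starts) {
      e0 <- min(s0 + ws, L)
      sm <- 0; st <- 0; ns <- 0L
      for (i in seq_len(nrow(sites))) {
        if (sites$chrom[i] == chrom && !is.na(sites$context[i]) &&
            sites$context[i] %in% context &&
            sites$pos[i] >= s0 && sites$pos[i] < e0) {
          sm <- sm + sites$n_meth[i]
          st <- st + sites$n_total[i]
          ns <- ns + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s0, end = e0, n_sites = ns,
        sum_meth = sm, sum_total = st,
        level = if (st > 0) sm / st else NA_real_,
        missing = ns < min_sites, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# island run-merging by an explicit scan over one chromosome's windows
oracle_call_islands <- function(levels, missing, theta, max_gap, min_bp,
                                ws = 10000L) {
  flagged <- !missing & !is.na(levels) & levels >= theta
  n <- length(flagged)
  res <- list()
  i <- 1L
  while (i <= n) {
    if (!flagged[i]) { i <- i + 1L; next }
    first <- i
    last <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (flagged[j]) {
        last <- j
        gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > max_gap) break
      }
      j <- j + 1L
    }
    start <- (first - 1L) * ws
    end <- last * ws
    if (end - start >= min_bp) {
      res[[length(res) + 1L]] <- c(start = start, end = end)
    }
    i <- last + 1L
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, res))
}

# TE base fraction of an interval by marking a base-by-base logical vector
oracle_te_fraction <- function(start, end, te_starts, te_ends) {
  covered <- logical(end - start)
  for (i in seq_along(te_starts)) {
    lo <- max(start, te_starts[i]); hi <- min(end, te_ends[i])
    if (hi > lo) covered[(lo - start + 1L):(hi - start)] <- TRUE
  }
  mean(covered)
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins,
# point probabilities from log-binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0L, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, xs) + lchoose(N - c1, r1 - xs) - lchoose(N, r1)
  probs <- exp(logp)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# decile assignment via an explicit stable sort on (level, gene_id)
oracle_deciles <- function(gene_id, level) {
  o <- order(level, gene_id)
  n <- length(o)
  dec <- integer(n)
  for (r in seq_len(n)) dec[o[r]] <- as.integer(ceiling(r * 10 / n))
  dec
}

# reactivation category truth table, one gene at a time
oracle_categories <- function(expr, groups, thr = 1) {
  conds <- setdiff(names(expr), "gene_id")
  base_cols <- conds[groups[conds] != "treatment"]
  treat_cols <- conds[groups[conds] == "treatment"]
  out <- character(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    broad <- FALSE; aza <- FALSE
    for (cn in base_cols) if (expr[[cn]][i] >= thr) broad <- TRUE
    for (cn in treat_cols) if (expr[[cn]][i] >= thr) aza <- TRUE
    out[i] <- if (broad) "Broad" else if (aza) "Aza" else "No"
  }
  out
}
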