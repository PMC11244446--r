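# Shared fixtures, built in code. The default simulation bundle and its
# pipeline run are expensive, so they are built once per session and cached.

.cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.cache$bundle)) {
    .cache$bundle <- simulate_methylome(sim_config(seed = 1))
  }
  .cache$bundle
}

default_results <- function() {
  if (is.null(.cache$results)) {
    .cache$results <- suppressMessages(suppressWarnings(
      run_geve_pipeline(default_sim())))
  }
  .cache$results
}

# a light-weight configuration for determinism / file round-trip checks
small_config <- function(seed = 42L) {
  sim_config(seed = seed, chrom_bp = 400000L, unplaced_bp = 80000L,
             geve_lengths = 30000L, adinto_lengths = 25000L,
             plavaka_lengths = 20000L, unplaced_geve_bp = 20000L,
             n_plain_tes = 15L, n_orf_tes = 8L)
}

rand_genome <- function(lens, gc = 0.45) {
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# all CG-dinucleotide cytosines of a genome as a zero-count site table
cg_site_table <- function(genome) {
  out <- list()
  for (chrom in names(genome)) {
    m <- gregexpr("CG", genome[[chrom]], fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    p0 <- as.integer(m) - 1L
    out[[chrom]] <- methylation_sites(chrom, c(p0, p0 + 1L),
                                      rep(c("+", "-"), each = length(p0)),
                                      0L, 1L)
  }
  do.call(rbind, out)
}

# build a window_track data.frame directly from window levels
mk_track <- function(levels, ws = 10000L, chrom = "c1", n_sites = 100L,
                     missing = NULL, reads_per_window = 1000L) {
  n <- length(levels)
  if (is.null(missing)) missing <- rep(FALSE, n)
  tr <- data.frame(chrom = chrom,
                   start = (seq_len(n) - 1L) * ws,
                   end = seq_len(n) * ws,
                   n_sites = ifelse(missing, 0L, n_sites),
                   sum_meth = ifelse(is.na(levels), 0,
                                     levels * reads_per_window),
                   sum_total = ifelse(is.na(levels), 0, reads_per_window),
                   level = levels,
                   missing = missing,
                   stringsAsFactors = FALSE)
  attr(tr, "window_size_bp") <- as.integer(ws)
  attr(tr, "context_filter") <- "CG_other"
  class(tr) <- c("window_track", "data.frame")
  tr
}

# minimal gene_models constructor
mk_models <- function(genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  }
  genes$n_exons <- as.integer(table(factor(exons$gene_id,
                                           levels = genes$gene_id)))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}
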