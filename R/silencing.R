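## Promoter-methylation deciles versus differential expression, reactivation
## categories under demethylating treatment, and Fisher exact domain
## enrichment.

#' Promoter methylation per gene
#'
#' The promoter is `promoter_bp` upstream of the TSS on the gene strand
#' (truncated at contig edges, never dropped). All CG contexts are pooled.
#' Genes with fewer than `min_promoter_sites` covered promoter sites are
#' excluded. Deciles are assigned by rank over the pooled level, ties broken
#' by gene id (stable); decile 10 is the most methylated.
#'
#' @param models A `gene_models` object.
#' @param sites Classified methylation sites.
#' @param promoter_bp Promoter length (default 1,000).
#' @param min_promoter_sites Minimum covered sites (default 5).
#' @param chrom_lengths Optional named lengths for 3'-side truncation.
#' @param context_filter Context classes pooled (default both CG classes).
#' @return `data.frame`: `gene_id`, `chrom`, `start`, `end` (promoter
#'   interval), `level`, `n_sites`, `decile`.
#' @export
promoter_methylation <- function(models, sites, promoter_bp = 1000L,
                                 min_promoter_sites = 5L,
                                 chrom_lengths = NULL,
                                 context_filter = c("CG_sym", "CG_other")) {
  g <- models$genes
  plus <- g$strand != "-"
  pstart <- ifelse(plus, g$start - promoter_bp, g$end)
  pend <- ifelse(plus, g$start, g$end + promoter_bp)
  pstart <- pmax(pstart, 0L)
  if (!is.null(chrom_lengths)) {
    pend <- pmin(pend, chrom_lengths[g$chrom])
  }
  use <- !is.na(sites$context) & sites$context %in% context_filter
  s <- sites[use, , drop = FALSE]
  per_chrom <- split(s, s$chrom)
  level <- numeric(nrow(g)); n_sites <- integer(nrow(g))
  for (k in seq_len(nrow(g))) {
    sc <- per_chrom[[g$chrom[k]]]
    if (is.null(sc)) { level[k] <- NA_real_; next }
    sel <- sc$pos >= pstart[k] & sc$pos < pend[k]
    n_sites[k] <- sum(sel)
    level[k] <- pooled_level(sc$n_meth[sel], sc$n_total[sel])
  }
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = as.integer(pstart), end = as.integer(pend),
                    level = level, n_sites = n_sites,
                    stringsAsFactors = FALSE)
  out <- out[out$n_sites >= min_promoter_sites & !is.na(out$level), ,
             drop = FALSE]
  o <- order(out$level, out$gene_id)
  out <- out[o, , drop = FALSE]
  n <- nrow(out)
  out$decile <- if (n > 0L) as.integer(ceiling(seq_len(n) * 10 / n))
                else integer(0)
  rownames(out) <- NULL
  out
}

#' Differential-expression response per promoter-methylation decile
#'
#' A gene is differentially expressed iff `padj < fdr` (strict) and
#' `|log2FC| > lfc_min`; its direction is the sign of `log2FC`. Scored genes
#' missing from the DE table count as not-DE, with a warning.
#'
#' @param records Output of [promoter_methylation()].
#' @param de Differential-expression table.
#' @param fdr Adjusted-p cutoff (default 0.01).
#' @param lfc_min Minimum absolute log2 fold change (default 0).
#' @return 10x3 `data.frame`: `decile`, `up`, `down`, `not_de`.
#' @export
decile_response_table <- function(records, de, fdr = 0.01, lfc_min = 0) {
  m <- match(records$gene_id, de$gene_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " scored gene(s) missing from the DE table; ",
            "counted as not-DE")
  }
  padj <- de$padj[m]; lfc <- de$log2FC[m]
  is_de <- !is.na(padj) & !is.na(lfc) & padj < fdr & abs(lfc) > lfc_min
  dir <- ifelse(!is_de, "not_de", ifelse(lfc > 0, "up", "down"))
  dec <- factor(records$decile, levels = 1:10)
  out <- data.frame(decile = 1:10,
                    up = as.integer(tapply(dir == "up", dec, sum,
                                           default = 0L)),
                    down = as.integer(tapply(dir == "down", dec, sum,
                                             default = 0L)),
                    not_de = as.integer(tapply(dir == "not_de", dec, sum,
                                               default = 0L)))
  rownames(out) <- NULL
  out
}

#' Transcriptional reactivation categories
#'
#' Per gene: `Broad` iff any baseline-condition TPM reaches
#' `tpm_threshold`; otherwise `Aza` iff any treatment-condition TPM reaches
#' it (transcribed only upon demethylating treatment); otherwise `No`.
#'
#' @param expr Expression table.
#' @param condition_groups Named character vector: condition column ->
#'   group (`"control"`, `"development"` or `"treatment"`). Every condition
#'   column must be labelled.
#' @param treatment_groups Group labels counted as treatment.
#' @param tpm_threshold Expression cutoff (default 1, inclusive `>=`).
#' @return `data.frame`: `gene_id`, `category` (factor Aza/Broad/No).
#' @export
reactivation_categories <- function(expr, condition_groups,
                                    treatment_groups = "treatment",
                                    tpm_threshold = 1) {
  conds <- setdiff(names(expr), "gene_id")
  unlab <- setdiff(conds, names(condition_groups))
  if (length(unlab) > 0L) {
    stop("condition(s) without group label: ", paste(unlab, collapse = ", "))
  }
  treat_cols <- conds[condition_groups[conds] %in% treatment_groups]
  base_cols <- setdiff(conds, treat_cols)
  if (length(treat_cols) == 0L || length(base_cols) == 0L) {
    stop("need at least one treatment and one baseline condition")
  }
  any_ge <- function(cols) {
    if (length(cols) == 1L) expr[[cols]] >= tpm_threshold
    else apply(expr[cols] >= tpm_threshold, 1L, any)
  }
  broad <- any_ge(base_cols)
  aza <- !broad & any_ge(treat_cols)
  category <- ifelse(broad, "Broad", ifelse(aza, "Aza", "No"))
  data.frame(gene_id = expr$gene_id,
             category = factor(category, levels = c("Aza", "Broad", "No")),
             stringsAsFactors = FALSE)
}

#' Reactivation-category counts per gene class
#'
#' Cross-tabulates reactivation categories against a gene classification
#' (e.g. GEVE / adintovirus / TE ORF), keeping zero rows.
#'
#' @param categories Output of [reactivation_categories()].
#' @param gene_classes `data.frame` with `gene_id`, `class`.
#' @return `data.frame`: `class`, `category`, `n`, `pct` (within class).
#' @export
reactivation_summary <- function(categories, gene_classes) {
  absent <- setdiff(gene_classes$gene_id, categories$gene_id)
  if (length(absent) > 0L) {
    stop("gene(s) without a reactivation category: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  m <- merge(gene_classes, categories, by = "gene_id")
  lev <- if (is.factor(gene_classes$class)) levels(gene_classes$class)
         else unique(gene_classes$class)
  cls <- factor(m$class, levels = lev)
  tab <- table(cls, factor(m$category, levels = c("Aza", "Broad", "No")))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("class", "category", "n")
  tot <- tapply(out$n, out$class, sum)[out$class]
  out$pct <- ifelse(tot > 0, 100 * out$n / tot, 0)
  out <- out[order(match(out$class, levels(cls)), out$category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Minimum-likelihood convention: the sum of hypergeometric point
#' probabilities not exceeding the observed table's probability, with a
#' relative tolerance of 1e-7 on the comparison to absorb floating-point
#' ties.
#'
#' @param a,b,c,d Counts: in-set with domain, in-set without, out-set with,
#'   out-set without.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  white <- a + c   # genes carrying the domain
  black <- b + d
  drawn <- a + b   # in-set genes
  k <- max(0L, drawn - black):min(drawn, white)
  probs <- stats::dhyper(k, white, black, drawn)
  p_obs <- stats::dhyper(a, white, black, drawn)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact domain enrichment
#'
#' For every domain observed among the background genes, builds the 2x2
#' presence/absence x in-set/out-set table, computes the two-sided Fisher
#' exact p ([fisher_exact_p()]) and Benjamini-Hochberg q-values across
#' domains. Hits on genes outside the background are skipped (a message
#' reports the count).
#'
#' @param domains Domain-hits table.
#' @param gene_set Character vector of in-set gene ids (must be contained in
#'   `background_genes`).
#' @param background_genes Character vector of all genes considered.
#' @return `data.frame` sorted by p then accession: `domain_accession`,
#'   `domain_name`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`.
#' @export
fisher_domain_enrichment <- function(domains, gene_set, background_genes) {
  gene_set <- unique(gene_set)
  background_genes <- unique(background_genes)
  if (!all(gene_set %in% background_genes)) {
    stop("gene_set must be a subset of background_genes")
  }
  outside <- !(domains$gene_id %in% background_genes)
  if (any(outside)) {
    message(sum(outside), " domain hit(s) on genes outside the background ",
            "skipped")
    domains <- domains[!outside, , drop = FALSE]
  }
  if (nrow(domains) == 0L) {
    return(data.frame(domain_accession = character(0),
                      domain_name = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  n_set <- length(gene_set)
  n_bg <- length(background_genes)
  accs <- sort(unique(domains$domain_accession))
  rows <- lapply(accs, function(acc) {
    hit <- domains[domains$domain_accession == acc, , drop = FALSE]
    with_dom <- unique(hit$gene_id)
    a <- sum(with_dom %in% gene_set)
    b <- n_set - a
    c <- length(with_dom) - a
    d <- (n_bg - n_set) - c
    data.frame(domain_accession = acc,
               domain_name = hit$domain_name[1L],
               a = a, b = b, c = c, d = d,
               odds_ratio = (a * d) / (b * c),
               p_value = fisher_exact_p(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$domain_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
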