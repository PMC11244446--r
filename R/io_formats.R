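## Readers and writers for the external formats the pipeline touches.
## Internal coordinate convention: 0-based half-open everywhere; conversion
## to/from 1-based formats (FASTA positions, GFF3, CGmap, RepeatMasker .out)
## happens only here, at the parse/write boundary.

#' Read a genome from FASTA
#'
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T`, `N`
#' is replaced by `N` (a single warning reports how many characters were
#' masked). Duplicate headers and empty files are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase sequence per record. The
#'   name is the first whitespace-delimited token of the header line.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  n_bad <- sum(vapply(out, function(s) nchar(gsub("[ACGTN]", "", s)),
                      integer(1)))
  if (n_bad > 0L) {
    out <- vapply(out, function(s) gsub("[^ACGTN]", "N", s), character(1))
    warning(n_bad, " non-ACGTN character(s) replaced by N")
  }
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Create a methylation-site table
#'
#' The common in-memory form of per-cytosine methylation calls: one row per
#' cytosine on its own strand, with a 0-based Watson-coordinate position.
#' `context` is `NA` ("unclassified") until [classify_sites()] is applied.
#'
#' @param chrom Chromosome ids.
#' @param pos 0-based positions (Watson coordinates of the cytosine's base).
#' @param strand `"+"` or `"-"` (or `"*"` when unknown, e.g. unstranded
#'   bedGraph input before strand inference).
#' @param n_meth,n_total Methylated / total read counts; `n_meth <= n_total`.
#' @param context Optional context class.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `n_meth`, `n_total`.
#' @export
methylation_sites <- function(chrom, pos, strand, n_meth, n_total,
                              context = NA_character_) {
  if (any(n_meth > n_total)) {
    stop("n_meth > n_total in methylation sites")
  }
  if (any(n_meth < 0) || any(n_total < 0)) {
    stop("negative read counts in methylation sites")
  }
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             strand = as.character(strand),
             context = as.character(context),
             n_meth = as.integer(n_meth), n_total = as.integer(n_total),
             stringsAsFactors = FALSE)
}

CONTEXT_LEVELS <- c("CG_sym", "CG_other", "CHG", "CHH", "ambiguous")

#' Read per-cytosine methylation calls
#'
#' Supported dialects:
#' \describe{
#'   \item{`cgmap`}{7/8-column CGmap: chrom, Watson base (`C` = plus strand,
#'     `G` = minus strand), 1-based position, context, dinucleotide, level,
#'     methylated count, total count.}
#'   \item{`bedgraph_cov`}{6-column coverage bedGraph: chrom, 0-based start,
#'     end, percent methylation, methylated count, unmethylated count.
#'     Strandless; pass `genome` to infer strand from the Watson base.}
#'   \item{`bedmethyl`}{9+ column bedMethyl: strand from column 6, coverage
#'     from column 10, percent methylation from column 11.}
#' }
#'
#' Positions are normalised to 0-based Watson coordinates. Sites with zero
#' total coverage are dropped (a message reports the count). A methylated
#' count exceeding the total is a hard error naming the offending line.
#'
#' @param path Input file.
#' @param dialect One of `"cgmap"`, `"bedgraph_cov"`, `"bedmethyl"`.
#' @param genome Optional genome (named character vector) used to infer the
#'   strand of strandless dialects: Watson base `C` maps to `+`, `G` to `-`.
#' @return A methylation-site `data.frame` (see [methylation_sites()]).
#' @export
read_methylation_calls <- function(path, dialect = c("cgmap", "bedgraph_cov",
                                                     "bedmethyl"),
                                   genome = NULL) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           comment.char = "", quote = "")
  if (dialect == "cgmap") {
    if (ncol(raw) < 8L) stop("CGmap input needs 8 columns")
    base <- raw[[2L]]
    if (!all(base %in% c("C", "G"))) {
      stop("CGmap nucleotide column must be C or G")
    }
    sites <- data.frame(chrom = raw[[1L]],
                        pos = as.integer(raw[[3L]]) - 1L,
                        strand = ifelse(base == "C", "+", "-"),
                        context = NA_character_,
                        n_meth = as.integer(raw[[7L]]),
                        n_total = as.integer(raw[[8L]]),
                        stringsAsFactors = FALSE)
  } else if (dialect == "bedgraph_cov") {
    if (ncol(raw) < 6L) stop("coverage bedGraph input needs 6 columns")
    n_meth <- as.integer(raw[[5L]])
    n_unmeth <- as.integer(raw[[6L]])
    sites <- data.frame(chrom = raw[[1L]],
                        pos = as.integer(raw[[2L]]),
                        strand = "*",
                        context = NA_character_,
                        n_meth = n_meth,
                        n_total = n_meth + n_unmeth,
                        stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 11L) stop("bedMethyl input needs at least 11 columns")
    cov <- as.integer(raw[[10L]])
    pct <- as.numeric(raw[[11L]])
    sites <- data.frame(chrom = raw[[1L]],
                        pos = as.integer(raw[[2L]]),
                        strand = raw[[6L]],
                        context = NA_character_,
                        n_meth = as.integer(round(cov * pct / 100)),
                        n_total = cov,
                        stringsAsFactors = FALSE)
  }
  bad <- which(sites$n_meth > sites$n_total)
  if (length(bad) > 0L) {
    stop("methylated count exceeds total count at line ", bad[1L],
         " of ", path)
  }
  zero <- sites$n_total == 0L
  if (any(zero)) {
    message(sum(zero), " zero-coverage site(s) dropped")
    sites <- sites[!zero, , drop = FALSE]
  }
  if (!is.null(genome) && any(sites$strand == "*")) {
    sites$strand <- infer_strand(genome, sites)
  }
  rownames(sites) <- NULL
  sites
}

#' Infer strand of strandless methylation calls from the genome
#'
#' The Watson base at each position decides the strand: `C` means the
#' cytosine is on the plus strand, `G` on the minus strand. Any other base
#' is a hard error (the calls do not match the genome).
#'
#' @param genome Named character vector of sequences.
#' @param sites Methylation-site data.frame.
#' @return Character vector of strands.
#' @export
infer_strand <- function(genome, sites) {
  strand <- sites$strand
  for (chr in unique(sites$chrom)) {
    sel <- sites$chrom == chr & sites$strand == "*"
    if (!any(sel)) next
    if (!chr %in% names(genome)) stop("chromosome not in genome: ", chr)
    base <- substring(genome[[chr]], sites$pos[sel] + 1L, sites$pos[sel] + 1L)
    if (any(!base %in% c("C", "G"))) {
      stop("site without C/G Watson base on ", chr,
           "; calls do not match the genome")
    }
    strand[sel] <- ifelse(base == "C", "+", "-")
  }
  strand
}

#' Write methylation calls
#'
#' The CGmap dialect writes the context column from the site's classified
#' context when available (`CG` / `CHG` / `CHH`), otherwise `"-"`. Re-reading
#' a written file restores the same `chrom`/`pos`/`strand`/counts records.
#'
#' @param sites Methylation-site data.frame.
#' @param path Output path.
#' @param dialect `"cgmap"` or `"bedgraph_cov"`.
#' @export
write_methylation_calls <- function(sites, path,
                                    dialect = c("cgmap", "bedgraph_cov")) {
  dialect <- match.arg(dialect)
  if (dialect == "cgmap") {
    ctx <- rep("-", nrow(sites))
    ctx[!is.na(sites$context) & sites$context %in% c("CG_sym", "CG_other")] <- "CG"
    ctx[!is.na(sites$context) & sites$context == "CHG"] <- "CHG"
    ctx[!is.na(sites$context) & sites$context == "CHH"] <- "CHH"
    lev <- ifelse(sites$n_total > 0,
                  sprintf("%.4f", sites$n_meth / sites$n_total), "0")
    lines <- paste(sites$chrom,
                   ifelse(sites$strand == "+", "C", "G"),
                   sites$pos + 1L, ctx, ctx, lev,
                   sites$n_meth, sites$n_total, sep = "\t")
  } else {
    pct <- ifelse(sites$n_total > 0,
                  sprintf("%.2f", 100 * sites$n_meth / sites$n_total), "0")
    lines <- paste(sites$chrom, sites$pos, sites$pos + 1L, pct,
                   sites$n_meth, sites$n_total - sites$n_meth, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one gene model per `gene` feature. Exon structure is taken from the
#' gene's longest mRNA (span on the genome; ties broken by file order); exons
#' parented directly on the gene are used when no mRNA is present. Genes
#' without any exon feature get a single exon spanning the gene, with a
#' warning. An exon extending outside its gene span is a hard error.
#' Coordinates are converted from GFF3 1-based inclusive to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return A list with class `"gene_models"`:
#'   \item{genes}{`data.frame` with `gene_id`, `chrom`, `start`, `end`,
#'     `strand`, `n_exons`.}
#'   \item{exons}{`data.frame` with `gene_id`, `start`, `end`, sorted by
#'     genomic start within gene.}
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))

  gi <- which(type == "gene")
  if (length(gi) == 0L) stop("no gene features in ", path)
  mi <- which(type %in% c("mRNA", "transcript"))
  ei <- which(type == "exon")

  genes <- data.frame(gene_id = ids[gi],
                      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
                      start = GenomicRanges::start(gr)[gi] - 1L,
                      end = GenomicRanges::end(gr)[gi],
                      strand = as.character(GenomicRanges::strand(gr))[gi],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in ", path)

  mrna_parent <- parents[mi]
  mrna_span <- GenomicRanges::end(gr)[mi] - GenomicRanges::start(gr)[mi] + 1L
  exon_parent <- parents[ei]
  exon_start <- GenomicRanges::start(gr)[ei] - 1L
  exon_end <- GenomicRanges::end(gr)[ei]

  exon_list <- vector("list", nrow(genes))
  n_defaulted <- 0L
  for (k in seq_len(nrow(genes))) {
    gid <- genes$gene_id[k]
    gm <- which(mrna_parent == gid)
    ex <- integer(0)
    if (length(gm) > 0L) {
      best <- gm[which.max(mrna_span[gm])]  # ties: which.max takes the first
      ex <- which(exon_parent == ids[mi][best])
    }
    if (length(ex) == 0L) {
      ex <- which(exon_parent == gid)  # exons directly under the gene
    }
    if (length(ex) == 0L) {
      n_defaulted <- n_defaulted + 1L
      exon_list[[k]] <- data.frame(gene_id = gid, start = genes$start[k],
                                   end = genes$end[k],
                                   stringsAsFactors = FALSE)
      next
    }
    s <- exon_start[ex]; e <- exon_end[ex]
    if (any(s < genes$start[k]) || any(e > genes$end[k])) {
      stop("exon outside gene span for gene ", gid)
    }
    o <- order(s)
    exon_list[[k]] <- data.frame(gene_id = gid, start = s[o], end = e[o],
                                 stringsAsFactors = FALSE)
  }
  if (n_defaulted > 0L) {
    warning(n_defaulted, " gene(s) without exon features; gene span used")
  }
  exons <- do.call(rbind, exon_list)
  genes$n_exons <- as.integer(table(factor(exons$gene_id,
                                           levels = genes$gene_id)))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models to GFF3
#'
#' One `gene`, one `mRNA` and its `exon` rows per gene model, 1-based
#' inclusive coordinates.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_len(nrow(g))) {
    gid <- g$gene_id[k]
    writeLines(sprintf("%s\tgevescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[k], g$start[k] + 1L, g$end[k], g$strand[k],
                       gid), con)
    mid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tgevescan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom[k], g$start[k] + 1L, g$end[k], g$strand[k],
                       mid, gid), con)
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\tgevescan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$chrom[k], ex$start[j] + 1L, ex$end[j], g$strand[k], mid, j, mid),
        con)
    }
  }
  invisible(path)
}

#' Read a transposable-element annotation table
#'
#' Two dialects:
#' \describe{
#'   \item{`bed_plus`}{Headered TSV with columns `chrom`, `start`, `end`
#'     (0-based half-open), `strand`, `family`, `divergence`,
#'     `consensus_length`.}
#'   \item{`repeatmasker_out`}{A RepeatMasker `.out` file (3 header lines,
#'     whitespace-separated fixed columns, 1-based inclusive query
#'     coordinates). The consensus length is reconstructed from the repeat
#'     begin/end/(left) columns.}
#' }
#' `consensus_span_fraction` is `(end - start) / consensus_length`.
#'
#' @param path Input file.
#' @param dialect `"bed_plus"` or `"repeatmasker_out"`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `family`, `divergence`, `consensus_length`, `consensus_span_fraction`.
#' @export
read_te_table <- function(path, dialect = c("bed_plus", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed_plus") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "family", "divergence",
              "consensus_length")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L) {
      stop("TE table missing column(s): ", paste(miss, collapse = ", "))
    }
    tes <- tab[need]
    tes$start <- as.integer(tes$start)
    tes$end <- as.integer(tes$end)
  } else {
    lines <- readLines(path)
    lines <- lines[-seq_len(min(3L, length(lines)))]  # column-header block
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[ \t]+")
    parse_one <- function(f) {
      strand <- f[[9L]]
      unparen <- function(x) as.integer(gsub("[()]", "", x))
      if (strand == "C") {
        # complement hits carry repeat columns as (left) end begin
        cons_len <- unparen(f[[13L]]) + unparen(f[[12L]])
      } else {
        cons_len <- unparen(f[[13L]]) + unparen(f[[14L]])
      }
      data.frame(chrom = f[[5L]],
                 start = as.integer(f[[6L]]) - 1L,
                 end = as.integer(f[[7L]]),
                 strand = if (strand == "C") "-" else "+",
                 family = f[[10L]],
                 divergence = as.numeric(f[[2L]]),
                 consensus_length = cons_len,
                 stringsAsFactors = FALSE)
    }
    tes <- do.call(rbind, lapply(fields, parse_one))
  }
  if (any(tes$start >= tes$end)) stop("TE interval with start >= end")
  tes$consensus_span_fraction <-
    ifelse(is.na(tes$consensus_length) | tes$consensus_length <= 0,
           NA_real_, (tes$end - tes$start) / tes$consensus_length)
  rownames(tes) <- NULL
  tes
}

#' Write a TE table in the headered `bed_plus` dialect
#'
#' @param tes TE `data.frame` (see [read_te_table()]).
#' @param path Output path.
#' @export
write_te_table <- function(tes, path) {
  cols <- c("chrom", "start", "end", "strand", "family", "divergence",
            "consensus_length")
  utils::write.table(tes[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TPM expression table
#'
#' A headered TSV with a `gene_id` column and one non-negative TPM column per
#' condition. Gene ids must be unique.
#'
#' @param path Input file.
#' @return `data.frame` with `gene_id` first, condition columns after.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("expression table needs a gene_id column")
  if (ncol(tab) < 2L) stop("expression table has no condition columns")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in expression table")
  for (cn in setdiff(names(tab), "gene_id")) {
    tab[[cn]] <- as.numeric(tab[[cn]])
    if (any(tab[[cn]] < 0, na.rm = TRUE)) stop("negative TPM in column ", cn)
  }
  tab
}

#' Read a differential-expression results table
#'
#' Headered TSV with `gene_id`, `log2FC`, `padj`; one row per gene; `padj`
#' in \[0, 1\].
#'
#' @param path Input file.
#' @return `data.frame` with the three columns.
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2FC", "padj")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("DE table missing: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in DE table")
  tab$log2FC <- as.numeric(tab$log2FC)
  tab$padj <- as.numeric(tab$padj)
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0, 1]")
  }
  tab[need]
}

#' Read a protein-domain hits table
#'
#' Headered TSV with `gene_id`, `domain_accession` and optionally
#' `domain_name`; (gene, accession) pairs must be unique.
#'
#' @param path Input file.
#' @return `data.frame` with the three columns (`domain_name` filled with the
#'   accession when absent).
#' @export
read_domain_hits <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain_accession")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("domain table missing: ", paste(miss, collapse = ", "))
  }
  if (!"domain_name" %in% names(tab)) tab$domain_name <- tab$domain_accession
  if (anyDuplicated(tab[c("gene_id", "domain_accession")])) {
    stop("duplicate (gene_id, domain_accession) pair in domain table")
  }
  tab[c("gene_id", "domain_accession", "domain_name")]
}

#' Read a viral marker-gene catalog
#'
#' Headered TSV mapping marker domain accessions to the island class they
#' support. Columns: `domain_accession`, `domain_name`, `class` (one of
#' `GEVE`, `adintovirus`, `plavaka`), `weight` (`required-any` or
#' `supporting`). Each accession maps to exactly one class.
#'
#' @param path Input file; defaults to the catalog shipped with the package.
#' @return `data.frame` with the four columns.
#' @export
read_marker_catalog <- function(path = system.file("extdata",
                                                   "marker_catalog.tsv",
                                                   package = "gevescan")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_accession", "domain_name", "class", "weight")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("catalog missing: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$domain_accession)) {
    stop("marker accession mapped to more than one class")
  }
  if (!all(tab$class %in% c("GEVE", "adintovirus", "plavaka"))) {
    stop("unknown class in marker catalog")
  }
  tab[need]
}
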