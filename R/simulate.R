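## Seeded synthetic-methylome generator. Emulates the statistical structure
## the analysis assumes -- intron-rich host genes with context-split gene
## body methylation, age-stratified methylated TEs, implanted intron-poor
## gene-dense uniformly hypermethylated viral islands, spike-in conversion
## controls, and a demethylating-treatment condition -- and records ground
## truth for every downstream stage. The seed fully determines the bundle.

#' Simulation configuration
#'
#' Defaults define the study conditions the package is validated under:
#' a 2-Mb chromosome plus a 120-kb unplaced contig; host CG_sym/CG_other
#' methylation 0.70/0.20; TE methylation decaying with divergence as
#' `0.9 - 0.02 * divergence`; islands uniformly methylated at 0.80 in all CG
#' contexts; negative-binomial coverage with mean 20; a 0.005 conversion
#' error (false-methylation rate); and a multiplicative treatment factor of
#' 0.33 on every methylation probability, taking the global CG level from
#' roughly 0.45 to roughly 0.15.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param chrom_bp Main chromosome length.
#' @param unplaced_bp Unplaced contig length.
#' @param gc Genome GC fraction.
#' @param geve_lengths,adinto_lengths,plavaka_lengths Island lengths (bp) to
#'   implant on the main chromosome.
#' @param unplaced_geve_bp GEVE length implanted on the unplaced contig.
#' @param host_exons_mean Mean exons per host gene (Poisson + 1).
#' @param silent_fraction Fraction of host genes transcriptionally silent.
#' @param p_sym,p_other Host CG_sym / CG_other methylation probabilities.
#' @param p_island Island methylation probability (all CG contexts).
#' @param te_p_intercept,te_p_slope TE methylation `intercept - slope * div`.
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage.
#' @param conversion_error False-methylation probability on unmethylated
#'   cytosines.
#' @param treatment_factor Multiplicative methylation retention under
#'   demethylating treatment.
#' @param methylation_scale Global multiplier on every true methylation
#'   probability (1 = as configured; 0 gives a fully unmethylated genome).
#' @param n_plain_tes,n_orf_tes Transposable-element copy counts.
#' @param aza_fraction Named per-class fractions of island/TE-ORF genes
#'   reactivated only under treatment.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_bp = 2000000L,
                       unplaced_bp = 120000L,
                       gc = 0.45,
                       geve_lengths = c(50000L, 80000L, 30000L),
                       adinto_lengths = c(30000L, 25000L),
                       plavaka_lengths = c(20000L, 40000L),
                       unplaced_geve_bp = 25000L,
                       host_exons_mean = 7.2,
                       silent_fraction = 0.25,
                       p_sym = 0.70, p_other = 0.20, p_island = 0.80,
                       te_p_intercept = 0.9, te_p_slope = 0.02,
                       coverage_mean = 20, coverage_dispersion = 5,
                       conversion_error = 0.005,
                       treatment_factor = 0.33,
                       methylation_scale = 1,
                       n_plain_tes = 60L, n_orf_tes = 30L,
                       aza_fraction = c(geve = 0.26, adintovirus = 0.32,
                                        plavaka = 0.20, te_orf = 0.50)) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## non-overlapping island placement with a minimum separation
.place_islands <- function(L, lengths, margin = 50000L, sep = 40000L,
                           max_attempts = 500L) {
  placed <- data.frame(start = integer(0), end = integer(0))
  for (len in lengths) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- sample.int(L - 2L * margin - len, 1L) + margin
      e <- s + len
      if (nrow(placed) == 0L ||
          all(s >= placed$end + sep | e <= placed$start - sep)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place islands without overlap")
  }
  placed  # in placement order; caller keeps the length/class pairing
}

## split `total` into `n` parts, each >= minimum, random proportions
.split_lengths <- function(total, n, minimum) {
  if (n == 1L) return(total)
  slack <- total - n * minimum
  w <- diff(c(0, sort(stats::runif(n - 1L)), 1))
  minimum + floor(w * slack) + c(slack - sum(floor(w * slack)),
                                 rep(0L, n - 1L))
}

## exon intervals for one gene: n exons alternating with n-1 introns
.make_exons <- function(start, end, n_exons) {
  len <- end - start
  n_exons <- max(1L, min(n_exons, (len + 50L) %/% 110L))
  if (n_exons == 1L) return(data.frame(start = start, end = end))
  exonic <- round(len * stats::runif(1L, 0.55, 0.75))
  exonic <- min(max(exonic, n_exons * 60L), len - (n_exons - 1L) * 50L)
  ex <- .split_lengths(exonic, n_exons, 60L)
  intr <- .split_lengths(len - exonic, n_exons - 1L, 50L)
  starts <- start + cumsum(c(0L, ex[-n_exons] + intr))
  data.frame(start = as.integer(starts), end = as.integer(starts + ex))
}

#' Generate a synthetic methylome bundle
#'
#' Produces an in-memory bundle: genome (analysis contigs plus unmethylated
#' lambda and methylated pUC19 spike contigs), gene models, TE annotation,
#' per-condition per-replicate methylomes (two control, two treated), a TPM
#' expression table with condition groups, a differential-expression table,
#' protein-domain hits (including viral marker genes on the implanted
#' islands), and ground truth for every downstream stage. Use
#' [write_bundle()] to materialise it in the standard file formats.
#'
#' @param config A [sim_config()].
#' @return Named list (class `sim_bundle`); see Details in the vignette.
#' @export
simulate_methylome <- function(config = sim_config()) {
  set.seed(config$seed)
  gc <- config$gc

  genome <- c(chr1 = .rand_seq(config$chrom_bp, gc),
              scaff_1 = .rand_seq(config$unplaced_bp, gc),
              lambda_spike = .rand_seq(20000L, 0.5),
              pUC19_spike = .rand_seq(3000L, 0.5))

  ## ---- islands -----------------------------------------------------------
  lens <- c(config$geve_lengths, config$adinto_lengths,
            config$plavaka_lengths)
  cls <- c(rep("GEVE", length(config$geve_lengths)),
           rep("adintovirus", length(config$adinto_lengths)),
           rep("plavaka", length(config$plavaka_lengths)))
  ord <- sample.int(length(lens))  # placement order independent of class
  pl <- .place_islands(config$chrom_bp, lens[ord])
  islands <- data.frame(chrom = "chr1", start = pl$start, end = pl$end,
                        class = cls[ord], stringsAsFactors = FALSE)
  up_start <- sample.int(config$unplaced_bp - config$unplaced_geve_bp -
                           40000L, 1L) + 20000L
  islands <- rbind(islands,
                   data.frame(chrom = "scaff_1", start = up_start,
                              end = up_start + config$unplaced_geve_bp,
                              class = "GEVE", stringsAsFactors = FALSE))
  islands <- islands[order(match(islands$chrom, names(genome)),
                           islands$start), , drop = FALSE]
  rownames(islands) <- NULL

  ## ---- host walk: genes, TE-ORF blocks, plain TEs ------------------------
  genes <- list(); exons <- list(); tes <- list()
  gene_meta <- list()
  n_orf_left <- config$n_orf_tes
  n_te_left <- config$n_plain_tes
  cool_down <- 0L  # slots since the last TE; keeps TEs isolated per window
  for (chrom in c("chr1", "scaff_1")) {
    L <- nchar(genome[[chrom]])
    isl <- islands[islands$chrom == chrom, , drop = FALSE]
    x <- 2000L
    while (x < L - 6000L) {
      ## skip past islands with a 3-kb clearance
      hit <- which(x + 6000L > isl$start - 3000L & x < isl$end + 3000L)
      if (length(hit) > 0L) {
        x <- max(isl$end[hit]) + 3000L
        next
      }
      roll <- stats::runif(1L)
      if (cool_down <= 0L && roll < 0.10 && n_orf_left > 0L) {
        ## TE carrying an ORF: gene promoter falls fully inside the TE
        glen <- as.integer(stats::runif(1L, 1000L, 1400L))
        gs <- x + 1150L; ge <- gs + glen
        te_s <- x; te_e <- ge + 150L
        div <- stats::runif(1L, 0, 8)
        tes[[length(tes) + 1L]] <- data.frame(
          chrom = chrom, start = te_s, end = te_e, strand = "+",
          family = "TE_orf_fam", divergence = div,
          consensus_length = as.integer((te_e - te_s) /
                                          stats::runif(1L, 0.8, 1)),
          stringsAsFactors = FALSE)
        gid <- sprintf("g_%s_%07d", chrom, gs)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, start = gs, end = ge, strand = "+",
          stringsAsFactors = FALSE)
        exons[[length(exons) + 1L]] <- data.frame(gene_id = gid, start = gs,
                                                  end = ge)
        gene_meta[[length(gene_meta) + 1L]] <- data.frame(
          gene_id = gid, role = "te_orf",
          promoter_p = config$te_p_intercept - config$te_p_slope * div,
          stringsAsFactors = FALSE)
        n_orf_left <- n_orf_left - 1L
        cool_down <- 2L
        x <- te_e + as.integer(stats::runif(1L, 2500L, 4000L))
      } else if (cool_down <= 0L && roll < 0.22 && n_te_left > 0L) {
        len <- as.integer(stats::runif(1L, 500L, 2000L))
        div <- stats::runif(1L, 0, 25)
        tes[[length(tes) + 1L]] <- data.frame(
          chrom = chrom, start = x, end = x + len,
          strand = sample(c("+", "-"), 1L),
          family = sprintf("TE_fam%d", sample.int(8L, 1L)),
          divergence = div,
          consensus_length = as.integer(len / stats::runif(1L, 0.55, 1)),
          stringsAsFactors = FALSE)
        n_te_left <- n_te_left - 1L
        cool_down <- 2L
        x <- x + len + as.integer(stats::runif(1L, 2500L, 4000L))
      } else {
        glen <- as.integer(stats::runif(1L, 2000L, 3200L))
        strand <- sample(c("+", "-"), 1L)
        gs <- x + 1000L; ge <- gs + glen  # 1-kb clearance for the promoter
        gid <- sprintf("g_%s_%07d", chrom, gs)
        silent <- stats::runif(1L) < config$silent_fraction
        n_ex <- 1L + stats::rpois(1L, config$host_exons_mean - 1)
        ex <- .make_exons(gs, ge, n_ex)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, start = gs, end = ge,
          strand = strand, stringsAsFactors = FALSE)
        exons[[length(exons) + 1L]] <- cbind(gene_id = gid, ex)
        gene_meta[[length(gene_meta) + 1L]] <- data.frame(
          gene_id = gid,
          role = if (silent) "host_silent" else "host_active",
          promoter_p = if (silent) stats::runif(1L, 0.50, 0.85)
                       else stats::runif(1L, 0.02, 0.40),
          stringsAsFactors = FALSE)
        cool_down <- cool_down - 1L
        x <- ge + as.integer(stats::runif(1L, 2500L, 4000L))
      }
    }
  }

  ## ---- island genes ------------------------------------------------------
  for (k in seq_len(nrow(islands))) {
    chrom <- islands$chrom[k]
    role <- c(GEVE = "geve", adintovirus = "adintovirus",
              plavaka = "plavaka")[[islands$class[k]]]
    x <- islands$start[k] + 1200L
    while (x + 1600L < islands$end[k]) {
      glen <- as.integer(stats::runif(1L, 1000L, 1500L))
      gid <- sprintf("g_%s_%07d", chrom, x)
      n_ex <- sample(c(1L, 1L, 1L, 2L), 1L)  # intron-poor viral genes
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, start = x, end = x + glen,
        strand = "+", stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <- cbind(gene_id = gid,
                                           .make_exons(x, x + glen, n_ex))
      gene_meta[[length(gene_meta) + 1L]] <- data.frame(
        gene_id = gid, role = role,
        promoter_p = stats::runif(1L, 0.65, 0.95),
        stringsAsFactors = FALSE)
      x <- x + glen + as.integer(stats::runif(1L, 400L, 800L))
    }
  }

  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  tes <- do.call(rbind, tes)
  meta <- do.call(rbind, gene_meta)
  o <- order(match(genes$chrom, names(genome)), genes$start)
  genes <- genes[o, , drop = FALSE]
  meta <- meta[match(genes$gene_id, meta$gene_id), , drop = FALSE]
  genes$n_exons <- as.integer(table(factor(exons$gene_id,
                                           levels = genes$gene_id)))
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(genes) <- rownames(exons) <- rownames(meta) <- NULL
  models <- structure(list(genes = genes, exons = exons),
                      class = "gene_models")
  tes$consensus_span_fraction <- (tes$end - tes$start) / tes$consensus_length
  ## island-gene islands carry which island each gene sits in
  meta$island_class <- "none"
  for (k in seq_len(nrow(islands))) {
    inside <- genes$chrom == islands$chrom[k] &
      genes$start >= islands$start[k] & genes$end <= islands$end[k]
    meta$island_class[inside] <- islands$class[k]
  }

  ## ---- per-site true methylation probabilities ---------------------------
  sites <- .cg_sites(genome)
  sites <- classify_sites(genome, sites)
  p <- ifelse(sites$context == "CG_sym", config$p_sym, config$p_other)
  region <- ifelse(sites$context == "CG_sym", "host_sym", "host_other")
  ovw <- function(chrom, start, end, value, label) {
    sel <- sites$chrom == chrom & sites$pos >= start & sites$pos < end
    p[sel] <<- value
    region[sel] <<- label
  }
  for (k in seq_len(nrow(tes))) {
    ovw(tes$chrom[k], tes$start[k], tes$end[k],
        config$te_p_intercept - config$te_p_slope * tes$divergence[k], "te")
  }
  for (k in seq_len(nrow(islands))) {
    ovw(islands$chrom[k], islands$start[k], islands$end[k],
        config$p_island, "island")
  }
  ## promoter overrides (1 kb upstream of every gene TSS, on its strand)
  for (k in seq_len(nrow(genes))) {
    if (meta$role[k] == "te_orf") next  # promoter p already set by its TE
    if (genes$strand[k] == "-") {
      ps <- genes$end[k]; pe <- genes$end[k] + 1000L
    } else {
      ps <- genes$start[k] - 1000L; pe <- genes$start[k]
    }
    ovw(genes$chrom[k], max(0L, ps), pe, meta$promoter_p[k], "promoter")
  }
  p[sites$chrom == "lambda_spike"] <- 0
  region[sites$chrom == "lambda_spike"] <- "spike_unmeth"
  p[sites$chrom == "pUC19_spike"] <- 0.99
  region[sites$chrom == "pUC19_spike"] <- "spike_meth"
  p <- p * config$methylation_scale

  ## ---- read-count sampling per condition/replicate -----------------------
  methylomes <- list()
  meth_conditions <- c(ctrl_1 = "control", ctrl_2 = "control",
                       aza_1 = "treatment", aza_2 = "treatment")
  err <- config$conversion_error
  for (cond in names(meth_conditions)) {
    p_use <- if (meth_conditions[[cond]] == "treatment") {
      p * config$treatment_factor
    } else p
    p_obs <- p_use + (1 - p_use) * err
    cov <- stats::rnbinom(nrow(sites), size = config$coverage_dispersion,
                          mu = config$coverage_mean)
    nm <- stats::rbinom(nrow(sites), cov, p_obs)
    s <- sites
    s$context <- NA_character_
    s$n_meth <- as.integer(nm)
    s$n_total <- as.integer(cov)
    methylomes[[cond]] <- s[cov > 0L, , drop = FALSE]
  }

  ## ---- differential expression tied to promoter methylation --------------
  n <- nrow(genes)
  r <- order(order(meta$promoter_p, genes$gene_id))  # rank by true promoter p
  q <- (r - 0.5) / n
  f_up <- stats::approx(x = c(0, 0.3, 0.5, 0.7, 0.85, 1),
                        y = c(0.06, 0.10, 0.25, 0.55, 0.80, 0.97),
                        xout = q)$y
  f_down <- 0.30 * (1 - q)^1.5 + 0.01
  u <- (r * 0.61803398874989479) %% 1  # low-discrepancy, deterministic
  v <- (r * 0.75487766624669276) %% 1
  up <- u < f_up
  down <- !up & v < f_down / (1 - f_up)
  de <- data.frame(gene_id = genes$gene_id,
                   log2FC = ifelse(up, stats::runif(n, 1.5, 6),
                                   ifelse(down, -stats::runif(n, 1.5, 6),
                                          stats::rnorm(n, 0, 0.25))),
                   padj = ifelse(up | down, 10^stats::runif(n, -8, -2.5),
                                 stats::runif(n, 0.02, 1)),
                   stringsAsFactors = FALSE)
  meta$de_status <- ifelse(up, "up", ifelse(down, "down", "not_de"))

  ## ---- reactivation categories and TPMs ----------------------------------
  meta$category <- "No"
  meta$category[meta$role == "host_active"] <- "Broad"
  for (cl in c("geve", "adintovirus", "plavaka", "te_orf")) {
    idx <- which(meta$role == cl)
    n_aza <- round(config$aza_fraction[[cl]] * length(idx))
    cand <- c(idx[up[idx]], idx[!up[idx]])  # prefer DE-up genes
    meta$category[cand[seq_len(min(n_aza, length(cand)))]] <- "Aza"
    rest <- setdiff(idx, cand[seq_len(min(n_aza, length(cand)))])
    n_broad <- round(0.03 * length(idx))
    meta$category[rest[seq_len(min(n_broad, length(rest)))]] <- "Broad"
  }
  low <- function(m) stats::runif(m, 0, 0.5)
  expr <- data.frame(gene_id = genes$gene_id,
                     dev = low(n), ctrl = low(n), aza = low(n),
                     stringsAsFactors = FALSE)
  broad <- meta$category == "Broad"
  expr$dev[broad] <- exp(stats::rnorm(sum(broad), 3, 1)) + 1
  expr$ctrl[broad] <- exp(stats::rnorm(sum(broad), 3, 1)) + 1
  expr$aza[broad] <- exp(stats::rnorm(sum(broad), 3, 1)) + 1
  aza_sel <- meta$category == "Aza"
  expr$aza[aza_sel] <- stats::runif(sum(aza_sel), 3, 40)
  expr_groups <- c(dev = "development", ctrl = "control", aza = "treatment")

  ## ---- protein-domain hits ------------------------------------------------
  domains <- .simulate_domains(genes, meta, islands)

  truth <- list(
    islands = islands,
    genes = data.frame(gene_id = genes$gene_id, role = meta$role,
                       island_class = meta$island_class,
                       category = meta$category,
                       promoter_p = meta$promoter_p,
                       de_status = meta$de_status,
                       stringsAsFactors = FALSE),
    sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                       strand = sites$strand, context = sites$context,
                       true_p = p, region = region,
                       stringsAsFactors = FALSE),
    te_model = c(intercept = config$te_p_intercept,
                 slope = config$te_p_slope))

  structure(list(genome = genome,
                 analysis_chroms = c("chr1", "scaff_1"),
                 placed_chroms = "chr1",
                 unplaced_chroms = "scaff_1",
                 spike_unmethylated = "lambda_spike",
                 spike_methylated = "pUC19_spike",
                 models = models, tes = tes,
                 methylomes = methylomes,
                 meth_conditions = meth_conditions,
                 expr = expr, expr_groups = expr_groups,
                 de = de, domains = domains,
                 catalog = read_marker_catalog(),
                 truth = truth, config = config),
            class = "sim_bundle")
}

## all CG-dinucleotide cytosines, both strands, as unclassified sites
.cg_sites <- function(genome) {
  out <- list()
  for (chrom in names(genome)) {
    m <- gregexpr("CG", genome[[chrom]], fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    pos0 <- as.integer(m) - 1L  # Watson C of the CG dinucleotide
    out[[chrom]] <- data.frame(
      chrom = chrom,
      pos = c(pos0, pos0 + 1L),
      strand = rep(c("+", "-"), each = length(pos0)),
      context = NA_character_,
      n_meth = 0L, n_total = 0L, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  all <- all[order(match(all$chrom, names(genome)), all$pos, all$strand), ,
             drop = FALSE]
  rownames(all) <- NULL
  all
}

.simulate_domains <- function(genes, meta, islands) {
  rows <- list()
  add <- function(gid, acc, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, domain_accession = acc, domain_name = name,
      stringsAsFactors = FALSE)
  }
  host_pool <- sprintf("PF%05d", 1:40)
  viral_pool <- sprintf("PF%05d", 9001:9015)
  for (k in seq_len(nrow(genes))) {
    gid <- genes$gene_id[k]
    role <- meta$role[k]
    if (role %in% c("host_active", "host_silent")) {
      for (acc in sample(host_pool, 1L + stats::rpois(1L, 0.8))) {
        add(gid, acc, acc)
      }
    } else if (role == "te_orf") {
      add(gid, sample(c("PF00078", "PF03017", "PF13456"), 1L),
          "TE_orf_domain")
    }
  }
  ## viral marker genes: the first genes of each island carry the markers
  marker_sets <- list(
    GEVE = list(c("PF04947", "Pox_VLTF3"), c("PF04665", "Pox_A32_ATPase"),
                c("PF03288", "Pox_D5_primase"),
                c("PF04451", "Capsid_NCLDV_major")),
    adintovirus = list(c("PF00136", "DNA_pol_B"),
                       c("PF17475", "Adinto_capsid_minor"),
                       c("PF16904", "Adinto_capsid_major"),
                       c("PF05869", "Dam_methylase")),
    plavaka = list(c("PF00589", "Tyrosine_recombinase"),
                   c("PF20469", "Plavaka_transposase")))
  for (k in seq_len(nrow(islands))) {
    inside <- genes$gene_id[genes$chrom == islands$chrom[k] &
                              genes$start >= islands$start[k] &
                              genes$end <= islands$end[k]]
    set <- marker_sets[[islands$class[k]]]
    for (j in seq_along(set)) {
      if (j > length(inside)) break
      add(inside[j], set[[j]][1L], set[[j]][2L])
    }
    rest <- inside[-seq_len(min(length(set), length(inside)))]
    if (islands$class[k] == "GEVE" && length(rest) > 0L) {
      jm <- rest[(seq_along(rest) %% 3L) == 1L]  # ~1/3 carry JmjC
      for (gid in jm) add(gid, "PF02373", "JmjC")
    }
    if (islands$class[k] == "plavaka" && length(rest) > 0L) {
      yr <- rest[(seq_along(rest) %% 2L) == 1L]
      for (gid in yr) add(gid, "PF00589", "Tyrosine_recombinase")
    }
    extra <- rest[stats::runif(length(rest)) < 0.4]
    for (gid in extra) {
      acc <- sample(viral_pool, 1L)
      add(gid, acc, acc)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("gene_id", "domain_accession")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated bundle to disk in standard formats
#'
#' FASTA genome, GFF3 gene models, headered TE table, one CGmap per
#' methylome condition/replicate, TPM and condition-group tables, DE table,
#' domain hits, marker catalog, and ground-truth island/gene tables.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(bundle$genome, fp("genome.fa"))
  write_gff3(bundle$models, fp("genes.gff3"))
  write_te_table(bundle$tes, fp("tes.tsv"))
  for (cond in names(bundle$methylomes)) {
    write_methylation_calls(bundle$methylomes[[cond]],
                            fp(sprintf("calls_%s.cgmap", cond)),
                            dialect = "cgmap")
  }
  utils::write.table(bundle$expr, fp("tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(condition = names(bundle$expr_groups),
               group = unname(bundle$expr_groups)),
    fp("conditions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$de, fp("de.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$domains, fp("domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$catalog, fp("marker_catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$islands, fp("truth_islands.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$genes, fp("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
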