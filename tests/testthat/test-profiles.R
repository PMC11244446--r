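test_that("expression stratification: strict TPM cutoff, sorted quantile split", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d"),
                     ctrl = c(0.5, 2, 20, 200), stringsAsFactors = FALSE)
  s <- stratify_genes_by_expression(expr, "ctrl")
  expect_equal(s$not_expressed, "a")
  expect_equal(s$expr_q1, "b")
  expect_equal(s$expr_q2, "c")
  expect_equal(s$expr_q3, "d")

  expr$ctrl[1] <- 1.0  # exactly at the threshold counts as expressed
  s <- stratify_genes_by_expression(expr, "ctrl")
  expect_equal(s$not_expressed, character(0))
  expect_equal(s$expr_q1, "a")
  expect_equal(s$expr_q3, c("c", "d"))

  expect_error(stratify_genes_by_expression(expr[0, ], "ctrl"), "empty")
})

test_that("stratification matches a sort-and-split oracle on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 57L
    expr <- data.frame(gene_id = sprintf("g%03d", sample.int(999L, n)),
                       x = round(runif(n, 0, 30), 1),
                       stringsAsFactors = FALSE)
    s <- stratify_genes_by_expression(expr, "x", n_strata = 4L)
    keep <- expr[expr$x >= 1, ]
    o <- keep[order(keep$x, keep$gene_id), ]
    m <- nrow(o)
    oracle <- split(o$gene_id, ceiling(seq_len(m) * 4 / m))
    for (k in seq_len(4L)) {
      expect_identical(s[[paste0("expr_q", k)]], oracle[[as.character(k)]])
    }
    expect_identical(s$not_expressed, sort(expr$gene_id[expr$x < 1]))
  }
})

test_that("uniform methylation yields flat body bins; orientation is respected", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 3000L,
                      end = 5000L, strand = "+", stringsAsFactors = FALSE)
  models <- mk_models(genes)
  pos <- seq(3000L, 4999L, by = 20L)
  sites <- methylation_sites("c1", pos, "+", 5L, 10L, context = "CG_other")
  prof <- metagene_profile(models, sites, context_filter = "CG_other")
  body <- prof$level[grepl("^body_", prof$bin_label)]
  expect_true(all(abs(body - 0.5) < 1e-12))
  expect_true(all(prof$n_sites[grepl("^up_", prof$bin_label)] == 0L))

  # minus-strand gene methylated only near its TSS (= high coordinates)
  genes$strand <- "-"
  models <- mk_models(genes)
  tss_sites <- methylation_sites("c1", seq(4800L, 4999L, by = 10L), "-",
                                 9L, 10L, context = "CG_other")
  far_sites <- methylation_sites("c1", seq(3000L, 3199L, by = 10L), "-",
                                 0L, 10L, context = "CG_other")
  prof <- metagene_profile(models, rbind(tss_sites, far_sites),
                           context_filter = "CG_other")
  body <- prof[grepl("^body_", prof$bin_label), ]
  expect_equal(body$level[1:2], c(0.9, 0.9))
  expect_equal(body$level[19:20], c(0, 0))
})

test_that("pooled metagene bins equal a per-gene loop oracle", {
  set.seed(22)
  layout <- profile_layout(upstream_bp = 500L, n_flank_bins = 5L,
                           n_body_bins = 10L, downstream_bp = 500L)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "c1",
                      start = seq(2000L, 97000L, length.out = 20),
                      strand = sample(c("+", "-"), 20, TRUE),
                      stringsAsFactors = FALSE)
  genes$start <- as.integer(genes$start)
  genes$end <- genes$start + as.integer(runif(20, 800, 3000))
  models <- mk_models(genes)
  n <- 4000L
  sites <- methylation_sites("c1", sort(sample.int(100000L, n)) - 1L, "+",
                             rbinom(n, 10, 0.5), 10L, context = "CG_other")
  prof <- metagene_profile(models, sites, layout,
                           context_filter = "CG_other")

  nb <- 2L * layout$n_flank_bins + layout$n_body_bins
  sm <- numeric(nb); st <- numeric(nb)
  for (k in seq_len(nrow(genes))) {
    len <- genes$end[k] - genes$start[k]
    for (i in seq_len(nrow(sites))) {
      d <- if (genes$strand[k] == "-") (genes$end[k] - 1L) - sites$pos[i]
           else sites$pos[i] - genes$start[k]
      bin <- if (d < 0 && d >= -layout$upstream_bp) {
        floor((d + layout$upstream_bp) * layout$n_flank_bins /
                layout$upstream_bp)
      } else if (d >= 0 && d < len) {
        layout$n_flank_bins + floor(d * layout$n_body_bins / len)
      } else if (d >= len && d < len + layout$downstream_bp) {
        layout$n_flank_bins + layout$n_body_bins +
          floor((d - len) * layout$n_flank_bins / layout$downstream_bp)
      } else NA_integer_
      if (!is.na(bin)) {
        sm[bin + 1L] <- sm[bin + 1L] + sites$n_meth[i]
        st[bin + 1L] <- st[bin + 1L] + sites$n_total[i]
      }
    }
  }
  expect_equal(prof$sum_meth, sm)
  expect_equal(prof$sum_total, st)
})

test_that("metagene profiles are invariant under genome mirroring", {
  set.seed(23)
  g <- rand_genome(c(c1 = 20000L))
  sites <- cg_site_table(g)
  sites$n_total <- 10L
  sites$n_meth <- rbinom(nrow(sites), 10L, 0.4)
  sites <- classify_sites(g, sites)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(3000L, 12000L), end = c(6000L, 15500L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  models <- mk_models(genes)
  layout <- profile_layout(1000L, 5L, 8L, 1000L)
  p1 <- metagene_profile(models, sites, layout)

  L <- nchar(g[["c1"]])
  g2 <- c(c1 = revcomp_str(g[["c1"]]))
  s2 <- sites
  s2$pos <- L - 1L - sites$pos
  s2$strand <- ifelse(sites$strand == "+", "-", "+")
  s2 <- classify_sites(g2, s2)
  genes2 <- genes
  genes2$start <- L - genes$end
  genes2$end <- L - genes$start
  genes2$strand <- ifelse(genes$strand == "+", "-", "+")
  p2 <- metagene_profile(mk_models(genes2), s2, layout)
  expect_equal(p2$level, p1$level)
  expect_equal(p2$n_sites, p1$n_sites)
})

test_that("pooling property: site-weighted mean of bins equals the pooled level", {
  b <- default_sim()
  sites <- classify_sites(b$genome, b$methylomes$ctrl_1)
  sub <- sites[sites$chrom == "scaff_1", ]
  models <- mk_models(b$models$genes[b$models$genes$chrom == "scaff_1", ],
                      b$models$exons[b$models$exons$gene_id %in%
                                       b$models$genes$gene_id[
                                         b$models$genes$chrom == "scaff_1"], ])
  prof <- metagene_profile(models, sub)
  expect_equal(sum(prof$sum_meth) / sum(prof$sum_total),
               pooled_level(prof$sum_meth, prof$sum_total))
})

test_that("TE profiles honour the consensus-span filter", {
  tes <- data.frame(chrom = "c1",
                    start = c(1000L, 11000L, 21000L),
                    end = c(1000L, 11000L, 21000L) + 1000L,
                    strand = "+", family = "f", divergence = 1,
                    consensus_length = c(1450L, 1429L, 1053L),
                    stringsAsFactors = FALSE)
  tes$consensus_span_fraction <- 1000 / tes$consensus_length  # .69, .70, .95
  sites <- methylation_sites(
    "c1", c(seq(1000L, 1999L, 50L), seq(11000L, 11999L, 50L),
            seq(21000L, 21999L, 50L)), "+",
    rep(c(10L, 0L, 0L), each = 20L), 10L, context = "CG_other")
  layout <- profile_layout(200L, 2L, 5L, 200L)
  prof <- te_profile(tes, sites, layout, context_filter = "CG_other")
  body <- prof$level[grepl("^body_", prof$bin_label)]
  expect_true(all(body == 0))  # the fully methylated copy spans only 69%

  prof_all <- te_profile(tes, sites, layout, min_span_fraction = NULL,
                         context_filter = "CG_other")
  expect_true(all(prof_all$level[grepl("^body_", prof_all$bin_label)] > 0))

  prof_eq <- te_profile(tes[2:3, ], sites, layout,
                        min_span_fraction = NULL,
                        context_filter = "CG_other")
  expect_equal(prof_eq$level, prof$level)  # filter == explicit subset

  expect_error(te_profile(tes, sites, layout, min_span_fraction = 0.96),
               "span filter")
})

test_that("saturated TEs profile near one and divergence bins recover the decay", {
  set.seed(24)
  tes <- data.frame(chrom = "c1",
                    start = seq(0L, 49000L, by = 5000L),
                    end = seq(0L, 49000L, by = 5000L) + 2000L,
                    strand = "+", family = "f",
                    divergence = rep(c(2, 10, 20, 28, 5), 2),
                    consensus_length = 2000L,
                    consensus_span_fraction = 1,
                    stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(nrow(tes))) {
    p <- 0.9 - 0.02 * tes$divergence[k]
    pos <- seq(tes$start[k], tes$end[k] - 1L, by = 25L)
    rows[[k]] <- methylation_sites("c1", pos, "+",
                                   as.integer(round(p * 20)), 20L,
                                   context = "CG_other")
  }
  sites <- do.call(rbind, rows)
  tab <- methylation_vs_divergence(tes, sites,
                                   divergence_breaks = c(0, 7.5, 15, 22.5,
                                                         30),
                                   context_filter = "CG_other")
  expect_true(all(diff(tab$level) < 0))  # monotone decay with age

  single <- methylation_vs_divergence(tes, sites,
                                      divergence_breaks = c(0, 30),
                                      context_filter = "CG_other")
  expect_equal(single$level, pooled_level(sites$n_meth, sites$n_total))

  with_empty <- methylation_vs_divergence(
    tes, sites, divergence_breaks = c(0, 30, 60),
    context_filter = "CG_other")
  expect_true(is.na(with_empty$level[2]))
  expect_true(with_empty$low_support[2])

  sat <- sites
  sat$n_meth <- sat$n_total
  prof <- te_profile(tes, sat, profile_layout(200L, 2L, 5L, 200L),
                     context_filter = "CG_other")
  expect_true(all(prof$level[grepl("^body_", prof$bin_label)] == 1))
})

test_that("silent genes show higher promoter-region methylation than expressed ones", {
  b <- default_sim()
  sites <- classify_sites(b$genome, merge_replicates(
    b$methylomes[c("ctrl_1", "ctrl_2")]))
  strata <- stratify_genes_by_expression(b$expr, "ctrl")
  layout <- profile_layout(1000L, 5L, 10L, 1000L)
  silent <- metagene_profile(b$models, sites, layout,
                             gene_ids = strata$not_expressed,
                             stratum = "not_expressed")
  active <- metagene_profile(b$models, sites, layout,
                             gene_ids = strata$expr_q3, stratum = "high")
  up_silent <- mean(silent$level[grepl("^up_", silent$bin_label)])
  up_active <- mean(active$level[grepl("^up_", active$bin_label)])
  expect_gt(up_silent, up_active)
})
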