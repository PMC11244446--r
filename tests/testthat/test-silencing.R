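test_that("promoter intervals follow strand and truncate at contig edges", {
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      chrom = "c1",
                      start = c(1000L, 100L, 20L),
                      end = c(2000L, 200L, 120L),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  m <- mk_models(genes)
  sites <- methylation_sites("c1", 0:2199, "+", 1L, 2L,
                             context = "CG_other")
  rec <- promoter_methylation(m, sites, promoter_bp = 50L,
                              min_promoter_sites = 1L)
  expect_equal(rec$start[rec$gene_id == "plus"], 950L)
  expect_equal(rec$end[rec$gene_id == "plus"], 1000L)
  expect_equal(rec$start[rec$gene_id == "minus"], 200L)
  expect_equal(rec$end[rec$gene_id == "minus"], 250L)
  expect_equal(rec$start[rec$gene_id == "edge"], 0L)  # truncated, kept
  expect_equal(rec$n_sites[rec$gene_id == "edge"], 20L)
})

test_that("deciles rank genes by level with stable gene-id tie-breaking", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "c1",
                      start = seq(1000L, 91000L, by = 10000L),
                      strand = "+", stringsAsFactors = FALSE)
  genes$end <- genes$start + 1000L
  m <- mk_models(genes)
  rows <- lapply(1:10, function(k) {
    pos <- seq(genes$start[k] - 500L, genes$start[k] - 1L, by = 50L)
    methylation_sites("c1", pos, "+", k, 10L, context = "CG_sym")
  })
  rec <- promoter_methylation(m, do.call(rbind, rows), promoter_bp = 500L)
  expect_equal(rec$decile[match(sprintf("g%02d", 1:10), rec$gene_id)], 1:10)

  set.seed(51)
  for (rep in 1:5) {
    n <- 83L
    ids <- sprintf("g%03d", sample.int(999L, n))
    lv <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    fake <- data.frame(gene_id = ids, level = lv,
                       stringsAsFactors = FALSE)
    o <- order(fake$level, fake$gene_id)
    dec <- integer(n)
    dec[o] <- as.integer(ceiling(seq_len(n) * 10 / n))
    expect_identical(oracle_deciles(ids, lv), dec)
    # drive the full function through sites with these exact levels
    genes_r <- data.frame(gene_id = ids, chrom = "c1",
                          start = seq(2000L, by = 2000L,
                                      length.out = n),
                          strand = "+", stringsAsFactors = FALSE)
    genes_r$end <- genes_r$start + 500L
    sites_r <- do.call(rbind, lapply(seq_len(n), function(k) {
      pos <- seq(genes_r$start[k] - 1000L, genes_r$start[k] - 1L,
                 by = 100L)
      methylation_sites("c1", pos, "+", as.integer(lv[k] * 20), 20L,
                        context = "CG_sym")
    }))
    rec_r <- promoter_methylation(mk_models(genes_r), sites_r)
    expect_identical(rec_r$decile[match(ids, rec_r$gene_id)], dec)
  }
})

test_that("promoter records exclude genes under the site floor", {
  genes <- data.frame(gene_id = c("rich", "poor"), chrom = "c1",
                      start = c(2000L, 10000L), end = c(3000L, 11000L),
                      strand = "+", stringsAsFactors = FALSE)
  sites <- rbind(
    methylation_sites("c1", seq(1000L, 1999L, 100L), "+", 1L, 2L,
                      context = "CG_sym"),
    methylation_sites("c1", 9500L, "+", 1L, 2L, context = "CG_sym"))
  rec <- promoter_methylation(mk_models(genes), sites)
  expect_equal(rec$gene_id, "rich")
})

test_that("decile response table applies strict DE thresholds and conserves margins", {
  rec <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    level = seq(0.05, 1, by = 0.05))
  rec$decile <- oracle_deciles(rec$gene_id, rec$level)
  de <- data.frame(gene_id = rec$gene_id,
                   log2FC = rep(c(2, -2, 0.1, 3), 5),
                   padj = rep(c(0.005, 0.001, 0.5, 0.01), 5),
                   stringsAsFactors = FALSE)
  tab <- decile_response_table(rec, de)
  # per decile of two genes: one up (padj .005), one down / padj-at-cutoff
  expect_equal(tab$up + tab$down + tab$not_de, rep(2L, 10))
  expect_equal(sum(tab$up + tab$down + tab$not_de), nrow(rec))
  # padj exactly at the cutoff is not DE
  at_cutoff <- de$padj == 0.01
  expect_equal(sum(tab$up), sum(de$padj < 0.01 & de$log2FC > 0))
  expect_equal(sum(tab$down), sum(de$padj < 0.01 & de$log2FC < 0))

  de_miss <- de[1:10, ]
  expect_warning(tab2 <- decile_response_table(rec, de_miss), "missing")
  expect_equal(sum(tab2$up + tab2$down + tab2$not_de), 20L)
})

test_that("reactivation categories follow the Aza/Broad/No truth table", {
  expr <- data.frame(gene_id = c("aza", "broad", "no", "edge"),
                     dev = c(0, 2, 0, 0.99),
                     ctrl = c(0, 0, 0, 0.5),
                     aza = c(5, 8, 0, 1.0), stringsAsFactors = FALSE)
  groups <- c(dev = "development", ctrl = "control", aza = "treatment")
  cats <- reactivation_categories(expr, groups)
  expect_equal(as.character(cats$category), c("Aza", "Broad", "No", "Aza"))

  expect_error(reactivation_categories(expr, groups[1:2]), "without group")

  set.seed(52)
  for (rep in 1:10) {
    n <- 60L
    rexpr <- data.frame(gene_id = sprintf("g%02d", 1:n),
                        dev = round(runif(n, 0, 3), 2),
                        ctrl = round(runif(n, 0, 3), 2),
                        aza = round(runif(n, 0, 3), 2),
                        stringsAsFactors = FALSE)
    cats <- reactivation_categories(rexpr, groups)
    expect_identical(as.character(cats$category),
                     oracle_categories(rexpr, groups))
    # partition: every gene gets exactly one category
    expect_equal(sum(table(cats$category)), n)
  }
})

test_that("reactivation summaries keep empty classes and match a group-by oracle", {
  cats <- data.frame(gene_id = sprintf("g%03d", 1:130),
                     category = factor(c(rep("Aza", 26), rep("No", 74),
                                         rep("Broad", 30)),
                                       levels = c("Aza", "Broad", "No")),
                     stringsAsFactors = FALSE)
  cls <- data.frame(gene_id = sprintf("g%03d", 1:130),
                    class = c(rep("GEVE", 100), rep("adintovirus", 30)),
                    stringsAsFactors = FALSE)
  cls$class <- factor(cls$class, levels = c("GEVE", "adintovirus",
                                            "empty_class"))
  tab <- reactivation_summary(cats, cls)
  expect_equal(tab$n[tab$class == "GEVE" & tab$category == "Aza"], 26L)
  expect_equal(tab$pct[tab$class == "GEVE" & tab$category == "Aza"], 26)
  expect_true("empty_class" %in% tab$class)
  expect_equal(sum(tab$n[tab$class == "empty_class"]), 0L)

  for (cl in c("GEVE", "adintovirus")) {
    for (ct in c("Aza", "Broad", "No")) {
      manual <- sum(cls$class == cl &
                      as.character(cats$category) == ct)
      expect_equal(tab$n[tab$class == cl & tab$category == ct], manual)
    }
  }

  expect_error(reactivation_summary(cats[1:10, ], cls), "without a")
})

test_that("two-sided Fisher p matches enumeration and standard implementations", {
  expect_equal(fisher_exact_p(0, 10, 0, 90), 1.0)
  expect_equal(fisher_exact_p(10, 90, 10, 990),
               oracle_fisher_p(10, 90, 10, 990), tolerance = 1e-10)
  # swapping in-set/out-set labels leaves the two-sided p unchanged
  expect_equal(fisher_exact_p(10, 90, 10, 990),
               fisher_exact_p(10, 990, 10, 90), tolerance = 1e-12)

  set.seed(53)
  for (rep in 1:50) {
    x <- as.integer(rmultinom(1, sample(20:200, 1L), runif(4, 0.05, 1)))
    p_pkg <- fisher_exact_p(x[1], x[2], x[3], x[4])
    p_ref <- stats::fisher.test(matrix(x, 2))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
})

test_that("domain enrichment builds correct tables, BH q-values monotone in p", {
  set.seed(54)
  bg <- sprintf("g%03d", 1:200)
  gs <- bg[1:40]
  rows <- list()
  for (acc in sprintf("D%02d", 1:12)) {
    carriers <- sample(bg, sample(5:60, 1L))
    if (acc == "D01") carriers <- union(carriers, gs[1:25])  # enriched
    rows[[acc]] <- data.frame(gene_id = carriers, domain_accession = acc,
                              domain_name = acc, stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, rows)
  res <- fisher_domain_enrichment(domains, gs, bg)
  expect_equal(res$domain_accession[1], "D01")
  for (k in seq_len(nrow(res))) {
    carriers <- unique(domains$gene_id[
      domains$domain_accession == res$domain_accession[k]])
    expect_equal(res$a[k], sum(carriers %in% gs))
    expect_equal(res$a[k] + res$b[k], length(gs))
    expect_equal(res$a[k] + res$b[k] + res$c[k] + res$d[k], length(bg))
    expect_equal(res$p_value[k],
                 oracle_fisher_p(res$a[k], res$b[k], res$c[k], res$d[k]),
                 tolerance = 1e-10)
  }
  expect_true(all(diff(res$q_value) >= -1e-12))  # sorted by p already
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  out_of_bg <- rbind(domains,
                     data.frame(gene_id = "stranger",
                                domain_accession = "D99",
                                domain_name = "D99"))
  expect_message(res2 <- fisher_domain_enrichment(out_of_bg, gs, bg),
                 "outside the background")
  expect_false("D99" %in% res2$domain_accession)
  expect_error(fisher_domain_enrichment(domains, c(gs, "stranger"), bg),
               "subset")
})
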