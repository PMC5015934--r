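test_that("dose-response fit recovers exact and degenerate lines", {
  fit <- fit_dose_response(data.frame(concentration = c(0, 25, 50, 100),
                                      level = c(0.8, 0.6, 0.4, 0.0)))
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$slope, -0.008)
  expect_equal(fit$intercept, 0.8)

  flat <- fit_dose_response(data.frame(concentration = c(0, 25, 50, 100),
                                       level = rep(0.5, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(fit_dose_response(data.frame(concentration = c(10, 10, 10),
                                            level = c(1, 2, 3))),
               "distinct concentrations")
})

test_that("OLS matches the closed-form normal equations", {
  withr::local_seed(3)
  for (i in 1:20) {
    x <- sample(c(0, 25, 50, 100))
    y <- runif(4)
    fit <- fit_dose_response(concentration = x, level = y)
    o <- oracle_ols(x, y)
    expect_equal(fit$slope, o$slope)
    expect_equal(fit$intercept, o$intercept)
    expect_equal(fit$r_squared, o$r_squared)
    # r^2 equals the squared Pearson correlation
    expect_equal(fit$r_squared, cor(x, y)^2)
  }
})

test_that("DE filter applies the pseudocount and strict thresholds", {
  e <- data.frame(gene_id = c("a", "b", "c", "d"),
                  fpkm_control = c(0.0, 2, 1, 5),
                  fpkm_treated = c(0.9, 2, (1 + 0.1) * 2^2 - 0.1, 0.1),
                  q_value = c(0.01, 0.01, 0.01, 0.01))
  de <- de_filter(e)
  expect_equal(de[de$gene_id == "a", log2fc], log2(10))
  expect_equal(de[de$gene_id == "a", status], "up")
  expect_equal(de[de$gene_id == "b", log2fc], 0)
  expect_equal(de[de$gene_id == "b", status], "unchanged")
  # log2fc of exactly 2.0 is excluded: "greater than 2.0" is strict
  expect_equal(de[de$gene_id == "c", log2fc], 2.0)
  expect_equal(de[de$gene_id == "c", status], "unchanged")
  expect_equal(de[de$gene_id == "d", status], "down")

  expect_error(de_filter(data.frame(gene_id = "x", fpkm_control = -1,
                                    fpkm_treated = 0, q_value = 0.5)),
               "negative")
})

test_that("DE filter is monotone in its thresholds", {
  withr::local_seed(13)
  e <- data.frame(gene_id = sprintf("g%03d", 1:300),
                  fpkm_control = rlnorm(300),
                  fpkm_treated = rlnorm(300, 1.5),
                  q_value = runif(300))
  base_up <- de_filter(e)$status == "up"
  looser_q <- de_filter(e, q_max = 0.2)$status == "up"
  looser_fc <- de_filter(e, lfc_min = 1)$status == "up"
  expect_true(all(base_up <= looser_q))
  expect_true(all(base_up <= looser_fc))
})

test_that("Fisher enrichment agrees with hypergeometric enumeration", {
  bg <- sprintf("g%04d", 1:1000)
  cat_ids <- bg[1:100]
  up <- c(bg[1:10], bg[101:110])   # table [[10, 90], [10, 890]]
  res <- fisher_enrichment(cat_ids, bg, up)
  expect_equal(unname(res$table["category", ]), c(10, 90))
  expect_equal(unname(res$table["rest", ]), c(10, 890))
  expect_equal(res$p_value, oracle_fisher_p(10, 90, 10, 890))
  expect_equal(res$odds_ratio, (10 * 890) / (90 * 10))

  # same up-fraction in category and background -> no signal
  up_null <- c(bg[1:5], bg[101:145])  # 5% everywhere
  expect_gt(fisher_enrichment(cat_ids, bg, up_null)$p_value, 0.5)

  # empty-up category over an up-free background
  expect_equal(fisher_enrichment(cat_ids, bg, character(0))$p_value, 1)

  expect_error(fisher_enrichment(c("zz"), bg, up), "subset")
  expect_error(fisher_enrichment(character(0), bg, up), "empty")
})

test_that("upregulation summary tallies kinds, classes and families", {
  ann <- data.table::data.table(
    chrom = "chr1", start = 0L, end = 1L, strand = "+",
    id = c(sprintf("pc%02d", 1:10), sprintf("te%02d", 1:10)),
    kind = rep(c("protein_coding_gene", "TE_gene"), each = 10),
    te_family = c(rep("", 10), rep(c("CACTA", "Copia"), each = 5)))
  cls <- data.frame(id = sprintf("pc%02d", 1:10),
                    class = rep(c("gbM", "mCHH"), each = 5))
  de <- data.frame(gene_id = c("pc01", "pc06", "te01", "te02", "te06"),
                   log2fc = 3, q_value = 0.01, status = "up")
  s <- upregulation_summary(de, ann, cls)
  expect_equal(s[group_type == "gene_kind" & group == "TE_gene", n_up], 3L)
  expect_equal(s[group_type == "meth_class" & group == "mCHH", pct_up], 20)
  expect_equal(s[group_type == "te_family" & group == "CACTA", pct_up], 40)
  expect_equal(s[group_type == "te_family" & group == "Copia", n_total], 5L)

  # no upregulated genes -> all percentages 0
  s0 <- upregulation_summary(de[0, ], ann, cls)
  expect_true(all(s0$pct_up == 0))

  # unresolvable ids are excluded with a message
  de_bad <- rbind(de, data.frame(gene_id = "ghost", log2fc = 5,
                                 q_value = 0.001, status = "up"))
  expect_message(s2 <- upregulation_summary(de_bad, ann, cls),
                 "not in annotation")
  expect_equal(s2$n_up, s$n_up)

  # unclassified protein-coding genes land in an explicit bucket
  s3 <- upregulation_summary(de, ann, cls[1:5, , drop = FALSE])
  expect_true("other/unclassified" %in%
                s3[group_type == "meth_class", group])
})

test_that("random summaries agree with a direct tally oracle", {
  withr::local_seed(23)
  fams <- c("CACTA", "Copia", "Gypsy", "LINE", "other")
  ann <- data.table::data.table(
    chrom = "chr1", start = 0L, end = 1L, strand = "+",
    id = sprintf("te%03d", 1:200), kind = "TE_gene",
    te_family = sample(fams, 200, replace = TRUE))
  up_ids <- sample(ann$id, 40)
  de <- data.frame(gene_id = up_ids, log2fc = 3, q_value = 0.001,
                   status = "up")
  s <- upregulation_summary(de, ann)
  for (fam in fams) {
    in_fam <- ann$id[ann$te_family == fam]
    expect_equal(s[group_type == "te_family" & group == fam, n_up],
                 length(intersect(in_fam, up_ids)))
    expect_equal(s[group_type == "te_family" & group == fam, pct_up],
                 100 * length(intersect(in_fam, up_ids)) / length(in_fam))
  }
})

test_that("BH utility agrees with the literal step-up oracle", {
  withr::local_seed(33)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
  # ties handled by the running minimum
  p <- c(0.01, 0.01, 0.5, 0.5, 0.9)
  expect_equal(adjust_bh(p), oracle_bh(p))
})
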