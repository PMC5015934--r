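test_that("weighted methylation follows the read-pooling formula", {
  m <- make_meth("chr1", c(10, 20), mc = c(5, 0), total = c(10, 10))
  expect_equal(weighted_methylation(m, "CG")$level, 0.25)
  m2 <- make_meth("chr1", c(10, 20), mc = c(10, 10), total = c(10, 10))
  expect_equal(weighted_methylation(m2, "CG")$level, 1.0)
  # zero-coverage sites never contribute; empty set is NA, not 0
  m3 <- make_meth("chr1", c(10, 20), mc = 0L, total = 0L)
  expect_true(is.na(weighted_methylation(m3, "CG")$level))
})

test_that("weighted methylation matches a loop oracle on random fixtures", {
  withr::local_seed(11)
  for (i in 1:20) {
    m <- random_meth(1000)
    expect_equal(weighted_methylation(m, "ALL")$level, oracle_weighted(m))
    ctx <- sample(c("CG", "CHG", "CHH"), 1)
    expect_equal(weighted_methylation(m, ctx)$level, oracle_weighted(m, ctx))
  }
})

test_that("region-restricted weighted methylation uses half-open membership", {
  m <- make_meth("chr1", c(100, 101, 200, 201), mc = c(1, 2, 3, 4),
                 total = 10L)
  # pos-1 in [100, 200): sites at pos 101..200
  r <- weighted_methylation(m, "ALL",
                            region = list(chrom = "chr1", start = 100,
                                          end = 200))
  expect_equal(r$n_sites, 2L)
  expect_equal(r$level, (2 + 3) / 20)
})

test_that("window tiling partitions every chromosome exactly", {
  w <- make_windows(c(chr1 = 250L), 100)
  expect_equal(w$start, c(0L, 100L, 200L))
  expect_equal(w$end, c(100L, 200L, 250L))
  expect_equal(make_windows(c(chr1 = 100L), 100)[, .N], 1L)
  withr::local_seed(2)
  for (i in 1:10) {
    len <- sample.int(10000, 1); wbp <- sample.int(700, 1)
    w <- make_windows(c(a = len), wbp)
    expect_equal(sum(w$end - w$start), len)
    expect_true(all(w$start[-1] == w$end[-nrow(w)]))  # contiguous
  }
})

test_that("chromosome profile equals brute-force per-window recomputation", {
  m <- make_meth("chr1", seq(5, 995, by = 10), mc = 9L, total = 10L)
  prof <- chromosome_profile(m, c(chr1 = 1000L), 100, contexts = "CG")
  expect_equal(prof$level, rep(0.9, 10))  # homogeneous input

  withr::local_seed(21)
  m <- random_meth(400, max_pos = 1000L)
  prof <- chromosome_profile(m, c(chr1 = 1000L), 100,
                             contexts = c("CG", "CHG", "CHH"))
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_equal(prof[context == ctx][order(start), level],
                 unname(oracle_window_levels(m, 1000L, 100, ctx)))
  }
  # windows with no covered sites are undefined with n_sites = 0
  empty <- make_meth("chr1", 5, mc = 1L, total = 2L)
  prof <- chromosome_profile(empty, c(chr1 = 300L), 100, contexts = "CG")
  expect_true(is.na(prof[start == 100, level]))
  expect_equal(prof[start == 100, n_sites], 0L)
})

test_that("profiles are invariant to input record order", {
  withr::local_seed(31)
  m <- random_meth(500, max_pos = 5000L)
  shuf <- m[sample(.N)]
  expect_equal(chromosome_profile(m, c(chr1 = 5000L), 500),
               chromosome_profile(shuf, c(chr1 = 5000L), 500))
})

test_that("relative profile is 1 for self, ratio otherwise, NA at control 0", {
  withr::local_seed(41)
  m <- random_meth(300, max_pos = 2000L)
  prof <- chromosome_profile(m, c(chr1 = 2000L), 200)
  self <- relative_profile(prof, prof)
  expect_true(all(self$ratio[!is.na(self$ratio)] == 1))

  a <- data.table::copy(prof); b <- data.table::copy(prof)
  a[, level := 0.2]; b[, level := 0.4]
  expect_true(all(relative_profile(a, b)$ratio == 0.5))
  b[1, level := 0]
  expect_true(is.na(relative_profile(a, b)$ratio[1]))

  other <- chromosome_profile(m, c(chr1 = 2000L), 250)
  expect_error(relative_profile(prof, other), "grids")
})

test_that("site level distribution normalizes and counts saturated sites", {
  m <- make_meth("chr1", c(1, 2, 3), mc = c(10, 10, 5), total = 10L)
  d <- site_level_distribution(m, "CG")
  expect_equal(d$fraction_fully_methylated, 2 / 3)
  expect_equal(sum(d$fraction), 1)

  m0 <- make_meth("chr1", 1:5, mc = 0L, total = 10L, call = 0L)
  d0 <- site_level_distribution(m0, "CG", only_methylated_sites = FALSE)
  expect_equal(d0$fraction_fully_methylated, 0)
  expect_equal(d0$fraction[1], 1)

  expect_error(site_level_distribution(m0, "CG",
                                       only_methylated_sites = TRUE),
               "no qualifying sites")

  withr::local_seed(51)
  for (i in 1:10) {
    m <- random_meth(500)
    d <- site_level_distribution(m, "ALL")
    expect_equal(sum(d$counts), sum(m$total_count > 0))
    expect_equal(sum(d$fraction), 1)
  }
})

test_that("high-methylation pairwise filter keeps qualifying windows only", {
  m <- make_meth("chr1", c(50, 150), mc = c(6, 4), total = 10L)
  ctl <- chromosome_profile(m, c(chr1 = 200L), 100, contexts = "CG")
  trt <- data.table::copy(ctl)
  trt[, `:=`(sum_mc = sum_mc / 2, level = level / 2)]
  pairs <- pairwise_high_meth_windows(trt, ctl, "CG",
                                      min_control_level = 0.5)
  expect_equal(nrow(pairs), 1L)   # only the 0.6 control window
  expect_equal(pairs$control_level, 0.6)
  expect_equal(pairs$ratio, 0.5)

  same <- pairwise_high_meth_windows(ctl, ctl, "CG", 0.3)
  expect_true(all(same$treated_level == same$control_level))
  expect_equal(unname(attr(same, "ratio_quantiles")["50%"]), 1)
})

test_that("pericentromere partition assigns each window by midpoint", {
  w <- make_windows(c(chr1 = 400L), 100)
  peri <- data.frame(chrom = "chr1", start = 50, end = 200)
  p <- partition_pericentromere(w, peri)
  # midpoints 50, 150, 250, 350
  expect_equal(p$compartment, c("pericentromere", "pericentromere",
                                "arm", "arm"))
  expect_equal(nrow(p), nrow(w))            # partition: every window once
  expect_true(all(p$compartment %in% c("pericentromere", "arm")))
})

test_that("pooled weighted methylation equals count-weighted union of parts", {
  withr::local_seed(61)
  m <- random_meth(600, max_pos = 3000L)
  parts <- list(list(chrom = "chr1", start = 0, end = 1000),
                list(chrom = "chr1", start = 1000, end = 2200),
                list(chrom = "chr1", start = 2200, end = 3000))
  per <- lapply(parts, function(r) weighted_methylation(m, "ALL", region = r))
  pooled_mc <- sum(sapply(per, `[[`, "sum_mc"))
  pooled_tot <- sum(sapply(per, `[[`, "sum_total"))
  expect_equal(weighted_methylation(m, "ALL")$level, pooled_mc / pooled_tot)
})

test_that("ALL-context level lies between per-context extremes", {
  withr::local_seed(71)
  for (i in 1:10) {
    m <- random_meth(400)
    lv <- sapply(c("CG", "CHG", "CHH"),
                 function(cx) weighted_methylation(m, cx)$level)
    lv <- lv[!is.na(lv)]
    all_lv <- weighted_methylation(m, "ALL")$level
    expect_gte(all_lv, min(lv) - 1e-12)
    expect_lte(all_lv, max(lv) + 1e-12)
  }
})

test_that("region profile matches direct per-feature computation", {
  withr::local_seed(81)
  m <- random_meth(500, max_pos = 5000L)
  feats <- data.table::data.table(
    chrom = "chr1", start = c(0L, 1500L, 4000L),
    end = c(1000L, 2500L, 5000L), strand = "+",
    id = c("a", "b", "c"), kind = "region", te_family = "")
  rp <- region_profile(m, feats, contexts = c("CG", "CHH"))
  for (i in seq_len(nrow(feats))) {
    for (ctx in c("CG", "CHH")) {
      direct <- weighted_methylation(m, ctx,
                                     region = as.list(feats[i, .(chrom, start, end)]))
      row <- rp[id == feats$id[i] & context == ctx]
      expect_equal(row$level, direct$level)
      expect_equal(row$n_sites, direct$n_sites)
    }
  }
})
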