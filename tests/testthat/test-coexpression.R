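# the core screen: correlation, t-test threshold, counting, selection

test_that("pearson_r matches the product-moment oracle and its symmetries", {
  x <- 1:7; y <- c(2, 1, 4, 3, 6, 5, 8)
  expect_equal(pearson_r(x, y), 0.896, tolerance = 5e-4)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  # invariance under positive affine transforms
  expect_equal(pearson_r(3 * x + 2, y), pearson_r(x, y))
  expect_equal(pearson_r(x, 0.1 * y + 100), pearson_r(x, y))
  expect_error(pearson_r(rep(1, 7), y), "zero-variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation t statistic is exact, odd in r, increasing in |r|", {
  expect_equal(corr_t_statistic(0, 7), 0.0)
  expect_equal(corr_t_statistic(0.5, 7), 0.5 * sqrt(5) / sqrt(0.75))
  expect_equal(corr_t_statistic(0.5, 7), 1.291, tolerance = 5e-4)
  rs <- seq(-0.95, 0.95, by = 0.05)
  ts <- corr_t_statistic(rs, 7)
  expect_equal(ts, -rev(ts))                 # odd
  expect_true(all(diff(ts) > 0))             # increasing
  expect_error(corr_t_statistic(1, 7), "infinite")
  expect_error(corr_t_statistic(0.5, 2), ">= 3")
})

test_that("significance threshold inverts the t test exactly", {
  # the study's operating point: n = 7 stages, two-sided alpha = 0.05
  expect_equal(round(significance_threshold_r(7, 0.05), 3), 0.754)
  expect_equal(round(significance_threshold_r(3, 0.05), 3), 0.997)
  expect_lt(significance_threshold_r(12, 0.05),
            significance_threshold_r(7, 0.05))
  expect_lt(significance_threshold_r(7, 0.10),
            significance_threshold_r(7, 0.05))
  # mutual inverse with the t statistic, to 1e-9
  for (n in c(4, 5, 7, 10, 30)) {
    for (alpha in c(0.01, 0.05, 0.2)) {
      thr <- significance_threshold_r(n, alpha)
      expect_equal(corr_t_statistic(thr, n), qt(1 - alpha / 2, n - 2),
                   tolerance = 1e-9)
    }
  }
  expect_error(significance_threshold_r(2, 0.05), ">= 3")
  expect_error(significance_threshold_r(7, 0), "> 0")
})

test_that("a toy screen classifies identical, negated and constant TFs", {
  sg1 <- c(5, 6, 8, 12, 20, 30, 50)
  m <- make_matrix(c(sg1, sg1 * 2, 60 - sg1,   # SG1, SG2, SG3
                     sg1,                      # TF1 == SG1 (and prop. SG2)
                     rep(9, 7)),               # TF2 constant
                   c("SG1", "SG2", "SG3", "TF1", "TF2"))
  rec <- screen_pathway(m, toy_catalog(), "demo")
  expect_identical(nrow(rec), 6L)
  tf1 <- rec[rec$source_id == "TF1", ]
  expect_true(all(tf1$significant))
  expect_identical(sort(tf1$sign), c("negative", "positive", "positive"))
  expect_equal(tf1$r[tf1$target_id == "SG3"], -1.0)
  tf2 <- rec[rec$source_id == "TF2", ]
  expect_true(all(tf2$excluded))
  expect_true(all(tf2$reason == "source_zero_variance"))
  expect_false(any(tf2$significant))

  rows <- summarize_tf(rec, toy_catalog())
  expect_identical(rows$n_correlated[rows$tf_id == "TF1"], 3L)
  expect_identical(rows$n_positive[rows$tf_id == "TF1"], 2L)
  expect_identical(rows$n_negative[rows$tf_id == "TF1"], 1L)
  expect_identical(rows$n_correlated[rows$tf_id == "TF2"], 0L)
  expect_identical(rows$family[rows$tf_id == "TF1"], "MYB")
})

test_that("screen output equals a brute-force double loop to 1e-12", {
  set.seed(30)
  n_tf <- 12; n_sg <- 8
  tf_ids <- sprintf("TF%02d", 1:n_tf); sg_ids <- sprintf("SG%02d", 1:n_sg)
  vals <- matrix(rexp(7 * (n_tf + n_sg), rate = 0.05) + 5,
                 n_tf + n_sg, 7, dimnames = list(c(tf_ids, sg_ids), NULL))
  m <- expression_matrix(vals, "AC")
  catalog <- gene_catalog(list(p = sg_ids), tf_ids)
  cfg <- screen_config(min_rpkm = 0)
  rec <- screen_pathway(m, catalog, "p", cfg)
  tc <- qt(0.975, 5)
  for (i in seq_len(nrow(rec))) {
    x <- vals[rec$source_id[i], ]; y <- vals[rec$target_id[i], ]
    r <- oracle_pearson(x, y)
    expect_equal(rec$r[i], r, tolerance = 1e-12)
    expect_equal(rec$t_stat[i], r * sqrt(5) / sqrt(1 - r^2),
                 tolerance = 1e-12)
    expect_identical(rec$significant[i],
                     abs(r) >= 0.8 && abs(r * sqrt(5) / sqrt(1 - r^2)) > tc)
  }
})

test_that("screen applies the expression floor with exclusion reasons", {
  sg <- c(5, 6, 8, 12, 20, 30, 50)
  m <- make_matrix(c(sg, sg / 100,      # SG1 kept, SG2 below floor
                     sg, sg / 100),     # TF1 kept, TF2 below floor
                   c("SG1", "SG2", "TF1", "TF2"))
  catalog <- gene_catalog(list(p = c("SG1", "SG2")), c("TF1", "TF2"))
  rec <- screen_pathway(m, catalog, "p", screen_config())
  expect_identical(nrow(rec), 4L)
  expect_true(rec$significant[rec$source_id == "TF1" & rec$target_id == "SG1"])
  expect_identical(
    rec$reason[rec$source_id == "TF2" & rec$target_id == "SG1"],
    "source_below_expression_floor")
  expect_identical(
    rec$reason[rec$source_id == "TF1" & rec$target_id == "SG2"],
    "target_below_expression_floor")
  expect_true(all(is.na(rec$r[rec$excluded])))
  # errors when nothing survives
  expect_error(screen_pathway(m, catalog, "p", screen_config(min_rpkm = 1e5)))
  expect_error(screen_pathway(m, catalog, "nope"), "unknown pathway")
})

test_that("counting identity: positives plus negatives equal correlated", {
  set.seed(31)
  for (rep in 1:5) {
    vals <- matrix(2^rnorm(30 * 7, 4, 2), 30, 7,
                   dimnames = list(c(sprintf("TF%02d", 1:20),
                                     sprintf("SG%02d", 1:10)), NULL))
    m <- expression_matrix(vals, "AC")
    catalog <- gene_catalog(list(p = sprintf("SG%02d", 1:10)),
                            sprintf("TF%02d", 1:20))
    rows <- summarize_tf(screen_pathway(m, catalog, "p",
                                        screen_config(min_rpkm = 0)))
    expect_identical(rows$n_positive + rows$n_negative, rows$n_correlated)
    expect_true(all(rows$n_correlated <= 10))
  }
})

test_that("candidate selection follows per-genotype count rules", {
  rows <- data.frame(
    tf_id = rep(c("tfA", "tfB", "tfC"), each = 2),
    family = NA_character_, pathway = "carotenoid",
    genotype_id = rep(c("AC", "HG6-61"), 3),
    n_correlated = c(9L, 6L, 16L, 3L, 2L, 2L),
    n_positive = c(4L, 2L, 10L, 1L, 2L, 2L),
    n_negative = c(5L, 4L, 6L, 2L, 0L, 0L),
    stringsAsFactors = FALSE)
  both <- select_candidates(rows, min_count = 5, require_both = TRUE)
  expect_setequal(unique(both$tf_id), "tfA")   # 9 and 6: kept; 16/3 dropped
  any1 <- select_candidates(rows, min_count = 5, require_both = FALSE)
  expect_setequal(unique(any1$tf_id), c("tfA", "tfB"))
  # sorted by max count descending, tf_id ascending tiebreak
  expect_identical(unique(any1$tf_id), c("tfB", "tfA"))
  all3 <- select_candidates(rows, min_count = 0)
  expect_setequal(unique(all3$tf_id), c("tfA", "tfB", "tfC"))
  expect_error(select_candidates(rows, min_count = -1), ">= 0")
})

test_that("summarize_tf refuses mixed pathways and empty records", {
  r1 <- data.frame(source_id = "t", target_id = "s", genotype_id = "AC",
                   pathway = c("a", "b"), r = 0.9, n = 7L, t_stat = 1,
                   df = 5L, significant = TRUE, sign = "positive",
                   excluded = FALSE, reason = NA, stringsAsFactors = FALSE)
  expect_error(summarize_tf(r1), "mix pathways")
  expect_error(summarize_tf(r1[0, ]), "empty")
})

test_that("cross-dataset validation consolidates counts across datasets", {
  sg1 <- c(5, 6, 8, 12, 20, 30, 50)
  m <- make_matrix(c(sg1, sg1 * 2, 60 - sg1, sg1, 2^(7:1) * 3),
                   c("SG1", "SG2", "SG3", "TF1", "TF2"))
  catalog <- toy_catalog()
  rows <- summarize_tf(screen_pathway(m, catalog, "demo"), catalog)

  # no extra matrices: unchanged
  expect_identical(cross_dataset_validate(rows, list(), catalog, "demo"),
                   rows)
  # identical extra dataset: identical counts
  heinz <- make_matrix(c(sg1, sg1 * 2, 60 - sg1, sg1, 2^(7:1) * 3),
                       c("SG1", "SG2", "SG3", "TF1", "TF2"),
                       genotype = "Heinz")
  tab <- cross_dataset_validate(rows, list(heinz), catalog, "demo")
  expect_identical(tab$AC_n_correlated, tab$Heinz_n_correlated)
  expect_identical(tab$AC_n_positive, tab$Heinz_n_positive)
  expect_true(tab$in_all[tab$tf_id == "TF1"])

  disjoint <- make_matrix(rep(sg1, 2), c("X1", "X2"), genotype = "Spim")
  expect_error(cross_dataset_validate(rows, list(disjoint), catalog, "demo"),
               "no gene ids")
})
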