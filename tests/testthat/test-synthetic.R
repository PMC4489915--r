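# the planted-truth generator and recovery scoring

test_that("archetype family covers the canonical shapes distinctly", {
  shapes <- generate_archetypes(20)
  expect_identical(dim(shapes), c(20L, 7L))
  expect_true(all(c("increasing", "decreasing", "late_induction",
                    "peak_mid", "valley_mid", "high_low_high", "flat_high")
                  %in% rownames(shapes)))
  # pairwise r below 0.95 between distinct shapes
  r <- cor(t(shapes))
  expect_lt(max(r[upper.tri(r)]), 0.95)
  # monotone pair anticorrelated
  expect_lt(cor(shapes["increasing", ], shapes["decreasing", ]), 0)
  # high-low-high dips at an interior stage
  hlh <- shapes["high_low_high", ]
  expect_true(which.min(hlh) > 1 && which.min(hlh) < 7)
  # k = 2 gives one increasing, one decreasing shape
  two <- generate_archetypes(2)
  expect_identical(rownames(two), c("increasing", "decreasing"))
  # parameterised variants keep the family distinct well past the base set
  many <- generate_archetypes(30)
  rm_ <- cor(t(many))
  expect_lt(max(rm_[upper.tri(rm_)]), 0.95)
  expect_identical(anyDuplicated(many), 0L)
  expect_error(generate_archetypes(1), ">= 2")
})

test_that("simulation is deterministic and matches the study dimensions", {
  cfg <- sim_config(n_tfs = 30, n_background_genes = 50, n_archetypes = 8,
                    seed = 5)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$expression$AC$values, s2$expression$AC$values)
  expect_identical(s1$truth$links, s2$truth$links)
  expect_identical(s1$metabolites[[1]]$values, s2$metabolites[[1]]$values)

  expect_named(s1$expression, c("AC", "HG6-61"))
  expect_identical(vapply(s1$catalog$pathways, length, 1L),
                   c(ascorbate = 46L, carotenoid = 18L, flavonoid = 14L))
  expect_identical(as.integer(s1$expression$AC$stages),
                   as.integer(stage_axis()))
  expect_true(all(s1$expression$AC$values >= 0))
  # default-config catalog dimensions (no expression generation needed)
  dflt <- sim_config()
  expect_identical(dflt$n_tfs, 823L)
  expect_identical(sum(dflt$n_links), 50L)
})

test_that("zero noise makes every planted link a perfect correlation", {
  cfg <- sim_config(n_tfs = 25, n_background_genes = 0, n_archetypes = 8,
                    noise_sd = 0, seed = 6)
  sim <- simulate_experiment(cfg)
  # targets are planted as affine functions of the TF on the log2 scale
  lvals <- log2(sim$expression$AC$values)
  links <- sim$truth$links
  for (i in seq_len(nrow(links)))
    expect_equal(
      pearson_r(lvals[links$tf_id[i], ], lvals[links$target_id[i], ]),
      links$sign[i] * 1.0, tolerance = 1e-9)

  # the log2-scale screen recovers everything: sensitivity exactly 1
  recs <- do.call(rbind, lapply(names(sim$catalog$pathways), function(p)
    screen_pathway(sim$expression$AC, sim$catalog, p,
                   screen_config(correlation_scale = "log2"))))
  met <- recovery_metrics(sim$truth, recs)
  expect_equal(met$sensitivity, 1.0)
  expect_equal(met$sign_accuracy, 1.0)
})

test_that("recovery metrics handle perfect, empty and partial calls", {
  truth <- structure(list(
    links = data.frame(tf_id = c("T1", "T2"), target_id = c("S1", "S2"),
                       pathway = "p", sign = c(1L, -1L), effect_size = 1,
                       stringsAsFactors = FALSE),
    archetype_of = c(T1 = 1L, T2 = 2L, S1 = 1L, S2 = 2L),
    noise_sd = 0, library_sizes = list(), seed = 1L, config = NULL),
    class = "SyntheticTruth")
  rec <- function(src, tgt, r, sig) data.frame(
    source_id = src, target_id = tgt, genotype_id = "AC", r = r, n = 7L,
    t_stat = 0, df = 5L, significant = sig,
    sign = ifelse(r > 0, "positive", "negative"),
    excluded = FALSE, reason = NA, stringsAsFactors = FALSE)
  perfect <- rbind(rec("T1", "S1", 0.9, TRUE), rec("T2", "S2", -0.9, TRUE))
  m <- recovery_metrics(truth, perfect)
  expect_equal(m$sensitivity, 1.0); expect_equal(m$fdp, 0.0)
  expect_equal(m$sign_accuracy, 1.0)

  none <- rbind(rec("T1", "S1", 0.2, FALSE), rec("T2", "S2", 0.1, FALSE))
  m0 <- recovery_metrics(truth, none)
  expect_equal(m0$sensitivity, 0.0); expect_equal(m0$fdp, 0.0)

  half <- rbind(rec("T1", "S1", 0.9, TRUE), rec("T2", "S2", -0.2, FALSE))
  mh <- recovery_metrics(truth, half)
  expect_equal(mh$sensitivity, 0.5); expect_equal(mh$fdp, 0.0)

  alien <- rec("X1", "Y1", 0.9, TRUE)
  expect_error(recovery_metrics(truth, alien), "share no gene ids")
})

test_that("RPKM recomputed from simulated counts converges with depth", {
  base <- function(lib) {
    cfg <- sim_config(n_tfs = 10, n_background_genes = 20, n_archetypes = 6,
                      noise_sd = 0, count_model = "nb", dispersion = 1e-4,
                      library_size = lib, seed = 12)
    simulate_experiment(cfg)
  }
  truth_cfg <- sim_config(n_tfs = 10, n_background_genes = 20,
                          n_archetypes = 6, noise_sd = 0, seed = 12)
  intended <- simulate_experiment(truth_cfg)$expression$AC$values
  deep <- base(1e7)$expression$AC$values
  shallow <- base(1e4)$expression$AC$values
  rel_err <- function(est) {
    keep <- intended > 1
    median(abs(est[keep] - intended[keep]) / intended[keep])
  }
  expect_lt(rel_err(deep), 0.05)
  expect_lt(rel_err(deep), rel_err(shallow))
  # counts respect the RPKM identity
  sim <- base(1e7)
  expect_true(all(sim$counts$AC >= 0))
})

test_that("null flat-profile data is calibrated at the exact-t rule", {
  cfg <- sim_config(n_tfs = 60, pathway_sizes = c(main = 40L),
                    n_links = 0L, n_background_genes = 0,
                    archetype_mode = "flat", noise_sd = 0.5, seed = 13)
  sim <- simulate_experiment(cfg)
  cfg_scr <- screen_config(r_threshold = significance_threshold_r(7, 0.05),
                           min_rpkm = 0)
  rec <- screen_pathway(sim$expression$AC, sim$catalog, "main", cfg_scr)
  frac <- mean(rec$significant)
  n_pairs <- nrow(rec)
  se <- sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-12)
})

test_that("screen sensitivity decreases with noise", {
  sens_at <- function(noise, seed) {
    cfg <- sim_config(n_tfs = 40, n_background_genes = 0, n_archetypes = 10,
                      noise_sd = noise, seed = seed)
    sim <- simulate_experiment(cfg)
    recs <- do.call(rbind, lapply(names(sim$catalog$pathways), function(p)
      screen_pathway(sim$expression$AC, sim$catalog, p,
                     screen_config(correlation_scale = "log2"))))
    recovery_metrics(sim$truth, recs)$sensitivity
  }
  seeds <- 1:8
  s_lo <- mean(vapply(seeds, function(s) sens_at(0.05, s), 1.0))
  s_hi <- mean(vapply(seeds, function(s) sens_at(1.5, s), 1.0))
  expect_gt(s_lo, s_hi)
  expect_gt(s_lo, 0.9)
})

test_that("the second genotype lags ripening archetypes by one stage", {
  cfg <- sim_config(n_tfs = 10, n_background_genes = 200, n_archetypes = 8,
                    noise_sd = 0, n_links = 0L, p_coreg = 0, seed = 14)
  sim <- simulate_experiment(cfg)
  shapes <- generate_archetypes(8)
  ripening <- which(apply(shapes, 1, which.max) == 7)
  expect_gt(length(ripening), 0)
  a <- sim$truth$archetype_of
  g <- names(a)[a %in% ripening][1]
  ac <- log2(sim$expression$AC$values[g, ])
  hg <- log2(sim$expression$`HG6-61`$values[g, ])
  expect_equal(unname(hg[2:7]), unname(ac[1:6]), tolerance = 1e-9)
  # non-ripening genes are identical across genotypes at zero noise
  g2 <- names(a)[!(a %in% ripening)][1]
  expect_equal(sim$expression$AC$values[g2, ],
               sim$expression$`HG6-61`$values[g2, ], tolerance = 1e-9)
})
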