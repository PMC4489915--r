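# Planted-truth synthetic data generator.
#
# Emulates the statistical structure the screening pipeline assumes: two
# genotypes sampled at seven weekly stages, ~26k genes whose log2
# expression follows one of 20 canonical temporal shapes plus
# multiplicative (log-scale Gaussian) noise, three biosynthetic pathways
# with planted signed TF -> structural-gene co-expression links, and
# metabolites accumulating as noisy integrals of their pathway's mean
# expression. Every random draw flows from a single seed; each generation
# phase draws in a fixed order, so outputs are bit-reproducible.

#' Canonical temporal archetype shapes
#'
#' Builds `k` distinct stage-course shapes on a `[0, 1]` scale, covering
#' the pattern families seen in developmental time courses: monotone
#' increase/decrease, early/late sigmoid induction, interior peaks and
#' valleys, a high-low-high course, and a flat-high profile (with a small
#' ripple so its variance is nonzero). Beyond the base family,
#' parameterised variants (shifted peak/sigmoid centres) are generated —
#' never duplicates. Pairwise Pearson r between distinct shapes is < 0.95.
#'
#' @param k Number of shapes, >= 2.
#' @param stages Stage axis, see [stage_axis()].
#' @return k x n_stages numeric matrix, one shape per row.
#' @export
generate_archetypes <- function(k = 20L, stages = stage_axis()) {
  check_number(k, "k", lower = 2)
  k <- as.integer(k)
  stages <- stage_axis(stages)
  u <- (stages - min(stages)) / (max(stages) - min(stages))
  n <- length(u)
  gauss <- function(c0, w) exp(-((u - c0) / w)^2)
  sig <- function(c0, s) 1 / (1 + exp(-s * (u - c0)))
  ripple <- 0.02 * rep_len(c(1, -1), n)
  base <- list(
    increasing   = u,
    decreasing   = 1 - u,
    late_induction  = sig(0.7, 12),
    early_induction = sig(0.3, 12),
    peak_mid     = gauss(0.5, 0.18),
    peak_early   = gauss(0.25, 0.18),
    peak_late    = gauss(0.75, 0.18),
    valley_mid   = 1 - gauss(0.5, 0.18),
    high_low_high = 1 - gauss(0.4, 0.3),
    broad_dome   = gauss(0.5, 0.4),
    flat_high    = 0.95 + ripple,
    late_decline = 1 - sig(0.7, 12),
    early_decline = 1 - sig(0.3, 12),
    ramp_plateau = pmin(1, 2 * u),
    plateau_drop = pmin(1, 2 * (1 - u))
  )
  # parameterised variants extend the family indefinitely
  variants <- list()
  centers <- seq(0.15, 0.85, by = 0.05)
  for (c0 in centers) {
    variants[[sprintf("peak_c%02.0f", 100 * c0)]] <- gauss(c0, 0.12)
    variants[[sprintf("valley_c%02.0f", 100 * c0)]] <- 1 - gauss(c0, 0.12)
    variants[[sprintf("sig_c%02.0f", 100 * c0)]] <- sig(c0, 18)
  }
  pool <- c(base, variants)
  shapes <- matrix(NA_real_, 0L, n)
  nm <- character(0)
  for (i in seq_along(pool)) {
    cand <- pool[[i]]
    if (stats::sd(cand) == 0) next
    ok <- TRUE
    if (nrow(shapes) > 0L) {
      rr <- apply(shapes, 1L, function(s) stats::cor(s, cand))
      if (any(rr >= 0.95)) ok <- FALSE
    }
    if (ok) {
      shapes <- rbind(shapes, cand)
      nm <- c(nm, names(pool)[i])
    }
    if (nrow(shapes) == k) break
  }
  if (nrow(shapes) < k)
    stop_ss("could only build %d distinct shapes for k = %d; reduce k",
            nrow(shapes), k)
  dimnames(shapes) <- list(nm, stage_labels(stages))
  shapes
}

# archetypes whose maximum sits at the final stage are "ripening-linked";
# the second genotype expresses those one stage later
is_ripening_shape <- function(shapes) {
  apply(shapes, 1L, function(s) which.max(s) == length(s))
}

lag_shape <- function(s) c(s[1L], s[-length(s)])

#' Synthetic experiment configuration
#'
#' Defaults mirror the tomato fruit study design: 2 genotypes x 7 weekly
#' stages (7-49 DAF), 823 TFs, pathway sets of 46/18/14 structural genes
#' (ascorbate / carotenoid / flavonoid), ~26k expressed genes in total, 20
#' temporal archetypes, and ~50 planted signed regulator links split
#' proportionally across pathways (29/12/9).
#'
#' @param n_stages Number of stages (weekly from 7 DAF), default 7.
#' @param n_genotypes 1 or 2 genotypes (labelled AC, HG6-61), default 2.
#' @param n_tfs Number of transcription factors, default 823.
#' @param pathway_sizes Named integer vector of structural-gene counts,
#'   default `c(ascorbate = 46, carotenoid = 18, flavonoid = 14)`.
#' @param n_background_genes Unannotated background genes, default 25500.
#' @param n_archetypes Number of temporal shapes, default 20.
#' @param n_links Planted links per pathway: single number recycled or a
#'   vector along `pathway_sizes`; each planted target follows exactly one
#'   regulator, so at most the pathway size. Default `c(29, 12, 9)`.
#' @param p_coreg Probability that an unlinked structural gene adopts its
#'   pathway's characteristic archetype instead of a random one, default
#'   0.7. Pathway genes are partially co-regulated; characteristic shapes
#'   follow the measured metabolite dynamics (ascorbate: high-low-high;
#'   carotenoid: increasing; flavonoid: late induction).
#' @param effect_size Multiplier on the regulator signal in planted
#'   targets (log2 units per log2 unit), > 0, default 1.
#' @param noise_sd Log2-scale Gaussian noise sd, >= 0, default 0.1.
#' @param prob_positive Probability a planted link is activating, default
#'   0.75.
#' @param count_model `"none"` (expression emitted directly as RPKM) or
#'   `"nb"` (negative-binomial read counts drawn per sample and RPKM
#'   recomputed from them).
#' @param dispersion NB dispersion (1/size), default 0.05.
#' @param library_size Reads per sample for the count model; default NULL
#'   draws uniformly in 2-7 million (the study's per-sample range).
#' @param stage_lag Stage lag of ripening-linked archetypes in the second
#'   genotype (0 or 1), default 1.
#' @param archetype_mode `"shapes"` (default) or `"flat"`: flat replaces
#'   all shapes by constants so profiles are pure noise — the null
#'   configuration used for type-I-error calibration.
#' @param met_noise_sd Multiplicative noise sd on metabolite series,
#'   default 0.05.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `SimConfig`.
#' @export
sim_config <- function(n_stages = 7L, n_genotypes = 2L, n_tfs = 823L,
                       pathway_sizes = c(ascorbate = 46L, carotenoid = 18L,
                                         flavonoid = 14L),
                       n_background_genes = 25500L, n_archetypes = 20L,
                       n_links = NULL, p_coreg = 0.7,
                       effect_size = 1.0, noise_sd = 0.1,
                       prob_positive = 0.75,
                       count_model = c("none", "nb"), dispersion = 0.05,
                       library_size = NULL, stage_lag = 1L,
                       archetype_mode = c("shapes", "flat"),
                       met_noise_sd = 0.05, seed = 1L) {
  check_number(n_stages, "n_stages", lower = 3)
  check_number(n_genotypes, "n_genotypes", lower = 1, upper = 2)
  check_number(n_tfs, "n_tfs", lower = 1)
  if (is.null(names(pathway_sizes)) || any(pathway_sizes < 1))
    stop_ss("pathway_sizes must be a named vector of positive counts")
  check_number(n_background_genes, "n_background_genes", lower = 0)
  check_number(n_archetypes, "n_archetypes", lower = 2)
  if (is.null(n_links)) {
    # proportional split of ~50 links across the default three pathways;
    # for other designs default to min(5, size) per pathway
    n_links <- if (identical(names(pathway_sizes),
                             c("ascorbate", "carotenoid", "flavonoid")))
      c(29L, 12L, 9L)
    else pmin(5L, as.integer(pathway_sizes))
  }
  n_links <- rep_len(as.integer(n_links), length(pathway_sizes))
  if (any(n_links < 0)) stop_ss("n_links must be >= 0")
  if (any(n_links > pathway_sizes))
    stop_ss("n_links exceeds pathway size for: %s (each planted target follows one regulator)",
            paste(names(pathway_sizes)[n_links > pathway_sizes],
                  collapse = ", "))
  check_number(p_coreg, "p_coreg", lower = 0, upper = 1)
  check_number(effect_size, "effect_size", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(prob_positive, "prob_positive", lower = 0, upper = 1)
  count_model <- match.arg(count_model)
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  if (!is.null(library_size))
    check_number(library_size, "library_size", lower = 1)
  check_number(stage_lag, "stage_lag", lower = 0, upper = 1)
  archetype_mode <- match.arg(archetype_mode)
  check_number(met_noise_sd, "met_noise_sd", lower = 0)
  structure(list(
    n_stages = as.integer(n_stages), n_genotypes = as.integer(n_genotypes),
    n_tfs = as.integer(n_tfs),
    pathway_sizes = stats::setNames(as.integer(pathway_sizes),
                                    names(pathway_sizes)),
    n_background_genes = as.integer(n_background_genes),
    n_archetypes = as.integer(n_archetypes),
    n_links = stats::setNames(n_links, names(pathway_sizes)),
    p_coreg = p_coreg,
    effect_size = effect_size, noise_sd = noise_sd,
    prob_positive = prob_positive,
    count_model = count_model, dispersion = dispersion,
    library_size = library_size, stage_lag = as.integer(stage_lag),
    archetype_mode = archetype_mode, met_noise_sd = met_noise_sd,
    seed = as.integer(seed)), class = "SimConfig")
}

# metabolite panel per pathway: id, units, accumulation rate relative to
# the pathway integral (fixed constants of the generator)
met_panel <- function(pathway) {
  switch(pathway,
    ascorbate = data.frame(
      metabolite_id = c("total-AsA", "AsA", "DHA"),
      units = "mg g-1 FW", rate = c(0.010, 0.007, 0.003),
      stringsAsFactors = FALSE),
    carotenoid = data.frame(
      metabolite_id = c("lycopene", "beta-carotene", "phytoene", "lutein"),
      units = "ug g-1 FW", rate = c(0.020, 0.008, 0.004, 0.002),
      stringsAsFactors = FALSE),
    flavonoid = data.frame(
      metabolite_id = c("naringenin chalcone", "rutin", "chlorogenic acid"),
      units = "mg g-1 DW", rate = c(0.015, 0.006, 0.004),
      stringsAsFactors = FALSE),
    data.frame(metabolite_id = paste0(pathway, "-product"),
               units = "a.u.", rate = 0.01, stringsAsFactors = FALSE))
}

#' Simulate a two-genotype stage-course experiment with planted truth
#'
#' Generates per-genotype expression matrices, the gene catalog, metabolite
#' series and a `SyntheticTruth` record of the planted regulator links.
#'
#' Mechanics: every gene gets a baseline log2 expression (TFs and
#' structural genes ~ N(5, 1); background ~ N(3.5, 1.8), so most genes pass
#' the RPKM >= 5 floor and most sit below RPKM 20, as bulk fruit
#' transcriptomes do), an amplitude ~ U(2, 6) log2 units and a temporal
#' archetype. A planted target's log2 profile is
#' `baseline + effect_size * sign * (amplitude_TF * shape_TF) + noise`;
#' all other genes follow their own archetype plus noise. Regulators of
#' planted links are drawn only from dynamic archetypes (shape sd >= 0.25):
#' a flat regulator is invisible to a correlation screen by construction.
#' In the second genotype, ripening-linked archetypes are lagged by
#' `stage_lag` stages (noise redrawn; baselines, amplitudes and links
#' shared). Metabolites accumulate as
#' `rate * cumsum(mean pathway RPKM)` with multiplicative Gaussian noise.
#' With `count_model = "nb"`, negative-binomial read counts are drawn per
#' sample and RPKM is recomputed from them.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `expression` (named list of
#'   `ExpressionMatrix`, one per genotype), `catalog` (`GeneCatalog`),
#'   `metabolites` (list of `MetaboliteSeries`), `truth` (class
#'   `SyntheticTruth`: `links` data.frame with `tf_id`, `target_id`,
#'   `pathway`, `sign`, `effect_size`; `archetype_of`; `noise_sd`;
#'   `library_sizes`; `seed`; `config`), and `counts` (per-genotype count
#'   matrices when the count model is active).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  stages <- stage_axis(seq(7L, by = 7L, length.out = cfg$n_stages))
  n <- length(stages)
  shapes <- generate_archetypes(cfg$n_archetypes, stages)
  if (cfg$archetype_mode == "flat")
    shapes[] <- 0  # null configuration: profiles are baseline + noise only
  ripening <- is_ripening_shape(shapes)

  genotypes <- c("AC", "HG6-61")[seq_len(cfg$n_genotypes)]
  pw_names <- names(cfg$pathway_sizes)
  tf_ids <- sprintf("TF%04d", seq_len(cfg$n_tfs))
  sg_ids <- unlist(lapply(pw_names, function(p)
    sprintf("%s_SG%03d", toupper(substr(p, 1L, 3L)),
            seq_len(cfg$pathway_sizes[[p]]))), use.names = FALSE)
  sg_pathway <- rep(pw_names, cfg$pathway_sizes)
  bg_ids <- if (cfg$n_background_genes > 0L)
    sprintf("BG%05d", seq_len(cfg$n_background_genes)) else character(0)
  all_ids <- c(tf_ids, sg_ids, bg_ids)
  n_genes <- length(all_ids)

  # phase 1: per-gene static attributes (shared across genotypes)
  archetype_of <- sample.int(cfg$n_archetypes, n_genes, replace = TRUE)
  names(archetype_of) <- all_ids
  # pathway co-regulation: unlinked structural genes adopt their pathway's
  # characteristic shape with probability p_coreg
  char_shape <- c(ascorbate = "high_low_high", carotenoid = "increasing",
                  flavonoid = "late_induction")
  for (p in pw_names) {
    want <- if (p %in% names(char_shape)) char_shape[[p]] else
      rownames(shapes)[1L]
    idx <- match(want, rownames(shapes))
    if (is.na(idx)) idx <- 1L
    members <- sg_ids[sg_pathway == p]
    adopt <- stats::runif(length(members)) < cfg$p_coreg
    archetype_of[members[adopt]] <- idx
  }
  baseline <- c(stats::rnorm(length(tf_ids) + length(sg_ids), 5, 1),
                stats::rnorm(length(bg_ids), 3.5, 1.8))
  names(baseline) <- all_ids
  amplitude <- stats::runif(n_genes, 2, 6)
  names(amplitude) <- all_ids

  # phase 2: planted links (regulators restricted to dynamic archetypes)
  shape_sd <- apply(shapes, 1L, stats::sd)
  dynamic_tfs <- tf_ids[shape_sd[archetype_of[tf_ids]] >= 0.25]
  if (sum(cfg$n_links) > 0L && length(dynamic_tfs) == 0L)
    stop_ss("no dynamically expressed TFs available to plant links on")
  links <- NULL
  for (p in pw_names) {
    npl <- cfg$n_links[[p]]
    if (npl == 0L) next
    targets <- sample(sg_ids[sg_pathway == p], npl)
    regs <- sample(dynamic_tfs, npl, replace = TRUE)
    signs <- ifelse(stats::runif(npl) < cfg$prob_positive, 1L, -1L)
    links <- rbind(links, data.frame(
      tf_id = regs, target_id = targets, pathway = p, sign = signs,
      effect_size = cfg$effect_size, stringsAsFactors = FALSE))
  }
  if (is.null(links))
    links <- data.frame(tf_id = character(0), target_id = character(0),
                        pathway = character(0), sign = integer(0),
                        effect_size = numeric(0), stringsAsFactors = FALSE)
  # planted targets inherit their regulator's archetype in the truth record
  archetype_of[links$target_id] <- archetype_of[links$tf_id]

  # phase 3: per-genotype expression
  expression <- list()
  counts_out <- list()
  library_sizes <- list()
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    gshapes <- shapes
    if (gi == 2L && cfg$stage_lag > 0L && any(ripening))
      gshapes[ripening, ] <- t(apply(shapes[ripening, , drop = FALSE],
                                     1L, lag_shape))
    signal <- gshapes[archetype_of[all_ids], , drop = FALSE] *
      amplitude[all_ids]
    logexpr <- baseline[all_ids] + signal
    rownames(logexpr) <- all_ids
    # planted targets track their regulator's signal instead of their own
    if (nrow(links) > 0L)
      logexpr[links$target_id, ] <- baseline[links$target_id] +
        links$effect_size * links$sign *
        (gshapes[archetype_of[links$tf_id], , drop = FALSE] *
           amplitude[links$tf_id])
    noise <- matrix(stats::rnorm(n_genes * n, 0, cfg$noise_sd), n_genes, n)
    logexpr <- logexpr + noise
    rpkm <- 2^logexpr
    rownames(rpkm) <- all_ids
    if (cfg$count_model == "nb") {
      gene_length <- stats::setNames(
        sample(500:5000, n_genes, replace = TRUE), all_ids)
      libs <- if (is.null(cfg$library_size))
        stats::runif(n, 2e6, 7e6) else rep(cfg$library_size, n)
      mu <- sweep(rpkm * gene_length / 1e9, 2L, libs, "*")
      cnt <- matrix(stats::rnbinom(n_genes * n, mu = mu,
                                   size = 1 / cfg$dispersion), n_genes, n)
      dimnames(cnt) <- list(all_ids, stage_labels(stages))
      rpkm <- sweep(1e9 * cnt / gene_length, 2L, libs, "/")
      rownames(rpkm) <- all_ids
      counts_out[[g]] <- cnt
      library_sizes[[g]] <- libs
    }
    expression[[g]] <- expression_matrix(rpkm, g, stages)
  }

  # phase 4: metabolites = noisy integrals of pathway mean expression
  metabolites <- list()
  for (g in genotypes) {
    vals <- expression[[g]]$values
    for (p in pw_names) {
      pmean <- colMeans(vals[sg_ids[sg_pathway == p], , drop = FALSE])
      integral <- cumsum(pmean)
      panel <- met_panel(p)
      for (i in seq_len(nrow(panel))) {
        conc <- panel$rate[i] * integral *
          pmax(0, 1 + stats::rnorm(n, 0, cfg$met_noise_sd))
        metabolites[[length(metabolites) + 1L]] <- metabolite_series(
          panel$metabolite_id[i], g, conc, stages, panel$units[i])
      }
    }
  }

  tf_family <- stats::setNames(
    sample(c("MYB", "NAC", "bHLH", "Dof", "AUX/IAA", "ZIF", "SBP-box",
             "MADS-box", "HSF", "TCP", "GRAS", "CCT"),
           length(tf_ids), replace = TRUE), tf_ids)
  catalog <- gene_catalog(
    pathways = split(sg_ids, factor(sg_pathway, levels = pw_names)),
    tf_ids = tf_ids, tf_family = tf_family)

  truth <- structure(list(
    links = links, archetype_of = archetype_of, noise_sd = cfg$noise_sd,
    library_sizes = library_sizes, seed = cfg$seed, config = cfg),
    class = "SyntheticTruth")

  list(expression = expression, catalog = catalog,
       metabolites = metabolites, truth = truth,
       counts = if (length(counts_out)) counts_out else NULL)
}

#' Score screen output against planted truth
#'
#' @param truth `SyntheticTruth` from [simulate_experiment()].
#' @param records Correlation records ([screen_pathway()] output, possibly
#'   row-bound across pathways/genotypes).
#' @return List: `sensitivity` (planted links with a significant record /
#'   planted links), `fdp` (significant source-target pairs not planted /
#'   significant pairs; 0 when nothing is called), `sign_accuracy`
#'   (fraction of recovered links whose correlation sign matches the
#'   planted sign; NA when nothing is recovered), `n_links`,
#'   `n_recovered`, `n_significant_pairs`.
#' @export
recovery_metrics <- function(truth, records) {
  stopifnot(inherits(truth, "SyntheticTruth"), is.data.frame(records))
  links <- truth$links
  rec_ids <- unique(c(records$source_id, records$target_id))
  truth_ids <- unique(c(links$tf_id, links$target_id,
                        names(truth$archetype_of)))
  if (length(intersect(rec_ids, truth_ids)) == 0L)
    stop_ss("records and truth share no gene ids")
  sig <- records[records$significant %in% TRUE, , drop = FALSE]
  pair_key <- function(a, b) paste(a, b, sep = "\r")
  sig_pairs <- unique(data.frame(
    key = pair_key(sig$source_id, sig$target_id),
    sign = sig$sign, stringsAsFactors = FALSE))
  # a pair significant in several genotypes counts once; first sign kept
  sig_pairs <- sig_pairs[!duplicated(sig_pairs$key), , drop = FALSE]
  link_key <- pair_key(links$tf_id, links$target_id)
  recovered <- link_key %in% sig_pairs$key
  sensitivity <- if (nrow(links) == 0L) NA_real_ else mean(recovered)
  fdp <- if (nrow(sig_pairs) == 0L) 0 else
    mean(!(sig_pairs$key %in% link_key))
  sign_accuracy <- if (!any(recovered)) NA_real_ else {
    obs <- sig_pairs$sign[match(link_key[recovered], sig_pairs$key)]
    expect <- ifelse(links$sign[recovered] > 0, "positive", "negative")
    mean(obs == expect)
  }
  list(sensitivity = sensitivity, fdp = fdp, sign_accuracy = sign_accuracy,
       n_links = nrow(links), n_recovered = sum(recovered),
       n_significant_pairs = nrow(sig_pairs))
}
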