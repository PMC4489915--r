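# Reproducible pipeline runner: simulate -> filter -> cluster -> screen ->
# metabolite correlation, with schema-validated JSON config, logging to
# stderr and a digested run manifest.

pipeline_stages <- c("simulate", "filter", "cluster", "screen", "metab_corr")

log_msg <- function(level, fmt, ..., min_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[min_level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Validate a pipeline configuration
#'
#' Checks the documented schema before any computation: section names,
#' types and ranges. Unknown top-level sections are rejected.
#'
#' @param config Named list (typically parsed from JSON): fields `seed`
#'   (integer) plus optional sections `sim` (arguments of [sim_config()]),
#'   `filter`/`screen` (arguments of [screen_config()], and for `screen`
#'   also `pathways`, `min_count`, `require_both`), `cluster` (`k`,
#'   `n_init`, `max_iter`, `pseudocount`) and `log_level`.
#' @return The normalised config (invisibly usable by [run_pipeline()]).
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop_ss("config must be a named list")
  known <- c("seed", "sim", "filter", "cluster", "screen", "metab_corr",
             "log_level")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop_ss("unknown config section(s): %s", paste(extra, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  check_number(config$seed, "seed", lower = 0, upper = 2^31 - 1)
  config$seed <- as.integer(config$seed)
  sim_args <- config$sim %||% list()
  if (!is.list(sim_args)) stop_ss("'sim' must be an object")
  sim_args$seed <- config$seed
  if (!is.null(sim_args$pathway_sizes))
    sim_args$pathway_sizes <- unlist(sim_args$pathway_sizes)
  if (!is.null(sim_args$n_links)) sim_args$n_links <- unlist(sim_args$n_links)
  config$sim <- do.call(sim_config, sim_args)  # validates
  scr <- config$screen %||% list()
  if (!is.list(scr)) stop_ss("'screen' must be an object")
  scr_cfg_args <- scr[intersect(names(scr),
                                names(formals(screen_config)))]
  config$screen_cfg <- do.call(screen_config, scr_cfg_args)
  if (!is.null(scr$min_count))
    check_number(scr$min_count, "screen.min_count", lower = 0)
  if (!is.null(scr$require_both))
    check_flag(scr$require_both, "screen.require_both")
  config$screen$min_count <- scr$min_count %||% 5
  config$screen$require_both <- scr$require_both %||% TRUE
  cl <- config$cluster %||% list()
  if (!is.list(cl)) stop_ss("'cluster' must be an object")
  check_number(cl$k %||% 20, "cluster.k", lower = 1)
  check_number(cl$n_init %||% 10, "cluster.n_init", lower = 1)
  check_number(cl$pseudocount %||% 1, "cluster.pseudocount", lower = 0,
               strict_lower = TRUE)
  config$cluster <- list(k = as.integer(cl$k %||% 20),
                         n_init = as.integer(cl$n_init %||% 10),
                         max_iter = as.integer(cl$max_iter %||% 100),
                         pseudocount = cl$pseudocount %||% 1)
  config$log_level <- config$log_level %||% "info"
  if (!config$log_level %in% c("debug", "info", "warn", "error"))
    stop_ss("log_level must be one of debug/info/warn/error")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> filter -> cluster -> screen (every catalog
#' pathway) -> metabolite correlation in dependency order, writes all
#' stage outputs as TSV under `out_dir`, and returns (and writes) a run
#' manifest with the config snapshot, seed, package version, per-stage
#' record counts, md5 digests of every output file and timestamps.
#' Identical config + seed gives byte-identical TSV outputs. On a partial
#' failure, outputs written so far remain on disk next to a
#' `failure.json` record.
#'
#' @param config Path to a JSON config file, or an equivalent named list;
#'   see [validate_pipeline_config()]. Validation happens before any
#'   computation.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_pipeline_config(config)
  lvl <- config$log_level
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outputs <- character(0)
  counts <- list()
  stage <- "simulate"
  manifest_path <- file.path(out_dir, "manifest.json")
  res <- tryCatch({
    # simulate ------------------------------------------------------------
    log_msg("info", "simulate: seed %d", config$seed, min_level = lvl)
    sim <- simulate_experiment(config$sim)
    for (g in names(sim$expression)) {
      f <- file.path(out_dir, sprintf("expression_%s.tsv", g))
      write_expression_matrix(sim$expression[[g]], f)
      outputs <- c(outputs, f)
    }
    f <- file.path(out_dir, "metabolites.tsv")
    write_metabolite_table(sim$metabolites, f)
    outputs <- c(outputs, f)
    cat_dir <- file.path(out_dir, "catalog")
    write_gene_catalog(sim$catalog, cat_dir)
    outputs <- c(outputs, list.files(cat_dir, full.names = TRUE))
    truth_f <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(links = sim$truth$links, noise_sd = sim$truth$noise_sd,
           seed = sim$truth$seed),
      truth_f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, truth_f)
    counts$simulate <- list(
      genes = nrow(sim$expression[[1L]]$values),
      genotypes = length(sim$expression),
      planted_links = nrow(sim$truth$links))

    # filter ---------------------------------------------------------------
    stage <- "filter"
    filtered <- lapply(sim$expression, expression_filter, cfg = config$screen_cfg)
    for (g in names(filtered)) {
      f <- file.path(out_dir, sprintf("expression_filtered_%s.tsv", g))
      write_expression_matrix(filtered[[g]], f)
      outputs <- c(outputs, f)
    }
    counts$filter <- lapply(filtered, function(m) nrow(m$values))
    log_msg("info", "filter: kept %s genes",
            paste(unlist(counts$filter), collapse = "/"), min_level = lvl)

    # cluster (per genotype) ----------------------------------------------
    stage <- "cluster"
    cl_counts <- list()
    for (g in names(filtered)) {
      prof <- log2_profiles(filtered[[g]], config$cluster$pseudocount)
      cl <- kmeans_profiles(prof, k = config$cluster$k, seed = config$seed,
                            n_init = config$cluster$n_init,
                            max_iter = config$cluster$max_iter)
      f1 <- file.path(out_dir, sprintf("cluster_labels_%s.tsv", g))
      write_tsv_ss(data.frame(gene_id = names(cl$labels),
                              group = unname(cl$labels)), f1)
      f2 <- file.path(out_dir, sprintf("cluster_centroids_%s.tsv", g))
      write_tsv_ss(data.frame(group = rownames(cl$centroids),
                              apply(cl$centroids, 2L, format_num),
                              check.names = FALSE), f2)
      outputs <- c(outputs, f1, f2)
      cl_counts[[g]] <- list(k = cl$k, sse = cl$sse)
    }
    counts$cluster <- cl_counts

    # screen ---------------------------------------------------------------
    stage <- "screen"
    scr_counts <- list()
    for (p in names(sim$catalog$pathways)) {
      recs <- NULL
      for (g in names(sim$expression)) {
        r <- screen_pathway(sim$expression[[g]], sim$catalog, p,
                            config$screen_cfg)
        recs <- rbind(recs, r)
      }
      f <- file.path(out_dir, sprintf("screen_records_%s.tsv", p))
      write_tsv_ss(recs, f)
      rows <- summarize_tf(recs, sim$catalog)
      f2 <- file.path(out_dir, sprintf("tf_summary_%s.tsv", p))
      write_tf_summary(rows, f2)
      cand <- select_candidates(rows, config$screen$min_count,
                                config$screen$require_both)
      f3 <- file.path(out_dir, sprintf("candidates_%s.tsv", p))
      write_tsv_ss(cand, f3)
      outputs <- c(outputs, f, f2, f3)
      scr_counts[[p]] <- list(pairs = nrow(recs),
                              significant = sum(recs$significant),
                              candidates = length(unique(cand$tf_id)))
      log_msg("info", "screen %s: %d pairs, %d significant, %d candidates",
              p, nrow(recs), sum(recs$significant),
              length(unique(cand$tf_id)), min_level = lvl)
    }
    counts$screen <- scr_counts

    # metabolite correlation ----------------------------------------------
    stage <- "metab_corr"
    met_recs <- NULL
    for (met in sim$metabolites) {
      m <- sim$expression[[met$genotype_id]]
      pth <- names(which(vapply(
        names(sim$catalog$pathways), function(p)
          met$metabolite_id %in% met_panel(p)$metabolite_id, TRUE)))[1L]
      ids <- c(sim$catalog$pathways[[pth]], sim$catalog$tf_ids)
      r <- metabolite_gene_correlation(met, m, ids, config$screen_cfg)
      r$pathway <- pth
      met_recs <- rbind(met_recs, r)
    }
    f <- file.path(out_dir, "metabolite_records.tsv")
    write_tsv_ss(met_recs, f)
    outputs <- c(outputs, f)
    rep_rows <- NULL
    for (p in names(sim$catalog$pathways)) {
      sub <- met_recs[met_recs$pathway == p, , drop = FALSE]
      rep1 <- pathway_metabolite_report(sub, sim$catalog, p)
      rep1$pathway <- p
      rep_rows <- rbind(rep_rows, rep1)
    }
    f2 <- file.path(out_dir, "metabolite_report.tsv")
    write_tsv_ss(rep_rows, f2)
    outputs <- c(outputs, f2)
    counts$metab_corr <- list(records = nrow(met_recs),
                              significant = sum(met_recs$significant))
    TRUE
  }, error = function(e) e)

  if (inherits(res, "error")) {
    fail <- list(failed_stage = stage, message = conditionMessage(res),
                 outputs_written = outputs)
    jsonlite::write_json(fail, file.path(out_dir, "failure.json"),
                         auto_unbox = TRUE)
    stop_ss("pipeline failed at stage '%s': %s", stage,
            conditionMessage(res))
  }

  manifest <- list(
    tool = "stagescreen",
    version = as.character(utils::packageVersion("stagescreen")),
    seed = config$seed,
    config = list(
      sim = unclass(config$sim),
      screen = c(unclass(config$screen_cfg),
                 list(min_count = config$screen$min_count,
                      require_both = config$screen$require_both)),
      cluster = config$cluster),
    stages = pipeline_stages,
    counts = counts,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run manifest against the files on disk
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return TRUE if every referenced output exists with a matching md5
#'   digest; otherwise an error naming the first mismatch.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  for (f in names(man$outputs)) {
    path <- if (file.exists(file.path(dir, f))) file.path(dir, f)
            else file.path(dir, "catalog", f)
    if (!file.exists(path)) stop_ss("manifest output missing: %s", f)
    if (!identical(unname(tools::md5sum(path)), man$outputs[[f]]))
      stop_ss("digest mismatch for %s", f)
  }
  TRUE
}
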