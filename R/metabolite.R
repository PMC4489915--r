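# Correlation of metabolite stage-courses with gene expression, and the
# per-metabolite structural-gene vs TF summary.

#' Correlate one metabolite series with gene expression
#'
#' Runs the same record-level machinery as the TF screen with the
#' metabolite series in place of the regulator series: one record per gene
#' where both series are non-constant, same |r| + t-test significance
#' rule. Metabolite concentrations are used on their measured scale; gene
#' expression follows `cfg$correlation_scale`.
#'
#' @param met A [metabolite_series()]; its stage axis and genotype must
#'   match `m`.
#' @param m `ExpressionMatrix` of the same genotype.
#' @param gene_ids Subset of genes to correlate against (default: all
#'   genes in `m`).
#' @param cfg A [screen_config()].
#' @return data.frame of correlation records (`source_id` = metabolite).
#' @export
metabolite_gene_correlation <- function(met, m, gene_ids = NULL,
                                        cfg = screen_config()) {
  stopifnot(inherits(met, "MetaboliteSeries"),
            inherits(m, "ExpressionMatrix"), inherits(cfg, "ScreenConfig"))
  if (!identical(as.integer(met$stages), as.integer(m$stages)))
    stop_ss("stage axis mismatch between metabolite '%s' and matrix",
            met$metabolite_id)
  if (!identical(met$genotype_id, m$genotype_id))
    stop_ss("genotype mismatch: metabolite is %s, matrix is %s",
            met$genotype_id, m$genotype_id)
  if (stats::sd(met$values) == 0)
    stop_ss("metabolite '%s' is constant across stages: correlation undefined",
            met$metabolite_id)
  if (is.null(gene_ids)) gene_ids <- rownames(m$values)
  missing <- setdiff(gene_ids, rownames(m$values))
  if (length(missing))
    stop_ss("gene id(s) not in matrix: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  keep_ids <- rownames(expression_filter(m, cfg)$values)
  src <- matrix(met$values, nrow = 1L,
                dimnames = list(met$metabolite_id, NULL))
  tgt <- scale_values(m$values[gene_ids, , drop = FALSE], cfg)
  correlate_rows(src, tgt, m$genotype_id, cfg,
                 source_keep = TRUE,
                 target_keep = gene_ids %in% keep_ids)
}

#' Per-metabolite correlation summary by gene class
#'
#' Splits correlation records into structural genes of one pathway vs
#' transcription factors and reports, per metabolite and class, counts and
#' percentages of significant, positive and negative correlations
#' (percentages over the tested, i.e. non-excluded, records; positive% +
#' negative% = significant%).
#'
#' @param records Row-bound [metabolite_gene_correlation()] outputs
#'   covering both gene classes.
#' @param catalog A [gene_catalog()].
#' @param pathway Pathway whose structural genes define the
#'   `"structural"` class.
#' @return data.frame: `metabolite_id`, `class`, `n_tested`,
#'   `n_significant`, `n_positive`, `n_negative`, `pct_significant`,
#'   `pct_positive`, `pct_negative`.
#' @export
pathway_metabolite_report <- function(records, catalog, pathway) {
  stopifnot(inherits(catalog, "GeneCatalog"))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_ss("empty record set")
  if (!pathway %in% names(catalog$pathways))
    stop_ss("unknown pathway '%s'", pathway)
  cls <- ifelse(records$target_id %in% catalog$pathways[[pathway]],
                "structural",
                ifelse(records$target_id %in% catalog$tf_ids, "TF",
                       NA_character_))
  rec <- records[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  if (nrow(rec) == 0L)
    stop_ss("no records match pathway '%s' structural genes or catalog TFs",
            pathway)
  key <- interaction(rec$source_id, cls, drop = TRUE)
  lev <- levels(key)
  first <- match(lev, as.character(key))
  tested <- !rec$excluded
  out <- data.frame(
    metabolite_id = rec$source_id[first],
    class = cls[first],
    n_tested = as.integer(tapply(tested, key, sum)),
    n_significant = as.integer(tapply(rec$significant, key, sum)),
    n_positive = as.integer(tapply(rec$significant & rec$r > 0, key, sum)),
    n_negative = as.integer(tapply(rec$significant & rec$r < 0, key, sum)),
    stringsAsFactors = FALSE)
  pct <- function(x) ifelse(out$n_tested > 0, 100 * x / out$n_tested, 0)
  out$pct_significant <- pct(out$n_significant)
  out$pct_positive <- pct(out$n_positive)
  out$pct_negative <- pct(out$n_negative)
  rownames(out) <- NULL
  out[order(out$metabolite_id, out$class), ]
}
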