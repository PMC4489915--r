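# The core screening procedure: Pearson correlation of every TF against
# every pathway structural gene across the stage course, significance via
# the exact correlation t-test (t = r * sqrt(n-2) / sqrt(1-r^2), df = n-2,
# two-sided), per-TF counting with sign partition, candidate selection,
# and consolidation across additional datasets.

#' Pearson product-moment correlation of two stage series
#'
#' @param x,y Numeric series of equal length >= 3 with nonzero variance.
#' @return r in `[-1, 1]`; symmetric in its arguments and invariant under
#'   positive affine transforms of either series.
#' @examples
#' pearson_r(1:7, c(2, 1, 4, 3, 6, 5, 8))  # 0.896
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_ss("x and y must be numeric series of equal length")
  if (length(x) < 3L)
    stop_ss("correlation needs at least 3 points (df = n - 2 >= 1)")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_ss("series must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ss("undefined correlation: zero-variance series")
  stats::cor(x, y)
}

#' t statistic of a Pearson correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Odd in `r` and strictly increasing in `|r|`.
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @param n Number of paired observations, >= 3.
#' @return The t value(s).
#' @examples
#' corr_t_statistic(0.5, 7)  # 1.291
#' @export
corr_t_statistic <- function(r, n) {
  check_number(n, "n", lower = 3)
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop_ss("r must be finite with |r| <= 1")
  if (any(abs(r) == 1))
    stop_ss("|r| = 1 gives an infinite t statistic")
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Minimal significant |r| for the correlation t-test
#'
#' Inverts the t formula at the two-sided Student-t critical value with
#' `df = n - 2`: the smallest `|r|` whose t statistic reaches
#' `qt(1 - alpha/2, n - 2)`. At `n = 7`, `alpha = 0.05` this is 0.754
#' (critical t 2.571). Strictly decreasing in `n` and in `alpha`.
#'
#' @param n Number of paired observations, >= 3.
#' @param alpha Two-sided significance level in (0, 1).
#' @return The threshold correlation magnitude.
#' @examples
#' significance_threshold_r(7, 0.05)  # 0.754
#' @export
significance_threshold_r <- function(n, alpha = 0.05) {
  check_number(n, "n", lower = 3)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

# shared correlation engine: all pairwise records between the rows of a
# source matrix and the rows of a target matrix over a common stage axis.
# Both the TF screen and the metabolite association run through here, so
# their record-level semantics are identical by construction.
correlate_rows <- function(source_mat, target_mat, genotype_id, cfg,
                           source_keep = NULL, target_keep = NULL) {
  n <- ncol(source_mat)
  stopifnot(ncol(target_mat) == n)
  df <- n - 2L
  tc <- stats::qt(1 - cfg$alpha / 2, df = df)
  if (is.null(source_keep)) source_keep <- rep(TRUE, nrow(source_mat))
  if (is.null(target_keep)) target_keep <- rep(TRUE, nrow(target_mat))
  src_var <- apply(source_mat, 1L, stats::sd) > 0
  tgt_var <- apply(target_mat, 1L, stats::sd) > 0
  src_ok <- source_keep & src_var
  tgt_ok <- target_keep & tgt_var

  rmat <- matrix(NA_real_, nrow(source_mat), nrow(target_mat))
  if (any(src_ok) && any(tgt_ok))
    rmat[src_ok, tgt_ok] <- stats::cor(t(source_mat[src_ok, , drop = FALSE]),
                                       t(target_mat[tgt_ok, , drop = FALSE]))
  grid <- expand.grid(si = seq_len(nrow(source_mat)),
                      ti = seq_len(nrow(target_mat)))
  r <- rmat[cbind(grid$si, grid$ti)]
  # clamp tiny numeric overshoot so |r| <= 1 exactly
  r <- pmin(1, pmax(-1, r))
  t_stat <- ifelse(is.na(r), NA_real_,
                   ifelse(abs(r) == 1, sign(r) * Inf,
                          r * sqrt(df) / sqrt(1 - r^2)))
  excluded <- is.na(r)
  reason <- rep(NA_character_, nrow(grid))
  reason[!source_keep[grid$si]] <- "source_below_expression_floor"
  reason[source_keep[grid$si] & !src_var[grid$si]] <- "source_zero_variance"
  tgt_bad <- is.na(reason) & excluded
  reason[tgt_bad & !target_keep[grid$ti]] <- "target_below_expression_floor"
  reason[tgt_bad & target_keep[grid$ti]] <- "target_zero_variance"
  significant <- !excluded & abs(r) >= cfg$r_threshold & abs(t_stat) > tc
  sign_lab <- ifelse(is.na(r), NA_character_,
                     ifelse(r > 0, "positive",
                            ifelse(r < 0, "negative", "zero")))
  data.frame(
    source_id = rownames(source_mat)[grid$si],
    target_id = rownames(target_mat)[grid$ti],
    genotype_id = genotype_id,
    r = r, n = as.integer(n), t_stat = t_stat, df = df,
    significant = significant, sign = sign_lab,
    excluded = excluded, reason = reason,
    stringsAsFactors = FALSE)
}

scale_values <- function(values, cfg) {
  if (cfg$correlation_scale == "log2") log2(values + 1) else values
}

#' Screen all TFs against one pathway's structural genes
#'
#' Applies the expression floor internally (RPKM >= `cfg$min_rpkm` in at
#' least `cfg$min_stages_expressed` stages), then computes one correlation
#' record per (TF, structural gene) pair in one genotype. A pair is
#' significant when `|r| >= cfg$r_threshold` **and** its t statistic
#' exceeds the two-sided critical value at `cfg$alpha` (at the default
#' `r_threshold = 0.8`, `n = 7`, `alpha = 0.05` the t-test is implied,
#' since the exact test threshold is r = 0.754). Pairs where a member
#' failed the floor or has zero variance are emitted as excluded records
#' with a reason — never as r = 0.
#'
#' @param m `ExpressionMatrix` of one genotype (TFs and structural genes
#'   among its rows).
#' @param catalog A [gene_catalog()].
#' @param pathway Pathway name present in `catalog$pathways`.
#' @param cfg A [screen_config()].
#' @return data.frame of correlation records: `source_id` (TF),
#'   `target_id` (structural gene), `genotype_id`, `pathway`, `r`, `n`,
#'   `t_stat`, `df`, `significant`, `sign`, `excluded`, `reason`.
#' @export
screen_pathway <- function(m, catalog, pathway, cfg = screen_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(catalog, "GeneCatalog"),
            inherits(cfg, "ScreenConfig"))
  if (!pathway %in% names(catalog$pathways))
    stop_ss("unknown pathway '%s' (catalog has: %s)", pathway,
            paste(names(catalog$pathways), collapse = ", "))
  tfs <- intersect(catalog$tf_ids, gene_ids(m))
  sgs <- intersect(catalog$pathways[[pathway]], gene_ids(m))
  if (length(tfs) == 0L)
    stop_ss("no catalog TFs present in the expression matrix")
  if (length(sgs) == 0L)
    stop_ss("no '%s' structural genes present in the expression matrix",
            pathway)
  keep_ids <- gene_ids(expression_filter(m, cfg))
  tf_keep <- tfs %in% keep_ids
  sg_keep <- sgs %in% keep_ids
  if (!any(tf_keep))
    stop_ss("no TFs pass the expression floor (min_rpkm = %s)", cfg$min_rpkm)
  if (!any(sg_keep))
    stop_ss("no '%s' structural genes pass the expression floor", pathway)
  vals <- scale_values(m$values, cfg)
  rec <- correlate_rows(vals[tfs, , drop = FALSE],
                        vals[sgs, , drop = FALSE],
                        m$genotype_id, cfg,
                        source_keep = tf_keep, target_keep = sg_keep)
  rec$pathway <- pathway
  rec[, c("source_id", "target_id", "genotype_id", "pathway", "r", "n",
          "t_stat", "df", "significant", "sign", "excluded", "reason")]
}

#' Per-TF summary counts (Table-3 style)
#'
#' For each TF and genotype over a single pathway: `n_correlated` = number
#' of structural genes with a significant correlation, `n_positive` = the
#' subset with r > 0. Every TF appearing in the records gets a row (zero
#' counts included).
#'
#' @param records One or more genotypes' [screen_pathway()] outputs,
#'   row-bound; must cover a single pathway.
#' @param catalog Optional [gene_catalog()] used to attach TF family
#'   labels.
#' @return Long data.frame: `tf_id`, `family`, `pathway`, `genotype_id`,
#'   `n_correlated`, `n_positive`, `n_negative`.
#' @export
summarize_tf <- function(records, catalog = NULL) {
  need <- c("source_id", "target_id", "genotype_id", "pathway", "r",
            "significant")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_ss("records must come from screen_pathway()")
  if (nrow(records) == 0L) stop_ss("empty record set")
  pw <- unique(records$pathway)
  if (length(pw) != 1L)
    stop_ss("records mix pathways (%s); summarize one pathway at a time",
            paste(pw, collapse = ", "))
  key <- interaction(records$source_id, records$genotype_id, drop = TRUE)
  lev <- levels(key)
  first <- match(lev, as.character(key))
  sig <- records$significant
  rpos <- records$significant & records$r > 0
  rneg <- records$significant & records$r < 0
  out <- data.frame(
    tf_id = records$source_id[first],
    pathway = pw,
    genotype_id = records$genotype_id[first],
    n_correlated = as.integer(tapply(sig, key, sum)),
    n_positive = as.integer(tapply(rpos, key, sum)),
    n_negative = as.integer(tapply(rneg, key, sum)),
    stringsAsFactors = FALSE)
  fam <- rep(NA_character_, nrow(out))
  if (!is.null(catalog) && !is.null(catalog$tf_family)) {
    hit <- match(out$tf_id, names(catalog$tf_family))
    fam <- unname(catalog$tf_family[hit])
  }
  out$family <- fam
  rownames(out) <- NULL
  out[, c("tf_id", "family", "pathway", "genotype_id",
          "n_correlated", "n_positive", "n_negative")]
}

#' Select candidate TFs by per-genotype correlated-gene counts
#'
#' Implements the study's selection slices, e.g. "at least 5 correlated
#' carotenoid structural genes in both genotypes" or "at least 15
#' ascorbate structural genes in AC".
#'
#' @param rows Long summary from [summarize_tf()] (one or more genotypes).
#' @param min_count Per-genotype threshold on `n_correlated`, >= 0.
#' @param require_both If TRUE (default) the threshold must hold in every
#'   genotype present; if FALSE, in at least one.
#' @return The kept rows (all genotype rows of each kept TF), stably
#'   sorted by max `n_correlated` descending, then `tf_id` ascending.
#' @export
select_candidates <- function(rows, min_count, require_both = TRUE) {
  check_number(min_count, "min_count", lower = 0)
  check_flag(require_both, "require_both")
  need <- c("tf_id", "genotype_id", "n_correlated")
  if (!is.data.frame(rows) || !all(need %in% names(rows)))
    stop_ss("rows must come from summarize_tf()")
  genos <- unique(rows$genotype_id)
  per_tf <- split(rows, rows$tf_id)
  keep_tf <- vapply(per_tf, function(d) {
    counts <- stats::setNames(rep(0L, length(genos)), genos)
    counts[d$genotype_id] <- d$n_correlated
    if (require_both) all(counts >= min_count) else any(counts >= min_count)
  }, TRUE)
  kept_ids <- names(keep_tf)[keep_tf]
  kept <- rows[rows$tf_id %in% kept_ids, , drop = FALSE]
  if (nrow(kept) == 0L) return(kept)
  maxc <- vapply(split(kept$n_correlated, kept$tf_id), max, 1L)
  kept$.max <- maxc[kept$tf_id]
  kept <- kept[order(-kept$.max, kept$tf_id, kept$genotype_id), ]
  kept$.max <- NULL
  rownames(kept) <- NULL
  kept
}

#' Validate candidates against additional expression datasets
#'
#' Re-runs the screen per extra dataset (e.g. other sequenced varieties)
#' and cross-tabulates per-TF correlated-gene counts, flagging TFs whose
#' count reaches `min_count` in the primary genotypes and every extra
#' dataset.
#'
#' @param primary_rows [summarize_tf()] rows from the primary genotypes.
#' @param extra List of `ExpressionMatrix` on the same gene-id namespace
#'   (may be empty: primary rows are returned unchanged).
#' @param catalog A [gene_catalog()].
#' @param pathway Pathway screened.
#' @param cfg A [screen_config()].
#' @param min_count Count threshold used for the `in_all` flag, default 1.
#' @return Wide data.frame: `tf_id`, then per dataset `<id>_n_correlated`
#'   and `<id>_n_positive`, plus logical `in_all`.
#' @export
cross_dataset_validate <- function(primary_rows, extra, catalog, pathway,
                                   cfg = screen_config(), min_count = 1L) {
  if (length(extra) == 0L) return(primary_rows)
  stopifnot(all(vapply(extra, inherits, TRUE, "ExpressionMatrix")))
  for (m in extra) {
    ids <- union(catalog$tf_ids, catalog$pathways[[pathway]])
    if (length(intersect(ids, gene_ids(m))) == 0L)
      stop_ss("dataset '%s' shares no gene ids with the catalog",
              m$genotype_id)
  }
  all_rows <- primary_rows
  for (m in extra) {
    rec <- screen_pathway(m, catalog, pathway, cfg)
    all_rows <- rbind(all_rows, summarize_tf(rec, catalog))
  }
  datasets <- unique(all_rows$genotype_id)
  tf_ids <- sort(unique(all_rows$tf_id))
  wide <- data.frame(tf_id = tf_ids, stringsAsFactors = FALSE)
  for (g in datasets) {
    sub <- all_rows[all_rows$genotype_id == g, ]
    i <- match(tf_ids, sub$tf_id)
    nc <- sub$n_correlated[i]; np <- sub$n_positive[i]
    nc[is.na(nc)] <- 0L; np[is.na(np)] <- 0L
    wide[[paste0(g, "_n_correlated")]] <- nc
    wide[[paste0(g, "_n_positive")]] <- np
  }
  count_cols <- paste0(datasets, "_n_correlated")
  wide$in_all <- apply(wide[, count_cols, drop = FALSE] >= min_count, 1L, all)
  wide
}
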