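# RPKM, expressed-gene summaries, expression filtering, and the
# stage-over-stage fold-change table with its zero-expression conventions.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * count / (library_size * gene_length)`. Vectorised over
#' genes; linear in `count` and inverse-linear in `library_size`.
#'
#' @param count Uniquely mapped read count(s), integer >= 0.
#' @param gene_length Mappable gene length(s) in bases, > 0.
#' @param library_size Total uniquely mapped reads of the sample, > 0.
#' @return Numeric RPKM value(s), finite and >= 0.
#' @examples
#' compute_rpkm(10, 1000, 1e6)    # 10
#' compute_rpkm(200, 2000, 5e6)   # 20
#' @export
compute_rpkm <- function(count, gene_length, library_size) {
  if (any(!is.finite(count)) || any(count < 0))
    stop_ss("count must be finite and >= 0")
  if (any(!is.finite(gene_length)) || any(gene_length <= 0))
    stop_ss("gene_length must be > 0")
  if (any(!is.finite(library_size)) || any(library_size <= 0))
    stop_ss("library_size must be > 0")
  if (any(count > library_size))
    stop_ss("count cannot exceed library_size")
  1e9 * count / (library_size * gene_length)
}

#' Count expressed genes in one sample
#'
#' A gene counts as expressed when its mapped read count exceeds `floor`
#' (the study's summary uses floors 0 and 10).
#'
#' @param counts Per-gene read counts, >= 0.
#' @param floor Non-negative integer floor; strictly-greater comparison.
#' @return Integer count in `[0, length(counts)]`, non-increasing in
#'   `floor`.
#' @export
count_expressed <- function(counts, floor = 0L) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_ss("counts must be finite and >= 0")
  check_number(floor, "floor", lower = 0)
  sum(counts > floor)
}

#' Filter an expression matrix on the RPKM floor
#'
#' Keeps exactly the genes with RPKM >= `cfg$min_rpkm` in at least
#' `cfg$min_stages_expressed` stages (default: >= 5.0 in at least one of
#' the stages). Idempotent; the stage axis is unchanged; may return an
#' empty matrix.
#'
#' @param m An `ExpressionMatrix`.
#' @param cfg A [screen_config()].
#' @return The filtered `ExpressionMatrix`.
#' @export
expression_filter <- function(m, cfg = screen_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(cfg, "ScreenConfig"))
  keep <- rowSums(m$values >= cfg$min_rpkm) >= cfg$min_stages_expressed
  expression_matrix(m$values[keep, , drop = FALSE], m$genotype_id, m$stages)
}

fc_kinds <- c("RATIO", "FROM_ZERO", "TO_ZERO", "NOT_DETECTED")

#' Stage-over-stage fold-change table
#'
#' For each gene and stage pair, classifies the change following the
#' published table conventions:
#' \itemize{
#'   \item `RATIO`: both stages detected; value = later/earlier RPKM.
#'   \item `FROM_ZERO`: not detected at the earlier stage; the value is the
#'     later-stage RPKM itself (rendered `"<value>/0"`).
#'   \item `TO_ZERO`: detected earlier, none later (rendered `"0"`).
#'   \item `NOT_DETECTED`: neither stage detected (rendered `"-"`).
#' }
#' "Detected" means RPKM strictly above `detection_floor` (default 0, i.e.
#' any non-zero expression counts as detected).
#'
#' @param m An `ExpressionMatrix` with at least two stages.
#' @param mode `"consecutive"` (each stage vs the previous; default) or
#'   `"vs_first"` (each later stage vs the first stage, e.g. vs 7 DAF).
#' @param detection_floor RPKM at or below which expression counts as not
#'   detected; default 0.
#' @return data.frame with columns `gene_id`, `pair` (e.g. `"14v7"`),
#'   `earlier_daf`, `later_daf`, `kind`, `value` (NA for `NOT_DETECTED`).
#'   In consecutive mode there are exactly
#'   `n_genes * (n_stages - 1)` rows.
#' @export
fold_change_table <- function(m, mode = c("consecutive", "vs_first"),
                              detection_floor = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mode <- match.arg(mode)
  check_number(detection_floor, "detection_floor", lower = 0)
  stages <- as.integer(m$stages)
  if (length(stages) < 2L)
    stop_ss("fold changes need at least 2 stages")
  if (mode == "consecutive") {
    earlier <- stages[-length(stages)]; later <- stages[-1L]
  } else {
    earlier <- rep(stages[1L], length(stages) - 1L); later <- stages[-1L]
  }
  out <- vector("list", length(later))
  gid <- gene_ids(m)
  for (p in seq_along(later)) {
    e <- m$values[, match(earlier[p], stages)]
    l <- m$values[, match(later[p], stages)]
    det_e <- e > detection_floor
    det_l <- l > detection_floor
    kind <- ifelse(det_e & det_l, "RATIO",
            ifelse(!det_e & det_l, "FROM_ZERO",
            ifelse(det_e & !det_l, "TO_ZERO", "NOT_DETECTED")))
    value <- ifelse(kind == "RATIO", l / e,
             ifelse(kind == "FROM_ZERO", l,
             ifelse(kind == "TO_ZERO", 0, NA_real_)))
    out[[p]] <- data.frame(
      gene_id = gid,
      pair = sprintf("%dv%d", later[p], earlier[p]),
      earlier_daf = earlier[p], later_daf = later[p],
      kind = kind, value = value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

render_fold_change <- function(kind, value) {
  ifelse(kind == "NOT_DETECTED", "-",
  ifelse(kind == "FROM_ZERO", paste0(vapply(value, format_num, ""), "/0"),
  ifelse(kind == "TO_ZERO", "0",
         vapply(value, format_num, ""))))
}

#' Write a fold-change table with the published rendering
#'
#' `NOT_DETECTED` is rendered `"-"`, `TO_ZERO` as `"0"`, `FROM_ZERO` as
#' `"<value>/0"` and ratios as plain numbers.
#'
#' @param fc data.frame from [fold_change_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fold_change_table <- function(fc, path) {
  need <- c("gene_id", "pair", "kind", "value")
  if (!is.data.frame(fc) || !all(need %in% names(fc)))
    stop_ss("fc must be a fold_change_table data.frame")
  df <- data.frame(gene_id = fc$gene_id, pair = fc$pair, kind = fc$kind,
                   rendered = render_fold_change(fc$kind, fc$value),
                   stringsAsFactors = FALSE)
  write_tsv_ss(df, path)
}

#' Read back a rendered fold-change table
#'
#' Inverse of [write_fold_change_table()]: parses the `"-"`, `"0"` and
#' `"<value>/0"` conventions back into kind/value records.
#'
#' @param path TSV written by [write_fold_change_table()].
#' @return data.frame with columns `gene_id`, `pair`, `kind`, `value`.
#' @export
read_fold_change_table <- function(path) {
  df <- read_tsv_ss(path)
  rendered <- df$rendered
  kind <- ifelse(rendered == "-", "NOT_DETECTED",
          ifelse(rendered == "0", "TO_ZERO",
          ifelse(grepl("/0$", rendered), "FROM_ZERO", "RATIO")))
  value <- rep(NA_real_, length(rendered))
  value[kind == "TO_ZERO"] <- 0
  value[kind == "FROM_ZERO"] <-
    as.numeric(sub("/0$", "", rendered[kind == "FROM_ZERO"]))
  value[kind == "RATIO"] <- as.numeric(rendered[kind == "RATIO"])
  data.frame(gene_id = df$gene_id, pair = df$pair, kind = kind,
             value = value, stringsAsFactors = FALSE)
}

#' Differential-expression thresholds
#'
#' @param log2_cut Threshold on |log2 fold change|, default 2.
#' @param p_cut Threshold on an externally supplied p-value, default 0.01.
#' @return Object of class `DEConfig`.
#' @export
de_config <- function(log2_cut = 2.0, p_cut = 0.01) {
  check_number(log2_cut, "log2_cut", lower = 0, strict_lower = TRUE)
  check_number(p_cut, "p_cut", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(log2_cut = log2_cut, p_cut = p_cut), class = "DEConfig")
}

#' Flag a fold-change record as differentially expressed
#'
#' True iff `|log2(value)| > log2_cut` and, when a p-value is supplied,
#' `p < p_cut`. P-values are externally supplied (the study used a count
#' model in a published tool for them); with none, the rule degrades to a
#' fold-change-only flag. `FROM_ZERO` records (expression appearing from
#' an undetected baseline) are flagged DE only when
#' `from_zero_is_de = TRUE`; `NOT_DETECTED` is never DE; `TO_ZERO` is
#' treated symmetrically to `FROM_ZERO`.
#'
#' @param kind Fold-change kind (see [fold_change_table()]).
#' @param value Fold change (later/earlier) for `RATIO` records.
#' @param p_value Optional externally supplied p-value in `[0, 1]`.
#' @param cfg A [de_config()].
#' @param from_zero_is_de Treat FROM_ZERO / TO_ZERO as infinite fold change
#'   (default FALSE).
#' @return Logical flag.
#' @export
de_flag <- function(kind, value = NA_real_, p_value = NULL,
                    cfg = de_config(), from_zero_is_de = FALSE) {
  stopifnot(inherits(cfg, "DEConfig"))
  if (!kind %in% fc_kinds) stop_ss("unknown fold-change kind '%s'", kind)
  if (!is.null(p_value)) {
    check_number(p_value, "p_value", lower = 0, upper = 1)
  }
  p_ok <- is.null(p_value) || p_value < cfg$p_cut
  if (kind == "NOT_DETECTED") return(FALSE)
  if (kind %in% c("FROM_ZERO", "TO_ZERO"))
    return(isTRUE(from_zero_is_de) && p_ok)
  check_number(value, "value", lower = 0, strict_lower = TRUE)
  abs(log2(value)) > cfg$log2_cut && p_ok
}
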