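# Shared domain types and tabular readers/writers.
#
# All tabular interchange uses TSV (tab-separated, UTF-8, "." decimal),
# with stage columns identified by name ("DAF7", ...) rather than position,
# so matrices from different genotypes cannot be silently column-swapped.

#' Default developmental stage axis
#'
#' The standard sampling design covers seven tomato fruit stages at weekly
#' intervals, 7 to 49 days after flowering (DAF).
#'
#' @param stages Integer vector of days-after-flowering values.
#' @return A validated integer vector of class `stage_axis`.
#' @details Stages must be strictly increasing and at least three (the
#'   correlation t-test needs `df = n - 2 >= 1`).
#' @examples
#' stage_axis()              # 7 14 21 28 35 42 49
#' stage_axis(c(5, 10, 20))
#' @export
stage_axis <- function(stages = c(7L, 14L, 21L, 28L, 35L, 42L, 49L)) {
  if (!is.numeric(stages) || anyNA(stages))
    stop_ss("stages must be numeric without missing values")
  if (any(stages != round(stages)))
    stop_ss("stages must be whole numbers of days after flowering")
  stages <- as.integer(stages)
  if (length(stages) < 3L)
    stop_ss("a stage axis needs at least 3 stages (got %d)", length(stages))
  if (any(diff(stages) <= 0L))
    stop_ss("stages must be strictly increasing")
  structure(stages, class = "stage_axis")
}

stage_labels <- function(stages) paste0("DAF", as.integer(stages))

#' Construct a genotype-labelled expression matrix
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   one column per stage, holding non-negative finite RPKM values.
#' @param genotype_id Genotype label, e.g. `"AC"` or `"HG6-61"`.
#' @param stages Stage axis (days after flowering), see [stage_axis()].
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `genotype_id`, `stages` and `values` (columns named `DAF<k>`).
#' @export
expression_matrix <- function(values, genotype_id,
                              stages = stage_axis()) {
  check_string(genotype_id, "genotype_id")
  stages <- stage_axis(stages)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ss("values must be a numeric matrix")
  if (is.null(rownames(values))) {
    # subsetting every row away drops dimnames; an empty matrix is valid
    if (nrow(values) == 0L)
      rownames(values) <- character(0)
    else
      stop_ss("values must have gene ids as rownames")
  }
  if (ncol(values) != length(stages))
    stop_ss("values has %d columns but the stage axis has %d stages",
            ncol(values), length(stages))
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_ss("duplicate gene ids: %s", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(values)))
    stop_ss("expression values must all be finite (no NA/NaN/Inf)")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_ss("negative expression value at gene '%s', stage %s",
            rownames(values)[bad[1L]], stage_labels(stages)[bad[2L]])
  }
  colnames(values) <- stage_labels(stages)
  structure(list(genotype_id = genotype_id,
                 stages = stages,
                 values = values),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: genotype %s, %d genes x %d stages (DAF %s)\n",
              x$genotype_id, nrow(x$values), length(x$stages),
              paste(as.integer(x$stages), collapse = ",")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Read an expression matrix from TSV
#'
#' Expects a header `gene_id` followed by one column per stage named
#' `DAF<k>`; stage order is taken from the header.
#'
#' @param path Path to the TSV file.
#' @param genotype_id Genotype label to attach.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, genotype_id) {
  df <- read_tsv_ss(path)
  hdr <- names(df)
  if (length(hdr) < 4L || hdr[1L] != "gene_id")
    stop_ss("malformed header in '%s': expected 'gene_id' then DAF<k> columns",
            path)
  stage_cols <- hdr[-1L]
  ok <- grepl("^DAF[0-9]+$", stage_cols)
  if (!all(ok))
    stop_ss("malformed header in '%s': bad stage column(s) %s",
            path, paste(stage_cols[!ok], collapse = ", "))
  stages <- as.integer(sub("^DAF", "", stage_cols))
  gid <- df[["gene_id"]]
  if (anyDuplicated(gid))
    stop_ss("duplicate gene id(s) in '%s': %s", path,
            paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(stage_cols),
                 dimnames = list(gid, stage_cols))
  for (j in seq_along(stage_cols)) {
    v <- suppressWarnings(as.numeric(df[[stage_cols[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop_ss("non-numeric value '%s' at gene '%s', column %s in '%s'",
              df[[stage_cols[j]]][i], gid[i], stage_cols[j], path)
    }
    if (any(v < 0)) {
      i <- which(v < 0)[1L]
      stop_ss("negative RPKM %s at gene '%s', column %s in '%s'",
              v[i], gid[i], stage_cols[j], path)
    }
    vals[, j] <- v
  }
  expression_matrix(vals, genotype_id, stages)
}

#' Write an expression matrix to TSV
#'
#' Values formatted with full double precision: matrices whose values carry
#' a fixed decimal precision round-trip bit-for-bit through
#' [read_expression_matrix()].
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m$values)))
    df[[colnames(m$values)[j]]] <- format_num(m$values[, j])
  write_tsv_ss(df, path)
}

#' Read a gene-id list
#'
#' One id per line; `#` comment lines and blank lines are ignored.
#' Duplicates are dropped (first occurrence kept) and their count is
#' reported via a message and the `"n_duplicates_dropped"` attribute.
#'
#' @param path Path to the list file.
#' @return Character vector of unique ids, order preserved.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop_ss("gene list '%s' contains no ids", path)
  n_dup <- sum(duplicated(lines))
  ids <- lines[!duplicated(lines)]
  if (n_dup > 0L)
    message(sprintf("read_gene_list: dropped %d duplicate id(s) from '%s'",
                    n_dup, path))
  attr(ids, "n_duplicates_dropped") <- n_dup
  ids
}

#' Construct a gene catalog
#'
#' Pathway structural-gene sets plus the transcription-factor universe.
#' In the tomato fruit study design the pathways are ascorbate, carotenoid
#' and flavonoid biosynthesis (46, 18 and 14 structural genes) and the TF
#' set holds the annotated tomato transcription factors.
#'
#' @param pathways Named list of character vectors: pathway name -> set of
#'   structural gene ids. Sets must be non-empty; a gene may appear in more
#'   than one pathway.
#' @param tf_ids Character vector of transcription-factor gene ids.
#' @param tf_family Optional named character vector mapping tf id -> family
#'   label (MYB, NAC, bHLH, ...).
#' @param allow_overlap Permit genes listed both as structural genes and
#'   TFs (default FALSE).
#' @return Object of class `GeneCatalog`.
#' @export
gene_catalog <- function(pathways, tf_ids, tf_family = NULL,
                         allow_overlap = FALSE) {
  if (!is.list(pathways) || is.null(names(pathways)) ||
      any(!nzchar(names(pathways))))
    stop_ss("pathways must be a named list of gene-id vectors")
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  empty <- names(pathways)[vapply(pathways, length, 1L) == 0L]
  if (length(empty))
    stop_ss("empty pathway set(s): %s", paste(empty, collapse = ", "))
  tf_ids <- unique(as.character(tf_ids))
  if (length(tf_ids) == 0L) stop_ss("tf_ids must be non-empty")
  if (!allow_overlap) {
    for (p in names(pathways)) {
      ov <- intersect(pathways[[p]], tf_ids)
      if (length(ov))
        stop_ss("gene(s) in both pathway '%s' and tf_ids: %s (set allow_overlap = TRUE to permit)",
                p, paste(ov, collapse = ", "))
    }
  }
  if (!is.null(tf_family)) {
    if (is.null(names(tf_family)))
      stop_ss("tf_family must be a named character vector (tf_id -> family)")
    tf_family <- vapply(tf_family, as.character, "")
  }
  structure(list(pathways = pathways, tf_ids = tf_ids,
                 tf_family = tf_family),
            class = "GeneCatalog")
}

#' @export
print.GeneCatalog <- function(x, ...) {
  sizes <- vapply(x$pathways, length, 1L)
  cat(sprintf("GeneCatalog: %d pathway(s) [%s], %d TFs\n",
              length(sizes),
              paste(sprintf("%s:%d", names(sizes), sizes), collapse = ", "),
              length(x$tf_ids)))
  invisible(x)
}

#' Read a gene catalog from a JSON manifest
#'
#' The manifest maps pathway names to gene-list file paths (relative to the
#' manifest's directory), names the TF list file, and optionally a TSV of
#' `tf_id <tab> family`.
#'
#' @param manifest_path Path to the JSON manifest with fields `pathways`
#'   (object: name -> list file), `tf_list` (file) and optional
#'   `tf_families` (TSV file).
#' @return A [gene_catalog()].
#' @export
read_gene_catalog <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  if (is.null(man$pathways) || is.null(man$tf_list))
    stop_ss("catalog manifest must have 'pathways' and 'tf_list' fields")
  pathways <- lapply(man$pathways, function(f) {
    as.character(suppressMessages(read_gene_list(file.path(base, f))))
  })
  tf_ids <- as.character(suppressMessages(
    read_gene_list(file.path(base, man$tf_list))))
  tf_family <- NULL
  if (!is.null(man$tf_families)) {
    fam <- read_tsv_ss(file.path(base, man$tf_families))
    if (!all(c("tf_id", "family") %in% names(fam)))
      stop_ss("tf_families TSV must have columns tf_id and family")
    tf_family <- stats::setNames(fam$family, fam$tf_id)
  }
  gene_catalog(pathways, tf_ids, tf_family)
}

#' Write a gene catalog as list files plus a JSON manifest
#'
#' @param catalog A `GeneCatalog`.
#' @param dir Output directory (created if needed).
#' @param manifest_name File name of the JSON manifest inside `dir`.
#' @return Path to the manifest, invisibly.
#' @export
write_gene_catalog <- function(catalog, dir, manifest_name = "catalog.json") {
  stopifnot(inherits(catalog, "GeneCatalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(pathways = list(), tf_list = "tf_ids.txt")
  for (p in names(catalog$pathways)) {
    f <- paste0("pathway_", gsub("[^A-Za-z0-9._-]", "_", p), ".txt")
    writeLines(catalog$pathways[[p]], file.path(dir, f))
    man$pathways[[p]] <- f
  }
  writeLines(catalog$tf_ids, file.path(dir, man$tf_list))
  if (!is.null(catalog$tf_family)) {
    man$tf_families <- "tf_families.tsv"
    write_tsv_ss(data.frame(tf_id = names(catalog$tf_family),
                            family = unname(catalog$tf_family),
                            stringsAsFactors = FALSE),
                 file.path(dir, man$tf_families))
  }
  path <- file.path(dir, manifest_name)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct a metabolite stage-course series
#'
#' @param metabolite_id Metabolite label (e.g. `"total-AsA"`, `"DHA"`,
#'   `"lycopene"`, `"rutin"`).
#' @param genotype_id Genotype label.
#' @param values Non-negative concentrations, one per stage.
#' @param stages Stage axis.
#' @param units Free-text units, e.g. `"mg g-1 FW"`.
#' @return Object of class `MetaboliteSeries`.
#' @export
metabolite_series <- function(metabolite_id, genotype_id, values,
                              stages = stage_axis(), units = "a.u.") {
  check_string(metabolite_id, "metabolite_id")
  check_string(genotype_id, "genotype_id")
  stages <- stage_axis(stages)
  if (!is.numeric(values) || length(values) != length(stages))
    stop_ss("values must be numeric with one entry per stage (%d)",
            length(stages))
  if (any(!is.finite(values)) || any(values < 0))
    stop_ss("metabolite concentrations must be finite and >= 0")
  structure(list(metabolite_id = metabolite_id, genotype_id = genotype_id,
                 stages = stages, values = as.numeric(values),
                 units = units),
            class = "MetaboliteSeries")
}

#' Read a metabolite table (one series per row)
#'
#' Columns: `metabolite_id`, `genotype`, `units`, then `DAF<k>` stage
#' columns.
#'
#' @param path Path to the TSV file.
#' @return List of [metabolite_series()] objects.
#' @export
read_metabolite_table <- function(path) {
  df <- read_tsv_ss(path)
  need <- c("metabolite_id", "genotype", "units")
  if (!all(need %in% names(df)))
    stop_ss("metabolite TSV '%s' must have columns %s then DAF<k>",
            path, paste(need, collapse = ", "))
  stage_cols <- setdiff(names(df), need)
  if (!all(grepl("^DAF[0-9]+$", stage_cols)))
    stop_ss("bad stage column(s) in '%s'", path)
  stages <- as.integer(sub("^DAF", "", stage_cols))
  lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(df[i, stage_cols])))
    if (anyNA(v))
      stop_ss("non-numeric concentration for metabolite '%s' in '%s'",
              df$metabolite_id[i], path)
    metabolite_series(df$metabolite_id[i], df$genotype[i], v,
                      stages, df$units[i])
  })
}

#' Write metabolite series to a TSV table
#'
#' @param series List of `MetaboliteSeries` (common stage axis).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(series, path) {
  stopifnot(length(series) > 0L,
            all(vapply(series, inherits, TRUE, "MetaboliteSeries")))
  stages <- series[[1L]]$stages
  for (s in series)
    if (!identical(as.integer(s$stages), as.integer(stages)))
      stop_ss("all metabolite series must share one stage axis")
  df <- data.frame(
    metabolite_id = vapply(series, `[[`, "", "metabolite_id"),
    genotype = vapply(series, `[[`, "", "genotype_id"),
    units = vapply(series, `[[`, "", "units"),
    stringsAsFactors = FALSE)
  vals <- t(vapply(series, `[[`, numeric(length(stages)), "values"))
  for (j in seq_along(stages))
    df[[stage_labels(stages)[j]]] <- format_num(vals[, j])
  write_tsv_ss(df, path)
}

#' Screening configuration
#'
#' Holds the thresholds of the co-expression screen: the expression floor
#' (RPKM >= 5 in at least one stage, the study's false-positive guard), the
#' correlation magnitude cut (|r| >= 0.8) and the two-sided significance
#' level of the correlation t-test (alpha = 0.05 at n = 7 stages, i.e.
#' r > 0.754).
#'
#' @param min_rpkm Expression floor (RPKM), default 5.
#' @param min_stages_expressed Minimum number of stages at or above the
#'   floor for a gene to be kept, default 1.
#' @param r_threshold Minimum |r| for a pair to count as correlated,
#'   default 0.8. Must be in (0, 1].
#' @param alpha Two-sided significance level for the correlation t-test,
#'   default 0.05.
#' @param correlation_scale Correlate on `"raw"` RPKM (default, matching a
#'   spreadsheet-style correlation of the expression values) or on
#'   `"log2"` (log2(RPKM + 1)).
#' @return Object of class `ScreenConfig`.
#' @export
screen_config <- function(min_rpkm = 5.0, min_stages_expressed = 1L,
                          r_threshold = 0.8, alpha = 0.05,
                          correlation_scale = c("raw", "log2")) {
  check_number(min_rpkm, "min_rpkm", lower = 0)
  check_number(min_stages_expressed, "min_stages_expressed", lower = 1)
  check_number(r_threshold, "r_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  correlation_scale <- match.arg(correlation_scale)
  structure(list(min_rpkm = min_rpkm,
                 min_stages_expressed = as.integer(min_stages_expressed),
                 r_threshold = r_threshold, alpha = alpha,
                 correlation_scale = correlation_scale),
            class = "ScreenConfig")
}

#' Write a Table-3-style TF summary
#'
#' Renders, per TF and genotype, the count of correlated structural genes
#' with the count of positively correlated ones in brackets — the
#' `"25(20)"` notation.
#'
#' @param rows Long-format summary as returned by [summarize_tf()]:
#'   columns `tf_id`, `family`, `pathway`, `genotype_id`, `n_correlated`,
#'   `n_positive`.
#' @param path Output TSV path.
#' @return The wide data.frame written, invisibly.
#' @export
write_tf_summary <- function(rows, path) {
  need <- c("tf_id", "family", "pathway", "genotype_id",
            "n_correlated", "n_positive")
  if (!is.data.frame(rows) || !all(need %in% names(rows)))
    stop_ss("rows must be a data.frame with columns %s",
            paste(need, collapse = ", "))
  bad <- rows$n_positive > rows$n_correlated
  if (any(bad))
    stop_ss("n_positive > n_correlated for tf '%s' (%d > %d): refusing to write",
            rows$tf_id[which(bad)[1L]],
            rows$n_positive[which(bad)[1L]],
            rows$n_correlated[which(bad)[1L]])
  genos <- unique(rows$genotype_id)
  base <- unique(rows[, c("tf_id", "family", "pathway")])
  wide <- base
  for (g in genos) {
    sub <- rows[rows$genotype_id == g, ]
    i <- match(paste(base$tf_id, base$pathway),
               paste(sub$tf_id, sub$pathway))
    nc <- sub$n_correlated[i]
    np <- sub$n_positive[i]
    nc[is.na(nc)] <- 0L; np[is.na(np)] <- 0L
    wide[[paste0(g, "_n_correlated")]] <- nc
    wide[[paste0(g, "_n_positive")]] <- np
    wide[[paste0(g, "_summary")]] <- render_count_pair(nc, np)
  }
  write_tsv_ss(wide, path)
  invisible(wide)
}

#' Render "N(P)" count cells
#'
#' @param n_correlated Count of correlated structural genes.
#' @param n_positive Count of those with positive correlation.
#' @return Character vector like `"25(20)"`.
#' @export
render_count_pair <- function(n_correlated, n_positive) {
  if (any(n_positive > n_correlated))
    stop_ss("n_positive cannot exceed n_correlated")
  sprintf("%d(%d)", as.integer(n_correlated), as.integer(n_positive))
}
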