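# K-means grouping of temporal log2 expression profiles and the
# all-samples stage correlation matrix.

#' Log2 expression profiles
#'
#' @param m An `ExpressionMatrix`.
#' @param pseudocount Offset added before the log; must be > 0 unless all
#'   values are strictly positive. Default 1, so zero RPKM maps to 0.
#' @return Numeric gene x stage matrix of `log2(RPKM + pseudocount)`.
#' @export
log2_profiles <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  check_number(pseudocount, "pseudocount", lower = 0)
  if (pseudocount == 0 && any(m$values == 0))
    stop_ss("zero expression values with pseudocount 0 would produce -Inf")
  log2(m$values + pseudocount)
}

# k-means++ style seeding: first center uniform, later centers sampled with
# probability proportional to squared distance from the nearest chosen
# center. Never selects a duplicate point while distinct points remain.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0))
      stop_ss("fewer than k = %d distinct profiles", k)
    idx[j] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ], "-")^2))
  }
  x[idx, , drop = FALSE]
}

#' Cluster temporal profiles with K-means
#'
#' Lloyd's algorithm with k-means++ style seeding; the best (lowest total
#' within-cluster sum of squares) of `n_init` restarts is returned.
#' Deterministic for a fixed `seed`. Groups are renumbered by descending
#' size so labels are stable and reportable.
#'
#' @param profiles Numeric gene x stage matrix (typically
#'   [log2_profiles()] output), rownames = gene ids.
#' @param k Number of groups (the study design uses 20 temporal patterns).
#' @param seed Integer RNG seed.
#' @param n_init Number of random restarts, default 10.
#' @param max_iter Maximum Lloyd iterations per restart, default 100.
#' @return Object of class `ClusterAssignment`: list with `k`, `labels`
#'   (named integer vector, gene -> group in 1..k), `centroids` (k x
#'   n_stages matrix), `sse` (total within-cluster sum of squared
#'   distances), `sizes` and `seed`.
#' @export
kmeans_profiles <- function(profiles, k = 20L, seed = 1L, n_init = 10L,
                            max_iter = 100L) {
  if (!is.matrix(profiles) || !is.numeric(profiles))
    stop_ss("profiles must be a numeric matrix")
  if (any(!is.finite(profiles)))
    stop_ss("profiles must be finite")
  n <- nrow(profiles)
  check_number(k, "k", lower = 1)
  k <- as.integer(k)
  if (k > n) stop_ss("k = %d exceeds the number of profiles (%d)", k, n)
  check_number(n_init, "n_init", lower = 1)
  check_number(max_iter, "max_iter", lower = 1)
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- tryCatch({
      centers <- kmeanspp_centers(profiles, k)
      suppressWarnings(stats::kmeans(profiles, centers = centers,
                                     iter.max = max_iter,
                                     algorithm = "Lloyd"))
    }, error = function(e) {
      if (grepl("distinct profiles", conditionMessage(e))) stop(e)
      NULL  # an empty-cluster restart is discarded, not fatal
    })
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop_ss("all %d k-means restarts failed", n_init)
  # renumber groups by descending size (ties: previous label order)
  ord <- order(-best$size, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[best$cluster]
  names(labels) <- rownames(profiles)
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(k = k, labels = labels, centroids = centroids,
                 sse = best$tot.withinss, sizes = best$size[ord],
                 seed = as.integer(seed)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: k = %d, %d profiles, SSE = %.4g (seed %d)\n",
              x$k, length(x$labels), x$sse, x$seed))
  invisible(x)
}

#' Correlation matrix over all genotype x stage samples
#'
#' Pearson correlation of genome-wide expression between every pair of
#' samples (each genotype x stage column), computed over the genes shared
#' by all matrices. With two genotypes at seven stages this is the 14 x 14
#' sample-similarity matrix used to compare developmental trajectories.
#'
#' @param ms A single `ExpressionMatrix` or list of them (one per
#'   genotype) on a common gene-id namespace.
#' @param log2 Correlate on log2(RPKM + pseudocount) scale (default TRUE).
#' @param pseudocount Offset for the log transform.
#' @return Object of class `StageCorrelationMatrix`: the square symmetric
#'   correlation matrix with unit diagonal, sample labels
#'   `<genotype>_DAF<k>`.
#' @export
stage_correlation_matrix <- function(ms, log2 = TRUE, pseudocount = 1) {
  if (inherits(ms, "ExpressionMatrix")) ms <- list(ms)
  stopifnot(length(ms) > 0L,
            all(vapply(ms, inherits, TRUE, "ExpressionMatrix")))
  shared <- Reduce(intersect, lapply(ms, gene_ids))
  if (length(shared) == 0L)
    stop_ss("no shared gene ids across matrices")
  cols <- lapply(ms, function(m) {
    v <- m$values[shared, , drop = FALSE]
    colnames(v) <- paste0(m$genotype_id, "_", colnames(v))
    v
  })
  combined <- do.call(cbind, cols)
  if (log2) combined <- base::log2(combined + pseudocount)
  sds <- apply(combined, 2L, stats::sd)
  if (any(sds == 0))
    stop_ss("zero-variance sample column(s): %s",
            paste(colnames(combined)[sds == 0], collapse = ", "))
  r <- stats::cor(combined)
  structure(r, class = c("StageCorrelationMatrix", class(r)))
}
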