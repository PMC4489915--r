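# fixtures built in code

make_matrix <- function(values, gene_ids, genotype = "AC",
                        stages = stage_axis()) {
  m <- matrix(values, nrow = length(gene_ids), byrow = TRUE,
              dimnames = list(gene_ids, NULL))
  expression_matrix(m, genotype, stages)
}

# small deterministic catalog: 3 SGs in one pathway, 2 TFs
toy_catalog <- function() {
  gene_catalog(pathways = list(demo = c("SG1", "SG2", "SG3")),
               tf_ids = c("TF1", "TF2"),
               tf_family = c(TF1 = "MYB", TF2 = "NAC"))
}

# textbook product-moment formula, written from sums: the independent
# oracle used against implementations that call stats::cor
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

read_tsv_ss_for_test <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
}

# exhaustive 2-part partition optimum of total within-cluster SSE
oracle_best_sse_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 2)) {  # fix point 1 in cluster A: 2^(n-1)-1 splits
    inA <- c(TRUE, bitwAnd(mask, 2^(0:(n - 2))) > 0)
    sse <- 0
    for (grp in list(x[inA, , drop = FALSE], x[!inA, , drop = FALSE])) {
      c0 <- colMeans(grp)
      sse <- sse + sum(sweep(grp, 2L, c0, "-")^2)
    }
    best <- min(best, sse)
  }
  best
}
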