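#' Spearman rank correlation with two-sided P
#'
#' Pairwise-complete Spearman correlation (average ranks for ties). Fewer
#' than 3 complete pairs yields an `NA` result rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p_value` and `n` (complete pairs used).
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # rho = 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Pairwise Spearman correlation matrix across experiments
#'
#' Correlates every pair of experiment columns of a gene x experiment FCC'
#' matrix, using the pairwise-complete gene set for each cell. Returns the
#' symmetric rho matrix with unit diagonal and the per-cell count of genes
#' used.
#'
#' @param fcc Numeric matrix, genes x experiments, `NA` permitted;
#'   column names are experiment labels.
#' @return List with `rho` (experiment x experiment) and `n` (pairs used).
#' @export
correlation_matrix <- function(fcc) {
  fcc <- as.matrix(fcc)
  if (ncol(fcc) < 2) stop("need at least 2 experiments", call. = FALSE)
  labs <- colnames(fcc)
  if (is.null(labs)) labs <- paste0("E", seq_len(ncol(fcc)))
  m <- ncol(fcc)
  rho <- diag(1, m); nmat <- matrix(nrow(fcc), m, m)
  dimnames(rho) <- dimnames(nmat) <- list(labs, labs)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sc <- spearman_cor(fcc[, i], fcc[, j])
    rho[i, j] <- rho[j, i] <- sc$rho
    nmat[i, j] <- nmat[j, i] <- sc$n
    nmat[i, i] <- sum(is.finite(fcc[, i]))
  }
  nmat[m, m] <- sum(is.finite(fcc[, m]))
  list(rho = rho, n = nmat)
}

#' Cluster experiments from a correlation matrix
#'
#' Complete-linkage agglomerative clustering of the experiments, each
#' represented by its row of the correlation matrix, using Euclidean row
#' distance. Rows are ordered lexicographically by label first, so merge
#' order is deterministic under ties.
#'
#' @param rho_matrix Square symmetric correlation matrix with labelled rows.
#' @return An [stats::hclust] tree.
#' @export
cluster_experiments <- function(rho_matrix) {
  rho_matrix <- as.matrix(rho_matrix)
  if (nrow(rho_matrix) != ncol(rho_matrix))
    stop("correlation matrix must be square", call. = FALSE)
  if (max(abs(rho_matrix - t(rho_matrix)), na.rm = TRUE) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  ord <- order(rownames(rho_matrix))
  rho_matrix <- rho_matrix[ord, ord, drop = FALSE]
  stats::hclust(stats::dist(rho_matrix, method = "euclidean"),
                method = "complete")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] tree (e.g. from [cluster_experiments()]).
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Correlate a per-gene covariate with FCC' values
#'
#' Aligns the two named vectors on shared gene ids and reports the Spearman
#' correlation on the pairwise-complete subset (e.g. FCC' versus expression
#' fold change, protein abundance, dosage compensation or interaction
#' degree).
#'
#' @param scores Named numeric vector of per-gene FCC' values.
#' @param covariate Named numeric vector of per-gene covariate values.
#' @return List with `rho`, `p_value` and `n`.
#' @export
covariate_correlation <- function(scores, covariate) {
  if (is.null(names(scores)) || is.null(names(covariate)))
    stop("scores and covariate must be named by gene id", call. = FALSE)
  shared <- intersect(names(scores), names(covariate))
  if (length(shared) < 3)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(shared)))
  spearman_cor(scores[shared], covariate[shared])
}
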