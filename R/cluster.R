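#' Select the most variable features
#'
#' Returns the `k` features with the largest per-feature standard deviation
#' across samples (computed over non-missing entries). Ties are broken by
#' feature id, lexicographically, so the selection is deterministic.
#'
#' @param expr numeric feature x sample matrix with dimnames.
#' @param k number of features to keep (default 50).
#' @return the subsetted matrix, features ordered by decreasing s.d.
#' @export
top_varying <- function(expr, k = 50) {
  stopifnot(is.matrix(expr), k > 0, k <= nrow(expr))
  sds <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  ord <- order(-sds, rownames(expr))
  expr[ord[seq_len(k)], , drop = FALSE]
}

#' Impute undetected expression with the per-feature minimum
#'
#' Undetected qPCR reactions correspond to low abundance; before distance
#' computations each missing entry is replaced by the smallest observed
#' value of its feature.
#'
#' @param expr numeric matrix with possible `NA`s.
#' @return matrix without `NA`s (features that are entirely missing error).
#' @export
impute_feature_min <- function(expr) {
  if (!anyNA(expr)) return(expr)
  for (i in which(rowSums(is.na(expr)) > 0)) {
    obs <- expr[i, !is.na(expr[i, ])]
    if (length(obs) == 0L) stop("feature ", rownames(expr)[i],
                                " has no observed values")
    expr[i, is.na(expr[i, ])] <- min(obs)
  }
  expr
}

#' Hierarchical sample clustering with silhouette-guided cluster number
#'
#' Complete-linkage agglomerative clustering of samples on Euclidean
#' distances; the number of clusters is the value in `k_range` whose flat
#' cut maximises the average silhouette width (ties go to the smallest k).
#'
#' @param expr numeric feature x sample matrix; `NA`s are imputed with the
#'   feature minimum when `impute = TRUE`, otherwise rejected.
#' @param k_range candidate cluster counts, all within `[2, n_samples - 1]`.
#' @param impute impute missing values with [impute_feature_min()]
#'   (default TRUE).
#' @return object of class `cluster_result`: `labels` (named integer
#'   vector), `k`, `avg_silhouette`, `silhouette_by_k` (named numeric),
#'   `hclust` (the dendrogram), `dist`.
#' @examples
#' set.seed(1)
#' x <- cbind(matrix(rnorm(40), 4), matrix(rnorm(40, 6), 4))
#' colnames(x) <- paste0("s", 1:20); rownames(x) <- paste0("f", 1:4)
#' hierarchical_cluster(x, k_range = 2:4)
#' @export
hierarchical_cluster <- function(expr, k_range = 2:6, impute = TRUE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  if (anyNA(expr)) {
    if (!impute) stop("expr contains missing values and impute = FALSE")
    expr <- impute_feature_min(expr)
  }
  n <- ncol(expr)
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n_samples - 1]")
  }
  d <- stats::dist(t(expr))
  if (max(d) == 0) stop("degenerate input: all samples identical")
  hc <- stats::hclust(d, method = "complete")
  avg <- vapply(k_range, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(avg) <- as.character(k_range)
  best <- k_range[which.max(avg)]  # ties resolve to the smallest k
  labels <- stats::cutree(hc, k = best)
  structure(list(labels = labels, k = best,
                 avg_silhouette = unname(avg[as.character(best)]),
                 silhouette_by_k = avg, hclust = hc, dist = d),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: k = %d clusters over %d samples\n",
              x$k, length(x$labels)))
  cat(sprintf("  average silhouette width: %.3f\n", x$avg_silhouette))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Permutation p-value for the average silhouette width
#'
#' Calibrates the observed average silhouette width against a null in which
#' each feature's values are independently shuffled across samples,
#' destroying sample structure while preserving each feature's marginal
#' distribution. Each permutation reruns the full cluster-number selection.
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#'
#' @param expr feature x sample matrix (missing values imputed as in
#'   [hierarchical_cluster()]).
#' @param observed_avg_silhouette observed statistic, e.g. from
#'   [hierarchical_cluster()].
#' @param k_range candidate cluster counts used for each permutation.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional RNG seed for reproducibility.
#' @return permutation p-value.
#' @export
silhouette_permutation_p <- function(expr, observed_avg_silhouette,
                                     k_range = 2:6, n_perm = 1000,
                                     seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  expr <- impute_feature_min(expr)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- t(apply(expr, 1L, sample))
    res <- hierarchical_cluster(perm, k_range = k_range)
    if (res$avg_silhouette >= observed_avg_silhouette) ge <- ge + 1L
  }
  (1 + ge) / (n_perm + 1)
}

#' Pearson chi-squared association between two categorical variables
#'
#' Pearson's chi-squared test without continuity correction, on the
#' contingency table of cluster labels (or group membership) against a
#' clinicopathological variable. A pre-tabulated contingency matrix may be
#' supplied directly as `x`.
#'
#' @param x categorical vector (e.g. cluster labels), or a contingency
#'   matrix of counts (then `y` is ignored).
#' @param y categorical vector of the same length as `x`.
#' @param variable label stored in the result (default deparsed `y`).
#' @return data.frame with `variable`, `statistic`, `df`, `p`.
#' @examples
#' chi_square_association(matrix(c(8, 12, 9, 41), 2),
#'                        variable = "HER2 amplification")
#' @export
chi_square_association <- function(x, y = NULL, variable = NULL) {
  if (is.matrix(x)) {
    tab <- as.table(x)
    if (is.null(variable)) variable <- "contingency"
  } else {
    stopifnot(!is.null(y), length(x) == length(y))
    if (is.null(variable)) variable <- deparse(substitute(y))
    tab <- table(x, y)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate contingency table: need >= 2 non-empty levels per margin")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(variable = variable,
             statistic = unname(ht$statistic),
             df = unname(ht$parameter),
             p = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Global test of association between an expression set and an outcome
#'
#' Tests whether a whole feature set's expression carries information about
#' a binary outcome, in the spirit of Goeman's global test: with `Z` the
#' feature-standardised expression matrix and `y` the centred outcome, the
#' statistic is the quadratic form `Q = y' Z'Z y` (the Gram matrix of the
#' samples in feature space), calibrated by permuting the outcome labels.
#' `Q` is invariant in p-value to feature rescaling (features are
#' standardised first) and to feature duplication.
#'
#' @param expr numeric feature x sample matrix (constant features dropped).
#' @param outcome binary vector/factor over samples, two non-empty levels.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional RNG seed.
#' @return list with `statistic` (observed Q), `p`, `n_perm`.
#' @export
global_test <- function(expr, outcome, n_perm = 10000, seed = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) == length(outcome))
  y <- as.integer(factor(outcome)) - 1L
  if (length(unique(y)) != 2L) stop("outcome must have exactly two levels")
  if (!is.null(seed)) set.seed(seed)
  sds <- apply(expr, 1L, stats::sd)
  Z <- expr[sds > 0, , drop = FALSE]
  Z <- t(scale(t(Z)))
  K <- crossprod(Z)           # samples x samples Gram matrix
  yc <- y - mean(y)
  q_obs <- drop(yc %*% K %*% yc)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    yp <- sample(yc)
    if (drop(yp %*% K %*% yp) >= q_obs) ge <- ge + 1L
  }
  list(statistic = q_obs, p = (1 + ge) / (n_perm + 1), n_perm = n_perm)
}
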