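#' Regulatory-effect (RE) rank score for one sample
#'
#' Within-sample rank score of how strongly an miRNA family's targets stand
#' out from the rest of the transcriptome. Two modes:
#' \describe{
#'   \item{signed}{genes are ranked ascending by expression (midranks on
#'     ties); `RE = (mean rank of non-targets - mean rank of targets) /
#'     ((G + 1) / 2)` with `G` the universe size. High RE means targets sit
#'     low in the expression ranking, i.e. strong repression.}
#'   \item{symmetric}{genes are ranked ascending by the absolute deviation
#'     of their expression from a per-gene reference (the cross-sample
#'     median, supplied via `center`); `RE = (mean rank of targets - mean
#'     rank of non-targets) / ((G + 1) / 2)`, so strong up- OR
#'     down-regulation of the targets both raise RE - inhibitory and
#'     activating effects are weighed equally.}
#' }
#' The `(G + 1) / 2` normalisation bounds `|RE| < 1` for every target-set
#' size, making scores comparable across universes.
#'
#' @param expr_sample numeric vector of one sample's per-gene expression
#'   (named, or indexed by `targets`).
#' @param targets gene names (or integer indices) of the family's targets;
#'   must be a non-empty strict subset of the genes.
#' @param mode `"signed"` or `"symmetric"`.
#' @param center per-gene reference values for symmetric mode (same length
#'   and order as `expr_sample`); required there, ignored for signed mode.
#' @return scalar RE score.
#' @export
re_score_sample <- function(expr_sample, targets,
                            mode = c("signed", "symmetric"), center = NULL) {
  mode <- match.arg(mode)
  G <- length(expr_sample)
  idx <- if (is.character(targets)) {
    match(targets, names(expr_sample))
  } else as.integer(targets)
  if (anyNA(idx)) stop("unknown target gene(s)")
  idx <- unique(idx)
  if (length(idx) < 1L || length(idx) >= G) {
    stop("targets must be a non-empty strict subset of the genes")
  }
  if (mode == "signed") {
    r <- rank(expr_sample)
    num <- mean(r[-idx]) - mean(r[idx])
  } else {
    if (is.null(center)) stop("symmetric mode needs per-gene center values")
    r <- rank(abs(expr_sample - center))
    num <- mean(r[idx]) - mean(r[-idx])
  }
  num / ((G + 1) / 2)
}

#' RE score matrix over miRNA families and samples
#'
#' Applies [re_score_sample()] to every (family, sample) combination.
#' Families with no target present on the matrix (or covering the whole
#' matrix) are dropped with a message. For symmetric mode the per-gene
#' reference is the cross-sample median of the supplied matrix.
#'
#' @param mrna_expr numeric gene x sample matrix.
#' @param db named list, miRNA family -> target gene symbols.
#' @param mode `"signed"` or `"symmetric"` (default symmetric).
#' @return numeric family x sample matrix of RE scores.
#' @export
re_matrix <- function(mrna_expr, db, mode = c("symmetric", "signed")) {
  mode <- match.arg(mode)
  G <- nrow(mrna_expr)
  idx_list <- lapply(db, function(g) {
    i <- match(unique(g), rownames(mrna_expr))
    i[!is.na(i)]
  })
  keep <- lengths(idx_list) >= 1L & lengths(idx_list) < G
  if (any(!keep)) {
    message(sum(!keep), " famil(ies) dropped: no usable target on the matrix")
  }
  idx_list <- idx_list[keep]
  if (length(idx_list) == 0L) stop("no family with targets on the matrix")
  ranks <- if (mode == "signed") {
    apply(mrna_expr, 2L, rank)
  } else {
    ctr <- apply(mrna_expr, 1L, stats::median)
    apply(abs(mrna_expr - ctr), 2L, rank)
  }
  total <- colSums(ranks)          # = G(G+1)/2 per sample, with midranks
  out <- matrix(NA_real_, length(idx_list), ncol(mrna_expr),
                dimnames = list(names(idx_list), colnames(mrna_expr)))
  for (f in seq_along(idx_list)) {
    idx <- idx_list[[f]]
    t_sum <- colSums(ranks[idx, , drop = FALSE])
    m_t <- t_sum / length(idx)
    m_nt <- (total - t_sum) / (G - length(idx))
    num <- if (mode == "signed") m_nt - m_t else m_t - m_nt
    out[f, ] <- num / ((G + 1) / 2)
  }
  out
}

#' SAM-style two-group comparison of RE scores
#'
#' Compares per-family RE scores between two groups with a moderated
#' difference statistic `d = (mean_1 - mean_2) / (se + s0)`, where `se` is
#' the pooled two-sample standard error and the fudge factor `s0` is a low
#' quantile of the per-family `se` distribution (variance stabilisation, as
#' in the significance analysis of microarrays). False discovery rates come
#' from group-label permutations: for each family's |d| cutoff, the q-value
#' is the median permuted count of exceedances divided by the observed
#' count, capped at 1 and made monotone. A per-family permutation p-value
#' (same-family exceedance rate) is also returned.
#'
#' @param re family x sample RE matrix from [re_matrix()].
#' @param groups binary factor over samples (first level = group of
#'   interest, e.g. IBC).
#' @param n_perm number of label permutations (default 1000).
#' @param s0_quantile quantile of the per-family se used as `s0`
#'   (default 0.05).
#' @param seed optional RNG seed.
#' @return data.frame per family: `family_id`, `d_stat`, `direction`
#'   (`"higher in <level1>"` / `"higher in <level2>"`), `p` (permutation),
#'   `q` (SAM-style FDR), `flagged` (constant RE row). The fraction of
#'   families with higher mean RE in the first group is attached as
#'   attribute `"frac_higher_group1"`.
#' @export
re_group_compare <- function(re, groups, n_perm = 1000, s0_quantile = 0.05,
                             seed = NULL) {
  stopifnot(is.matrix(re), ncol(re) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (min(table(groups)) < 3L) stop("need >= 3 samples per group")
  if (!is.null(seed)) set.seed(seed)
  g1 <- groups == levels(groups)[1]
  d_of <- function(mat, g, s0) {
    n1 <- sum(g); n2 <- sum(!g)
    m1 <- rowMeans(mat[, g, drop = FALSE])
    m2 <- rowMeans(mat[, !g, drop = FALSE])
    v1 <- apply(mat[, g, drop = FALSE], 1L, stats::var)
    v2 <- apply(mat[, !g, drop = FALSE], 1L, stats::var)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    se <- sp * sqrt(1 / n1 + 1 / n2)
    list(d = (m1 - m2) / (se + s0), se = se, diff = m1 - m2)
  }
  base <- d_of(re, g1, 0)
  flagged <- base$se == 0
  s0 <- stats::quantile(base$se[!flagged], s0_quantile, names = FALSE)
  obs <- d_of(re, g1, s0)
  nf <- nrow(re)
  perm_d <- matrix(NA_real_, nf, n_perm)
  for (b in seq_len(n_perm)) {
    perm_d[, b] <- d_of(re, sample(g1), s0)$d
  }
  abs_obs <- abs(obs$d)
  abs_perm <- abs(perm_d)
  p <- (1 + rowSums(abs_perm >= abs_obs)) / (n_perm + 1)
  # SAM median false-call estimate at each family's own |d| cutoff
  q <- vapply(seq_len(nf), function(i) {
    called <- sum(abs_obs >= abs_obs[i])
    false_calls <- stats::median(colSums(abs_perm >= abs_obs[i]))
    min(1, false_calls / called)
  }, numeric(1))
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])   # monotone: weaker statistics never get lower q
  lev <- levels(groups)
  out <- data.frame(
    family_id = rownames(re),
    d_stat = obs$d,
    direction = ifelse(obs$diff >= 0, paste("higher in", lev[1]),
                       paste("higher in", lev[2])),
    p = p, q = q, flagged = flagged,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "frac_higher_group1") <- mean(obs$diff > 0)
  out
}
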