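#' Genome-wide miRNA-mRNA Spearman correlations with joint FDR
#'
#' For each requested miRNA, computes the Spearman correlation (midranks for
#' ties) between its relative expression and every gene on the mRNA matrix,
#' over the samples shared by the two matrices. P-values use the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`, and BH correction is
#' applied jointly over all tested pairs (one family). Both signs are kept:
#' a negative pair is consistent with target repression, a positive pair
#' with indirect or activating regulation.
#'
#' @param mirna_expr numeric miRNA x sample matrix (NAs = undetected are
#'   dropped pairwise per miRNA).
#' @param mrna_expr numeric gene x sample matrix (complete).
#' @param mirna_ids miRNAs to test (default: all rows of `mirna_expr`).
#' @param fdr q-value cutoff for the returned pairs (default 0.1).
#' @param return_all return every tested pair instead of only those with
#'   `q < fdr`.
#' @return data.frame of pairs: `mirna_id`, `gene_id`, `rho`, `p`, `q`,
#'   `sign` ("pos"/"neg"). Constant vectors are skipped with a message.
#' @export
mirna_mrna_correlations <- function(mirna_expr, mrna_expr,
                                    mirna_ids = rownames(mirna_expr),
                                    fdr = 0.1, return_all = FALSE) {
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 5L) stop("need >= 5 shared samples")
  mirna_ids <- intersect(mirna_ids, rownames(mirna_expr))
  out <- vector("list", length(mirna_ids))
  skipped <- 0L
  for (k in seq_along(mirna_ids)) {
    id <- mirna_ids[k]
    m <- mirna_expr[id, shared]
    ok <- !is.na(m)
    n <- sum(ok)
    if (n < 5L || stats::sd(m[ok]) == 0) { skipped <- skipped + 1L; next }
    rho <- .spearman_vec_matrix(m[ok], mrna_expr[, shared[ok], drop = FALSE])
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1] <- 0
    out[[k]] <- data.frame(mirna_id = id, gene_id = rownames(mrna_expr),
                           rho = rho, p = p, stringsAsFactors = FALSE)
  }
  if (skipped > 0) message(skipped, " miRNA(s) skipped (constant or < 5 detected)")
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) stop("no testable miRNA")
  pairs <- pairs[!is.na(pairs$rho), ]
  pairs$q <- bh_fdr(pairs$p)
  pairs$sign <- ifelse(pairs$rho >= 0, "pos", "neg")
  rownames(pairs) <- NULL
  if (return_all) pairs else pairs[pairs$q < fdr, ]
}

# Spearman rho of one vector against every row of a matrix: midrank both,
# then Pearson via centred cross-products. Constant rows return NA.
.spearman_vec_matrix <- function(x, m) {
  rx <- rank(x)
  rm_ <- t(apply(m, 1L, rank))
  zx <- rx - mean(rx)
  zx <- zx / sqrt(sum(zx^2))
  mc <- rm_ - rowMeans(rm_)
  denom <- sqrt(rowSums(mc^2))
  rho <- as.numeric(mc %*% zx) / denom
  rho[denom == 0] <- NA_real_
  names(rho) <- rownames(m)
  rho
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least the realised overlap between `set_a`
#' and `reference` when `|set_a|` elements are drawn without replacement
#' from `universe` containing `|reference|` marked elements.
#'
#' @param set_a,reference character vectors, both subsets of `universe`
#'   (violations are an error).
#' @param universe character vector of all testable elements.
#' @return one-row data.frame: `overlap_k`, `set_size`, `reference_size`,
#'   `universe_size`, `p`. An empty `set_a` gives `p = 1`.
#' @examples
#' hypergeometric_test(letters[1:3], letters[1:5], letters[1:10])  # p = 1/12
#' @export
hypergeometric_test <- function(set_a, reference, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); reference <- unique(reference)
  if (!all(set_a %in% universe)) stop("set_a is not a subset of universe")
  if (!all(reference %in% universe)) stop("reference is not a subset of universe")
  k <- length(intersect(set_a, reference))
  ns <- length(set_a); nr <- length(reference); nu <- length(universe)
  p <- if (ns == 0L) 1 else
    stats::phyper(k - 1, nr, nu - nr, ns, lower.tail = FALSE)
  data.frame(overlap_k = k, set_size = ns, reference_size = nr,
             universe_size = nu, p = p)
}

#' Are miRNA-correlated gene sets enriched for group-differential genes?
#'
#' For each miRNA's correlated gene set, tests (hypergeometric, upper tail)
#' its overlap with the reference list of genes differentially expressed
#' between the two groups (rank test at `q < de_q` on the mRNA matrix), and
#' summarises whether the set's mean expression is increased or decreased in
#' the group of interest. BH correction across miRNAs.
#'
#' @param pairs correlation pairs from [mirna_mrna_correlations()].
#' @param mrna_expr gene x sample matrix used for the DE reference.
#' @param groups binary factor over `colnames(mrna_expr)` (first level =
#'   group of interest).
#' @param universe gene universe (default: all rows of `mrna_expr`).
#' @param de_q q-value threshold defining the DE reference list.
#' @return data.frame per miRNA: enrichment fields as in
#'   [hypergeometric_test()] plus `q` and `direction` ("increased" /
#'   "decreased" in the group of interest); miRNAs with an empty correlated
#'   set get `NA` rows.
#' @export
de_concordance_gsea <- function(pairs, mrna_expr, groups,
                                universe = rownames(mrna_expr), de_q = 0.1) {
  de <- rank_test(mrna_expr, groups)
  de_ref <- intersect(de$feature_id[!is.na(de$q) & de$q < de_q], universe)
  groups <- factor(groups)
  g1 <- groups == levels(groups)[1]
  mirnas <- unique(pairs$mirna_id)
  rows <- lapply(mirnas, function(m) {
    set <- intersect(unique(pairs$gene_id[pairs$mirna_id == m]), universe)
    if (length(set) == 0L) {
      return(data.frame(mirna_id = m, overlap_k = NA, set_size = 0L,
                        reference_size = length(de_ref),
                        universe_size = length(universe), p = NA,
                        direction = NA, stringsAsFactors = FALSE))
    }
    ht <- hypergeometric_test(set, de_ref, universe)
    d <- mean(rowMeans(mrna_expr[set, g1, drop = FALSE]) -
                rowMeans(mrna_expr[set, !g1, drop = FALSE]))
    cbind(data.frame(mirna_id = m, stringsAsFactors = FALSE), ht,
          data.frame(direction = if (d >= 0) "increased" else "decreased",
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Concordance of correlated genes with predicted miRNA targets
#'
#' For each miRNA, tests whether its database-predicted targets are enriched
#' for its correlation-defined targets: universe = all testable genes,
#' reference = the miRNA-correlated genes, set = the predicted targets
#' (intersected with the universe first). miRNAs passing `q < fdr` (BH
#' across miRNAs) are flagged concordant; downstream analyses should use
#' only the intersection (correlated AND predicted) genes, returned per
#' miRNA. miRNAs absent from the database yield `NA` rows.
#'
#' @param pairs correlation pairs from [mirna_mrna_correlations()].
#' @param db target database, named list miRNA -> gene symbols.
#' @param universe gene universe (all genes on the mRNA matrix).
#' @param fdr concordance q-value cutoff (default 0.1).
#' @return list with `summary` (data.frame: `mirna_id`, `n_correlated`,
#'   `n_predicted`, `overlap_k`, `p`, `q`, `concordant`) and
#'   `intersection_genes` (named list of the common genes per miRNA).
#' @export
concordant_targets <- function(pairs, db, universe, fdr = 0.1) {
  mirnas <- unique(pairs$mirna_id)
  genes <- stats::setNames(vector("list", length(mirnas)), mirnas)
  rows <- lapply(mirnas, function(m) {
    correlated <- intersect(unique(pairs$gene_id[pairs$mirna_id == m]),
                            universe)
    if (!m %in% names(db)) {
      return(data.frame(mirna_id = m, n_correlated = length(correlated),
                        n_predicted = NA_integer_, overlap_k = NA_integer_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    predicted <- intersect(db[[m]], universe)
    inter <- intersect(correlated, predicted)
    genes[[m]] <<- inter
    ht <- hypergeometric_test(predicted, correlated, universe)
    data.frame(mirna_id = m, n_correlated = length(correlated),
               n_predicted = length(predicted), overlap_k = ht$overlap_k,
               p = ht$p, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$q <- NA_real_
  ok <- !is.na(summary$p)
  summary$q[ok] <- bh_fdr(summary$p[ok])
  summary$concordant <- !is.na(summary$q) & summary$q < fdr
  rownames(summary) <- NULL
  list(summary = summary, intersection_genes = genes)
}

#' Functional enrichment of a gene list over gene-set collections
#'
#' Hypergeometric upper-tail test of the gene list against each term in the
#' collections (GO/KEGG-style GMT sets), conditioning on the testable
#' universe. Terms with no universe overlap are skipped; a term larger than
#' the universe violates the sampling model and is an error. Results are
#' ranked by ascending p with BH q across all tested terms.
#'
#' @param genes character vector of query genes (intersected with
#'   `universe`).
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @param universe gene universe.
#' @param top_n number of top terms to return (default 10).
#' @return data.frame: `term_id`, `overlap_k`, `set_size`,
#'   `reference_size`, `universe_size`, `p`, `q`.
#' @export
functional_enrichment <- function(genes, collections, universe, top_n = 10) {
  stopifnot(length(collections) > 0)
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  rows <- lapply(names(collections), function(term) {
    tg <- unique(collections[[term]])
    if (length(tg) > length(universe)) {
      stop("term ", term, " is larger than the universe")
    }
    tg <- intersect(tg, universe)
    if (length(tg) == 0L) return(NULL)
    cbind(data.frame(term_id = term, stringsAsFactors = FALSE),
          hypergeometric_test(genes, tg, universe))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the universe")
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
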