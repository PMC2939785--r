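#' Per-feature two-group rank test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test per feature between two
#' groups, with Benjamini-Hochberg q-values attached. Direction is called
#' from the difference of group medians (falling back to means on median
#' ties) and refers to the first factor level of `groups` (the "group of
#' interest", e.g. IBC). Being rank-based, the p-value is invariant under
#' any strictly monotone transform of a feature. Features that are constant
#' across all observed samples get `p = 1` and are flagged.
#'
#' @param expr numeric feature x sample matrix (NAs allowed; a feature needs
#'   at least 2 observed values per group, otherwise it is flagged with
#'   `p = NA`).
#' @param groups factor (or coercible) of length `ncol(expr)` with exactly
#'   two levels; the first level is the group of interest.
#' @return data.frame: `feature_id`, `direction` ("up"/"down" in the group
#'   of interest), `stat` (Mann-Whitney U), `p`, `q` (BH over non-flagged
#'   features), `flagged`.
#' @export
rank_test <- function(expr, groups) {
  stopifnot(is.matrix(expr), ncol(expr) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  g1 <- groups == levels(groups)[1]
  res <- t(vapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, g1]; y <- expr[i, !g1]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(c(NA, NA, NA, 1))
    if (stats::sd(c(x, y)) == 0) {
      return(c(length(x) * length(y) / 2, 1, 0, 1))  # constant: p = 1
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    dm <- stats::median(x) - stats::median(y)
    if (dm == 0) dm <- mean(x) - mean(y)
    c(unname(ht$statistic), ht$p.value, dm, 0)
  }, numeric(4)))
  out <- data.frame(
    feature_id = rownames(expr),
    direction = ifelse(res[, 3] >= 0, "up", "down"),
    stat = res[, 1],
    p = res[, 2],
    q = NA_real_,
    flagged = res[, 4] == 1,
    stringsAsFactors = FALSE)
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min_{j : p_(j) >= p_(i)} m * p_(j) / j`, the step-up false
#' discovery rate adjustment; input order is preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted association of one miRNA with a binary group
#'
#' Logistic regression of group membership on an miRNA's expression plus
#' clinicopathological covariates (typically N status, M status, tumour
#' stage and HER2 amplification), isolating miRNAs associated with the group
#' itself rather than with confounded clinical factors. With ~70 samples and
#' several binary covariates quasi-separation is common, so a Firth-type
#' penalized fit (Jeffreys-prior score adjustment) is used as a flagged
#' fallback whenever the maximum-likelihood fit fails to converge or shows
#' separation.
#'
#' @param mirna_expr numeric vector, one miRNA's relative expression.
#' @param group binary vector/factor; the second factor level is modelled as
#'   the event.
#' @param covariates data.frame of covariates (rows aligned with samples);
#'   constant columns are an error.
#' @return list: `coef` (log-odds per expression unit), `se`, `p` (Wald),
#'   `method` ("glm" or "firth"), `n`.
#' @export
independent_association <- function(mirna_expr, group, covariates) {
  stopifnot(length(mirna_expr) == length(group),
            nrow(covariates) == length(group))
  if (stats::sd(mirna_expr, na.rm = TRUE) == 0) {
    stop("degenerate predictor: miRNA expression is constant")
  }
  for (nm in names(covariates)) {
    if (length(unique(covariates[[nm]])) < 2L) {
      stop("constant covariate: ", nm)
    }
  }
  y <- as.integer(factor(group)) - 1L
  dat <- data.frame(.y = y, .mir = mirna_expr, covariates)
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 10 * (ncol(covariates) + 2L)) {
    warning("fewer than 10 samples per model parameter")
  }
  sep_warning <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          sep_warning <<- TRUE
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) NULL)
  separated <- is.null(fit) || !fit$converged || sep_warning ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(is.na(stats::coef(fit))) ||
    any(stats::fitted(fit) < 1e-7 | stats::fitted(fit) > 1 - 1e-7)
  if (!separated) {
    sm <- summary(fit)$coefficients
    return(list(coef = sm[".mir", 1], se = sm[".mir", 2],
                p = sm[".mir", 4], method = "glm", n = nrow(dat)))
  }
  X <- stats::model.matrix(.y ~ ., data = dat)
  ff <- firth_logistic(X, dat$.y)
  list(coef = ff$coef[".mir"], se = ff$se[".mir"], p = ff$p[".mir"],
       method = "firth", n = nrow(dat))
}

#' Firth-penalized logistic regression
#'
#' Maximum penalized likelihood logistic regression with Jeffreys-prior
#' penalty, fitted by iteratively reweighted least squares with the
#' hat-value score adjustment `U*(b) = X'(y - p + h (1/2 - p))`. The penalty
#' keeps estimates finite under complete or quasi-complete separation.
#' Standard errors come from the inverse Fisher information at convergence.
#'
#' @param X model matrix (including intercept column).
#' @param y binary 0/1 response.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   score-step norm.
#' @return list with `coef`, `se`, `p` (Wald), `iter`, `converged`.
#' @export
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  b <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    pr <- stats::plogis(eta)
    W <- pr * (1 - pr)
    XW <- X * W
    info <- crossprod(X, XW)
    # hat values of the weighted design
    inv <- solve(info)
    h <- rowSums((X %*% inv) * XW)
    U <- crossprod(X, y - pr + h * (0.5 - pr))
    step <- drop(inv %*% U)
    b <- b + step
    if (sqrt(sum(step^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("Firth logistic regression did not converge")
  se <- sqrt(diag(solve(info)))
  z <- b / se
  names(b) <- names(se) <- colnames(X)
  list(coef = b, se = se, p = 2 * stats::pnorm(-abs(z)),
       iter = it, converged = converged)
}

#' Differential expression of the miRNA-processing genes
#'
#' Restricts the two-group rank test to the canonical miRNA biogenesis
#' machinery (TRBP2, DICER1, AGO1, AGO2, DROSHA) and applies BH correction
#' within that 5-gene family. Genes absent from the matrix are reported,
#' not fatal.
#'
#' @param mrna_expr numeric gene x sample matrix.
#' @param groups binary factor over samples (first level = group of
#'   interest).
#' @param genes processing-gene symbols to test.
#' @return data.frame as in [rank_test()], with a `"missing_genes"`
#'   attribute listing symbols not found.
#' @export
processing_gene_de <- function(mrna_expr, groups,
                               genes = c("TRBP2", "DICER1", "AGO1",
                                         "AGO2", "DROSHA")) {
  present <- intersect(genes, rownames(mrna_expr))
  missing <- setdiff(genes, present)
  if (length(missing)) {
    message("processing genes absent from the matrix: ",
            paste(missing, collapse = ", "))
  }
  if (length(present) == 0L) {
    out <- rank_test(mrna_expr[0, , drop = FALSE], groups)
  } else {
    out <- rank_test(mrna_expr[present, , drop = FALSE], groups)
  }
  attr(out, "missing_genes") <- missing
  out
}
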