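#' Signed target-gene expression score
#'
#' Per-sample proxy for an miRNA's activity built from its concordant target
#' genes: the mean expression of the positively correlated targets minus the
#' mean expression of the negatively correlated targets. Genes missing from
#' the matrix are dropped with a message; an empty side contributes 0 with a
#' warning; both sides empty is an error. The score is linear in the
#' expression matrix.
#'
#' @param mrna_expr numeric gene x sample matrix.
#' @param pos_set,neg_set character vectors of positively / negatively
#'   correlated target genes.
#' @return named numeric vector, one raw score per sample.
#' @export
target_score <- function(mrna_expr, pos_set, neg_set = character()) {
  use <- function(set, label) {
    hit <- intersect(unique(set), rownames(mrna_expr))
    miss <- setdiff(unique(set), hit)
    if (length(miss)) message(length(miss), " ", label,
                              " gene(s) absent from the matrix")
    hit
  }
  pos <- use(pos_set, "positive-set")
  neg <- use(neg_set, "negative-set")
  if (length(pos) == 0L && length(neg) == 0L) {
    stop("both gene sets are empty after intersection with the matrix")
  }
  side <- function(set) {
    if (length(set) == 0L) {
      warning("empty gene set contributes 0 to the score")
      return(rep(0, ncol(mrna_expr)))
    }
    colMeans(mrna_expr[set, , drop = FALSE])
  }
  stats::setNames(side(pos) - side(neg), colnames(mrna_expr))
}

#' Standardise a score to median 0 and s.d. 1
#'
#' `(x - median(x)) / sd(x)`: centring on the median with unit standard
#' deviation, making scores comparable across datasets with different
#' expression scales. Invariant to affine transforms of the input.
#'
#' @param scores numeric vector with at least two distinct values.
#' @return standardised numeric vector (names preserved).
#' @export
standardize_score <- function(scores) {
  if (length(unique(scores)) < 2L) stop("scores have zero variance")
  (scores - stats::median(scores)) / stats::sd(scores)
}

#' Spearman concordance between a target score and miRNA expression
#'
#' The target-gene score is a valid miRNA proxy only if it tracks the
#' measured miRNA; this returns their Spearman correlation over shared
#' samples.
#'
#' @param score named numeric vector (e.g. from [target_score()]).
#' @param mirna_expr named numeric vector of the miRNA's relative expression.
#' @return Spearman rho.
#' @export
score_mirna_concordance <- function(score, mirna_expr) {
  shared <- intersect(names(score), names(mirna_expr))
  shared <- shared[!is.na(mirna_expr[shared]) & !is.na(score[shared])]
  if (length(shared) < 5L) stop("fewer than 5 shared samples")
  stats::cor(score[shared], mirna_expr[shared], method = "spearman")
}

#' Cox proportional-hazards evaluation of a target score
#'
#' Fits a Cox model of survival on the (standardised) target score, per
#' dataset and pooled across datasets, and summarises Kaplan-Meier strata
#' defined by dichotomising the score at 0 (the standardised median).
#' Pooling is a dataset-stratified partial likelihood by default (each
#' dataset keeps its own baseline hazard); `pooling = "fixed"` fits a single
#' baseline instead. Supplying `covariates` gives the multivariate setting.
#'
#' @param score named numeric vector of per-sample scores.
#' @param survival data.frame with `sample_id`, `dataset_id`, `time`,
#'   `event` (see [read_survival_table()]).
#' @param covariates optional data.frame of covariates with a `sample_id`
#'   column.
#' @param pooling `"strata"` (default) or `"fixed"` for the pooled fit.
#' @return object of class `cox_result`: `table` (data.frame with one row
#'   per dataset plus `"Total"`: `dataset_id`, `hazard_ratio`, `log_hr`,
#'   `se`, `p`, `n`, `events`, `setting`, `flagged`), `km` (pooled
#'   [survival::survfit] over score > 0 strata), `km_strata` (counts).
#' @export
cox_evaluate <- function(score, survival, covariates = NULL,
                         pooling = c("strata", "fixed")) {
  pooling <- match.arg(pooling)
  dat <- survival[survival$sample_id %in% names(score), , drop = FALSE]
  dat$score <- as.numeric(score[dat$sample_id])
  if (!is.null(covariates)) {
    dat <- merge(dat, covariates, by = "sample_id", sort = FALSE)
  }
  if (sum(dat$event) == 0L) stop("no events in the survival table")
  if (sum(dat$event) < 10L) stop("fewer than 10 events")
  setting <- if (is.null(covariates)) "univariate" else "multivariate"
  covs <- if (is.null(covariates)) character() else
    setdiff(names(covariates), "sample_id")
  fit_one <- function(d, strat = FALSE) {
    rhs <- c("score", covs, if (strat) "strata(dataset_id)")
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(rhs, collapse = " + ")))
    flagged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(f, data = d),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    data.frame(hazard_ratio = exp(sm["score", "coef"]),
               log_hr = sm["score", "coef"],
               se = sm["score", "se(coef)"],
               p = sm["score", "Pr(>|z|)"],
               n = nrow(d), events = sum(d$event),
               setting = setting,
               flagged = flagged || abs(sm["score", "coef"]) > 10,
               stringsAsFactors = FALSE)
  }
  ids <- unique(dat$dataset_id)
  per <- lapply(ids, function(id) {
    cbind(data.frame(dataset_id = id, stringsAsFactors = FALSE),
          fit_one(dat[dat$dataset_id == id, ]))
  })
  pooled <- cbind(data.frame(dataset_id = "Total", stringsAsFactors = FALSE),
                  fit_one(dat, strat = (pooling == "strata" &&
                                          length(ids) > 1L)))
  tab <- rbind(do.call(rbind, per), pooled)
  rownames(tab) <- NULL
  dat$stratum <- factor(ifelse(dat$score > 0, "high", "low"),
                        levels = c("low", "high"))
  km <- survival::survfit(survival::Surv(time, event) ~ stratum, data = dat)
  structure(list(table = tab, km = km,
                 km_strata = table(dat$stratum, dat$event,
                                   dnn = c("stratum", "event"))),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards evaluation of a target-gene score\n")
  tab <- x$table
  tab$hazard_ratio <- round(tab$hazard_ratio, digits)
  tab$p <- signif(tab$p, digits)
  print(tab[, c("dataset_id", "hazard_ratio", "p", "n", "events",
                "setting")], row.names = FALSE)
  cat("Kaplan-Meier strata (score dichotomised at 0):\n")
  print(x$km_strata)
  invisible(x)
}
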