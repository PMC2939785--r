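#' Filter informative miRNA assays by detection rate
#'
#' Keeps assays detected below a Ct cutoff in at least a given fraction of
#' samples. qPCR arrays report a threshold cycle (Ct) per assay per sample;
#' low Ct means abundant template, and assays that rarely amplify below the
#' cutoff carry mostly technical noise. An undetected reaction is encoded as
#' `NA`, never as an imputed ceiling cycle.
#'
#' @param ct numeric matrix of Ct values, miRNAs in rows, samples in columns,
#'   `NA` for undetected reactions. Row and column names are required and must
#'   be unique.
#' @param ct_cutoff detection cutoff in PCR cycles; a reaction counts as
#'   detected when its Ct is strictly below this value. Default 35.
#' @param min_fraction minimum fraction of samples (inclusive) in which an
#'   assay must be detected to be retained. Default 0.25.
#' @return the input matrix restricted to informative rows, order preserved.
#'   Warns (and returns a 0-row matrix) when nothing survives.
#' @examples
#' ct <- matrix(c(30, 30, 36, 36), 2, 2,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' filter_informative(ct)
#' @export
filter_informative <- function(ct, ct_cutoff = 35, min_fraction = 0.25) {
  .check_ct_matrix(ct)
  stopifnot(is.numeric(ct_cutoff), length(ct_cutoff) == 1L,
            is.numeric(min_fraction), length(min_fraction) == 1L,
            min_fraction > 0, min_fraction <= 1)
  detected <- !is.na(ct) & ct < ct_cutoff
  keep <- rowMeans(detected) >= min_fraction
  if (!any(keep)) {
    warning("no miRNA passes the detection filter")
  }
  ct[keep, , drop = FALSE]
}

#' Globally centre a Ct matrix into relative expression
#'
#' Per-sample global normalisation for qPCR arrays: each sample's centring
#' statistic (mean or median Ct over its detected assays) is subtracted from
#' that sample's Ct values, and the sign is flipped so that larger values mean
#' more abundant (one unit is about a two-fold change). This is the deltaCt
#' idea with a global normalisation factor instead of an endogenous control.
#'
#' @param ct numeric Ct matrix (miRNA x sample) with `NA` for undetected;
#'   typically the output of [filter_informative()].
#' @param statistic per-sample centring statistic, `"mean"` (default) or
#'   `"median"`, computed over detected assays only.
#' @return numeric matrix of relative expression, same shape and dimnames;
#'   undetected entries stay `NA`. Carries a `"scale_note"` attribute.
#' @examples
#' ct <- matrix(c(28, 32, 29, 31), 2, 2,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' normalize_global_centre(ct)
#' @export
normalize_global_centre <- function(ct, statistic = c("mean", "median")) {
  .check_ct_matrix(ct)
  statistic <- match.arg(statistic)
  n_det <- colSums(!is.na(ct))
  if (any(n_det == 0L)) {
    stop("sample(s) with no detected values: ",
         paste(colnames(ct)[n_det == 0L], collapse = ", "))
  }
  fun <- if (statistic == "mean") mean else stats::median
  centre <- apply(ct, 2L, fun, na.rm = TRUE)
  out <- -sweep(ct, 2L, centre, "-")
  attr(out, "scale_note") <- paste0("negative ", statistic, "-centred Ct")
  out
}

#' Per-sample concordance between replicate expression matrices
#'
#' Pearson correlation per matched sample between two expression matrices
#' (e.g. technical qPCR duplicates), computed over pairwise-complete features.
#'
#' @param a,b numeric feature x sample matrices with identical dimnames
#'   (any common subset of features/samples is used; ids must overlap).
#' @return named numeric vector of per-sample Pearson r.
#' @export
replicate_concordance <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  feats <- intersect(rownames(a), rownames(b))
  samps <- intersect(colnames(a), colnames(b))
  if (length(feats) < 3L || length(samps) < 1L) {
    stop("need at least 3 shared features and 1 shared sample")
  }
  a <- a[feats, samps, drop = FALSE]
  b <- b[feats, samps, drop = FALSE]
  r <- vapply(samps, function(s) {
    ok <- !is.na(a[, s]) & !is.na(b[, s])
    if (sum(ok) < 3L) stop("sample ", s, ": fewer than 3 complete pairs")
    stats::cor(a[ok, s], b[ok, s])
  }, numeric(1))
  r
}

.check_ct_matrix <- function(ct) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop("ct must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("ct must have row (miRNA) and column (sample) names")
  }
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct))) {
    stop("duplicate miRNA or sample ids")
  }
  if (any(ct <= 0 | ct > 45, na.rm = TRUE)) {
    stop("detected Ct values must lie in (0, 45]")
  }
  invisible(TRUE)
}
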