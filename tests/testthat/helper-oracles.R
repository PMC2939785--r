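# Independent oracles used to cross-check the implementation routes.

# Brute-force Benjamini-Hochberg step-up: q_i = min over j with p_j >= p_i
# of m * p_j / rank(p_j). O(m^2), no call to p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# Exact upper-tail hypergeometric probability by exhaustive enumeration of
# all draws of size `ns` from a universe of size `nu` with `nr` marked
# elements. Feasible for nu <= 15.
enum_hypergeom <- function(nu, nr, ns, k) {
  if (ns == 0) return(1)
  draws <- utils::combn(nu, ns)
  overlaps <- colSums(draws <= nr)  # marked elements are 1..nr
  mean(overlaps >= k)
}

# Silhouette widths from the definition: a(i) = mean distance to own
# cluster, b(i) = min over other clusters of mean distance, s(i) =
# (b - a) / max(a, b); singletons get 0.
brute_silhouette <- function(labels, d) {
  dm <- as.matrix(d)
  vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dm[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Brute-force signed RE score from first principles: explicit midranks,
# explicit mean difference, explicit normalisation.
brute_re_signed <- function(x, target_idx) {
  G <- length(x)
  r <- rank(x)
  (mean(r[-target_idx]) - mean(r[target_idx])) / ((G + 1) / 2)
}

# Small cohort configuration for fast unit tests.
small_config <- function(seed = 1, ...) {
  args <- list(n_mirna = 60, n_gene = 300, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

ibc_factor <- function(samples, ids = samples$sample_id) {
  factor(samples$subtype[match(ids, samples$sample_id)],
         levels = c("IBC", "non-IBC"))
}
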