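#' Configuration for a synthetic miRNA/mRNA case-control cohort
#'
#' Defaults emulate a two-group inflammatory breast cancer (IBC) versus
#' non-IBC study: 20 + 50 samples assayed on a 384-assay qPCR miRNA array,
#' with genome-wide mRNA profiles for a 44-sample subset, a small set of
#' planted differential miRNAs (about 13 of 384), signed miRNA-target
#' correlations, shifted miRNA-processing genes and proportional-hazards
#' survival structure tied to a planted target score.
#'
#' @param n_ibc,n_nonibc group sizes (samples).
#' @param n_mirna number of miRNA assays.
#' @param n_gene number of mRNA genes (includes the five miRNA-processing
#'   genes TRBP2, DICER1, AGO1, AGO2, DROSHA).
#' @param n_mrna_samples number of samples with mRNA profiles (all IBC first,
#'   then non-IBC); must not exceed `n_ibc + n_nonibc`.
#' @param de_mirna_frac fraction of miRNAs with a planted group shift.
#' @param de_shift_ct planted |shift| in Ct units; an miRNA planted "up in
#'   IBC" has its IBC Ct lowered by this amount (lower Ct = more abundant).
#' @param target_rho planted Spearman correlation magnitude, in (0, 1),
#'   between a planted miRNA's relative expression and each of its true
#'   target genes.
#' @param frac_pos_targets fraction of planted target pairs with positive
#'   sign.
#' @param noise_sd_ct per-reaction Ct noise s.d.
#' @param undetected_frac fraction of Ct entries masked as undetected (`NA`).
#' @param hazard_log_hr log hazard ratio per unit of the planted
#'   (standardised) target score in the survival generator.
#' @param seed integer RNG seed; the whole cohort is deterministic given the
#'   config.
#' @return a validated `cohort_config` list.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_ibc = 20, n_nonibc = 50, n_mirna = 384,
                          n_gene = 2000, n_mrna_samples = 44,
                          de_mirna_frac = 13 / 384, de_shift_ct = 2,
                          target_rho = 0.7, frac_pos_targets = 0.6,
                          noise_sd_ct = 1, undetected_frac = 0.05,
                          hazard_log_hr = 0.5, seed = 1L) {
  cfg <- list(n_ibc = as.integer(n_ibc), n_nonibc = as.integer(n_nonibc),
              n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              n_mrna_samples = as.integer(n_mrna_samples),
              de_mirna_frac = de_mirna_frac, de_shift_ct = de_shift_ct,
              target_rho = target_rho, frac_pos_targets = frac_pos_targets,
              noise_sd_ct = noise_sd_ct, undetected_frac = undetected_frac,
              hazard_log_hr = hazard_log_hr, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_ibc >= 2, n_nonibc >= 2, n_mirna >= 2, n_gene >= 2,
              n_mrna_samples >= 2,
              de_mirna_frac >= 0, de_mirna_frac <= 1,
              frac_pos_targets >= 0, frac_pos_targets <= 1,
              undetected_frac >= 0, undetected_frac <= 1,
              target_rho > 0, target_rho < 1,
              noise_sd_ct >= 0, de_shift_ct >= 0)
  })
  if (cfg$n_mrna_samples > cfg$n_ibc + cfg$n_nonibc) {
    stop("n_mrna_samples exceeds the cohort size")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# number of true target genes planted per differential miRNA
.n_targets_per_mirna <- function(n_gene, n_de) {
  max(2L, min(30L, (n_gene - 5L) %/% max(1L, 4L * n_de)))
}

#' Generate a synthetic cohort with a planted-effect truth table
#'
#' Draws a full multi-layer cohort: a raw miRNA Ct matrix with an undetected
#' sentinel, a log-scale mRNA matrix for an mRNA subset of samples, sample
#' annotations, a target prediction database (true planted targets plus
#' decoys), gene-set collections, a survival table with exponential event
#' times driven by a planted target score, and the truth table needed to
#' measure recovery downstream.
#'
#' Planted structure, in order:
#' \itemize{
#'   \item `round(de_mirna_frac * n_mirna)` miRNAs receive a signed group
#'     shift of `de_shift_ct` Ct cycles in IBC (half up, half down).
#'   \item each planted miRNA gets a disjoint set of true target genes whose
#'     mRNA values are linear (hence monotone) in the miRNA's realised
#'     relative expression, with Pearson link `2*sin(pi*target_rho/6)` so the
#'     planted Spearman magnitude is about `target_rho`; the planted sign is
#'     a sign flip of the link. Gene noise is split into a biological
#'     component shared within each (miRNA, sign) target set and independent
#'     measurement noise, so a multi-gene score tracks the miRNA more closely
#'     than any single target without becoming deterministic.
#'   \item processing genes: AGO2 +1.5 and DICER1 -1.5 log-units in IBC.
#'   \item survival: event times exponential with log-hazard
#'     `hazard_log_hr * planted_score`, where the planted score is the
#'     standardised target-gene expression score of the first planted miRNA;
#'     uniform censoring on 12-120 months; samples split over two dataset
#'     ids.
#' }
#'
#' @param config a [cohort_config()].
#' @return an object of class `mirna_cohort`: list with elements `ct`
#'   (miRNA x sample Ct matrix, `NA` = undetected), `mrna` (gene x sample
#'   log-expression), `samples` (annotation data.frame), `target_db` (named
#'   list), `gene_sets` (named list), `survival` (data.frame) and `truth`
#'   (list: `de_mirnas`, `planted_pairs`, `predicted_targets`,
#'   `planted_hazard_scores`).
#' @examples
#' coh <- generate_cohort(cohort_config(n_mirna = 40, n_gene = 200, seed = 7))
#' dim(coh$ct)
#' head(coh$truth$de_mirnas)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_ibc <- config$n_ibc; n_non <- config$n_nonibc
  n_all <- n_ibc + n_non
  ibc_ids <- sprintf("IBC%03d", seq_len(n_ibc))
  non_ids <- sprintf("NBC%03d", seq_len(n_non))
  sample_ids <- c(ibc_ids, non_ids)
  is_ibc <- c(rep(TRUE, n_ibc), rep(FALSE, n_non))
  mirna_ids <- sprintf("miR-%03d", seq_len(config$n_mirna))

  ## planted differential miRNAs: half up in IBC (+1), half down (-1)
  n_de <- as.integer(round(config$de_mirna_frac * config$n_mirna))
  de_idx <- if (n_de > 0) sort(sample.int(config$n_mirna, n_de)) else integer()
  de_sign <- if (n_de > 0) rep_len(c(1L, -1L), n_de) else integer()

  ## latent Ct: baseline + group shift + noise (lower Ct = more abundant)
  baseline <- stats::runif(config$n_mirna, 24, 33)
  ct <- matrix(stats::rnorm(config$n_mirna * n_all, sd = config$noise_sd_ct),
               config$n_mirna, n_all,
               dimnames = list(mirna_ids, sample_ids))
  ct <- ct + baseline
  if (n_de > 0) {
    shift <- -de_sign * config$de_shift_ct
    ct[de_idx, is_ibc] <- ct[de_idx, is_ibc] + shift
  }
  ct <- pmin(pmax(ct, 1), 45)
  ct_latent <- ct
  drop_mask <- matrix(stats::runif(length(ct)) < config$undetected_frac,
                      nrow(ct), ncol(ct))
  ct[drop_mask] <- NA_real_

  ## mRNA subset: all IBC first, then non-IBC
  mrna_samples <- sample_ids[seq_len(config$n_mrna_samples)]
  mrna_is_ibc <- is_ibc[seq_len(config$n_mrna_samples)]
  n_ms <- length(mrna_samples)

  proc_genes <- c("TRBP2", "DICER1", "AGO1", "AGO2", "DROSHA")
  if (config$n_gene < 5L + 2L) stop("n_gene too small for processing genes")
  gene_ids <- c(sprintf("GENE%05d", seq_len(config$n_gene - 5L)), proc_genes)
  mu <- stats::runif(config$n_gene, 5, 12)
  mrna <- matrix(stats::rnorm(config$n_gene * n_ms), config$n_gene, n_ms,
                 dimnames = list(gene_ids, mrna_samples))
  mrna <- mrna + mu

  ## plant target genes as monotone functions of miRNA relative expression
  n_per <- .n_targets_per_mirna(config$n_gene, n_de)
  if (config$n_gene - 5L < n_de * n_per) {
    stop("n_gene too small for the planted target sets")
  }
  a <- 2 * sin(pi * config$target_rho / 6)   # Pearson link for Spearman rho
  c_sh <- sqrt(min(0.36, max(0, 0.99 - a^2)))  # shared biological noise
  sig_e <- sqrt(max(1e-6, 1 - a^2 - c_sh^2))
  assignable <- seq_len(config$n_gene - 5L)
  target_idx <- if (n_de > 0) {
    matrix(sample(assignable, n_de * n_per), nrow = n_de)
  } else matrix(integer(), 0, 0)
  pairs <- NULL
  if (n_de > 0) {
    pair_list <- vector("list", n_de)
    n_pos <- round(config$frac_pos_targets * n_per)
    for (k in seq_len(n_de)) {
      i <- de_idx[k]
      x <- -(ct_latent[i, mrna_samples] - baseline[i])
      z <- as.numeric(scale(x))
      w <- list(pos = stats::rnorm(n_ms), neg = stats::rnorm(n_ms))
      pair_sign <- c(rep(1L, n_pos), rep(-1L, n_per - n_pos))
      for (j in seq_len(n_per)) {
        g <- target_idx[k, j]
        side <- if (pair_sign[j] > 0) "pos" else "neg"
        mrna[g, ] <- mu[g] + a * pair_sign[j] * z + c_sh * w[[side]] +
          stats::rnorm(n_ms, sd = sig_e)
      }
      pair_list[[k]] <- data.frame(
        mirna_id = mirna_ids[i], gene_id = gene_ids[target_idx[k, ]],
        sign = ifelse(pair_sign > 0, "pos", "neg"),
        rho = config$target_rho, stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pair_list)
  }

  ## miRNA processing genes: AGO2 up, DICER1 down in IBC
  mrna["AGO2", mrna_is_ibc] <- mrna["AGO2", mrna_is_ibc] + 1.5
  mrna["DICER1", mrna_is_ibc] <- mrna["DICER1", mrna_is_ibc] - 1.5

  ## prediction database: true targets + equally many decoys per planted
  ## miRNA, plus decoy-only families
  target_db <- list()
  if (n_de > 0) {
    for (k in seq_len(n_de)) {
      true_g <- gene_ids[target_idx[k, ]]
      pool <- setdiff(assignable, as.vector(target_idx))
      decoys <- gene_ids[sample(pool, min(n_per, length(pool)))]
      target_db[[mirna_ids[de_idx[k]]]] <- c(true_g, decoys)
    }
  }
  n_dec_fam <- min(10L, config$n_mirna - n_de)
  if (n_dec_fam > 0) {
    dec_mirs <- setdiff(seq_len(config$n_mirna), de_idx)[seq_len(n_dec_fam)]
    for (i in dec_mirs) {
      target_db[[mirna_ids[i]]] <-
        gene_ids[sample(assignable, min(2L * n_per, length(assignable)))]
    }
  }
  attr(target_db, "source_label") <- "synthetic prediction database"

  ## gene sets: random terms plus the planted target sets
  gene_sets <- lapply(seq_len(40), function(t) {
    sample(gene_ids, sample(10:min(60, config$n_gene), 1))
  })
  names(gene_sets) <- sprintf("RANDSET_%02d", seq_len(40))
  if (n_de > 0) {
    planted_sets <- lapply(seq_len(n_de),
                           function(k) gene_ids[target_idx[k, ]])
    names(planted_sets) <- paste0("TARGETSET_", mirna_ids[de_idx])
    gene_sets <- c(gene_sets, planted_sets)
  }

  ## sample annotations with IBC-skewed clinicopathological distributions
  samples <- .draw_annotations(sample_ids, is_ibc)

  ## survival driven by the planted target score of the first planted miRNA
  if (n_de > 0) {
    p1 <- pairs[pairs$mirna_id == mirna_ids[de_idx[1]], ]
    raw <- target_score(mrna, p1$gene_id[p1$sign == "pos"],
                        p1$gene_id[p1$sign == "neg"])
    score <- standardize_score(raw)
  } else {
    score <- stats::setNames(rep(0, n_ms), mrna_samples)
  }
  t_event <- stats::rexp(n_ms, rate = 0.01 * exp(config$hazard_log_hr * score))
  cens <- stats::runif(n_ms, 12, 120)
  survival <- data.frame(
    sample_id = mrna_samples,
    dataset_id = rep(c("DS1", "DS2"), length.out = n_ms),
    endpoint = "DMFS",
    time = round(pmin(t_event, cens), 2),
    event = as.integer(t_event <= cens),
    stringsAsFactors = FALSE)

  truth <- list(
    de_mirnas = data.frame(mirna_id = mirna_ids[de_idx], sign = de_sign,
                           stringsAsFactors = FALSE),
    planted_pairs = pairs,
    predicted_targets = target_db,
    planted_hazard_scores = score)

  structure(list(ct = ct, mrna = mrna, samples = samples,
                 target_db = target_db, gene_sets = gene_sets,
                 survival = survival, truth = truth, config = config),
            class = "mirna_cohort")
}

.draw_annotations <- function(sample_ids, is_ibc) {
  n <- length(sample_ids)
  pick <- function(ibc_probs, non_probs, levels) {
    ifelse(is_ibc,
           sample(levels, n, replace = TRUE, prob = ibc_probs),
           sample(levels, n, replace = TRUE, prob = non_probs))
  }
  stage <- pick(c(0, 0, .5, .5), c(.42, .30, .22, .06),
                c("I", "II", "III", "IV"))
  data.frame(
    sample_id = sample_ids,
    subtype = ifelse(is_ibc, "IBC", "non-IBC"),
    t_status = pick(c(.2, .8), c(.6, .4), c("low", "high")),
    n_status = pick(c(.9, .1), c(.5, .5), c("pos", "neg")),
    m_status = ifelse(stage == "IV", "M+", "M0"),
    stage = stage,
    grade = pick(c(.02, .45, .53), c(.16, .46, .38),
                 c("well", "moderate", "poor")),
    er = pick(c(.8, .2), c(.7, .3), c("pos", "neg")),
    her2 = pick(c(.4, .6), c(.18, .82), c("pos", "neg")),
    age = pmin(pmax(round(stats::rnorm(n, 59, 12)), 30), 89),
    stringsAsFactors = FALSE)
}

#' @export
print.mirna_cohort <- function(x, ...) {
  cat("Synthetic miRNA/mRNA cohort\n")
  cat(sprintf("  miRNA Ct matrix : %d assays x %d samples (%.1f%% undetected)\n",
              nrow(x$ct), ncol(x$ct), 100 * mean(is.na(x$ct))))
  cat(sprintf("  mRNA matrix     : %d genes x %d samples\n",
              nrow(x$mrna), ncol(x$mrna)))
  cat(sprintf("  planted DE miRNAs: %d; target db families: %d\n",
              nrow(x$truth$de_mirnas), length(x$target_db)))
  invisible(x)
}

#' Write a cohort to disk as plain-text fixture tables
#'
#' Emits `mirna_ct.tsv`, `mrna_expr.tsv`, `samples.tsv`, `targets.tsv`,
#' `genesets.gmt`, `survival.tsv` and `truth.json` in the dialects the
#' package readers consume; matrices round-trip losslessly (undetected Ct
#' serialises as an empty cell).
#'
#' @param cohort a `mirna_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return named character vector of the file paths, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mirna_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ct = file.path(dir, "mirna_ct.tsv"),
    mrna = file.path(dir, "mrna_expr.tsv"),
    samples = file.path(dir, "samples.tsv"),
    targets = file.path(dir, "targets.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json"))
  write_matrix_tsv(cohort$ct, paths["ct"], id_col = "mirna_id")
  write_matrix_tsv(cohort$mrna, paths["mrna"], id_col = "gene_id")
  utils::write.table(cohort$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_target_db(cohort$target_db, paths["targets"])
  write_gmt(cohort$gene_sets, paths["gmt"], descriptions = "synthetic")
  utils::write.table(cohort$survival, paths["survival"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$planted_hazard_scores <- list(
    sample_id = names(truth$planted_hazard_scores),
    score = as.numeric(truth$planted_hazard_scores))
  truth$predicted_targets <- unclass(truth$predicted_targets)
  attr(truth$predicted_targets, "source_label") <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
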