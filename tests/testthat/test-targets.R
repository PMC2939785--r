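toy_matrices <- function(seed = 31, n_gene = 50, n_samp = 12) {
  set.seed(seed)
  mirna <- matrix(rnorm(3 * n_samp), 3, n_samp,
                  dimnames = list(paste0("miR-", 1:3), paste0("s", 1:n_samp)))
  mrna <- matrix(rnorm(n_gene * n_samp), n_gene, n_samp,
                 dimnames = list(sprintf("G%03d", 1:n_gene),
                                 paste0("s", 1:n_samp)))
  list(mirna = mirna, mrna = mrna)
}

test_that("monotone relationships give |rho| = 1 and ties match the rank-then-Pearson oracle", {
  tm <- toy_matrices()
  tm$mrna["G001", ] <- exp(tm$mirna["miR-1", ])        # monotone increasing
  pairs <- mirna_mrna_correlations(tm$mirna, tm$mrna, return_all = TRUE)
  r1 <- pairs[pairs$mirna_id == "miR-1" & pairs$gene_id == "G001", ]
  expect_equal(r1$rho, 1)
  expect_equal(r1$p, 0)
  expect_equal(r1$sign, "pos")

  # 8-sample toy with ties, against stats::cor's Spearman (independent route)
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  mi <- matrix(x, 1, dimnames = list("m", paste0("s", 1:8)))
  mr <- matrix(y, 1, dimnames = list("g", paste0("s", 1:8)))
  ours <- mirna_mrna_correlations(mi, mr, return_all = TRUE)
  expect_equal(ours$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("negating the mRNA matrix flips signs but preserves |rho|, p and q", {
  tm <- toy_matrices(32)
  a <- mirna_mrna_correlations(tm$mirna, tm$mrna, return_all = TRUE)
  b <- mirna_mrna_correlations(tm$mirna, -tm$mrna, return_all = TRUE)
  expect_equal(b$rho, -a$rho)
  expect_equal(b$p, a$p)
  expect_equal(b$q, a$q)
  expect_true(all(b$sign != a$sign | a$rho == 0))
})

test_that("independent matrices yield (almost) no significant pairs", {
  set.seed(33)
  mirna <- matrix(rnorm(5 * 44), 5, 44,
                  dimnames = list(paste0("miR-", 1:5), paste0("s", 1:44)))
  mrna <- matrix(rnorm(2000 * 44), 2000, 44,
                 dimnames = list(sprintf("G%04d", 1:2000), paste0("s", 1:44)))
  pairs <- mirna_mrna_correlations(mirna, mrna, fdr = 0.1)
  expect_lt(nrow(pairs), 5)
})

test_that("constant miRNAs are skipped and undetected samples dropped pairwise", {
  tm <- toy_matrices(34)
  tm$mirna["miR-2", ] <- 3
  tm$mirna["miR-3", c(1, 5)] <- NA
  expect_message(
    pairs <- mirna_mrna_correlations(tm$mirna, tm$mrna, return_all = TRUE),
    "skipped")
  expect_false("miR-2" %in% pairs$mirna_id)
  ok <- !is.na(tm$mirna["miR-3", ])
  oracle <- cor(tm$mirna["miR-3", ok], tm$mrna["G007", ok],
                method = "spearman")
  expect_equal(pairs$rho[pairs$mirna_id == "miR-3" & pairs$gene_id == "G007"],
               oracle, tolerance = 1e-12)
})

test_that("hypergeometric p matches exact enumeration and handles edge cases", {
  u <- letters[1:10]
  res <- hypergeometric_test(letters[1:3], letters[1:5], u)
  expect_equal(res$p, 10 / 120)   # C(5,3)/C(10,3)
  expect_equal(res$overlap_k, 3)
  expect_equal(hypergeometric_test(character(), letters[1:5], u)$p, 1)
  expect_equal(hypergeometric_test(u, letters[1:5], u)$p, 1)  # certain event
  expect_error(hypergeometric_test(c("a", "zz"), letters[1:5], u), "subset")

  set.seed(35)
  for (i in 1:60) {
    nu <- sample(5:15, 1)
    nr <- sample(0:nu, 1)
    ns <- sample(0:nu, 1)
    univ <- sprintf("g%02d", 1:nu)
    ref <- univ[seq_len(nr)]
    seta <- sample(univ, ns)
    ours <- hypergeometric_test(seta, ref, univ)
    expect_equal(ours$p,
                 enum_hypergeom(nu, nr, ns, ours$overlap_k),
                 tolerance = 1e-12)
  }
})

test_that("DE-concordance enrichment matches the exact oracle on constructed sets", {
  set.seed(36)
  n <- 24
  grp <- factor(rep(c("IBC", "non-IBC"), each = n / 2))
  mrna <- matrix(rnorm(12 * n), 12, n,
                 dimnames = list(sprintf("G%02d", 1:12), paste0("s", 1:n)))
  # plant 6 strongly DE genes; the correlated set sits wholly inside them
  mrna[1:6, grp == "IBC"] <- mrna[1:6, grp == "IBC"] + 6
  pairs <- data.frame(mirna_id = "miR-x", gene_id = sprintf("G%02d", 1:3),
                      stringsAsFactors = FALSE)
  res <- de_concordance_gsea(pairs, mrna, grp, de_q = 0.1)
  expect_equal(res$reference_size, 6)
  expect_equal(res$overlap_k, 3)
  expect_equal(res$p, enum_hypergeom(12, 6, 3, 3), tolerance = 1e-12)
  expect_equal(res$direction, "increased")
  # empty correlated set -> NA row
  empty <- data.frame(mirna_id = "miR-y", gene_id = "NOT_ON_ARRAY",
                      stringsAsFactors = FALSE)
  res2 <- de_concordance_gsea(empty, mrna, grp)
  expect_true(is.na(res2$p))
})

test_that("target-database concordance flags planted miRNAs and handles absences", {
  # disjoint correlated and predicted sets: overlap empty, p = 1
  univ <- sprintf("G%02d", 1:20)
  pairs <- data.frame(mirna_id = "miR-a", gene_id = univ[1:5],
                      stringsAsFactors = FALSE)
  db <- list("miR-a" = univ[10:14])
  res <- concordant_targets(pairs, db, univ)
  expect_equal(res$summary$overlap_k, 0)
  expect_equal(res$summary$p, 1)
  expect_identical(res$intersection_genes[["miR-a"]], character())
  # miRNA absent from the database -> NA row
  pairs2 <- rbind(pairs, data.frame(mirna_id = "miR-b", gene_id = univ[1:2]))
  res2 <- concordant_targets(pairs2, db, univ)
  expect_true(is.na(res2$summary$p[res2$summary$mirna_id == "miR-b"]))

  # synthetic cohort: planted miRNAs are flagged concordant
  coh <- generate_cohort(small_config(seed = 37))
  expr <- normalize_global_centre(filter_informative(coh$ct))
  truth <- coh$truth$de_mirnas$mirna_id
  pr <- mirna_mrna_correlations(expr[truth, , drop = FALSE], coh$mrna)
  cc <- concordant_targets(pr, coh$target_db, rownames(coh$mrna))
  flagged <- cc$summary$mirna_id[cc$summary$concordant]
  expect_true(all(truth %in% flagged))
})

test_that("reported per-miRNA totals always equal negative + positive counts", {
  coh <- generate_cohort(small_config(seed = 38))
  expr <- normalize_global_centre(filter_informative(coh$ct))
  pr <- mirna_mrna_correlations(expr[coh$truth$de_mirnas$mirna_id, ,
                                     drop = FALSE], coh$mrna)
  tab <- table(pr$mirna_id, pr$sign)
  totals <- table(pr$mirna_id)
  expect_equal(as.vector(totals),
               as.vector(tab[, "neg"] + tab[, "pos"]))
})

test_that("functional enrichment ranks an exact term first and validates terms", {
  univ <- sprintf("G%03d", 1:100)
  genes <- univ[1:10]
  sets <- list(exact = genes, half = univ[6:25], rand = univ[40:70])
  res <- functional_enrichment(genes, sets, univ)
  expect_identical(res$term_id[1], "exact")
  expect_lt(res$p[1], res$p[2])
  expect_equal(res$overlap_k[res$term_id == "exact"], 10)
  expect_error(functional_enrichment(genes, list(big = c(univ, "EXTRA")), univ),
               "larger than the universe")
  # top_n truncates after ranking
  expect_equal(nrow(functional_enrichment(genes, sets, univ, top_n = 2)), 2)
})
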