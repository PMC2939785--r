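test_that("signed RE matches brute-force mean-rank oracles", {
  x <- setNames(1:10, letters[1:10])
  # targets are the 3 lowest-expressed of 10: oracle (7 - 2) / 5.5
  expect_equal(re_score_sample(x, letters[1:3], "signed"),
               (mean(4:10) - mean(1:3)) / 5.5)
  expect_equal(re_score_sample(x, letters[1:3], "signed"),
               brute_re_signed(x, 1:3))
  # targets occupying exactly the middle ranks of an odd universe -> 0
  y <- setNames(1:9, letters[1:9])
  expect_equal(re_score_sample(y, letters[4:6], "signed"), 0)
  # swapping targets and non-targets negates RE after set-size reweighting
  set.seed(51)
  for (i in 1:20) {
    G <- sample(5:40, 1)
    z <- setNames(round(rnorm(G), 1), paste0("g", seq_len(G)))  # ties likely
    t_idx <- sample(G, sample(seq_len(G - 1), 1))
    a <- re_score_sample(z, names(z)[t_idx], "signed")
    b <- re_score_sample(z, names(z)[-t_idx], "signed")
    expect_equal(a, brute_re_signed(z, t_idx))
    # the mean-rank difference is exactly antisymmetric under the swap
    expect_equal(b, -a)
  }
})

test_that("RE normalisation bounds |RE| below 1 for all set sizes", {
  set.seed(52)
  for (i in 1:100) {
    G <- sample(4:60, 1)
    x <- setNames(sample(round(rnorm(G), 1)), paste0("g", seq_len(G)))
    t_idx <- sample(G, sample(seq_len(G - 1), 1))
    expect_lt(abs(re_score_sample(x, names(x)[t_idx], "signed")), 1)
    expect_lt(abs(re_score_sample(x, names(x)[t_idx], "symmetric",
                                  center = rep(0, G))), 1)
  }
})

test_that("signed RE is antisymmetric and symmetric RE invariant under negation", {
  set.seed(53)
  m <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  db <- list(famA = paste0("g", 1:20), famB = paste0("g", 50:60))
  signed <- re_matrix(m, db, mode = "signed")
  signed_neg <- re_matrix(-m, db, mode = "signed")
  expect_equal(signed_neg, -signed, tolerance = 1e-12)
  sym <- re_matrix(m, db, mode = "symmetric")
  sym_neg <- re_matrix(-m, db, mode = "symmetric")
  expect_equal(sym_neg, sym, tolerance = 1e-12)
})

test_that("re_matrix reproduces per-sample scores, drops unusable families", {
  set.seed(54)
  m <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:20)))
  db <- list(famA = paste0("g", 1:10), famB = paste0("g", 1:10),
             ghost = c("nope1", "nope2"))
  expect_message(re <- re_matrix(m, db, mode = "signed"), "dropped")
  expect_identical(rownames(re), c("famA", "famB"))
  # identical target sets give identical RE rows
  expect_equal(re["famA", ], re["famB", ])
  # matches the single-sample operation
  for (s in 1:6) {
    expect_equal(re["famA", s],
                 re_score_sample(m[, s], paste0("g", 1:10), "signed"))
  }
  # iid noise: RE centred near zero (null RE s.d. here is about 0.16)
  expect_lt(abs(mean(re["famA", ])), 3 * 0.16 / sqrt(20))
})

test_that("strong target regulation in one group raises symmetric RE there", {
  # IBC is the minority group, so the per-gene cross-sample median tracks
  # the unperturbed non-IBC level and target deviations surface in IBC
  set.seed(55)
  m <- matrix(rnorm(300 * 20), 300, 20,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
  grp <- factor(rep(c("IBC", "non-IBC"), c(6, 14)), c("IBC", "non-IBC"))
  targets <- paste0("g", 1:25)
  m[targets, grp == "IBC"] <- m[targets, grp == "IBC"] - 3  # repression in IBC
  re <- re_matrix(m, list(fam = targets), mode = "symmetric")
  expect_gt(mean(re[, grp == "IBC"]), mean(re[, grp == "non-IBC"]))
  # the signed score sees the direction explicitly
  res <- re_matrix(m, list(fam = targets), mode = "signed")
  expect_gt(mean(res[, grp == "IBC"]), mean(res[, grp == "non-IBC"]))
})

test_that("SAM-style group comparison is reproducible and detects planted shifts", {
  set.seed(56)
  G <- 400
  m <- matrix(rnorm(G * 24), G, 24,
              dimnames = list(paste0("g", seq_len(G)), paste0("s", 1:24)))
  db <- lapply(1:40, function(i) paste0("g", sample(G, 15)))
  names(db) <- paste0("fam", 1:40)
  re <- re_matrix(m, db, mode = "symmetric")
  grp <- factor(rep(c("IBC", "non-IBC"), each = 12), c("IBC", "non-IBC"))
  shifted <- paste0("fam", 1:8)
  re[shifted, grp == "IBC"] <- re[shifted, grp == "IBC"] + 0.3
  a <- re_group_compare(re, grp, n_perm = 200, seed = 9)
  b <- re_group_compare(re, grp, n_perm = 200, seed = 9)
  expect_identical(a, b)
  hits <- a$family_id[a$q < 0.1]
  expect_gte(mean(shifted %in% hits), 0.8)
  expect_true(all(a$direction[match(intersect(shifted, hits), a$family_id)] ==
                    "higher in IBC"))
  expect_true(all(a$q >= 0 & a$q <= 1))
})

test_that("SAM q-values stay quiet under random labels", {
  set.seed(57)
  n_called <- replicate(15, {
    re <- matrix(rnorm(40 * 24, sd = 0.1), 40, 24,
                 dimnames = list(paste0("f", 1:40), paste0("s", 1:24)))
    res <- re_group_compare(re, factor(rep(c("a", "b"), each = 12)),
                            n_perm = 100)
    sum(res$q < 0.1)
  })
  expect_lt(mean(n_called), 2)
})

test_that("degenerate RE inputs are rejected or flagged", {
  x <- setNames(1:6, letters[1:6])
  expect_error(re_score_sample(x, letters[1:6], "signed"), "strict subset")
  expect_error(re_score_sample(x, character(), "signed"))
  expect_error(re_score_sample(x, "zz", "signed"), "unknown")
  expect_error(re_score_sample(x, "a", "symmetric"), "center")
  re <- matrix(c(rep(1, 12), rnorm(12)), 2, 12, byrow = TRUE,
               dimnames = list(c("const", "ok"), paste0("s", 1:12)))
  res <- re_group_compare(re, factor(rep(c("a", "b"), each = 6)),
                          n_perm = 100, seed = 1)
  expect_true(res$flagged[res$family_id == "const"])
})
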