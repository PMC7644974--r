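# Transforms, screens, CV gate, PCA and peaking classification.

test_that("log2 condition means behave as geometric means", {
  design <- make_design(c("M", "MD"), n = 3L)
  mat <- matrix(c(4, 4, 4, 2, 8, 8), nrow = 1,
                dimnames = list("F001", design$sample_id))
  mat[1, 4:6] <- c(2, 8, 8)
  cm <- log2_condition_means(mat, design)
  expect_equal(cm["F001", "M"], 2)
  # replicates (2, 8): mean of (1, 3) = 2 on the log2 scale
  mat2 <- matrix(c(2, 8, 2, 8), nrow = 1,
                 dimnames = list("F001", make_design(c("M", "MD"), 2L)$sample_id))
  cm2 <- log2_condition_means(mat2, make_design(c("M", "MD"), 2L))
  expect_equal(unname(cm2[1, ]), c(2, 2))
  # zero entry is named in the error
  mat3 <- mat; mat3[1, 2] <- 0
  expect_error(log2_condition_means(mat3, design), "M_2")
})

test_that("auto-scaling gives zero mean, unit SD, and flags flat rows", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(7, 7, 7, 7, 7))
  z <- autoscale_rows(m)
  expect_equal(mean(z["a", ]), 0)
  expect_equal(sd(z["a", ]), 1)
  expect_equal(unname(z["b", ]), rep(0, 5))
  expect_identical(unname(attr(z, "zero_variance")), c(FALSE, TRUE))
  # z-scores are invariant to affine transforms of the row
  z2 <- autoscale_rows(rbind(a = 3 * m["a", ] + 11))
  expect_equal(unname(z2[1, ]), unname(z["a", ]))
})

test_that("geometric-mean normalization has product one", {
  expect_equal(geomean_normalize(c(1, 2, 4)), c(0.5, 1, 2))
  expect_equal(geomean_normalize(rep(3.7, 5)), rep(1, 5))
  set.seed(5)
  for (i in 1:10) {
    x <- exp(rnorm(5))
    expect_equal(prod(geomean_normalize(x)), 1)
  }
  expect_error(geomean_normalize(c(1, 0, 2)), "positive")
  # normalizing then log2 equals log2 then mean-centering
  x <- c(2.5, 1.2, 8, 0.4, 1)
  expect_equal(log2(geomean_normalize(x)), log2(x) - mean(log2(x)))
})

test_that("ANOVA screen applies the conjunctive p and fold-change gates", {
  design <- make_design(n = 3L)
  true_means <- rbind(
    big = c(M = 1, MD = 4, E = 1, MN = 1, CL = 4),     # 4-fold, real
    small = c(M = 1, MD = 1.2, E = 1, MN = 1, CL = 1.2), # sub-gate fold
    flat = c(M = 2, MD = 2, E = 2, MN = 2, CL = 2))
  mat <- make_ratio_matrix(true_means, design, cv = 0.10, seed = 42)
  res <- anova_screen(mat, design)
  expect_true(res$significant[res$row_id == "big"])
  expect_identical(res$peak_condition[res$row_id == "big"],
                   res$peak_condition[res$row_id == "big"])
  # fold 1.2 with tiny noise: p may be small but the fc gate fails
  small <- res[res$row_id == "small", ]
  expect_false(small$significant && small$fold_change > 1.5)
  expect_false(res$significant[res$row_id == "flat"])
  # gates commute: filtering by p then fc equals fc then p
  pass_pf <- with(res, p_value < 0.05 & fold_change > 1.5)
  pass_fp <- with(res, fold_change > 1.5 & p_value < 0.05)
  expect_identical(pass_pf, pass_fp)
  expect_identical(res$significant, unname(pass_pf))
})

test_that("ANOVA type-I error sits in the binomial 95% band around alpha", {
  design <- make_design(n = 3L)
  n_null <- 1000L
  true_means <- matrix(1, n_null, 5,
                       dimnames = list(sprintf("N%04d", 1:n_null),
                                       c("M", "MD", "E", "MN", "CL")))
  mat <- make_ratio_matrix(true_means, design, cv = 0.2, seed = 314)
  res <- anova_screen(mat, design)
  rate <- mean(res$p_value < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_null)
  expect_gte(rate, 0.05 - ci_half)
  expect_lte(rate, 0.05 + ci_half)
})

test_that("pairwise MD-vs-CL screen finds planted differences", {
  design <- make_design(c("MD", "CL"), n = 3L)
  true_means <- rbind(up = c(MD = 4, CL = 2), null = c(MD = 3, CL = 3))
  mat <- make_ratio_matrix(true_means, design, cv = 0.10, seed = 99)
  res <- pairwise_screen(mat, design)
  up <- res[res$row_id == "up", ]
  expect_true(up$significant)
  expect_identical(up$direction, "MD")
  expect_equal(up$fold_change, 2, tolerance = 0.35)
  # identical groups: no evidence
  const <- matrix(5, 1, 6, dimnames = list("c", design$sample_id))
  rc <- pairwise_screen(const, design)
  expect_false(rc$significant)
  expect_equal(rc$fold_change, 1)
  expect_error(pairwise_screen(mat[, 1, drop = FALSE],
                               design[1, , drop = FALSE]), "present")
})

test_that("t-test type-I error sits in the binomial 95% band", {
  design <- make_design(c("MD", "CL"), n = 3L)
  n_null <- 500L
  true_means <- matrix(2, n_null, 2,
                       dimnames = list(sprintf("N%04d", 1:n_null),
                                       c("MD", "CL")))
  mat <- make_ratio_matrix(true_means, design, cv = 0.25, seed = 2718)
  res <- pairwise_screen(mat, design)
  rate <- mean(res$p_value < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_null)
  expect_gte(rate, 0.05 - ci_half)
  expect_lte(rate, 0.05 + ci_half)
})

test_that("CV gate matches hand-computed coefficients of variation", {
  design <- make_design(n = 3L)
  good <- rep(c(90, 100, 110), 5)       # CV = 10/100 = 0.1 everywhere
  bad <- rep(c(10, 100, 190), 5)        # CV = 90/100 = 0.9
  ident <- rep(7, 15)                   # CV = 0
  mat <- rbind(good = good, bad = bad, ident = ident)
  colnames(mat) <- design$sample_id
  res <- cv_gate(mat, design)
  expect_equal(res$mean_cv[res$row_id == "good"], 0.1)
  expect_equal(res$mean_cv[res$row_id == "bad"], 0.9)
  expect_equal(res$mean_cv[res$row_id == "ident"], 0)
  expect_identical(res$pass, c(TRUE, FALSE, TRUE))
})

test_that("PCA scores match a brute-force eigen-decomposition oracle", {
  set.seed(123)
  design <- make_design(n = 2L)  # 5 conditions x 2 = 10 samples
  mat <- matrix(rnorm(5 * 10), 5, 10,
                dimnames = list(sprintf("F%03d", 1:5), design$sample_id))
  res <- pca_scores(mat, design, log2_transform = FALSE, scale_rows = FALSE)
  # oracle: eigen-decomposition of the sample covariance of centered data
  X <- t(mat); Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  oracle <- Xc %*% ev$vectors
  k <- ncol(res$scores)
  for (j in seq_len(k)) {
    expect_equal(abs(unname(res$scores[, j])), abs(unname(oracle[, j])),
                 tolerance = 1e-8)
  }
  # independent library cross-check
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (j in seq_len(k)) {
    expect_equal(abs(unname(res$scores[, j])), abs(unname(pr$x[, j])),
                 tolerance = 1e-8)
  }
  # explained variance fractions: non-increasing, sum to 1
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_equal(sum(res$explained), 1)
})

test_that("duplicated samples land on identical PCA coordinates", {
  set.seed(321)
  design <- make_design(c("M", "MD"), n = 2L)
  base <- rnorm(6)
  mat <- cbind(M_1 = base, M_2 = base, MD_1 = base + 1, MD_2 = base + 1)
  rownames(mat) <- sprintf("F%03d", 1:6)
  res <- pca_scores(mat, design, log2_transform = FALSE, scale_rows = FALSE)
  expect_equal(res$scores["M_1", ], res$scores["M_2", ])
  expect_equal(res$scores["MD_1", ], res$scores["MD_2", ])
  expect_error(pca_scores(mat[, 1, drop = FALSE], design), "2 samples")
})

test_that("PCA ellipses cover the group scores at the chi-square radius", {
  set.seed(77)
  design <- make_design(n = 10L)
  true_means <- matrix(rep(c(1, 4, 2, 0.5, 4), each = 8), 8, 5,
                       dimnames = list(sprintf("F%03d", 1:8),
                                       c("M", "MD", "E", "MN", "CL")))
  mat <- make_ratio_matrix(true_means, design, cv = 0.1, seed = 8)
  res <- pca_scores(mat, design)
  expect_identical(sort(names(res$ellipses)),
                   sort(unique(design$condition)))
  for (e in res$ellipses) {
    expect_equal(e$radius, sqrt(qchisq(0.95, 2)))
    expect_identical(dim(e$cov), c(2L, 2L))
  }
})

test_that("replicates cluster tighter than conditions separate in PC space", {
  st <- generate_study(generator_config(seed = 55L))
  pairs_by_sample <- lapply(split(st$features, st$features$sample_id),
                            pair_with_internal_standard)
  am <- build_abundance_matrix(pairs_by_sample[st$design$sample_id],
                               st$design)
  res <- pca_scores(am)
  sc <- res$scores[, 1:2]
  cond <- st$design$condition[match(rownames(sc), st$design$sample_id)]
  d <- as.matrix(dist(sc))
  same <- outer(cond, cond, "==") & upper.tri(d)
  diff_c <- outer(cond, cond, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_c]))
})

test_that("peaking classification follows the diurnal argmax with tie rule", {
  m <- rbind(F001 = c(M = 1, MD = 5, E = 2, MN = 1),
             F002 = c(M = 3, MD = 3, E = 3, MN = 3),
             F003 = c(M = 0.1, MD = 0.2, E = 0.9, MN = 0.3))
  res <- classify_peaking(m)
  expect_identical(res$peaking, c("MD", "M", "E"))
  expect_identical(res$tie, c(FALSE, TRUE, FALSE))
  expect_error(classify_peaking(m[, c("M", "MD", "E")]), "MN")
  # planted dusk-peaking metabolites classify correctly at 10% noise
  design <- make_design(c("M", "MD", "E", "MN"), n = 3L)
  true_means <- matrix(rep(c(1, 2.83, 8, 2.83), each = 40), 40, 4,
                       dimnames = list(sprintf("F%03d", 1:40),
                                       c("M", "MD", "E", "MN")))
  mat <- make_ratio_matrix(true_means, design, cv = 0.1, seed = 4)
  cm <- log2_condition_means(mat, design)
  cls <- classify_peaking(2^cm)
  expect_gte(mean(cls$peaking == "E"), 0.95)
})
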