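# Internal-standard pairing, credentialing and the ratio matrix.

feat_row <- function(id, mz, rt, area, sample = "S1") {
  data.frame(sample_id = sample, feature_id = id, mz = mz, rt_min = rt,
             area = area, stringsAsFactors = FALSE)
}

test_that("a planted pair is recovered with its carbon count and ratio", {
  u <- mz_deprotonated("C3H7O7P")
  l <- as.numeric(labeled_mz("C3H7O7P", "13C"))
  feats <- rbind(feat_row("u1", u, 5.0, 2000),
                 feat_row("l1", l, 5.0, 1000))
  pairs <- pair_with_internal_standard(feats)
  expect_equal(nrow(pairs), 1L)
  expect_identical(pairs$unlabeled_id, "u1")
  expect_identical(pairs$labeled_id, "l1")
  expect_identical(pairs$n_carbon, 3L)
  expect_equal(pairs$ratio, 2.0)
  expect_equal(pairs$observed_shift, 3 * iso_constants$delta_13C,
               tolerance = 1e-9)
})

test_that("features without a mass-shifted partner stay unpaired", {
  u <- mz_deprotonated("C3H7O7P")
  feats <- rbind(feat_row("u1", u, 5.0, 2000),
                 feat_row("bg", 321.0404, 9.1, 500))
  expect_identical(nrow(pair_with_internal_standard(feats)), 0L)
  expect_identical(nrow(pair_with_internal_standard(feats[0, ])), 0L)
})

test_that("the retention-time gate picks the co-eluting candidate", {
  u <- mz_deprotonated("C3H7O7P")
  l <- as.numeric(labeled_mz("C3H7O7P", "13C"))
  feats <- rbind(feat_row("u1", u, 5.0, 2000),
                 feat_row("far", l, 9.0, 800),   # isobaric, wrong RT
                 feat_row("near", l, 5.02, 1000))
  pairs <- pair_with_internal_standard(feats, rt_tol = 0.1)
  expect_identical(pairs$labeled_id, "near")
})

test_that("credentialing recovers C/N composition for planted compounds", {
  mk <- function(tag, formulas, labels) {
    mz <- mapply(function(f, lab) {
      if (is.na(lab)) mz_deprotonated(f)
      else as.numeric(suppressWarnings(labeled_mz(f, lab)))
    }, formulas, labels)
    data.frame(sample_id = tag,
               feature_id = paste0(tag, "_", seq_along(formulas)),
               mz = mz, rt_min = c(5, 8, 11)[seq_along(formulas)],
               area = 1000, stringsAsFactors = FALSE)
  }
  forms <- c("C14H22N2O16P2", "C6H12O6")
  ctrl <- mk("CTRL", forms, c(NA, NA))
  c13 <- mk("C13", forms, c("13C", "13C"))
  n15 <- mk("N15", forms, c("15N", "15N"))
  # a solvent contaminant at identical m/z in all three cultures
  contam <- function(d) rbind(d, feat_row("contam", 400.1234, 15.0, 9e4,
                                          d$sample_id[1]))
  res <- credential_features(contam(ctrl), contam(c13), contam(n15))
  expect_identical(res$biological, c(TRUE, TRUE, FALSE))
  expect_identical(res$n_carbon[1:2], c(14L, 6L))
  # UDP-xylose has 2 nitrogens; glucose is N-free (zero-shift match)
  expect_identical(res$n_nitrogen[1:2], c(2L, 0L))
  expect_true(is.na(res$n_carbon[3]))
})

test_that("[2M-H]- multimers of annotated compounds are flagged", {
  M <- monoisotopic_mass("C3H7O7P")
  dimer_mz <- 2 * M - iso_constants$masses[["H"]] + iso_constants$electron
  feats <- rbind(feat_row("dimer", dimer_mz, 5.0, 100),
                 feat_row("other", dimer_mz + 0.3, 5.0, 100))
  expect_identical(flag_multimers(feats, "C3H7O7P"), c(TRUE, FALSE))
  expect_identical(flag_multimers(feats, character(0)), c(FALSE, FALSE))
})

test_that("abundance matrix assembles, aligns and reports missing cells", {
  u <- mz_deprotonated("C3H7O7P"); l <- as.numeric(labeled_mz("C3H7O7P", "13C"))
  u2 <- mz_deprotonated("C6H12O6"); l2 <- as.numeric(labeled_mz("C6H12O6", "13C"))
  mk_sample <- function(s, with_second = TRUE, r1 = 2, r2 = 5) {
    f <- rbind(feat_row("a", u, 5, 1000 * r1, s), feat_row("b", l, 5, 1000, s))
    if (with_second)
      f <- rbind(f, feat_row("c", u2, 9, 1000 * r2, s),
                 feat_row("d", l2, 9, 1000, s))
    f
  }
  design <- data.frame(sample_id = c("S1", "S2", "S3"),
                       condition = c("M", "MD", "E"), replicate = 1L,
                       stringsAsFactors = FALSE)
  pairs <- list(S1 = pair_with_internal_standard(mk_sample("S1")),
                S2 = pair_with_internal_standard(mk_sample("S2")),
                S3 = pair_with_internal_standard(mk_sample("S3")))
  am <- build_abundance_matrix(pairs, design)
  expect_s3_class(am, "abundance_matrix")
  expect_identical(dim(am$ratios), c(2L, 3L))
  expect_false(anyNA(am$ratios))
  # rows sorted by m/z: glucose (179.056) before 3PGA (184.986)
  expect_equal(unname(am$ratios[1, ]), rep(5, 3))
  expect_equal(unname(am$ratios[2, ]), rep(2, 3))
  # a metabolite absent in one sample leaves exactly one missing cell
  pairs$S3 <- pair_with_internal_standard(mk_sample("S3", with_second = FALSE))
  am2 <- build_abundance_matrix(pairs, design)
  expect_identical(sum(is.na(am2$ratios)), 1L)
  expect_true(is.na(am2$ratios[1, "S3"]))
  # unknown sample rejected
  expect_error(build_abundance_matrix(list(SX = pairs$S1), design),
               "absent from design")
})

test_that("per-sample matrix effects cancel exactly in the ratios", {
  cfg <- generator_config(n_metabolites = 15L, n_background = 5L,
                          noise_cv = 0, matrix_spread = 0, mz_noise_ppm = 0,
                          rt_jitter_min = 0, seed = 31L)
  st <- generate_study(cfg)
  one <- st$features[st$features$sample_id == "E_1", ]
  base <- pair_with_internal_standard(one)
  for (g in c(0.2, 3.7)) {
    scaled <- one; scaled$area <- scaled$area * g
    ps <- pair_with_internal_standard(scaled)
    expect_equal(ps$ratio, base$ratio)
  }
})

test_that("ratios cut replicate CV far below raw-area CV under area noise", {
  # constant truth, lognormal area noise sigma = 0.3, shared per-injection
  # matrix effect: the IS cancels the injection factor so the ratio CV
  # collapses while raw-area CV stays near 0.3
  set.seed(77)
  sigma <- 0.3
  n_rep <- 60L
  u <- mz_deprotonated("C6H13O9P"); l <- as.numeric(labeled_mz("C6H13O9P", "13C"))
  ratios <- numeric(n_rep); raw <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    g <- exp(rnorm(1, 0, sigma))          # injection/matrix effect
    eps <- exp(rnorm(1, 0, 0.02))         # small residual peak-area error
    a_u <- 5000 * g * eps
    a_l <- 2500 * g * exp(rnorm(1, 0, 0.02))
    feats <- rbind(feat_row("u", u, 7, a_u), feat_row("l", l, 7, a_l))
    ratios[i] <- pair_with_internal_standard(feats)$ratio
    raw[i] <- a_u
  }
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(ratios), 0.05)
  expect_gt(cv(raw), 0.2)
})

test_that("pairing on the default synthetic study is sensitive and specific", {
  st <- generate_study(generator_config(seed = 19L))
  truth <- st$truth$feature_map
  sens <- spec_ok <- numeric(0)
  for (s in unique(st$design$sample_id)) {
    pairs <- pair_with_internal_standard(
      st$features[st$features$sample_id == s, ])
    role_u <- truth$role[match(pairs$unlabeled_id, truth$feature_id)]
    role_l <- truth$role[match(pairs$labeled_id, truth$feature_id)]
    correct <- role_u == "unlabeled" & role_l == "labeled_is" &
      truth$name[match(pairs$unlabeled_id, truth$feature_id)] ==
      truth$name[match(pairs$labeled_id, truth$feature_id)]
    sens <- c(sens, sum(correct) / nrow(st$library))
    spec_ok <- c(spec_ok, sum(role_u == "background"))
  }
  expect_gte(mean(sens), 0.95)
  # background decoys essentially never enter a pair
  expect_lte(sum(spec_ok) / (length(spec_ok) * st$config$n_background), 0.01)
})

test_that("credentialing the default synthetic cultures recovers all compounds", {
  st <- generate_study(generator_config(seed = 23L))
  res <- credential_features(st$control, st$c13_culture, st$n15_culture)
  n <- nrow(st$library)
  planted <- res[seq_len(n), ]
  expect_true(all(planted$biological))
  expect_identical(planted$n_carbon, st$library$n_carbon)
  expect_identical(planted$n_nitrogen, st$library$n_nitrogen)
  # background contaminants (same m/z in every culture) are rejected
  expect_true(all(!res$biological[(n + 1):nrow(res)]))
})
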