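# Statistics cascade for the diurnal sampling design: log2 condition
# means, auto-scaling, geometric-mean normalization, ANOVA / t-test
# fold-change screens, the coefficient-of-variation gate, PCA with
# per-condition confidence ellipses, and peaking-time classification.

CONDITIONS <- c("M", "MD", "E", "MN", "CL")
DIURNAL_ORDER <- c("M", "MD", "E", "MN")

ratios_of <- function(x) if (inherits(x, "abundance_matrix")) x$ratios else x
design_of <- function(x, design) {
  if (inherits(x, "abundance_matrix") && missing(design)) x$design else design
}

check_design <- function(mat, design) {
  if (!all(colnames(mat) %in% design$sample_id))
    stop("matrix columns missing from design: ",
         paste(setdiff(colnames(mat), design$sample_id), collapse = ", "))
  design$condition[match(colnames(mat), design$sample_id)]
}

#' Per-condition means of log2 ratios
#'
#' For each row, the mean of `log2(entry)` over the replicates of each
#' condition (missing entries excluded). Averaging on the log scale makes
#' the condition summary a geometric mean on the ratio scale.
#'
#' @param x an `abundance_matrix` or a numeric matrix (rows = features,
#'   columns = samples).
#' @param design design data.frame (`sample_id`, `condition`, `replicate`);
#'   taken from `x` when it is an `abundance_matrix`.
#' @return Numeric matrix, rows as in `x`, one column per condition present
#'   in the design (diurnal order M, MD, E, MN, CL).
#' @export
log2_condition_means <- function(x, design) {
  design <- design_of(x, design)
  mat <- ratios_of(x)
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive ratio at row '", rownames(mat)[bad[1, 1]],
         "', sample '", colnames(mat)[bad[1, 2]], "'")
  cond <- check_design(mat, design)
  conds <- intersect(CONDITIONS, unique(cond))
  out <- sapply(conds, function(cc)
    rowMeans(log2(mat[, cond == cc, drop = FALSE]), na.rm = TRUE))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), conds))
  out[is.nan(out)] <- NA_real_
  out
}

#' Auto-scale rows to zero mean and unit variance
#'
#' Z-scores each row (sample standard deviation). Constant rows cannot be
#' scaled: they are returned as all zeros and flagged in the
#' `zero_variance` attribute.
#'
#' @param mat numeric matrix with >= 2 columns.
#' @return Matrix of the same shape with attribute `zero_variance`
#'   (logical per row).
#' @export
autoscale_rows <- function(mat) {
  stopifnot(ncol(mat) >= 2L)
  mu <- rowMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  flat <- !is.na(sd) & sd == 0
  sd[flat] <- 1
  out <- (mat - mu) / sd
  out[flat, ] <- 0
  attr(out, "zero_variance") <- flat
  out
}

#' Normalize a positive vector by its geometric mean
#'
#' Divides each value by the geometric mean of the vector, so the product of
#' the outputs is 1. Used to display per-condition levels relative to the
#' across-condition typical level.
#'
#' @param x positive numeric vector (e.g. one row of condition means on the
#'   ratio scale).
#' @return Normalized vector of the same length.
#' @export
geomean_normalize <- function(x) {
  if (any(is.na(x)) || any(x <= 0)) stop("all values must be positive")
  x / exp(mean(log(x)))
}

# geometric means per condition on the ratio scale, via log2 means
condition_geomeans <- function(mat, cond) {
  conds <- intersect(CONDITIONS, unique(cond))
  gm <- sapply(conds, function(cc)
    2^rowMeans(log2(mat[, cond == cc, drop = FALSE]), na.rm = TRUE))
  matrix(gm, nrow = nrow(mat), dimnames = list(rownames(mat), conds))
}

#' One-way ANOVA / fold-change screen across all conditions
#'
#' Per feature: a classical one-way ANOVA (equal-variance F test) on the
#' log2 ratios across all conditions, and the fold change computed as the
#' maximum over minimum of the per-condition geometric means. A feature is
#' significant when `p < alpha` AND `fold change > fc_min` — the conjunctive
#' gate used for calling diurnal variation.
#'
#' @param x an `abundance_matrix` or numeric ratio matrix.
#' @param design design data.frame (see [log2_condition_means()]).
#' @param alpha p-value threshold (default 0.05).
#' @param fc_min fold-change threshold (default 1.5).
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching a raw p < alpha gate; `"BH"` available).
#' @return data.frame with one row per feature: `row_id`, `p_value`,
#'   `fold_change`, `peak_condition`, `trough_condition`, `significant`.
#'   Rows with fewer than 2 conditions observed get `NA` p and
#'   `significant = FALSE`.
#' @export
anova_screen <- function(x, design, alpha = 0.05, fc_min = 1.5,
                         adjust = "none") {
  design <- design_of(x, design)
  mat <- ratios_of(x)
  cond <- check_design(mat, design)
  lmat <- log2(mat)
  gm <- condition_geomeans(mat, cond)
  p <- vapply(seq_len(nrow(lmat)), function(i) {
    y <- lmat[i, ]
    ok <- !is.na(y)
    if (length(unique(cond[ok])) < 2L) return(NA_real_)
    if (any(table(cond[ok]) < 2L)) return(NA_real_)
    stats::oneway.test(y[ok] ~ factor(cond[ok]), var.equal = TRUE)$p.value
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = adjust)
  fc <- apply(gm, 1L, function(g) max(g, na.rm = TRUE) / min(g, na.rm = TRUE))
  peak <- colnames(gm)[apply(gm, 1L, which.max)]
  trough <- colnames(gm)[apply(gm, 1L, which.min)]
  data.frame(row_id = rownames(mat), p_value = p_adj, fold_change = fc,
             peak_condition = peak, trough_condition = trough,
             significant = !is.na(p_adj) & p_adj < alpha & fc > fc_min,
             stringsAsFactors = FALSE)
}

#' Two-condition t-test / fold-change screen
#'
#' Equal-variance two-sample Student t test on log2 ratios between two
#' conditions (by default midday vs continuous light), with the fold change
#' as the ratio of geometric means oriented max over min. Significant when
#' both gates pass.
#'
#' @param x an `abundance_matrix` or numeric ratio matrix.
#' @param design design data.frame.
#' @param cond_a,cond_b the two conditions (defaults `"MD"`, `"CL"`).
#' @param alpha,fc_min gates as in [anova_screen()].
#' @param adjust p-adjustment method (default `"none"`).
#' @return data.frame: `row_id`, `p_value`, `fold_change`, `direction`
#'   (which condition is higher), `significant`.
#' @export
pairwise_screen <- function(x, design, cond_a = "MD", cond_b = "CL",
                            alpha = 0.05, fc_min = 1.5, adjust = "none") {
  design <- design_of(x, design)
  mat <- ratios_of(x)
  cond <- check_design(mat, design)
  if (!all(c(cond_a, cond_b) %in% cond))
    stop("conditions ", cond_a, " and ", cond_b, " must both be present")
  a <- mat[, cond == cond_a, drop = FALSE]
  b <- mat[, cond == cond_b, drop = FALSE]
  res <- lapply(seq_len(nrow(mat)), function(i) {
    ya <- log2(a[i, ]); yb <- log2(b[i, ])
    ya <- ya[!is.na(ya)]; yb <- yb[!is.na(yb)]
    if (length(ya) < 2L || length(yb) < 2L)
      stop("fewer than 2 replicates for row '", rownames(mat)[i], "'")
    dm <- mean(ya) - mean(yb)
    if (stats::sd(c(ya, yb)) == 0) {
      p <- 1  # identical groups: no evidence of difference
    } else {
      p <- stats::t.test(ya, yb, var.equal = TRUE)$p.value
    }
    c(p = p, fc = 2^abs(dm), dir = sign(dm))
  })
  res <- do.call(rbind, res)
  p_adj <- stats::p.adjust(res[, "p"], method = adjust)
  data.frame(row_id = rownames(mat), p_value = p_adj,
             fold_change = res[, "fc"],
             direction = ifelse(res[, "dir"] >= 0, cond_a, cond_b),
             significant = !is.na(p_adj) & p_adj < alpha &
               res[, "fc"] > fc_min,
             stringsAsFactors = FALSE)
}

#' Intra-sample coefficient-of-variation gate
#'
#' Per feature and condition, CV = sample SD / mean of the replicate ratios;
#' the feature survives when the mean of its per-condition CVs is at most
#' `cv_max`. Conditions whose replicate mean is zero make the CV undefined
#' and drop the feature.
#'
#' @param x an `abundance_matrix` or numeric ratio matrix.
#' @param design design data.frame.
#' @param cv_max threshold on the average intra-sample CV (default 0.3).
#' @return data.frame: `row_id`, `mean_cv`, `pass`.
#' @export
cv_gate <- function(x, design, cv_max = 0.3) {
  design <- design_of(x, design)
  mat <- ratios_of(x)
  cond <- check_design(mat, design)
  conds <- unique(cond)
  cvs <- sapply(conds, function(cc) {
    sub <- mat[, cond == cc, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    ifelse(m == 0, NA_real_, s / m)
  })
  cvs <- matrix(cvs, nrow = nrow(mat))
  mean_cv <- rowMeans(cvs)
  data.frame(row_id = rownames(mat), mean_cv = mean_cv,
             pass = !is.na(mean_cv) & mean_cv <= cv_max,
             stringsAsFactors = FALSE)
}

#' PCA of samples with per-condition 95% confidence ellipses
#'
#' Principal-component analysis of the samples: the feature-by-sample
#' matrix is transposed so samples are observations, columns (features) are
#' mean-centered, and scores come from the singular value decomposition.
#' Missing entries are imputed by the feature's row mean beforehand (PCA
#' only; the inferential screens never impute). For each condition a 95%
#' coverage ellipse of a bivariate normal fitted on the PC1/PC2 scores is
#' returned (chi-square quantile with 2 df scaling of the group
#' covariance).
#'
#' @param x an `abundance_matrix`, or a numeric matrix (features x
#'   samples) of values already on the scale to be analyzed (e.g. log2).
#' @param design design data.frame.
#' @param log2_transform log2-transform ratios first (default TRUE when `x`
#'   is an `abundance_matrix`).
#' @param scale_rows auto-scale rows before PCA (default TRUE).
#' @return List with `scores` (samples x PCs), `loadings`, `explained`
#'   (variance fractions, non-increasing), `ellipses` (named list per
#'   condition: `center`, `cov`, `radius`), `design`.
#' @export
pca_scores <- function(x, design, log2_transform = inherits(x, "abundance_matrix"),
                       scale_rows = TRUE) {
  design <- design_of(x, design)
  mat <- ratios_of(x)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  cond <- check_design(mat, design)
  if (log2_transform) mat <- log2(mat)
  # row-mean imputation of missing cells
  if (anyNA(mat)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1]]
    mat <- mat[is.finite(rowMeans(mat)), , drop = FALSE]
  }
  if (scale_rows) {
    mat <- autoscale_rows(mat)
    mat <- mat[!attr(mat, "zero_variance"), , drop = FALSE]
  }
  X <- t(mat)                          # samples x features
  X <- sweep(X, 2L, colMeans(X))       # column-center
  sv <- svd(X)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(k)))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(rownames(mat), paste0("PC", seq_len(k)))
  ev <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  r95 <- sqrt(stats::qchisq(0.95, df = 2))
  ellipses <- lapply(split(seq_len(nrow(scores)), cond), function(idx) {
    # rank-1 data: pad PC2 with zeros so the ellipse is still defined
    sc <- cbind(PC1 = scores[idx, 1],
                PC2 = if (ncol(scores) >= 2L) scores[idx, 2] else 0)
    list(center = colMeans(sc),
         cov = if (length(idx) > 1L) stats::cov(sc) else diag(0, 2),
         radius = r95)
  })
  list(scores = scores, loadings = loadings, explained = ev,
       ellipses = ellipses, design = design)
}

#' Classify a feature's diurnal peaking time
#'
#' The peaking label is the diurnal condition (M, MD, E, MN) with the
#' largest mean level; ties are broken in diurnal order M < MD < E < MN and
#' flagged.
#'
#' @param means numeric matrix of per-condition means (rows = features)
#'   containing at least the four diurnal conditions as columns, or a named
#'   vector for a single feature.
#' @return data.frame: `row_id`, `peaking`, `tie`.
#' @export
classify_peaking <- function(means) {
  if (is.vector(means)) means <- matrix(means, 1L, dimnames = list("F001", names(means)))
  if (!all(DIURNAL_ORDER %in% colnames(means)))
    stop("need all four diurnal conditions: ",
         paste(setdiff(DIURNAL_ORDER, colnames(means)), collapse = ", "))
  m <- means[, DIURNAL_ORDER, drop = FALSE]
  peak <- apply(m, 1L, function(v) DIURNAL_ORDER[which.max(v)])
  tie <- apply(m, 1L, function(v) sum(v == max(v)) > 1L)
  data.frame(row_id = rownames(m) %||% sprintf("F%03d", seq_len(nrow(m))),
             peaking = peak, tie = tie, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
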