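# Internal-standard pairing, biological-origin credentialing, and
# construction of the sample/IS isotopic-area-ratio matrix.
#
# The internal standard is a fully 13C-labeled metabolite extract spiked in
# equal amount into every sample, so each metabolite -- annotated or not --
# gains a co-eluting partner peak shifted by nC * (13C - 12C). The ratio of
# the 12C (sample) to 13C (IS) monoisotopic peak areas is the relative
# abundance measure; because both peaks see the same injection, extraction
# and matrix effects, those effects cancel in the ratio.

# Candidate (unlabeled, labeled) matches within rt/ppm tolerance; shared by
# pairing and credentialing. Returns a data.frame of candidate matches with
# ppm and rt deviations.
match_shifted <- function(unlab, lab, delta, rt_tol, ppm_tol, n_range,
                          charge = 1L) {
  out <- vector("list", nrow(unlab))
  for (i in seq_len(nrow(unlab))) {
    rt_ok <- which(abs(lab$rt_min - unlab$rt_min[i]) <= rt_tol)
    if (length(rt_ok) == 0L) next
    shift <- (lab$mz[rt_ok] - unlab$mz[i]) * charge
    n <- round(shift / delta)
    ppm_dev <- abs(shift - n * delta) / (charge * lab$mz[rt_ok]) * 1e6
    keep <- which(n >= n_range[1] & n <= n_range[2] & ppm_dev <= ppm_tol)
    if (length(keep) == 0L) next
    out[[i]] <- data.frame(
      u = i, l = rt_ok[keep], n = as.integer(n[keep]),
      ppm_dev = ppm_dev[keep],
      rt_dev = abs(lab$rt_min[rt_ok[keep]] - unlab$rt_min[i]),
      shift = shift[keep], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(u = integer(), l = integer(), n = integer(),
                      ppm_dev = numeric(), rt_dev = numeric(),
                      shift = numeric()))
  do.call(rbind, out)
}

#' Pair unlabeled features with their 13C internal-standard partners
#'
#' Within one mixed injection (sample + fully 13C-labeled IS extract), each
#' candidate unlabeled feature is matched to a feature at the same retention
#' time (within `rt_tol`) whose m/z is higher by `n * delta13C / charge` for
#' some integer `n` in `nc_range`, within `ppm_tol`. Assignment is one-to-one
#' and greedy by smallest ppm deviation (retention-time deviation breaks
#' ties). The pair's isotopic area ratio is `area(unlabeled) /
#' area(labeled)`.
#'
#' @param features data.frame for a single mixed injection with columns
#'   `feature_id`, `mz`, `rt_min`, `area`.
#' @param rt_tol retention-time tolerance in minutes (default 0.1).
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @param nc_range integer interval of admissible carbon counts
#'   (default `c(1, 60)`).
#' @param charge charge state assumed for all features (default 1).
#' @return data.frame with one row per pair: `unlabeled_id`, `labeled_id`,
#'   `mz`, `rt_min`, `n_carbon`, `observed_shift`, `ratio`.
#' @export
pair_with_internal_standard <- function(features, rt_tol = 0.1, ppm_tol = 10,
                                        nc_range = c(1L, 60L), charge = 1L) {
  empty <- data.frame(unlabeled_id = character(), labeled_id = character(),
                      mz = numeric(), rt_min = numeric(),
                      n_carbon = integer(), observed_shift = numeric(),
                      ratio = numeric(), stringsAsFactors = FALSE)
  if (nrow(features) == 0L) return(empty)
  cand <- match_shifted(features, features, iso_constants$delta_13C,
                        rt_tol, ppm_tol, nc_range, charge)
  cand <- cand[cand$u != cand$l, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$ppm_dev, cand$rt_dev), , drop = FALSE]
  used <- logical(nrow(features))
  rows <- list()
  for (j in seq_len(nrow(cand))) {
    u <- cand$u[j]; l <- cand$l[j]
    if (used[u] || used[l]) next
    used[u] <- TRUE; used[l] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      unlabeled_id = features$feature_id[u],
      labeled_id = features$feature_id[l],
      mz = features$mz[u], rt_min = features$rt_min[u],
      n_carbon = cand$n[j], observed_shift = cand$shift[j],
      ratio = features$area[u] / features$area[l],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$mz), , drop = FALSE]
}

#' Credential features as biological and infer C/N composition
#'
#' A feature from the unlabeled control culture is credentialed as
#' biological when the fully 13C-grown culture shows a feature at the same
#' retention time whose mass shift equals `nC * delta13C` for some `nC >= 1`
#' within tolerance. The nitrogen count comes from the matching shift in the
#' fully 15N-grown culture when one exists (`nN = 0` is allowed, via a
#' zero-shift match, for nitrogen-free compounds); otherwise it is `NA`.
#'
#' @param unlabeled data.frame of control-culture features (`feature_id`,
#'   `mz`, `rt_min`, `area`).
#' @param c13 data.frame of features from the fully 13C-labeled culture.
#' @param n15 data.frame of features from the fully 15N-labeled culture.
#' @param rt_tol retention-time tolerance in minutes (default 0.1).
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @param nc_range admissible carbon-count interval (default `c(1, 60)`).
#' @param charge assumed charge state (default 1).
#' @return data.frame with one row per input feature: `feature_id`, `mz`,
#'   `rt_min`, `biological`, `n_carbon`, `n_nitrogen`.
#' @export
credential_features <- function(unlabeled, c13, n15, rt_tol = 0.1,
                                ppm_tol = 10, nc_range = c(1L, 60L),
                                charge = 1L) {
  res <- data.frame(feature_id = unlabeled$feature_id, mz = unlabeled$mz,
                    rt_min = unlabeled$rt_min, biological = FALSE,
                    n_carbon = NA_integer_, n_nitrogen = NA_integer_,
                    stringsAsFactors = FALSE)
  cmatch <- match_shifted(unlabeled, c13, iso_constants$delta_13C,
                          rt_tol, ppm_tol, nc_range, charge)
  if (nrow(cmatch) > 0L) {
    cmatch <- cmatch[order(cmatch$ppm_dev, cmatch$rt_dev), , drop = FALSE]
    best <- cmatch[!duplicated(cmatch$u), , drop = FALSE]
    res$biological[best$u] <- TRUE
    res$n_carbon[best$u] <- best$n
  }
  # nitrogen: zero-shift matches allowed (N-free compounds appear unshifted
  # in the 15N culture), so the admissible range starts at 0
  nmatch <- match_shifted(unlabeled, n15, iso_constants$delta_15N,
                          rt_tol, ppm_tol, c(0L, nc_range[2]), charge)
  if (nrow(nmatch) > 0L) {
    nmatch <- nmatch[order(nmatch$ppm_dev, nmatch$rt_dev), , drop = FALSE]
    bestn <- nmatch[!duplicated(nmatch$u), , drop = FALSE]
    idx <- bestn$u[res$biological[bestn$u]]
    res$n_nitrogen[idx] <- bestn$n[match(idx, bestn$u)]
  }
  res
}

#' Flag likely [2M-H]- multimer adducts of annotated compounds
#'
#' Marks features whose m/z matches `2 * M - mass(H) + mass(electron)` of an
#' annotated compound within `ppm_tol`, so dimer adducts are not mistaken
#' for independent biological features.
#'
#' @param features data.frame with columns `feature_id`, `mz`.
#' @param formulas character vector of Hill-notation formulas of annotated
#'   compounds.
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @return Logical vector, TRUE where the feature matches a 2M-H ion.
#' @export
flag_multimers <- function(features, formulas, ppm_tol = 10) {
  if (length(formulas) == 0L || nrow(features) == 0L)
    return(rep(FALSE, nrow(features)))
  dimer_mz <- vapply(formulas, function(f) {
    2 * monoisotopic_mass(f) - iso_constants$masses[["H"]] + iso_constants$electron
  }, numeric(1))
  vapply(features$mz, function(m)
    any(abs(m - dimer_mz) <= ppm_tol * 1e-6 * m), logical(1))
}

#' Assemble the metabolite-by-sample isotopic-area-ratio matrix
#'
#' Pairs from all samples are aligned across samples by (m/z, retention
#' time): pairs agreeing within `ppm_tol` and `rt_tol` are treated as the
#' same metabolite/feature. Entries are the sample/IS area ratios; a
#' metabolite missing from a sample yields `NA`.
#'
#' @param pairs_by_sample named list (sample id -> data.frame from
#'   [pair_with_internal_standard()]).
#' @param design data.frame with columns `sample_id`, `condition`,
#'   `replicate`; every name of `pairs_by_sample` must appear.
#' @param rt_tol,ppm_tol cross-sample alignment tolerances (defaults 0.1
#'   min, 10 ppm).
#' @return An `abundance_matrix`: a list with `ratios` (numeric matrix, rows
#'   = aligned features, columns = samples), `features` (data.frame of
#'   consensus `mz`, `rt_min`, `n_carbon` per row) and `design`.
#' @export
build_abundance_matrix <- function(pairs_by_sample, design, rt_tol = 0.1,
                                   ppm_tol = 10) {
  stopifnot(is.list(pairs_by_sample), !is.null(names(pairs_by_sample)))
  samples <- names(pairs_by_sample)
  missing_design <- setdiff(samples, design$sample_id)
  if (length(missing_design))
    stop("samples absent from design: ", paste(missing_design, collapse = ", "))
  # greedy cross-sample clustering by (m/z, RT)
  ref_mz <- numeric(); ref_rt <- numeric(); ref_nc <- integer()
  cells <- list()
  for (s in samples) {
    p <- pairs_by_sample[[s]]
    if (is.null(p) || nrow(p) == 0L) next
    for (i in seq_len(nrow(p))) {
      hit <- which(abs(ref_mz - p$mz[i]) <= ppm_tol * 1e-6 * p$mz[i] &
                     abs(ref_rt - p$rt_min[i]) <= rt_tol)
      if (length(hit) == 0L) {
        ref_mz <- c(ref_mz, p$mz[i]); ref_rt <- c(ref_rt, p$rt_min[i])
        ref_nc <- c(ref_nc, p$n_carbon[i])
        row <- length(ref_mz)
      } else {
        row <- hit[which.min(abs(ref_mz[hit] - p$mz[i]))]
      }
      key <- paste(row, s, sep = "\r")
      if (!is.null(cells[[key]]))
        stop("duplicate entry for feature row ", row, " in sample '", s, "'")
      cells[[key]] <- p$ratio[i]
    }
  }
  n_row <- length(ref_mz)
  ratios <- matrix(NA_real_, n_row, length(samples),
                   dimnames = list(sprintf("F%03d", seq_len(max(n_row, 0))),
                                   samples))
  for (key in names(cells)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ratios[as.integer(parts[1]), parts[2]] <- cells[[key]]
  }
  ord <- order(ref_mz)
  ratios <- ratios[ord, , drop = FALSE]
  rownames(ratios) <- sprintf("F%03d", seq_len(n_row))
  feat <- data.frame(row_id = rownames(ratios), mz = ref_mz[ord],
                     rt_min = ref_rt[ord], n_carbon = ref_nc[ord],
                     stringsAsFactors = FALSE)
  structure(list(ratios = ratios, features = feat,
                 design = design[match(samples, design$sample_id), ,
                                 drop = FALSE]),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d features x %d samples (%d conditions)\n",
              nrow(x$ratios), ncol(x$ratios),
              length(unique(x$design$condition))))
  invisible(x)
}

#' Drop sparsely observed rows from an abundance matrix
#'
#' Rows (features) with more than `max_missing_frac` missing entries are
#' removed before statistics; remaining missing entries are handled pairwise
#' by the tests themselves.
#'
#' @param am an `abundance_matrix`.
#' @param max_missing_frac maximum tolerated fraction of missing entries per
#'   row (default 0.5).
#' @return The filtered `abundance_matrix`.
#' @export
filter_missing <- function(am, max_missing_frac = 0.5) {
  keep <- rowMeans(is.na(am$ratios)) <= max_missing_frac
  am$ratios <- am$ratios[keep, , drop = FALSE]
  am$features <- am$features[keep, , drop = FALSE]
  am
}
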