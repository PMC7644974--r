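# End-to-end pipeline driver: annotate -> credential -> pair/quantify ->
# statistics, with stage outputs written as files so stages can be rerun
# individually, and a run manifest recording thresholds and stage counts.

default_pipeline_params <- function() {
  list(rt_tol = 0.1, ppm_tol = 10, nc_range = c(1L, 60L),
       precursor_tol = 10, frag_tol = 0.01, score_min = 0.7,
       alpha = 0.05, fc_min = 1.5, cv_max = 0.3,
       max_missing_frac = 0.5, adjust = "none", mu_window = 3L)
}

#' Run the full analysis pipeline
#'
#' Executes the workflow in its natural order: (1) annotate mixed-sample
#' features against the MS2 library, (2) credential control-culture
#' features as biological from the 13C/15N culture shifts, (3) pair each
#' sample's features with their internal-standard partners and assemble the
#' sample/IS ratio matrix (excluding [2M-H]- multimers of annotated
#' compounds), (4) run the diurnal statistics (ANOVA/fold-change screen,
#' MD-vs-CL t-test screen, CV gate, PCA, peaking classification) and, when
#' an OD series is present, the growth-rate estimation.
#'
#' The configuration is a YAML file (or an equivalent list) with keys:
#' \describe{
#'   \item{simulate}{logical; if TRUE inputs are generated by
#'     [generate_study()] using the `generator` block (any
#'     [generator_config()] argument, e.g. `seed`).}
#'   \item{inputs}{when `simulate` is FALSE: paths `features`, `design`,
#'     `library_msp`, `control`, `c13_culture`, `n15_culture`,
#'     optional `od`.}
#'   \item{params}{optional overrides of the analysis defaults
#'     (`rt_tol` 0.1 min, `ppm_tol` 10, `precursor_tol` 10 ppm, `frag_tol`
#'     0.01 Da, `score_min` 0.7, `alpha` 0.05, `fc_min` 1.5, `cv_max` 0.3,
#'     `max_missing_frac` 0.5, `adjust` "none", `mu_window` 3).}
#' }
#'
#' @param config path to a YAML config file, or a config list.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `annotations`, `credentials`, `matrix`,
#'   `anova`, `pairwise`, `cv`, `pca`, `peaking`, `mu` (NULL without OD),
#'   `manifest`; all also written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: '", config, "'")
    config <- yaml::read_yaml(config)
  }
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(config$simulate)) {
    gcfg <- do.call(generator_config, config$generator %||% list())
    study <- generate_study(gcfg)
    features <- study$features
    design <- study$design
    lib <- study$library
    lib_df <- data.frame(name = lib$name, formula = lib$formula,
                         mz = lib$mz, stringsAsFactors = FALSE)
    lib_df$ms2 <- lib$ms2
    control <- study$control
    c13 <- study$c13_culture
    n15 <- study$n15_culture
    od <- study$od
  } else {
    ins <- config$inputs
    need <- c("features", "design", "library_msp", "control",
              "c13_culture", "n15_culture")
    miss <- setdiff(need, names(ins))
    if (length(miss))
      stop("config$inputs lacks: ", paste(miss, collapse = ", "))
    features <- read_feature_table(ins$features)
    features$ms2 <- features$ms2 %||% vector("list", nrow(features))
    design <- read_design(ins$design)
    lib_df <- read_msp(ins$library_msp)
    control <- read_feature_table(ins$control)
    c13 <- read_feature_table(ins$c13_culture)
    n15 <- read_feature_table(ins$n15_culture)
    od <- if (!is.null(ins$od)) read_od_series(ins$od) else NULL
  }

  log_msg <- function(...) message("[isodiel] ", sprintf(...))

  # 1. annotation
  ann <- annotate_features(features, lib_df,
                           precursor_tol = params$precursor_tol,
                           frag_tol = params$frag_tol,
                           score_min = params$score_min)
  log_msg("annotation: %d features in, %d annotated",
          nrow(features), sum(ann$accepted))

  # 2. credentialing on the culture injections. The [2M-H]- multimer rule
  # prunes only the untargeted (unannotated) list: an annotated compound
  # may be exactly isobaric with a dimer of a smaller metabolite (FBP vs
  # 2x DHAP share one formula) and must not be vetoed by it.
  cred <- credential_features(control, c13, n15,
                              rt_tol = params$rt_tol,
                              ppm_tol = params$ppm_tol,
                              nc_range = params$nc_range)
  control$ms2 <- control$ms2 %||% vector("list", nrow(control))
  ann_ctrl <- annotate_features(control, lib_df,
                                precursor_tol = params$precursor_tol,
                                frag_tol = params$frag_tol,
                                score_min = params$score_min)
  annotated_ids <- ann_ctrl$feature_id[ann_ctrl$accepted]
  cred$annotated <- cred$feature_id %in% annotated_ids
  cred$multimer <- flag_multimers(control, unique(lib_df$formula),
                                  ppm_tol = params$ppm_tol)
  cred$untargeted <- cred$biological & !cred$annotated & !cred$multimer
  log_msg("credentialing: %d features, %d biological, %d untargeted (%d multimers excluded)",
          nrow(cred), sum(cred$biological), sum(cred$untargeted),
          sum(cred$multimer & !cred$annotated))

  # 3. pairing + ratio matrix
  pairs_by_sample <- lapply(split(features, features$sample_id),
                            pair_with_internal_standard,
                            rt_tol = params$rt_tol,
                            ppm_tol = params$ppm_tol,
                            nc_range = params$nc_range)
  pairs_by_sample <- pairs_by_sample[design$sample_id]
  names(pairs_by_sample) <- design$sample_id
  am <- build_abundance_matrix(pairs_by_sample, design,
                               rt_tol = params$rt_tol,
                               ppm_tol = params$ppm_tol)
  am <- filter_missing(am, params$max_missing_frac)
  log_msg("pairing: %d pairs/sample (median), matrix %d x %d",
          stats::median(vapply(pairs_by_sample, nrow, integer(1))),
          nrow(am$ratios), ncol(am$ratios))

  # 4. statistics
  screen <- anova_screen(am, alpha = params$alpha, fc_min = params$fc_min,
                         adjust = params$adjust)
  pw <- if (all(c("MD", "CL") %in% design$condition)) {
    pairwise_screen(am, cond_a = "MD", cond_b = "CL",
                    alpha = params$alpha, fc_min = params$fc_min,
                    adjust = params$adjust)
  } else NULL
  cv <- cv_gate(am, cv_max = params$cv_max)
  pca <- pca_scores(am)
  cm <- log2_condition_means(am)
  peaking <- if (all(DIURNAL_ORDER %in% colnames(cm)))
    classify_peaking(2^cm) else NULL
  mu <- if (!is.null(od)) instantaneous_mu(od, window = params$mu_window)
  else NULL
  log_msg("statistics: %d significant (ANOVA), %d MD-vs-CL, %d pass CV gate",
          sum(screen$significant), if (is.null(pw)) 0L else
            sum(pw$significant), sum(cv$pass))

  manifest <- list(
    package_version = as.character(utils::packageVersion("isodiel")),
    params = params,
    counts = list(
      features_in = nrow(features),
      annotated = sum(ann$accepted),
      credentialed_biological = sum(cred$biological),
      untargeted_features = sum(cred$untargeted),
      multimers_excluded = sum(cred$multimer & !cred$annotated),
      matrix_rows = nrow(am$ratios),
      matrix_samples = ncol(am$ratios),
      anova_significant = sum(screen$significant),
      pairwise_significant = if (is.null(pw)) NA_integer_ else
        sum(pw$significant),
      cv_pass = sum(cv$pass)))

  write_tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv(ann, "annotations.tsv")
  write_tsv(cred[, c("feature_id", "mz", "rt_min", "biological",
                     "n_carbon", "n_nitrogen", "annotated", "multimer",
                     "untargeted")],
            "credentials.tsv")
  write_abundance_matrix(am, file.path(out_dir, "abundance_matrix.tsv"))
  write_tsv(screen, "anova_screen.tsv")
  if (!is.null(pw)) write_tsv(pw, "pairwise_md_cl.tsv")
  write_tsv(cv, "cv_gate.tsv")
  write_tsv(data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, 1:min(5, ncol(pca$scores)),
                                  drop = FALSE]),
            "pca_scores.tsv")
  if (!is.null(peaking)) write_tsv(peaking, "peaking.tsv")
  if (!is.null(mu))
    utils::write.csv(data.frame(time_h = mu$time_h,
                                mu = sprintf("%.6f", mu$mu)),
                     file.path(out_dir, "mu.csv"),
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(annotations = ann, credentials = cred, matrix = am,
                 anova = screen, pairwise = pw, cv = cv, pca = pca,
                 peaking = peaking, mu = mu, manifest = manifest))
}
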