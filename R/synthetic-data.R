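# Synthetic study generator.
#
# Emulates the full dual-isotope study design: mixed injections of
# unlabeled samples spiked with a fully 13C-labeled internal-standard
# extract (one co-eluting, mass-shifted partner peak per metabolite),
# separate fully 13C- and fully 15N-labeled culture injections for
# credentialing, five conditions (M, MD, E, MN, CL) with replicates,
# diurnal abundance classes with multiplicative noise and per-sample matrix
# effects, and non-biological background features. Every draw is governed
# by the config seed, and a ground-truth bundle scores each downstream
# stage without any external file.

#' Generator configuration
#'
#' Bundles the knobs of the synthetic study with the defaults that define
#' its standard conditions: 67 metabolites across five diurnal classes, 30
#' background features, five conditions with 3 replicates each,
#' 10% multiplicative area noise, lognormal per-sample matrix effects
#' (sigma 0.3), 2 ppm m/z jitter and 100% isotopic label purity.
#'
#' @param n_metabolites number of planted metabolites (default 67).
#' @param n_background number of non-biological background features per
#'   injection (default 30).
#' @param conditions condition labels (default M, MD, E, MN, CL).
#' @param n_replicates replicates per condition (default 3).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   area noise (default 0.1).
#' @param matrix_spread sigma of the lognormal per-sample matrix-effect
#'   factor (default 0.3).
#' @param mz_noise_ppm uniform m/z jitter, half-width in ppm (default 2).
#' @param rt_jitter_min uniform retention-time jitter, half-width in
#'   minutes (default 0.01).
#' @param ms2_noise_cv CV of lognormal fragment-intensity noise on acquired
#'   MS2 spectra (default 0 = clean).
#' @param label_purity isotopic enrichment of the labeled extracts; the
#'   fully labeled monoisotopic peak area scales as `purity^nC`
#'   (default 1).
#' @param amplitude peak:trough fold ratio of the diurnal classes
#'   (default 8).
#' @param cl_shift_fraction fraction of metabolites whose continuous-light
#'   level departs from their midday level (default 0.3, mirroring the
#'   roughly one-third of compounds that separate the two regimes in
#'   diurnal studies); the rest have CL tracking MD.
#' @param cl_shift_fold fold applied to the CL level of the shifted subset,
#'   alternating up/down (default 2).
#' @param heavy_tail if TRUE, a random tenth of the rhythmic metabolites
#'   get amplitude 100, emulating the heavy tail of fold changes
#'   (default FALSE).
#' @param seed integer random seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_metabolites = 67L, n_background = 30L,
                             conditions = c("M", "MD", "E", "MN", "CL"),
                             n_replicates = 3L, noise_cv = 0.1,
                             matrix_spread = 0.3, mz_noise_ppm = 2,
                             rt_jitter_min = 0.01, ms2_noise_cv = 0,
                             label_purity = 1, amplitude = 8,
                             cl_shift_fraction = 0.3, cl_shift_fold = 2,
                             heavy_tail = FALSE, seed = 1L) {
  stopifnot(n_metabolites >= 1L, n_background >= 0L, n_replicates >= 2L,
            noise_cv >= 0, noise_cv < 1, matrix_spread >= 0,
            mz_noise_ppm >= 0, label_purity > 0, label_purity <= 1,
            amplitude >= 1, cl_shift_fraction >= 0, cl_shift_fraction <= 1,
            cl_shift_fold >= 1)
  structure(as.list(environment()), class = "generator_config")
}

# Named catalog of polar metabolites spanning the compound classes of the
# study: CBB-cycle / glycolytic sugar phosphates, nucleotides, sugar
# nucleotides, amino acids and gamma-glutamyl dipeptides. The two worked
# exemplars (3PGA, UDP-xylose) come first.
metabolite_catalog <- function() {
  c("3PGA" = "C3H7O7P",
    "UDP-xylose" = "C14H22N2O16P2",
    "G6P" = "C6H13O9P", "F6P" = "C6H13O9P", "FBP" = "C6H14O12P2",
    "RuBP" = "C5H12O11P2", "S7P" = "C7H15O10P", "SBP" = "C7H16O13P2",
    "R5P" = "C5H11O8P", "PEP" = "C3H5O6P", "Pyruvate" = "C3H4O3",
    "Citrate" = "C6H8O7", "Malate" = "C4H6O5", "Succinate" = "C4H6O4",
    "2-OG" = "C5H6O5", "Fumarate" = "C4H4O4", "G1P" = "C6H13O9P",
    "6PG" = "C6H13O10P", "DHAP" = "C3H7O6P", "Glycerate" = "C3H6O4",
    "ATP" = "C10H16N5O13P3", "ADP" = "C10H15N5O10P2",
    "AMP" = "C10H14N5O7P", "GTP" = "C10H16N5O14P3",
    "GMP" = "C10H14N5O8P", "UTP" = "C9H15N2O15P3", "UMP" = "C9H13N2O9P",
    "CTP" = "C9H16N3O14P3", "CMP" = "C9H14N3O8P", "IMP" = "C10H13N4O8P",
    "XMP" = "C10H13N4O9P", "NAD" = "C21H27N7O14P2",
    "NADP" = "C21H28N7O17P3", "UDP-glucose" = "C15H24N2O17P2",
    "ADP-glucose" = "C16H25N5O15P2", "UDP-GlcNAc" = "C17H27N3O17P2",
    "GDP-mannose" = "C16H25N5O16P2", "CMP-Neu5Ac" = "C20H31N4O16P",
    "Glutamate" = "C5H9NO4", "Aspartate" = "C4H7NO4",
    "Glutamine" = "C5H10N2O3", "Glycine" = "C2H5NO2",
    "Alanine" = "C3H7NO2", "Serine" = "C3H7NO3", "Valine" = "C5H11NO2",
    "Pyroglutamate" = "C5H7NO3", "N-Acetyl-Glu" = "C7H11NO5",
    "gGlu-Leu" = "C11H20N2O5", "gGlu-Ile" = "C11H20N2O5",
    "gGlu-Phe" = "C14H18N2O5", "gGlu-Tyr" = "C14H18N2O6",
    "gGlu-Trp" = "C16H19N3O5", "gGlu-Met" = "C10H18N2O5S",
    "gGlu-Val" = "C10H18N2O5", "Glutathione" = "C10H17N3O6S",
    "Acetyl-CoA" = "C23H38N7O17P3S", "Glucose" = "C6H12O6",
    "Sucrose" = "C12H22O11", "Trehalose-6P" = "C12H23O14P",
    "Shikimate" = "C7H10O5", "Chorismate" = "C10H10O6",
    "Homoserine" = "C4H9NO3", "Threonine" = "C4H9NO3",
    "Ornithine" = "C5H12N2O2", "Citrulline" = "C6H13N3O3",
    "Arginine" = "C6H14N4O2", "Histidine" = "C6H9N3O2",
    "Proline" = "C5H9NO2", "Lysine" = "C6H14N2O2")
}

# deterministic-but-random MS2 fragment template for one precursor
random_ms2 <- function(precursor_mz, n_frag = 6L) {
  fr <- sort(stats::runif(n_frag, 0.15, 0.95)) * precursor_mz
  ints <- stats::runif(n_frag, 0.05, 1)
  ints[which.max(ints)] <- 1
  ms2_spectrum(precursor_mz, fr, ints)
}

#' Generate a synthetic metabolite library
#'
#' Draws `n_metabolites` specs from a catalog of real polar metabolites
#' (sugar phosphates, nucleotides, sugar nucleotides, amino acids,
#' gamma-glutamyl dipeptides), always including the exemplars 3PGA
#' (C3H7O7P) and UDP-xylose (C14H22N2O16P2). Diurnal classes (M-, MD-, E-,
#' MN-peaking, flat) are assigned round-robin; each metabolite gets a fixed
#' retention time, base abundance and a seeded MS2 fragment template.
#'
#' @param config a [generator_config()].
#' @return data.frame of class `metabolite_library`: `name`, `formula`,
#'   `mz` ([M-H]-), `rt_min`, `base_abundance`, `class`, `amplitude`,
#'   `n_carbon`, `n_nitrogen`, list-column `ms2`.
#' @export
generate_library <- function(config = generator_config()) {
  set.seed(config$seed)
  cat_all <- metabolite_catalog()
  n <- config$n_metabolites
  if (n <= length(cat_all)) {
    forms <- cat_all[seq_len(n)]
  } else {
    # pad with random plausible CHNOP formulas
    extra <- n - length(cat_all)
    pads <- vapply(seq_len(extra), function(i) {
      nc <- sample(3:20, 1); nh <- sample(5:30, 1)
      nn <- sample(0:4, 1); no <- sample(2:12, 1); np <- sample(0:2, 1)
      format_formula(chem_formula(c(C = nc, H = nh, N = nn, O = no, P = np)))
    }, character(1))
    names(pads) <- sprintf("compound_%03d", seq_len(extra))
    forms <- c(cat_all, pads)
  }
  classes <- rep(c("M", "MD", "E", "MN", "flat"), length.out = n)
  amp <- ifelse(classes == "flat", 1, config$amplitude)
  if (config$heavy_tail) {
    rhythmic <- which(classes != "flat")
    heavy <- sample(rhythmic, max(1L, length(rhythmic) %/% 10L))
    amp[heavy] <- 100
  }
  fl <- lapply(forms, chem_formula)
  mz <- vapply(fl, mz_deprotonated, numeric(1))
  lib <- data.frame(
    name = names(forms),
    formula = unname(forms),
    mz = unname(mz),
    # random permutation of an even grid: isobars (e.g. G6P/F6P/G1P) are
    # guaranteed chromatographic separation well beyond rt_tol
    rt_min = round(sample(seq(1, 20, length.out = n)), 3),
    base_abundance = round(10^stats::runif(n, 3, 5), 1),
    class = classes,
    amplitude = amp,
    n_carbon = vapply(fl, function(f) f[["C"]], integer(1)),
    n_nitrogen = vapply(fl, function(f) f[["N"]], integer(1)),
    stringsAsFactors = FALSE)
  lib$ms2 <- lapply(lib$mz, random_ms2)
  rownames(lib) <- NULL
  class(lib) <- c("metabolite_library", "data.frame")
  lib
}

# Condition multiplier of a diurnal class. Cyclic distance on the diurnal
# wheel M -> MD -> E -> MN: the peak condition gets the full amplitude, its
# neighbors sqrt(amplitude), the opposite phase 1. CL mirrors MD by
# default (continuous light tracks midday levels for most compounds),
# except for the cl-shifted subset handled in generate_study.
class_multiplier <- function(class, condition, amplitude) {
  if (class == "flat") return(1)
  cond <- ifelse(condition == "CL", "MD", condition)
  pos <- match(cond, c("M", "MD", "E", "MN"))
  ppk <- match(class, c("M", "MD", "E", "MN"))
  d <- abs(pos - ppk); d <- pmin(d, 4 - d)
  amplitude^(1 - d / 2)
}

lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes plus ground truth:
#' \itemize{
#'   \item `features`: mixed-injection feature table (unlabeled metabolite
#'     peak + fully 13C IS peak per metabolite + background decoys) for
#'     each sample of the design, with areas
#'     `base * class_multiplier * matrix_effect * noise` (IS areas use an
#'     equal spike in every sample, so the true sample/IS ratio equals the
#'     class multiplier), m/z jitter at the configured ppm, and MS2 spectra
#'     on unlabeled and background peaks;
#'   \item `control`, `c13_culture`, `n15_culture`: single-injection
#'     feature tables of the unlabeled, fully 13C- and fully 15N-labeled
#'     cultures used for credentialing (background contaminants appear
#'     unshifted in all three);
#'   \item `design`: sample_id / condition / replicate table;
#'   \item `od`: an OD720 series from the light/growth model;
#'   \item `library`: the metabolite library;
#'   \item `truth`: ground-truth bundle (true ratio matrix, classes,
#'     significant set, feature roles) sufficient to score pairing,
#'     credentialing, annotation and the statistical screens.
#' }
#'
#' @param config a [generator_config()].
#' @param library optionally a pre-built library (default: generated from
#'   `config`).
#' @param mu_peak,od_dip_depth growth-model settings for the bundled OD
#'   series (defaults 0.16 h-1, no transition dips).
#' @return A list of class `synthetic_study` with the components above.
#' @export
generate_study <- function(config = generator_config(),
                           library = generate_library(config),
                           mu_peak = 0.16, od_dip_depth = 0) {
  set.seed((config$seed %% 2147483600L) + 1L)
  n <- nrow(library)
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        condition = config$conditions,
                        stringsAsFactors = FALSE)
  design <- design[, c("condition", "replicate")]
  design$sample_id <- paste0(design$condition, "_", design$replicate)
  design <- design[, c("sample_id", "condition", "replicate")]

  bg_n <- config$n_background
  bg <- data.frame(
    name = sprintf("background_%03d", seq_len(bg_n)),
    mz = round(stats::runif(bg_n, 80, 800), 5),
    rt_min = round(stats::runif(bg_n, 0.5, 22), 3),
    area = round(10^stats::runif(bg_n, 3, 4.5), 1),
    stringsAsFactors = FALSE)
  bg$ms2 <- lapply(bg$mz, random_ms2)

  true_mult <- sapply(design$sample_id, function(s) {
    cc <- design$condition[design$sample_id == s]
    vapply(seq_len(n), function(i)
      class_multiplier(library$class[i], cc, library$amplitude[i]),
      numeric(1))
  })
  true_mult <- matrix(true_mult, nrow = n,
                      dimnames = list(library$name, design$sample_id))

  # a seeded subset of metabolites departs from its midday level under
  # continuous light (alternating up/down by cl_shift_fold); the rest have
  # CL tracking MD
  n_shift <- round(config$cl_shift_fraction * n)
  cl_shifted <- rep(FALSE, n)
  if (n_shift > 0 && "CL" %in% design$condition) {
    shifted <- sort(sample(n, n_shift))
    cl_shifted[shifted] <- TRUE
    dirs <- rep(c(1, -1), length.out = n_shift)
    cl_cols <- design$sample_id[design$condition == "CL"]
    true_mult[shifted, cl_cols] <-
      true_mult[shifted, cl_cols] * config$cl_shift_fold^dirs
  }

  jitter_mz <- function(mz) {
    if (config$mz_noise_ppm <= 0) return(mz)
    mz * (1 + stats::runif(length(mz), -config$mz_noise_ppm,
                           config$mz_noise_ppm) * 1e-6)
  }
  jitter_rt <- function(rt) {
    if (config$rt_jitter_min <= 0) return(rt)
    rt + stats::runif(length(rt), -config$rt_jitter_min, config$rt_jitter_min)
  }
  noisy_ms2 <- function(sp) {
    if (config$ms2_noise_cv <= 0) return(sp)
    ms2_spectrum(sp$precursor_mz, sp$mz,
                 sp$intensity * lognoise(length(sp$intensity),
                                         config$ms2_noise_cv))
  }

  mz_u <- library$mz
  mz_l <- mz_u + library$n_carbon * iso_constants$delta_13C
  is_area_true <- library$base_abundance * config$label_purity^library$n_carbon

  feat <- list(); fmap <- list()
  matrix_effect <- stats::setNames(
    if (config$matrix_spread > 0)
      exp(stats::rnorm(nrow(design), 0, config$matrix_spread))
    else rep(1, nrow(design)),
    design$sample_id)

  for (si in seq_len(nrow(design))) {
    s <- design$sample_id[si]
    g <- matrix_effect[[s]]
    area_u <- library$base_abundance * true_mult[, s] * g *
      lognoise(n, config$noise_cv)
    area_l <- is_area_true * g * lognoise(n, config$noise_cv)
    fu <- data.frame(
      sample_id = rep(s, n),
      feature_id = sprintf("%s_U%03d", s, seq_len(n)),
      mz = jitter_mz(mz_u), rt_min = jitter_rt(library$rt_min),
      area = area_u, stringsAsFactors = FALSE)
    fu$ms2 <- lapply(library$ms2, noisy_ms2)
    fl <- data.frame(
      sample_id = rep(s, n),
      feature_id = sprintf("%s_L%03d", s, seq_len(n)),
      mz = jitter_mz(mz_l), rt_min = jitter_rt(library$rt_min),
      area = area_l, stringsAsFactors = FALSE)
    fl$ms2 <- vector("list", n)
    fb <- data.frame(
      sample_id = rep(s, bg_n),
      feature_id = sprintf("%s_B%03d", s, seq_len(bg_n)),
      mz = jitter_mz(bg$mz), rt_min = jitter_rt(bg$rt_min),
      area = bg$area * g * lognoise(bg_n, config$noise_cv),
      stringsAsFactors = FALSE)
    fb$ms2 <- lapply(bg$ms2, noisy_ms2)
    feat[[si]] <- rbind(fu, fl, fb)
    fmap[[si]] <- data.frame(
      feature_id = c(fu$feature_id, fl$feature_id, fb$feature_id),
      name = c(library$name, library$name, bg$name),
      role = rep(c("unlabeled", "labeled_is", "background"),
                 c(n, n, bg_n)), stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feat)

  # credentialing injections: unlabeled control, fully 13C and fully 15N
  # cultures; background contaminants appear unshifted in all three
  culture <- function(tag, mzs) {
    d <- data.frame(
      sample_id = rep(tag, n + bg_n),
      feature_id = sprintf("%s_F%03d", tag, seq_len(n + bg_n)),
      mz = jitter_mz(c(mzs, bg$mz)),
      rt_min = jitter_rt(c(library$rt_min, bg$rt_min)),
      area = c(library$base_abundance, bg$area) *
        lognoise(n + bg_n, config$noise_cv),
      stringsAsFactors = FALSE)
    d$ms2 <- c(lapply(library$ms2, noisy_ms2), lapply(bg$ms2, noisy_ms2))
    d
  }
  mz_n15 <- mz_u + library$n_nitrogen * iso_constants$delta_15N
  control <- culture("CTRL", mz_u)
  c13_culture <- culture("C13", mz_l)
  n15_culture <- culture("N15", mz_n15)

  profile <- light_profile()
  od <- simulate_od(profile, mu_peak = mu_peak, od0 = 0.1, dt = 0.05,
                    horizon_h = 48, dip_depth = od_dip_depth)

  truth <- list(
    ratio_matrix = true_mult,
    classes = stats::setNames(library$class, library$name),
    significant = stats::setNames(
      (library$class != "flat" & library$amplitude > 1.5) |
        (cl_shifted & config$cl_shift_fold > 1.5), library$name),
    cl_shifted = stats::setNames(cl_shifted, library$name),
    md_cl_significant = stats::setNames(
      cl_shifted & config$cl_shift_fold > 1.5, library$name),
    feature_map = do.call(rbind, fmap),
    matrix_effect = matrix_effect,
    is_area = stats::setNames(is_area_true, library$name))

  structure(list(features = features, control = control,
                 c13_culture = c13_culture, n15_culture = n15_culture,
                 design = design, od = od, library = library,
                 truth = truth, config = config, light = profile),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d metabolites + %d background, ",
                     "%d samples (%d conditions x %d reps), seed %d\n"),
              nrow(x$library), x$config$n_background, nrow(x$design),
              length(x$config$conditions), x$config$n_replicates,
              x$config$seed))
  invisible(x)
}
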