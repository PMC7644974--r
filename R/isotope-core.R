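# Exact-mass arithmetic for negative-mode LC-MS and stable-isotope labeling.

#' Isotope and atomic-mass constants
#'
#' Monoisotopic atomic masses, heavy-isotope mass differences, the electron
#' mass and the natural 13C abundance used throughout the package. All masses
#' are in Da.
#'
#' @format A list with components:
#' \describe{
#'   \item{masses}{named numeric, monoisotopic atomic masses of C, H, N, O, P, S}
#'   \item{delta_13C}{mass difference 13C - 12C (1.0033548 Da)}
#'   \item{delta_15N}{mass difference 15N - 14N (0.9970349 Da)}
#'   \item{electron}{electron mass (Da)}
#'   \item{abundance_13C}{natural abundance of 13C (fraction)}
#' }
#' The same values ship as a plain-text table at
#' `system.file("extdata", "isotope_constants.tsv", package = "isodiel")`.
#' @export
iso_constants <- list(
  masses = c(
    C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    P = 30.97376163,
    S = 31.97207100
  ),
  delta_13C = 1.0033548378,
  delta_15N = 0.9970348934,
  electron  = 0.00054857990907,
  abundance_13C = 0.0107
)

#' Construct an elemental formula
#'
#' Parses a Hill-notation formula string (e.g. `"C6H12O6"`) or accepts named
#' atom counts, restricted to the elements C, H, N, O, P and S that dominate
#' polar metabolites. Counts are non-negative integers and the formula must
#' contain at least one atom.
#'
#' @param x a Hill-notation string, or a named numeric vector / list of atom
#'   counts (names among C, H, N, O, P, S).
#' @return An object of class `elemental_formula`: a named integer vector
#'   over all six supported elements (absent elements are 0).
#' @examples
#' chem_formula("C3H7O7P")     # 3-phosphoglycerate
#' chem_formula(c(C = 6, H = 12, O = 6))
#' @export
chem_formula <- function(x) {
  elements <- names(iso_constants$masses)
  counts <- stats::setNames(integer(length(elements)), elements)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, !is.na(x))
    s <- gsub("\\s", "", x)
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
      stop("malformed formula string: '", x, "'")
    m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
    for (tok in regmatches(s, list(m))[[1]]) {
      el <- gsub("[0-9]", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% elements)
        stop("unknown element symbol: '", el, "'")
      counts[el] <- counts[el] + n
    }
  } else if (is.numeric(x) || is.list(x)) {
    x <- unlist(x)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("atom counts must be named")
    bad <- setdiff(names(x), elements)
    if (length(bad)) stop("unknown element symbol: '", bad[1], "'")
    if (any(x < 0) || any(x != round(x)))
      stop("atom counts must be non-negative integers")
    counts[names(x)] <- as.integer(x)
  } else {
    stop("cannot interpret 'x' as a formula")
  }
  if (sum(counts) == 0L) stop("formula must contain at least one atom")
  structure(counts, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Format a formula in Hill notation
#'
#' @param f an `elemental_formula`.
#' @return A Hill-notation string (C first, then H, then other elements
#'   alphabetically).
#' @export
format_formula <- function(f) {
  f <- unclass(f)
  ord <- c("C", "H", sort(setdiff(names(f), c("C", "H"))))
  f <- f[ord]
  f <- f[f > 0]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) x else chem_formula(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of atom count times monoisotopic atomic mass.
#'
#' @param f an `elemental_formula` or Hill-notation string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C3H7O7P")  # 186.99294
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * iso_constants$masses[names(f)])
}

#' m/z of the deprotonated ion [M - zH]^z-
#'
#' Negative-ion-mode m/z: `(M - z * mass(H) + z * mass(electron)) / z`.
#' The electron mass is included so the value is exact rather than
#' proton-approximate.
#'
#' @param f an `elemental_formula` or string.
#' @param charge positive integer charge state (default 1, i.e. [M-H]-).
#' @return m/z in Th.
#' @examples
#' mz_deprotonated("C3H7O7P")  # 185.98566
#' @export
mz_deprotonated <- function(f, charge = 1L) {
  f <- as_formula(f)
  if (length(charge) != 1L || is.na(charge) || charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  if (f[["H"]] < charge)
    stop("formula has fewer hydrogens (", f[["H"]], ") than charge ", charge)
  M <- monoisotopic_mass(f)
  (M - charge * iso_constants$masses[["H"]] + charge * iso_constants$electron) / charge
}

#' m/z of a fully labeled deprotonated ion
#'
#' m/z of [M - zH]^z- after full substitution of 12C by 13C
#' (`label = "13C"`) or 14N by 15N (`label = "15N"`). If the formula lacks
#' the labeled element the unlabeled m/z is returned and the result carries
#' attribute `warning = TRUE`.
#'
#' @param f an `elemental_formula` or string.
#' @param label `"13C"` or `"15N"`.
#' @param charge positive integer charge state.
#' @return m/z in Th, with attribute `warning` set to TRUE when the label
#'   element is absent.
#' @examples
#' labeled_mz("C3H7O7P", "13C")  # 185.98566 + 3 * 1.0033548
#' @export
labeled_mz <- function(f, label = c("13C", "15N"), charge = 1L) {
  f <- as_formula(f)
  label <- match.arg(label)
  base <- mz_deprotonated(f, charge)
  n <- if (label == "13C") f[["C"]] else f[["N"]]
  delta <- if (label == "13C") iso_constants$delta_13C else iso_constants$delta_15N
  if (n == 0L) {
    warning("formula ", format_formula(f), " contains no ",
            if (label == "13C") "carbon" else "nitrogen",
            "; labeled m/z equals unlabeled m/z")
    return(structure(base, warning = TRUE))
  }
  structure(base + n * delta / charge, warning = FALSE)
}

#' Natural-abundance mass isotopologue distribution
#'
#' Carbon-only binomial model of the natural mass isotopologue distribution
#' (MID): `P(M+i) = choose(nC, i) a^i (1-a)^(nC-i)` with `a` the natural 13C
#' abundance, truncated at `M+k` and renormalized to sum to one. Heavier
#' isotopes of H, N, O, P, S are neglected; carbon dominates the M+1 peak of
#' the polar metabolites this package targets.
#'
#' @param f an `elemental_formula` or string.
#' @param k highest isotopologue index retained (`M+0` ... `M+k`).
#' @param abundance natural 13C abundance (default from [iso_constants]).
#' @return Numeric vector of length `min(k, nC) + 1` named `M+0` ...; sums
#'   to 1.
#' @examples
#' natural_mid("C6H12O6", k = 2)
#' @export
natural_mid <- function(f, k, abundance = iso_constants$abundance_13C) {
  f <- as_formula(f)
  if (length(k) != 1L || is.na(k) || k < 0 || k != round(k))
    stop("k must be a non-negative integer")
  nC <- f[["C"]]
  if (nC == 0L) return(c("M+0" = 1))
  i <- 0:min(k, nC)
  p <- stats::dbinom(i, size = nC, prob = abundance)
  p <- p / sum(p)
  stats::setNames(p, paste0("M+", i))
}

#' Infer an atom count from a labeling-induced mass shift
#'
#' Given the m/z of an unlabeled ion and of its fully 13C- (or 15N-) labeled
#' counterpart at the same charge, estimates the number of atoms of the
#' labeled element as `n = round(charge * (mz_labeled - mz_unlabeled) /
#' delta)`. The candidate is accepted only when the reconstructed shift
#' `n * delta / charge` agrees with the observed shift within `ppm_tol` parts
#' per million of the labeled m/z.
#'
#' @param mz_unlabeled,mz_labeled observed m/z values (labeled >= unlabeled).
#' @param element `"C"` or `"N"`.
#' @param charge positive integer charge state.
#' @param ppm_tol acceptance tolerance in ppm (default 10).
#' @return Integer atom count (>= 0), or `NA_integer_` when no integer count
#'   reproduces the shift within tolerance (including negative shifts).
#' @examples
#' infer_atom_count(185.98566, 188.99573, "C")  # 3 (3PGA)
#' @export
infer_atom_count <- function(mz_unlabeled, mz_labeled, element = c("C", "N"),
                             charge = 1L, ppm_tol = 10) {
  element <- match.arg(element)
  delta <- if (element == "C") iso_constants$delta_13C else iso_constants$delta_15N
  shift <- mz_labeled - mz_unlabeled
  if (is.na(shift) || shift < 0) return(NA_integer_)
  n <- as.integer(round(charge * shift / delta))
  expected <- n * delta / charge
  if (abs(shift - expected) <= ppm_tol * 1e-6 * mz_labeled) n else NA_integer_
}
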