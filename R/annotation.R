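# MS2 spectral matching against a reference library.
#
# A deliberately minimal annotator: the field's heavyweight tools do SWATH
# deconvolution and retention-indexed libraries; here identity assignment is
# by precursor m/z gating plus a greedy cosine score on square-root
# intensities, which is all the downstream credentialing and quantification
# require.

#' Construct an MS2 spectrum
#'
#' @param precursor_mz precursor m/z (Th).
#' @param fragments_mz numeric vector of fragment m/z values.
#' @param intensities numeric vector of (relative) intensities, same length.
#' @return An object of class `ms2_spectrum`: a list with `precursor_mz`,
#'   `mz`, `intensity`, fragments sorted by m/z.
#' @export
ms2_spectrum <- function(precursor_mz, fragments_mz, intensities) {
  stopifnot(length(precursor_mz) == 1L, precursor_mz > 0,
            length(fragments_mz) == length(intensities))
  if (length(fragments_mz) == 0L)
    stop("a spectrum needs at least one fragment")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (any(fragments_mz > precursor_mz + 0.5))
    stop("fragment m/z above precursor m/z + 0.5")
  ord <- order(fragments_mz)
  structure(list(precursor_mz = precursor_mz,
                 mz = as.numeric(fragments_mz[ord]),
                 intensity = as.numeric(intensities[ord])),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.5f, %d fragments\n",
              x$precursor_mz, length(x$mz)))
  invisible(x)
}

#' Cosine similarity between two MS2 spectra
#'
#' Fragments are paired greedily one-to-one within `frag_tol` Da (closest
#' pairs first); the score is the normalized dot product of square-root
#' intensities over matched pairs. The score lies in [0, 1], is symmetric in
#' its arguments and is invariant to global intensity scaling of either
#' spectrum.
#'
#' @param query,reference `ms2_spectrum` objects.
#' @param frag_tol fragment matching tolerance in Da (default 0.01).
#' @return Similarity score in [0, 1].
#' @export
cosine_match <- function(query, reference, frag_tol = 0.01) {
  stopifnot(inherits(query, "ms2_spectrum"), inherits(reference, "ms2_spectrum"))
  if (frag_tol <= 0) stop("frag_tol must be > 0")
  qw <- sqrt(query$intensity)
  rw <- sqrt(reference$intensity)
  # all candidate pairs within tolerance, closest-in-mass first, one-to-one
  d <- abs(outer(query$mz, reference$mz, "-"))
  cand <- which(d <= frag_tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_q <- logical(length(qw)); used_r <- logical(length(rw))
  dot <- 0
  for (j in seq_len(nrow(cand))) {
    qi <- cand[j, 1L]; ri <- cand[j, 2L]
    if (used_q[qi] || used_r[ri]) next
    used_q[qi] <- TRUE; used_r[ri] <- TRUE
    dot <- dot + qw[qi] * rw[ri]
  }
  denom <- sqrt(sum(qw^2)) * sqrt(sum(rw^2))
  if (denom == 0) return(0)
  min(1, dot / denom)
}

#' Annotate features against a spectral library
#'
#' For each feature carrying an MS2 spectrum, candidate library entries are
#' those whose precursor m/z lies within `precursor_tol` ppm; the
#' best-scoring candidate by [cosine_match()] is reported and accepted when
#' its score reaches `score_min`. Features without MS2 or without any
#' candidate remain unannotated ("m/z features").
#'
#' @param features data.frame with columns `feature_id`, `mz` and a
#'   list-column `ms2` of `ms2_spectrum` objects (or NULL entries).
#' @param library a spectral library as returned by [read_msp()]: data.frame
#'   with columns `name`, `formula` (Hill string), `mz` and list-column
#'   `ms2`.
#' @param precursor_tol precursor tolerance in ppm (default 10).
#' @param frag_tol fragment tolerance in Da (default 0.01).
#' @param score_min acceptance threshold on the cosine score (default 0.7).
#' @return data.frame with one row per feature that had MS2 and at least one
#'   precursor-matched candidate: `feature_id`, `library_name`, `score`,
#'   `accepted`.
#' @export
annotate_features <- function(features, library, precursor_tol = 10,
                              frag_tol = 0.01, score_min = 0.7) {
  stopifnot(is.data.frame(library), nrow(library) > 0)
  out <- list()
  for (i in seq_len(nrow(features))) {
    sp <- features$ms2[[i]]
    if (is.null(sp)) next
    fmz <- features$mz[i]
    cand <- which(abs(library$mz - fmz) <= precursor_tol * 1e-6 * fmz)
    if (length(cand) == 0L) next
    scores <- vapply(cand, function(j) cosine_match(sp, library$ms2[[j]], frag_tol),
                     numeric(1))
    best <- which.max(scores)
    out[[length(out) + 1L]] <- data.frame(
      feature_id = features$feature_id[i],
      library_name = library$name[cand[best]],
      score = scores[best],
      accepted = scores[best] >= score_min,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(feature_id = character(), library_name = character(),
                      score = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a spectral library from MSP format
#'
#' Parses the plain-text NIST MSP dialect written by [write_msp()]: records
#' with `NAME:`, `PRECURSORMZ:`, `FORMULA:`, `Num Peaks:` headers followed by
#' one `m/z intensity` pair per line, blank-line separated.
#'
#' @param path file path.
#' @return data.frame with columns `name`, `formula`, `mz` and list-column
#'   `ms2`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^NAME:", lines, ignore.case = TRUE)))
  recs <- recs[names(recs) != "0"]
  parse_one <- function(rl) {
    get <- function(key) {
      hit <- grep(paste0("^", key, ":"), rl, ignore.case = TRUE, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      trimws(sub("^[^:]+:", "", hit[1]))
    }
    name <- get("NAME")
    prec <- as.numeric(get("PRECURSORMZ"))
    form <- get("FORMULA")
    npk <- as.integer(get("Num Peaks"))
    peak_lines <- grep("^[[:space:]]*[0-9.]+[[:space:]]+[0-9.eE+-]+[[:space:]]*$",
                       rl, value = TRUE)
    pk <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[[:space:]]+"),
                                function(p) as.numeric(p[1:2])))
    if (!is.na(npk) && nrow(pk) != npk)
      warning("record '", name, "': Num Peaks header (", npk,
              ") disagrees with ", nrow(pk), " peak lines")
    list(name = name, formula = form, mz = prec,
         ms2 = ms2_spectrum(prec, pk[, 1], pk[, 2]))
  }
  parsed <- lapply(recs, parse_one)
  out <- data.frame(
    name = vapply(parsed, `[[`, character(1), "name"),
    formula = vapply(parsed, `[[`, character(1), "formula"),
    mz = vapply(parsed, `[[`, numeric(1), "mz"),
    stringsAsFactors = FALSE)
  out$ms2 <- lapply(parsed, `[[`, "ms2")
  rownames(out) <- NULL
  out
}

#' Write a spectral library to MSP format
#'
#' @param library data.frame as returned by [read_msp()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(library))) {
    sp <- library$ms2[[i]]
    writeLines(c(
      paste0("NAME: ", library$name[i]),
      paste0("PRECURSORMZ: ", sprintf("%.6f", library$mz[i])),
      paste0("FORMULA: ", library$formula[i]),
      "IONMODE: Negative",
      paste0("Num Peaks: ", length(sp$mz)),
      paste(sprintf("%.6f", sp$mz), sprintf("%.4f", sp$intensity)),
      ""), con)
  }
  invisible(path)
}
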