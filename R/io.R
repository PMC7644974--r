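# Plain-text readers and writers for the pipeline's tables.

#' Write / read an LC-MS feature table
#'
#' Tab-separated with header `sample_id, feature_id, mz, rt_min, area`.
#' MS2 spectra are not carried by this format; use [write_msp()] for
#' spectra.
#'
#' @param features data.frame with the columns above (a list-column `ms2`
#'   is dropped on write).
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_table <- function(features, path) {
  df <- features[, c("sample_id", "feature_id", "mz", "rt_min", "area")]
  df$mz <- sprintf("%.6f", df$mz)
  df$rt_min <- sprintf("%.4f", df$rt_min)
  df$area <- sprintf("%.4f", df$area)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "feature_id", "mz", "rt_min", "area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write / read a study-design table
#'
#' Tab-separated with header `sample_id, condition, replicate`.
#'
#' @param design data.frame.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample_id", "condition", "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "condition", "replicate"), names(df))
  if (length(miss))
    stop("design table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write / read an OD720 time series
#'
#' Comma-separated with header `time_h, od720`.
#'
#' @param series data.frame with `time_h`, `od720`.
#' @param path file path.
#' @export
write_od_series <- function(series, path) {
  utils::write.csv(data.frame(time_h = series$time_h,
                              od720 = sprintf("%.8g", series$od720)),
                   path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_od_series
#' @export
read_od_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time_h", "od720"), names(df))
  if (length(miss))
    stop("OD series '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write an abundance matrix with its design header block
#'
#' Tab-separated: comment lines `#design sample condition replicate` carry
#' the design, then a header row `row_id, mz, rt_min, n_carbon` followed by
#' one column per sample.
#'
#' @param am an `abundance_matrix`.
#' @param path file path.
#' @export
write_abundance_matrix <- function(am, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- am$design
  writeLines(sprintf("#design\t%s\t%s\t%s",
                     d$sample_id, d$condition, d$replicate), con)
  df <- cbind(am$features[, c("row_id", "mz", "rt_min", "n_carbon")],
              as.data.frame(am$ratios))
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix written by [write_abundance_matrix()]
#'
#' @param path file path.
#' @return An `abundance_matrix`.
#' @export
read_abundance_matrix <- function(path) {
  lines <- readLines(path)
  dlines <- grep("^#design\t", lines, value = TRUE)
  parts <- do.call(rbind, strsplit(sub("^#design\t", "", dlines), "\t"))
  design <- data.frame(sample_id = parts[, 1], condition = parts[, 2],
                       replicate = as.integer(parts[, 3]),
                       stringsAsFactors = FALSE)
  df <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, c("row_id", "mz", "rt_min", "n_carbon")]
  ratios <- as.matrix(df[, design$sample_id, drop = FALSE])
  rownames(ratios) <- meta$row_id
  structure(list(ratios = ratios, features = meta, design = design),
            class = "abundance_matrix")
}
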