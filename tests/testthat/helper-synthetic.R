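# Shared fixtures: all built in code, nothing read from disk.

# design table for ad-hoc matrices: n replicates per condition
make_design <- function(conditions = c("M", "MD", "E", "MN", "CL"), n = 3L) {
  data.frame(
    sample_id = paste0(rep(conditions, each = n), "_", rep(seq_len(n),
                                                           length(conditions))),
    condition = rep(conditions, each = n),
    replicate = rep(seq_len(n), length(conditions)),
    stringsAsFactors = FALSE)
}

# ratio matrix with given per-condition true means and lognormal noise
make_ratio_matrix <- function(true_means, design, cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_row <- nrow(true_means)
  mat <- sapply(design$sample_id, function(s) {
    cc <- design$condition[design$sample_id == s]
    mu <- true_means[, cc]
    if (cv > 0) mu <- mu * exp(rnorm(n_row, 0, sqrt(log(1 + cv^2)))) else mu
  })
  mat <- matrix(mat, nrow = n_row,
                dimnames = list(rownames(true_means), design$sample_id))
  mat
}

# map rows of a recovered abundance matrix back to library metabolites
# by (m/z, RT); NA where no library compound matches
map_rows_to_library <- function(am, library, ppm_tol = 10, rt_tol = 0.1) {
  vapply(seq_len(nrow(am$features)), function(i) {
    hit <- which(abs(library$mz - am$features$mz[i]) <=
                   ppm_tol * 1e-6 * am$features$mz[i] &
                   abs(library$rt_min - am$features$rt_min[i]) <= rt_tol)
    if (length(hit) == 1L) library$name[hit] else NA_character_
  }, character(1))
}
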