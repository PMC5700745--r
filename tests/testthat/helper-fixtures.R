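# Small in-code fixtures shared across test files.

tiny_count_matrix <- function() {
  counts <- matrix(c(10, 0, 5,
                     20, 2, 5,
                     0, 4, 8,
                     1, 3, 9),
                   nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("F_1", "F_2", "L_1", "L_2")))
  count_matrix(counts,
               gene_lengths = c(gA = 1000, gB = 2000, gC = 500),
               sample_organ = c(F_1 = "F", F_2 = "F",
                                L_1 = "L", L_2 = "L"),
               sample_replicate = c(F_1 = 1, F_2 = 2, L_1 = 1, L_2 = 2))
}

write_fixture_files <- function(dir, cm = tiny_count_matrix()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                lengths = file.path(dir, "lengths.tsv"))
  write_count_matrix(cm, paths$counts, paths$samples, paths$lengths)
  paths
}

# ExpressionMatrix from a plain matrix; columns get organ labels `organs`
# (recycled per replicate) and replicate indices within organ.
make_expr <- function(values, organs) {
  stopifnot(ncol(values) == length(organs))
  if (is.null(colnames(values)))
    colnames(values) <- paste0(organs, "_",
                               stats::ave(seq_along(organs), organs,
                                          FUN = seq_along))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  ids <- colnames(values)
  expression_matrix(values,
                    sample_organ = stats::setNames(organs, ids),
                    sample_replicate = stats::setNames(
                      stats::ave(seq_along(organs), organs, FUN = seq_along),
                      ids))
}

# brute-force double count over noise points; the independent oracle for
# deg_probability
brute_probability <- function(m, d, m_star, d_star) {
  cnt <- 0L
  for (i in seq_along(m_star)) {
    if (abs(m_star[i]) < abs(m) && d_star[i] < d) cnt <- cnt + 1L
  }
  cnt / length(m_star)
}

# exact hypergeometric upper tail by explicit enumeration of the support
enum_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}
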