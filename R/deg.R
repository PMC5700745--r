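# Noise-distribution differential-expression screen. For each organ pair,
# within-organ replicate variability yields an empirical null of (M*, D*)
# points; a gene's signal (m, d), computed from replicate-mean RPKM, is
# scored by the fraction of null points it strictly dominates in both
# coordinates. Genes with P > 0.8 and |M| > 2 are called differentially
# expressed.

#' M and D statistics for a pair of expression values
#'
#' `M = log2(x1 / x2)` and `D = |x1 - x2|`. Zero expression is replaced by
#' `zero_substitute` (default 0.001) inside the log ratio only, guarding
#' against `log(0)`; D is computed from the original values unless
#' `substitute_in_d` is set (substituting inside D would add a spurious
#' offset).
#'
#' @param x1,x2 Non-negative expression values (vectorized).
#' @param zero_substitute Positive stand-in for zeros inside the ratio.
#' @param substitute_in_d Also apply the substitution inside D.
#' @return List with numeric vectors `m` and `d`.
#' @export
compute_md <- function(x1, x2, zero_substitute = 0.001,
                       substitute_in_d = FALSE) {
  if (any(x1 < 0, na.rm = TRUE) || any(x2 < 0, na.rm = TRUE))
    stop("domain error: negative expression value")
  stopifnot(zero_substitute > 0)
  x1s <- ifelse(x1 == 0, zero_substitute, x1)
  x2s <- ifelse(x2 == 0, zero_substitute, x2)
  list(m = log2(x1s / x2s),
       d = if (substitute_in_d) abs(x1s - x2s) else abs(x1 - x2))
}

#' Empirical noise distribution from within-organ replicate pairs
#'
#' For every unordered pair of replicates within the same organ, over both
#' organs of the comparison, the per-gene (M*, D*) values are computed and
#' pooled. With `r1` and `r2` replicates the pool holds
#' `n_genes * (choose(r1,2) + choose(r2,2))` points. Replicates are ordered
#' by replicate index inside each pair; since the null enters probability
#' queries only through |M*| and D*, the ordering convention does not affect
#' results.
#'
#' @param expr An [expression_matrix()].
#' @param organ_pair Character vector of two organ labels.
#' @param config A [pipeline_config()].
#' @return An object of class `NoiseDistribution`: list with `m_star`,
#'   `d_star`, `n_points`.
#' @export
build_noise <- function(expr, organ_pair, config = pipeline_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(organ_pair) == 2)
  m_star <- list()
  d_star <- list()
  for (o in organ_pair) {
    cols <- organ_samples(expr, o)
    if (length(cols) < 2)
      stop("insufficient replicates: organ '", o,
           "' has fewer than 2 replicate samples")
    idx <- utils::combn(seq_along(cols), 2)
    for (j in seq_len(ncol(idx))) {
      md <- compute_md(expr$values[, cols[idx[1, j]]],
                       expr$values[, cols[idx[2, j]]],
                       config$zero_substitute, config$substitute_in_d)
      m_star[[length(m_star) + 1L]] <- md$m
      d_star[[length(d_star) + 1L]] <- md$d
    }
  }
  m_star <- unlist(m_star, use.names = FALSE)
  d_star <- unlist(d_star, use.names = FALSE)
  structure(list(m_star = m_star, d_star = d_star,
                 n_points = length(m_star)),
            class = "NoiseDistribution")
}

#' @export
print.NoiseDistribution <- function(x, ...) {
  cat(sprintf("NoiseDistribution: %d pooled (M*, D*) points\n", x$n_points))
  invisible(x)
}

# internal: sample ids of an organ ordered by replicate index
organ_samples <- function(expr, organ) {
  org <- expr$sample_organ[colnames(expr$values)]
  cols <- names(org)[org == organ]
  cols[order(expr$sample_replicate[cols])]
}

#' Per-gene signal statistics for an organ pair
#'
#' Applies [compute_md()] to the replicate-mean expression of each organ;
#' the first organ of the pair is the numerator of the log ratio.
#'
#' @inheritParams build_noise
#' @return data.frame with columns `gene`, `m`, `d`.
#' @export
signal_md <- function(expr, organ_pair, config = pipeline_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(organ_pair) == 2)
  means <- organ_means(expr, organ_pair)
  md <- compute_md(means[, 1], means[, 2],
                   config$zero_substitute, config$substitute_in_d)
  data.frame(gene = rownames(means), m = unname(md$m), d = unname(md$d),
             stringsAsFactors = FALSE)
}

#' Probability of differential expression against a noise distribution
#'
#' `P = #\{(M*, D*) : |M*| < |m| and D* < d\} / n_points`, with strict
#' inequalities in both coordinates, so `m = 0` or `d = 0` gives exactly 0
#' and a query dominating every noise point gives exactly 1. Values are
#' always multiples of `1 / n_points`.
#'
#' @param m,d Signal statistics (vectorized, equal length).
#' @param noise A [build_noise()] result.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
deg_probability <- function(m, d, noise) {
  stopifnot(inherits(noise, "NoiseDistribution"))
  if (noise$n_points < 1)
    stop("state error: empty noise distribution")
  stopifnot(length(m) == length(d))
  am_star <- abs(noise$m_star)
  d_star <- noise$d_star
  am <- abs(m)
  vapply(seq_along(am),
         function(i) sum(am_star < am[i] & d_star < d[i]),
         numeric(1)) / noise$n_points
}

#' Call differential expression from (m, d, p) records
#'
#' The call rule: `up` when `p > p_threshold` and `m > m_threshold`; `down`
#' when `p > p_threshold` and `-m > m_threshold`; otherwise `not_de`. Both
#' inequalities are strict. Direction is relative to the first organ of the
#' pair (`up` = higher there). Setting `config$signed_m` restricts calls to
#' the signed rule (`m > m_threshold` only).
#'
#' @param records data.frame with columns `gene`, `m`, `d`, `p`.
#' @param config A [pipeline_config()].
#' @return The data.frame with an added `call` column
#'   (`up` / `down` / `not_de`).
#' @export
call_degs <- function(records, config = pipeline_config()) {
  stopifnot(all(c("gene", "m", "p") %in% colnames(records)))
  if (any(records$p < 0 | records$p > 1))
    stop("p must lie in [0, 1]")
  de <- records$p > config$p_threshold
  up <- de & records$m > config$m_threshold
  down <- if (config$signed_m) rep(FALSE, nrow(records))
          else de & -records$m > config$m_threshold
  records$call <- ifelse(up, "up", ifelse(down, "down", "not_de"))
  records
}

#' Screen all organ pairs for differentially expressed genes
#'
#' Runs the full noise-distribution screen per organ pair: pool the
#' within-organ replicate null, compute per-gene signal from replicate
#' means, score each gene against the null and apply the call thresholds.
#' Genes with zero expression in every sample of both organs come out with
#' `m = 0, d = 0, p = 0` and call `not_de`, so the output row count always
#' equals the input gene count.
#'
#' @param expr An [expression_matrix()].
#' @param organ_pairs List of 2-vectors of organ labels; default all
#'   unordered pairs of the organs present, in order of first appearance.
#' @param config A [pipeline_config()].
#' @return Named list (keys like `"F-vs-L"`) of data.frames with columns
#'   `gene`, `m`, `d`, `p`, `call`; each carries its pair in
#'   `attr(, "organ_pair")`.
#' @export
pairwise_screen <- function(expr, organ_pairs = NULL,
                            config = pipeline_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(organ_pairs)) {
    organs <- unique(unname(expr$sample_organ[colnames(expr$values)]))
    cmb <- utils::combn(organs, 2)
    organ_pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  out <- lapply(organ_pairs, function(pr) {
    noise <- build_noise(expr, pr, config)
    sig <- signal_md(expr, pr, config)
    sig$p <- deg_probability(sig$m, sig$d, noise)
    res <- call_degs(sig, config)
    attr(res, "organ_pair") <- pr
    res
  })
  names(out) <- vapply(organ_pairs,
                       function(pr) pair_key(pr[1], pr[2]), character(1))
  out
}
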