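# Hypergeometric over-representation analysis of a DEG set against flat
# gene-set annotations, with multiple-testing correction.

#' Upper-tail hypergeometric test for term over-representation
#'
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing the `n` DEGs
#' from a background of `N` genes of which `K` carry the term, the
#' probability of seeing `k` or more annotated DEGs by chance. Vectorized
#' over its arguments.
#'
#' @param k Annotated DEGs observed.
#' @param K Background genes carrying the term.
#' @param n DEG-set size within the background.
#' @param N Background size.
#' @return Numeric vector of upper-tail p-values.
#' @export
hypergeom_test <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  k <- args[, 1]; K <- args[, 2]; n <- args[, 3]; N <- args[, 4]
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)))
    stop("parameter error: inconsistent hypergeometric counts")
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Term over-representation analysis of a DEG set
#'
#' Every term in the map is tested (terms with no annotated DEG are kept
#' with `p = 1`), p-values are corrected across all tested terms
#' (Benjamini-Hochberg by default; `config$adjust_method` accepts any
#' [stats::p.adjust()] method, e.g. `"bonferroni"`), and a term is
#' significant when its corrected p-value is at most `config$enrich_alpha`.
#' The background is the term map's measured universe; DEGs outside it are
#' ignored.
#'
#' @param deg_set Character vector of DEG ids.
#' @param terms A [term_map()].
#' @param config A [pipeline_config()].
#' @return data.frame sorted by `p_adj` then `term_id`, with columns
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
enrich <- function(deg_set, terms, config = pipeline_config()) {
  stopifnot(inherits(terms, "TermMap"))
  bg <- terms$background
  if (!length(bg)) stop("parameter error: empty background")
  deg <- intersect(unique(as.character(deg_set)), bg)
  if (!length(deg))
    stop("parameter error: DEG set does not intersect the background")
  N <- length(bg)
  n <- length(deg)
  K <- vapply(terms$term_genes, length, integer(1))
  k <- vapply(terms$term_genes,
              function(g) length(intersect(g, deg)), integer(1))
  p_raw <- hypergeom_test(k, K, n, N)
  p_adj <- stats::p.adjust(p_raw, method = config$adjust_method)
  out <- data.frame(term_id = terms$term_ids,
                    term_name = unname(terms$term_names[terms$term_ids]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p_raw = unname(p_raw), p_adj = unname(p_adj),
                    significant = unname(p_adj <= config$enrich_alpha),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$term_id), ]
  rownames(out) <- NULL
  out
}
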