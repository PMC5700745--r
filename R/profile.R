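# Organ-level summaries: uniquely expressed genes, up/down tallies per
# comparison and the DEGs shared by all three comparisons.

#' Find organ-unique genes
#'
#' A gene is unique to an organ when its replicate-mean expression is
#' exactly zero in both other organs and greater than zero there. The
#' comparison is exact (no epsilon): the RPKM of an all-zero count row is
#' exactly zero. All-zero genes belong to no organ.
#'
#' @param expr An [expression_matrix()] over exactly three organs.
#' @param organs Optional 3-vector of organ labels; default the organs
#'   present, in order of first appearance.
#' @return Named list mapping each organ to a character vector of unique
#'   gene ids (pairwise disjoint by construction).
#' @export
find_unique_genes <- function(expr, organs = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(organs))
    organs <- unique(unname(expr$sample_organ[colnames(expr$values)]))
  if (length(organs) != 3)
    stop("parameter error: exactly three organs are required, got ",
         length(organs))
  means <- organ_means(expr, organs)
  out <- lapply(organs, function(o) {
    others <- setdiff(organs, o)
    sel <- means[, o] > 0 &
      rowSums(means[, others, drop = FALSE] == 0) == length(others)
    rownames(means)[sel]
  })
  stats::setNames(out, organs)
}

#' Summarize organ-unique gene sets
#'
#' @param unique_genes Result of [find_unique_genes()].
#' @return data.frame with columns `organ`, `n_unique`.
#' @export
organ_summary <- function(unique_genes) {
  data.frame(organ = names(unique_genes),
             n_unique = unname(lengths(unique_genes)),
             stringsAsFactors = FALSE)
}

#' Tally up- and down-regulated calls
#'
#' @param records One screen data.frame (from [pairwise_screen()]) or a
#'   named list of them.
#' @return For a single data.frame, a one-row data.frame with `n_up`,
#'   `n_down`; for a list, one row per comparison with a `pair` column.
#' @export
updown_tally <- function(records) {
  one <- function(df) data.frame(n_up = sum(df$call == "up"),
                                 n_down = sum(df$call == "down"))
  if (is.data.frame(records)) return(one(records))
  out <- do.call(rbind, lapply(records, one))
  cbind(data.frame(pair = names(records), stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Genes called differentially expressed in every comparison
#'
#' Intersection of the called DEG sets (either direction) across all
#' supplied comparisons; invariant to their order.
#'
#' @param screens Named list of screen data.frames from
#'   [pairwise_screen()].
#' @return Sorted character vector of shared DEG ids.
#' @export
common_degs <- function(screens) {
  stopifnot(length(screens) >= 1)
  sets <- lapply(screens, function(df) df$gene[df$call != "not_de"])
  sort(Reduce(intersect, sets))
}
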