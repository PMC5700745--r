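# Regulator-to-target co-expression network: Pearson correlation over the
# shared replicate samples with a joint |r| / p-value retention rule, a TF
# family breakdown of the retained regulators and hierarchical clustering
# for heatmap row ordering.

#' Pearson correlation with a t-distribution significance test
#'
#' Product-moment correlation of two equal-length profiles and the
#' two-sided p-value of `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, the standard significance test for a Pearson
#' coefficient.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return List with elements `r` and `p`.
#' @export
pcc_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("profiles must have equal length")
  if (n < 3) stop("at least 3 samples are required")
  cx <- x - mean(x)
  cy <- y - mean(y)
  vx <- sum(cx^2)
  vy <- sum(cy^2)
  if (vx == 0 || vy == 0)
    stop("undefined correlation: constant profile")
  r <- sum(cx * cy) / sqrt(vx * vy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) >= 1) 0
       else 2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2,
                          lower.tail = FALSE)
  list(r = r, p = p)
}

#' Build the regulator-target co-expression network
#'
#' Tests every regulator x target pair over their shared samples and
#' retains an edge when `|r| >= config$pcc_threshold` (non-strict, so an
#' exact 0.95 passes) and `p < config$pcc_alpha` (strict). The sign of `r`
#' is preserved on the edge; constant profiles are skipped with a warning.
#' Correlations are computed over all replicate columns, not organ means,
#' so the significance test has usable degrees of freedom.
#'
#' @param tf_expr Numeric matrix of regulator profiles (TFs x samples).
#' @param target_expr Numeric matrix of target profiles (genes x samples)
#'   sharing the sample axis.
#' @param tf_table Optional data.frame (`gene`, `family`) annotating the
#'   regulators; families are joined onto retained edges.
#' @param config A [pipeline_config()].
#' @return data.frame with columns `regulator`, `target`, `r`, `p`,
#'   `family`, one row per retained edge.
#' @export
build_network <- function(tf_expr, target_expr, tf_table = NULL,
                          config = pipeline_config()) {
  if (!is.matrix(tf_expr)) tf_expr <- as.matrix(tf_expr)
  if (!is.matrix(target_expr)) target_expr <- as.matrix(target_expr)
  shared <- intersect(colnames(tf_expr), colnames(target_expr))
  if (!length(shared))
    stop("consistency error: no shared samples between the two matrices")
  tf_expr <- tf_expr[, shared, drop = FALSE]
  target_expr <- target_expr[, shared, drop = FALSE]
  tfs <- rownames(tf_expr)
  targets <- rownames(target_expr)
  rows <- vector("list", 0L)
  skipped <- character(0)
  for (i in seq_along(tfs)) {
    for (j in seq_along(targets)) {
      res <- tryCatch(pcc_test(tf_expr[i, ], target_expr[j, ]),
                      error = function(e) NULL)
      if (is.null(res)) {
        skipped <- c(skipped, paste0(tfs[i], "~", targets[j]))
        next
      }
      if (abs(res$r) >= config$pcc_threshold && res$p < config$pcc_alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          regulator = tfs[i], target = targets[j],
          r = res$r, p = res$p, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped pair(s) with a constant profile: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ...")
  edges <- if (length(rows)) do.call(rbind, rows)
           else data.frame(regulator = character(0), target = character(0),
                           r = numeric(0), p = numeric(0),
                           stringsAsFactors = FALSE)
  edges$family <- if (!is.null(tf_table))
    tf_table$family[match(edges$regulator, tf_table$gene)]
  else NA_character_
  rownames(edges) <- NULL
  edges
}

#' Family breakdown of network regulators
#'
#' Counts the TF families of the distinct regulators in an edge list (or of
#' a plain gene vector), sorted by descending count with ties broken
#' alphabetically.
#'
#' @param x Edge data.frame with a `regulator` column, or a character
#'   vector of TF gene ids.
#' @param tf_table data.frame (`gene`, `family`) covering every queried
#'   gene.
#' @return data.frame with columns `family`, `n`.
#' @export
family_distribution <- function(x, tf_table) {
  genes <- if (is.data.frame(x)) unique(x$regulator) else unique(x)
  if (!length(genes))
    return(data.frame(family = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  missing <- setdiff(genes, tf_table$gene)
  if (length(missing))
    stop("annotation error: gene(s) absent from the TF table: ",
         paste(missing, collapse = ", "))
  fam <- tf_table$family[match(genes, tf_table$gene)]
  tab <- table(fam)
  out <- data.frame(family = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$family), ]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering order for heatmap rows
#'
#' Agglomerative clustering of expression profiles with correlation
#' distance (1 - PCC) and average linkage by default; both are
#' configurable. The leaf order is the deterministic [stats::hclust()]
#' ordering.
#'
#' @param mat Numeric matrix of profiles (rows are clustered), `>= 2` rows.
#' @param distance `"correlation"` (1 - PCC) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `order` (row indices), `labels` (row names in leaf
#'   order), `merge`, `height` and the full `hclust` object.
#' @export
hcluster_order <- function(mat, distance = c("correlation", "euclidean"),
                           linkage = "average") {
  distance <- match.arg(distance)
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("at least 2 rows are required")
  if (distance == "correlation") {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0))
      stop("preprocessing error: constant row(s) under correlation ",
           "distance (", paste(rownames(mat)[sds == 0], collapse = ", "),
           "); use distance = \"euclidean\"")
    d <- stats::as.dist(1 - stats::cor(t(mat)))
  } else {
    d <- stats::dist(mat)
  }
  hc <- stats::hclust(d, method = linkage)
  list(order = hc$order,
       labels = rownames(mat)[hc$order],
       merge = hc$merge,
       height = hc$height,
       hclust = hc)
}
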