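# Expression quantification: RPKM from read counts, and 2^-ddCt relative
# quantification of qPCR Ct values for concordance checks against RNA-seq.

#' RPKM normalization of a count matrix
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM(g, s) = 10^9 \cdot C_{gs} / (N_s \cdot L_g)}
#' where `C` is the read count, `N_s` the sample's total mapped reads
#' (column sum of the count matrix) and `L_g` the gene length in
#' nucleotides. The unit removes the influence of transcript length and
#' sequencing depth, so columns scaled by any positive constant give
#' identical RPKM.
#'
#' @param counts A [count_matrix()].
#' @return An [expression_matrix()] of RPKM values on the same axes.
#' @export
rpkm <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  totals <- colSums(counts$counts)
  if (any(totals == 0))
    stop("computation error: zero total counts in sample(s): ",
         paste(colnames(counts$counts)[totals == 0], collapse = ", "))
  len <- counts$gene_lengths[rownames(counts$counts)]
  vals <- sweep(counts$counts / len, 2, totals, "/") * 1e9
  expression_matrix(vals, counts$sample_organ, counts$sample_replicate)
}

#' Construct a validated qPCR Ct table
#'
#' @param x data.frame with columns `sample`, `organ`, `gene`, `ct`
#'   (threshold cycles).
#' @param reference_gene Internal-control gene (e.g. actin); must be
#'   measured in every sample.
#' @param calibrator_organ Organ used as the relative-quantification
#'   baseline.
#' @return An object of class `QpcrTable` (the data.frame with the two
#'   designations stored as attributes).
#' @export
qpcr_table <- function(x, reference_gene, calibrator_organ) {
  need <- c("sample", "organ", "gene", "ct")
  if (length(setdiff(need, colnames(x))))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  if (anyNA(x$ct) || any(!is.finite(x$ct)))
    stop("data error: non-finite Ct value(s)")
  samples <- unique(x$sample)
  has_ref <- samples %in% x$sample[x$gene == reference_gene]
  if (!all(has_ref))
    stop("data error: reference gene '", reference_gene,
         "' missing in sample(s): ",
         paste(samples[!has_ref], collapse = ", "))
  if (!calibrator_organ %in% x$organ)
    stop("data error: calibrator organ '", calibrator_organ,
         "' absent from the table")
  structure(x[, need], class = c("QpcrTable", "data.frame"),
            reference_gene = reference_gene,
            calibrator_organ = calibrator_organ)
}

#' @rdname qpcr_table
#' @param path Ct TSV with columns sample, organ, gene, ct.
#' @export
read_qpcr_table <- function(path, reference_gene, calibrator_organ) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$ct <- as.numeric(df$ct)
  qpcr_table(df, reference_gene, calibrator_organ)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, each gene's Ct is normalized to the reference gene
#' (dCt = Ct_gene - Ct_reference); dCt is averaged over the replicates of
#' each organ, referenced to the calibrator organ
#' (ddCt = dCt_organ - dCt_calibrator) and converted to a fold level
#' RQ = 2^-ddCt. The calibrator organ's RQ is exactly 1 for every gene.
#'
#' @param x A [qpcr_table()].
#' @return data.frame with columns `gene`, `organ`, `delta_ct`,
#'   `delta_delta_ct`, `rq` (reference gene excluded).
#' @export
ddct_rq <- function(x) {
  stopifnot(inherits(x, "QpcrTable"))
  ref <- attr(x, "reference_gene")
  cal <- attr(x, "calibrator_organ")
  ref_rows <- x$gene == ref
  ref_ct <- tapply(x$ct[ref_rows], x$sample[ref_rows], mean)
  dat <- x[!ref_rows, , drop = FALSE]
  dct_row <- dat$ct - as.numeric(ref_ct[dat$sample])
  agg <- stats::aggregate(dct_row,
                          by = list(gene = dat$gene, organ = dat$organ),
                          FUN = mean)
  names(agg)[3] <- "delta_ct"
  cal_rows <- agg$organ == cal
  cal_dct <- stats::setNames(agg$delta_ct[cal_rows], agg$gene[cal_rows])
  missing_cal <- setdiff(unique(agg$gene), names(cal_dct))
  if (length(missing_cal))
    stop("data error: gene(s) not measured in the calibrator organ: ",
         paste(missing_cal, collapse = ", "))
  agg$delta_delta_ct <- agg$delta_ct - as.numeric(cal_dct[agg$gene])
  agg$rq <- 2^(-agg$delta_delta_ct)
  agg <- agg[order(agg$gene, agg$organ), ]
  rownames(agg) <- NULL
  agg
}

#' Rank concordance between qPCR and RNA-seq expression across organs
#'
#' For each gene, the Spearman rank correlation between its qPCR RQ values
#' and its replicate-mean RPKM values over the shared organs. A pattern
#' (rank) statistic is used because qPCR validation asks whether the two
#' platforms order the organs the same way, not whether magnitudes agree.
#'
#' @param rq data.frame from [ddct_rq()].
#' @param expr An [expression_matrix()] of RPKM values.
#' @param genes Genes to evaluate; must be present in both inputs.
#' @return Named numeric vector of per-gene Spearman correlations; `NA` with
#'   a warning when fewer than 3 shared organs make the correlation
#'   undefined.
#' @export
expression_concordance <- function(rq, expr, genes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  missing_expr <- setdiff(genes, rownames(expr$values))
  if (length(missing_expr))
    stop("gene(s) absent from the expression matrix: ",
         paste(missing_expr, collapse = ", "))
  missing_rq <- setdiff(genes, rq$gene)
  if (length(missing_rq))
    stop("gene(s) absent from the RQ table: ",
         paste(missing_rq, collapse = ", "))
  organs <- intersect(unique(rq$organ),
                      unique(unname(expr$sample_organ[colnames(expr$values)])))
  if (length(organs) < 3) {
    warning("fewer than 3 shared organs; concordance undefined")
    return(stats::setNames(rep(NA_real_, length(genes)), genes))
  }
  means <- organ_means(expr, organs)
  out <- vapply(genes, function(g) {
    sub <- rq[rq$gene == g, ]
    rq_vec <- stats::setNames(sub$rq, sub$organ)[organs]
    if (anyNA(rq_vec)) return(NA_real_)
    suppressWarnings(stats::cor(rq_vec, means[g, organs],
                                method = "spearman"))
  }, numeric(1))
  out
}
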