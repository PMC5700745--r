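#' Construct a validated count matrix
#'
#' A `CountMatrix` bundles a gene-by-sample matrix of read counts with the
#' per-gene transcript lengths and the sample metadata (organ and replicate
#' index) that every downstream stage needs.
#'
#' @param counts Numeric matrix of non-negative integer read counts with gene
#'   ids as row names and sample ids as column names.
#' @param gene_lengths Named vector of positive integer transcript lengths in
#'   nucleotides, one per gene.
#' @param sample_organ Named character vector mapping each sample id to its
#'   organ label.
#' @param sample_replicate Named integer vector mapping each sample id to its
#'   replicate index within the organ.
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `gene_lengths`, `sample_organ` and `sample_replicate`.
#' @seealso [read_count_matrix()], [rpkm()], [simulate_counts()]
#' @export
count_matrix <- function(counts, gene_lengths, sample_organ, sample_replicate) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  gene_lengths <- stats::setNames(as.numeric(gene_lengths),
                                  names(gene_lengths))
  sample_replicate <- stats::setNames(as.integer(sample_replicate),
                                      names(sample_replicate))
  obj <- structure(
    list(counts = counts,
         gene_lengths = gene_lengths,
         sample_organ = sample_organ,
         sample_replicate = sample_replicate),
    class = "CountMatrix")
  validate_count_matrix(obj)
  obj
}

#' Validate the invariants of a CountMatrix
#'
#' Checks identifier uniqueness, matrix shape, non-negative integer counts,
#' positive lengths and complete sample metadata. Called by [count_matrix()]
#' and [read_count_matrix()]; exported so the same checks back
#' [validate_inputs()].
#'
#' @param x A `CountMatrix`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_count_matrix <- function(x) {
  counts <- x$counts
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("count matrix must carry gene row names and sample column names")
  if (anyDuplicated(gene_ids))
    stop("format error: duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("format error: duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    stop("format error: counts must be finite numbers")
  if (any(counts < 0))
    stop("format error: negative count(s) present")
  if (any(counts != round(counts)))
    stop("format error: non-integer count(s) present")
  len <- x$gene_lengths
  if (is.null(names(len)) || !setequal(names(len), gene_ids) ||
      length(len) != length(gene_ids))
    stop("gene lengths must be named and cover every gene exactly once")
  if (anyNA(len) || any(len <= 0) || any(len != round(len)))
    stop("format error: gene lengths must be positive integers")
  org <- x$sample_organ
  missing_org <- setdiff(sample_ids, names(org))
  if (length(missing_org))
    stop("consistency error: sample(s) missing from sample sheet: ",
         paste(missing_org, collapse = ", "))
  if (anyNA(org[sample_ids]) || any(!nzchar(org[sample_ids])))
    stop("consistency error: every sample needs a non-empty organ label")
  rep_idx <- x$sample_replicate
  missing_rep <- setdiff(sample_ids, names(rep_idx))
  if (length(missing_rep))
    stop("consistency error: sample(s) missing a replicate index: ",
         paste(missing_rep, collapse = ", "))
  invisible(x)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$sample_organ)),
                            as.integer(table(x$sample_organ))),
                    collapse = ", ")))
  invisible(x)
}

#' Construct a validated expression matrix
#'
#' An `ExpressionMatrix` holds non-negative expression values (RPKM units in
#' this pipeline) on the same gene-by-sample axes as its source
#' `CountMatrix`, together with the organ/replicate sample metadata.
#'
#' @param values Numeric matrix of non-negative expression values with gene
#'   row names and sample column names.
#' @inheritParams count_matrix
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_organ, sample_replicate) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene row names and sample column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("format error: duplicate gene or sample id(s)")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("format error: expression values must be finite and non-negative")
  sample_ids <- colnames(values)
  if (length(setdiff(sample_ids, names(sample_organ))))
    stop("consistency error: sample(s) missing from sample sheet: ",
         paste(setdiff(sample_ids, names(sample_organ)), collapse = ", "))
  structure(list(values = values,
                 sample_organ = sample_organ,
                 sample_replicate = sample_replicate),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Collapse an expression matrix to per-organ replicate means
#'
#' @param expr An `ExpressionMatrix`.
#' @param organs Optional character vector restricting/ordering the organs;
#'   defaults to the organs in order of first appearance.
#' @return Numeric matrix, genes x organs, of replicate-mean expression.
#' @export
organ_means <- function(expr, organs = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  org <- expr$sample_organ[colnames(expr$values)]
  if (is.null(organs)) organs <- unique(unname(org))
  out <- vapply(organs, function(o) {
    cols <- names(org)[org == o]
    if (!length(cols)) stop("organ not present in expression matrix: ", o)
    rowMeans(expr$values[, cols, drop = FALSE])
  }, numeric(nrow(expr$values)))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), organs))
  out
}

#' Read a count matrix with its sample sheet and gene lengths
#'
#' The count file is tab-separated with a header row of sample ids and the
#' gene id in the first column. The sample sheet needs columns `sample`,
#' `organ`, `replicate`; the lengths file needs columns `gene`, `length`
#' (nucleotides).
#'
#' @param path Count matrix TSV.
#' @param sample_sheet Sample sheet TSV.
#' @param lengths Gene length TSV.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, sample_sheet, lengths) {
  for (f in c(path, sample_sheet, lengths))
    if (!file.exists(f)) stop("file not found: ", f)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("format error: non-numeric count(s) in ", path)
  rownames(mat) <- gene_ids
  sheet <- read_sample_sheet(sample_sheet)
  len <- utils::read.delim(lengths, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (length(setdiff(c("gene", "length"), colnames(len))))
    stop("lengths file must have columns: gene, length")
  missing_len <- setdiff(gene_ids, len$gene)
  if (length(missing_len))
    stop("consistency error: gene(s) missing a length: ",
         paste(utils::head(missing_len, 5L), collapse = ", "))
  count_matrix(
    mat,
    gene_lengths = stats::setNames(len$length, len$gene)[gene_ids],
    sample_organ = stats::setNames(as.character(sheet$organ), sheet$sample),
    sample_replicate = stats::setNames(as.integer(sheet$replicate),
                                       sheet$sample))
}

#' Write a count matrix and its companion tables
#'
#' Inverse of [read_count_matrix()]: emits the count TSV and, when paths are
#' given, the sample sheet and gene length tables in the dialect that
#' [read_count_matrix()] accepts.
#'
#' @param x A `CountMatrix`.
#' @param path Output count TSV.
#' @param sample_sheet,lengths Optional output paths for the companions.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(x, path, sample_sheet = NULL, lengths = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    ids <- colnames(x$counts)
    utils::write.table(
      data.frame(sample = ids,
                 organ = unname(x$sample_organ[ids]),
                 replicate = unname(x$sample_replicate[ids])),
      sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(lengths)) {
    utils::write.table(
      data.frame(gene = rownames(x$counts),
                 length = unname(x$gene_lengths[rownames(x$counts)])),
      lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read an expression matrix TSV
#'
#' Same tabular dialect as the count matrix (gene id first column, sample ids
#' in the header). Reading re-attaches organ/replicate metadata from a sample
#' sheet.
#'
#' @param x An `ExpressionMatrix`.
#' @param path TSV path.
#' @return `write_expression_matrix`: `path` invisibly;
#'   `read_expression_matrix`: an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param sample_sheet Sample sheet TSV (columns sample, organ, replicate).
#' @export
read_expression_matrix <- function(path, sample_sheet) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(vals) <- as.character(raw[[1L]])
  sheet <- read_sample_sheet(sample_sheet)
  expression_matrix(
    vals,
    sample_organ = stats::setNames(as.character(sheet$organ), sheet$sample),
    sample_replicate = stats::setNames(as.integer(sheet$replicate),
                                       sheet$sample))
}

#' Construct a term map (gene-set annotation universe)
#'
#' @param term_genes Named list mapping term id to a character vector of
#'   member genes.
#' @param term_names Optional named character vector of human-readable term
#'   names; defaults to the term ids.
#' @param background Optional character vector of the measured gene universe;
#'   defaults to the union of all term members. Every annotated gene must lie
#'   in the background.
#' @return An object of class `TermMap` with elements `term_ids`,
#'   `term_names`, `term_genes`, `background`.
#' @export
term_map <- function(term_genes, term_names = NULL, background = NULL) {
  term_ids <- names(term_genes)
  if (is.null(term_ids) || anyDuplicated(term_ids) || any(!nzchar(term_ids)))
    stop("term_genes must be a uniquely named list")
  term_genes <- lapply(term_genes, function(g) unique(as.character(g)))
  if (is.null(term_names)) term_names <- stats::setNames(term_ids, term_ids)
  missing_names <- setdiff(term_ids, names(term_names))
  if (length(missing_names))
    stop("term(s) without a name entry: ", paste(missing_names, collapse = ", "))
  annotated <- unique(unlist(term_genes, use.names = FALSE))
  if (is.null(background)) background <- annotated
  background <- unique(as.character(background))
  stray <- setdiff(annotated, background)
  if (length(stray))
    stop("annotated gene(s) outside the background: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  structure(list(term_ids = term_ids,
                 term_names = term_names[term_ids],
                 term_genes = term_genes,
                 background = background),
            class = "TermMap")
}

#' @export
print.TermMap <- function(x, ...) {
  cat(sprintf("TermMap: %d terms over %d background genes\n",
              length(x$term_ids), length(x$background)))
  invisible(x)
}

#' Read / write a GMT-style gene-set file
#'
#' One term per line: term id, term name, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @param background Optional measured gene universe; defaults to the union
#'   of all members.
#' @return `read_gmt`: a [term_map()]; `write_gmt`: `path` invisibly.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("format error: GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  nms <- vapply(parts, `[[`, character(1), 2L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  term_map(stats::setNames(genes, ids),
           term_names = stats::setNames(nms, ids),
           background = background)
}

#' @rdname read_gmt
#' @param x A `TermMap`.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "TermMap"))
  lines <- vapply(x$term_ids, function(id) {
    paste(c(id, x$term_names[[id]], x$term_genes[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcription-factor annotation table
#'
#' TSV with columns `gene` and `family` (e.g. bHLH, MYB related, C3H).
#'
#' @param path TF table TSV.
#' @return data.frame with columns `gene`, `family`.
#' @export
read_tf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (length(setdiff(c("gene", "family"), colnames(df))))
    stop("TF table must have columns: gene, family")
  validate_tf_table(df)
  df[, c("gene", "family")]
}

#' @rdname read_tf_table
#' @param x A TF table data.frame.
#' @export
validate_tf_table <- function(x) {
  if (anyDuplicated(x$gene))
    stop("format error: duplicate TF gene id(s): ",
         paste(unique(x$gene[duplicated(x$gene)]), collapse = ", "))
  if (anyNA(x$family) || any(!nzchar(x$family)))
    stop("format error: empty TF family label(s)")
  invisible(x)
}

#' Write a co-expression edge list
#'
#' SIF writes `regulator <tab> coexpr <tab> target`, one edge per line, no
#' header (loadable by network viewers). TSV adds the correlation `r`, its
#' p-value `p` and the regulator `family` at full precision, with a header.
#'
#' @param edges data.frame with columns `regulator`, `target`, `r`, `p` and
#'   optionally `family` (as produced by [build_network()]).
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  need <- c("regulator", "target", "r", "p")
  if (length(setdiff(need, colnames(edges))))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  if (format == "sif") {
    writeLines(if (nrow(edges)) paste(edges$regulator, "coexpr",
                                      edges$target, sep = "\t")
               else character(0), path)
  } else {
    df <- data.frame(regulator = edges$regulator,
                     target = edges$target,
                     r = sprintf("%.17g", edges$r),
                     p = sprintf("%.17g", edges$p),
                     family = if ("family" %in% colnames(edges))
                       edges$family else NA_character_,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable cut-off of the pipeline with the defaults used
#' throughout: the 0.001 stand-in for zero expression inside log ratios, the
#' differential-expression call rule (P > 0.8 and |M| > 2), the network
#' retention rule (|PCC| >= 0.95 with p < 0.01) and the enrichment
#' significance level (corrected p <= 0.05).
#'
#' @param zero_substitute Positive value substituted for zero expression
#'   inside the log2 ratio only. Default 0.001.
#' @param p_threshold DEG probability threshold (strict `>`). Default 0.8.
#' @param m_threshold log2 fold-change threshold (strict `>`, applied to
#'   |M| unless `signed_m`). Default 2.
#' @param pcc_threshold Absolute Pearson correlation retention threshold
#'   (`>=`). Default 0.95.
#' @param pcc_alpha Correlation p-value threshold (strict `<`). Default 0.01.
#' @param enrich_alpha Adjusted enrichment p-value threshold (`<=`).
#'   Default 0.05.
#' @param rng_seed Integer seed used by simulation-backed runs.
#' @param signed_m If `TRUE`, only M > m_threshold yields a call (signed
#'   rule); default `FALSE` uses |M| so both directions are callable.
#' @param substitute_in_d If `TRUE`, the zero substitution is also applied
#'   inside D; default `FALSE` computes D from the original values.
#' @param adjust_method Multiple-testing correction for enrichment, passed to
#'   [stats::p.adjust()]. Default `"BH"`.
#' @param cluster_dist Distance for heatmap ordering: `"correlation"`
#'   (1 - PCC) or `"euclidean"`.
#' @param cluster_method Agglomeration method for [stats::hclust()].
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(zero_substitute = 0.001,
                            p_threshold = 0.8,
                            m_threshold = 2,
                            pcc_threshold = 0.95,
                            pcc_alpha = 0.01,
                            enrich_alpha = 0.05,
                            rng_seed = 1L,
                            signed_m = FALSE,
                            substitute_in_d = FALSE,
                            adjust_method = "BH",
                            cluster_dist = "correlation",
                            cluster_method = "average") {
  stopifnot(is.numeric(zero_substitute), zero_substitute > 0,
            is.numeric(p_threshold), p_threshold > 0, p_threshold <= 1,
            is.numeric(m_threshold), m_threshold >= 0,
            is.numeric(pcc_threshold), pcc_threshold >= 0, pcc_threshold <= 1,
            is.numeric(pcc_alpha), pcc_alpha > 0, pcc_alpha < 1,
            is.numeric(enrich_alpha), enrich_alpha > 0, enrich_alpha < 1,
            is.numeric(rng_seed))
  structure(list(zero_substitute = zero_substitute,
                 p_threshold = p_threshold,
                 m_threshold = m_threshold,
                 pcc_threshold = pcc_threshold,
                 pcc_alpha = pcc_alpha,
                 enrich_alpha = enrich_alpha,
                 rng_seed = as.integer(rng_seed),
                 signed_m = isTRUE(signed_m),
                 substitute_in_d = isTRUE(substitute_in_d),
                 adjust_method = adjust_method,
                 cluster_dist = cluster_dist,
                 cluster_method = cluster_method),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# internal: sample sheet reader; organ labels like "F" or "T" must survive
# as character, so no type sniffing
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("sample", "organ", "replicate")
  if (length(setdiff(need, colnames(sheet))))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$replicate <- as.integer(sheet$replicate)
  sheet
}

# internal: run code under a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# internal: derive an independent substream seed below 2^31
sub_seed <- function(seed, stream) {
  ((as.double(seed) %% 2146483647) * 69069 + as.double(stream) * 104729) %%
    2147483629
}

# internal: canonical organ-pair key, e.g. "F-vs-L"
pair_key <- function(o1, o2) paste0(o1, "-vs-", o2)
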