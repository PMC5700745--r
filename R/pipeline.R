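# End-to-end orchestration: quantify -> pairwise DEG screen -> organ
# profile -> enrichment -> network, with a machine-readable run manifest.
# Stage outputs are plain TSVs consumable as standalone stage inputs.

#' Validate pipeline input files without running any stage
#'
#' Runs the type-level invariant checks (parseability, identifier
#' uniqueness, count integrality, sample-sheet coverage, length positivity,
#' replicate sufficiency, annotation well-formedness) and reports each as a
#' pass/fail/warn row instead of stopping at the first failure.
#'
#' @param counts,sample_sheet,lengths Paths to the count matrix, sample
#'   sheet and gene length TSVs.
#' @param gmt,tf_table Optional annotation paths.
#' @return data.frame with columns `check`, `status`
#'   (`"pass"`/`"fail"`/`"warn"`), `message`.
#' @export
validate_inputs <- function(counts, sample_sheet, lengths,
                            gmt = NULL, tf_table = NULL) {
  res <- list()
  add <- function(check, status, message = "") {
    res[[length(res) + 1L]] <<- data.frame(
      check = check, status = status, message = message,
      stringsAsFactors = FALSE)
  }
  files <- c(counts = counts, sample_sheet = sample_sheet,
             lengths = lengths)
  if (!is.null(gmt)) files <- c(files, gmt = gmt)
  if (!is.null(tf_table)) files <- c(files, tf_table = tf_table)
  for (nm in names(files)) {
    ok <- file.exists(files[[nm]])
    add(paste0("file_exists:", nm), if (ok) "pass" else "fail",
        if (ok) "" else paste("missing file:", files[[nm]]))
  }
  if (!all(file.exists(c(counts, sample_sheet, lengths))))
    return(do.call(rbind, res))
  cm <- tryCatch(read_count_matrix(counts, sample_sheet, lengths),
                 error = function(e) e)
  if (inherits(cm, "error")) {
    add("count_matrix_valid", "fail", conditionMessage(cm))
    return(do.call(rbind, res))
  }
  add("count_matrix_valid", "pass",
      sprintf("%d genes x %d samples", nrow(cm$counts), ncol(cm$counts)))
  tab <- table(cm$sample_organ[colnames(cm$counts)])
  thin <- names(tab)[tab < 2]
  add("replicates_per_organ", if (length(thin)) "warn" else "pass",
      if (length(thin))
        paste0("organ(s) with a single replicate (DEG screen will fail): ",
               paste(thin, collapse = ", "))
      else "")
  zero <- colnames(cm$counts)[colSums(cm$counts) == 0]
  add("nonzero_library", if (length(zero)) "fail" else "pass",
      if (length(zero)) paste("zero total counts:",
                              paste(zero, collapse = ", ")) else "")
  if (!is.null(gmt) && file.exists(gmt)) {
    tm <- tryCatch(read_gmt(gmt), error = function(e) e)
    add("term_map_valid",
        if (inherits(tm, "error")) "fail" else "pass",
        if (inherits(tm, "error")) conditionMessage(tm) else "")
  }
  if (!is.null(tf_table) && file.exists(tf_table)) {
    tf <- tryCatch(read_tf_table(tf_table), error = function(e) e)
    add("tf_table_valid",
        if (inherits(tf, "error")) "fail" else "pass",
        if (inherits(tf, "error")) conditionMessage(tf) else "")
  }
  do.call(rbind, res)
}

# internal: write a data.frame as an uncommented TSV
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes quantification, the pairwise DEG screen over all organ pairs,
#' the organ profile (unique genes, up/down tallies, common DEGs),
#' per-pair term enrichment and the TF-target co-expression network,
#' writing every stage product as a TSV under `out_dir` together with a
#' JSON run manifest. With `simulate = TRUE` the inputs are generated by
#' the synthetic-data module (seeded from `config$rng_seed`) and written
#' under `out_dir/input/`, so reruns with the same configuration are
#' byte-identical on every stage output (the manifest carries a wall-clock
#' timestamp and is the one exception).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param simulate Generate inputs with [simulate_counts()],
#'   [simulate_annotation()] and [simulate_tf_panel()].
#' @param sim Named list of overrides passed to [simulate_counts()] (and
#'   `n_terms`/`term_size`/`enrichment_bias` for the annotation;
#'   `n_tfs`/`n_linked`/`link_strength`/`noise_sd` for the TF panel).
#' @param counts,sample_sheet,lengths Input paths (file mode).
#' @param gmt Optional gene-set file; enrichment is skipped without it.
#' @param tf_table,targets Optional TF table path and a text file of target
#'   gene ids (one per line); the network stage is skipped without both.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(out_dir, config = pipeline_config(),
                    simulate = FALSE, sim = list(),
                    counts = NULL, sample_sheet = NULL, lengths = NULL,
                    gmt = NULL, tf_table = NULL, targets = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  tm <- NULL
  tf <- NULL
  tf_expr <- NULL
  target_ids <- NULL
  input_digests <- list()

  if (simulate) {
    in_dir <- file.path(out_dir, "input")
    dir.create(in_dir, showWarnings = FALSE)
    sim_counts_args <- sim[intersect(names(sim),
                                     names(formals(simulate_counts)))]
    sim_counts_args$seed <- sub_seed(config$rng_seed, 1)
    gen <- stage("simulate", do.call(simulate_counts, sim_counts_args))
    cm <- gen$counts
    truth <- gen$truth
    ann_args <- sim[intersect(names(sim),
                              c("n_terms", "term_size", "enrichment_bias"))]
    tm <- stage("simulate", do.call(
      simulate_annotation,
      c(list(truth = truth, seed = sub_seed(config$rng_seed, 2)),
        ann_args)))
    truth$enriched_terms <- attr(tm, "planted_term")
    write_count_matrix(cm, file.path(in_dir, "counts.tsv"),
                       file.path(in_dir, "samples.tsv"),
                       file.path(in_dir, "lengths.tsv"))
    write_gmt(tm, file.path(in_dir, "terms.gmt"))
  } else {
    for (f in c(counts, sample_sheet, lengths))
      if (!file.exists(f)) stop("stage 'read' failed: file not found: ", f,
                                call. = FALSE)
    cm <- stage("read", read_count_matrix(counts, sample_sheet, lengths))
    input_digests <- as.list(tools::md5sum(
      c(counts = counts, sample_sheet = sample_sheet, lengths = lengths)))
    if (!is.null(gmt)) {
      tm <- stage("read", read_gmt(gmt))
      input_digests$gmt <- unname(tools::md5sum(gmt))
    }
    if (!is.null(tf_table)) {
      tf <- stage("read", read_tf_table(tf_table))
      input_digests$tf_table <- unname(tools::md5sum(tf_table))
    }
    if (!is.null(targets)) {
      target_ids <- readLines(targets)
      target_ids <- target_ids[nzchar(target_ids)]
    }
  }

  message("[quantify] computing RPKM")
  expr <- stage("quantify", rpkm(cm))
  write_expression_matrix(expr, file.path(out_dir, "rpkm.tsv"))

  message("[deg] screening organ pairs")
  screens <- stage("deg", pairwise_screen(expr, config = config))
  for (key in names(screens))
    write_tsv(screens[[key]], file.path(out_dir, paste0("deg_", key, ".tsv")))

  message("[profile] organ-unique genes and tallies")
  organs <- unique(unname(cm$sample_organ[colnames(cm$counts)]))
  uniq <- NULL
  if (length(organs) == 3) {
    uniq <- stage("profile", find_unique_genes(expr, organs))
    for (o in organs)
      write_tsv(data.frame(gene = uniq[[o]], stringsAsFactors = FALSE),
                file.path(out_dir, paste0("unique_genes_", o, ".tsv")))
    write_tsv(organ_summary(uniq), file.path(out_dir, "organ_summary.tsv"))
  } else {
    message("[profile] skipping unique-gene stage (needs 3 organs)")
  }
  write_tsv(updown_tally(screens), file.path(out_dir, "updown.tsv"))
  if (length(screens) == 3)
    writeLines(common_degs(screens), file.path(out_dir, "common_degs.txt"))

  enr <- NULL
  if (!is.null(tm)) {
    message("[enrich] per-pair term over-representation")
    enr <- lapply(names(screens), function(key) {
      degs <- screens[[key]]$gene[screens[[key]]$call != "not_de"]
      if (!length(intersect(degs, tm$background))) return(NULL)
      res <- stage("enrich", enrich(degs, tm, config))
      write_tsv(res, file.path(out_dir, paste0("enrichment_", key, ".tsv")))
      res
    })
    names(enr) <- names(screens)
  }

  if (simulate) {
    # scent-gene stand-ins: planted genes up-regulated in the first organ
    first_org <- organs[1]
    up_first <- unique(unlist(lapply(names(truth$de_genes), function(key) {
      pr <- strsplit(key, "-vs-", fixed = TRUE)[[1]]
      df <- truth$de_genes[[key]]
      c(df$gene[pr[1] == first_org & df$direction == "up"],
        df$gene[pr[2] == first_org & df$direction == "down"])
    }), use.names = FALSE))
    target_ids <- utils::head(up_first, 7L)
    if (length(target_ids)) {
      panel_args <- sim[intersect(names(sim),
                                  c("n_tfs", "n_linked", "link_strength",
                                    "noise_sd"))]
      panel <- stage("simulate", do.call(
        simulate_tf_panel,
        c(list(target_expr = expr$values[target_ids, , drop = FALSE],
               seed = sub_seed(config$rng_seed, 3)),
          panel_args)))
      tf_expr <- panel$expr
      tf <- panel$tf_table
      truth$planted_edges <- panel$edges
      in_dir <- file.path(out_dir, "input")
      write_tsv(tf, file.path(in_dir, "tf_table.tsv"))
      write_tsv(data.frame(gene = rownames(tf_expr), tf_expr,
                           check.names = FALSE),
                file.path(in_dir, "tf_expr.tsv"))
      writeLines(target_ids, file.path(in_dir, "targets.txt"))
      jsonlite::write_json(truth_as_list(truth),
                           file.path(in_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else if (!is.null(tf) && !is.null(target_ids)) {
    tf_expr <- expr$values[intersect(tf$gene, rownames(expr$values)), ,
                           drop = FALSE]
  }

  edges <- NULL
  if (!is.null(tf_expr) && length(target_ids)) {
    message("[network] correlating TFs against target genes")
    edges <- stage("network", build_network(
      tf_expr, expr$values[target_ids, , drop = FALSE], tf, config))
    write_edge_list(edges, file.path(out_dir, "network.tsv"), "tsv")
    write_edge_list(edges, file.path(out_dir, "network.sif"), "sif")
    write_tsv(family_distribution(edges, tf),
              file.path(out_dir, "family_distribution.tsv"))
    if (nrow(edges) >= 2 &&
        length(unique(edges$regulator)) >= 2) {
      ord <- stage("network", hcluster_order(
        tf_expr[unique(edges$regulator), , drop = FALSE],
        distance = config$cluster_dist, linkage = config$cluster_method))
      writeLines(ord$labels, file.path(out_dir, "heatmap_order.txt"))
    }
  }

  outputs <- setdiff(list.files(out_dir, recursive = TRUE),
                     "manifest.json")
  manifest <- list(
    package = "scentnet",
    version = as.character(utils::packageVersion("scentnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$rng_seed,
    config = unclass(config),
    simulated = simulate,
    inputs = if (simulate) list(parameters = truth$parameters)
             else input_digests,
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))),
    rows = c(list(genes = nrow(cm$counts), samples = ncol(cm$counts)),
             stats::setNames(lapply(names(screens), function(k)
               sum(screens[[k]]$call != "not_de")),
               paste0("degs_", names(screens))),
             if (!is.null(uniq)) list(unique_genes = sum(lengths(uniq))),
             if (!is.null(edges)) list(network_edges = nrow(edges))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# internal: JSON-friendly view of a SimulationTruth
truth_as_list <- function(truth) {
  list(de_genes = truth$de_genes,
       unique_genes = truth$unique_genes,
       enriched_terms = truth$enriched_terms,
       planted_edges = truth$planted_edges,
       parameters = truth$parameters)
}
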