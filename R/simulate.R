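# Synthetic three-organ datasets with planted ground truth. The generator is
# the test bed for every downstream stage: it plants differentially expressed
# genes at a known fold change, organ-unique genes as structural zeros, an
# over-represented annotation term and a panel of regulators sharing latent
# signal with designated target genes.

# 53 transcription-factor family labels used to annotate the simulated panel,
# mirroring the family vocabulary of plant TF databases.
TF_FAMILIES <- c(
  "bHLH", "MYB related", "C3H", "bZIP", "ERF", "WRKY", "NAC", "MYB", "GRAS",
  "C2H2", "ARF", "HB", "MADS", "AP2", "B3", "FAR1", "G2-like", "GATA",
  "HSF", "LBD", "NF-YA", "NF-YB", "NF-YC", "SBP", "TCP", "Trihelix",
  "Dof", "E2F/DP", "EIL", "GeBP", "GRF", "CO-like", "CPP", "DBB", "ARR-B",
  "BBR-BPC", "BES1", "CAMTA", "HD-ZIP", "LSD", "M-type MADS", "NF-X1",
  "Nin-like", "RAV", "S1Fa-like", "SAP", "SRS", "STAT", "TALE", "VOZ",
  "Whirly", "YABBY", "ZF-HD")

#' Simulate a three-organ replicate count matrix with planted truth
#'
#' Counts are drawn from a gamma-mixed Poisson (negative binomial) model
#' around organ-specific means. Baseline abundances are log-normal so the
#' expression dynamic range spans several orders of magnitude. A fraction of
#' genes is planted as differentially expressed between one organ pair at a
#' fixed mean ratio, and a further set of genes is organ-unique: structural
#' zeros (mean exactly 0) in every other organ.
#'
#' @param n_genes Number of genes. Default 2000.
#' @param organs Organ labels; at least two. Default `c("F","L","S")`
#'   (flower, leaf, bulb scale).
#' @param reps Biological replicates per organ. Default 3.
#' @param de_fraction Fraction of genes planted as DE. Default 0.05.
#' @param fold_change Planted mean ratio between the designated organ pair
#'   (> 1). Default 8.
#' @param dispersion Negative binomial dispersion (`1/size`). Default 0.1.
#' @param unique_per_organ Organ-unique genes planted per organ. Default 30.
#' @param depth Target library size per sample (reads). Default 1e6.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (class `SimulationTruth`): `de_genes` (per organ-pair data.frames of
#'   gene, direction, fold_change; direction `"up"` means higher in the
#'   first organ of the pair), `unique_genes` (per-organ gene sets),
#'   `enriched_terms`, `planted_edges` (filled by the downstream
#'   generators), `universe` and `parameters`.
#' @details Planted DE genes are assigned round-robin to the unordered organ
#'   pairs with alternating direction. Organ-unique genes receive a floor on
#'   their baseline abundance so that, at the default depth, a planted gene
#'   is effectively never an all-zero sampling artifact in its own organ.
#' @seealso [simulate_annotation()], [simulate_tf_panel()]
#' @export
simulate_counts <- function(n_genes = 2000, organs = c("F", "L", "S"),
                            reps = 3, de_fraction = 0.05, fold_change = 8,
                            dispersion = 0.1, unique_per_organ = 30,
                            depth = 1e6, seed = 1L) {
  stopifnot(n_genes >= 1, length(organs) >= 2, !anyDuplicated(organs),
            reps >= 1, de_fraction >= 0, de_fraction < 1,
            fold_change > 1, dispersion > 0, unique_per_organ >= 0,
            depth > 0)
  n_de <- round(de_fraction * n_genes)
  if (de_fraction > 0 && n_de < 1)
    stop("parameter error: de_fraction * n_genes < 1; nothing to plant")
  n_unique <- unique_per_organ * length(organs)
  if (n_de + n_unique >= n_genes)
    stop("parameter error: planted sets (", n_de + n_unique,
         ") must be smaller than n_genes (", n_genes, ")")
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    lengths <- pmin(pmax(round(stats::rlnorm(n_genes, log(1500), 0.6)),
                         200), 15000)
    names(lengths) <- gene_ids
    w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
    pairs <- utils::combn(organs, 2)
    mu <- matrix(w, n_genes, length(organs),
                 dimnames = list(gene_ids, organs))

    de_genes <- stats::setNames(
      rep(list(data.frame(gene = character(0), direction = character(0),
                          fold_change = numeric(0),
                          stringsAsFactors = FALSE)),
          ncol(pairs)),
      apply(pairs, 2, function(p) pair_key(p[1], p[2])))
    if (n_de > 0) {
      de_idx <- seq_len(n_de)
      pair_of <- rep(seq_len(ncol(pairs)), length.out = n_de)
      dir_of <- rep(c("up", "down"), length.out = n_de)
      for (i in de_idx) {
        o1 <- pairs[1, pair_of[i]]
        mu[i, o1] <- if (dir_of[i] == "up") w[i] * fold_change
                     else w[i] / fold_change
      }
      for (j in seq_len(ncol(pairs))) {
        sel <- de_idx[pair_of == j]
        de_genes[[j]] <- data.frame(gene = gene_ids[sel],
                                    direction = dir_of[sel],
                                    fold_change = rep(fold_change,
                                                      length(sel)),
                                    stringsAsFactors = FALSE)
      }
    }

    unique_genes <- stats::setNames(
      rep(list(character(0)), length(organs)), organs)
    if (unique_per_organ > 0) {
      nxt <- n_de
      for (o in organs) {
        sel <- nxt + seq_len(unique_per_organ)
        nxt <- nxt + unique_per_organ
        mu[sel, ] <- 0
        # abundance floor keeps structural zeros separable from sampling
        # zeros at the default depth
        mu[sel, o] <- pmax(w[sel], 0.5)
        unique_genes[[o]] <- gene_ids[sel]
      }
    }

    sample_ids <- as.vector(vapply(
      organs, function(o) paste0(o, "_", seq_len(reps)),
      character(reps)))
    sample_organ <- stats::setNames(rep(organs, each = reps), sample_ids)
    sample_replicate <- stats::setNames(rep(seq_len(reps), length(organs)),
                                        sample_ids)
    counts <- matrix(0, n_genes, length(sample_ids),
                     dimnames = list(gene_ids, sample_ids))
    for (s in sample_ids) {
      o <- sample_organ[[s]]
      mu_s <- depth * mu[, o] / sum(mu[, o])
      counts[, s] <- stats::rnbinom(n_genes, mu = mu_s,
                                    size = 1 / dispersion)
    }

    truth <- structure(
      list(de_genes = de_genes,
           unique_genes = unique_genes,
           enriched_terms = character(0),
           planted_edges = data.frame(regulator = character(0),
                                      target = character(0),
                                      stringsAsFactors = FALSE),
           universe = gene_ids,
           parameters = list(n_genes = n_genes, organs = organs,
                             reps = reps, de_fraction = de_fraction,
                             fold_change = fold_change,
                             dispersion = dispersion,
                             unique_per_organ = unique_per_organ,
                             depth = depth, seed = as.integer(seed))),
      class = "SimulationTruth")
    list(counts = count_matrix(counts, lengths, sample_organ,
                               sample_replicate),
         truth = truth)
  })
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf(
    "SimulationTruth: %d genes; %d DE planted; %d unique; %d planted edges\n",
    length(x$universe),
    sum(vapply(x$de_genes, nrow, integer(1))),
    sum(lengths(x$unique_genes)),
    nrow(x$planted_edges)))
  invisible(x)
}

#' Simulate a term annotation with one over-represented term
#'
#' Builds `n_terms` gene sets of size `term_size` over the simulated gene
#' universe. One designated term samples its members with weight
#' `enrichment_bias` on the planted DE genes; all other terms sample
#' uniformly. With `enrichment_bias = 1` the designated term is statistically
#' indistinguishable from the rest (a null construction).
#'
#' @param truth A `SimulationTruth` from [simulate_counts()].
#' @param n_terms Number of terms. Default 50.
#' @param term_size Genes per term. Default 20.
#' @param enrichment_bias Sampling weight (>= 1) of DE genes for the
#'   designated term. Default 20.
#' @param seed Integer seed.
#' @return A [term_map()] whose background is the simulated universe; the
#'   designated term id is recorded in `attr(, "planted_term")`.
#' @export
simulate_annotation <- function(truth, n_terms = 50, term_size = 20,
                                enrichment_bias = 20, seed = 1L) {
  stopifnot(inherits(truth, "SimulationTruth"), n_terms >= 1,
            enrichment_bias >= 1)
  universe <- truth$universe
  if (term_size > length(universe))
    stop("parameter error: term_size exceeds the gene universe")
  de <- unique(unlist(lapply(truth$de_genes, `[[`, "gene"),
                      use.names = FALSE))
  with_seed(seed, {
    ids <- sprintf("T%03d", seq_len(n_terms))
    wts <- ifelse(universe %in% de, enrichment_bias, 1)
    genes <- vector("list", n_terms)
    genes[[1]] <- sample(universe, term_size, prob = wts)
    for (j in seq_len(n_terms)[-1])
      genes[[j]] <- sample(universe, term_size)
    tm <- term_map(stats::setNames(genes, ids),
                   term_names = stats::setNames(
                     paste("synthetic term", seq_len(n_terms)), ids),
                   background = universe)
    attr(tm, "planted_term") <- ids[1]
    tm
  })
}

#' Simulate a transcription-factor expression panel with planted links
#'
#' Each linked TF's profile is `link_strength` times a designated target
#' profile plus Gaussian noise whose standard deviation is `noise_sd` times
#' the target profile's standard deviation (so the achieved correlation is
#' roughly `link_strength / sqrt(link_strength^2 + noise_sd^2)` regardless of
#' the target's scale). Unlinked TFs are independent log-normal noise.
#' Targets are assigned to linked TFs round-robin.
#'
#' @param target_expr Numeric matrix: designated target (scent structural
#'   gene) expression profiles, genes x samples.
#' @param n_tfs Number of TFs in the panel. Default 839.
#' @param n_linked Number of TFs sharing latent signal with a target
#'   (`<= n_tfs`). Default 31.
#' @param link_strength Multiplier on the target profile in `[0, 1]`.
#'   Default 1.
#' @param noise_sd Relative noise level (> 0). Default 0.05.
#' @param seed Integer seed.
#' @return List with `expr` (TF x sample matrix), `tf_table` (data.frame
#'   gene/family) and `edges` (planted regulator-target pairs).
#' @export
simulate_tf_panel <- function(target_expr, n_tfs = 839, n_linked = 31,
                              link_strength = 1, noise_sd = 0.05,
                              seed = 1L) {
  if (!is.matrix(target_expr)) target_expr <- as.matrix(target_expr)
  if (nrow(target_expr) < 1)
    stop("parameter error: at least one target profile is required")
  if (ncol(target_expr) < 1)
    stop("parameter error: zero samples in target rows")
  stopifnot(n_tfs >= 1, n_linked >= 0, n_linked <= n_tfs,
            link_strength >= 0, link_strength <= 1, noise_sd > 0)
  n_samp <- ncol(target_expr)
  targets <- rownames(target_expr)
  if (is.null(targets)) targets <- paste0("target", seq_len(nrow(target_expr)))
  with_seed(seed, {
    tf_ids <- sprintf("TF%04d", seq_len(n_tfs))
    expr <- matrix(0, n_tfs, n_samp,
                   dimnames = list(tf_ids, colnames(target_expr)))
    edges <- data.frame(regulator = character(0), target = character(0),
                        stringsAsFactors = FALSE)
    if (n_linked > 0) {
      tgt_of <- rep(seq_len(nrow(target_expr)), length.out = n_linked)
      for (i in seq_len(n_linked)) {
        t_prof <- target_expr[tgt_of[i], ]
        s <- stats::sd(t_prof)
        if (!is.finite(s) || s <= 0) s <- max(mean(t_prof), 1)
        expr[i, ] <- link_strength * t_prof +
          stats::rnorm(n_samp, 0, noise_sd * s)
      }
      edges <- data.frame(regulator = tf_ids[seq_len(n_linked)],
                          target = targets[tgt_of],
                          stringsAsFactors = FALSE)
    }
    if (n_linked < n_tfs) {
      idx <- (n_linked + 1):n_tfs
      expr[idx, ] <- matrix(
        stats::rlnorm(length(idx) * n_samp, meanlog = log(10), sdlog = 1),
        length(idx), n_samp)
    }
    tf_table <- data.frame(
      gene = tf_ids,
      family = sample(TF_FAMILIES, n_tfs, replace = TRUE),
      stringsAsFactors = FALSE)
    list(expr = expr, tf_table = tf_table, edges = edges)
  })
}
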