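test_that("count matrix round-trips through its TSV dialect unchanged", {
  dir <- withr::local_tempdir()
  cm <- tiny_count_matrix()
  paths <- write_fixture_files(dir, cm)
  back <- read_count_matrix(paths$counts, paths$samples, paths$lengths)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$gene_lengths, cm$gene_lengths)
  expect_identical(back$sample_organ[colnames(back$counts)],
                   cm$sample_organ[colnames(cm$counts)])
  expect_identical(back$sample_replicate[colnames(back$counts)],
                   cm$sample_replicate[colnames(cm$counts)])
})

test_that("a minimal one-organ fixture reads back with its structure", {
  dir <- withr::local_tempdir()
  counts <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  cm <- count_matrix(counts,
                     gene_lengths = c(g1 = 100, g2 = 200, g3 = 300),
                     sample_organ = c(s1 = "F", s2 = "F"),
                     sample_replicate = c(s1 = 1, s2 = 2))
  paths <- write_fixture_files(dir, cm)
  back <- read_count_matrix(paths$counts, paths$samples, paths$lengths)
  expect_equal(nrow(back$counts), 3)
  expect_equal(ncol(back$counts), 2)
  expect_equal(unique(unname(back$sample_organ)), "F")
})

test_that("format violations are rejected with informative errors", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)

  # negative count
  writeLines(c("gene\tF_1\tF_2", "gA\t-1\t2", "gB\t3\t4"),
             file.path(dir, "neg.tsv"))
  expect_error(read_count_matrix(file.path(dir, "neg.tsv"),
                                 paths$samples, paths$lengths),
               "negative")

  # sample sheet missing one matrix column, named in the error
  sheet <- utils::read.delim(paths$samples)
  utils::write.table(sheet[sheet$sample != "L_2", ],
                     file.path(dir, "short.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_matrix(paths$counts, file.path(dir, "short.tsv"),
                                 paths$lengths),
               "L_2")
})

test_that("every constructed invariant violation is rejected", {
  cm <- tiny_count_matrix()
  base <- list(counts = cm$counts, gene_lengths = cm$gene_lengths,
               sample_organ = cm$sample_organ,
               sample_replicate = cm$sample_replicate)
  mutations <- list(
    dup_gene = function(a) {
      rownames(a$counts)[2] <- rownames(a$counts)[1]; a
    },
    dup_sample = function(a) {
      colnames(a$counts)[2] <- colnames(a$counts)[1]; a
    },
    negative_count = function(a) { a$counts[1, 1] <- -3; a },
    fractional_count = function(a) { a$counts[2, 2] <- 1.5; a },
    nonfinite_count = function(a) { a$counts[1, 2] <- Inf; a },
    zero_length = function(a) { a$gene_lengths[["gB"]] <- 0; a },
    missing_length = function(a) {
      a$gene_lengths <- a$gene_lengths[-1]; a
    },
    missing_organ = function(a) {
      a$sample_organ <- a$sample_organ[-3]; a
    },
    empty_organ = function(a) { a$sample_organ[["F_1"]] <- ""; a },
    missing_replicate = function(a) {
      a$sample_replicate <- a$sample_replicate[-2]; a
    })
  for (nm in names(mutations)) {
    bad <- mutations[[nm]](base)
    expect_error(do.call(count_matrix, bad), info = nm)
  }
  # the unmutated fixture is accepted
  expect_s3_class(do.call(count_matrix, base), "CountMatrix")
})

test_that("GMT term maps round-trip and enforce their invariants", {
  dir <- withr::local_tempdir()
  tm <- term_map(list(T1 = c("gA", "gB"), T2 = c("gB", "gC")),
                 term_names = c(T1 = "first", T2 = "second"),
                 background = c("gA", "gB", "gC", "gD"))
  p <- file.path(dir, "sets.gmt")
  write_gmt(tm, p)
  back <- read_gmt(p, background = tm$background)
  expect_identical(back$term_genes, tm$term_genes)
  expect_identical(unname(back$term_names), unname(tm$term_names))
  expect_setequal(back$background, tm$background)
  # annotated gene outside the background is an invariant violation
  expect_error(term_map(list(T1 = "gZ"), background = "gA"), "background")
  # malformed GMT line
  writeLines("T1\tonly-two-fields", p)
  expect_error(read_gmt(p), "fewer than 3")
})

test_that("edge lists export in SIF and TSV dialects", {
  dir <- withr::local_tempdir()
  one <- data.frame(regulator = "tfA", target = "geneB", r = 1.0, p = 0.0)
  sif <- file.path(dir, "one.sif")
  write_edge_list(one, sif, "sif")
  expect_identical(readLines(sif), "tfA\tcoexpr\tgeneB")

  empty <- one[0, ]
  write_edge_list(empty, sif, "sif")
  expect_identical(readLines(sif), character(0))

  two <- data.frame(regulator = c("tfA", "tfB"),
                    target = c("g1", "g2"),
                    r = c(0.987654321098765, -0.96),
                    p = c(1.234e-05, 0.004),
                    family = c("bHLH", "MYB"))
  tsv <- file.path(dir, "two.tsv")
  write_edge_list(two, tsv, "tsv")
  lines <- readLines(tsv)
  expect_length(lines, 3L)  # header + 2 rows
  expect_match(lines[1], "^regulator\ttarget\tr\tp\tfamily$")
  got <- utils::read.delim(tsv)
  expect_equal(got$r, two$r, tolerance = 1e-15)
})

test_that("pipeline configuration validates its ranges and reads YAML", {
  expect_error(pipeline_config(zero_substitute = 0))
  expect_error(pipeline_config(p_threshold = 1.5))
  expect_error(pipeline_config(pcc_threshold = -0.1))
  expect_error(pipeline_config(pcc_alpha = 1))
  cfg <- pipeline_config()
  expect_equal(cfg$zero_substitute, 0.001)
  expect_equal(cfg$p_threshold, 0.8)
  expect_equal(cfg$m_threshold, 2)
  expect_equal(cfg$pcc_threshold, 0.95)

  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("p_threshold: 0.9", "m_threshold: 1", "rng_seed: 42"), yml)
  cfg2 <- read_pipeline_config(yml)
  expect_equal(cfg2$p_threshold, 0.9)
  expect_equal(cfg2$m_threshold, 1)
  expect_equal(cfg2$rng_seed, 42L)
  expect_equal(cfg2$zero_substitute, 0.001)
  writeLines("no_such_key: 1", yml)
  expect_error(read_pipeline_config(yml), "unknown config key")
})
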