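test_that("the correlation statistic matches hand and library values", {
  x <- c(1, 2, 3)
  expect_identical(pcc_test(x, x)$r, 1)
  expect_identical(pcc_test(x, -x)$r, -1)
  expect_equal(pcc_test(c(1, 2, 3), c(1, 2, 4))$r, 9 / sqrt(84),
               tolerance = 1e-12)
  expect_error(pcc_test(c(1, 1, 1), x), "constant")
  expect_error(pcc_test(1:2, 1:2), "3 samples")
  # oracle: direct covariance formula and cor.test agree to 1e-12
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    got <- pcc_test(a, b)
    r_direct <- cov(a, b) / (sd(a) * sd(b))
    ct <- cor.test(a, b)
    expect_equal(got$r, r_direct, tolerance = 1e-12)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("correlation is affine-invariant with sign from the slope", {
  set.seed(6)
  a <- rnorm(10)
  b <- rnorm(10)
  r0 <- pcc_test(a, b)$r
  expect_equal(pcc_test(2.5 * a + 7, b)$r, r0, tolerance = 1e-12)
  expect_equal(pcc_test(a, -3 * b + 1)$r, -r0, tolerance = 1e-12)
})

test_that("edges are retained by |r| >= threshold and p < alpha", {
  set.seed(8)
  n <- 8
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))            # orthogonal component
  mk <- function(rho) rho * scale(x)[, 1] + sqrt(1 - rho^2) * scale(z)[, 1]
  tf <- rbind(hi = mk(0.99), mid = mk(0.9))
  colnames(tf) <- paste0("s", 1:n)
  tg <- matrix(x, 1, dimnames = list("target", colnames(tf)))
  cfg <- pipeline_config()
  edges <- build_network(tf, tg, config = cfg)
  expect_identical(edges$regulator, "hi")
  # non-strict >= on |r|: a threshold equal to the achieved correlation
  # still retains the edge; strict < on p
  r_mid <- pcc_test(tf["mid", ], tg[1, ])$r
  cfg_eq <- pipeline_config(pcc_threshold = abs(r_mid))
  edges_eq <- build_network(tf, tg, config = cfg_eq)
  expect_true("mid" %in% edges_eq$regulator)
  # every retained edge satisfies both predicates post hoc
  expect_true(all(abs(edges_eq$r) >= cfg_eq$pcc_threshold))
  expect_true(all(edges_eq$p < cfg_eq$pcc_alpha))
  # perfect self-profile edge
  self <- build_network(tg, tg, config = cfg)
  expect_identical(self$r, 1)
  # no shared samples is a consistency error
  tg2 <- tg
  colnames(tg2) <- paste0("q", 1:n)
  expect_error(build_network(tf, tg2), "no shared samples")
  # constant profiles are skipped with a warning, not an error
  tf_const <- rbind(tf, flat = rep(1, n))
  expect_warning(edges_c <- build_network(tf_const, tg, config = cfg),
                 "constant")
  expect_false("flat" %in% edges_c$regulator)
})

test_that("planted TF links are recovered against an independent panel", {
  gen <- simulate_counts(n_genes = 300, de_fraction = 0.1, seed = 41)
  expr <- rpkm(gen$counts)
  targets <- utils::head(gen$truth$de_genes[["F-vs-L"]]$gene, 4)
  panel <- simulate_tf_panel(expr$values[targets, , drop = FALSE],
                             n_tfs = 60, n_linked = 12,
                             link_strength = 1, noise_sd = 0.05, seed = 41)
  edges <- build_network(panel$expr, expr$values[targets, , drop = FALSE],
                         panel$tf_table)
  planted <- paste(panel$edges$regulator, panel$edges$target)
  found <- paste(edges$regulator, edges$target)
  expect_true(all(planted %in% found))
})

test_that("family counts sort by size with alphabetical ties", {
  tft <- data.frame(gene = c("t1", "t2", "t3", "t4", "t5"),
                    family = c("bHLH", "bHLH", "MYB", "bZIP", "bZIP"))
  edges <- data.frame(regulator = c("t1", "t2", "t3", "t1"),
                      target = c("a", "a", "b", "b"))
  fd <- family_distribution(edges, tft)
  expect_identical(fd$family, c("bHLH", "MYB"))
  expect_identical(fd$n, c(2L, 1L))
  # tie at equal counts resolves alphabetically
  fd2 <- family_distribution(c("t1", "t2", "t4", "t5"), tft)
  expect_identical(fd2$family, c("bHLH", "bZIP"))
  empty <- family_distribution(edges[0, ], tft)
  expect_equal(nrow(empty), 0L)
  expect_error(family_distribution(c("t1", "nope"), tft), "nope")
})

test_that("hierarchical ordering merges duplicates first, keeps blocks", {
  set.seed(9)
  base <- matrix(rnorm(10 * 8), 10, 8,
                 dimnames = list(paste0("r", 1:10), paste0("s", 1:8)))
  base["r2", ] <- base["r1", ]  # identical pair
  ord <- hcluster_order(base)
  expect_equal(min(ord$height), 0, tolerance = 1e-12)
  first_merge <- ord$merge[1, ]
  expect_setequal(-first_merge, c(1, 2))
  # two planted correlated blocks stay contiguous in the leaf order
  s1 <- rnorm(8)
  s2 <- rnorm(8)
  blocks <- rbind(
    t(sapply(1:5, function(i) s1 + rnorm(8, 0, 0.05))),
    t(sapply(1:5, function(i) s2 + rnorm(8, 0, 0.05))))
  rownames(blocks) <- paste0(rep(c("a", "b"), each = 5), 1:5)
  ob <- hcluster_order(blocks)
  groups <- rep(1:2, each = 5)[ob$order]
  expect_equal(sum(diff(groups) != 0), 1)  # one boundary: contiguous
  # degenerate two-row input has a single merge
  two <- hcluster_order(blocks[c(1, 6), ])
  expect_equal(length(two$height), 1L)
  # constant rows are refused under correlation distance
  flat <- rbind(blocks[1:2, ], c0 = rep(3, 8))
  expect_error(hcluster_order(flat), "euclidean")
  expect_silent(hcluster_order(flat, distance = "euclidean"))
})
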