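test_that("M and D statistics follow their definitions", {
  md <- compute_md(5, 5)
  expect_identical(md$m, 0)
  expect_identical(md$d, 0)
  md <- compute_md(8, 2)
  expect_identical(md$m, 2)
  expect_identical(md$d, 6)
  # zero expression enters the ratio as 0.001; D keeps the original values
  md <- compute_md(10, 0)
  expect_equal(md$m, log2(10 / 0.001))
  expect_identical(md$d, 10)
  md <- compute_md(0, 4)
  expect_equal(md$m, log2(0.001 / 4))
  expect_identical(md$d, 4)
  # the documented alternative substitutes inside D too
  md <- compute_md(10, 0, substitute_in_d = TRUE)
  expect_equal(md$d, 10 - 0.001)
  expect_error(compute_md(-1, 2), "domain error")
})

test_that("the noise pool enumerates within-organ replicate pairs", {
  # two identical replicates per organ: every noise point is (0, 0)
  vals <- matrix(c(3, 3, 7, 7,
                   1, 1, 2, 2), nrow = 2, byrow = TRUE)
  expr <- make_expr(vals, c("F", "F", "L", "L"))
  ns <- build_noise(expr, c("F", "L"))
  expect_equal(ns$n_points, 4L)  # 2 genes x (1 + 1) pairs
  expect_true(all(ns$m_star == 0 & ns$d_star == 0))

  # 1 gene; organ A replicates (2, 4), organ B replicates (3, 3)
  expr2 <- make_expr(matrix(c(2, 4, 3, 3), nrow = 1),
                     c("A", "A", "B", "B"))
  ns2 <- build_noise(expr2, c("A", "B"))
  expect_equal(ns2$n_points, 2L)
  expect_setequal(abs(ns2$m_star), c(1, 0))
  expect_setequal(ns2$d_star, c(2, 0))

  # 100 genes, 3+3 replicates: 100 x (3 + 3) = 600 pooled points
  set.seed(1)
  expr3 <- make_expr(matrix(rlnorm(600), 100, 6),
                     rep(c("F", "L"), each = 3))
  expect_equal(build_noise(expr3, c("F", "L"))$n_points, 600L)

  # an organ with a single replicate cannot give a null
  expr4 <- make_expr(matrix(1:6, 2, 3), c("F", "F", "L"))
  expect_error(build_noise(expr4, c("F", "L")), "insufficient replicates")
})

test_that("signal statistics use replicate means with the zero rule", {
  vals <- matrix(c(6, 10, 2, 2,     # means 8 vs 2
                   5, 5, 5, 5,      # equal means
                   0, 0, 4, 4),     # zero vs 4
                 nrow = 3, byrow = TRUE)
  expr <- make_expr(vals, c("F", "F", "L", "L"))
  sig <- signal_md(expr, c("F", "L"))
  expect_equal(sig$m, c(2, 0, log2(0.001 / 4)))
  expect_equal(sig$d, c(6, 0, 4))
})

test_that("the probability is a strict double-domination count", {
  noise <- structure(list(m_star = c(0.5, 1, 2), d_star = c(1, 2, 3),
                          n_points = 3L), class = "NoiseDistribution")
  # worked case: points (0.5,1) and (1,2) are strictly dominated
  expect_equal(deg_probability(1.5, 2.5, noise), 2 / 3)
  # m = 0 or d = 0 can never strictly dominate
  expect_identical(deg_probability(0, 10, noise), 0)
  expect_identical(deg_probability(10, 0, noise), 0)
  # a query beyond every noise point reaches exactly 1
  expect_identical(deg_probability(5, 100, noise), 1)
  empty <- structure(list(m_star = numeric(0), d_star = numeric(0),
                          n_points = 0L), class = "NoiseDistribution")
  expect_error(deg_probability(1, 1, empty), "empty noise")
})

test_that("probabilities match the brute-force oracle and its granularity", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:500, 1)
    ns <- structure(list(m_star = rnorm(n), d_star = abs(rnorm(n)),
                         n_points = n), class = "NoiseDistribution")
    m <- rnorm(1, sd = 2)
    d <- abs(rnorm(1, sd = 2))
    p <- deg_probability(m, d, ns)
    expect_identical(p, brute_probability(m, d, ns$m_star, ns$d_star))
    # p is an exact multiple of 1/n
    expect_equal(p * n, round(p * n), tolerance = 1e-9)
  }
})

test_that("probability is monotone in |m| and in d", {
  set.seed(7)
  ns <- structure(list(m_star = rnorm(300), d_star = abs(rnorm(300)),
                       n_points = 300L), class = "NoiseDistribution")
  ms <- seq(-3, 3, length.out = 25)
  d0 <- 1
  p_m <- deg_probability(ms, rep(d0, 25), ns)
  expect_true(all(diff(p_m[ms >= 0]) >= 0))
  expect_true(all(diff(p_m[ms <= 0]) <= 0))
  ds <- seq(0, 4, length.out = 25)
  p_d <- deg_probability(rep(1.5, 25), ds, ns)
  expect_true(all(diff(p_d) >= 0))
})

test_that("the call rule applies strict thresholds in both directions", {
  cfg <- pipeline_config()
  rec <- data.frame(gene = paste0("g", 1:6),
                    m = c(2.5, 2.5, -3, 2, 5, -5),
                    d = 1,
                    p = c(0.85, 0.8, 0.95, 0.9, 0.79, 0.81))
  out <- call_degs(rec, cfg)
  expect_identical(out$call,
                   c("up",      # p > 0.8 and m > 2
                     "not_de",  # p exactly at the threshold: strict
                     "down",    # |m| > 2 with negative sign
                     "not_de",  # m exactly at the threshold: strict
                     "not_de",  # p below threshold
                     "down"))
  # the signed variant never calls down
  out_s <- call_degs(rec, pipeline_config(signed_m = TRUE))
  expect_false(any(out_s$call == "down"))
  expect_error(call_degs(transform(rec, p = p + 1), cfg), "\\[0, 1\\]")
})

test_that("swapping organ order negates m, keeps d and p, swaps calls", {
  gen <- simulate_counts(n_genes = 100, reps = 3, de_fraction = 0.1,
                         unique_per_organ = 5, seed = 21)
  expr <- rpkm(gen$counts)
  fwd <- pairwise_screen(expr, list(c("F", "L")))[[1]]
  rev <- pairwise_screen(expr, list(c("L", "F")))[[1]]
  expect_equal(rev$m, -fwd$m)
  expect_identical(rev$d, fwd$d)
  expect_identical(rev$p, fwd$p)
  expect_identical(rev$call == "up", fwd$call == "down")
  expect_identical(rev$call == "not_de", fwd$call == "not_de")
})

test_that("all-zero genes are reported as not_de with p = 0", {
  vals <- matrix(c(0, 0, 0, 0,
                   5, 6, 1, 2), nrow = 2, byrow = TRUE)
  expr <- make_expr(vals, c("F", "F", "L", "L"))
  scr <- pairwise_screen(expr, list(c("F", "L")))[[1]]
  expect_equal(nrow(scr), 2L)  # output rows = input genes
  expect_identical(scr$p[1], 0)
  expect_identical(scr$call[1], "not_de")
})

test_that("three organs yield exactly three unordered comparisons", {
  gen <- simulate_counts(n_genes = 60, unique_per_organ = 0, seed = 2)
  scr <- pairwise_screen(rpkm(gen$counts))
  expect_named(scr, c("F-vs-L", "F-vs-S", "L-vs-S"))
})
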