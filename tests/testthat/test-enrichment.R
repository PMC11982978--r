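test_that("pseudocounted frequencies normalise each sample to 1", {
  ct <- toy_count_table(matrix(c(100, 300, 200, 200), 2,
                               dimnames = list(c("a", "b"), NULL)),
                        doublings = c(0, 2))
  f0 <- frequencies(ct, pseudocount = 0)
  expect_equal(unname(f0$F[, 1]), c(0.25, 0.75))
  f <- frequencies(toy_count_table(
    matrix(c(0, 100, 50, 50), 2, dimnames = list(c("a", "b"), NULL)),
    doublings = c(0, 2)), pseudocount = 0.5)
  expect_equal(unname(f$F[, 1]), c(0.5 / 101, 100.5 / 101))
  # uniform counts give uniform frequencies for any pseudocount
  u <- toy_count_table(matrix(50, 4, 2, dimnames = list(letters[1:4], NULL)),
                       doublings = c(0, 2))
  for (pc in c(0, 0.5, 2)) {
    fu <- frequencies(u, pc)
    expect_true(all(abs(fu$F - 0.25) < 1e-12))
  }
  expect_true(all(abs(colSums(f$F) - 1) < 1e-9))
})

test_that("two-point fit is exact: frequency doubling over two doublings", {
  ct <- toy_count_table(matrix(c(100, 300, 200, 200), 2,
                               dimnames = list(c("a", "b"), NULL)),
                        doublings = c(0, 2))
  es <- enrichment_scores(frequencies(ct, pseudocount = 0))
  expect_equal(es$es[es$member_id == "a"], log(2) / 2)
})

test_that("constant frequencies give exactly zero slope", {
  ct <- toy_count_table(matrix(c(100, 300, 200, 600, 300, 900), 2,
                               dimnames = list(c("a", "b"), NULL)),
                        doublings = c(0, 3, 7))
  es <- enrichment_scores(frequencies(ct, pseudocount = 0))
  expect_equal(es$es, c(0, 0))
  expect_equal(es$r2, c(NA_real_, NA_real_))  # zero variance in y
})

test_that("vectorised slope agrees with per-member lm() to 1e-10", {
  set.seed(33)
  for (trial in 1:50) {
    n <- sample(3:10, 1)
    tp <- sample(3:6, 1)
    d <- sort(c(0, runif(tp - 1, 0.5, 8)))
    counts <- matrix(rpois(n * tp, 200) + 1, n,
                     dimnames = list(paste0("m", 1:n), NULL))
    ct <- toy_count_table(counts, doublings = d)
    fm <- frequencies(ct, pseudocount = 0.5)
    es <- enrichment_scores(fm)
    y <- log(fm$F / fm$F[, 1])
    for (i in seq_len(n)) {
      ref <- unname(coef(lm(y[i, ] ~ d))[2])
      expect_equal(es$es[i], ref, tolerance = 1e-10)
    }
  }
})

test_that("members with zero baseline are excluded, not imputed to 0", {
  counts <- matrix(c(0, 100, 30, 100, 60, 100), 2,
                   dimnames = list(c("a", "b"), NULL))
  es <- enrichment_scores(frequencies(toy_count_table(counts,
                                                      c(0, 3, 7))))
  expect_true(is.na(es$es[es$member_id == "a"]))
  expect_false(is.na(es$es[es$member_id == "b"]))
})

test_that("replicate averaging follows the missing-value policy", {
  rep_es <- data.frame(member_id = "m", genotype = "WT",
                       condition = "selective", replicate = 1:3,
                       es = c(0.1, 0.2, 0.3))
  expect_equal(average_replicates(rep_es)$mean_es, 0.2)
  rep_es$es <- c(0.5, NA, 0.1)
  avg <- average_replicates(rep_es)
  expect_equal(avg$mean_es, 0.3)
  expect_equal(avg$n_replicates_used, 2)
  rep_es$es <- rep(NA_real_, 3)
  avg <- average_replicates(rep_es)
  expect_true(is.na(avg$mean_es))
  expect_equal(avg$n_replicates_used, 0)
})

test_that("Z-scores are standard scores over scored members", {
  expect_equal(zscores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(9)
  x <- rnorm(200, 5, 3)
  z <- zscores(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  # one member 10 sd above the rest must exceed Z = 3
  x <- c(rnorm(100), 10 * sd(rnorm(100)) + 15)
  expect_gt(zscores(x)[101], 3)
  expect_error(zscores(rep(1, 5)), "degenerate")
  expect_error(zscores(c(1, NA)), ">= 2")
})

test_that("screen correlation uses the shared scored members", {
  a <- setNames(c(1, 2, 3, 4, 5), paste0("m", 1:5))
  expect_equal(screen_correlation(a, a)$r, 1)
  expect_equal(screen_correlation(a, -2 * a + 7)$r, -1)
  b <- setNames(c(2, 1, 4, 3, 6), paste0("m", 1:5))
  # hand-computed covariance formula
  ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(screen_correlation(a, b)$r, ref)
  expect_equal(screen_correlation(a, b)$n, 5)
  expect_error(screen_correlation(a[1:2], b[1:2]), ">= 3")
})

test_that("scores are invariant to sequencing depth rescaling", {
  set.seed(14)
  counts <- matrix(rpois(40 * 4, 500) + 50, 40,
                   dimnames = list(paste0("m", 1:40), NULL))
  d <- c(0, 2, 4, 7)
  es1 <- enrichment_scores(frequencies(toy_count_table(counts, d), 0))
  es2 <- enrichment_scores(frequencies(toy_count_table(counts * 7, d), 0))
  expect_equal(es1$es, es2$es, tolerance = 1e-12)
  # with the default pseudocount the perturbation stays tiny at real depths
  es3 <- enrichment_scores(frequencies(toy_count_table(counts, d), 0.5))
  es4 <- enrichment_scores(frequencies(toy_count_table(counts * 10, d), 0.5))
  expect_lt(max(abs(es3$es - es4$es)), 1e-3)
})

test_that("slopes straddle zero whenever frequencies are not constant", {
  set.seed(15)
  for (trial in 1:20) {
    counts <- matrix(rpois(20 * 3, 300) + 1, 20,
                     dimnames = list(paste0("m", 1:20), NULL))
    es <- enrichment_scores(frequencies(toy_count_table(counts, c(0, 3, 7))))
    if (all(es$es == 0)) next
    expect_lte(min(es$es), 0)
    expect_gte(max(es$es), 0)
  }
})

test_that("selection widens the ES spread relative to nonselective growth", {
  cfg <- simulation_config(n_members = 300, read_depth = 2e4, seed = 31,
                           genotypes = "WT")
  lib <- build_synthetic_library(cfg)
  sc <- screen_scores(simulate_selection(lib, assign_fitness(lib, cfg), cfg))
  s <- sc$summary
  expect_gt(sd(s$mean_es[s$condition == "selective"]),
            sd(s$mean_es[s$condition == "nonselective"]))
})

test_that("all-zero samples are rejected", {
  counts <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(frequencies(toy_count_table(counts, c(0, 2))), "all-zero")
})
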