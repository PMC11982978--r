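test_that("occupancy follows the saturation formula", {
  expect_equal(occupancy(5, 5), 0.5)
  # a 10-fold affinity loss at Kd = C drops occupancy from 1/2 to 1/11
  expect_equal(occupancy(50, 5), 1 / 11)
  expect_equal(occupancy(0, 5), 1)
})

test_that("neutral selection (s = 0) gives uniform growth rates", {
  cfg <- small_config(n_members = 50, s = 0)
  lib <- build_synthetic_library(cfg)
  fit <- assign_fitness(lib, cfg)
  expect_true(all(fit$g_selective == cfg$r0))
  expect_true(all(fit$g_nonselective == cfg$r0))
})

test_that("a single saturated binder uniquely gets the full advantage", {
  cfg <- small_config(n_members = 20, s = 1)
  lib <- build_synthetic_library(cfg)
  g <- rep(cfg$r0, 20)
  g[7] <- cfg$r0 * (1 + cfg$s)   # theta -> 1; all others theta -> 0
  fit <- make_fitness(lib, g)
  ct <- simulate_selection(lib, fit, cfg, sampling = FALSE)
  final <- ct$counts[, ncol(ct$counts)]
  expect_equal(unname(which.max(final)), 7)
  expect_true(all(final[7] > final[-7]))
})

test_that("mutant fold-loss multiplies HEPTP-type Kd only", {
  cfg <- simulation_config(n_members = 60, frac_heptp = 0.3,
                           fold_loss = c(3, 40), seed = 9,
                           conditions = "selective")
  lib <- build_synthetic_library(cfg)
  fit <- assign_fitness(lib, cfg)
  wt <- fit[fit$genotype == "WT", ]
  for (mut in c("D319N", "E320K")) {
    m <- fit[fit$genotype == mut, ]
    fold <- m$kd / wt$kd
    heptp <- wt$motif_class == "HEPTP_like"
    expect_true(all(abs(fold[!heptp] - 1) < 1e-12))
    expect_true(all(fold[heptp] >= 3 - 1e-9 & fold[heptp] <= 40 + 1e-9))
  }
})

test_that("equal growth rates conserve frequencies at every doubling", {
  cfg <- small_config(n_members = 30, s = 0, doublings = c(0, 2, 4, 7))
  lib <- build_synthetic_library(cfg)
  fit <- assign_fitness(lib, cfg)
  ct <- simulate_selection(lib, fit, cfg, sampling = FALSE)
  f <- sweep(ct$counts, 2, colSums(ct$counts), "/")
  for (j in 2:ncol(f)) expect_equal(f[, j], f[, 1], tolerance = 1e-12)
})

test_that("log-frequency slope of a rare fast grower matches theory", {
  # one member at double rate starting at 1% abundance (99 neutral members)
  n <- 100
  cfg <- small_config(n_members = n, doublings = c(0, 0.5, 1),
                      read_depth = 1e6, n_replicates = 1)
  lib <- build_synthetic_library(cfg)
  r0 <- cfg$r0
  g <- c(2 * r0, rep(r0, n - 1))
  fit <- make_fitness(lib, g)
  ct <- simulate_selection(lib, fit, cfg, sampling = FALSE)
  es <- enrichment_scores(frequencies(ct, pseudocount = 0))
  slope <- es$es[es$member_id == lib$member_id[1]]
  # theory: slope -> ln 2 * (g_fast / gbar - 1) with gbar ~ r0 while rare
  expect_lt(abs(slope - log(2)) / log(2), 0.05)
  # independent numerical oracle: bisection for tau at each doubling,
  # then an lm() fit of ln(F_t/F_0) on doublings
  w <- rep(1, n)
  oracle_freq <- function(d) {
    f <- function(tau) log2(sum(w * exp(g * tau)) / sum(w)) - d
    lo <- 0; hi <- 10
    while (f(hi) < 0) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    nn <- w * exp(g * (lo + hi) / 2)
    (nn / sum(nn))[1]
  }
  fr <- vapply(cfg$doublings, oracle_freq, numeric(1))
  y <- log(fr / fr[1])
  oracle_slope <- unname(coef(lm(y ~ cfg$doublings))[2])
  expect_equal(slope, oracle_slope, tolerance = 1e-8)
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- simulation_config(n_members = 40, read_depth = 1000, seed = 21)
  lib <- build_synthetic_library(cfg)
  fit <- assign_fitness(lib, cfg)
  ct1 <- simulate_selection(lib, fit, cfg)
  ct2 <- simulate_selection(lib, fit, cfg)
  expect_identical(ct1$counts, ct2$counts)
  # replicates differ from one another (independent sampling substreams)
  sel <- ct1$samples$condition == "selective" & ct1$samples$doublings > 0
  reps <- split(ct1$samples$sample_id[sel],
                ct1$samples$replicate[sel])
  expect_false(identical(ct1$counts[, reps[[1]][1]],
                         ct1$counts[, reps[[2]][1]]))
})

test_that("sample counts always sum to the configured depth", {
  cfg <- simulation_config(n_members = 25, read_depth = 4321, seed = 2)
  lib <- build_synthetic_library(cfg)
  ct <- simulate_selection(lib, assign_fitness(lib, cfg), cfg)
  expect_true(all(colSums(ct$counts) == 4321))
})

test_that("raising one member's occupancy never lowers its final frequency", {
  lib <- build_synthetic_library(small_config(n_members = 10))
  cfg <- small_config(n_members = 10, doublings = c(0, 3, 7))
  base_g <- seq(0.35, 0.7, length.out = 10)
  for (theta_step in c(0.1, 0.3)) {
    g1 <- base_g
    g2 <- base_g
    g2[4] <- base_g[4] + cfg$r0 * cfg$s * theta_step  # higher occupancy
    f1 <- simulate_selection(lib, make_fitness(lib, g1), cfg, sampling = FALSE)
    f2 <- simulate_selection(lib, make_fitness(lib, g2), cfg, sampling = FALSE)
    last <- ncol(f1$counts)
    expect_gte(f2$counts[4, last] / sum(f2$counts[, last]),
               f1$counts[4, last] / sum(f1$counts[, last]))
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(doublings = c(1, 2)), "start at 0")
  expect_error(simulation_config(doublings = c(0, 2, 2)), "increasing")
  expect_error(simulation_config(read_depth = 0), "read_depth")
  expect_error(simulation_config(fold_loss = c(0.5, 2)), "fold_loss")
  expect_error(simulation_config(frac_heptp = 1.2), "frac_heptp")
})

test_that("FASTQ emission conserves counts and round-trips exactly", {
  cfg <- simulation_config(n_members = 20, read_depth = 400, seed = 5,
                           n_replicates = 2, doublings = c(0, 3.5, 7),
                           conditions = "selective",
                           genotypes = c("WT", "D319N"))
  lib <- build_synthetic_library(cfg)
  ct <- simulate_selection(lib, assign_fitness(lib, cfg), cfg)
  dir <- tempfile("fq")
  files <- emit_fastq(ct, lib, dir, seed = 5)
  expect_equal(unname(files$n_reads), unname(colSums(ct$counts)))
  # a member with count k contributes exactly k reads containing its insert
  one <- readLines(files$path[1])
  seqs <- one[seq(2, length(one), by = 4)]
  m <- lib$member_id[3]
  expect_equal(sum(grepl(lib$dna[3], seqs, fixed = TRUE)),
               unname(ct$counts[m, files$sample_id[1]]))
  back <- suppressMessages(count_samples(files, ct$samples, lib))
  expect_equal(back$counts, ct$counts)
  expect_true(all(as.matrix(back$unmatched[, -1]) == 0))
})

test_that("empty count table yields a valid empty FASTQ", {
  lib <- two_member_library()
  ct <- toy_count_table(matrix(0, 2, 2, dimnames = list(lib$member_id, NULL)),
                        doublings = c(0, 7))
  files <- emit_fastq(ct, lib, tempfile("fq0"))
  expect_true(all(file.exists(files$path)))
  expect_equal(files$n_reads, c(0, 0))
  expect_length(readLines(files$path[1]), 0)
})
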