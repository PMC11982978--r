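#' Configuration for a synthetic competitive screen
#'
#' Bundles the library-design, affinity, fitness-link, growth-sampling and
#' sequencing parameters that define one simulated screen of all genotypes.
#' Defaults emulate the study conditions of a pooled docking-site Y2H screen:
#' a library of ~10^4 consensus-conformant 14-mers, three replicates sampled
#' five times over ~7 population doublings, and common-docking-site mutants
#' that lose 3-40-fold affinity for HEPTP-type (I/L-x-x-R-R) members.
#'
#' @param n_members library size.
#' @param frac_heptp fraction of members carrying an N-terminal I/L-x-x-R-R
#'   match.
#' @param kd_bounds log-uniform bounds (uM) for wild-type dissociation
#'   constants of non-HEPTP members.
#' @param kd_bounds_heptp log-uniform Kd bounds (uM) for HEPTP-type members.
#'   The default is a narrow band just below `c_bait`: validated
#'   wild-type-selective docking peptides bind wild-type kinase with similar,
#'   near-saturating affinity, and only a Kd near the saturation knee lets a
#'   3-40-fold mutant penalty pull occupancy below the hit range.
#' @param fold_loss range of the multiplicative Kd penalty applied to
#'   HEPTP-type members in mutant genotypes (log-uniform draw); lower bound
#'   must be >= 1.
#' @param r0 baseline growth rate (per hour) shared by all members under
#'   nonselective conditions.
#' @param s selection coefficient: the maximal fractional growth advantage of
#'   a fully bait-occupied member under selective conditions.
#' @param c_bait effective bait concentration (uM), the half-saturation scale
#'   of the occupancy fitness link.
#' @param doublings cumulative population doublings at which samples are
#'   drawn; strictly increasing, starting at 0.
#' @param read_depth sequencing reads per sample.
#' @param n_replicates independent screen replicates (shared fitness,
#'   independent sampling).
#' @param genotypes character vector; the first entry is the wild-type
#'   reference, the rest are common-docking-site mutants.
#' @param conditions subset of `c("selective", "nonselective")`.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives plain multinomial read sampling, larger values inflate sampling
#'   variance (Dirichlet concentration `p/overdispersion`).
#' @param bottleneck optional founding-bottleneck size: mean number of
#'   founding colonies per library member (Poisson draw per replicate);
#'   `Inf` disables the bottleneck and founds every member equally.
#' @param heptp_window allowed start window of the I/L-x-x-R-R match, or
#'   `NULL` to disable HEPTP members entirely.
#' @param seed integer master seed; all randomness derives from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_members = 10000,
                              frac_heptp = 0.2,
                              kd_bounds = c(0.5, 500),
                              kd_bounds_heptp = c(0.4, 0.9),
                              fold_loss = c(3, 40),
                              r0 = 0.35,
                              s = 1,
                              c_bait = 5,
                              doublings = c(0, 1.75, 3.5, 5.25, 7),
                              read_depth = 1e5,
                              n_replicates = 3,
                              genotypes = c("WT", "D319N", "E320K"),
                              conditions = c("selective", "nonselective"),
                              overdispersion = 0,
                              bottleneck = Inf,
                              heptp_window = c(1, 4),
                              seed = 1) {
  config <- list(n_members = as.integer(n_members), frac_heptp = frac_heptp,
                 kd_bounds = kd_bounds, kd_bounds_heptp = kd_bounds_heptp,
                 fold_loss = fold_loss, r0 = r0, s = s, c_bait = c_bait,
                 doublings = doublings, read_depth = read_depth,
                 n_replicates = as.integer(n_replicates),
                 genotypes = genotypes, conditions = conditions,
                 overdispersion = overdispersion, bottleneck = bottleneck,
                 heptp_window = heptp_window, seed = as.integer(seed))
  class(config) <- "simulation_config"
  validate_simulation_config(config)
}

validate_simulation_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with(config, {
    if (n_members < 0) stop("n_members must be >= 0")
    if (frac_heptp < 0 || frac_heptp > 1) stop("frac_heptp must be in [0, 1]")
    if (frac_heptp > 0 && is.null(heptp_window))
      stop("frac_heptp > 0 requires an enabled heptp_window")
    if (doublings[1] != 0 || any(diff(doublings) <= 0))
      stop("doublings must be strictly increasing and start at 0")
    if (read_depth <= 0) stop("read_depth must be > 0")
    if (fold_loss[1] < 1 || fold_loss[2] < fold_loss[1])
      stop("fold_loss must satisfy 1 <= lower <= upper")
    if (r0 <= 0) stop("r0 must be > 0")
    if (c_bait <= 0) stop("c_bait must be > 0")
    if (overdispersion < 0) stop("overdispersion must be >= 0")
    if (n_replicates < 1) stop("n_replicates must be >= 1")
    if (!all(conditions %in% c("selective", "nonselective")))
      stop("conditions must be a subset of selective/nonselective")
  })
  config
}

## deterministic substream seeds below 2^31, derived from the master seed
substream_seed <- function(seed, index) {
  (as.double(seed) * 48271 + index * 1299721) %% 2147483647
}

#' Fractional bait occupancy
#'
#' `c_bait / (c_bait + kd)`: the equilibrium fraction of library peptide bound
#' to bait at effective bait concentration `c_bait`.
#'
#' @param kd dissociation constant(s), uM.
#' @param c_bait effective bait concentration, uM.
#' @return occupancy in `[0, 1)`.
#' @export
occupancy <- function(kd, c_bait) c_bait / (c_bait + kd)

#' Assign genotype-dependent fitness to library members
#'
#' Wild-type dissociation constants are drawn log-uniformly within
#' class-specific bounds; in mutant genotypes, HEPTP-type members have their
#' Kd multiplied by a fold-loss drawn log-uniformly from `config$fold_loss`.
#' Growth rates follow a saturating occupancy link: under selection,
#' `g = r0 * (1 + s * occupancy)`; under nonselective growth every member
#' grows at `r0`.
#'
#' @param library a [dsite_library()].
#' @param config a [simulation_config()].
#' @return a `fitness_map` data.frame with one row per (genotype, member):
#'   columns `genotype`, `member_id`, `motif_class`, `kd`, `occupancy`,
#'   `g_selective`, `g_nonselective`.
#' @export
assign_fitness <- function(library, config) {
  config <- validate_simulation_config(config)
  if (nrow(library) == 0) stop("library must be non-empty")
  set.seed(substream_seed(config$seed, 2))
  n <- nrow(library)
  is_heptp <- library$motif_class == "HEPTP_like"
  lg <- function(b, k) 10^runif(k, log10(b[1]), log10(b[2]))
  kd_wt <- numeric(n)
  kd_wt[!is_heptp] <- lg(config$kd_bounds, sum(!is_heptp))
  kd_wt[is_heptp] <- lg(config$kd_bounds_heptp, sum(is_heptp))
  out <- lapply(seq_along(config$genotypes), function(gi) {
    genotype <- config$genotypes[gi]
    kd <- kd_wt
    if (gi > 1 && any(is_heptp))
      kd[is_heptp] <- kd[is_heptp] * lg(config$fold_loss, sum(is_heptp))
    theta <- occupancy(kd, config$c_bait)
    data.frame(genotype = genotype, member_id = library$member_id,
               motif_class = library$motif_class, kd = kd,
               occupancy = theta,
               g_selective = config$r0 * (1 + config$s * theta),
               g_nonselective = config$r0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fitness_map", "data.frame")
  res
}

## solve for chronological time tau at which the population has completed
## `d` cumulative doublings: log2(sum(w exp(g tau)) / sum(w)) = d
time_at_doubling <- function(d, w, g) {
  if (d == 0) return(0)
  if (max(g) <= 0) stop("internal error: total abundance is non-increasing")
  f <- function(tau) log2(sum(w * exp(g * tau)) / sum(w)) - d
  upper <- d * log(2) / min(g[g > 0])
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Simulate competitive selection and sequencing
#'
#' The deterministic core grows member abundances exponentially,
#' `N_i(tau) = N_i(0) * exp(g_i * tau)`, and solves for the chronological time
#' at which the whole population has completed each requested cumulative
#' doubling. Reads are then drawn multinomially (optionally
#' Dirichlet-multinomially) at the configured depth. Replicates share the true
#' fitness and differ only through independent sampling substreams of the
#' master seed.
#'
#' @param library a [dsite_library()].
#' @param fitness a `fitness_map` from [assign_fitness()].
#' @param config a [simulation_config()].
#' @param sampling if `FALSE`, emit expected (real-valued) counts
#'   `depth * frequency` with no sampling noise ("infinite-depth" mode).
#' @return a [count_table()] with one column per
#'   (genotype, condition, replicate, doubling).
#' @export
simulate_selection <- function(library, fitness, config, sampling = TRUE) {
  config <- validate_simulation_config(config)
  if (config$read_depth <= 0) stop("read_depth must be > 0")
  n <- nrow(library)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = config$conditions,
                      genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  cols <- list()
  meta <- list()
  for (row in seq_len(nrow(grid))) {
    genotype <- grid$genotype[row]
    condition <- grid$condition[row]
    rep_i <- grid$replicate[row]
    fit <- fitness[fitness$genotype == genotype, ]
    fit <- fit[match(library$member_id, fit$member_id), ]
    g <- if (condition == "selective") fit$g_selective else fit$g_nonselective
    set.seed(substream_seed(config$seed, 1000 + row))
    w0 <- if (is.finite(config$bottleneck))
      rpois(n, config$bottleneck) else rep(1, n)
    if (sum(w0) == 0) stop("founding bottleneck extinguished the library")
    for (ti in seq_along(config$doublings)) {
      d <- config$doublings[ti]
      tau <- time_at_doubling(d, w0, g)
      p <- w0 * exp(g * tau)
      p <- p / sum(p)
      counts <- if (!sampling) {
        config$read_depth * p
      } else {
        set.seed(substream_seed(config$seed, 10000 + row * 100 + ti))
        if (config$overdispersion > 0) {
          alpha <- p / config$overdispersion
          pp <- rgamma(n, shape = alpha)
          if (sum(pp) == 0) pp <- p
          p <- pp / sum(pp)
        }
        as.numeric(rmultinom(1, size = config$read_depth, prob = p))
      }
      sample_id <- sprintf("%s_%s_r%d_t%d", genotype,
                           substr(condition, 1, 3), rep_i, ti)
      cols[[sample_id]] <- counts
      meta[[sample_id]] <- data.frame(sample_id = sample_id,
                                      genotype = genotype,
                                      condition = condition,
                                      replicate = rep_i, doublings = d)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- library$member_id
  count_table(counts, do.call(rbind, meta))
}

#' Default amplicon anchor sequences
#'
#' Fixed construct flanks written around each library insert by
#' [emit_fastq()] and searched for by [extract_variable_region()].
#'
#' @return named character vector with entries `anchor5` and `anchor3`.
#' @export
default_anchors <- function() {
  c(anchor5 = "GGATCCGAAGGAGG", anchor3 = "TAAGCTTGGCACTG")
}

#' Write simulated reads as FASTQ
#'
#' Each sample's counts become reads of structure
#' `anchor5 + member_dna + anchor3` with constant quality, shuffled
#' deterministically under the sample's seed substream.
#'
#' @param ct a [count_table()] whose rownames appear in `library`.
#' @param library a [dsite_library()].
#' @param dir output directory (created if needed).
#' @param anchors length-2 character vector `(anchor5, anchor3)`.
#' @param seed integer seed controlling read order.
#' @param gzip write gzip-compressed files.
#' @return data.frame with `sample_id`, `path`, `n_reads`.
#' @export
emit_fastq <- function(ct, library, dir, anchors = default_anchors(),
                       seed = 1, gzip = FALSE) {
  if (any(!nzchar(anchors)) || length(anchors) != 2)
    stop("anchors must be two non-empty DNA strings")
  if (nrow(library) > 0 &&
      any(grepl(anchors[1], library$dna, fixed = TRUE) |
          grepl(anchors[2], library$dna, fixed = TRUE)))
    warning("an anchor occurs inside a library insert; ",
            "round-trip counting may be inexact", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- setNames(library$dna, library$member_id)
  out <- vector("list", ncol(ct$counts))
  for (j in seq_len(ncol(ct$counts))) {
    sample_id <- colnames(ct$counts)[j]
    counts <- round(ct$counts[, j])
    ids <- rep(rownames(ct$counts), counts)
    set.seed(substream_seed(seed, 20000 + j))
    if (length(ids) > 1) ids <- ids[sample.int(length(ids))]
    path <- file.path(dir, paste0(sample_id, ".fastq",
                                  if (gzip) ".gz" else ""))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    on.exit(close(con), add = TRUE)
    if (length(ids) > 0) {
      reads <- paste0(anchors[1], dna[ids], anchors[2])
      qual <- strrep("I", nchar(reads[1]))
      writeLines(paste0("@", sample_id, "_", seq_along(ids), "\n",
                        reads, "\n+\n", qual), con)
    }
    close(con)
    on.exit()
    out[[j]] <- data.frame(sample_id = sample_id, path = path,
                           n_reads = length(ids))
  }
  do.call(rbind, out)
}
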