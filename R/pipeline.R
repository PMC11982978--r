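#' Default run configuration
#'
#' One nested list drives every pipeline stage. Any element can be overridden
#' via a YAML file ([read_run_config()]) or by argument.
#'
#' @param simulation a [simulation_config()].
#' @param pseudocount frequency pseudocount for scoring.
#' @param z_threshold,relaxed_pct,top_n comparison options.
#' @param heptp_window motif-scan start window.
#' @param via_fastq route the simulated counts through FASTQ emission and
#'   re-counting (slower; exercises the counting stage).
#' @param seed master seed (overrides `simulation$seed`).
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       pseudocount = 0.5, z_threshold = 3,
                       relaxed_pct = 3, top_n = 20,
                       heptp_window = c(1, 4), via_fastq = FALSE,
                       seed = NULL) {
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(simulation = validate_simulation_config(simulation),
                 pseudocount = pseudocount, z_threshold = z_threshold,
                 relaxed_pct = relaxed_pct, top_n = top_n,
                 heptp_window = heptp_window, via_fastq = via_fastq),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `simulation` block
#' mirrors [simulation_config()].
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$doublings)) sim_args$doublings <-
    as.numeric(sim_args$doublings)
  sim <- do.call(simulation_config, sim_args)
  args <- y[setdiff(names(y), "simulation")]
  do.call(run_config, c(list(simulation = sim), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-screen workflow
#'
#' simulate -> (optionally FASTQ + count) -> score -> compare -> motif, for
#' one wild-type + two-mutant screen trio. Deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, all intermediate TSVs and a
#'   `summary.json` are written there.
#' @return list with `library`, `fitness`, `counts`, `scores`, `comparison`,
#'   `plogo_wt_unique` and `summary` (hit counts per genotype, Venn cells,
#'   wild-type-unique motif fraction, screen correlations, seed).
#' @export
run_end_to_end <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  library <- stage("simulate", build_synthetic_library(sim))
  fitness <- stage("simulate", assign_fitness(library, sim))
  counts <- stage("simulate", simulate_selection(library, fitness, sim))
  if (config$via_fastq) {
    dir <- file.path(outdir %||% tempdir(), "fastq")
    files <- stage("count", emit_fastq(counts, library, dir, seed = sim$seed))
    counts <- stage("count",
                    suppressMessages(count_samples(files, counts$samples,
                                                   library)))
  }
  scores <- stage("score", screen_scores(counts, config$pseudocount))
  comparison <- stage("compare",
                      compare_screens(scores, genotypes = sim$genotypes,
                                      z_threshold = config$z_threshold,
                                      relaxed_pct = config$relaxed_pct,
                                      n_top = config$top_n))
  wt_unique <- comparison$categories$wt_unique
  heptp <- heptp_motif(window = config$heptp_window)
  pep <- setNames(library$peptide, library$member_id)
  motif_frac <- if (length(wt_unique) > 0)
    mean(matches_motif(pep[wt_unique], heptp)) else NA_real_
  plogo <- if (length(wt_unique) > 0) {
    stage("motif",
          positional_overrepresentation(pep[wt_unique], library$peptide))
  } else NULL
  es <- lapply(sim$genotypes, function(g) mean_es_vector(scores, g))
  correlations <- list()
  for (i in seq_along(es)) for (j in seq_along(es)) if (i < j)
    correlations[[paste(sim$genotypes[i], sim$genotypes[j], sep = "_vs_")]] <-
      screen_correlation(es[[i]], es[[j]])$r
  summary <- list(
    seed = sim$seed,
    n_members = nrow(library),
    hits = as.list(lengths(comparison$hits)),
    venn = as.list(comparison$categories$venn),
    n_wt_unique = length(wt_unique),
    n_common = length(comparison$categories$common),
    n_gained = length(comparison$categories$gained),
    wt_unique_heptp_fraction = motif_frac,
    gained_in_wt_relaxed_frac = comparison$gained_in_wt_relaxed_frac,
    screen_correlations = correlations)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_library_tsv(library, file.path(outdir, "library.tsv"))
    write_count_table(counts, file.path(outdir, "screen"))
    write_screen_scores(scores, file.path(outdir, "scores"))
    utils::write.table(comparison$differential,
                       file.path(outdir, "differential_top.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(library = library, fitness = fitness, counts = counts,
       scores = scores, comparison = comparison,
       plogo_wt_unique = plogo, summary = summary)
}

#' Recompute the published screen comparison from deposited score tables
#'
#' Consumes the study's supplementary per-screen score tables (one TSV per
#' genotype with columns `member_id`, `mean_es`, `z`; deposited alongside GEO
#' series GSE286340/GSE286341) and recomputes hit counts, Venn categories,
#' the relaxed-threshold fraction of gained hits, and the HEPTP-motif
#' fraction of the top differential sequences. The tables are not shipped
#' with the package; supply the downloaded files.
#'
#' @param paths named character vector of TSV paths, wild type first.
#' @param peptides optional named character vector (member id -> peptide) for
#'   the motif fraction.
#' @param z_threshold,relaxed_pct,n_top analysis parameters.
#' @return list with `hits`, `venn`, `n_gained`, `wt_unique_fraction`,
#'   `gained_in_wt_relaxed_frac`, `differential`, `top_heptp_fraction`.
#' @export
reproduce_published_comparison <- function(paths, peptides = NULL,
                                           z_threshold = 3, relaxed_pct = 3,
                                           n_top = 20) {
  if (length(paths) != 3) stop("expected three score tables, wild type first")
  tabs <- lapply(paths, function(p) {
    t <- utils::read.delim(p)
    if (!all(c("member_id", "mean_es", "z") %in% names(t)))
      stop("score table ", p, " needs member_id, mean_es, z columns")
    t
  })
  zs <- lapply(tabs, function(t) setNames(t$z, t$member_id))
  es <- lapply(tabs, function(t) setNames(t$mean_es, t$member_id))
  hits <- lapply(zs, call_hits, z_threshold = z_threshold)
  categories <- categorize_hits(hits[[1]], hits[[2]], hits[[3]],
                                mutant_names = names(paths)[2:3] %||%
                                  c("m1", "m2"))
  relaxed_wt <- relaxed_rank_threshold(es[[1]], pct = relaxed_pct)
  differential <- rank_differential(es[[1]], es[[2]], es[[3]],
                                    candidates = categories$wt_unique,
                                    n_top = n_top)
  top_frac <- if (!is.null(peptides))
    mean(matches_motif(peptides[differential$member_id], heptp_motif()))
  else NA_real_
  list(hits = lengths(hits), venn = categories$venn,
       n_gained = length(categories$gained),
       wt_unique_fraction = length(categories$wt_unique) /
         max(1L, length(hits[[1]])),
       gained_in_wt_relaxed_frac = if (length(categories$gained) > 0)
         mean(categories$gained %in% relaxed_wt) else NA_real_,
       differential = differential, top_heptp_fraction = top_frac)
}
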