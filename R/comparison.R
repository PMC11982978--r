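#' Call hits from Z-scores
#'
#' A member is a hit when its Z-score strictly exceeds the threshold
#' (the boundary `Z == z_threshold` is excluded; set `strict = FALSE` for an
#' inclusive boundary).
#'
#' @param z named numeric vector of Z-scores (names are member ids; `NA`
#'   never qualifies).
#' @param z_threshold hit threshold, default 3.
#' @param strict use strict `>` (default) or `>=`.
#' @return character vector of hit member ids.
#' @export
call_hits <- function(z, z_threshold = 3, strict = TRUE) {
  ok <- !is.na(z) & if (strict) z > z_threshold else z >= z_threshold
  names(z)[ok]
}

#' Categorise hits across wild-type and two mutant screens
#'
#' `WT_unique` (lost interactors) are wild-type hits in neither mutant;
#' `common` are wild-type hits shared with at least one mutant; `gained` are
#' hits in *both* mutants but not wild type. All seven Venn cells are also
#' reported.
#'
#' @param hits_wt,hits_m1,hits_m2 character vectors of hit member ids over a
#'   shared member universe.
#' @param mutant_names labels for the two mutant screens.
#' @return list with `wt_unique`, `common`, `gained`, `m1_only`, `m2_only`,
#'   `common_either` / `common_both` (wild-type hits shared with >= 1 / both
#'   mutants) and `venn` (named cell sizes).
#' @export
categorize_hits <- function(hits_wt, hits_m1, hits_m2,
                            mutant_names = c("m1", "m2")) {
  u <- union(hits_m1, hits_m2)
  b <- intersect(hits_m1, hits_m2)
  venn <- c(
    wt_only = length(setdiff(hits_wt, u)),
    m1_only = length(setdiff(hits_m1, union(hits_wt, hits_m2))),
    m2_only = length(setdiff(hits_m2, union(hits_wt, hits_m1))),
    wt_m1 = length(setdiff(intersect(hits_wt, hits_m1), hits_m2)),
    wt_m2 = length(setdiff(intersect(hits_wt, hits_m2), hits_m1)),
    m1_m2 = length(setdiff(b, hits_wt)),
    all = length(intersect(hits_wt, b)))
  names(venn) <- c("wt_only", paste0(mutant_names[1], "_only"),
                   paste0(mutant_names[2], "_only"),
                   paste0("wt_", mutant_names[1]),
                   paste0("wt_", mutant_names[2]),
                   paste(mutant_names, collapse = "_"), "all")
  list(wt_unique = sort(setdiff(hits_wt, u)),
       common = sort(intersect(hits_wt, u)),
       gained = sort(setdiff(b, hits_wt)),
       m1_only = sort(setdiff(hits_m1, union(hits_wt, hits_m2))),
       m2_only = sort(setdiff(hits_m2, union(hits_wt, hits_m1))),
       common_either = sort(intersect(hits_wt, u)),
       common_both = sort(intersect(hits_wt, b)),
       venn = venn)
}

#' Relaxed top-percentile membership
#'
#' The `ceil(pct * N / 100)` members with the highest mean ES; boundary ties
#' are broken by lexicographic member id.
#'
#' @param mean_es named numeric vector (`NA` members are not eligible).
#' @param pct percentage of the scored members to keep.
#' @return character vector of member ids.
#' @export
relaxed_rank_threshold <- function(mean_es, pct = 3) {
  mean_es <- mean_es[!is.na(mean_es)]
  n_keep <- ceiling(pct * length(mean_es) / 100)
  ord <- order(-mean_es, names(mean_es))
  names(mean_es)[ord][seq_len(min(n_keep, length(mean_es)))]
}

#' Rank wild-type-selective differentials
#'
#' For each candidate, `delta = mean_es_wt - (mean_es_m1 + mean_es_m2) / 2`
#' (alternative metrics: the maximum of the two mutant scores, or per-mutant
#' differences). Candidates missing a score in any screen are dropped with a
#' warning. Returned in descending delta order, ties broken by member id.
#'
#' @param es_wt,es_m1,es_m2 named numeric mean-ES vectors.
#' @param candidates member ids to rank (default: all wild-type-scored
#'   members).
#' @param n_top number of top entries to return.
#' @param metric `"mean"` (default) or `"max"` of the mutant scores.
#' @return data.frame `member_id`, `es_wt`, `es_m1`, `es_m2`, `delta`, with
#'   the full ranking as attribute `"full"`.
#' @export
rank_differential <- function(es_wt, es_m1, es_m2,
                              candidates = names(es_wt), n_top = 20,
                              metric = c("mean", "max")) {
  metric <- match.arg(metric)
  d <- data.frame(member_id = candidates,
                  es_wt = es_wt[candidates],
                  es_m1 = es_m1[candidates],
                  es_m2 = es_m2[candidates], row.names = NULL)
  bad <- is.na(d$es_wt) | is.na(d$es_m1) | is.na(d$es_m2)
  if (any(bad)) {
    warning(sum(bad), " candidate(s) missing a screen score were dropped",
            call. = FALSE)
    d <- d[!bad, ]
  }
  mut <- if (metric == "mean") (d$es_m1 + d$es_m2) / 2 else pmax(d$es_m1, d$es_m2)
  d$delta <- d$es_wt - mut
  d <- d[order(-d$delta, d$member_id), ]
  rownames(d) <- NULL
  top <- utils::head(d, n_top)
  attr(top, "full") <- d
  top
}

#' Compare wild-type and mutant screens
#'
#' Hit calling, Venn categorisation, relaxed top-percentile membership and
#' differential ranking for one condition of a multi-genotype
#' [screen_scores()] object. The first genotype in `genotypes` is treated as
#' the wild-type reference; exactly two mutants are compared.
#'
#' @param scores a `screen_scores` object.
#' @param genotypes length-3 character vector, wild type first.
#' @param condition screen condition to compare.
#' @param z_threshold hit threshold (strict `>`).
#' @param relaxed_pct percentage for [relaxed_rank_threshold()].
#' @param n_top differential ranking depth.
#' @return a `comparison_result` list: `hits` (per genotype), `categories`
#'   (from [categorize_hits()]), `relaxed` (per genotype),
#'   `gained_in_wt_relaxed_frac` (fraction of gained hits inside the
#'   wild-type relaxed set), `differential` (top table), `params`.
#' @export
compare_screens <- function(scores, genotypes = c("WT", "D319N", "E320K"),
                            condition = "selective", z_threshold = 3,
                            relaxed_pct = 3, n_top = 20) {
  if (length(genotypes) != 3)
    stop("compare_screens expects one wild type and two mutants")
  s <- scores$summary
  zs <- lapply(genotypes, function(g) {
    gi <- s[s$genotype == g & s$condition == condition, ]
    if (nrow(gi) == 0) stop("no scores for genotype ", g)
    setNames(gi$z, gi$member_id)
  })
  es <- lapply(genotypes, function(g) mean_es_vector(scores, g, condition))
  names(zs) <- names(es) <- genotypes
  hits <- lapply(zs, call_hits, z_threshold = z_threshold)
  categories <- categorize_hits(hits[[1]], hits[[2]], hits[[3]],
                                mutant_names = genotypes[2:3])
  relaxed <- lapply(es, relaxed_rank_threshold, pct = relaxed_pct)
  gained <- categories$gained
  gained_frac <- if (length(gained) > 0)
    mean(gained %in% relaxed[[1]]) else NA_real_
  differential <- rank_differential(es[[1]], es[[2]], es[[3]],
                                    candidates = categories$wt_unique,
                                    n_top = n_top)
  structure(list(hits = hits, categories = categories, relaxed = relaxed,
                 gained_in_wt_relaxed_frac = gained_frac,
                 differential = differential,
                 params = list(genotypes = genotypes, condition = condition,
                               z_threshold = z_threshold,
                               relaxed_pct = relaxed_pct, n_top = n_top)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Screen comparison (", x$params$condition, ", Z > ",
      x$params$z_threshold, ")\n", sep = "")
  cat("hits:", paste(sprintf("%s=%d", names(x$hits),
                             lengths(x$hits)), collapse = ", "), "\n")
  cat(sprintf("lost (wt-unique): %d, common: %d, gained: %d\n",
              length(x$categories$wt_unique), length(x$categories$common),
              length(x$categories$gained)))
  invisible(x)
}
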