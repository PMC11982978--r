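#' Member frequencies with pseudocounting
#'
#' `F_ij = (c_ij + pseudocount) / sum_i (c_ij + pseudocount)`, so every column
#' sums to 1 and all entries are positive. Members whose *raw* baseline
#' (doublings-0) count is zero in a replicate are flagged: their slope in
#' that replicate would be anchored at an imputed baseline, so they are
#' excluded from enrichment scoring there rather than rescued by the
#' pseudocount.
#'
#' @param ct a [count_table()].
#' @param pseudocount added uniformly to every cell before normalisation.
#' @return a `frequency_matrix` object: list with `F` (member x sample),
#'   `samples`, `pseudocount` and `baseline_zero` (member x series logical
#'   matrix, columns named `genotype.condition.replicate`).
#' @export
frequencies <- function(ct, pseudocount = 0.5) {
  if (any(ct$totals == 0))
    stop("all-zero sample(s): ",
         paste(ct$samples$sample_id[ct$totals == 0], collapse = ", "))
  cc <- ct$counts + pseudocount
  f <- sweep(cc, 2, colSums(cc), "/")
  base <- ct$samples$doublings == 0
  series <- interaction(ct$samples$genotype, ct$samples$condition,
                        ct$samples$replicate, drop = TRUE)
  bz <- sapply(levels(series), function(l) {
    j <- which(series == l & base)
    ct$counts[, j[1]] == 0
  })
  if (!is.matrix(bz))
    bz <- matrix(bz, nrow = nrow(ct$counts),
                 dimnames = list(rownames(ct$counts), levels(series)))
  structure(list(F = f, samples = ct$samples, pseudocount = pseudocount,
                 baseline_zero = bz),
            class = "frequency_matrix")
}

## vectorised OLS of y (members x timepoints) on d, free intercept;
## returns slope, intercept, r2, residual standard error per member
ols_by_row <- function(y, d) {
  dc <- d - mean(d)
  ybar <- rowMeans(y)
  sxx <- sum(dc^2)
  slope <- as.numeric((y %*% dc) / sxx)
  intercept <- ybar - slope * mean(d)
  fitted <- outer(slope, d) + intercept
  resid <- y - fitted
  sse <- rowSums(resid^2)
  sst <- rowSums((y - ybar)^2)
  n <- length(d)
  data.frame(
    es = slope, intercept = intercept,
    r2 = ifelse(sst > 0, 1 - sse / sst, NA_real_),
    rse = if (n > 2) sqrt(pmax(sse, 0) / (n - 2)) else NA_real_,
    n_points = n)
}

#' Per-replicate enrichment scores
#'
#' For each member and replicate series, `y_t = ln(F_t / F_0)` is regressed on
#' cumulative population doublings by ordinary least squares with a free
#' intercept; the enrichment score (ES) is the fitted slope. The baseline
#' point `(0, 0)` enters the regression as data. Members flagged at baseline
#' (raw count 0 at doublings 0) get `NA` for that replicate.
#'
#' @param fm a `frequency_matrix` from [frequencies()].
#' @return data.frame with one row per (genotype, condition, replicate,
#'   member): `es`, `intercept`, `r2`, `rse`, `n_points`.
#' @export
enrichment_scores <- function(fm) {
  stopifnot(inherits(fm, "frequency_matrix"))
  s <- fm$samples
  series <- interaction(s$genotype, s$condition, s$replicate, drop = TRUE)
  out <- lapply(levels(series), function(l) {
    j <- which(series == l)
    j <- j[order(s$doublings[j])]
    d <- s$doublings[j]
    if (length(d) < 2 || d[1] != 0)
      stop("series ", l, " needs >= 2 timepoints including doublings 0")
    f <- fm$F[, j, drop = FALSE]
    y <- log(f / f[, 1])
    fit <- ols_by_row(y, d)
    flag <- fm$baseline_zero[, l]
    fit[flag, c("es", "intercept", "r2", "rse")] <- NA_real_
    data.frame(member_id = rownames(fm$F),
               genotype = s$genotype[j[1]], condition = s$condition[j[1]],
               replicate = s$replicate[j[1]], fit, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Average enrichment scores across replicates
#'
#' Unweighted mean over replicates where the ES is defined; members with no
#' usable replicate stay missing.
#'
#' @param rep_es per-replicate ES data.frame from [enrichment_scores()].
#' @return data.frame with one row per (genotype, condition, member):
#'   `mean_es`, `n_replicates_used`.
#' @export
average_replicates <- function(rep_es) {
  key <- interaction(rep_es$genotype, rep_es$condition, rep_es$member_id,
                     drop = TRUE)
  agg <- lapply(split(rep_es, key), function(g) {
    ok <- !is.na(g$es)
    data.frame(member_id = g$member_id[1], genotype = g$genotype[1],
               condition = g$condition[1],
               mean_es = if (any(ok)) mean(g$es[ok]) else NA_real_,
               n_replicates_used = sum(ok))
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$genotype, res$condition, res$member_id), ]
  rownames(res) <- NULL
  res
}

#' Standard scores within a screen
#'
#' `Z_i = (x_i - mean) / sd` over the scored (non-missing) members, with the
#' sample (n-1) standard deviation.
#'
#' @param x numeric vector of replicate-averaged enrichment scores.
#' @return numeric vector of Z-scores (`NA` preserved).
#' @export
zscores <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need >= 2 scored members to compute Z-scores")
  s <- sd(x[ok])
  if (s == 0) stop("degenerate screen: zero ES standard deviation")
  (x - mean(x[ok])) / s
}

#' Score one or more screens end to end
#'
#' Convenience wrapper: frequencies, per-replicate slopes, replicate
#' averaging, and per-(genotype, condition) Z-scores.
#'
#' @param ct a [count_table()].
#' @param pseudocount passed to [frequencies()].
#' @return a `screen_scores` list with elements `replicates` (per-replicate
#'   ES table) and `summary` (per-member `mean_es`, `n_replicates_used`,
#'   `z`).
#' @export
screen_scores <- function(ct, pseudocount = 0.5) {
  rep_es <- enrichment_scores(frequencies(ct, pseudocount))
  summary <- average_replicates(rep_es)
  ## per-replicate Z supports the "hit in all replicates" consistency filter
  rep_key <- interaction(rep_es$genotype, rep_es$condition, rep_es$replicate,
                         drop = TRUE)
  rep_es$z <- unsplit(lapply(split(rep_es$es, rep_key), zscores), rep_key)
  key <- interaction(summary$genotype, summary$condition, drop = TRUE)
  summary$z <- unsplit(lapply(split(summary$mean_es, key), zscores), key)
  structure(list(replicates = rep_es, summary = summary),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("screen_scores: %d members, screens: %s\n",
              length(unique(x$summary$member_id)),
              paste(unique(paste(x$summary$genotype, x$summary$condition,
                                 sep = "/")), collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between two screens
#'
#' Computed over members scored in both screens.
#'
#' @param es_a,es_b named numeric vectors of replicate-averaged ES (names are
#'   member ids).
#' @return list with `r` and `n` (members used).
#' @export
screen_correlation <- function(es_a, es_b) {
  shared <- intersect(names(es_a)[!is.na(es_a)], names(es_b)[!is.na(es_b)])
  if (length(shared) < 3)
    stop("need >= 3 members scored in both screens")
  list(r = cor(es_a[shared], es_b[shared]), n = length(shared))
}

#' Extract a named mean-ES vector for one screen
#'
#' @param scores a `screen_scores` object.
#' @param genotype,condition screen selector.
#' @return named numeric vector of `mean_es`.
#' @export
mean_es_vector <- function(scores, genotype, condition = "selective") {
  s <- scores$summary
  s <- s[s$genotype == genotype & s$condition == condition, ]
  setNames(s$mean_es, s$member_id)
}

#' Write screen scores as TSV
#'
#' @param scores a `screen_scores` object.
#' @param stem path stem; writes `<stem>_replicate_es.tsv` and
#'   `<stem>_summary.tsv`.
#' @return the stem, invisibly.
#' @export
write_screen_scores <- function(scores, stem) {
  utils::write.table(scores$replicates, paste0(stem, "_replicate_es.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scores$summary, paste0(stem, "_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}
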