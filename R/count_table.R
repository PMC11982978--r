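#' Member-by-sample count table
#'
#' The central container linking a read-count matrix to its sample metadata
#' and, for counted FASTQ input, the per-sample tally of discarded reads.
#'
#' @param counts numeric matrix, members x samples, non-negative; rownames are
#'   member ids, colnames sample ids. Non-integer values are allowed only for
#'   expected-count (infinite-depth) simulations.
#' @param samples data.frame with columns `sample_id`, `genotype`,
#'   `condition` (`"selective"` or `"nonselective"`), `replicate`,
#'   `doublings` (cumulative population doublings, >= 0).
#' @param unmatched optional data.frame of per-sample discarded-read counts
#'   with columns `sample_id`, `no_anchor`, `bad_length`,
#'   `stop_or_ambiguous`, `not_in_whitelist`.
#' @param require_baseline if `TRUE`, every (genotype, condition, replicate)
#'   series must include a sample at doublings 0 (the enrichment-score
#'   baseline).
#' @return a `count_table` object.
#' @export
count_table <- function(counts, samples, unmatched = NULL,
                        require_baseline = TRUE) {
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples)
  req <- c("sample_id", "genotype", "condition", "replicate", "doublings")
  missing <- setdiff(req, names(samples))
  if (length(missing) > 0)
    stop("sample metadata missing columns: ", paste(missing, collapse = ", "))
  if (!all(samples$condition %in% c("selective", "nonselective")))
    stop("condition must be 'selective' or 'nonselective'")
  if (any(samples$doublings < 0)) stop("doublings must be >= 0")
  if (ncol(counts) != nrow(samples) ||
      !identical(colnames(counts), samples$sample_id))
    stop("count columns must match samples$sample_id exactly, in order")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (require_baseline) {
    grp <- interaction(samples$genotype, samples$condition, samples$replicate,
                       drop = TRUE)
    has0 <- tapply(samples$doublings, grp, function(d) any(d == 0))
    if (!all(has0))
      stop("missing doublings-0 baseline sample for: ",
           paste(names(has0)[!has0], collapse = ", "))
  }
  ## order columns for stable downstream output
  ord <- order(samples$genotype, samples$condition, samples$replicate,
               samples$doublings)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (!is.null(unmatched)) {
    unmatched <- as.data.frame(unmatched)
    unmatched <- unmatched[match(samples$sample_id, unmatched$sample_id), ,
                           drop = FALSE]
    rownames(unmatched) <- NULL
  }
  structure(list(counts = counts, samples = samples,
                 totals = colSums(counts), unmatched = unmatched),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d members x %d samples (%s genotypes, %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$genotype), collapse = "/"),
              paste(unique(x$samples$condition), collapse = "/")))
  invisible(x)
}

#' Subset a count table to one screen
#'
#' @param ct a [count_table()].
#' @param genotype,condition values to keep (either may be `NULL` for all).
#' @return a [count_table()].
#' @export
subset_count_table <- function(ct, genotype = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(ct$samples))
  if (!is.null(genotype)) keep <- keep & ct$samples$genotype %in% genotype
  if (!is.null(condition)) keep <- keep & ct$samples$condition %in% condition
  count_table(ct$counts[, keep, drop = FALSE],
              ct$samples[keep, , drop = FALSE],
              unmatched = if (is.null(ct$unmatched)) NULL else
                ct$unmatched[keep, , drop = FALSE])
}

#' Read / write count tables as TSV
#'
#' `write_count_table` writes `<stem>_counts.tsv` (member_id x sample matrix),
#' `<stem>_samples.tsv` and, when present, `<stem>_unmatched.tsv`;
#' `read_count_table` reads them back.
#'
#' @param ct a [count_table()].
#' @param stem path stem for the three TSV files.
#' @return `read_count_table` returns a [count_table()];
#'   `write_count_table` the stem, invisibly.
#' @export
write_count_table <- function(ct, stem) {
  cdf <- data.frame(member_id = rownames(ct$counts), ct$counts,
                    check.names = FALSE)
  utils::write.table(cdf, paste0(stem, "_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ct$samples, paste0(stem, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ct$unmatched))
    utils::write.table(ct$unmatched, paste0(stem, "_unmatched.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(stem) {
  cdf <- utils::read.delim(paste0(stem, "_counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$member_id
  samples <- utils::read.delim(paste0(stem, "_samples.tsv"),
                               colClasses = c(sample_id = "character",
                                              genotype = "character",
                                              condition = "character"))
  upath <- paste0(stem, "_unmatched.tsv")
  unmatched <- if (file.exists(upath)) utils::read.delim(upath) else NULL
  count_table(counts, samples, unmatched = unmatched)
}
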