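#' Extract the variable region between amplicon anchors
#'
#' Returns the substring strictly between the first exact occurrence of
#' `anchor5` and the first subsequent exact occurrence of `anchor3`;
#' `NA` when either anchor is absent. Forward strand only, no mismatch
#' tolerance.
#'
#' @param read_dna character vector of read sequences.
#' @param anchors length-2 character vector `(anchor5, anchor3)`.
#' @return character vector of extracted regions (`NA` = miss).
#' @export
#' @examples
#' extract_variable_region("AAAGGGTTT", c("AAA", "TTT"))
extract_variable_region <- function(read_dna, anchors = default_anchors()) {
  if (any(!nzchar(anchors)) || length(anchors) != 2)
    stop("anchors must be two non-empty DNA strings")
  p5 <- regexpr(anchors[1], read_dna, fixed = TRUE)
  region <- rep(NA_character_, length(read_dna))
  has5 <- p5 > 0
  if (any(has5)) {
    from <- p5[has5] + nchar(anchors[1])
    tail5 <- substr(read_dna[has5], from, nchar(read_dna[has5]))
    p3 <- regexpr(anchors[2], tail5, fixed = TRUE)
    got <- p3 > 0
    region[has5][got] <- substr(tail5[got], 1, p3[got] - 1)
  }
  region
}

#' Match an extracted region to a library member
#'
#' Regions with the wrong length are rejected (`bad_length`: length different
#' from the library insert length or not divisible by 3); regions whose
#' translation contains a stop or ambiguous codon are rejected
#' (`stop_or_ambiguous`). Surviving regions are matched first by exact DNA,
#' then by exact translated peptide (tolerating synonymous substitutions);
#' anything else is `not_in_whitelist`. Matching is exact, 0 mismatches.
#'
#' @param region character vector of extracted regions (`NA` allowed,
#'   reported as `no_anchor`).
#' @param library a [dsite_library()].
#' @return data.frame with columns `member_id` (`NA` if rejected) and
#'   `reason` (`"matched"`, `"no_anchor"`, `"bad_length"`,
#'   `"stop_or_ambiguous"`, `"not_in_whitelist"`).
#' @export
translate_and_match <- function(region, library) {
  insert_len <- unique(nchar(library$dna))
  if (length(insert_len) != 1)
    stop("library inserts must share a single length")
  n <- length(region)
  member <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  reason[is.na(region)] <- "no_anchor"
  todo <- is.na(reason)
  badlen <- todo & (nchar(region) != insert_len | nchar(region) %% 3 != 0)
  reason[badlen] <- "bad_length"
  todo <- is.na(reason)
  if (any(todo)) {
    ## DNA-exact first; only the remainder pays for translation
    hit <- match(region[todo], library$dna)
    idx <- which(todo)
    member[idx[!is.na(hit)]] <- library$member_id[hit[!is.na(hit)]]
    reason[idx[!is.na(hit)]] <- "matched"
    rest <- idx[is.na(hit)]
    if (length(rest) > 0) {
      valid_chars <- !grepl("[^ACGT]", region[rest])
      pep <- rep(NA_character_, length(rest))
      pep[valid_chars] <- translate_dna(region[rest][valid_chars])
      bad <- !valid_chars | grepl("[*X]", pep)
      reason[rest[bad]] <- "stop_or_ambiguous"
      ok <- rest[!bad]
      if (length(ok) > 0) {
        phit <- match(pep[!bad], library$peptide)
        member[ok[!is.na(phit)]] <- library$member_id[phit[!is.na(phit)]]
        reason[ok[!is.na(phit)]] <- "matched"
        reason[ok[is.na(phit)]] <- "not_in_whitelist"
      }
    }
  }
  data.frame(member_id = member, reason = reason)
}

#' Count amplicon reads against a library whitelist
#'
#' Applies [extract_variable_region()] and [translate_and_match()] to each
#' sample's FASTQ and assembles a [count_table()]. Per-sample match rates are
#' reported via `message()`; discarded reads are tallied by reason.
#'
#' @param files data.frame with columns `sample_id` and `path` (FASTQ,
#'   optionally gzipped), e.g. the return value of [emit_fastq()].
#' @param samples sample metadata data.frame (`sample_id`, `genotype`,
#'   `condition`, `replicate`, `doublings`); every
#'   (genotype, condition, replicate) series must include a doublings-0
#'   baseline sample.
#' @param library a [dsite_library()].
#' @param anchors length-2 character vector `(anchor5, anchor3)`.
#' @return a [count_table()] with the `unmatched` report populated.
#' @export
count_samples <- function(files, samples, library,
                          anchors = default_anchors()) {
  if (!all(samples$sample_id %in% files$sample_id))
    stop("missing FASTQ paths for samples: ",
         paste(setdiff(samples$sample_id, files$sample_id), collapse = ", "))
  files <- files[match(samples$sample_id, files$sample_id), ]
  counts <- matrix(0, nrow = nrow(library), ncol = nrow(samples),
                   dimnames = list(library$member_id, samples$sample_id))
  reasons <- c("no_anchor", "bad_length", "stop_or_ambiguous",
               "not_in_whitelist")
  unmatched <- matrix(0L, nrow = nrow(samples), ncol = length(reasons),
                      dimnames = list(samples$sample_id, reasons))
  for (j in seq_len(nrow(samples))) {
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(files$path[j],
                                                format = "fastq")),
      error = function(e) character(0))
    if (length(reads) == 0) {
      warning("no reads in sample ", samples$sample_id[j], call. = FALSE)
      next
    }
    region <- extract_variable_region(reads, anchors)
    res <- translate_and_match(region, library)
    matched <- res$reason == "matched"
    if (any(matched)) {
      tab <- table(res$member_id[matched])
      counts[names(tab), j] <- as.integer(tab)
    }
    for (r in reasons) unmatched[j, r] <- sum(res$reason == r)
    message(sprintf("%s: %d/%d reads matched (%.1f%%)",
                    samples$sample_id[j], sum(matched), length(reads),
                    100 * mean(matched)))
  }
  count_table(counts, samples,
              unmatched = data.frame(sample_id = samples$sample_id,
                                     unmatched, row.names = NULL))
}
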