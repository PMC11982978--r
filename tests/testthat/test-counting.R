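# brute-force oracle for anchored substring extraction
oracle_extract <- function(read, a5, a3) {
  i <- regexpr(a5, read, fixed = TRUE)
  if (i < 0) return(NA_character_)
  rest <- substring(read, i + nchar(a5))
  j <- regexpr(a3, rest, fixed = TRUE)
  if (j < 0) return(NA_character_)
  substr(rest, 1, j - 1)
}

test_that("variable region extraction finds the first anchored insert", {
  expect_equal(extract_variable_region("AAAGGGCCCTTT", c("AAA", "TTT")),
               "GGGCCC")
  expect_true(is.na(extract_variable_region("AAAGGGCCC", c("AAA", "TTT"))))
  expect_true(is.na(extract_variable_region("GGGCCCTTT", c("AAA", "TTT"))))
  # two anchor5 occurrences: region after the FIRST, to first downstream a3
  read <- "xxAAAgggAAAcccTTTyy"
  expect_equal(extract_variable_region(read, c("AAA", "TTT")),
               oracle_extract(read, "AAA", "TTT"))
  expect_equal(extract_variable_region(read, c("AAA", "TTT")), "gggAAAccc")
  # vectorised agreement with the brute-force oracle on random reads
  set.seed(4)
  nt <- c("A", "C", "G", "T")
  reads <- replicate(200, paste(sample(nt, 30, TRUE), collapse = ""))
  a5 <- "ACG"; a3 <- "TGT"
  got <- extract_variable_region(reads, c(a5, a3))
  want <- vapply(reads, oracle_extract, character(1), a5, a3,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("whitelist matching is exact, DNA-first then peptide", {
  lib <- two_member_library()
  # identity DNA match
  r <- translate_and_match(lib$dna[1], lib)
  expect_equal(r$member_id, lib$member_id[1])
  expect_equal(r$reason, "matched")
  # synonymous substitution still matches via the translated peptide
  syn <- sub("^ATT", "ATC", lib$dna[1])   # Ile: ATT -> ATC
  expect_false(syn %in% lib$dna)
  expect_equal(translate_dna(syn), lib$peptide[1])  # translation oracle
  r <- translate_and_match(syn, lib)
  expect_equal(r$member_id, lib$member_id[1])
  # wrong length
  r <- translate_and_match(substr(lib$dna[1], 1, 41), lib)
  expect_equal(r$reason, "bad_length")
  # premature stop codon
  stopd <- paste0("TAA", substr(lib$dna[1], 4, 42))
  expect_equal(translate_and_match(stopd, lib)$reason, "stop_or_ambiguous")
  # ambiguous base
  fuzzy <- paste0("NTT", substr(lib$dna[1], 4, 42))
  expect_equal(translate_and_match(fuzzy, lib)$reason, "stop_or_ambiguous")
  # valid but unknown insert
  alien <- reverse_translate(strrep("A", 14))
  expect_equal(translate_and_match(alien, lib)$reason, "not_in_whitelist")
  # missing anchor propagates
  expect_equal(translate_and_match(NA_character_, lib)$reason, "no_anchor")
})

make_fastq <- function(path, seqs) {
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

counting_fixture <- function() {
  cfg <- simulation_config(n_members = 15, read_depth = 300, seed = 8,
                           n_replicates = 1, doublings = c(0, 7),
                           conditions = "selective", genotypes = "WT")
  lib <- build_synthetic_library(cfg)
  ct <- simulate_selection(lib, assign_fitness(lib, cfg), cfg)
  files <- emit_fastq(ct, lib, tempfile("fqc"), seed = 8)
  list(lib = lib, ct = ct, files = files)
}

test_that("per-sample read accounting is conserved", {
  fx <- counting_fixture()
  back <- suppressMessages(count_samples(fx$files, fx$ct$samples, fx$lib))
  matched <- colSums(back$counts)
  discarded <- rowSums(as.matrix(back$unmatched[, -1]))
  expect_equal(unname(matched + discarded), unname(fx$files$n_reads))
  expect_equal(back$counts, fx$ct$counts)
})

test_that("read order within a FASTQ does not affect counts", {
  fx <- counting_fixture()
  path <- fx$files$path[1]
  lines <- readLines(path)
  rec <- split(lines, rep(seq_len(length(lines) / 4), each = 4))
  set.seed(1)
  writeLines(unlist(rec[sample(length(rec))]), path)
  back <- suppressMessages(count_samples(fx$files, fx$ct$samples, fx$lib))
  expect_equal(back$counts, fx$ct$counts)
})

test_that("anchor-free decoy reads change only the no_anchor tally", {
  fx <- counting_fixture()
  before <- suppressMessages(count_samples(fx$files, fx$ct$samples, fx$lib))
  path <- fx$files$path[1]
  decoys <- strrep("C", 70)
  cat(paste0("@d", 1:5, "\n", decoys, "\n+\n", strrep("I", 70), "\n",
             collapse = ""), file = path, append = TRUE)
  after <- suppressMessages(count_samples(fx$files, fx$ct$samples, fx$lib))
  expect_equal(after$counts, before$counts)
  expect_equal(after$unmatched$no_anchor - before$unmatched$no_anchor,
               c(5, rep(0, nrow(before$unmatched) - 1)))
  same <- setdiff(names(before$unmatched), c("sample_id", "no_anchor"))
  expect_equal(after$unmatched[same], before$unmatched[same])
})

test_that("an empty FASTQ yields an all-zero column and a warning", {
  fx <- counting_fixture()
  writeLines(character(0), fx$files$path[2])
  expect_warning(
    back <- suppressMessages(count_samples(fx$files, fx$ct$samples, fx$lib)),
    "no reads")
  expect_true(all(back$counts[, fx$files$sample_id[2]] == 0))
})

test_that("a missing doublings-0 baseline sample is a hard error", {
  fx <- counting_fixture()
  nobase <- fx$ct$samples[fx$ct$samples$doublings > 0, ]
  expect_error(
    suppressMessages(count_samples(fx$files, nobase, fx$lib)),
    "baseline")
})
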