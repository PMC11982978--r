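## canonical residue alphabet, fixed order used throughout
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## one codon per residue (preferred S. cerevisiae codons) so that reverse
## translation is deterministic and invertible under the standard code
YEAST_CODON <- c(
  A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "TTG", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Reverse-translate peptides with a fixed codon choice
#'
#' Each residue maps to a single preferred yeast codon, so the same peptide
#' always yields the same coding DNA.
#'
#' @param peptides character vector of amino-acid strings (canonical 20-letter
#'   alphabet).
#' @return character vector of coding DNA strings, 3x the peptide length.
#' @export
#' @examples
#' reverse_translate("IRAR")
reverse_translate <- function(peptides) {
  vapply(strsplit(peptides, ""), function(aa) {
    cod <- YEAST_CODON[aa]
    if (anyNA(cod)) stop("non-canonical residue in peptide", call. = FALSE)
    paste(cod, collapse = "")
  }, character(1))
}

#' Translate coding DNA to peptides
#'
#' Standard genetic code via Biostrings; fuzzy (ambiguous) codons become `X`
#' and stop codons `*`, which callers treat as rejection signals.
#'
#' @param dna character vector of DNA strings with length divisible by 3.
#' @return character vector of amino-acid strings.
#' @export
translate_dna <- function(dna) {
  if (length(dna) == 0L) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' D-site library container
#'
#' A whitelist of screened docking-site variants. Each member couples a
#' 14-residue peptide to its coding DNA and a motif class label
#' (`HEPTP_like` for peptides carrying an I/L-x-x-R-R match near the
#' N-terminus, `Pro_phi` for proline-containing linker types, `other`).
#'
#' @param members data.frame with columns `member_id`, `source_name`,
#'   `peptide`, `dna`, `motif_class`.
#' @param strict logical; if `TRUE` (synthetic libraries) a peptide that does
#'   not match the library consensus is an error, otherwise a warning.
#' @return a `dsite_library` object (a validated data.frame).
#' @export
dsite_library <- function(members, strict = FALSE) {
  required <- c("member_id", "source_name", "peptide", "dna", "motif_class")
  missing <- setdiff(required, names(members))
  if (length(missing) > 0)
    stop("library is missing columns: ", paste(missing, collapse = ", "))
  members <- as.data.frame(members)[required]
  if (nrow(members) > 0) {
    if (anyDuplicated(members$member_id))
      stop("duplicate member_id values in library")
    if (anyDuplicated(members$dna))
      stop("duplicate DNA sequences in library")
    if (!all(nchar(members$peptide) == 14L))
      stop("all library peptides must be 14 residues long")
    bad_aa <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")),
                    members$peptide)
    if (any(bad_aa))
      stop("non-canonical residues in peptides: ",
           paste(utils::head(members$member_id[bad_aa], 3), collapse = ", "))
    retrans <- translate_dna(members$dna)
    if (!all(retrans == members$peptide))
      stop("dna does not translate to peptide for some members")
    ok_class <- members$motif_class %in% c("HEPTP_like", "Pro_phi", "other")
    if (!all(ok_class)) stop("motif_class must be HEPTP_like, Pro_phi or other")
    consensus_ok <- matches_motif(members$peptide, library_consensus_motif())
    if (!all(consensus_ok)) {
      msg <- sprintf("%d peptide(s) do not match the library consensus",
                     sum(!consensus_ok))
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
  }
  rownames(members) <- NULL
  class(members) <- c("dsite_library", "data.frame")
  members
}

#' @export
print.dsite_library <- function(x, ...) {
  cat(sprintf("D-site library: %d members (%d HEPTP_like, %d Pro_phi, %d other)\n",
              nrow(x), sum(x$motif_class == "HEPTP_like"),
              sum(x$motif_class == "Pro_phi"), sum(x$motif_class == "other")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

## draw one consensus-conformant 14-mer: place the basic pair, linker and
## hydrophobic phi-x-phi according to random spacings, fill the rest uniformly
random_consensus_peptide <- function() {
  repeat {
    s1 <- sample(0:2, 1)          # gap between the two basic residues
    s2 <- sample(3:5, 1)          # linker to the hydrophobic motif
    len <- 5L + s1 + s2           # [RK] s1 [RK] s2 [ILV] x [FILMV]
    start <- sample.int(14L - len + 1L, 1)
    aa <- sample(AA20, 14, replace = TRUE)
    pos <- start
    aa[pos] <- sample(c("R", "K"), 1); pos <- pos + 1L + s1
    aa[pos] <- sample(c("R", "K"), 1); pos <- pos + 1L + s2
    aa[pos] <- sample(c("I", "L", "V"), 1)
    aa[pos + 2L] <- sample(c("F", "I", "L", "M", "V"), 1)
    pep <- paste(aa, collapse = "")
    if (matches_motif(pep, library_consensus_motif())) return(pep)
  }
}

## HEPTP-like member: I/L-x-x-R-R starting within the N-terminal window, with
## the di-Arg doubling as the consensus basic pair (zero spacing), followed by
## a 3-5 residue linker and the phi-x-phi motif
random_heptp_peptide <- function(window = c(1L, 4L)) {
  start <- sample(seq.int(window[1], window[2]), 1)
  gap <- sample(3:5, 1)
  aa <- sample(AA20, 14, replace = TRUE)
  aa[start] <- sample(c("I", "L"), 1)
  aa[start + 3L] <- "R"
  aa[start + 4L] <- "R"
  phi <- start + 4L + gap + 1L
  if (phi + 2L > 14L) return(random_heptp_peptide(window))
  aa[phi] <- sample(c("I", "L", "V"), 1)
  aa[phi + 2L] <- sample(c("F", "I", "L", "M", "V"), 1)
  paste(aa, collapse = "")
}

#' Generate a synthetic D-site library
#'
#' Emits `n_members` unique 14-mers conforming to the library consensus
#' \code{[R/K]-x(0-2)-[R/K]-x(3-5)-[ILV]-x-[FILMV]}. A fraction
#' `frac_heptp` additionally carries an I/L-x-x-R-R (HEPTP-type) match
#' starting within the configured N-terminal window; the remaining members are
#' guaranteed not to. Deterministic for a fixed `seed`.
#'
#' @param config a [simulation_config()] list.
#' @return a [dsite_library()].
#' @export
#' @examples
#' lib <- build_synthetic_library(simulation_config(n_members = 20, seed = 1))
#' table(lib$motif_class)
build_synthetic_library <- function(config) {
  config <- validate_simulation_config(config)
  n <- config$n_members
  if (n == 0L) {
    return(dsite_library(data.frame(member_id = character(0),
                                    source_name = character(0),
                                    peptide = character(0),
                                    dna = character(0),
                                    motif_class = character(0)), strict = TRUE))
  }
  set.seed(config$seed)
  n_heptp <- round(config$frac_heptp * n)
  heptp_motif_def <- heptp_motif(window = config$heptp_window)
  peptides <- character(0)
  classes <- character(0)
  seen <- new.env(hash = TRUE)
  draw_unique <- function(gen, check) {
    repeat {
      p <- gen()
      if (!check(p)) next
      if (!is.null(seen[[p]])) next
      seen[[p]] <- TRUE
      return(p)
    }
  }
  for (i in seq_len(n_heptp)) {
    p <- draw_unique(function() random_heptp_peptide(config$heptp_window),
                     function(p) matches_motif(p, heptp_motif_def) &&
                       matches_motif(p, library_consensus_motif()))
    peptides <- c(peptides, p)
    classes <- c(classes, "HEPTP_like")
  }
  for (i in seq_len(n - n_heptp)) {
    p <- draw_unique(random_consensus_peptide,
                     function(p) !matches_motif(p, heptp_motif_def))
    peptides <- c(peptides, p)
    # proline in the linker region marks the DCC/MEF2-type docking classes
    classes <- c(classes,
                 if (grepl("P", substr(p, 7, 9))) "Pro_phi" else "other")
  }
  ord <- sample.int(n)   # shuffle so class does not encode in member order
  peptides <- peptides[ord]
  classes <- classes[ord]
  dsite_library(data.frame(
    member_id = sprintf("M%05d", seq_len(n)),
    source_name = paste0("synthetic_", classes),
    peptide = peptides,
    dna = reverse_translate(peptides),
    motif_class = classes,
    stringsAsFactors = FALSE), strict = TRUE)
}

#' Read / write a D-site library as TSV
#'
#' @param path file path.
#' @param library a [dsite_library()].
#' @param strict passed to [dsite_library()] validation.
#' @return `read_library_tsv` returns a [dsite_library()];
#'   `write_library_tsv` returns the path invisibly.
#' @export
read_library_tsv <- function(path, strict = FALSE) {
  dsite_library(utils::read.delim(path, stringsAsFactors = FALSE,
                                  colClasses = "character"),
                strict = strict)
}

#' @rdname read_library_tsv
#' @export
write_library_tsv <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write library sequences as FASTA
#'
#' @param library a [dsite_library()].
#' @param path output file.
#' @param what `"peptide"` or `"dna"`.
#' @return the path, invisibly.
#' @export
write_library_fasta <- function(library, path, what = c("peptide", "dna")) {
  what <- match.arg(what)
  seqs <- library[[what]]
  names(seqs) <- library$member_id
  set <- if (what == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
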