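#' Define a gapped short-linear-motif pattern
#'
#' A motif is an ordered list of residue classes separated by variable-length
#' spacers, plus a window of allowed start positions for the first element.
#' Positions are 1-based.
#'
#' @param elements list of lists, each with `class` (character vector of
#'   allowed residues), `gap_min` and `gap_max` (spacer length to the *next*
#'   element; ignored for the last element).
#' @param window integer length-2: allowed start positions (inclusive) for
#'   the first element, or `NULL` for anywhere in the peptide.
#' @param name optional label.
#' @return a `motif_definition` object.
#' @export
motif_definition <- function(elements, window = NULL, name = NULL) {
  if (length(elements) == 0) stop("motif needs at least one element")
  for (e in elements) {
    if (length(e$class) == 0 || !all(e$class %in% AA20))
      stop("motif element classes must be non-empty subsets of the 20 residues")
    if (!is.null(e$gap_min) &&
        (e$gap_min < 0 || e$gap_max < e$gap_min))
      stop("motif spacings must satisfy 0 <= gap_min <= gap_max")
  }
  if (!is.null(window)) {
    window <- as.integer(window)
    if (length(window) != 2 || window[1] < 1 || window[2] < window[1])
      stop("window must be c(first, last) with first >= 1")
  }
  structure(list(elements = elements, window = window, name = name),
            class = "motif_definition")
}

#' Parse a motif pattern string
#'
#' Grammar: residue classes in brackets (`[RK]`) or single letters; `x` for
#' any residue; spacers as `x{min,max}`. Example, the D-site library
#' consensus: `"[RK]x{0,2}[RK]x{3,5}[ILV]x[FILMV]"`.
#'
#' @param pattern motif string.
#' @inheritParams motif_definition
#' @return a [motif_definition()].
#' @export
#' @examples
#' parse_motif("[IL]xx[R][R]", window = c(1, 4))
parse_motif <- function(pattern, window = NULL, name = pattern) {
  tokens <- list()
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed '[' in motif pattern")
      cls <- strsplit(substr(pattern, i + 1L, i + j - 2L), "")[[1]]
      tokens[[length(tokens) + 1L]] <- list(type = "class", class = cls)
      i <- i + j
    } else if (ch == "x") {
      rest <- substr(pattern, i + 1L, n)
      m <- regmatches(rest, regexpr("^\\{\\d+,\\d+\\}", rest))
      if (length(m) == 1 && nzchar(m)) {
        nums <- as.integer(strsplit(gsub("[{}]", "", m), ",")[[1]])
        tokens[[length(tokens) + 1L]] <- list(type = "gap", gap_min = nums[1],
                                              gap_max = nums[2])
        i <- i + 1L + nchar(m)
      } else {
        tokens[[length(tokens) + 1L]] <- list(type = "gap", gap_min = 1L,
                                              gap_max = 1L)
        i <- i + 1L
      }
    } else if (ch %in% AA20) {
      tokens[[length(tokens) + 1L]] <- list(type = "class", class = ch)
      i <- i + 1L
    } else stop("unexpected character '", ch, "' in motif pattern")
  }
  ## fold gap tokens into the preceding class element
  elements <- list()
  k <- 0L
  for (t in tokens) {
    if (t$type == "class") {
      k <- k + 1L
      elements[[k]] <- list(class = t$class, gap_min = 0L, gap_max = 0L)
    } else {
      if (k == 0L) stop("motif pattern cannot start with a spacer")
      elements[[k]]$gap_min <- elements[[k]]$gap_min + t$gap_min
      elements[[k]]$gap_max <- elements[[k]]$gap_max + t$gap_max
    }
  }
  motif_definition(elements, window = window, name = name)
}

#' The D-site library consensus motif
#'
#' \code{[R/K]-x(0-2)-[R/K]-x(3-5)-[ILV]-x-[FILMV]}: a basic patch joined to a
#' hydrophobic phi-x-phi module by a variable linker, matched anywhere in the
#' peptide.
#'
#' @return a [motif_definition()].
#' @export
library_consensus_motif <- function() {
  parse_motif("[RK]x{0,2}[RK]x{3,5}[ILV]x[FILMV]",
              name = "library_consensus")
}

#' The HEPTP-type I/L-x-x-R-R motif
#'
#' Diagnostic of docking sites that engage the kinase common-docking site in a
#' helical turn; in this package it marks peptides whose binding is selective
#' for wild-type ERK2 over common-docking-site mutants. By default the match
#' must start within the first four positions ("near the N-terminus").
#'
#' @param window allowed start positions, default `c(1, 4)`.
#' @return a [motif_definition()].
#' @export
heptp_motif <- function(window = c(1, 4)) {
  parse_motif("[IL]x{2,2}[R][R]", window = window, name = "heptp")
}

#' Scan a peptide for a motif
#'
#' Enumerates every match over all allowed spacing combinations and start
#' positions. At equal start positions the shortest-spacing match is listed
#' first.
#'
#' @param peptide a single amino-acid string.
#' @param motif a [motif_definition()].
#' @return data.frame with columns `start`, `end`, `span` (the matched
#'   substring); zero rows if no match.
#' @export
#' @examples
#' scan_motif("IRARRGLPRLAVSD", heptp_motif())
scan_motif <- function(peptide, motif) {
  stopifnot(length(peptide) == 1L, inherits(motif, "motif_definition"))
  aa <- strsplit(peptide, "")[[1]]
  L <- length(aa)
  win <- if (is.null(motif$window)) c(1L, L) else motif$window
  win[2] <- min(win[2], L)
  els <- motif$elements
  hits <- list()
  ## depth-first over elements; gaps tried smallest-first so matches at one
  ## start come out shortest-spacing first
  recurse <- function(pos, idx) {
    if (pos > L || !(aa[pos] %in% els[[idx]]$class)) return(invisible())
    if (idx == length(els)) {
      hits[[length(hits) + 1L]] <<- c(start_pos, pos)
      return(invisible())
    }
    for (g in seq.int(els[[idx]]$gap_min, els[[idx]]$gap_max)) {
      recurse(pos + 1L + g, idx + 1L)
    }
  }
  for (start_pos in seq.int(win[1], max(win[1], win[2]))) {
    if (win[1] > L) break
    recurse(start_pos, 1L)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      span = character(0)))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], end = m[, 2],
             span = substring(peptide, m[, 1], m[, 2]))
}

#' Test peptides against a motif
#'
#' Vectorised boolean wrapper over [scan_motif()].
#'
#' @param peptides character vector.
#' @param motif a [motif_definition()].
#' @return logical vector.
#' @export
matches_motif <- function(peptides, motif) {
  vapply(peptides, function(p) nrow(scan_motif(p, motif)) > 0, logical(1),
         USE.NAMES = FALSE)
}

#' Classify peptides against a set of motifs
#'
#' @param peptides character vector.
#' @param motifs named list of [motif_definition()] objects; defaults to the
#'   library consensus and the HEPTP motif.
#' @return list with `table` (logical peptide x motif data.frame) and
#'   `fractions` (named numeric; `NA` for an empty peptide set).
#' @export
classify_peptides <- function(peptides,
                              motifs = list(
                                consensus = library_consensus_motif(),
                                heptp = heptp_motif())) {
  tab <- as.data.frame(lapply(motifs, function(m) matches_motif(peptides, m)))
  rownames(tab) <- NULL
  tab <- cbind(data.frame(peptide = peptides), tab)
  fractions <- if (length(peptides) == 0) {
    setNames(rep(NA_real_, length(motifs)), names(motifs))
  } else {
    vapply(names(motifs), function(nm) mean(tab[[nm]]), numeric(1))
  }
  list(table = tab, fractions = fractions)
}

#' Positional residue overrepresentation (probability-logo statistics)
#'
#' For each position and residue, the foreground count is compared with the
#' background residue frequency at that position by exact binomial tail
#' probabilities: overrepresentation p = P(X >= k), underrepresentation
#' p = P(X <= k), X ~ Binomial(n = |foreground|, p0). Letter height is
#' -log10(p) of the favoured tail, signed positive for over- and negative for
#' underrepresentation, and exactly 0 when k/n equals p0. Significance is
#' Bonferroni-corrected over all 20 x L tests.
#'
#' @param foreground,background character vectors of equal-length peptides;
#'   the background defaults in downstream helpers to the full screened
#'   library, which corrects for its built-in consensus bias.
#' @param alpha family-wise error level for the Bonferroni flag.
#' @return a `positional_enrichment` data.frame with columns `position`,
#'   `residue`, `k`, `n`, `p0`, `p_over`, `p_under`, `height`, `significant`,
#'   plus attributes `L`, `alpha`, `bonferroni_p`.
#' @export
positional_overrepresentation <- function(foreground, background,
                                          alpha = 0.05) {
  if (length(foreground) < 1) stop("foreground must contain >= 1 peptide")
  L <- unique(nchar(c(foreground, background)))
  if (length(L) != 1)
    stop("foreground and background peptides must all have the same length")
  n <- length(foreground)
  fg <- do.call(rbind, strsplit(foreground, ""))
  bg <- do.call(rbind, strsplit(background, ""))
  out <- vector("list", L)
  for (pos in seq_len(L)) {
    k <- vapply(AA20, function(r) sum(fg[, pos] == r), numeric(1))
    p0 <- vapply(AA20, function(r) mean(bg[, pos] == r), numeric(1))
    p_over <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    p_under <- pbinom(k, n, p0)
    zero_bg <- p0 == 0 & k > 0
    if (any(zero_bg)) {
      warning("residue(s) absent from background observed in foreground; ",
              "p set to machine minimum", call. = FALSE)
      p_over[zero_bg] <- .Machine$double.xmin
    }
    over <- k / n > p0
    height <- ifelse(k / n == p0, 0,
                     ifelse(over, -log10(p_over), log10(p_under)))
    out[[pos]] <- data.frame(position = pos, residue = AA20, k = k, n = n,
                             p0 = p0, p_over = p_over, p_under = p_under,
                             height = height, row.names = NULL)
  }
  res <- do.call(rbind, out)
  bonf <- alpha / (20 * L)
  res$significant <- ifelse(res$height >= 0, res$p_over, res$p_under) < bonf &
    res$height != 0
  attr(res, "L") <- L
  attr(res, "alpha") <- alpha
  attr(res, "bonferroni_p") <- bonf
  class(res) <- c("positional_enrichment", "data.frame")
  res
}

#' Plot a probability logo
#'
#' Stacks residue letters at each position with heights equal to the signed
#' -log10 binomial tail p-values from [positional_overrepresentation()];
#' dashed lines mark the Bonferroni significance threshold.
#'
#' @param pe a `positional_enrichment` object.
#' @param min_height letters with |height| below this are dropped for
#'   legibility.
#' @return a ggplot object.
#' @export
plot_plogo <- function(pe, min_height = 0.1) {
  stopifnot(inherits(pe, "positional_enrichment"))
  thr <- -log10(attr(pe, "bonferroni_p"))
  d <- pe[abs(pe$height) >= min_height, , drop = FALSE]
  d <- d[order(d$position, abs(d$height)), ]
  pieces <- split(d, list(d$position, d$height >= 0), drop = TRUE)
  d <- do.call(rbind, lapply(pieces, function(g) {
    tops <- cumsum(abs(g$height))
    g$y <- sign(g$height[1]) * (tops - abs(g$height) / 2)
    g
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$y,
                                  label = .data$residue,
                                  size = abs(.data$height))) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-thr, 0, thr),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("red", "grey30", "red")) +
    ggplot2::scale_x_continuous(breaks = seq_len(attr(pe, "L"))) +
    ggplot2::scale_size_continuous(range = c(2, 8)) +
    ggplot2::labs(x = "position", y = "signed -log10 p") +
    ggplot2::theme_minimal()
}
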