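#' Published ISG20 peptide-variant IC50 table
#'
#' Competitive-inhibition IC50 summaries (mean and 95% CI over three
#' replicates, in uM) for the ISG20 docking-site peptide and single-residue
#' variants against wild-type ERK2 and three common-docking-site mutants.
#' Useful as motif-scanner fixtures (the sequences probe the I/L-x-x-R-R
#' register) and as [fit_result()] inputs for [fold_change()].
#'
#' @return data.frame with columns `peptide_id`, `sequence`, `kinase`,
#'   `ic50`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' tab <- isg20_ic50_table()
#' unique(tab$sequence)
isg20_ic50_table <- function() {
  utils::read.delim(system.file("extdata", "isg20_peptide_ic50.tsv",
                                package = "dsitescreen"),
                    stringsAsFactors = FALSE)
}

#' Turn one row of a published IC50 table into a fit result
#'
#' @param tab a data.frame as returned by [isg20_ic50_table()].
#' @param peptide_id,kinase row selector.
#' @return a [fit_result()].
#' @export
ic50_fit_from_table <- function(tab, peptide_id, kinase) {
  row <- tab[tab$peptide_id == peptide_id & tab$kinase == kinase, ]
  if (nrow(row) != 1) stop("no unique row for ", peptide_id, "/", kinase)
  fit_result(ic50 = row$ic50, ci = c(row$ci_lower, row$ci_upper))
}
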