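# shared in-code fixtures; everything is generated, nothing read from disk
# except the published ISG20 IC50 table shipped with the package

# two consensus-conformant peptides with known motif content
PEP_ISG20 <- "IRARRGLPRLAVSD"   # HEPTP-type: I1-x-x-R4-R5
PEP_KMT2C <- "RKRSKPKLKLKIIN"   # consensus yes, HEPTP no

two_member_library <- function() {
  dsite_library(data.frame(
    member_id = c("fast", "slow"),
    source_name = c("ISG20", "KMT2C"),
    peptide = c(PEP_ISG20, PEP_KMT2C),
    dna = reverse_translate(c(PEP_ISG20, PEP_KMT2C)),
    motif_class = c("HEPTP_like", "other")))
}

# hand-built fitness map for deterministic growth scenarios
make_fitness <- function(library, g_selective, genotype = "WT", r0 = 0.35) {
  structure(data.frame(genotype = genotype,
                       member_id = library$member_id,
                       motif_class = library$motif_class,
                       kd = NA_real_, occupancy = NA_real_,
                       g_selective = g_selective,
                       g_nonselective = r0),
            class = c("fitness_map", "data.frame"))
}

# minimal single-genotype, selective-only config; list-based overrides so
# that short argument names (s, r0) are never partially matched away
small_config <- function(...) {
  args <- list(n_members = 2, genotypes = "WT", conditions = "selective",
               seed = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# count table built directly from a matrix and doubling grid (one replicate)
toy_count_table <- function(counts, doublings, genotype = "WT",
                            condition = "selective", replicate = 1) {
  colnames(counts) <- sprintf("%s_%s_r%d_t%d", genotype,
                              substr(condition, 1, 3), replicate,
                              seq_along(doublings))
  count_table(counts,
              data.frame(sample_id = colnames(counts), genotype = genotype,
                         condition = condition, replicate = replicate,
                         doublings = doublings))
}

# independent regex oracles for the two motif grammars
oracle_heptp <- function(peptides) grepl("^.{0,3}[IL]..RR", peptides)
oracle_consensus <- function(peptides)
  grepl("[RK].{0,2}[RK].{3,5}[ILV].[FILMV]", peptides)

random_peptides <- function(n, len = 14) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  vapply(seq_len(n),
         function(i) paste(sample(aa, len, replace = TRUE), collapse = ""),
         character(1))
}

# noise-free four-parameter logistic generator
gen_4pl <- function(conc, ic50, h = 1, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ic50)^h)
}
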