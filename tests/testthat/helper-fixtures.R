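# Shared fixtures built in code at test time.

# Three-clade base-population composition mirrored throughout the tests:
# relative cytoplasmic clade frequencies ~55/25/20 with clade V at 0.25.
bp_clades <- c("V", "VI", "I_II_III")
bp_frequencies <- c(V = 0.25, VI = 0.55, I_II_III = 0.20, uninfected = 0)

# A diagnostic SNP panel with n SNPs per clade, alleles chosen so each
# clade owns a distinct base.
make_snp_panel <- function(n_per_clade, clades = bp_clades,
                           contig = "wolb") {
  data.frame(
    contig = contig,
    position = seq_len(n_per_clade * length(clades)),
    allele = rep(c("A", "C", "G")[seq_along(clades)], each = n_per_clade),
    clade = rep(clades, each = n_per_clade),
    stringsAsFactors = FALSE
  )
}

bp_params <- function(..., seed = 1L) {
  defaults <- list(
    n_lineages = 75L, generations = 15L, clades = bp_clades,
    initial_frequencies = bp_frequencies,
    selection = c(V = 1, VI = 1, I_II_III = 1, uninfected = 1),
    n_replicates = 1L, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# The published 12-sample coverage table shipped with the package.
bp_coverage <- function() {
  read_coverage_summary(cytodrift_example("bp_individuals_coverage.tsv"))
}
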