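# Build prioritizeTargets() inputs from the shipped 7-pair flag matrix
# (inst/extdata/prioritization_flags.tsv). All pairs satisfy the inclusion
# prerequisites (DSE present, gene association, CRC association); the four
# flags vary per row. The near-miss row carries a seed-qualified site whose
# duplex energy misses the cutoff.
loadFlagFixture <- function() {
  tab <- read.delim(system.file("extdata", "prioritization_flags.tsv",
                                package = "miRtaq", mustWork = TRUE),
                    stringsAsFactors = FALSE)
  evidence <- data.frame(
    mirna = tab$mirna, gene = tab$gene,
    db_count = ifelse(tab$two_dbs, 2L, 1L),
    cancer_assoc = TRUE, crc_assoc = TRUE, gene_assoc = TRUE,
    direct_validation = tab$direct_validation, mirbase_valid = TRUE,
    stringsAsFactors = FALSE)
  verdicts <- data.frame(
    mirna = tab$mirna, gene = tab$gene,
    dse_present = TRUE, energy_gap_pass = tab$energy,
    stringsAsFactors = FALSE)
  hasSite <- tab$rna22 | tab$near_miss
  rna22 <- data.frame(
    mirna = tab$mirna[hasSite], gene = tab$gene[hasSite],
    start = 10L, end = 17L, site_class = "7mer",
    unpaired_in_seed = 0L, wobbles = 0L,
    duplex_energy = ifelse(tab$near_miss[hasSite], -10.5, -15.2),
    pass = tab$rna22[hasSite] & !tab$near_miss[hasSite],
    stringsAsFactors = FALSE)
  list(flags = tab, evidence = evidence, verdicts = verdicts, rna22 = rna22)
}
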