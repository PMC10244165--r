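## Shared fixtures: the deterministic locus model and small helpers used
## across test files.

fixture_gm <- ubtf_fixture_model()

## Simulate one TD-positive sample (wild-type + one mutant haplotype).
sim_td_sample <- function(td, depth = 500, seed = 1L, read_length = 150L) {
  simulate_reads(
    fixture_gm,
    list(list(td = NULL, fraction = 1 - td$allele_fraction),
         list(td = td, fraction = td$allele_fraction)),
    read_sim_config(read_length = read_length, depth = depth, seed = seed))
}

## CDS projection of cohort truth intervals, matching the caller's fields.
truth_cds_table <- function(cohort, gm = fixture_gm) {
  proj <- t(vapply(seq_len(nrow(cohort)), function(i) {
    g <- seq.int(cohort$dup_start[i], cohort$dup_end[i] - 1L)
    cds <- genomic_to_cds(gm, g)
    cds <- cds[!is.na(cds)]
    c(min(cds), max(cds))
  }, numeric(2L)))
  cohort$cds_start <- as.integer(proj[, 1L])
  cohort$cds_end <- as.integer(proj[, 2L])
  cohort
}

## Independent brute-force codon-table translation oracle.
oracle_translate <- function(seq) {
  codon_table <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(codon_table[codons], collapse = "")
}

## Canonical 48-bp duplicated interval on the fixture (starts at the core).
canonical_48 <- function(f = 0.45) {
  g <- cds_to_genomic(fixture_gm, td_core_cds()[1L])
  td_spec(g, g + 48L, allele_fraction = f)
}

## The large intron-spanning duplication used for the exon13-exon13 case.
large_598 <- function(f = 0.45) {
  td_spec(730L, 1328L, allele_fraction = f)
}
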