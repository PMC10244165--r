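test_that("codon arithmetic maps CDS positions to the printed residues", {
  expect_identical(codon_of(1306), 436L)   # Glu436, motif start
  expect_identical(codon_of(1326), 442L)   # Ala442, motif end
  expect_identical(codon_of(3), 1L)
  expect_identical(position_in_codon(c(1, 2, 3, 4)), c(1L, 2L, 3L, 1L))
  expect_error(codon_of(0), "coordinate error")
  ## first/last base of every codon agree, exhaustively
  k <- 0:999
  expect_identical(codon_of(3 * k + 1), k + 1L)
  expect_identical(codon_of(3 * k + 3), k + 1L)
  ## the 1306-1326 interval spans exactly codons 436-442 (7 codons, 21 nt)
  expect_identical(unique(codon_of(1306:1326)), 436:442)
  expect_identical(1326L - 1306L + 1L, 21L)
})

test_that("fixture model satisfies its structural contract", {
  gm <- fixture_gm
  expect_s3_class(gm, "gene_model")
  expect_identical(gm$wt_amplicon, 617L)
  expect_identical(nrow(gm$exons), 3L)
  ## CDS contiguity across exons
  w <- gm$exons$end - gm$exons$start
  expect_identical(gm$exons$cds_start,
                   gm$exons$cds_start[1] + cumsum(c(0L, w[-3])))
  ## the fixture regenerates identically
  expect_identical(ubtf_fixture_model()$sequence, gm$sequence)
  ## 15-mers are unique, so seed re-anchoring is unambiguous
  n <- gm$sequence_length - 14L
  kmers <- substring(gm$sequence, seq_len(n), seq_len(n) + 14L)
  expect_false(anyDuplicated(kmers) > 0)
})

test_that("genomic and CDS coordinates are a bijection on coding positions", {
  gm <- fixture_gm
  for (i in seq_len(nrow(gm$exons))) {
    g <- gm$exons$start[i]:(gm$exons$end[i] - 1L)
    cds <- genomic_to_cds(gm, g)
    expect_false(anyNA(cds))
    expect_identical(cds_to_genomic(gm, cds), g)
    expect_false(anyDuplicated(cds) > 0)
  }
  ## anchor: first coding base of the model
  expect_identical(genomic_to_cds(gm, gm$exons$start[1]),
                   gm$exons$cds_start[1])
  ## intronic and flanking positions are non-coding
  expect_true(is.na(genomic_to_cds(gm, 900L)))
  expect_true(is.na(genomic_to_cds(gm, 10L)))
  expect_error(genomic_to_cds(gm, -1L), "coordinate error")
  expect_error(genomic_to_cds(gm, gm$sequence_length), "coordinate error")
})

test_that("translation matches a brute-force codon-table oracle", {
  expect_identical(as.character(translate_cds("GAA")), "E")
  expect_error(translate_cds("GAAA"), "frame error")
  ## the fixture core encodes ELLTRLA
  core <- td_core_cds()
  coreseq <- substr(ubtftd:::model_cds(fixture_gm),
                    core[1] - 1170L, core[2] - 1170L)
  expect_identical(as.character(translate_cds(coreseq)), "ELLTRLA")
  ## random ORFs against the oracle
  set.seed(11)
  for (r in 1:20) {
    orf <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    expect_identical(as.character(translate_cds(orf)), oracle_translate(orf))
  }
  ## stop codons flag truncation
  p <- translate_cds("GAATAAGAA")
  expect_true(grepl("\\*", as.character(p)))
  expect_true(attr(p, "truncated"))
})

test_that("gene models round-trip through FASTA + exon TSV", {
  gm <- fixture_gm
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_gene_model(gm, fa, tsv)
  gm2 <- read_gene_model(fa, tsv)
  expect_identical(gm2$sequence, gm$sequence)
  expect_identical(gm2$exons$cds_start, gm$exons$cds_start)
  expect_identical(gm2$wt_amplicon, gm$wt_amplicon)
  unlink(c(fa, tsv))
})

test_that("gene model constructor rejects malformed input", {
  ex <- data.frame(name = "e1", start = 10L, end = 5L, cds_start = 1L)
  expect_error(gene_model("x", "ACGT", ex, 0L, 3L), "non-empty")
  ex2 <- data.frame(name = c("e1", "e2"), start = c(0L, 2L),
                    end = c(4L, 6L), cds_start = c(1L, 10L))
  expect_error(gene_model("x", "ACGTACGTAC", ex2, 0L, 9L), "disjoint|contiguous")
})
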