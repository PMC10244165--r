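#' Gene model for a tandem-duplication locus
#'
#' A `gene_model` holds the genomic sequence of a locus together with its
#' exon structure, the CDS coordinate of each exon's first base, and the
#' positions of the two screening-amplicon primers. Genomic intervals are
#' 0-based half-open throughout the package; CDS (c.) positions are 1-based,
#' following the HGVS convention. Conversions happen only through
#' [genomic_to_cds()] and [cds_to_genomic()].
#'
#' @param locus_name Name used as the SAM/FASTA reference name.
#' @param sequence Locus sequence, a single upper-case ACGT string.
#' @param exons `data.frame` with columns `name`, `start`, `end` (0-based
#'   half-open genomic) and `cds_start` (1-based CDS coordinate of the exon's
#'   first base). Exons must be sorted, disjoint, and CDS-contiguous.
#' @param forward_primer_pos,reverse_primer_pos 0-based genomic positions of
#'   the amplicon ends; the wild-type amplicon is
#'   `[forward_primer_pos, reverse_primer_pos)`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(locus_name, sequence, exons,
                       forward_primer_pos, reverse_primer_pos) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGT]", sequence)) {
    stop("locus sequence must contain only A, C, G, T")
  }
  len <- nchar(sequence)
  stopifnot(is.data.frame(exons),
            all(c("name", "start", "end", "cds_start") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start < 0L) || any(exons$end > len) ||
      any(exons$end <= exons$start)) {
    stop("exon intervals must be non-empty and lie within the locus")
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exons must be pairwise disjoint")
  }
  widths <- exons$end - exons$start
  expected <- exons$cds_start[1L] + cumsum(c(0L, widths[-length(widths)]))
  if (any(exons$cds_start != expected)) {
    stop("exon cds_start values must be contiguous across exons")
  }
  if (forward_primer_pos < 0L || reverse_primer_pos > len ||
      reverse_primer_pos <= forward_primer_pos) {
    stop("primer positions must define a non-empty interval in the locus")
  }
  structure(
    list(locus_name = locus_name,
         sequence = sequence,
         sequence_length = len,
         exons = exons,
         forward_primer_pos = as.integer(forward_primer_pos),
         reverse_primer_pos = as.integer(reverse_primer_pos),
         wt_amplicon = as.integer(reverse_primer_pos - forward_primer_pos)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d bp, %d exons, %d-bp amplicon\n",
              x$locus_name, x$sequence_length, nrow(x$exons), x$wt_amplicon))
  print(x$exons, row.names = FALSE)
  invisible(x)
}

#' Codon index of a CDS position
#'
#' Maps a 1-based coding (c.) position to the 1-based index of the codon
#' containing it, e.g. the first base of the duplicated-core motif, c.1306,
#' falls in codon 436 (Glu436).
#'
#' @param cds_position 1-based CDS position(s).
#' @return Integer codon index, `floor((p - 1) / 3) + 1`.
#' @export
codon_of <- function(cds_position) {
  if (any(is.na(cds_position)) || any(cds_position < 1)) {
    stop("coordinate error: CDS positions are 1-based and positive")
  }
  as.integer((as.numeric(cds_position) - 1) %/% 3 + 1)
}

#' Position of a CDS base within its codon (1, 2 or 3)
#' @inheritParams codon_of
#' @export
position_in_codon <- function(cds_position) {
  if (any(is.na(cds_position)) || any(cds_position < 1)) {
    stop("coordinate error: CDS positions are 1-based and positive")
  }
  as.integer((as.numeric(cds_position) - 1) %% 3 + 1)
}

#' Convert CDS positions to genomic positions
#'
#' @param gm A [gene_model()].
#' @param cds_position 1-based CDS position(s) covered by the model's exons.
#' @return 0-based genomic position(s).
#' @export
cds_to_genomic <- function(gm, cds_position) {
  stopifnot(inherits(gm, "gene_model"))
  ex <- gm$exons
  lo <- min(ex$cds_start)
  hi <- max(ex$cds_start + (ex$end - ex$start)) - 1L
  if (any(cds_position < lo) || any(cds_position > hi)) {
    stop(sprintf("coordinate error: CDS position outside model range c.%d-c.%d",
                 lo, hi))
  }
  vapply(as.integer(cds_position), function(p) {
    i <- which(p >= ex$cds_start & p < ex$cds_start + (ex$end - ex$start))
    ex$start[i] + (p - ex$cds_start[i])
  }, integer(1L))
}

#' Convert genomic positions to CDS positions
#'
#' Exonic positions map bijectively to their c. coordinate; intronic and
#' flanking positions return `NA` ("non-coding").
#'
#' @param gm A [gene_model()].
#' @param genomic_pos 0-based genomic position(s) within the locus.
#' @return Integer CDS position(s), `NA` for non-coding positions.
#' @export
genomic_to_cds <- function(gm, genomic_pos) {
  stopifnot(inherits(gm, "gene_model"))
  if (any(genomic_pos < 0L) || any(genomic_pos >= gm$sequence_length)) {
    stop("coordinate error: genomic position outside the locus")
  }
  ex <- gm$exons
  vapply(as.integer(genomic_pos), function(g) {
    i <- which(g >= ex$start & g < ex$end)
    if (length(i) == 0L) NA_integer_
    else as.integer(ex$cds_start[i] + (g - ex$start[i]))
  }, integer(1L))
}

#' Translate a coding nucleotide sequence
#'
#' Standard-code translation of an in-frame coding sequence. Stop codons are
#' rendered as `"*"` and flagged via the `"truncated"` attribute.
#'
#' @param cds_subsequence ACGT string whose length is a multiple of 3.
#' @return Peptide string; attribute `truncated` is `TRUE` when a stop codon
#'   occurs before the last codon.
#' @export
translate_cds <- function(cds_subsequence) {
  stopifnot(is.character(cds_subsequence), length(cds_subsequence) == 1L)
  if (nchar(cds_subsequence) %% 3L != 0L) {
    stop("frame error: sequence length must be divisible by 3")
  }
  if (grepl("[^ACGT]", cds_subsequence)) {
    stop("sequence must contain only A, C, G, T")
  }
  if (nchar(cds_subsequence) == 0L) {
    return(structure("", truncated = FALSE))
  }
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_subsequence), no.init.codon = TRUE))
  structure(pep, truncated = grepl("*", pep, fixed = TRUE))
}

#' CDS interval of the exon-13 duplicated core
#'
#' The 21-nt region c.1306-c.1326 encoding the leucine-rich ELLTRLA motif
#' (codons 436-442) that nearly all cohort duplications share.
#'
#' @return Integer vector `c(start = 1306, end = 1326)` (1-based, closed).
#' @export
td_core_cds <- function() c(start = 1306L, end = 1326L)

## Codons used when building the fixture coding sequence. ELLTRLA occupies
## codons 436-442; Trp445/Asn446/Asp447 are the preferred internal-deletion
## targets; GLCLRFNQLDLDQA is the single non-core leucine-rich class.
.elltrla_codons <- c("GAA", "CTG", "CTG", "ACC", "CGT", "CTG", "GCC")
.wnd_codons <- c("TGG", "AAC", "GAT")
.glcl_codons <- c("GGT", "CTG", "TGC", "CTG", "CGT", "TTC", "AAC", "CAG",
                  "CTG", "GAT", "CTG", "GAT", "CAG", "GCC")

## Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## TRUE when every k-mer of the sequence occurs exactly once.
.kmers_unique <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  !anyDuplicated(kmers)
}

#' Packaged synthetic gene model
#'
#' Builds the deterministic synthetic locus used throughout the package: a
#' 2052-bp forward-strand region holding exons 12-14 of a UBTF-like gene.
#' Exon 13 carries the 21-nt core c.1306-c.1326 encoding ELLTRLA at codons
#' 436-442, codons 445-447 are Trp-Asn-Asp (the preferred deletion targets),
#' and the exon-12 to exon-14 amplicon is exactly 617 bp. Intron lengths
#' (150 and 142 bp) are chosen so that a 598-bp duplication spanning both
#' introns carries 306 exonic bases, an in-frame multiple of 3. The sequence
#' is regenerated from an internal fixed seed until every 15-mer in the locus
#' is unique, which makes seed-based breakpoint placement unambiguous.
#'
#' @return A [gene_model()].
#' @export
ubtf_fixture_model <- function() {
  flank5 <- 700L
  exon_widths <- c(120L, 120L, 120L)
  intron_widths <- c(150L, 142L)
  s12 <- flank5
  e12 <- s12 + exon_widths[1L]
  s13 <- e12 + intron_widths[1L]
  e13 <- s13 + exon_widths[2L]
  s14 <- e13 + intron_widths[2L]
  e14 <- s14 + exon_widths[3L]
  total <- e14 + 700L

  sense_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1L, paste0, collapse = ""),
    c("TAA", "TAG", "TGA"))

  build <- function(seed) {
    with_seed(seed, {
      codons <- sample(sense_codons, 120L, replace = TRUE)
      ## CDS c.1171-c.1530 = codons 391-510; index within fixture = codon - 390
      codons[(436:442) - 390L] <- .elltrla_codons
      codons[(445:447) - 390L] <- .wnd_codons
      codons[(453:466) - 390L] <- .glcl_codons
      cds <- paste(codons, collapse = "")
      rb <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
      paste0(rb(flank5),
             substr(cds, 1L, 120L), rb(intron_widths[1L]),
             substr(cds, 121L, 240L), rb(intron_widths[2L]),
             substr(cds, 241L, 360L), rb(700L))
    })
  }
  seed <- 104729L
  seq <- build(seed)
  while (!.kmers_unique(seq, 15L)) {
    seed <- seed + 1L
    seq <- build(seed)
  }

  exons <- data.frame(
    name = c("exon12", "exon13", "exon14"),
    start = c(s12, s13, s14),
    end = c(e12, e13, e14),
    cds_start = c(1171L, 1291L, 1411L))
  gene_model("UBTF_fixture", seq, exons,
             forward_primer_pos = s12 + 18L,
             reverse_primer_pos = e14 - 17L)
}

#' Read and write gene models as FASTA + exon TSV
#'
#' The exon table is a plain TSV with columns `name`, `start`, `end`,
#' `cds_start` and `## key value` header lines carrying the primer
#' positions, so a real locus can be supplied without code changes.
#'
#' @param fasta,exon_tsv File paths.
#' @return `read_gene_model()` returns a [gene_model()];
#'   `write_gene_model()` returns the model invisibly.
#' @export
read_gene_model <- function(fasta, exon_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  stopifnot(length(seqs) == 1L)
  lines <- readLines(exon_tsv)
  meta <- lines[startsWith(lines, "##")]
  kv <- do.call(rbind, strsplit(sub("^##\\s*", "", meta), "\\s+"))
  vals <- stats::setNames(as.integer(kv[, 2L]), kv[, 1L])
  ex <- utils::read.table(text = lines[!startsWith(lines, "##")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_model(sub("\\s.*$", "", names(seqs)[1L]),
             as.character(seqs[[1L]]), ex,
             vals[["forward_primer_pos"]], vals[["reverse_primer_pos"]])
}

#' @rdname read_gene_model
#' @param gm A [gene_model()] to serialize.
#' @export
write_gene_model <- function(gm, fasta, exon_tsv) {
  stopifnot(inherits(gm, "gene_model"))
  dna <- Biostrings::DNAStringSet(gm$sequence)
  names(dna) <- gm$locus_name
  Biostrings::writeXStringSet(dna, fasta)
  con <- file(exon_tsv, "w")
  on.exit(close(con))
  writeLines(c(sprintf("## forward_primer_pos %d", gm$forward_primer_pos),
               sprintf("## reverse_primer_pos %d", gm$reverse_primer_pos)),
             con)
  utils::write.table(gm$exons, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(gm)
}

## CDS sequence of the model (concatenated exons).
model_cds <- function(gm) {
  paste(substring(gm$sequence, gm$exons$start + 1L, gm$exons$end),
        collapse = "")
}

## Extract CDS subsequence by closed 1-based c. interval.
cds_sequence <- function(gm, cds_start, cds_end) {
  cds <- model_cds(gm)
  off <- gm$exons$cds_start[1L] - 1L
  substr(cds, cds_start - off, cds_end - off)
}

## Total exonic overlap (bp) of a 0-based half-open genomic interval.
exonic_overlap <- function(gm, start, end) {
  ex <- gm$exons
  as.integer(sum(pmax(0, pmin(ex$end, end) - pmax(ex$start, start))))
}
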