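#' Write TD calls as a VCF
#'
#' Symbolic `<DUP:TANDEM>` records with the duplication coordinates, total
#' inserted length, non-templated insert and deletion load in INFO, and the
#' reported VAF in the sample FORMAT field.
#'
#' @param calls A [call_tds()] result.
#' @param gm A [gene_model()].
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_td_vcf <- function(calls, gm, path, sample_name = "SAMPLE") {
  stopifnot(inherits(gm, "gene_model"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", gm$locus_name, gm$sequence_length),
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Duplication end (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Total inserted length\">",
    "##INFO=<ID=NTINS,Number=1,Type=String,Description=\"Non-templated junction insert\">",
    "##INFO=<ID=DELLEN,Number=1,Type=Integer,Description=\"Internally deleted length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Junction-supporting reads\">",
    "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- character(0L)
  for (i in seq_len(nrow(calls))) {
    pos1 <- calls$dup_start[i] + 1L
    ref <- substr(gm$sequence, pos1, pos1)
    info <- sprintf("END=%d;SVLEN=%d;NTINS=%s;DELLEN=%d;SUPPORT=%d",
                    calls$dup_end[i], calls$total_inserted_length[i],
                    if (nzchar(calls$insert[i])) calls$insert[i] else ".",
                    calls$deleted_length[i],
                    calls$support_junction_reads[i])
    body <- c(body, paste(gm$locus_name, pos1, sprintf("TD%d", i), ref,
                          "<DUP:TANDEM>", ".", "PASS", info, "VAF",
                          sprintf("%.4f", calls$vaf[i]), sep = "\t"))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
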