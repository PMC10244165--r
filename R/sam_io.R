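## Plain-text SAM reading/writing and CIGAR helpers. Alignments travel
## through the package as a data.frame with columns qname, flag, pos
## (1-based leftmost), mapq, cigar, seq (plus mate fields when present).

## Parse CIGAR strings into a list of op matrices (len, op).
cigar_ops <- function(cigar) {
  lapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(x) {
    list(len = as.integer(sub("[A-Z=]$", "", x)),
         op = sub("^\\d+", "", x))
  })
}

## Reference bases consumed by each CIGAR (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  vapply(cigar_ops(cigar), function(o) {
    sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L))
}

## Leading / trailing soft-clip lengths.
cigar_clips <- function(cigar) {
  ops <- cigar_ops(cigar)
  left <- vapply(ops, function(o) {
    if (length(o$op) && o$op[1L] == "S") o$len[1L] else 0L
  }, integer(1L))
  right <- vapply(ops, function(o) {
    n <- length(o$op)
    if (n && o$op[n] == "S") o$len[n] else 0L
  }, integer(1L))
  cbind(left = left, right = right)
}

#' Write alignments as a plain-text SAM file
#'
#' @param aln Alignment `data.frame` (as produced by [simulate_reads()]).
#' @param gm The [gene_model()] supplying the `@SQ` header line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, gm, path) {
  stopifnot(inherits(gm, "gene_model"))
  aln <- aln[order(aln$pos, aln$qname), , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", gm$locus_name, gm$sequence_length))
  rnext <- if ("rnext" %in% names(aln)) aln$rnext else "*"
  pnext <- if ("pnext" %in% names(aln)) aln$pnext else 0L
  tlen <- if ("tlen" %in% names(aln)) aln$tlen else 0L
  body <- paste(aln$qname, aln$flag, gm$locus_name, aln$pos, aln$mapq,
                aln$cigar, rnext, pnext, tlen, aln$seq,
                strrep("I", nchar(aln$seq)), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a plain-text SAM file into an alignment data.frame
#'
#' Only the fields the caller consumes are retained; header lines are
#' skipped and unmapped records dropped.
#'
#' @param path SAM file path.
#' @return Alignment `data.frame`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  out <- data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    cigar = vapply(f, `[`, "", 6L),
    rnext = vapply(f, `[`, "", 7L),
    pnext = as.integer(vapply(f, `[`, "", 8L)),
    tlen = as.integer(vapply(f, `[`, "", 9L)),
    seq = vapply(f, `[`, "", 10L),
    stringsAsFactors = FALSE)
  out[bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]
}

## Mean per-base aligned depth over a 0-based half-open interval, from the
## aligned spans (pos .. pos + ref_width) of the reads.
interval_depth <- function(aln, start, end) {
  if (nrow(aln) == 0L || end <= start) return(0)
  s <- aln$pos - 1L                      # 0-based aligned start
  e <- s + cigar_ref_width(aln$cigar)    # 0-based half-open end
  ov <- pmax(0L, pmin(e, end) - pmax(s, start))
  sum(ov) / (end - start)
}
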