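#' Splice-aware frame and peptide annotation of a TD
#'
#' Projects the mutant haplotype through the exon model: duplicated exonic
#' bases are retained in the spliced transcript, duplicated intronic bases
#' are spliced out (canonical splice sites assumed intact), and a junction
#' insert contributes only when the junction lies in an exon. The inserted
#' coding length after projection determines frame; the peptide reports the
#' residues encoded by the codons spanned by the duplicated coding region.
#' A TD whose breakpoint interrupts a splice-site dinucleotide is annotated
#' `splice_disrupting` with undefined frame.
#'
#' @param td A [td_spec()] (genomic scale) or one row of a [call_tds()]
#'   result.
#' @param gm A [gene_model()].
#' @return A one-row `data.frame`: `spliced_inserted_length`, `in_frame`,
#'   `peptide`, `leucine_rich` (>= 3 Leu), `contains_core`, `exon_span`,
#'   `exon13_fusion` (duplication carries the whole of exon 13, producing a
#'   tandem exon13-exon13 transcript), `splice_disrupting`.
#' @export
splice_aware_frame <- function(td, gm) {
  stopifnot(inherits(gm, "gene_model"))
  if (inherits(td, "td_spec")) {
    a <- td$dup_start; b <- td$dup_end
    ins <- td$insert
    dels <- td$deletions
  } else {
    a <- td$dup_start; b <- td$dup_end
    ins <- td$insert
    dels <- list()  # call rows carry only the total deleted length
  }
  if (a < 0L || b > gm$sequence_length) {
    stop("coordinate error: TD interval outside the locus")
  }
  ex <- gm$exons
  ## splice-site dinucleotides: first/last 2 intronic bases of each intron
  ss <- c()
  for (i in seq_len(nrow(ex))) {
    ss <- c(ss, ex$start[i] - 2L, ex$start[i] - 1L, ex$end[i], ex$end[i] + 1L)
  }
  ss <- ss[ss >= 0L & ss < gm$sequence_length]
  disrupt <- (a %in% ss) || ((b - 1L) %in% ss)
  exonic <- exonic_overlap(gm, a, b)
  jun_cds <- if (b < gm$sequence_length) genomic_to_cds(gm, b) else NA_integer_
  ins_coding <- if (!is.na(jun_cds)) nchar(ins) else 0L
  del_exonic <- sum(vapply(dels, function(d) exonic_overlap(gm, d[1L], d[2L]),
                           integer(1L)))
  ## calls (not td_specs) carry only the total deleted length; attribute it
  ## to exonic sequence when the whole duplication is exonic
  if (!inherits(td, "td_spec") && length(dels) == 0L &&
      !is.null(td$deleted_length) && td$deleted_length > 0L) {
    del_exonic <- if (exonic == b - a) td$deleted_length else 0L
  }
  spliced <- exonic + ins_coding - del_exonic
  in_frame <- if (disrupt) NA else spliced %% 3L == 0L
  touched <- ex$name[ex$start < b & ex$end > a]
  full13 <- any(ex$name == "exon13" & ex$start >= a & ex$end <= b)
  ## peptide: residues encoded by the codons spanned by the duplicated CDS
  gpos <- seq.int(a, b - 1L)
  cds <- genomic_to_cds(gm, gpos[gpos >= min(ex$start) & gpos < max(ex$end)])
  cds <- cds[!is.na(cds)]
  pep <- ""
  if (length(cds) && !disrupt) {
    c1 <- (codon_of(min(cds)) - 1L) * 3L + 1L
    c2 <- codon_of(max(cds)) * 3L
    lo <- gm$exons$cds_start[1L]
    hi <- lo + sum(gm$exons$end - gm$exons$start) - 1L
    if (c1 >= lo && c2 <= hi) {
      pep <- as.character(translate_cds(cds_sequence(gm, c1, c2)))
    }
  }
  core <- td_core_cds()
  data.frame(
    spliced_inserted_length = as.integer(spliced),
    in_frame = in_frame,
    peptide = pep,
    leucine_rich = lengths(regmatches(pep, gregexpr("L", pep))) >= 3L,
    contains_core = length(cds) > 0L && min(cds) <= core[1L] &&
      max(cds) >= core[2L],
    exon_span = paste(touched, collapse = ","),
    exon13_fusion = full13,
    splice_disrupting = disrupt,
    stringsAsFactors = FALSE)
}

#' Cohort minimal duplicated region
#'
#' Interval intersection of the duplicated CDS intervals over all
#' core-containing calls; non-core calls are excluded and listed. An empty
#' intersection is reported as `NA` with pairwise-overlap diagnostics
#' attached.
#'
#' @param calls `data.frame` with `cds_start`, `cds_end` (closed, 1-based)
#'   and `contains_core` columns ([call_tds()] output or a cohort truth
#'   table annotated the same way).
#' @return Integer vector `c(start, end)` (closed CDS interval), with
#'   attributes `n_used`, `excluded_non_core` and (when empty)
#'   `diagnostics`.
#' @export
minimal_duplicated_region <- function(calls) {
  stopifnot(all(c("cds_start", "cds_end", "contains_core") %in% names(calls)))
  core_calls <- calls[!is.na(calls$contains_core) & calls$contains_core &
                        !is.na(calls$cds_start), , drop = FALSE]
  if (nrow(core_calls) == 0L) {
    stop("no core-containing calls: minimal region undefined")
  }
  s <- max(core_calls$cds_start)
  e <- min(core_calls$cds_end)
  excluded <- which(!calls$contains_core | is.na(calls$cds_start))
  if (s > e) {
    pairs <- utils::combn(seq_len(nrow(core_calls)), 2L)
    overlap <- apply(pairs, 2L, function(p) {
      min(core_calls$cds_end[p]) - max(core_calls$cds_start[p]) + 1L
    })
    return(structure(c(start = NA_integer_, end = NA_integer_),
                     n_used = nrow(core_calls),
                     excluded_non_core = excluded,
                     diagnostics = data.frame(i = pairs[1L, ],
                                              j = pairs[2L, ],
                                              overlap = overlap)))
  }
  structure(c(start = s, end = e), n_used = nrow(core_calls),
            excluded_non_core = excluded)
}

#' Cohort-level TD summary
#'
#' Size histogram, share of the recurrent 48/51/54-bp sizes, internal
#' deletion frequency stratified at 100 bp, and the minimal duplicated
#' region.
#'
#' @param calls Cohort call (or truth) `data.frame` with
#'   `total_inserted_length`, `n_deletions`, `cds_start`, `cds_end`,
#'   `contains_core`.
#' @return List of class `cohort_summary`.
#' @export
summarize_cohort <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  sz <- calls$total_inserted_length
  big <- sz > 100L
  has_del <- calls$n_deletions > 0L
  structure(list(
    n = nrow(calls),
    size_histogram = table(sz),
    fraction_sizes_48_51_54 = mean(sz %in% c(48L, 51L, 54L)),
    fraction_with_deletion = mean(has_del),
    fraction_with_deletion_large = if (any(big)) mean(has_del[big]) else NA_real_,
    fraction_with_deletion_small = if (any(!big)) mean(has_del[!big]) else NA_real_,
    minimal_region = minimal_duplicated_region(calls)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  cat(sprintf("  48/51/54-bp share: %.1f%%\n",
              100 * x$fraction_sizes_48_51_54))
  cat(sprintf("  internal deletions: %.1f%% overall (>100 bp: %.1f%%, <=100 bp: %.1f%%)\n",
              100 * x$fraction_with_deletion,
              100 * x$fraction_with_deletion_large,
              100 * x$fraction_with_deletion_small))
  mr <- x$minimal_region
  cat(sprintf("  minimal duplicated region: c.%d-c.%d (%d nt, %d calls)\n",
              mr[1L], mr[2L], mr[2L] - mr[1L] + 1L, attr(mr, "n_used")))
  invisible(x)
}
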