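#' Tandem-duplication specification
#'
#' Describes one TD allele at genomic scale: the duplicated interval
#' `[dup_start, dup_end)` (0-based half-open), an optional non-templated
#' insert placed at the junction between the two copies, and internal
#' deletions applied inside the second copy. The mutant haplotype is
#' `ref[0, dup_end) + insert + copy(ref[dup_start, dup_end) - deletions) +
#' ref[dup_end, ...)`, so the junction sits at `dup_end` and the total
#' inserted length is `span + nchar(insert) - sum(deletion widths)`.
#'
#' @param dup_start,dup_end 0-based half-open duplicated genomic interval.
#' @param insert Non-templated junction insert (possibly `""`).
#' @param deletions List of 0-based half-open genomic intervals (length-2
#'   integer vectors) strictly inside the duplicated interval.
#' @param allele_fraction Fraction of alleles carrying the TD, in (0, 1].
#' @param contains_core Logical; whether the duplicated interval contains the
#'   exon-13 core (set by [sample_cohort()], recomputed by the annotator).
#' @return An object of class `td_spec`.
#' @export
td_spec <- function(dup_start, dup_end, insert = "", deletions = list(),
                    allele_fraction = 0.45, contains_core = NA) {
  dup_start <- as.integer(dup_start); dup_end <- as.integer(dup_end)
  if (dup_end < dup_start) stop("spec error: dup_end < dup_start")
  if (nchar(insert) > 0L && grepl("[^ACGT]", insert)) {
    stop("spec error: insert must be an ACGT string")
  }
  deletions <- lapply(deletions, function(d) as.integer(d[1:2]))
  for (d in deletions) {
    if (d[1L] < dup_start || d[2L] > dup_end || d[2L] <= d[1L]) {
      stop("spec error: deletion outside duplication")
    }
  }
  if (length(deletions) > 1L) {
    o <- order(vapply(deletions, `[`, integer(1L), 1L))
    deletions <- deletions[o]
  }
  del_len <- sum(vapply(deletions, function(d) d[2L] - d[1L], integer(1L)))
  if (!(allele_fraction > 0 && allele_fraction <= 1)) {
    stop("spec error: allele_fraction must be in (0, 1]")
  }
  structure(
    list(dup_start = dup_start, dup_end = dup_end, insert = insert,
         deletions = deletions,
         total_inserted_length =
           (dup_end - dup_start) + nchar(insert) - as.integer(del_len),
         allele_fraction = allele_fraction,
         contains_core = contains_core),
    class = "td_spec")
}

#' @export
print.td_spec <- function(x, ...) {
  cat(sprintf(
    "<td_spec> dup [%d,%d) span %d, insert %d nt, %d deletion(s), total +%d bp, f=%.3f\n",
    x$dup_start, x$dup_end, x$dup_end - x$dup_start, nchar(x$insert),
    length(x$deletions), x$total_inserted_length, x$allele_fraction))
  invisible(x)
}

#' Cohort-level simulation parameters
#'
#' Defaults encode the study conditions of the adult UBTF-TD cohort: discrete
#' mass on TD sizes 48/51/54 bp (18/59, 10/59, 6/59 of patients) plus a
#' log-uniform tail over 39-950 bp; one non-core patient class in 59;
#' internal-deletion probabilities 0.13 (TDs <= 100 bp) and 0.64 (> 100 bp);
#' a logit-normal allele-fraction distribution with median 0.45; and
#' co-mutation rates led by WT1 (0.63) and FLT3-ITD (0.53).
#'
#' @param n_patients Number of patients to simulate.
#' @param modal_weights Named probabilities for the recurrent sizes.
#' @param p_tail Probability of a size drawn from the long tail.
#' @param tail_range Inclusive genomic-size range of the tail.
#' @param p_non_core Probability of the non-core 42-bp class.
#' @param p_internal_deletion_small,p_internal_deletion_large Deletion
#'   probabilities for TDs <= 100 bp and > 100 bp.
#' @param vaf_logit_mean,vaf_logit_sd Logit-normal allele-fraction parameters.
#' @param co_mutation_rates Named per-gene co-mutation probabilities.
#' @param seed Integer seed; fixed seeds give byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 59L,
                        modal_weights = c("48" = 18 / 59, "51" = 10 / 59,
                                          "54" = 6 / 59),
                        p_tail = 24 / 59,
                        tail_range = c(39L, 950L),
                        p_non_core = 1 / 59,
                        p_internal_deletion_small = 0.13,
                        p_internal_deletion_large = 0.64,
                        vaf_logit_mean = stats::qlogis(0.45),
                        vaf_logit_sd = 0.335,
                        co_mutation_rates = c(WT1 = 0.63, FLT3_ITD = 0.53,
                                              trisomy8 = 0.28, NRAS = 0.23,
                                              KRAS = 0.12, PTPN11 = 0.11,
                                              RIT1 = 0.11),
                        seed = 1L) {
  if (n_patients < 1L) stop("config error: n_patients must be >= 1")
  probs <- c(modal_weights, p_tail, p_non_core)
  if (any(probs < 0) || any(probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]")
  }
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("config error: size-class weights must sum to 1")
  }
  if (any(co_mutation_rates < 0) || any(co_mutation_rates > 1)) {
    stop("config error: co-mutation rates must lie in [0, 1]")
  }
  structure(
    list(n_patients = as.integer(n_patients), modal_weights = modal_weights,
         p_tail = p_tail, tail_range = as.integer(tail_range),
         p_non_core = p_non_core,
         p_internal_deletion_small = p_internal_deletion_small,
         p_internal_deletion_large = p_internal_deletion_large,
         vaf_logit_mean = vaf_logit_mean, vaf_logit_sd = vaf_logit_sd,
         co_mutation_rates = co_mutation_rates, seed = as.integer(seed)),
    class = "cohort_spec")
}

## Canonical recurrent duplicated intervals (genomic, 0-based half-open) on
## the fixture model. The 48- and 51-bp classes start at the core 5' edge
## (c.1306); the 54-bp class crosses the intron-12/exon-13 boundary and ends
## at the core 3' edge, so cohort intersection recovers c.1306-c.1326.
.canonical_dup <- function(gm, size) {
  core_g <- cds_to_genomic(gm, td_core_cds())
  switch(as.character(size),
         "48" = c(core_g[1L], core_g[1L] + 48L),
         "51" = c(core_g[1L], core_g[1L] + 51L),
         "54" = c(core_g[2L] + 1L - 54L, core_g[2L] + 1L),
         stop("no canonical interval for size ", size))
}

## Place a tail-class duplicated interval of the given genomic span so that
## it contains the core, fits in the locus, and (via small end adjustments)
## carries an exonic content that is a multiple of 3.
.place_tail_interval <- function(gm, span) {
  core_g <- cds_to_genomic(gm, td_core_cds())
  core_start <- core_g[1L]; core_end <- core_g[2L] + 1L
  margin <- 60L
  ## breakpoints must not interrupt a splice-site dinucleotide
  ss <- integer(0L)
  for (i in seq_len(nrow(gm$exons))) {
    ss <- c(ss, gm$exons$start[i] - 2L, gm$exons$start[i] - 1L,
            gm$exons$end[i], gm$exons$end[i] + 1L)
  }
  lo <- max(margin, core_end - span)
  hi <- min(core_start, gm$sequence_length - margin - span)
  if (lo > hi) stop("spec error: tail span does not fit in the locus")
  a <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  ## nudge the 5' end off splice sites, then the 3' end into frame, keeping
  ## core containment throughout
  for (adj in c(0L, -1L, -2L, -3L, 1L, 2L, 3L)) {
    a2 <- a + adj
    if (a2 < margin || a2 > core_start || (a2 %in% ss)) next
    b2 <- a2 + span
    if (b2 < core_end) next
    for (d in 0:12) {
      if (exonic_overlap(gm, a2, b2 + d) %% 3L == 0L &&
          b2 + d <= gm$sequence_length - margin &&
          !((b2 + d - 1L) %in% ss)) {
        return(c(a2, b2 + d))
      }
    }
  }
  stop("spec error: could not phase tail interval")
}

## Draw an internal deletion for a duplicated interval. Preferentially hits
## the codon 445-447 target (c.1333-1341) when the copy covers it; otherwise
## a codon-aligned exonic (or intronic, for large TDs) triplet block at least
## 18 bp from the copy 5' end (junction-proximal deletions are equivalent to
## longer non-templated inserts and are therefore not generated).
.draw_deletion <- function(gm, a, b, d_len) {
  target <- cds_to_genomic(gm, c(1333L, 1341L))
  t0 <- target[1L]; t1 <- target[2L] + 1L
  if (t0 >= a + 18L && t0 + d_len <= b - 3L) {
    return(list(c(t0, t0 + d_len)))
  }
  ## fall back to any frame-aligned position inside the copy
  cand <- seq.int(a + 18L, b - 3L - d_len, by = 3L)
  cand <- cand[cand + d_len < b]
  if (length(cand) == 0L) return(list())
  core_g <- cds_to_genomic(gm, td_core_cds())
  keep <- !(cand < core_g[2L] + 1L & cand + d_len > core_g[1L])
  cand <- cand[keep]
  ## deletions must not straddle an exon boundary (frame preservation)
  ov <- vapply(cand, function(p) exonic_overlap(gm, p, p + d_len), integer(1L))
  cand <- cand[ov == 0L | ov == d_len]
  if (length(cand) == 0L) return(list())
  p <- cand[sample.int(length(cand), 1L)]
  list(c(p, p + d_len))
}

#' Sample a synthetic UBTF-TD cohort
#'
#' Draws one TD allele and a co-mutation set per patient from the
#' distributions in a [cohort_spec()]. Modal sizes use recurrent canonical
#' breakpoints; tail sizes are placed randomly around the core with exonic
#' content kept in frame; one class in 59 is the non-core 42-bp duplication
#' encoding GLCLRFNQLDLDQA. Deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param gm A [gene_model()]; defaults to the packaged fixture.
#' @return `data.frame` with one row per patient (`patient_id`, `size_class`,
#'   interval, insert/deletion structure, `vaf`, `contains_core`,
#'   `co_mutations`) and the full [td_spec()] objects in
#'   `attr(, "td_specs")`.
#' @export
sample_cohort <- function(spec, gm = ubtf_fixture_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(gm, "gene_model"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    classes <- sample(
      c(names(spec$modal_weights), "tail", "non_core"), n, replace = TRUE,
      prob = c(spec$modal_weights, spec$p_tail, spec$p_non_core))
    specs <- vector("list", n)
    rows <- vector("list", n)
    nc_g <- cds_to_genomic(gm, c(1357L, 1398L))
    for (i in seq_len(n)) {
      vaf <- stats::plogis(stats::rnorm(1L, spec$vaf_logit_mean,
                                        spec$vaf_logit_sd))
      cls <- classes[i]
      if (cls == "non_core") {
        ab <- c(nc_g[1L], nc_g[2L] + 1L)
        ins <- ""
        dels <- list()
      } else {
        if (cls == "tail") {
          lr <- log(spec$tail_range)
          size <- as.integer(round(exp(stats::runif(1L, lr[1L], lr[2L]))))
          if (size <= 100L) size <- max(39L, 3L * round(size / 3))
        } else {
          size <- as.integer(cls)
        }
        ## decompose the target genomic size into span - deletions + insert
        big <- size > 100L
        p_del <- if (big) spec$p_internal_deletion_large
                 else spec$p_internal_deletion_small
        want_del <- stats::runif(1L) < p_del
        ins_len <- sample(0:6, 1L)
        d_guess <- if (want_del) sample(c(3L, 6L, 9L), 1L) else 0L
        span <- size - ins_len + d_guess
        if (cls %in% names(spec$modal_weights) && cls != "54") {
          core_g <- cds_to_genomic(gm, td_core_cds())
          ab <- c(core_g[1L], core_g[1L] + span)
        } else if (cls == "54") {
          core_g <- cds_to_genomic(gm, td_core_cds())
          ## exonic junction at the core 3' edge: keep insert in frame
          ins_len <- 3L * (ins_len %/% 3L)
          span <- size - ins_len + d_guess
          ab <- c(core_g[2L] + 1L - span, core_g[2L] + 1L)
        } else if (!big) {
          lo_c <- max(1291L, 1326L - span + 1L)
          hi_c <- min(1306L, 1410L - span + 1L)
          a_c <- if (lo_c >= hi_c) lo_c
                 else lo_c + sample.int(hi_c - lo_c + 1L, 1L) - 1L
          g <- cds_to_genomic(gm, a_c)
          ab <- c(g, g + span)
        } else {
          ab <- .place_tail_interval(gm, span)
          ## intronic junctions leave the insert unconstrained; exonic
          ## junctions need a frame-neutral insert
          if (!is.na(genomic_to_cds(gm, min(ab[2L], gm$sequence_length - 1L)))) {
            ins_len <- 3L * (ins_len %/% 3L)
          }
        }
        dels <- if (want_del) .draw_deletion(gm, ab[1L], ab[2L], d_guess)
                else list()
        if (length(dels) == 0L && want_del) {
          span <- span - d_guess
          ab[2L] <- ab[1L] + span
        }
        ins <- if (ins_len > 0L) {
          bases <- sample(c("A", "C", "G", "T"), ins_len, TRUE)
          ## left-most normal form: an insert ending in the base that
          ## precedes the duplication is the same allele as a 1-bp-shifted
          ## duplication with a shorter insert
          before <- substr(gm$sequence, ab[1L], ab[1L])
          if (bases[ins_len] == before) {
            bases[ins_len] <- sample(setdiff(c("A", "C", "G", "T"), before),
                                     1L)
          }
          paste(bases, collapse = "")
        } else ""
      }
      td <- td_spec(ab[1L], ab[2L], ins, dels, allele_fraction = vaf,
                    contains_core = cls != "non_core")
      specs[[i]] <- td
      genes <- names(spec$co_mutation_rates)
      mut <- genes[stats::runif(length(genes)) < spec$co_mutation_rates]
      rows[[i]] <- data.frame(
        patient_id = sprintf("P%03d", i),
        size_class = cls,
        dup_start = td$dup_start, dup_end = td$dup_end,
        span = td$dup_end - td$dup_start,
        insert = td$insert,
        n_deletions = length(td$deletions),
        deleted_length = (td$dup_end - td$dup_start) + nchar(td$insert) -
          td$total_inserted_length,
        total_inserted_length = td$total_inserted_length,
        vaf = vaf,
        contains_core = td$contains_core,
        co_mutations = paste(mut, collapse = ","),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "td_specs") <- specs
    out
  })
}

#' Build the mutant haplotype for a TD allele
#'
#' Applies a [td_spec()] to the locus: the duplicated segment is repeated in
#' tandem at its 3' end, the non-templated insert is placed at the junction,
#' and internal deletions are removed from the second copy.
#'
#' @param gm A [gene_model()].
#' @param td A [td_spec()].
#' @return List with the mutant `sequence`, the reference `junction`
#'   (0-based position where the inserted block starts), `inserted_length`,
#'   and the kept second-copy `copy_chunks` (reference intervals).
#' @export
mutate_locus <- function(gm, td) {
  stopifnot(inherits(gm, "gene_model"), inherits(td, "td_spec"))
  if (td$dup_end > gm$sequence_length) {
    stop("spec error: duplicated interval outside the locus")
  }
  a <- td$dup_start; b <- td$dup_end
  if (a == b) {
    return(list(sequence = gm$sequence, junction = b, inserted_length = 0L,
                copy_chunks = list()))
  }
  ## kept chunks of the second copy, as 0-based half-open ref intervals
  chunks <- list(c(a, b))
  for (d in td$deletions) {
    new <- list()
    for (ch in chunks) {
      if (d[2L] <= ch[1L] || d[1L] >= ch[2L]) { new <- c(new, list(ch)); next }
      if (d[1L] > ch[1L]) new <- c(new, list(c(ch[1L], d[1L])))
      if (d[2L] < ch[2L]) new <- c(new, list(c(d[2L], ch[2L])))
    }
    chunks <- new
  }
  copy_seq <- paste(vapply(chunks, function(ch)
    substr(gm$sequence, ch[1L] + 1L, ch[2L]), character(1L)), collapse = "")
  mutant <- paste0(substr(gm$sequence, 1L, b), td$insert, copy_seq,
                   substr(gm$sequence, b + 1L, gm$sequence_length))
  stopifnot(nchar(mutant) == gm$sequence_length + td$total_inserted_length)
  list(sequence = mutant, junction = b,
       inserted_length = td$total_inserted_length, copy_chunks = chunks)
}
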