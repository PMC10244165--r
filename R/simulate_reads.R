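#' Read-simulation configuration
#'
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Insert-size distribution (bp).
#' @param depth Target mean fold-coverage across the locus.
#' @param error_rate Per-base substitution error rate (no indel errors, so
#'   alignment signal is not confounded).
#' @param min_anchor Minimum matched bases on both sides for a junction read
#'   to be represented as a CIGAR insertion rather than a soft clip.
#' @param min_mapped Minimum matched bases for a read to be emitted as
#'   aligned at all (shorter anchors are dropped, as an aligner would).
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 150L, fragment_mean = 350,
                            fragment_sd = 50, depth = 500,
                            error_rate = 0.001, min_anchor = 15L,
                            min_mapped = 20L, seed = 1L) {
  stopifnot(read_length > 0L, depth > 0, read_length < fragment_mean,
            error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth, error_rate = error_rate,
                 min_anchor = as.integer(min_anchor),
                 min_mapped = as.integer(min_mapped),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

## Mutant-to-reference coordinate map used by the in-silico aligner.
.hap_map <- function(gm, td) {
  if (is.null(td)) {
    return(list(mutant = gm$sequence, b = NA_integer_, i_len = 0L, L = 0L,
                chunks = list(), chunk_mut = integer(0L)))
  }
  mut <- mutate_locus(gm, td)
  chunks <- mut$copy_chunks
  i_len <- nchar(td$insert)
  widths <- vapply(chunks, function(ch) ch[2L] - ch[1L], integer(1L))
  chunk_mut <- mut$junction + i_len + cumsum(c(0L, widths[-length(widths)]))
  list(mutant = mut$sequence, b = mut$junction, i_len = i_len,
       L = mut$inserted_length, chunks = chunks, chunk_mut = chunk_mut)
}

## Align the right-hand portion [rs, m2) of a mutant read (rs at or after
## the start of the second copy) back to the reference. Returns NULL when
## nothing overlaps; otherwise pos0 (0-based ref), cigar op vectors and the
## number of matched bases.
.walk_right <- function(rs, m2, map) {
  lens <- integer(0L); ops <- character(0L)
  pos0 <- NA_integer_; last_ref_end <- NA_integer_
  segs <- map$chunks
  seg_mut <- map$chunk_mut
  ## the post-block tail behaves as one more segment starting at ref b
  segs <- c(segs, list(c(map$b, .Machine$integer.max)))
  seg_mut <- c(seg_mut, map$b + map$L)
  for (k in seq_along(segs)) {
    w <- segs[[k]][2L] - segs[[k]][1L]
    s_mut <- seg_mut[k]; e_mut <- if (k < length(segs)) s_mut + w else m2
    o1 <- max(rs, s_mut); o2 <- min(m2, e_mut)
    if (o2 <= o1) next
    ref_s <- segs[[k]][1L] + (o1 - s_mut)
    if (is.na(pos0)) {
      pos0 <- ref_s
    } else {
      gap <- ref_s - last_ref_end
      if (gap > 0L) { lens <- c(lens, gap); ops <- c(ops, "D") }
    }
    ## merge with a preceding contiguous M
    if (length(ops) && ops[length(ops)] == "M" && ref_s == last_ref_end) {
      lens[length(lens)] <- lens[length(lens)] + (o2 - o1)
    } else {
      lens <- c(lens, o2 - o1); ops <- c(ops, "M")
    }
    last_ref_end <- ref_s + (o2 - o1)
  }
  if (is.na(pos0)) return(NULL)
  list(pos0 = pos0, lens = lens, ops = ops,
       matched = sum(lens[ops == "M"]))
}

.render_cigar <- function(lens, ops) paste0(paste0(lens, ops), collapse = "")

## In-silico alignment of one mutant-haplotype read [m1, m2) against the
## reference: emulates the junction signatures an aligner would produce
## (full-block CIGAR insertion, left/right soft clips, M/D through the
## second copy). Returns NULL for reads with no adequate anchor.
.align_mutant_read <- function(m1, m2, map, cfg) {
  b <- map$b; L <- map$L; i_len <- map$i_len
  r_len <- m2 - m1
  if (m2 <= b) {
    return(list(pos0 = m1, cigar = sprintf("%dM", r_len), rep = "M"))
  }
  if (m1 >= b + L) {
    return(list(pos0 = m1 - L, cigar = sprintf("%dM", r_len), rep = "M"))
  }
  if (m1 >= b + i_len) {
    ## starts inside the second copy: reference-contiguous (with D gaps)
    wr <- .walk_right(m1, m2, map)
    if (is.null(wr) || wr$matched < cfg$min_mapped) return(NULL)
    return(list(pos0 = wr$pos0, cigar = .render_cigar(wr$lens, wr$ops),
                rep = "M"))
  }
  ## junction-crossing read
  left_len <- max(0L, b - m1)
  if (left_len >= cfg$min_anchor && m2 - (b + L) >= cfg$min_anchor &&
      L <= r_len - 2L * cfg$min_anchor) {
    return(list(pos0 = m1,
                cigar = sprintf("%dM%dI%dM", left_len, L, m2 - b - L),
                rep = "I"))
  }
  rs <- b + i_len
  wr <- if (m2 > rs) .walk_right(rs, m2, map) else NULL
  right_matched <- if (is.null(wr)) 0L else wr$matched
  if (left_len >= right_matched) {
    if (left_len < cfg$min_mapped) return(NULL)
    return(list(pos0 = m1,
                cigar = sprintf("%dM%dS", left_len, m2 - b), rep = "SR"))
  }
  if (right_matched < cfg$min_mapped) return(NULL)
  clip <- rs - m1
  list(pos0 = wr$pos0,
       cigar = paste0(sprintf("%dS", clip), .render_cigar(wr$lens, wr$ops)),
       rep = "SL")
}

#' Simulate aligned paired-end reads over the locus
#'
#' Generates pre-aligned paired-end reads from a mixture of haplotypes
#' (wild-type and/or TD-bearing). Reads from a mutant haplotype that cross
#' the TD junction carry soft clips, or a CIGAR insertion when the whole
#' inserted block fits within one read; reads inside the duplicated copy
#' align as reference matches (with deletion gaps where the copy carries
#' internal deletions), which produces the characteristic coverage excess
#' over the duplicated interval. Substitution errors are added at
#' `cfg$error_rate`. Deterministic under `cfg$seed`.
#'
#' @param gm A [gene_model()].
#' @param haplotypes List of `list(td = td_spec-or-NULL, fraction = ...)`;
#'   fractions must sum to 1.
#' @param cfg A [read_sim_config()].
#' @return List with `alignments` (data.frame ready for [write_sam()]) and
#'   `truth` (per-read haplotype of origin, junction overlap and alignment
#'   representation).
#' @export
simulate_reads <- function(gm, haplotypes, cfg = read_sim_config()) {
  stopifnot(inherits(gm, "gene_model"))
  if (length(haplotypes) == 0L) stop("config error: no haplotypes supplied")
  fr <- vapply(haplotypes, function(h) h$fraction, numeric(1L))
  if (abs(sum(fr) - 1) > 1e-6) stop("config error: fractions must sum to 1")
  with_seed(cfg$seed, {
    maps <- lapply(haplotypes, function(h) .hap_map(gm, h$td))
    R <- cfg$read_length
    n_pairs <- round(cfg$depth * gm$sequence_length / (2L * R))
    ## fragments per haplotype scale with molecule abundance x length, so
    ## per-base depth is the same for every haplotype
    hlens <- vapply(maps, function(m) nchar(m$mutant), numeric(1L))
    hap_of <- sample.int(length(haplotypes), n_pairs, replace = TRUE,
                         prob = fr * hlens / sum(fr * hlens))
    frag <- pmax(R + 10L,
                 as.integer(round(stats::rnorm(n_pairs, cfg$fragment_mean,
                                               cfg$fragment_sd))))
    n_reads <- 2L * n_pairs
    v_keep <- logical(n_reads); v_qname <- character(n_reads)
    v_flag <- integer(n_reads); v_pos <- integer(n_reads)
    v_cigar <- character(n_reads); v_seq <- character(n_reads)
    v_pnext <- integer(n_reads); v_tlen <- integer(n_reads)
    v_mate <- integer(n_reads); v_hap <- integer(n_reads)
    v_junc <- logical(n_reads); v_rep <- character(n_reads)
    for (p in seq_len(n_pairs)) {
      map <- maps[[hap_of[p]]]
      hlen <- nchar(map$mutant)
      f <- min(frag[p], hlen)
      s <- sample.int(hlen - f + 1L, 1L) - 1L
      qname <- sprintf("frag%06d", p)
      m1s <- c(s, s + f - R); m2s <- c(s + R, s + f)
      als <- vector("list", 2L)
      for (m in 1:2) {
        als[[m]] <- if (is.na(map$b)) {
          list(pos0 = m1s[m], cigar = sprintf("%dM", R), rep = "M")
        } else .align_mutant_read(m1s[m], m2s[m], map, cfg)
      }
      for (m in 1:2) {
        al <- als[[m]]
        if (is.null(al)) next
        other <- als[[if (m == 1L) 2L else 1L]]
        idx <- 2L * (p - 1L) + m
        v_keep[idx] <- TRUE
        v_qname[idx] <- qname
        v_flag[idx] <- if (m == 1L) 99L else 147L
        v_pos[idx] <- al$pos0 + 1L
        v_cigar[idx] <- al$cigar
        v_seq[idx] <- substr(map$mutant, m1s[m] + 1L, m2s[m])
        v_pnext[idx] <- if (is.null(other)) 0L else other$pos0 + 1L
        v_tlen[idx] <- if (m == 1L) f else -f
        v_mate[idx] <- m; v_hap[idx] <- hap_of[p]
        v_junc[idx] <- !is.na(map$b) && m1s[m] < map$b + map$L &&
          m2s[m] > map$b
        v_rep[idx] <- al$rep
      }
    }
    k <- which(v_keep)
    aln <- data.frame(
      qname = v_qname[k], flag = v_flag[k], pos = v_pos[k], mapq = 60L,
      cigar = v_cigar[k], seq = v_seq[k], rnext = "=", pnext = v_pnext[k],
      tlen = v_tlen[k], stringsAsFactors = FALSE)
    truth <- data.frame(
      qname = v_qname[k], mate = v_mate[k], haplotype = v_hap[k],
      junction = v_junc[k], representation = v_rep[k],
      stringsAsFactors = FALSE)
    ## substitution errors
    if (cfg$error_rate > 0 && nrow(aln) > 0L) {
      n_err <- stats::rbinom(nrow(aln), nchar(aln$seq), cfg$error_rate)
      for (i in which(n_err > 0L)) {
        sq <- strsplit(aln$seq[i], "")[[1L]]
        at <- sample.int(length(sq), n_err[i])
        for (j in at) {
          sq[j] <- sample(setdiff(c("A", "C", "G", "T"), sq[j]), 1L)
        }
        aln$seq[i] <- paste(sq, collapse = "")
      }
    }
    o <- order(aln$pos, aln$qname)
    list(alignments = aln[o, , drop = FALSE],
         truth = truth[o, , drop = FALSE])
  })
}
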