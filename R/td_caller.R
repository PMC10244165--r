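#' TD caller configuration
#'
#' @param min_clip_length Minimum soft-clip length (bp) for a read to count
#'   as junction evidence.
#' @param cluster_tolerance Breakpoint grouping tolerance (bp).
#' @param min_support Minimum junction-supporting reads per call.
#' @param search_window Distance (bp) upstream of a clip breakpoint searched
#'   for the duplication origin.
#' @param min_vaf_report Calls below this VAF are suppressed (the assay's
#'   stated 1% sensitivity threshold).
#' @param seed_length Exact-match seed length used to re-anchor clip
#'   consensus sequences on the reference.
#' @param max_insert_prefix Longest non-templated junction insert searched
#'   for (consensus prefix left unanchored).
#' @param max_deletion Largest internal deletion bridged during consensus
#'   walking (bp).
#' @param min_span_anchor Mapped bases required on both sides of a junction
#'   for a read to count as reference-spanning.
#' @param min_insertion_op Minimum CIGAR insertion length treated as TD
#'   evidence.
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(min_clip_length = 10L, cluster_tolerance = 3L,
                          min_support = 3L, search_window = 1500L,
                          min_vaf_report = 0.01, seed_length = 15L,
                          max_insert_prefix = 12L, max_deletion = 120L,
                          min_span_anchor = 10L, min_insertion_op = 6L) {
  vals <- c(min_clip_length, cluster_tolerance, min_support, search_window,
            min_vaf_report, seed_length, max_insert_prefix, max_deletion,
            min_span_anchor, min_insertion_op)
  if (any(vals <= 0)) stop("config error: all caller parameters are positive")
  structure(list(min_clip_length = as.integer(min_clip_length),
                 cluster_tolerance = as.integer(cluster_tolerance),
                 min_support = as.integer(min_support),
                 search_window = as.integer(search_window),
                 min_vaf_report = min_vaf_report,
                 seed_length = as.integer(seed_length),
                 max_insert_prefix = as.integer(max_insert_prefix),
                 max_deletion = as.integer(max_deletion),
                 min_span_anchor = as.integer(min_span_anchor),
                 min_insertion_op = as.integer(min_insertion_op)),
            class = "caller_config")
}

## Per-read alignment features used across the caller. Parsed once per
## sample and threaded through the stages as `ctx`.
.aln_features <- function(aln) {
  ops <- cigar_ops(aln$cigar)
  cl <- cigar_clips(aln$cigar)
  rw <- vapply(ops, function(o) {
    sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L))
  list(ft = data.frame(pos0 = aln$pos - 1L, end0 = aln$pos - 1L + rw,
                       clip_left = cl[, "left"], clip_right = cl[, "right"],
                       has_indel = grepl("[ID]", aln$cigar)),
       ops = ops)
}

#' Scan a window for any non-reference signal
#'
#' Cheap pre-filter mirroring the observation that every TD-positive sample
#' shows at least one small-variant signal in the gene: returns `TRUE` when
#' the window contains soft-clipped reads, CIGAR indels, or a substitution
#' pileup clearly above the sequencing error rate.
#'
#' @param aln Alignment `data.frame`.
#' @param gm A [gene_model()].
#' @param window 0-based half-open genomic window; defaults to exon 13
#'   +/- 1500 bp.
#' @param min_clip Clip length regarded as signal.
#' @param error_rate Assumed per-base substitution error rate for the
#'   mismatch-pileup threshold.
#' @param ctx Optional precomputed alignment features (internal reuse).
#' @return Logical, with attribute `summary` (counts of each evidence type).
#' @export
suspicion_scan <- function(aln, gm, window = NULL, min_clip = 5L,
                           error_rate = 0.001, ctx = NULL) {
  stopifnot(inherits(gm, "gene_model"))
  if (is.null(window)) {
    e13 <- gm$exons[gm$exons$name == "exon13", ]
    if (nrow(e13) == 0L) e13 <- gm$exons[ceiling(nrow(gm$exons) / 2), ]
    window <- c(max(0L, e13$start - 1500L),
                min(gm$sequence_length, e13$end + 1500L))
  }
  if (window[2L] <= window[1L]) stop("config error: empty window")
  if (nrow(aln) == 0L) {
    return(structure(FALSE, summary = c(clips = 0L, indels = 0L,
                                        mismatch_sites = 0L)))
  }
  if (is.null(ctx)) ctx <- .aln_features(aln)
  ft <- ctx$ft
  in_win <- ft$end0 > window[1L] & ft$pos0 < window[2L]
  n_clip <- sum(in_win & (ft$clip_left >= min_clip |
                            ft$clip_right >= min_clip))
  n_indel <- sum(in_win & ft$has_indel)
  n_mm_sites <- 0L
  if (n_clip == 0L && n_indel == 0L) {
    ## substitution pileup over plain-matched reads
    k <- which(in_win & !ft$has_indel & ft$clip_left == 0L &
                 ft$clip_right == 0L)
    if (length(k)) {
      reads <- utf8ToInt(paste0(aln$seq[k], collapse = ""))
      refs <- utf8ToInt(paste0(substring(gm$sequence, ft$pos0[k] + 1L,
                                         ft$end0[k]), collapse = ""))
      lens <- nchar(aln$seq[k])
      gpos <- sequence(lens) - 1L + rep(ft$pos0[k], lens)
      mm <- gpos[reads != refs]
      if (length(mm)) {
        counts <- table(mm)
        depth <- length(gpos) / gm$sequence_length  # coarse mean depth
        thr <- max(5, stats::qbinom(1 - 1e-9, round(depth * 3),
                                    error_rate) + 1)
        n_mm_sites <- sum(counts >= thr)
      }
    }
  }
  structure(n_clip > 0L || n_indel > 0L || n_mm_sites > 0L,
            summary = c(clips = n_clip, indels = n_indel,
                        mismatch_sites = n_mm_sites))
}

## Majority-vote consensus of clip sequences. Right clips are anchored at
## the junction (column 1 = first clipped base); left clips are anchored at
## their 3' end. Ties break to the lexicographically smallest base;
## columns covered by fewer than two reads are dropped (unless the cluster
## has a single read).
.clip_consensus <- function(seqs, side) {
  if (side == "left") {
    seqs <- vapply(lapply(strsplit(seqs, ""), rev), paste, "", collapse = "")
  }
  n <- length(seqs)
  lens <- nchar(seqs)
  maxlen <- max(lens)
  mincov <- if (n == 1L) 1L else 2L
  out <- character(0L)
  for (j in seq_len(maxlen)) {
    chars <- substr(seqs[lens >= j], j, j)
    if (length(chars) < mincov) break
    tab <- sort(table(chars), decreasing = TRUE)
    top <- names(tab)[tab == tab[1L]]
    out <- c(out, sort(top)[1L])
  }
  cons <- paste(out, collapse = "")
  if (side == "left") {
    cons <- paste(rev(strsplit(cons, "")[[1L]]), collapse = "")
  }
  cons
}

#' Cluster soft-clipped reads by breakpoint
#'
#' Reads with a soft clip of at least `min_clip_length` are grouped by clip
#' side and breakpoint (within `cluster_tolerance`); each cluster reports a
#' majority-vote clip consensus. Clusters below `min_support` reads are
#' discarded.
#'
#' @param aln Alignment `data.frame`.
#' @param cfg A [caller_config()].
#' @param ctx Optional precomputed alignment features (internal reuse).
#' @return `data.frame` with `side`, `breakpoint` (0-based; for right clips
#'   the first clipped reference position, for left clips the first aligned
#'   one), `read_count`, `clip_consensus`, `mean_clip_length`.
#' @export
cluster_softclips <- function(aln, cfg = caller_config(), ctx = NULL) {
  empty <- data.frame(side = character(0), breakpoint = integer(0),
                      read_count = integer(0), clip_consensus = character(0),
                      mean_clip_length = numeric(0), stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  if (is.null(ctx)) ctx <- .aln_features(aln)
  ft <- ctx$ft
  ev <- rbind(
    data.frame(side = "right", bp = ft$end0,
               len = ft$clip_right,
               seq = substr(aln$seq, nchar(aln$seq) - ft$clip_right + 1L,
                            nchar(aln$seq)),
               stringsAsFactors = FALSE)[ft$clip_right >= cfg$min_clip_length, ],
    data.frame(side = "left", bp = ft$pos0,
               len = ft$clip_left,
               seq = substr(aln$seq, 1L, ft$clip_left),
               stringsAsFactors = FALSE)[ft$clip_left >= cfg$min_clip_length, ])
  if (nrow(ev) == 0L) return(empty)
  out <- list()
  for (sd in c("left", "right")) {
    e <- ev[ev$side == sd, , drop = FALSE]
    if (nrow(e) == 0L) next
    e <- e[order(e$bp), , drop = FALSE]
    grp <- cumsum(c(1L, diff(e$bp) > cfg$cluster_tolerance))
    for (g in split(seq_len(nrow(e)), grp)) {
      if (length(g) < cfg$min_support) next
      bps <- e$bp[g]
      tab <- sort(table(bps), decreasing = TRUE)
      modal <- as.integer(names(tab)[tab == tab[1L]])
      out[[length(out) + 1L]] <- data.frame(
        side = sd, breakpoint = min(modal), read_count = length(g),
        clip_consensus = .clip_consensus(e$seq[g], sd),
        mean_clip_length = mean(e$len[g]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$breakpoint, res$side), , drop = FALSE]
}

## Re-anchor a junction consensus on the reference by exact seed matching
## and chunk walking. `cons` starts at the junction (insert first, then the
## second copy); `p2` is the junction's reference position. Returns the
## 5'-most consistent duplication start p1, the non-templated insert, and
## internal deletions observed within the walked region.
.reconstruct_consensus <- function(cons, p2, gm, cfg) {
  k <- cfg$seed_length
  win_s <- max(0L, p2 - cfg$search_window)
  win <- substr(gm$sequence, win_s + 1L, p2)
  fail <- list(ok = FALSE, reason = "no-seed")
  if (nchar(cons) < k + 1L) return(fail)
  p1 <- NA_integer_; ins_len <- NA_integer_
  for (j in 0:min(cfg$max_insert_prefix, nchar(cons) - k)) {
    seed <- substr(cons, j + 1L, j + k)
    hit <- regexpr(seed, win, fixed = TRUE)
    if (hit > 0L) {
      p1 <- win_s + as.integer(hit) - 1L
      ins_len <- j
      break
    }
  }
  if (is.na(p1)) return(fail)
  if (p1 >= p2) return(list(ok = FALSE, reason = "no-duplication"))
  ## walk the remaining consensus in seed-sized chunks, bridging deletions
  dels <- list()
  cumdel <- 0L
  c_at <- ins_len + k
  repeat {
    if (c_at + k > nchar(cons)) break
    chunk <- substr(cons, c_at + 1L, c_at + k)
    e <- p1 + (c_at - ins_len) + cumdel
    ref_chunk <- substr(gm$sequence, e + 1L, e + k)
    if (chunk == ref_chunk) { c_at <- c_at + k; next }
    ## leading agreement, then look for the rest downstream (deletion)
    m <- 0L
    while (m < k && substr(chunk, m + 1L, m + 1L) ==
             substr(gm$sequence, e + m + 1L, e + m + 1L)) m <- m + 1L
    rest <- substr(chunk, m + 1L, k)
    zone <- substr(gm$sequence, e + m + 1L,
                   min(gm$sequence_length, e + m + cfg$max_deletion + k))
    hit <- regexpr(rest, zone, fixed = TRUE)
    if (hit <= 1L) break   # mismatch noise or unbridgeable: stop the walk
    d <- as.integer(hit) - 1L
    dels[[length(dels) + 1L]] <- c(e + m, e + m + d)
    cumdel <- cumdel + d
    c_at <- c_at + k
  }
  list(ok = TRUE, p1 = p1, insert = substr(cons, 1L, ins_len),
       deletions = dels, walked = c_at,
       complete = c_at + k > nchar(cons))
}

## Candidate junctions from CIGAR insertion operations: reads whose whole
## inserted block fits inside the read. Returns one candidate per insertion
## site with the modal inserted sequence.
.insertion_candidates <- function(aln, cfg, ctx = NULL) {
  if (is.null(ctx)) ctx <- .aln_features(aln)
  ops <- ctx$ops
  has_i <- vapply(ops, function(o) any(o$op == "I" &
                                         o$len >= cfg$min_insertion_op),
                  logical(1L))
  idx <- which(has_i)
  if (length(idx) == 0L) {
    return(data.frame(junction = integer(0), ins_seq = character(0),
                      read_count = integer(0), stringsAsFactors = FALSE))
  }
  recs <- lapply(idx, function(i) {
    o <- ops[[i]]
    qoff <- 0L; roff <- aln$pos[i] - 1L
    out <- NULL
    for (t in seq_along(o$op)) {
      if (o$op[t] == "I" && o$len[t] >= cfg$min_insertion_op) {
        out <- rbind(out, data.frame(
          junction = roff,
          ins_seq = substr(aln$seq[i], qoff + 1L, qoff + o$len[t]),
          stringsAsFactors = FALSE))
      }
      if (o$op[t] %in% c("M", "I", "S", "=", "X")) qoff <- qoff + o$len[t]
      if (o$op[t] %in% c("M", "D", "N", "=", "X")) roff <- roff + o$len[t]
    }
    out
  })
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$junction), , drop = FALSE]
  grp <- cumsum(c(1L, diff(recs$junction) > cfg$cluster_tolerance))
  out <- lapply(split(seq_len(nrow(recs)), grp), function(g) {
    tab <- sort(table(recs$ins_seq[g]), decreasing = TRUE)
    modal_seq <- names(tab)[1L]
    jt <- recs$junction[g][recs$ins_seq[g] == modal_seq]
    data.frame(junction = min(as.integer(names(sort(table(jt),
                                                    decreasing = TRUE))[1L])),
               ins_seq = modal_seq, read_count = length(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.empty_calls <- function() {
  data.frame(dup_start = integer(0), dup_end = integer(0), span = integer(0),
             insert = character(0), n_deletions = integer(0),
             deleted_length = integer(0), total_inserted_length = integer(0),
             status = character(0), partial_evidence = logical(0),
             support_junction_reads = integer(0),
             spanning_ref_reads = integer(0), vaf_breakpoint = numeric(0),
             vaf_coverage = numeric(0), depth_dup = numeric(0),
             depth_flank = numeric(0), vaf = numeric(0),
             vaf_method = character(0), suspicion_flag = logical(0),
             cds_start = integer(0), cds_end = integer(0),
             contains_core = logical(0), stringsAsFactors = FALSE)
}

#' Reconstruct tandem duplications from junction evidence
#'
#' Right-clip clusters and CIGAR-insertion groups are re-anchored on the
#' reference: a right clip at `p2` whose consensus re-aligns from `p1 < p2`
#' implies the duplicated interval `[p1, p2)`; the unanchored consensus
#' prefix is the non-templated insert and walk gaps are internal deletions.
#' Matching left-clip evidence at `p1` is required for a fully supported
#' call; calls lacking it are flagged `partial_evidence`. Consensus
#' sequences re-anchoring outside the search window (or downstream) are
#' reported with status `"no-duplication"`.
#'
#' @param clusters Output of [cluster_softclips()].
#' @param aln Alignment `data.frame` (for CIGAR-insertion candidates).
#' @param gm A [gene_model()].
#' @param cfg A [caller_config()].
#' @param ctx Optional precomputed alignment features (internal reuse).
#' @return Call `data.frame` (one row per candidate TD), without VAF fields.
#' @export
reconstruct_td <- function(clusters, aln, gm, cfg = caller_config(),
                           ctx = NULL) {
  cands <- list()
  rights <- clusters[clusters$side == "right", , drop = FALSE]
  lefts <- clusters[clusters$side == "left", , drop = FALSE]
  for (i in seq_len(nrow(rights))) {
    cands[[length(cands) + 1L]] <- list(
      p2 = rights$breakpoint[i], cons = rights$clip_consensus[i],
      n = rights$read_count[i], known_total = NA_integer_, from = "clip")
  }
  ins <- .insertion_candidates(aln, cfg, ctx)
  for (i in seq_len(nrow(ins))) {
    if (ins$read_count[i] < cfg$min_support &&
        !any(abs(rights$breakpoint - ins$junction[i]) <=
               cfg$cluster_tolerance)) next
    cands[[length(cands) + 1L]] <- list(
      p2 = ins$junction[i], cons = ins$ins_seq[i],
      n = ins$read_count[i], known_total = nchar(ins$ins_seq[i]),
      from = "cigar-I")
  }
  calls <- list()
  for (cd in cands) {
    rec <- .reconstruct_consensus(cd$cons, cd$p2, gm, cfg)
    if (!isTRUE(rec$ok)) {
      if (identical(rec$reason, "no-duplication")) {
        calls[[length(calls) + 1L]] <- data.frame(
          dup_start = NA_integer_, dup_end = cd$p2, span = NA_integer_,
          insert = "", n_deletions = 0L, deleted_length = 0L,
          total_inserted_length = NA_integer_, status = "no-duplication",
          partial_evidence = TRUE, stringsAsFactors = FALSE)
      }
      next
    }
    p1 <- rec$p1; p2 <- cd$p2
    del_len <- sum(vapply(rec$deletions, function(d) d[2L] - d[1L],
                          integer(1L)))
    total <- if (!is.na(cd$known_total)) cd$known_total
             else (p2 - p1) + nchar(rec$insert) - del_len
    paired <- any(abs(lefts$breakpoint - p1) <= cfg$cluster_tolerance) ||
      identical(cd$from, "cigar-I")
    calls[[length(calls) + 1L]] <- data.frame(
      dup_start = p1, dup_end = p2, span = p2 - p1,
      insert = rec$insert, n_deletions = length(rec$deletions),
      deleted_length = as.integer(del_len),
      total_inserted_length = as.integer(total),
      status = "TD", partial_evidence = !paired,
      stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) {
    out <- .empty_calls()
    return(out[, 1:9, drop = FALSE])
  }
  out <- do.call(rbind, calls)
  ## merge duplicate candidates (clip- and insertion-derived) per interval
  key <- paste(round(out$dup_start / (cfg$cluster_tolerance + 1L)),
               round(out$dup_end / (cfg$cluster_tolerance + 1L)))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate TD variant allele fraction from reads
#'
#' Two estimators per call. The junction estimator counts
#' junction-supporting reads (soft clips at either breakpoint, CIGAR
#' insertions) against junction-free reads spanning the duplication 3'
#' breakpoint; because the mutant allele's second copy also produces
#' spanning reference-like reads, the denominator is corrected by the
#' expected mutant spanning contribution given the reconstructed TD length
#' (see the methods vignette). The coverage estimator is the mean-depth
#' excess of the (junction-trimmed) duplicated interval over its flanks.
#' The reported VAF uses the junction estimate when support is sufficient
#' and the coverage estimate otherwise.
#'
#' @param call One row of the [reconstruct_td()] output.
#' @param aln Alignment `data.frame`.
#' @param gm A [gene_model()].
#' @param cfg A [caller_config()].
#' @param ctx Optional precomputed alignment features (internal reuse).
#' @return The call row with support counts, both VAF estimates, depths,
#'   the reported `vaf` and `vaf_method`.
#' @export
estimate_vaf <- function(call, aln, gm, cfg = caller_config(), ctx = NULL) {
  stopifnot(nrow(call) == 1L)
  if (is.null(ctx)) ctx <- .aln_features(aln)
  ft <- ctx$ft
  p1 <- call$dup_start; p2 <- call$dup_end
  theta <- cfg$min_span_anchor
  R <- max(nchar(aln$seq))
  sup_right <- ft$clip_right >= cfg$min_clip_length &
    abs(ft$end0 - p2) <= cfg$cluster_tolerance
  sup_left <- ft$clip_left >= cfg$min_clip_length &
    abs(ft$pos0 - p1) <= cfg$cluster_tolerance
  has_i <- vapply(ctx$ops, function(o) any(o$op == "I" &
                                             o$len >= cfg$min_insertion_op),
                  logical(1L))
  ## insertion reads support the junction when the I op sits at p2
  sup_i <- has_i & ft$pos0 <= p2 - 1L & ft$end0 >= p2 + 1L
  support <- sum(sup_right | sup_left | sup_i)
  clean <- ft$clip_left < cfg$min_clip_length &
    ft$clip_right < cfg$min_clip_length & !has_i
  spanning <- sum(clean & ft$pos0 <= p2 - theta & ft$end0 >= p2 + theta)
  L <- call$total_inserted_length
  i_len <- nchar(call$insert)
  w_j <- R - 2L * theta + 1L
  w_m <- max(0L, min(L - i_len - theta, R - 2L * theta) + 1L)
  denom <- spanning + support * (1 - w_m / w_j)
  vaf_bp <- if (support + spanning == 0L) NA_real_
            else min(1.05, support / denom)
  ## coverage estimator on the junction-trimmed interval
  span <- p2 - p1
  trim <- min(R %/% 2L, span %/% 4L)
  idepth <- function(a, b) {
    if (b <= a) return(0)
    ov <- pmax(0L, pmin(ft$end0, b) - pmax(ft$pos0, a))
    sum(ov) / (b - a)
  }
  d_dup <- idepth(p1 + trim, p2 - trim)
  fw <- min(span, 300L)
  d_fl <- (idepth(max(0L, p1 - 20L - fw), max(0L, p1 - 20L)) +
             idepth(p2 + 20L, min(gm$sequence_length, p2 + 20L + fw))) / 2
  vaf_cov <- if (d_fl == 0) NA_real_
             else min(1.05, max(0, d_dup / d_fl - 1))
  call$support_junction_reads <- support
  call$spanning_ref_reads <- spanning
  call$vaf_breakpoint <- vaf_bp
  call$vaf_coverage <- vaf_cov
  call$depth_dup <- d_dup
  call$depth_flank <- d_fl
  use_bp <- support >= cfg$min_support && !is.na(vaf_bp)
  call$vaf <- if (use_bp) vaf_bp else vaf_cov
  call$vaf_method <- if (use_bp) "junction" else "coverage"
  call
}

#' Call tandem duplications from aligned reads
#'
#' Full caller: suspicion pre-scan, soft-clip clustering, breakpoint
#' reconstruction, VAF estimation, CDS projection and core annotation.
#' Calls below `min_vaf_report` are suppressed. No call is emitted for a
#' sample without a mismatch/clip suspicion signal.
#'
#' @param aln Alignment `data.frame` (from [simulate_reads()] or
#'   [read_sam()]).
#' @param gm A [gene_model()].
#' @param cfg A [caller_config()].
#' @return Call `data.frame`, one row per TD call.
#' @export
call_tds <- function(aln, gm, cfg = caller_config()) {
  ctx <- if (nrow(aln) > 0L) .aln_features(aln) else NULL
  susp <- suspicion_scan(aln, gm, ctx = ctx)
  if (!isTRUE(as.logical(susp))) return(.empty_calls())
  clusters <- cluster_softclips(aln, cfg, ctx = ctx)
  calls <- reconstruct_td(clusters, aln, gm, cfg, ctx = ctx)
  calls <- calls[calls$status == "TD", , drop = FALSE]
  if (nrow(calls) == 0L) return(.empty_calls())
  out <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    estimate_vaf(calls[i, , drop = FALSE], aln, gm, cfg, ctx = ctx)
  }))
  out$suspicion_flag <- TRUE
  ## CDS projection of the duplicated interval (exonic portion)
  ex <- gm$exons
  proj <- t(vapply(seq_len(nrow(out)), function(i) {
    g <- seq.int(out$dup_start[i], out$dup_end[i] - 1L)
    g <- g[g >= min(ex$start) & g < max(ex$end)]
    cds <- genomic_to_cds(gm, g)
    cds <- cds[!is.na(cds)]
    if (length(cds) == 0L) c(NA_integer_, NA_integer_)
    else c(min(cds), max(cds))
  }, integer(2L)))
  out$cds_start <- proj[, 1L]
  out$cds_end <- proj[, 2L]
  core <- td_core_cds()
  out$contains_core <- !is.na(out$cds_start) & out$cds_start <= core[1L] &
    out$cds_end >= core[2L]
  out <- out[!is.na(out$vaf) & out$vaf >= cfg$min_vaf_report, , drop = FALSE]
  out <- out[order(-out$support_junction_reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}
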