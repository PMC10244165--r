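#' Expected mutant fragment size for the screening amplicon
#'
#' The exon-12 to exon-14 PCR amplicon grows by the TD's total inserted
#' length, e.g. the 617-bp wild-type amplicon becomes 665 bp for a 48-bp
#' tandem duplication.
#'
#' @param wt_amplicon Wild-type amplicon size in bp.
#' @param td A [td_spec()] or a plain total inserted length in bp.
#' @return Expected mutant fragment size in bp.
#' @export
expected_mutant_size <- function(wt_amplicon, td) {
  if (wt_amplicon <= 0) stop("spec error: wild-type amplicon must be > 0")
  L <- if (inherits(td, "td_spec")) td$total_inserted_length else td
  if (L < 0) stop("spec error: negative total inserted length")
  wt_amplicon + L
}

#' Simulate a capillary-electrophoresis fragment trace
#'
#' Gaussian-shaped peaks at the wild-type size and (when a TD allele is
#' present) at `wt_size + total_inserted_length`, with heights proportional
#' to `1 - f` and `f`, optional +/-1 bp stutter satellites, and additive
#' baseline noise.
#'
#' @param wt_size Wild-type amplicon size (bp).
#' @param td A [td_spec()], a plain TD size in bp, or `NULL` for a
#'   wild-type-only trace.
#' @param allele_fraction Mutant allele fraction; taken from `td` when it is
#'   a [td_spec()].
#' @param peak_sd Peak standard deviation in bp.
#' @param stutter Relative height of +/-1 bp stutter satellites.
#' @param noise Baseline noise amplitude relative to the main peak.
#' @param seed Integer seed for the baseline noise.
#' @return A `data.frame` of class `fragment_trace` with columns `size`
#'   (bp, strictly increasing) and `height`.
#' @export
simulate_trace <- function(wt_size = 617, td = NULL, allele_fraction = NULL,
                           peak_sd = 0.6, stutter = 0.08, noise = 0.01,
                           seed = 1L) {
  if (wt_size <= 0) stop("spec error: wt_size must be > 0")
  L <- if (is.null(td)) 0L
       else if (inherits(td, "td_spec")) td$total_inserted_length
       else as.integer(td)
  f <- if (!is.null(allele_fraction)) allele_fraction
       else if (inherits(td, "td_spec")) td$allele_fraction
       else if (L > 0L) 0.5 else 0
  sizes <- seq(max(1, wt_size - 60), wt_size + max(L, 0) + 60, by = 0.5)
  peak <- function(mu, h) h * exp(-((sizes - mu)^2) / (2 * peak_sd^2))
  height <- peak(wt_size, 1 - f)
  if (L > 0L) height <- height + peak(wt_size + L, f)
  if (stutter > 0) {
    height <- height + peak(wt_size - 1, stutter * (1 - f)) +
      peak(wt_size + 1, stutter * (1 - f))
    if (L > 0L) {
      height <- height + peak(wt_size + L - 1, stutter * f) +
        peak(wt_size + L + 1, stutter * f)
    }
  }
  height <- height + with_seed(seed, stats::runif(length(sizes), 0, noise))
  structure(data.frame(size = sizes, height = height),
            class = c("fragment_trace", "data.frame"))
}

#' Call peaks in a fragment trace and classify alleles
#'
#' Local maxima above `min_height_fraction` of the trace maximum are called
#' as peaks. The peak nearest `wt_size` (within +/- 2 bp) is the wild-type
#' allele; peaks 1 bp either side of a taller peak with less than 15% of its
#' height are stutter; remaining peaks above the wild-type size are mutant
#' alleles with TD size estimate `round(size - wt_size)`. Mutant peaks
#' beyond the upper limit of the sizing standard are flagged. A trace with
#' no wild-type peak is flagged `no_wt` (possible homozygous mutant or
#' failed reaction) rather than raising an error.
#'
#' @param trace A trace `data.frame` with `size` and `height` columns.
#' @param min_height_fraction Minimum peak height relative to the maximum.
#' @param wt_size Expected wild-type amplicon size (bp).
#' @param size_standard_max Upper sizing limit of the ladder (bp).
#' @return `data.frame` of peak calls (`size`, `height`, `classification`,
#'   `td_size`, `flag`), with attribute `no_wt`.
#' @export
call_peaks <- function(trace, min_height_fraction = 0.05, wt_size = 617,
                       size_standard_max = 1200) {
  stopifnot(is.data.frame(trace), nrow(trace) > 0L,
            all(c("size", "height") %in% names(trace)))
  if (any(diff(trace$size) <= 0)) stop("trace sizes must be increasing")
  h <- trace$height
  n <- length(h)
  thr <- min_height_fraction * max(h)
  empty <- data.frame(size = numeric(0), height = numeric(0),
                      classification = character(0), td_size = integer(0),
                      flag = character(0), stringsAsFactors = FALSE)
  if (max(h) <= 0) return(structure(empty, no_wt = TRUE))
  ## strict local maxima above threshold
  is_max <- c(FALSE, h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n],
              FALSE) & h > thr
  idx <- which(is_max)
  ## collapse maxima closer than 1 bp to the tallest
  if (length(idx) > 1L) {
    keep <- logical(length(idx))
    o <- idx[order(-h[idx])]
    taken <- numeric(0)
    for (i in o) {
      if (!any(abs(trace$size[i] - taken) < 1)) taken <- c(taken, trace$size[i])
    }
    idx <- sort(idx[trace$size[idx] %in% taken])
  }
  if (length(idx) == 0L) return(structure(empty, no_wt = TRUE))
  peaks <- data.frame(size = trace$size[idx], height = h[idx],
                      classification = "noise", td_size = NA_integer_,
                      flag = "", stringsAsFactors = FALSE)
  ## wild-type: nearest peak within +/- 2 bp
  d_wt <- abs(peaks$size - wt_size)
  wt_i <- which(d_wt <= 2)
  no_wt <- length(wt_i) == 0L
  if (!no_wt) {
    wt_i <- wt_i[which.max(peaks$height[wt_i])]
    peaks$classification[wt_i] <- "wild-type"
  }
  ## stutter: +/- 1 bp satellites below 15% of their neighbour
  for (i in seq_len(nrow(peaks))) {
    if (!is.na(match(i, wt_i))) next
    nb <- which(abs(peaks$size - peaks$size[i]) >= 0.5 &
                  abs(peaks$size - peaks$size[i]) <= 1.5)
    if (length(nb) && peaks$height[i] < 0.15 * max(peaks$height[nb])) {
      peaks$classification[i] <- "stutter"
    }
  }
  ## mutant: remaining peaks above the wild-type size
  mut <- peaks$classification == "noise" & peaks$size > wt_size + 2
  peaks$classification[mut] <- "mutant"
  peaks$td_size[mut] <- as.integer(round(peaks$size[mut] - wt_size))
  peaks$flag[mut & peaks$size > size_standard_max] <-
    "beyond size-standard range"
  out <- peaks[peaks$classification != "noise", , drop = FALSE]
  rownames(out) <- NULL
  structure(out, no_wt = no_wt)
}
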