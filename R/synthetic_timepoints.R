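#' Build a clone architecture by hand
#'
#' An architecture is the planted truth for the clonal-evolution module:
#' a clone tree with inclusive CCFs (fraction of tumor cells in the clone
#' or any descendant) at diagnosis and relapse, and the variants arising in
#' each clone. Children must be contained in their parents and sibling
#' CCFs may not exceed their parent's at either timepoint.
#'
#' @param clones `data.frame` with `clone`, `parent` (0 = founding),
#'   `ccf_dx`, `ccf_rel`.
#' @param variants `data.frame` with `variant_id`, `gene`, `clone`,
#'   `cn_dx`, `cn_rel` (copy-number state per timepoint; see [ccf()]), and
#'   optional `total_copies`/`mutated_copies` for `"custom"` states.
#' @return List of class `clone_architecture`.
#' @export
clone_architecture <- function(clones, variants) {
  stopifnot(all(c("clone", "parent", "ccf_dx", "ccf_rel") %in% names(clones)),
            all(c("variant_id", "gene", "clone", "cn_dx", "cn_rel") %in%
                  names(variants)))
  for (i in seq_len(nrow(clones))) {
    p <- clones$parent[i]
    if (p == 0L) next
    k <- which(clones$clone == p)
    if (length(k) != 1L) stop("architecture error: unknown parent clone")
    if (clones$ccf_dx[i] > clones$ccf_dx[k] + 1e-9 ||
        clones$ccf_rel[i] > clones$ccf_rel[k] + 1e-9) {
      stop("architecture error: child clone exceeds its parent's CCF")
    }
  }
  for (p in unique(clones$parent)) {
    ch <- clones$parent == p
    cap_dx <- if (p == 0L) 1 else clones$ccf_dx[clones$clone == p]
    cap_rel <- if (p == 0L) 1 else clones$ccf_rel[clones$clone == p]
    if (sum(clones$ccf_dx[ch]) > cap_dx + 1e-9 ||
        sum(clones$ccf_rel[ch]) > cap_rel + 1e-9) {
      stop("architecture error: sibling CCFs exceed their parent's")
    }
  }
  if (!all(variants$clone %in% clones$clone)) {
    stop("architecture error: variant assigned to unknown clone")
  }
  structure(list(clones = clones, variants = variants),
            class = "clone_architecture")
}

#' Simulate paired diagnosis/relapse variant tables from an architecture
#'
#' Each variant's true VAF at a timepoint is its clone's inclusive CCF
#' times mutated/total copies for its copy-number state; observed VAFs add
#' binomial sampling noise at the given depth.
#'
#' @param arch A [clone_architecture()].
#' @param depth Sequencing depth per variant and timepoint.
#' @param seed Integer seed.
#' @return Variant `data.frame` ready for [build_clone_tree()], with the
#'   noise-free truth in `attr(, "truth")`.
#' @export
simulate_paired_timepoints <- function(arch, depth = 500L, seed = 1L) {
  stopifnot(inherits(arch, "clone_architecture"))
  with_seed(seed, {
    v <- arch$variants
    n <- nrow(v)
    out <- data.frame(variant_id = v$variant_id, gene = v$gene,
                      cn_dx = v$cn_dx, cn_rel = v$cn_rel,
                      total_copies = if ("total_copies" %in% names(v))
                        v$total_copies else NA,
                      mutated_copies = if ("mutated_copies" %in% names(v))
                        v$mutated_copies else NA,
                      depth_dx = as.integer(depth),
                      depth_rel = as.integer(depth),
                      stringsAsFactors = FALSE)
    truth <- out
    for (t in c("dx", "rel")) {
      cc <- arch$clones[[paste0("ccf_", t)]][match(v$clone,
                                                   arch$clones$clone)]
      cn <- v[[paste0("cn_", t)]]
      frac <- ifelse(cn == "diploid-het", 0.5,
              ifelse(cn == "UPD-hom", 1,
              ifelse(cn == "mut-plus-del", 1,
                     out$mutated_copies / out$total_copies)))
      p <- pmin(1, cc * frac)
      truth[[paste0("vaf_", t)]] <- p
      truth[[paste0("ccf_", t)]] <- cc
      out[[paste0("vaf_", t)]] <- stats::rbinom(n, depth, p) / depth
    }
    truth$clone <- v$clone
    structure(out, truth = truth)
  })
}

## Gene pool for non-founding clones of planted architectures.
.subclone_genes <- c("WT1", "FLT3_ITD", "NRAS", "KRAS", "PTPN11", "NF1",
                     "RIT1", "IDH1", "TET2")

#' Plant a random clone architecture
#'
#' Random trees of 2-5 clones used for parameter-recovery experiments. The
#' founding clone carries the UBTF-TD at high CCF at both timepoints;
#' subclones attach at random and receive 1-2 variants each. Clone CCF
#' vectors are rejection-sampled so that every pair of clones differs by at
#' least `separation` at one timepoint (bulk-VAF clustering is only
#' identifiable for separated clones) while respecting nesting and sibling
#' constraints.
#'
#' @param n_clones Number of clones (2-5).
#' @param seed Integer seed.
#' @param separation Minimum pairwise CCF separation at >= 1 timepoint.
#' @return A [clone_architecture()].
#' @export
plant_architecture <- function(n_clones = 3L, seed = 1L, separation = 0.3) {
  stopifnot(n_clones >= 2L, n_clones <= 5L)
  with_seed(seed, {
    ## ancestor test on a parent vector
    is_anc <- function(parent, a, b) {
      p <- b
      while (p != 0L) { p <- parent[p]; if (p == a) return(TRUE) }
      FALSE
    }
    sepn <- separation
    for (attempt in 1:5000) {
      if (attempt %% 1000L == 0L) sepn <- max(0.2, sepn - 0.05)
      ## bias toward chains; branchy trees need CCF dominance swaps to be
      ## identifiable from two bulk timepoints
      parent <- c(0L, vapply(2:n_clones, function(k) {
        if (stats::runif(1L) < 0.6) k - 1L else sample.int(k - 1L, 1L)
      }, integer(1L)))
      ccf_dx <- numeric(n_clones); ccf_rel <- numeric(n_clones)
      ccf_dx[1L] <- stats::runif(1L, 0.85, 1)
      ccf_rel[1L] <- stats::runif(1L, 0.85, 1)
      ok <- TRUE
      for (k in 2:n_clones) {
        p <- parent[k]
        sib <- which(parent[seq_len(k - 1L)] == p)
        room_dx <- ccf_dx[p] - sum(ccf_dx[sib]) - 0.05
        room_rel <- ccf_rel[p] - sum(ccf_rel[sib]) - 0.05
        if (room_dx < 0.05 && room_rel < 0.05) { ok <- FALSE; break }
        ## allow loss (rel ~ 0) and gain (dx ~ 0) scenarios
        ccf_dx[k] <- stats::runif(1L, 0, max(0, room_dx))
        ccf_rel[k] <- stats::runif(1L, 0, max(0, room_rel))
        if (stats::runif(1L) < 0.2) ccf_dx[k] <- 0
        if (stats::runif(1L) < 0.2) ccf_rel[k] <- 0
        if (ccf_dx[k] < 0.02 && ccf_rel[k] < 0.02) { ok <- FALSE; break }
      }
      if (!ok) next
      ## identifiability: pairwise separation, and any clone that is not an
      ## ancestor of another must be clearly smaller at some timepoint
      ## (otherwise the smallest-container nesting rule has no unique answer)
      sep_ok <- TRUE
      for (i in seq_len(n_clones)) for (j in seq_len(n_clones)) {
        if (i == j) next
        if (j > i && abs(ccf_dx[i] - ccf_dx[j]) < sepn &&
            abs(ccf_rel[i] - ccf_rel[j]) < sepn) sep_ok <- FALSE
        if (!is_anc(parent, i, j) &&
            !(ccf_dx[i] <= ccf_dx[j] - 0.2 ||
                ccf_rel[i] <= ccf_rel[j] - 0.2)) sep_ok <- FALSE
      }
      if (!sep_ok) next
      clones <- data.frame(clone = seq_len(n_clones), parent = parent,
                           ccf_dx = ccf_dx, ccf_rel = ccf_rel)
      n_var <- c(1L, sample(1:2, n_clones - 1L, replace = TRUE))
      genes <- c("UBTF_TD",
                 sample(.subclone_genes, sum(n_var) - 1L, replace = FALSE))
      variants <- data.frame(
        variant_id = sprintf("v%02d", seq_len(sum(n_var))),
        gene = genes,
        clone = rep(seq_len(n_clones), n_var),
        cn_dx = "diploid-het", cn_rel = "diploid-het",
        stringsAsFactors = FALSE)
      return(clone_architecture(clones, variants))
    }
    stop("architecture error: could not satisfy separation constraints")
  })
}

#' Compare a recovered clone tree with its planted architecture
#'
#' A replicate counts as an exact topology recovery when variants of each
#' planted clone land in one recovered clone, distinct planted clones stay
#' distinct, and every recovered parent link maps to the planted one.
#' Clones undetectable at both timepoints (CCF < threshold) are ignored.
#'
#' @param arch The planted [clone_architecture()].
#' @param tree The [build_clone_tree()] result.
#' @param threshold Detectability threshold on planted CCF.
#' @return List: `exact` (logical), `prevalence_mae` (mean absolute error
#'   of recovered clone CCFs vs truth, over detectable clones and
#'   timepoints).
#' @export
compare_clone_tree <- function(arch, tree, threshold = 0.02) {
  truth_v <- arch$variants
  det <- arch$clones$ccf_dx >= threshold | arch$clones$ccf_rel >= threshold
  det_clones <- arch$clones$clone[det]
  tv <- truth_v[truth_v$clone %in% det_clones, , drop = FALSE]
  rec <- tree$assignment$clone[match(tv$variant_id,
                                     tree$assignment$variant_id)]
  ## planted clone -> recovered clone must be a bijection
  map <- tapply(rec, tv$clone, function(x) if (length(unique(x)) == 1L)
    x[1L] else NA_integer_)
  exact <- !anyNA(map) && !anyDuplicated(map)
  if (exact) {
    ## parent links must correspond
    for (cl in names(map)) {
      tp <- arch$clones$parent[arch$clones$clone == as.integer(cl)]
      rp <- tree$clones$parent[map[[cl]]]
      tp_mapped <- if (tp %in% names(map) || as.character(tp) %in% names(map))
        map[[as.character(tp)]] else 0L
      if (!(tp == 0L && rp == 0L) && !identical(rp, tp_mapped)) {
        exact <- FALSE
      }
    }
  }
  err <- c()
  for (cl in names(map)) {
    if (is.na(map[[cl]])) next
    ti <- which(arch$clones$clone == as.integer(cl))
    err <- c(err,
             abs(tree$clones$ccf_dx[map[[cl]]] - arch$clones$ccf_dx[ti]),
             abs(tree$clones$ccf_rel[map[[cl]]] - arch$clones$ccf_rel[ti]))
  }
  list(exact = exact, prevalence_mae = mean(err))
}
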