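#' Cancer-cell fraction from VAF and copy-number state
#'
#' CCF = VAF x total copies / mutated copies: x2 for a diploid heterozygous
#' variant, x1 for a copy-neutral homozygous (UPD) variant, x1 for a
#' mutation with loss of the other allele (CN 1). Values above 1 are capped
#' with the overflow recorded.
#'
#' @param vaf Variant allele fraction(s) in `[0, 1]`.
#' @param cn_state One of `"diploid-het"`, `"UPD-hom"`, `"mut-plus-del"`,
#'   `"custom"` (recycled).
#' @param total_copies,mutated_copies Copy numbers used when
#'   `cn_state == "custom"`.
#' @return Numeric CCF(s) capped at 1; attribute `overflow` flags capped
#'   values.
#' @export
ccf <- function(vaf, cn_state = "diploid-het", total_copies = NA,
                mutated_copies = NA) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  n <- max(length(vaf), length(cn_state))
  vaf <- rep_len(vaf, n); cn_state <- rep_len(cn_state, n)
  total_copies <- rep_len(total_copies, n)
  mutated_copies <- rep_len(mutated_copies, n)
  tc <- ifelse(cn_state == "diploid-het", 2,
        ifelse(cn_state == "UPD-hom", 2,
        ifelse(cn_state == "mut-plus-del", 1, total_copies)))
  mc <- ifelse(cn_state == "diploid-het", 1,
        ifelse(cn_state == "UPD-hom", 2,
        ifelse(cn_state == "mut-plus-del", 1, mutated_copies)))
  if (any(is.na(mc)) || any(mc == 0)) {
    stop("state error: mutated_copies must be a positive count")
  }
  if (any(mc > tc)) stop("state error: mutated_copies > total_copies")
  raw <- vaf * tc / mc
  structure(pmin(1, raw), overflow = raw > 1)
}

## Per-timepoint CCFs and their binomial standard errors for a variant table.
.variant_ccfs <- function(variants) {
  for (t in c("dx", "rel")) {
    v <- variants[[paste0("vaf_", t)]]
    cn <- variants[[paste0("cn_", t)]]
    cc <- ccf(v, cn, variants$total_copies, variants$mutated_copies)
    variants[[paste0("ccf_", t)]] <- as.numeric(cc)
    dep <- variants[[paste0("depth_", t)]]
    fac <- ifelse(cn == "diploid-het", 2, ifelse(cn == "UPD-hom", 1,
                  ifelse(cn == "mut-plus-del", 1,
                         variants$total_copies / variants$mutated_copies)))
    variants[[paste0("se_", t)]] <- fac * sqrt(pmax(v * (1 - v), 0.25 / dep) / dep)
  }
  variants
}

#' Infer a clone tree from paired-timepoint variants
#'
#' Variants are clustered into clones by CCF proximity at both timepoints
#' (merge threshold `max(merge_floor, 3 x pooled SE)`), then nested
#' greedily in descending CCF order under pigeonhole constraints: a clone
#' nests inside the smallest already-placed clone whose CCF contains it
#' (within `tol`) at both timepoints; when sibling CCFs would exceed their
#' parent's, the new clone is forced into the largest sibling's lineage
#' (the variants must co-occur in one lineage). Founding ties prefer
#' UBTF-TD-class variants, then diagnosis CCF, then variant id.
#'
#' @param variants `data.frame` with columns `variant_id`, `gene`,
#'   `vaf_dx`, `vaf_rel`, `depth_dx`, `depth_rel`, `cn_dx`, `cn_rel` (and
#'   `total_copies`/`mutated_copies` for `"custom"` states).
#' @param tol Pigeonhole tolerance on CCF inequalities.
#' @param merge_floor Minimum CCF distance treated as clone-splitting.
#' @return List of class `clone_tree`: `clones` (id, parent, `ccf_dx`,
#'   `ccf_rel`, member variants), `assignment` (variant to clone),
#'   `resolved` flag and `violations`.
#' @export
build_clone_tree <- function(variants, tol = 0.1, merge_floor = 0.1) {
  stopifnot(nrow(variants) >= 1L)
  v <- .variant_ccfs(variants)
  pref <- grepl("UBTF", v$gene)
  o <- order(-(v$ccf_dx + v$ccf_rel), -pref, -v$ccf_dx, v$variant_id)
  v <- v[o, , drop = FALSE]
  ## sequential clustering into clones
  cl_members <- list()
  for (i in seq_len(nrow(v))) {
    placed <- FALSE
    best <- NA_integer_; best_d <- Inf
    for (k in seq_along(cl_members)) {
      m <- cl_members[[k]]
      mu_dx <- mean(v$ccf_dx[m]); mu_rel <- mean(v$ccf_rel[m])
      se_dx <- sqrt(mean(v$se_dx[m])^2 / length(m) + v$se_dx[i]^2)
      se_rel <- sqrt(mean(v$se_rel[m])^2 / length(m) + v$se_rel[i]^2)
      d_dx <- abs(v$ccf_dx[i] - mu_dx); d_rel <- abs(v$ccf_rel[i] - mu_rel)
      if (d_dx <= max(merge_floor, 3 * se_dx) &&
          d_rel <= max(merge_floor, 3 * se_rel)) {
        d <- max(d_dx, d_rel)
        if (d < best_d) { best <- k; best_d <- d }
      }
    }
    if (!is.na(best)) {
      cl_members[[best]] <- c(cl_members[[best]], i)
      placed <- TRUE
    }
    if (!placed) cl_members[[length(cl_members) + 1L]] <- i
  }
  n_cl <- length(cl_members)
  ccf_dx <- vapply(cl_members, function(m) mean(v$ccf_dx[m]), numeric(1L))
  ccf_rel <- vapply(cl_members, function(m) mean(v$ccf_rel[m]), numeric(1L))
  ## nesting, in descending CCF order (clusters are already near-sorted)
  ord <- order(-(ccf_dx + ccf_rel))
  parent <- rep(NA_integer_, n_cl)
  placed <- integer(0L)
  violations <- character(0L)
  contains <- function(p, c) {
    ccf_dx[p] >= ccf_dx[c] - tol && ccf_rel[p] >= ccf_rel[c] - tol
  }
  sib_ok <- function(p, c) {
    ch <- which(parent == p)
    sum(ccf_dx[c(ch, c)]) <= ccf_dx[p] + tol &&
      sum(ccf_rel[c(ch, c)]) <= ccf_rel[p] + tol
  }
  for (c_i in ord) {
    if (length(placed) == 0L) {
      parent[c_i] <- 0L; placed <- c(placed, c_i); next
    }
    cand <- placed[vapply(placed, contains, logical(1L), c = c_i)]
    if (length(cand) == 0L) {
      violations <- c(violations, sprintf(
        "clone %d (CCF %.2f/%.2f) fits under no placed clone",
        c_i, ccf_dx[c_i], ccf_rel[c_i]))
      parent[c_i] <- 0L; placed <- c(placed, c_i); next
    }
    cand <- cand[order(ccf_dx[cand] + ccf_rel[cand])]
    done <- FALSE
    for (p_i in cand) {
      cur <- p_i
      repeat {
        if (sib_ok(cur, c_i)) {
          parent[c_i] <- cur; done <- TRUE; break
        }
        ## pigeonhole: descend into the largest sibling's lineage
        ch <- which(parent == cur)
        big <- ch[which.max(ccf_dx[ch] + ccf_rel[ch])]
        if (length(big) == 0L || !contains(big, c_i)) break
        cur <- big
      }
      if (done) break
    }
    if (!done) {
      violations <- c(violations, sprintf(
        "clone %d (CCF %.2f/%.2f) violates sibling pigeonhole everywhere",
        c_i, ccf_dx[c_i], ccf_rel[c_i]))
      parent[c_i] <- cand[length(cand)]
    }
    placed <- c(placed, c_i)
  }
  clones <- data.frame(
    clone = seq_len(n_cl), parent = parent,
    ccf_dx = ccf_dx, ccf_rel = ccf_rel,
    variants = vapply(cl_members, function(m)
      paste(v$variant_id[m], collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  amap <- integer(nrow(v))
  for (k in seq_len(n_cl)) amap[cl_members[[k]]] <- k
  assignment <- data.frame(variant_id = v$variant_id, clone = amap,
                           stringsAsFactors = FALSE)
  structure(list(clones = clones, assignment = assignment,
                 variants = v, resolved = length(violations) == 0L,
                 violations = violations),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d clones%s\n", nrow(x$clones),
              if (x$resolved) "" else " (UNRESOLVED)"))
  print(x$clones, row.names = FALSE)
  if (!x$resolved) cat(paste0("  ! ", x$violations, collapse = "\n"), "\n")
  invisible(x)
}

## TRUE when clone a is an ancestor of clone b (or equal) in the tree.
.in_lineage <- function(tree, a, b) {
  if (a == b) return(TRUE)
  p <- b
  while (p != 0L) {
    p <- tree$clones$parent[p]
    if (identical(p, a)) return(TRUE)
  }
  FALSE
}

#' Classify WT1 allelic status at each timepoint
#'
#' Biallelic (`bi_alt`) when two WT1 mutations share one lineage (same
#' clone or ancestor-descendant), or a WT1 mutation is copy-neutral
#' homozygous (UPD), or co-occurs with deletion of the other allele;
#' `mono_alt` for a single heterozygous alteration at or above the
#' detection threshold; `none` otherwise.
#'
#' @param variants Variant table (see [build_clone_tree()]).
#' @param tree A [build_clone_tree()] result.
#' @param threshold Detection threshold on VAF (default 1%).
#' @return Named character vector with elements `dx` and `rel`.
#' @export
classify_wt1 <- function(variants, tree, threshold = 0.01) {
  out <- c(dx = "none", rel = "none")
  v <- tree$variants
  a <- tree$assignment
  for (t in c("dx", "rel")) {
    vaf <- v[[paste0("vaf_", t)]]
    cn <- v[[paste0("cn_", t)]]
    w <- which(v$gene == "WT1" & vaf >= threshold)
    if (length(w) == 0L) next
    bi <- any(cn[w] %in% c("UPD-hom", "mut-plus-del"))
    if (!bi && length(w) >= 2L) {
      for (i in w) for (j in w) {
        if (i < j) {
          ci <- a$clone[i]; cj <- a$clone[j]
          if (.in_lineage(tree, ci, cj) || .in_lineage(tree, cj, ci)) {
            bi <- TRUE
          }
        }
      }
    }
    out[t] <- if (bi) "bi_alt" else "mono_alt"
  }
  out
}

#' Classify the relapse pattern of a paired case
#'
#' * `bi_alt_preexisting`: the relapse-driving biallelic WT1 configuration
#'   is already detectable (>= 1% VAF) at diagnosis.
#' * `bi_alt_from_mono`: only its monoallelic component is detectable at
#'   diagnosis.
#' * `bi_alt_emergent`: neither component is detectable at diagnosis.
#' * `mono_on_flt3`: relapse is WT1-monoallelic, newly arising inside a
#'   persistent FLT3-ITD clone.
#' * `other`: anything else.
#'
#' @inheritParams classify_wt1
#' @return Single character label.
#' @export
classify_relapse_pattern <- function(variants, tree, threshold = 0.01) {
  cls <- classify_wt1(variants, tree, threshold)
  v <- tree$variants
  a <- tree$assignment
  w_rel <- which(v$gene == "WT1" & v$vaf_rel >= threshold)
  if (cls["rel"] == "bi_alt") {
    ## components of the relapse bi_alt configuration
    upd <- w_rel[v$cn_rel[w_rel] %in% c("UPD-hom", "mut-plus-del")]
    if (length(upd)) {
      i <- upd[1L]
      bi_at_dx <- v$vaf_dx[i] >= threshold &&
        v$cn_dx[i] %in% c("UPD-hom", "mut-plus-del")
      mono_at_dx <- v$vaf_dx[i] >= threshold && !bi_at_dx
      if (bi_at_dx) return("bi_alt_preexisting")
      if (mono_at_dx) return("bi_alt_from_mono")
      return("bi_alt_emergent")
    }
    ## two-mutant configuration: find a lineage pair
    pair <- NULL
    for (i in w_rel) for (j in w_rel) {
      if (i < j) {
        ci <- a$clone[i]; cj <- a$clone[j]
        if (.in_lineage(tree, ci, cj) || .in_lineage(tree, cj, ci)) {
          pair <- c(i, j)
        }
      }
    }
    if (!is.null(pair)) {
      det <- v$vaf_dx[pair] >= threshold
      if (all(det)) return("bi_alt_preexisting")
      if (any(det)) return("bi_alt_from_mono")
      return("bi_alt_emergent")
    }
    return("other")
  }
  if (cls["rel"] == "mono_alt") {
    flt3 <- which(grepl("FLT3", v$gene) & v$vaf_dx >= threshold &
                    v$vaf_rel >= threshold)
    gained_wt1 <- w_rel[v$vaf_dx[w_rel] < threshold]
    for (i in gained_wt1) for (f in flt3) {
      if (.in_lineage(tree, a$clone[f], a$clone[i])) return("mono_on_flt3")
    }
  }
  "other"
}

#' Per-variant evolution status between timepoints
#'
#' @param variants Variant table with `vaf_dx` and `vaf_rel`.
#' @param threshold Detection threshold (default 1% VAF).
#' @return The table with a `status` column: `gained`, `lost`,
#'   `persistent`, or `absent`.
#' @export
evolution_report <- function(variants, threshold = 0.01) {
  dx <- variants$vaf_dx >= threshold
  rel <- variants$vaf_rel >= threshold
  variants$status <- ifelse(dx & rel, "persistent",
                     ifelse(dx & !rel, "lost",
                     ifelse(!dx & rel, "gained", "absent")))
  variants
}

#' Fishplot-ready prevalence matrix
#'
#' Inclusive clone prevalences (percent) per timepoint plus the parent
#' vector, with children clamped into their parents so the nesting
#' constraints of fishplot-style drawing hold exactly.
#'
#' @param tree A [build_clone_tree()] result.
#' @return List with `frac` (clones x timepoints matrix, percent) and
#'   `parents` (0 = founding clone).
#' @export
fishplot_matrix <- function(tree) {
  cl <- tree$clones
  frac <- 100 * cbind(dx = cl$ccf_dx, rel = cl$ccf_rel)
  ## clamp sibling sums into the parent, top-down
  for (p in unique(cl$parent[cl$parent != 0L])) {
    ch <- which(cl$parent == p)
    for (t in 1:2) {
      cap <- frac[p, t]
      tot <- sum(frac[ch, t])
      if (tot > cap && tot > 0) frac[ch, t] <- frac[ch, t] * cap / tot
    }
  }
  rownames(frac) <- cl$variants
  list(frac = frac, parents = cl$parent)
}
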