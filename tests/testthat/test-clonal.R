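make_variants <- function(ids, genes, vaf_dx, vaf_rel,
                          cn_dx = "diploid-het", cn_rel = "diploid-het",
                          depth = 500L) {
  data.frame(variant_id = ids, gene = genes, vaf_dx = vaf_dx,
             vaf_rel = vaf_rel, depth_dx = depth, depth_rel = depth,
             cn_dx = cn_dx, cn_rel = cn_rel, total_copies = NA,
             mutated_copies = NA, stringsAsFactors = FALSE)
}

test_that("CCF applies the copy-number correction factors", {
  expect_equal(as.numeric(ccf(0.45)), 0.9, tolerance = 1e-12)
  expect_equal(as.numeric(ccf(0.80, "UPD-hom")), 0.8, tolerance = 1e-12)
  expect_equal(as.numeric(ccf(0.45, "mut-plus-del")), 0.45,
               tolerance = 1e-12)
  expect_equal(as.numeric(ccf(0.30, "custom", total_copies = 3,
                              mutated_copies = 1)), 0.9, tolerance = 1e-12)
  ## linear in VAF, capped at 1 with overflow recorded
  v <- c(0.1, 0.2, 0.4)
  expect_equal(as.numeric(ccf(v)), 2 * v, tolerance = 1e-12)
  over <- ccf(0.7)
  expect_identical(as.numeric(over), 1)
  expect_true(attr(over, "overflow"))
  expect_error(ccf(0.4, "custom", total_copies = 2, mutated_copies = 0),
               "state error")
  ## cross-check the UPD factor with a binomial sampling oracle
  set.seed(19)
  draws <- rbinom(20000, 2, 0.8) / 2  # allele count in a UPD-hom clone
  expect_lt(abs(mean(draws) - 0.8), 0.01)
})

test_that("clone trees nest subclonal variants inside the founder", {
  v <- make_variants(c("u", "w"), c("UBTF_TD", "WT1"),
                     c(0.45, 0.25), c(0.45, 0.45))
  tr <- build_clone_tree(v)
  expect_identical(nrow(tr$clones), 2L)
  expect_identical(tr$clones$parent, c(0L, 1L))
  expect_true(grepl("u", tr$clones$variants[1]))
  ## single variant: one clone, prevalence = CCF
  t1 <- build_clone_tree(v[1, ])
  expect_identical(nrow(t1$clones), 1L)
  expect_equal(t1$clones$ccf_dx, 0.9, tolerance = 1e-9)
})

test_that("pigeonhole arithmetic forces co-occurring WT1 pairs into one clone", {
  v <- make_variants(c("u", "w1", "w2"), c("UBTF_TD", "WT1", "WT1"),
                     c(0.46, 0.44, 0.43), c(0.46, 0.44, 0.43))
  tr <- build_clone_tree(v)
  expect_identical(nrow(tr$clones), 1L)
  cls <- classify_wt1(v, tr)
  expect_identical(unname(cls), c("bi_alt", "bi_alt"))
})

test_that("WT1 allelic classification covers all three biallelic routes", {
  ## (a) two mutants in one lineage
  v_pair <- make_variants(c("u", "w1", "w2"), c("UBTF_TD", "WT1", "WT1"),
                          c(0.45, 0.30, 0.005), c(0.45, 0.45, 0.43))
  cls <- classify_wt1(v_pair, build_clone_tree(v_pair))
  expect_identical(unname(cls), c("mono_alt", "bi_alt"))
  ## (b) UPD homozygosity
  v_upd <- make_variants(c("u", "w"), c("UBTF_TD", "WT1"),
                         c(0.45, 0.20), c(0.45, 0.80),
                         cn_dx = c("diploid-het", "diploid-het"),
                         cn_rel = c("diploid-het", "UPD-hom"))
  cls2 <- classify_wt1(v_upd, build_clone_tree(v_upd))
  expect_identical(unname(cls2), c("mono_alt", "bi_alt"))
  ## (c) mutation plus deletion of the other allele
  v_del <- make_variants(c("u", "w"), c("UBTF_TD", "WT1"),
                         c(0.45, 0.40), c(0.45, 0.42),
                         cn_dx = c("diploid-het", "mut-plus-del"),
                         cn_rel = c("diploid-het", "mut-plus-del"))
  cls3 <- classify_wt1(v_del, build_clone_tree(v_del))
  expect_identical(unname(cls3), c("bi_alt", "bi_alt"))
  ## two mutants in disjoint branches are not biallelic
  v_sib <- make_variants(c("u", "w1", "w2"), c("UBTF_TD", "WT1", "WT1"),
                         c(0.48, 0.30, 0.02), c(0.48, 0.02, 0.35))
  cls4 <- classify_wt1(v_sib, build_clone_tree(v_sib))
  expect_identical(unname(cls4), c("mono_alt", "mono_alt"))
})

test_that("relapse patterns label the E / F / A / G archetypes", {
  ## E-like: biallelic (UPD) configuration already present at low level
  v_e <- make_variants(c("u", "w"), c("UBTF_TD", "WT1"),
                       c(0.45, 0.03), c(0.45, 0.80),
                       cn_dx = c("diploid-het", "UPD-hom"),
                       cn_rel = c("diploid-het", "UPD-hom"))
  expect_identical(classify_relapse_pattern(v_e, build_clone_tree(v_e)),
                   "bi_alt_preexisting")
  ## J-like: both mutants of the pair detectable at diagnosis
  v_j <- make_variants(c("u", "w1", "w2"), c("UBTF_TD", "WT1", "WT1"),
                       c(0.46, 0.03, 0.02), c(0.46, 0.44, 0.43))
  expect_identical(classify_relapse_pattern(v_j, build_clone_tree(v_j)),
                   "bi_alt_preexisting")
  ## F-like: second hit lands on a pre-existing monoallelic clone
  v_f <- make_variants(c("u", "w1", "w2"), c("UBTF_TD", "WT1", "WT1"),
                       c(0.45, 0.30, 0), c(0.46, 0.45, 0.43))
  expect_identical(classify_relapse_pattern(v_f, build_clone_tree(v_f)),
                   "bi_alt_from_mono")
  ## G-like: biallelic clone fully emergent at relapse
  v_g <- make_variants(c("u", "w1", "w2"), c("UBTF_TD", "WT1", "WT1"),
                       c(0.45, 0, 0), c(0.46, 0.41, 0.40))
  expect_identical(classify_relapse_pattern(v_g, build_clone_tree(v_g)),
                   "bi_alt_emergent")
  ## A-like: monoallelic WT1 gained inside a persistent FLT3-ITD clone
  v_a <- make_variants(c("u", "f", "w"), c("UBTF_TD", "FLT3_ITD", "WT1"),
                       c(0.45, 0.30, 0), c(0.45, 0.40, 0.25))
  expect_identical(classify_relapse_pattern(v_a, build_clone_tree(v_a)),
                   "mono_on_flt3")
})

test_that("variant gain/loss status tracks the 1% threshold", {
  v <- make_variants(c("a", "b", "c", "d"), c("FLT3_ITD", "WT1", "NRAS", "KRAS"),
                     c(0.30, 0.25, 0.005, 0.002), c(0.005, 0.30, 0.22, 0.001))
  r <- evolution_report(v)
  expect_identical(r$status, c("lost", "persistent", "gained", "absent"))
})

test_that("planted architectures are recovered from noisy bulk VAFs", {
  res <- vapply(1:20, function(s) {
    arch <- plant_architecture(n_clones = 2L + (s %% 4L), seed = s)
    sim <- simulate_paired_timepoints(arch, depth = 500L, seed = s + 900L)
    cmp <- compare_clone_tree(arch, build_clone_tree(sim))
    c(cmp$exact, cmp$prevalence_mae)
  }, numeric(2L))
  expect_gte(mean(res[1, ]), 0.9)
  expect_lte(mean(res[2, ]), 0.05)
})

test_that("pigeonhole consistency holds on every accepted tree", {
  for (s in 1:10) {
    arch <- plant_architecture(n_clones = 2L + (s %% 4L), seed = 100L + s)
    sim <- simulate_paired_timepoints(arch, depth = 500L, seed = 200L + s)
    tr <- build_clone_tree(sim)
    for (p in unique(tr$clones$parent[tr$clones$parent != 0L])) {
      ch <- tr$clones$parent == p
      expect_lte(sum(tr$clones$ccf_dx[ch]), tr$clones$ccf_dx[p] + 0.1)
      expect_lte(sum(tr$clones$ccf_rel[ch]), tr$clones$ccf_rel[p] + 0.1)
    }
  }
})

test_that("fishplot matrices respect nesting constraints exactly", {
  arch <- plant_architecture(n_clones = 4L, seed = 3L)
  sim <- simulate_paired_timepoints(arch, depth = 500L, seed = 4L)
  tr <- build_clone_tree(sim)
  fm <- fishplot_matrix(tr)
  for (i in seq_along(fm$parents)) {
    p <- fm$parents[i]
    if (p != 0L) expect_true(all(fm$frac[i, ] <= fm$frac[p, ] + 1e-9))
  }
  expect_identical(sum(fm$parents == 0L), 1L)
})

test_that("architecture validation rejects inconsistent inputs", {
  clones <- data.frame(clone = 1:2, parent = c(0L, 1L),
                       ccf_dx = c(0.5, 0.9), ccf_rel = c(0.9, 0.5))
  vars <- data.frame(variant_id = "v1", gene = "WT1", clone = 1L,
                     cn_dx = "diploid-het", cn_rel = "diploid-het")
  expect_error(clone_architecture(clones, vars), "architecture error")
  clones2 <- data.frame(clone = 1:3, parent = c(0L, 1L, 1L),
                        ccf_dx = c(0.8, 0.5, 0.5), ccf_rel = c(0.8, 0.3, 0.3))
  expect_error(clone_architecture(clones2, vars), "architecture error")
})

test_that("paired-timepoint simulation matches its planted truth", {
  arch <- plant_architecture(n_clones = 3L, seed = 12L)
  sim <- simulate_paired_timepoints(arch, depth = 5000L, seed = 13L)
  truth <- attr(sim, "truth")
  expect_lt(max(abs(sim$vaf_dx - truth$vaf_dx)), 0.05)
  expect_lt(max(abs(sim$vaf_rel - truth$vaf_rel)), 0.05)
  ## deterministic under seed
  sim2 <- simulate_paired_timepoints(arch, depth = 5000L, seed = 13L)
  expect_identical(sim, sim2)
})
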