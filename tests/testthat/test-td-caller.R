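test_that("suspicion scan flags TD samples and clears wild-type", {
  sim_wt <- simulate_reads(fixture_gm, list(list(td = NULL, fraction = 1)),
                           read_sim_config(depth = 300, seed = 1L))
  expect_false(as.logical(suspicion_scan(sim_wt$alignments, fixture_gm)))
  sim48 <- sim_td_sample(canonical_48(0.45), depth = 300, seed = 2L)
  expect_true(as.logical(suspicion_scan(sim48$alignments, fixture_gm)))
  sim598 <- sim_td_sample(large_598(0.45), depth = 300, seed = 3L)
  expect_true(as.logical(suspicion_scan(sim598$alignments, fixture_gm)))
  expect_error(suspicion_scan(sim48$alignments, fixture_gm,
                              window = c(100L, 100L)), "config error")
})

test_that("soft-clip clustering finds the two junction clusters", {
  sim <- sim_td_sample(large_598(0.45), depth = 400, seed = 4L)
  cl <- cluster_softclips(sim$alignments)
  expect_identical(sort(unique(cl$side)), c("left", "right"))
  r <- cl[cl$side == "right", ]
  l <- cl[cl$side == "left", ]
  expect_identical(r$breakpoint, 1328L)  # duplication 3' end
  expect_identical(l$breakpoint, 730L)   # duplication 5' start
  expect_gte(min(cl$read_count), 3L)
  ## wild-type sample gives no clusters
  sim_wt <- simulate_reads(fixture_gm, list(list(td = NULL, fraction = 1)),
                           read_sim_config(depth = 300, seed = 5L))
  expect_identical(nrow(cluster_softclips(sim_wt$alignments)), 0L)
})

test_that("caller recovers size and structure over a seeded mini-cohort", {
  ## recall and exact-size bar on TDs below ~read scale, f >= 0.2, 300x
  co <- sample_cohort(cohort_spec(n_patients = 200L, seed = 61L),
                      fixture_gm)
  specs <- attr(co, "td_specs")
  sizes <- co$total_inserted_length
  keep <- which(sizes >= 39L & sizes <= 120L)[1:40]
  hit <- 0L; exact <- 0L
  for (i in keep) {
    td <- specs[[i]]
    td$allele_fraction <- max(0.2, td$allele_fraction)
    sim <- sim_td_sample(td, depth = 300, seed = 7000L + i)
    calls <- call_tds(sim$alignments, fixture_gm)
    if (nrow(calls) >= 1L) {
      hit <- hit + 1L
      if (any(calls$total_inserted_length == td$total_inserted_length)) {
        exact <- exact + 1L
      }
    }
  }
  expect_gte(hit / length(keep), 0.98)
  expect_gte(exact / length(keep), 0.98)
})

test_that("composite duplication structure is reconstructed", {
  td <- td_spec(985L, 1036L, insert = "ACG",
                deletions = list(c(1012L, 1018L)), allele_fraction = 0.4)
  sim <- sim_td_sample(td, depth = 500, seed = 17L)
  calls <- call_tds(sim$alignments, fixture_gm)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$dup_start, 985L)
  expect_identical(calls$dup_end, 1036L)
  expect_identical(calls$insert, "ACG")
  expect_identical(calls$deleted_length, 6L)
  expect_identical(calls$total_inserted_length, 48L)
})

test_that("a TD larger than the read length is called from clip pairs", {
  td <- large_598(0.45)
  sim <- sim_td_sample(td, depth = 500, seed = 19L)
  calls <- call_tds(sim$alignments, fixture_gm)
  expect_identical(nrow(calls), 1L)
  expect_lte(abs(calls$total_inserted_length - 598L), 5L)
  expect_false(calls$partial_evidence)
  ## coverage excess is visible and close to the junction estimate
  expect_gt(calls$depth_dup / calls$depth_flank, 1.2)
})

test_that("two co-occurring TDs resolve into two calls", {
  td_a <- canonical_48(0.3)
  td_b <- td_spec(988L, 1048L, allele_fraction = 0.25)  # 60-bp, shifted
  sim <- simulate_reads(
    fixture_gm,
    list(list(td = NULL, fraction = 0.45),
         list(td = td_a, fraction = 0.3),
         list(td = td_b, fraction = 0.25)),
    read_sim_config(depth = 600, seed = 23L))
  cl <- cluster_softclips(sim$alignments)
  expect_gte(nrow(cl), 3L)
  calls <- call_tds(sim$alignments, fixture_gm)
  expect_identical(nrow(calls), 2L)
  expect_setequal(calls$total_inserted_length, c(48L, 60L))
})

test_that("VAF estimators track the planted allele fraction", {
  for (f in c(0.2, 0.45, 0.8)) {
    err_bp <- c()
    for (r in 1:5) {
      sim <- sim_td_sample(canonical_48(f), depth = 1000,
                           seed = 1000L * r + round(100 * f))
      calls <- call_tds(sim$alignments, fixture_gm)
      expect_identical(nrow(calls), 1L)
      err_bp <- c(err_bp, abs(calls$vaf_breakpoint - f))
    }
    expect_lte(mean(err_bp), 0.03)
  }
})

test_that("junction and coverage VAF agree for large TDs at high depth", {
  sim <- sim_td_sample(large_598(0.45), depth = 1200, seed = 29L)
  calls <- call_tds(sim$alignments, fixture_gm)
  expect_lt(abs(calls$vaf_breakpoint - calls$vaf_coverage), 0.08)
})

test_that("homozygous TDs report VAF near 1 by both estimators", {
  td <- large_598(1)
  sim <- simulate_reads(fixture_gm, list(list(td = td, fraction = 1)),
                        read_sim_config(depth = 500, seed = 31L))
  calls <- call_tds(sim$alignments, fixture_gm)
  expect_gt(calls$vaf_breakpoint, 0.9)
  expect_gt(calls$vaf_coverage, 0.9)
})

test_that("no false calls on wild-type simulations", {
  for (r in 1:25) {
    sim <- simulate_reads(fixture_gm, list(list(td = NULL, fraction = 1)),
                          read_sim_config(depth = 300, seed = 5000L + r))
    expect_identical(nrow(call_tds(sim$alignments, fixture_gm)), 0L)
  }
})

test_that("every emitted call implies the suspicion flag", {
  sim <- sim_td_sample(canonical_48(0.45), depth = 300, seed = 37L)
  calls <- call_tds(sim$alignments, fixture_gm)
  expect_true(all(calls$suspicion_flag))
})
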