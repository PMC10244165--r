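test_that("cohort sampling reproduces the configured distributions", {
  co <- sample_cohort(cohort_spec(n_patients = 5000L, seed = 42L),
                      fixture_gm)
  expect_identical(nrow(co), 5000L)
  ## recurrent-size share ~ 34/59
  expect_lt(abs(mean(co$size_class %in% c("48", "51", "54")) - 34 / 59),
            0.02)
  ## deletion frequency stratified at 100 bp
  big <- co$total_inserted_length > 100
  small <- !big & co$size_class != "non_core"
  expect_lt(abs(mean(co$n_deletions[big] > 0) - 0.64), 0.03)
  expect_lt(abs(mean(co$n_deletions[small] > 0) - 0.13), 0.03)
  ## VAF distribution centred on 0.45
  expect_lt(abs(median(co$vaf) - 0.45), 0.01)
  ## sizes span the configured range (large tails may gain up to 12 bp
  ## from the frame-phasing nudge)
  expect_gte(min(co$total_inserted_length), 39L)
  expect_lte(max(co$total_inserted_length), 962L)
  ## co-mutation rates
  expect_lt(abs(mean(grepl("WT1", co$co_mutations)) - 0.63), 0.03)
})

test_that("degenerate size weights give a constant cohort", {
  sp <- cohort_spec(n_patients = 10L, modal_weights = c("48" = 1),
                    p_tail = 0, p_non_core = 0, seed = 1L)
  co <- sample_cohort(sp, fixture_gm)
  expect_true(all(co$total_inserted_length == 48L))
  expect_error(cohort_spec(n_patients = 0L), "config error")
  expect_error(cohort_spec(p_tail = 0.9), "sum to 1")
})

test_that("cohort sampling is deterministic under a fixed seed", {
  a <- sample_cohort(cohort_spec(n_patients = 100L, seed = 9L), fixture_gm)
  b <- sample_cohort(cohort_spec(n_patients = 100L, seed = 9L), fixture_gm)
  expect_identical(a, b)
})

test_that("every sampled TD is in frame after splice projection", {
  co <- sample_cohort(cohort_spec(n_patients = 300L, seed = 21L),
                      fixture_gm)
  ann <- do.call(rbind, lapply(attr(co, "td_specs"), splice_aware_frame,
                               gm = fixture_gm))
  expect_true(all(ann$in_frame))
})

test_that("mutate_locus applies duplication, insert and deletions", {
  gm <- fixture_gm
  td <- canonical_48()
  mut <- mutate_locus(gm, td)
  expect_identical(nchar(mut$sequence), gm$sequence_length + 48L)
  ## mutant amplicon is wild-type + TD size
  amp_mut <- gm$reverse_primer_pos + 48L - gm$forward_primer_pos
  expect_identical(amp_mut, 665L)
  ## empty duplication leaves the sequence unchanged
  td0 <- td_spec(985L, 985L)
  expect_identical(mutate_locus(gm, td0)$sequence, gm$sequence)
  ## 51-bp duplication + 3-nt insert - 6-nt deletion = +48 bp
  td2 <- td_spec(985L, 1036L, insert = "ACG",
                 deletions = list(c(1012L, 1018L)))
  expect_identical(td2$total_inserted_length, 48L)
  expect_identical(nchar(mutate_locus(gm, td2)$sequence),
                   gm$sequence_length + 48L)
  expect_error(td_spec(985L, 1033L, deletions = list(c(900L, 906L))),
               "spec error")
})

test_that("read simulation shows the expected junction signatures", {
  sim <- sim_td_sample(canonical_48(0.45), depth = 300, seed = 3L)
  reps <- table(sim$truth$representation[sim$truth$haplotype == 2])
  ## small TD: junction reads appear as CIGAR insertions and soft clips
  expect_gt(reps[["I"]], 0)
  expect_gt(sum(reps[c("SL", "SR")]), 0)
  ## wild-type haplotype never clips
  expect_true(all(sim$truth$representation[sim$truth$haplotype == 1] == "M"))
  ## large TD: no read contains the full insertion
  sim598 <- sim_td_sample(large_598(0.45), depth = 200, seed = 4L)
  expect_false(any(sim598$truth$representation == "I"))
  expect_gt(sum(sim598$truth$representation %in% c("SL", "SR")), 0)
})

test_that("wild-type-only simulations contain no clipped reads", {
  sim <- simulate_reads(fixture_gm, list(list(td = NULL, fraction = 1)),
                        read_sim_config(depth = 150, seed = 8L))
  cl <- ubtftd:::cigar_clips(sim$alignments$cigar)
  expect_identical(sum(cl), 0L)
})

test_that("read simulation is byte-deterministic under a fixed seed", {
  a <- sim_td_sample(canonical_48(), depth = 100, seed = 5L)
  b <- sim_td_sample(canonical_48(), depth = 100, seed = 5L)
  expect_identical(a, b)
})

test_that("duplicated-interval depth ratio converges to 1 + allele fraction", {
  ## large TD so clipped junction bases are a negligible share of the
  ## interval; checked at depth 2000x
  td <- large_598(0.45)
  sim <- sim_td_sample(td, depth = 2000, seed = 11L)
  aln <- sim$alignments
  trim <- 75L
  d_dup <- ubtftd:::interval_depth(aln, 730L + trim, 1328L - trim)
  d_fl <- (ubtftd:::interval_depth(aln, 430L, 730L) +
             ubtftd:::interval_depth(aln, 1328L, 1628L)) / 2
  expect_lt(abs(d_dup / d_fl - 1 - 0.45), 0.03)
})

test_that("fragment fractions are honoured at the junction", {
  ## junction-crossing read share among breakpoint-crossing reads tracks f
  td <- large_598(0.45)
  sim <- sim_td_sample(td, depth = 800, seed = 13L)
  tr <- sim$truth
  expect_lt(abs(mean(tr$haplotype == 2) -
                  0.45 * 2650 / (0.55 * 2052 + 0.45 * 2650)), 0.03)
})

test_that("simulated traces put peaks at the configured sizes", {
  tr <- simulate_trace(617, canonical_48(0.45), seed = 2L)
  pk <- call_peaks(tr)
  expect_setequal(pk$classification[pk$height > 0.3],
                  c("wild-type", "mutant"))
  expect_identical(pk$td_size[pk$classification == "mutant"], 48L)
  tr0 <- simulate_trace(617, NULL)
  pk0 <- call_peaks(tr0)
  expect_identical(pk0$classification[which.max(pk0$height)], "wild-type")
})
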