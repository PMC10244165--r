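test_that("splice-aware frame annotation covers the three TD geometries", {
  ## 48-bp wholly exonic: spliced length 48, in frame, leucine-rich
  a1 <- splice_aware_frame(canonical_48(), fixture_gm)
  expect_identical(a1$spliced_inserted_length, 48L)
  expect_true(a1$in_frame)
  expect_true(a1$contains_core)
  expect_true(a1$leucine_rich)
  expect_true(grepl("ELLTRLA", a1$peptide))
  ## 598-bp intron-spanning: 306 exonic bases, in-frame exon13-exon13
  a2 <- splice_aware_frame(large_598(), fixture_gm)
  expect_identical(a2$spliced_inserted_length, 306L)
  expect_true(a2$in_frame)
  expect_true(a2$exon13_fusion)
  expect_identical(a2$exon_span, "exon12,exon13,exon14")
  ## 47-bp exonic TD is out of frame (never observed in the cohort)
  a3 <- splice_aware_frame(td_spec(985L, 985L + 47L), fixture_gm)
  expect_false(a3$in_frame)
  ## a breakpoint inside a splice dinucleotide is flagged, frame undefined
  a4 <- splice_aware_frame(td_spec(820L, 990L), fixture_gm)
  expect_true(a4$splice_disrupting)
  expect_true(is.na(a4$in_frame))
})

test_that("intronic junction inserts do not count toward frame", {
  ## 54-bp class: crosses the intron-12/exon-13 boundary, 36 exonic bases
  td <- td_spec(952L, 1006L)
  a <- splice_aware_frame(td, fixture_gm)
  expect_identical(a$spliced_inserted_length, 36L)
  expect_true(a$in_frame)
  expect_true(a$contains_core)
})

test_that("minimal duplicated region is the interval intersection", {
  calls <- data.frame(cds_start = c(1300L, 1306L, 1290L),
                      cds_end = c(1350L, 1339L, 1326L),
                      contains_core = TRUE)
  mr <- minimal_duplicated_region(calls)
  expect_identical(as.integer(mr), c(1306L, 1326L))
  ## order-invariant and idempotent
  mr2 <- minimal_duplicated_region(calls[c(3, 1, 2), ])
  expect_identical(as.integer(mr2), as.integer(mr))
  one <- minimal_duplicated_region(calls[1, , drop = FALSE])
  expect_identical(as.integer(one), c(1300L, 1350L))
  ## non-core calls are excluded and listed
  calls$contains_core[2] <- FALSE
  mr3 <- minimal_duplicated_region(calls)
  expect_identical(as.integer(mr3), c(1300L, 1326L))
  expect_identical(attr(mr3, "excluded_non_core"), 2L)
  ## disjoint intervals: NA with diagnostics
  dj <- data.frame(cds_start = c(1200L, 1320L), cds_end = c(1210L, 1340L),
                   contains_core = TRUE)
  mrd <- minimal_duplicated_region(dj)
  expect_true(all(is.na(mrd)))
  expect_s3_class(attr(mrd, "diagnostics"), "data.frame")
})

test_that("cohort summary reproduces the printed share arithmetic", {
  ## printed counts: 18 + 10 + 6 of 59 = 58%
  sizes <- c(rep(48L, 18), rep(51L, 10), rep(54L, 6), rep(39L, 10),
             rep(90L, 5), rep(598L, 9), 42L)
  calls <- data.frame(total_inserted_length = sizes,
                      n_deletions = c(rep(1L, 15), rep(0L, 44)),
                      cds_start = 1300L, cds_end = 1340L,
                      contains_core = c(rep(TRUE, 58), FALSE))
  s <- summarize_cohort(calls)
  expect_identical(s$n, 59L)
  expect_identical(round(100 * s$fraction_sizes_48_51_54), 58)
  expect_equal(s$fraction_with_deletion, 15 / 59, tolerance = 1e-12)
  expect_identical(as.integer(s$minimal_region), c(1300L, 1340L))
})

test_that("caller output feeds the annotator end to end", {
  sim <- sim_td_sample(canonical_48(0.45), depth = 300, seed = 41L)
  calls <- call_tds(sim$alignments, fixture_gm)
  a <- splice_aware_frame(calls[1, ], fixture_gm)
  expect_true(a$in_frame)
  expect_true(a$contains_core)
  expect_identical(calls$cds_start, 1306L)
  expect_identical(calls$cds_end, 1353L)
})
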