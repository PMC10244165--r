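#' Pipeline configuration
#'
#' Single place holding every tunable of the end-to-end run. Unknown keys
#' are rejected by name.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Root seed; each stage derives its own substream from it.
#' @param n_patients Cohort size.
#' @param call_patients Number of patients taken through read simulation and
#'   TD calling (the most expensive stage).
#' @param depth Read-simulation depth for the calling stage.
#' @param read_length Read length (bp).
#' @param wt_size Wild-type amplicon size (bp).
#' @param n_clonal_cases Number of planted paired-timepoint cases.
#' @param clonal_depth Depth for paired-timepoint VAF sampling.
#' @param ... Must be empty; any unknown key raises a validation error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "ubtftd_run", seed = 1L,
                            n_patients = 20L, call_patients = 6L,
                            depth = 150, read_length = 150L,
                            wt_size = 617, n_clonal_cases = 3L,
                            clonal_depth = 500L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("config error: unknown key(s): ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(n_patients >= 1L, call_patients >= 0L, depth > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 call_patients = as.integer(min(call_patients, n_patients)),
                 depth = depth, read_length = as.integer(read_length),
                 wt_size = wt_size,
                 n_clonal_cases = as.integer(n_clonal_cases),
                 clonal_depth = as.integer(clonal_depth)),
            class = "pipeline_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes cohort simulation, fragment-trace screening, read-level TD
#' calling, annotation/cohort summary, clonal-evolution inference on
#' planted paired-timepoint cases, and co-mutation contingency statistics.
#' Every stage writes TSV/JSON outputs under `cfg$out_dir` and is recorded
#' in `manifest.json`; reruns with the same seed are byte-identical. A
#' stage failure is recorded in the manifest and downstream stages are
#' skipped.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- ubtf_fixture_model()
  manifest <- list(
    package = "ubtftd",
    version = tryCatch(as.character(utils::packageVersion("ubtftd")),
                       error = function(e) "dev"),
    seed = cfg$seed,
    parameters = unclass(cfg),
    stages = list())
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }
  env <- new.env()

  run_stage("cohort", function() {
    spec <- cohort_spec(n_patients = cfg$n_patients, seed = cfg$seed)
    env$cohort <- sample_cohort(spec, gm)
    f <- .write_tsv(env$cohort, file.path(cfg$out_dir, "cohort_truth.tsv"))
    list(outputs = basename(f), n = nrow(env$cohort))
  })

  run_stage("screen", function() {
    specs <- attr(env$cohort, "td_specs")
    rows <- lapply(seq_along(specs), function(i) {
      tr <- simulate_trace(cfg$wt_size, specs[[i]],
                           seed = cfg$seed + 100L + i)
      pk <- call_peaks(tr, wt_size = cfg$wt_size)
      mut <- pk[pk$classification == "mutant", , drop = FALSE]
      data.frame(patient_id = env$cohort$patient_id[i],
                 screen_positive = nrow(mut) > 0L,
                 td_size_estimate = if (nrow(mut)) mut$td_size[1L]
                                    else NA_integer_,
                 flag = if (nrow(mut)) mut$flag[1L] else "",
                 stringsAsFactors = FALSE)
    })
    env$screen <- do.call(rbind, rows)
    f <- .write_tsv(env$screen, file.path(cfg$out_dir, "screen.tsv"))
    list(outputs = basename(f),
         n_positive = sum(env$screen$screen_positive))
  })

  run_stage("call", function() {
    specs <- attr(env$cohort, "td_specs")
    idx <- seq_len(cfg$call_patients)
    calls <- lapply(idx, function(i) {
      td <- specs[[i]]
      sim <- simulate_reads(
        gm, list(list(td = NULL, fraction = 1 - td$allele_fraction),
                 list(td = td, fraction = td$allele_fraction)),
        read_sim_config(read_length = cfg$read_length, depth = cfg$depth,
                        seed = cfg$seed + 200L + i))
      cl <- call_tds(sim$alignments, gm)
      if (nrow(cl)) cl$patient_id <- env$cohort$patient_id[i]
      cl
    })
    env$calls <- do.call(rbind, calls[vapply(calls, nrow, 1L) > 0L])
    f1 <- .write_tsv(env$calls, file.path(cfg$out_dir, "td_calls.tsv"))
    f2 <- write_td_vcf(env$calls, gm,
                       file.path(cfg$out_dir, "td_calls.vcf"))
    list(outputs = c(basename(f1), basename(f2)),
         n_calls = nrow(env$calls))
  })

  run_stage("annotate", function() {
    specs <- attr(env$cohort, "td_specs")
    ann <- do.call(rbind, lapply(specs, splice_aware_frame, gm = gm))
    truth <- cbind(env$cohort, ann[, c("spliced_inserted_length",
                                       "in_frame", "exon13_fusion")])
    g2c <- function(i) {
      g <- seq.int(env$cohort$dup_start[i], env$cohort$dup_end[i] - 1L)
      cds <- genomic_to_cds(gm, g)
      range(cds[!is.na(cds)])
    }
    cds <- t(vapply(seq_len(nrow(truth)), g2c, numeric(2L)))
    truth$cds_start <- as.integer(cds[, 1L])
    truth$cds_end <- as.integer(cds[, 2L])
    env$summary <- summarize_cohort(truth)
    f1 <- .write_tsv(truth, file.path(cfg$out_dir, "annotated_cohort.tsv"))
    s <- env$summary
    f2 <- file.path(cfg$out_dir, "cohort_summary.json")
    jsonlite::write_json(list(
      n = s$n,
      fraction_sizes_48_51_54 = s$fraction_sizes_48_51_54,
      fraction_with_deletion = s$fraction_with_deletion,
      fraction_with_deletion_large = s$fraction_with_deletion_large,
      fraction_with_deletion_small = s$fraction_with_deletion_small,
      minimal_region = as.integer(s$minimal_region)),
      f2, auto_unbox = TRUE, digits = NA)
    list(outputs = c(basename(f1), basename(f2)),
         minimal_region = unname(as.integer(s$minimal_region)))
  })

  run_stage("clonal", function() {
    outs <- character(0L)
    for (i in seq_len(cfg$n_clonal_cases)) {
      arch <- plant_architecture(n_clones = 2L + (i %% 3L),
                                 seed = cfg$seed + 300L + i)
      sim <- simulate_paired_timepoints(arch, depth = cfg$clonal_depth,
                                        seed = cfg$seed + 400L + i)
      tree <- build_clone_tree(sim)
      rep <- evolution_report(sim)
      rep$wt1_dx <- classify_wt1(sim, tree)[["dx"]]
      rep$wt1_rel <- classify_wt1(sim, tree)[["rel"]]
      rep$relapse_pattern <- classify_relapse_pattern(sim, tree)
      fm <- fishplot_matrix(tree)
      tag <- sprintf("case%02d", i)
      o1 <- .write_tsv(rep, file.path(cfg$out_dir,
                                      paste0(tag, "_evolution.tsv")))
      fm_df <- data.frame(clone = seq_len(nrow(fm$frac)),
                          parent = fm$parents, frac_dx = fm$frac[, 1L],
                          frac_rel = fm$frac[, 2L],
                          variants = rownames(fm$frac))
      o2 <- .write_tsv(fm_df, file.path(cfg$out_dir,
                                        paste0(tag, "_fishplot.csv")))
      outs <- c(outs, basename(o1), basename(o2))
    }
    list(outputs = outs, n_cases = cfg$n_clonal_cases)
  })

  run_stage("stats", function() {
    has <- function(g) grepl(g, env$cohort$co_mutations)
    tab <- function(x, y) {
      data.frame(a = sum(x & y), b = sum(x & !y), c = sum(!x & y),
                 d = sum(!x & !y))
    }
    tables <- rbind(
      cbind(comparison = "WT1_vs_FLT3_ITD", tab(has("WT1"), has("FLT3_ITD"))),
      cbind(comparison = "WT1_vs_trisomy8", tab(has("WT1"), has("trisomy8"))),
      cbind(comparison = "FLT3_ITD_vs_NRAS",
            tab(has("FLT3_ITD"), has("NRAS"))))
    env$stats <- fisher_batch(tables)
    f <- .write_tsv(env$stats, file.path(cfg$out_dir, "comutation_stats.tsv"))
    list(outputs = basename(f))
  })

  ## markdown report
  if (!failed) {
    s <- env$summary
    rpt <- c(
      "# UBTF-TD synthetic cohort report", "",
      sprintf("Seed %d; %d patients.", cfg$seed, cfg$n_patients), "",
      sprintf("* Screen-positive: %d/%d", sum(env$screen$screen_positive),
              cfg$n_patients),
      sprintf("* TD calls on %d sequenced patients: %d",
              cfg$call_patients, nrow(env$calls)),
      sprintf("* 48/51/54-bp share: %.1f%%",
              100 * s$fraction_sizes_48_51_54),
      sprintf("* Internal deletions: %.1f%% overall",
              100 * s$fraction_with_deletion),
      sprintf("* Minimal duplicated region: c.%d-c.%d",
              s$minimal_region[1L], s$minimal_region[2L]),
      "")
    writeLines(rpt, file.path(cfg$out_dir, "report.md"))
  }
  manifest$completed <- !failed
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (failed) warning("pipeline failed; see manifest.json")
  invisible(manifest)
}
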