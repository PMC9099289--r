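# End-to-end orchestration: HWE screen -> single-locus tables -> genetic
# models -> per-class combination scan -> backward elimination -> sex
# strata, with a reproducibility manifest.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order: demographic summary, control-stratum HWE screen
#' (dropping violating loci), genotype/allele frequency analysis, genetic
#' models, genotype dichotomization, per-class combination scans, backward
#' elimination from each class's smallest-P pattern, and sex-stratified
#' re-analysis of each elimination path. Writes five display tables plus
#' JSON records and a manifest under `out_dir`. Any stage failure aborts
#' with the stage named, after writing a `FAILED` marker next to whatever
#' partial outputs exist.
#'
#' @param cohort_path Path to the cohort TSV (or a `cohort` object, in
#'   which case `meta_path` is ignored).
#' @param meta_path Path to the locus metadata YAML.
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level (default 0.05).
#' @param scan_m Bonferroni divisor for the combination scan; default is
#'   the number of kept loci, mirroring the motivating study's display
#'   convention (see [scan_class()]).
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cohort_path, meta_path = NULL, out_dir = ".",
                         alpha = 0.05, scan_m = NULL, seed = NA_integer_) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "setup"
  outputs <- character(0)
  on_fail <- function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(c(paste("stage:", stage), paste("error:", conditionMessage(e))),
               marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  manifest <- tryCatch({
    stage <- "read_cohort"
    input_hash <- NULL
    if (inherits(cohort_path, "cohort")) {
      cohort <- cohort_path
    } else {
      cohort <- read_cohort(cohort_path, meta_path)
      input_hash <- unname(tools::md5sum(c(cohort_path, meta_path)))
    }

    stage <- "cohort_summary"
    summ <- cohort_summary(cohort)
    demo <- data.frame(
      group = c("case", "control"),
      n = c(summ$n_cases, summ$n_controls),
      male = summ$sex_counts[, "male"],
      female = summ$sex_counts[, "female"],
      age_median = c(summ$age$case[["median"]], summ$age$control[["median"]]),
      age_q1 = c(summ$age$case[["q1"]], summ$age$control[["q1"]]),
      age_q3 = c(summ$age$case[["q3"]], summ$age$control[["q3"]]),
      sex_p = fmt_p(summ$sex_p), age_p = fmt_p(summ$age_p))
    outputs <- c(outputs, write_tsv(demo, file.path(out_dir, "cohort_summary.tsv")))

    stage <- "hwe_screen"
    screen <- hwe_screen(cohort, alpha = alpha)
    outputs <- c(outputs, write_tsv(screen, file.path(out_dir, "hwe_screen.tsv")))
    kept <- apply_screen(cohort, screen)

    stage <- "single_locus"
    tab <- locus_table(kept, alpha = alpha)
    outputs <- c(outputs,
                 write_tsv(render_table(tab, "table1"),
                           file.path(out_dir, "single_locus.tsv")))

    stage <- "genetic_models"
    outputs <- c(outputs,
                 write_tsv(render_table(tab, "table2", loci = kept$loci),
                           file.path(out_dir, "genetic_models.tsv")))

    stage <- "synergy"
    groupings <- derive_groupings(kept)
    classes <- intersect(ENZYME_CLASSES, unique(kept$loci$enzyme_class))
    scans <- lapply(setNames(classes, classes), function(cls) {
      scan_class(kept, cls, groupings, alpha = alpha, m = scan_m)
    })
    paths <- lapply(scans, function(sc) {
      backward_eliminate(kept, sc$results[[1L]]$pattern, groupings)
    })
    strata <- lapply(paths, function(p) stratified_results(kept, p, groupings))
    tab3 <- render_table(paths, "table3", loci = kept$loci, strata = strata)
    outputs <- c(outputs, write_tsv(tab3, file.path(out_dir, "synergy.tsv")))
    path_records <- lapply(names(paths), function(cls) {
      p <- paths[[cls]]
      list(enzyme_class = cls,
           threshold = scans[[cls]]$threshold,
           steps = lapply(p$steps, function(s) {
             list(pattern = pattern_string(s$pattern, kept$loci),
                  p_value = result_p(s),
                  or = if (!isTRUE(s$separated)) s$exposure$or else NULL,
                  carriers = s$counts)
           }),
           core = pattern_string(p$core$pattern, kept$loci))
    })
    json_path <- file.path(out_dir, "synergy_paths.json")
    jsonlite::write_json(path_records, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    outputs <- c(outputs, json_path)

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("xmsynergy")),
      r_version = as.character(getRversion()),
      seed = seed, alpha = alpha,
      threshold_loci = tab$threshold_loci,
      threshold_models = tab$threshold_models,
      scan_thresholds = lapply(scans, function(s) s$threshold),
      input_md5 = input_hash,
      grouping_footnote = grouping_footnote(groupings),
      n_output_tables = sum(grepl("\\.tsv$", outputs)),
      outputs = basename(outputs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = on_fail)
  invisible(manifest)
}
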