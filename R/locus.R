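# Single-locus pipeline: stratified genotype/allele tables, HWE screening,
# genetic-model association with age/sex adjustment, and the demographic
# summary. All computations are complete-case per locus.

GENETIC_MODELS <- c("genotypic", "allelic", "dominant", "recessive", "additive")

# Resolve a stratum selector into a row index. `stratum` is one of
# "all"/"case"/"control"; `sex` optionally restricts to 0 (male)/1 (female).
stratum_rows <- function(data, stratum, sex = NULL) {
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(data)),
                 case = data$status == 1L,
                 control = data$status == 0L,
                 stop("unknown stratum: '", stratum, "'"))
  if (!is.null(sex)) keep <- keep & data$sex == sex
  keep
}

get_locus <- function(cohort, rsid) {
  i <- match(rsid, cohort$loci$rsid)
  if (is.na(i)) stop("locus not in cohort: ", rsid)
  cohort$loci[i, ]
}

#' Genotype counts for one locus in a stratum
#'
#' Complete-case genotype counts for the selected subjects, in the
#' canonical state order of the locus (hom_ref/het/hom_alt for SNPs,
#' present/null for deletion loci).
#'
#' @param cohort A `cohort`.
#' @param rsid Locus identifier.
#' @param stratum `"all"`, `"case"` or `"control"`.
#' @param sex Optional 0/1 to restrict by sex.
#' @return A [genotype_table()].
#' @export
genotype_counts <- function(cohort, rsid, stratum = "all", sex = NULL) {
  locus <- get_locus(cohort, rsid)
  g <- cohort$data[[rsid]][stratum_rows(cohort$data, stratum, sex)]
  states <- locus_states(locus)
  counts <- vapply(states, function(s) sum(g == s, na.rm = TRUE), integer(1))
  genotype_table(counts, kind = locus$kind, locus = rsid, stratum = stratum)
}

#' Allele counts from genotype counts
#'
#' Collapses a SNP genotype table into allele counts:
#' allele1 = 2*hom_ref + het, allele2 = 2*hom_alt + het.
#'
#' @param table A `genotype_table` of kind `snp`.
#' @return List of class `allele_table`: `counts` (named pair),
#'   `n_total_alleles`, `freq`.
#' @export
allele_counts <- function(table) {
  if (!inherits(table, "genotype_table") || table$kind != "snp") {
    stop("allele_counts: requires a snp-kind genotype_table")
  }
  k <- table$counts
  counts <- c(allele1 = 2L * k[["hom_ref"]] + k[["het"]],
              allele2 = 2L * k[["hom_alt"]] + k[["het"]])
  n <- sum(counts)
  structure(list(counts = counts, n_total_alleles = n,
                 freq = if (n > 0) counts / n else counts * NA_real_,
                 locus = table$locus, stratum = table$stratum),
            class = "allele_table")
}

#' Hardy-Weinberg screen of all loci
#'
#' Tests every SNP locus for HWE in the control stratum and flags which
#' loci are kept for downstream analysis (kept iff control HWE P >= alpha).
#' Deletion loci scored present/null carry no HWE information; they are
#' flagged untestable and always kept.
#'
#' @param cohort A `cohort`.
#' @param alpha Screening level (default 0.05).
#' @return A `data.frame` with one row per locus: `rsid`, `testable`,
#'   `chi2`, `p_value`, `keep`.
#' @export
hwe_screen <- function(cohort, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(cohort$loci)), function(i) {
    locus <- cohort$loci[i, ]
    if (locus$kind != "snp") {
      return(data.frame(rsid = locus$rsid, testable = FALSE,
                        chi2 = NA_real_, p_value = NA_real_, keep = TRUE))
    }
    res <- hwe_chi2(genotype_counts(cohort, locus$rsid, "control"))
    data.frame(rsid = locus$rsid, testable = TRUE, chi2 = res$chi2,
               p_value = res$p_value, keep = res$p_value >= alpha)
  })
  do.call(rbind, rows)
}

#' Drop loci removed by the HWE screen
#'
#' @param cohort A `cohort`.
#' @param screen Output of [hwe_screen()].
#' @return A `cohort` restricted to the kept loci.
#' @export
apply_screen <- function(cohort, screen) {
  kept <- screen$rsid[screen$keep]
  loci <- cohort$loci[cohort$loci$rsid %in% kept, , drop = FALSE]
  data <- cohort$data[, c("subject_id", "status", "sex", "age", loci$rsid),
                      drop = FALSE]
  new_cohort(data, loci)
}

# Exposure coding for one subject vector of canonical genotype states.
# Returns a numeric vector (or a 2-column indicator matrix for genotypic).
code_genotypes <- function(g, locus, model) {
  states <- locus_states(locus)
  if (locus$kind == "presence") {
    if (!model %in% c("dominant", "presence")) {
      stop("locus ", locus$rsid, ": presence-kind loci support only the ",
           "2-level coding")
    }
    return(as.numeric(g == states[["null"]]))  # null vs present
  }
  switch(model,
    dominant = as.numeric(g != states[["hom_ref"]]),      # carrier of allele2
    recessive = as.numeric(g == states[["hom_alt"]]),     # hom_alt vs rest
    additive = (g == states[["het"]]) + 2 * (g == states[["hom_alt"]]),
    genotypic = cbind(het = as.numeric(g == states[["het"]]),
                      hom_alt = as.numeric(g == states[["hom_alt"]])),
    stop("unknown model coding: ", model))
}

#' Single-locus association under a genetic model
#'
#' Logistic regression of case status on the model-coded genotype exposure,
#' optionally adjusted for age and sex, on complete cases at the locus.
#' Codings: dominant = hom_ref vs het+hom_alt; recessive = hom_ref+het vs
#' hom_alt; additive = effect-allele dose 0/1/2 (log-additive term);
#' genotypic = two indicator terms with a 2-df likelihood-ratio P;
#' allelic = the unadjusted allele-count 2x2 odds ratio, reported alongside
#' the covariate-adjusted allele-dose (additive) odds ratio, because a
#' subject-level adjusted model cannot be fitted to alleles directly.
#' Deletion loci use the 2-level null-vs-present coding (reported under
#' `dominant`).
#'
#' @param cohort A `cohort`.
#' @param rsid Locus identifier.
#' @param model One of `"genotypic"`, `"allelic"`, `"dominant"`,
#'   `"recessive"`, `"additive"`.
#' @param adjust Character vector of covariates among `"age"`, `"sex"`
#'   (default both).
#' @param sex Optional 0/1 stratum restriction (covariate `sex` is then
#'   dropped automatically).
#' @return List of class `assoc_result`: locus/model labels, group counts,
#'   the fitted exposure slice (`or`, `ci_lower`, `ci_upper`, `p_value`),
#'   `separated` flag, and model-specific extras (`lrt_p` for genotypic,
#'   `allelic_unadjusted` for allelic).
#' @export
run_model <- function(cohort, rsid, model = "additive",
                      adjust = c("age", "sex"), sex = NULL) {
  model <- match.arg(model, GENETIC_MODELS)
  locus <- get_locus(cohort, rsid)
  d <- cohort$data[stratum_rows(cohort$data, "all", sex), ]
  d <- d[!is.na(d[[rsid]]), ]
  if (!is.null(sex)) adjust <- setdiff(adjust, "sex")
  covs <- NULL
  if (length(adjust)) {
    covs <- as.matrix(d[, adjust, drop = FALSE])
  }
  counts <- list(case = genotype_counts(cohort, rsid, "case", sex)$counts,
                 control = genotype_counts(cohort, rsid, "control", sex)$counts)

  if (model == "allelic") {
    ac_case <- allele_counts(genotype_counts(cohort, rsid, "case", sex))
    ac_ctrl <- allele_counts(genotype_counts(cohort, rsid, "control", sex))
    raw <- or_2x2(ac_case$counts[["allele2"]], ac_case$counts[["allele1"]],
                  ac_ctrl$counts[["allele2"]], ac_ctrl$counts[["allele1"]])
    adj <- run_model(cohort, rsid, "additive", adjust = adjust, sex = sex)
    out <- adj
    out$model <- "allelic"
    out$allelic_unadjusted <- raw
    return(out)
  }

  if (model == "genotypic") {
    if (locus$kind == "presence") {
      # only one non-reference level: genotypic reduces to the 2-level coding
      return(run_model(cohort, rsid, "dominant", adjust = adjust, sex = sex))
    }
    x <- code_genotypes(d[[rsid]], locus, "genotypic")
    design1 <- cbind(`(Intercept)` = 1, x, covs)
    design0 <- cbind(`(Intercept)` = 1, covs)
    fit1 <- fit_logistic(d$status, design1)
    fit0 <- fit_logistic(d$status, design0)
    lrt <- 2 * (fit1$log_lik - fit0$log_lik)
    res <- structure(list(
      locus = rsid, model = "genotypic", adjusted = length(adjust) > 0,
      counts = counts, fit = fit1,
      exposure = fit1$coefficients[fit1$coefficients$term %in%
                                     c("het", "hom_alt"), ],
      lrt_chi2 = lrt, lrt_df = 2L,
      lrt_p = pchisq(lrt, df = 2L, lower.tail = FALSE),
      separated = fit1$separated, n = fit1$n
    ), class = "assoc_result")
    return(res)
  }

  coding_model <- if (locus$kind == "presence") "dominant" else model
  x <- code_genotypes(d[[rsid]], locus, coding_model)
  fit <- fit_exposure(d$status, x, covs, exposure_name = model)
  structure(list(locus = rsid, model = model, adjusted = length(adjust) > 0,
                 counts = counts, fit = fit, exposure = fit$exposure,
                 separated = fit$separated, n = fit$n),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  e <- x$exposure
  cat(sprintf("%s [%s%s] n=%d: ", x$locus, x$model,
              if (isTRUE(x$adjusted)) ", adjusted" else "", x$n))
  if (isTRUE(x$separated)) {
    cat("separation detected; OR withheld\n")
  } else if (!is.null(x$lrt_p)) {
    cat(sprintf("2-df LRT P = %.3g\n", x$lrt_p))
  } else {
    cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), P = %.3g\n",
                e$or, e$ci_lower, e$ci_upper, e$p_value))
  }
  invisible(x)
}

#' Assemble per-locus association reports
#'
#' Runs the requested genetic models for every locus of a (screened)
#' cohort and attaches the Bonferroni context: for the genotype/allele
#' frequency analysis m = number of kept loci; for the genetic-model
#' analysis m = number of SNP loci (deletion loci have no dominant/
#' recessive/additive distinction).
#'
#' @param cohort A `cohort` (after [apply_screen()]).
#' @param models Models to fit (default all five).
#' @param alpha Family-wise level (default 0.05).
#' @param adjust Covariates (default age and sex).
#' @return List of class `locus_table`: per-locus reports (`genotypes`,
#'   `alleles` per stratum; `hwe`; `models`), plus `m_loci`, `m_snp`,
#'   `threshold_loci`, `threshold_models`.
#' @export
locus_table <- function(cohort, models = GENETIC_MODELS, alpha = 0.05,
                        adjust = c("age", "sex")) {
  m_loci <- nrow(cohort$loci)
  m_snp <- sum(cohort$loci$kind == "snp")
  reports <- lapply(seq_len(m_loci), function(i) {
    locus <- cohort$loci[i, ]
    gt <- lapply(c(case = "case", control = "control"),
                 function(s) genotype_counts(cohort, locus$rsid, s))
    at <- if (locus$kind == "snp") lapply(gt, allele_counts) else NULL
    hwe <- if (locus$kind == "snp") hwe_chi2(gt$control) else NULL
    usable <- if (locus$kind == "snp") models
              else intersect(models, c("dominant", "genotypic"))
    fits <- lapply(setNames(usable, usable), function(m) {
      run_model(cohort, locus$rsid, m, adjust = adjust)
    })
    list(rsid = locus$rsid, gene = locus$gene,
         enzyme_class = locus$enzyme_class, kind = locus$kind,
         genotypes = gt, alleles = at, hwe = hwe, models = fits)
  })
  structure(list(reports = reports, m_loci = m_loci, m_snp = m_snp,
                 alpha = alpha,
                 threshold_loci = bonferroni(alpha, m_loci),
                 threshold_models = bonferroni(alpha, max(m_snp, 1L))),
            class = "locus_table")
}

#' Demographic summary of a cohort
#'
#' Per-group sizes, sex counts, median age with interquartile range, the
#' chi-square P for a sex difference, the Mann-Whitney P for an age
#' difference (preceded by a KS normality check per group, reported as a
#' note), mirroring the usual first table of a case-control report.
#'
#' @param cohort A `cohort`.
#' @return List of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort) {
  d <- cohort$data
  grp <- function(s) d[d$status == s, ]
  cases <- grp(1L); controls <- grp(0L)
  age_stats <- function(x) {
    if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    c(median = median(x), q1 = unname(quantile(x, 0.25)),
      q3 = unname(quantile(x, 0.75)))
  }
  sex_tab <- rbind(case = c(male = sum(cases$sex == 0L),
                            female = sum(cases$sex == 1L)),
                   control = c(male = sum(controls$sex == 0L),
                               female = sum(controls$sex == 1L)))
  sex_p <- if (all(rowSums(sex_tab) > 0) && all(colSums(sex_tab) > 0)) {
    chi2_independence(sex_tab)$p_value
  } else NA_real_
  age_p <- if (nrow(cases) >= 2L && nrow(controls) >= 2L) {
    mann_whitney(cases$age, controls$age)$p_value
  } else NA_real_
  ks <- lapply(list(case = cases$age, control = controls$age), function(x) {
    if (length(x) >= 2L && sd(x) > 0) ks_normality(x) else NULL
  })
  structure(list(n_cases = nrow(cases), n_controls = nrow(controls),
                 sex_counts = sex_tab,
                 age = list(case = age_stats(cases$age),
                            control = age_stats(controls$age)),
                 sex_p = sex_p, age_p = age_p, ks_normality = ks),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_age <- function(a) sprintf("%.0f (IQR %.0f-%.0f)", a[["median"]],
                                 a[["q1"]], a[["q3"]])
  cat("Cohort demographics\n")
  cat(sprintf("  cases:    n = %d (%d M / %d F), age %s\n", x$n_cases,
              x$sex_counts["case", "male"], x$sex_counts["case", "female"],
              fmt_age(x$age$case)))
  cat(sprintf("  controls: n = %d (%d M / %d F), age %s\n", x$n_controls,
              x$sex_counts["control", "male"], x$sex_counts["control", "female"],
              fmt_age(x$age$control)))
  cat(sprintf("  sex chi-square P = %.3g; age Mann-Whitney P = %.3g\n",
              x$sex_p, x$age_p))
  invisible(x)
}
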