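# Synthetic case-control cohort generator. Genotypes are drawn under
# Hardy-Weinberg equilibrium at configured base-population frequencies;
# disease status follows a prospective logistic model (age, sex, and
# optional planted multi-locus carrier effects) whose intercept is
# calibrated by bisection so the expected case fraction matches the
# requested design; exact group sizes are then reached by case-control
# (rejection) sampling from the base population.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-cohort
#' generator. Frequencies are per-locus base-population (control)
#' frequencies: the effect-allele (second-allele) frequency for SNP loci,
#' the null-genotype frequency for deletion loci. Demographics are
#' specified per group; the base population is drawn from their
#' design-weighted mixture, and the logistic age/sex effects then induce
#' the case-control differences.
#'
#' @param n_cases,n_controls Group sizes (> 0).
#' @param loci Locus-definition table (default [study_loci()]).
#' @param freq Named per-locus frequency vector in `[0,1]`, keyed by rsid
#'   (default: derived from [study_genotype_counts()] control rows).
#' @param sex_frac_female Length-2 named vector (`case`, `control`).
#' @param age_center,age_spread Length-2 named vectors (`case`, `control`),
#'   years; ages are normal, truncated to `[30, 95]`.
#' @param beta_age Disease log-OR per year of age (default 0.05, so cases
#'   end up older, matching the observed ~8-year median gap).
#' @param beta_female Disease log-OR for female sex (default 0).
#' @param planted List of planted carrier effects, each a list with
#'   elements `loci` (named list: rsid -> character vector of canonical
#'   genotype states defining the carrier group) and `or` (> 0).
#' @param seed Integer seed; the whole run consumes a single stream seeded
#'   from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cases = 527L, n_controls = 499L,
                       loci = study_loci(), freq = NULL,
                       sex_frac_female = c(case = 257 / 527,
                                           control = 229 / 499),
                       age_center = c(case = 66, control = 58),
                       age_spread = c(case = 14 / 1.349,
                                      control = 18 / 1.349),
                       beta_age = 0.05, beta_female = 0,
                       planted = list(), seed = 1L) {
  if (n_cases <= 0 || n_controls <= 0) stop("sim_config: group sizes must be > 0")
  if (is.null(freq)) freq <- control_frequencies(loci)
  missing_freq <- setdiff(loci$rsid, names(freq))
  if (length(missing_freq)) {
    stop("sim_config: no frequency for loci: ",
         paste(missing_freq, collapse = ", "))
  }
  freq <- freq[loci$rsid]
  if (any(freq < 0 | freq > 1)) stop("sim_config: frequencies must lie in [0,1]")
  for (pe in planted) {
    if (is.null(pe$loci) || is.null(pe$or) || pe$or <= 0) {
      stop("sim_config: each planted effect needs 'loci' and a positive 'or'")
    }
    bad <- setdiff(names(pe$loci), loci$rsid)
    if (length(bad)) stop("sim_config: planted effect names unknown loci: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 loci = loci, freq = freq,
                 sex_frac_female = sex_frac_female,
                 age_center = age_center, age_spread = age_spread,
                 beta_age = beta_age, beta_female = beta_female,
                 planted = planted, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration
#'
#' The packaged 13-locus configuration that emulates the motivating
#' study's design: 527 cases / 499 controls, control genotype frequencies
#' from the published frequency table, sex fractions and age medians/IQRs
#' from its demographics, no planted effects.
#'
#' @param seed Integer seed (default 1).
#' @return A [sim_config()].
#' @export
default_config <- function(seed = 1L) {
  sim_config(seed = seed)
}

#' Base-population frequencies from the published control counts
#'
#' @param loci Locus-definition table.
#' @param counts Genotype-count table in the layout of
#'   [study_genotype_counts()].
#' @return Named vector: effect-allele frequency for SNP loci, null
#'   frequency for deletion loci.
#' @export
control_frequencies <- function(loci = study_loci(),
                                counts = study_genotype_counts()) {
  ctrl <- counts[counts$group == "control", ]
  freq <- vapply(seq_len(nrow(loci)), function(i) {
    row <- ctrl[ctrl$rsid == loci$rsid[i], ]
    if (nrow(row) != 1L) stop("no control counts for ", loci$rsid[i])
    if (loci$kind[i] == "snp") {
      (2 * row$g3 + row$g2) / (2 * (row$g1 + row$g2 + row$g3))
    } else {
      row$g2 / (row$g1 + row$g2)
    }
  }, numeric(1))
  names(freq) <- loci$rsid
  freq
}

# Draw n base-population subjects: genotype columns (canonical states),
# sex, age, and the fixed (non-intercept) part of the disease logit.
draw_base <- function(n, config) {
  loci <- config$loci
  wt_case <- config$n_cases / (config$n_cases + config$n_controls)
  p_female <- wt_case * config$sex_frac_female[["case"]] +
    (1 - wt_case) * config$sex_frac_female[["control"]]
  mu_age <- wt_case * config$age_center[["case"]] +
    (1 - wt_case) * config$age_center[["control"]]
  sd_age <- mean(config$age_spread)
  sex <- as.integer(runif(n) < p_female)
  lo <- pnorm(30, mu_age, sd_age); hi <- pnorm(95, mu_age, sd_age)
  age <- round(qnorm(runif(n, lo, hi), mu_age, sd_age), 1)
  geno <- lapply(seq_len(nrow(loci)), function(i) {
    states <- locus_states(loci[i, ])
    q <- config$freq[[loci$rsid[i]]]
    probs <- if (loci$kind[i] == "snp") c((1 - q)^2, 2 * q * (1 - q), q^2)
             else c(1 - q, q)
    unname(states[1L + findInterval(runif(n), cumsum(probs)[-length(probs)],
                                    left.open = TRUE)])
  })
  names(geno) <- loci$rsid
  d <- data.frame(sex = sex, age = age, geno, check.names = FALSE,
                  stringsAsFactors = FALSE)
  lp <- config$beta_age * age + config$beta_female * sex
  for (pe in config$planted) {
    z <- rep(TRUE, n)
    for (rs in names(pe$loci)) z <- z & d[[rs]] %in% pe$loci[[rs]]
    lp <- lp + log(pe$or) * as.numeric(z)
  }
  d$lp <- lp
  d
}

#' Generate a synthetic case-control cohort
#'
#' Draws a base population (HWE genotypes, mixture demographics), assigns
#' disease status from the calibrated logistic model, and accumulates
#' subjects until both group quotas are filled exactly. Deterministic
#' given `config$seed`: the same seed yields a byte-identical cohort file.
#'
#' @param config A [sim_config()].
#' @param n_calibration Base-population sample used to calibrate the
#'   intercept by bisection (default 20000).
#' @return A list with `cohort` (a [new_cohort()] object, cases first) and
#'   `report` (class `sim_report`: realized per-group genotype counts and
#'   frequencies, realized carrier counts per planted effect, the
#'   calibrated intercept, seed echo).
#' @export
simulate_cohort <- function(config, n_calibration = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- config$n_cases + config$n_controls
  target <- config$n_cases / n_total

  cal <- draw_base(n_calibration, config)
  expected_case_frac <- function(alpha) mean(plogis(alpha + cal$lp))
  lo <- -50; hi <- 50
  if (expected_case_frac(lo) > target || expected_case_frac(hi) < target) {
    stop("simulate_cohort: intercept calibration failed; the requested ",
         "case fraction ", signif(target, 3), " is unreachable under the ",
         "configured effects (check 'planted' odds ratios and covariate ",
         "betas)")
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (expected_case_frac(mid) < target) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2

  cases <- controls <- NULL
  chunk <- max(2L * n_total, 2000L)
  guard <- 0L
  while ((is.null(cases) || nrow(cases) < config$n_cases) ||
         (is.null(controls) || nrow(controls) < config$n_controls)) {
    guard <- guard + 1L
    if (guard > 1000L) stop("simulate_cohort: rejection sampling failed to ",
                            "fill the group quotas; case fraction too extreme")
    b <- draw_base(chunk, config)
    is_case <- runif(chunk) < plogis(alpha + b$lp)
    cases <- rbind(cases, b[is_case, , drop = FALSE])
    controls <- rbind(controls, b[!is_case, , drop = FALSE])
  }
  cases <- cases[seq_len(config$n_cases), ]
  controls <- controls[seq_len(config$n_controls), ]
  cases$status <- 1L
  controls$status <- 0L
  d <- rbind(cases, controls)
  d$subject_id <- sprintf("S%05d", seq_len(n_total))
  d <- d[, c("subject_id", "status", "sex", "age", config$loci$rsid)]
  rownames(d) <- NULL
  cohort <- new_cohort(d, config$loci)

  realized <- lapply(setNames(config$loci$rsid, config$loci$rsid), function(rs) {
    lapply(c(case = "case", control = "control"), function(s) {
      gt <- genotype_counts(cohort, rs, s)
      out <- list(counts = gt$counts)
      if (gt$kind == "snp") out$allele_freq <- allele_counts(gt)$freq
      else out$null_freq <- gt$counts[["null"]] / gt$n_total
      out
    })
  })
  planted_carriers <- lapply(config$planted, function(pe) {
    z <- rep(TRUE, nrow(d))
    for (rs in names(pe$loci)) z <- z & d[[rs]] %in% pe$loci[[rs]]
    c(case = sum(z & d$status == 1L), control = sum(z & d$status == 0L))
  })
  report <- structure(list(seed = config$seed, intercept = alpha,
                           n_cases = config$n_cases,
                           n_controls = config$n_controls,
                           genotypes = realized,
                           planted_carriers = planted_carriers),
                      class = "sim_report")
  list(cohort = cohort, report = report)
}

#' @export
print.sim_report <- function(x, ...) {
  cat("<sim_report> seed ", x$seed, ", ", x$n_cases, " cases / ",
      x$n_controls, " controls, intercept ", sprintf("%.3f", x$intercept),
      "\n", sep = "")
  if (length(x$planted_carriers)) {
    for (i in seq_along(x$planted_carriers)) {
      pc <- x$planted_carriers[[i]]
      cat("  planted effect ", i, ": carriers case/control = ",
          pc[["case"]], "/", pc[["control"]], "\n", sep = "")
    }
  }
  invisible(x)
}
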