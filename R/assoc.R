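# Statistical primitives shared by the single-locus and combination stages.
# Conventions: no continuity corrections anywhere; Wald 95% CIs at z = 1.96;
# two-sided P-values.

Z95 <- qnorm(0.975)
SEPARATION_COEF_LIMIT <- 15  # |log-OR| beyond this is treated as separation

#' Build a genotype-count table
#'
#' @param counts Integer vector of genotype counts: length 3
#'   (hom_ref, het, hom_alt) for SNP loci, length 2 (present, null) for
#'   deletion loci.
#' @param kind `"snp"` or `"presence"`.
#' @param locus Optional rsid label.
#' @param stratum Optional stratum label (e.g. `"control"`).
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(counts, kind = c("snp", "presence"),
                           locus = NA_character_, stratum = NA_character_) {
  kind <- match.arg(kind)
  counts <- as.integer(counts)
  expected_len <- if (kind == "snp") 3L else 2L
  if (length(counts) != expected_len || any(is.na(counts)) || any(counts < 0)) {
    stop("genotype_table: need ", expected_len,
         " non-negative counts for kind '", kind, "'")
  }
  names(counts) <- if (kind == "snp") c("hom_ref", "het", "hom_alt")
                   else c("present", "null")
  structure(list(counts = counts, n_total = sum(counts), kind = kind,
                 locus = locus, stratum = stratum),
            class = "genotype_table")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) of observed genotype
#' counts against the expected proportions \eqn{p^2, 2pq, q^2} at the
#' observed allele frequency. Defined only for biallelic SNP counts;
#' deletion loci scored present/null carry no het/hom information so the
#' test is unsupported for them.
#'
#' @param table A `genotype_table` of kind `snp`, or a bare length-3 count
#'   vector (hom_ref, het, hom_alt).
#' @return List of class `hwe_result`: `chi2`, `df`, `p_value`,
#'   `expected` (counts), `allele_freq` (first-allele frequency p).
#' @export
hwe_chi2 <- function(table) {
  if (inherits(table, "genotype_table")) {
    if (table$kind != "snp") {
      stop("hwe_chi2: unsupported for presence-kind loci (",
           "HWE is undefined for present/null scoring)")
    }
    counts <- table$counts
  } else {
    counts <- as.numeric(table)
    if (length(counts) != 3L) stop("hwe_chi2: need 3 genotype counts")
  }
  n <- sum(counts)
  if (n <= 0) stop("hwe_chi2: empty table")
  p <- (2 * counts[[1]] + counts[[2]]) / (2 * n)
  q <- 1 - p
  expected <- c(hom_ref = p^2, het = 2 * p * q, hom_alt = q^2) * n
  if (p == 0 || q == 0) {  # monomorphic: observed == expected by construction
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(list(chi2 = unname(chi2), df = 1L,
                 p_value = pchisq(unname(chi2), df = 1L, lower.tail = FALSE),
                 expected = expected, allele_freq = unname(p)),
            class = "hwe_result")
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with Woolf (log-scale Wald) 95% confidence
#' interval. If any cell is zero the Haldane-Anscombe correction (+0.5 to
#' every cell) is applied and flagged. Cell layout: `a` = exposed cases,
#' `b` = unexposed cases, `c` = exposed controls, `d` = unexposed controls,
#' so OR = ad/(bc) is the case odds of exposure over the control odds.
#'
#' @param a,b,c,d Non-negative counts.
#' @return List of class `or_result`: `or`, `log_or`, `se_log_or`,
#'   `ci_lower`, `ci_upper`, `p_value` (Wald), `haldane` flag and the
#'   original counts.
#' @export
or_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) stop("or_2x2: counts must be >= 0")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("or_2x2: a zero margin leaves the odds ratio undefined")
  }
  haldane <- any(cells == 0)
  w <- if (haldane) cells + 0.5 else cells
  log_or <- log(w[["a"]]) + log(w[["d"]]) - log(w[["b"]]) - log(w[["c"]])
  se <- sqrt(sum(1 / w))
  z <- log_or / se
  structure(list(or = exp(log_or), log_or = log_or, se_log_or = se,
                 ci_lower = exp(log_or - Z95 * se),
                 ci_upper = exp(log_or + Z95 * se),
                 p_value = 2 * pnorm(-abs(z)),
                 haldane = haldane, counts = cells),
            class = "or_result")
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits status on a named design matrix by iteratively reweighted least
#' squares (convergence on relative log-likelihood change below 1e-8,
#' at most 100 iterations) and reports per-coefficient Wald inference on
#' the odds-ratio scale. Complete or quasi-complete separation is detected
#' as a non-intercept coefficient exceeding 15 in absolute value on the
#' logit scale (odds ratios beyond exp(15) are never meaningful at cohort
#' scale); separated or non-converged fits are flagged and their odds
#' ratios withheld rather than reported as numbers.
#'
#' @param response 0/1 vector.
#' @param design Numeric matrix with named columns, including an
#'   `(Intercept)` column; rows with missing values must be excluded
#'   beforehand.
#' @return List of class `logistic_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `z`, `p_value`, `or`, `ci_lower`,
#'   `ci_upper`), `log_lik`, `converged`, `separated`, `n`.
#' @export
fit_logistic <- function(response, design) {
  response <- as.numeric(response)
  if (!all(response %in% c(0, 1))) stop("fit_logistic: response must be 0/1")
  design <- as.matrix(design)
  if (is.null(colnames(design))) stop("fit_logistic: design columns must be named")
  if (nrow(design) != length(response)) stop("fit_logistic: dimension mismatch")
  if (anyNA(design)) stop("fit_logistic: design contains missing values; exclude rows first")
  fit <- suppressWarnings(
    glm.fit(design, response, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100))
  )
  est <- fit$coefficients
  # Fisher-information covariance from the final IRLS weights
  w <- fit$weights
  xtwx <- crossprod(design * sqrt(w))
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(est)) else sqrt(diag(cov))
  non_int <- colnames(design) != "(Intercept)"
  separated <- any(abs(est[non_int]) > SEPARATION_COEF_LIMIT, na.rm = TRUE) ||
    is.null(cov)
  usable <- fit$converged && !separated
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  coefs <- data.frame(
    term = colnames(design), estimate = unname(est), se = unname(se),
    z = unname(z), p_value = unname(p),
    or = if (usable) exp(unname(est)) else rep(NA_real_, length(est)),
    ci_lower = if (usable) exp(unname(est - Z95 * se)) else NA_real_,
    ci_upper = if (usable) exp(unname(est + Z95 * se)) else NA_real_,
    stringsAsFactors = FALSE
  )
  mu <- fit$fitted.values
  ll <- sum(response * log(mu) + (1 - response) * log1p(-mu))
  structure(list(coefficients = coefs, log_lik = ll,
                 converged = fit$converged, separated = separated,
                 n = length(response)),
            class = "logistic_fit")
}

# Convenience: fit with a one-row-per-subject data.frame and term names.
# Returns the full fit plus the exposure-term slice.
fit_exposure <- function(status, exposure, covariates = NULL,
                         exposure_name = "exposure") {
  design <- cbind(`(Intercept)` = 1, exposure)
  colnames(design)[2L] <- exposure_name
  if (!is.null(covariates) && ncol(covariates) > 0) {
    design <- cbind(design, as.matrix(covariates))
  }
  fit <- fit_logistic(status, design)
  fit$exposure <- fit$coefficients[fit$coefficients$term == exposure_name, ]
  fit
}

#' Pearson chi-square test of independence
#'
#' Thin wrapper over [stats::chisq.test()] with the continuity correction
#' disabled; rejects tables with a zero margin.
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("chi2_independence: need at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi2_independence: zero margin")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test using the tie-corrected
#' normal approximation, without continuity correction.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return List with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("mann_whitney: need n >= 2 per group")
  res <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Kolmogorov-Smirnov test against a fitted normal
#'
#' One-sample KS test of `x` against a normal distribution with the sample
#' mean and standard deviation, used as the normality screen before rank
#' tests on age.
#'
#' @param x Numeric vector (length >= 2).
#' @return List with `D` and `p_value`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 2L) stop("ks_normality: need n >= 2")
  res <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(D = unname(res$statistic), p_value = res$p.value)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0,1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("bonferroni: alpha must be in (0,1)")
  if (!is.numeric(m) || m < 1) stop("bonferroni: m must be >= 1")
  alpha / m
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square: chi2 = %.3f (df = %d), P = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), P = %.3g%s\n",
              x$or, x$ci_lower, x$ci_upper, x$p_value,
              if (x$haldane) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (n = ", x$n, ", logLik = ", sprintf("%.2f", x$log_lik),
      if (!x$converged) ", NOT CONVERGED" else "",
      if (x$separated) ", SEPARATED" else "", ")\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
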