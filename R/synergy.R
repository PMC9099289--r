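# Genotype dichotomization, within-class combination scans and
# backward-elimination search for core synergistic genotype patterns.
#
# Pattern strings follow the study's display convention: "/"-separated
# slots in the metadata order of the class loci, "1"/"2" for the two
# genotype groups of a SNP locus, "P"/"N" for present/null at deletion
# loci, and "-" (or the typographic minus) for a wildcarded locus.

#' Dichotomize the genotypes of one locus
#'
#' Sorts the genotype states of a locus into two groups for the
#' combination analysis. Rules, in order of precedence: (1) deletion loci
#' keep their natural present/null split; (2) if the pooled
#' (cases + controls) frequency of the hom_alt genotype is below
#' `rare_hom_threshold`, the rare homozygote is merged into its
#' heterozygote, giving hom_ref vs het + hom_alt — this merge takes
#' precedence over model choice; (3) otherwise the dominant or recessive
#' split with the smaller association P-value is adopted (tie goes to
#' dominant).
#'
#' @param locus One-row slice of a locus-definition table.
#' @param pooled_counts Pooled-cohort [genotype_table()] for the locus
#'   (or a bare count vector).
#' @param dom_p,rec_p Dominant- and recessive-model P-values (required for
#'   SNP loci unless the rare-homozygote merge applies).
#' @param rare_hom_threshold Pooled hom_alt frequency below which the merge
#'   rule fires (default 0.05).
#' @return List of class `genotype_grouping`: `rsid`, `group1`, `group2`
#'   (character vectors of canonical states), `rule`.
#' @export
derive_grouping <- function(locus, pooled_counts, dom_p = NULL, rec_p = NULL,
                            rare_hom_threshold = 0.05) {
  states <- locus_states(locus)
  if (locus$kind == "presence") {
    return(structure(list(rsid = locus$rsid,
                          group1 = unname(states[["present"]]),
                          group2 = unname(states[["null"]]),
                          rule = "presence"),
                     class = "genotype_grouping"))
  }
  counts <- if (inherits(pooled_counts, "genotype_table")) pooled_counts$counts
            else as.numeric(pooled_counts)
  if (length(counts) != 3L) stop("derive_grouping: need 3 pooled genotype counts")
  n <- sum(counts)
  if (n <= 0) stop("derive_grouping: empty pooled table for ", locus$rsid)
  hom_alt_freq <- counts[[3]] / n
  dominant_split <- list(group1 = unname(states[["hom_ref"]]),
                         group2 = unname(states[c("het", "hom_alt")]))
  if (hom_alt_freq < rare_hom_threshold) {
    split <- dominant_split
    rule <- "rare_hom_merge"
  } else {
    if (is.null(dom_p) || is.null(rec_p) || is.na(dom_p) || is.na(rec_p)) {
      stop("derive_grouping: dominant/recessive P-values required for ",
           locus$rsid)
    }
    if (dom_p <= rec_p) {
      split <- dominant_split
      rule <- "dominant_by_p"
    } else {
      split <- list(group1 = unname(states[c("hom_ref", "het")]),
                    group2 = unname(states[["hom_alt"]]))
      rule <- "recessive_by_p"
    }
  }
  structure(c(list(rsid = locus$rsid), split, list(rule = rule)),
            class = "genotype_grouping")
}

#' Derive groupings for every locus of a cohort
#'
#' Computes pooled genotype counts from the cohort and the dominant and
#' recessive model P-values (age/sex-adjusted, via [run_model()]) unless a
#' precomputed P-value table is supplied, then applies [derive_grouping()]
#' per locus.
#'
#' @param cohort A `cohort`.
#' @param model_p Optional `data.frame` with columns `rsid`, `dominant_p`,
#'   `recessive_p` (e.g. [study_model_pvalues()]); if `NULL` the models are
#'   fitted on the cohort.
#' @param rare_hom_threshold Passed to [derive_grouping()].
#' @param adjust Covariates for the fitted models when `model_p` is `NULL`.
#' @return Named list of `genotype_grouping`, keyed by rsid.
#' @export
derive_groupings <- function(cohort, model_p = NULL,
                             rare_hom_threshold = 0.05,
                             adjust = c("age", "sex")) {
  out <- lapply(seq_len(nrow(cohort$loci)), function(i) {
    locus <- cohort$loci[i, ]
    if (locus$kind == "presence") {
      return(derive_grouping(locus, NULL))
    }
    pooled <- genotype_counts(cohort, locus$rsid, "all")
    if (pooled$counts[["hom_alt"]] / max(pooled$n_total, 1L) <
          rare_hom_threshold) {
      return(derive_grouping(locus, pooled,
                             rare_hom_threshold = rare_hom_threshold))
    }
    if (!is.null(model_p)) {
      j <- match(locus$rsid, model_p$rsid)
      if (is.na(j)) stop("derive_groupings: no model P-values for ", locus$rsid)
      dom_p <- model_p$dominant_p[j]; rec_p <- model_p$recessive_p[j]
    } else {
      dom_p <- run_model(cohort, locus$rsid, "dominant",
                         adjust = adjust)$exposure$p_value
      rec_p <- run_model(cohort, locus$rsid, "recessive",
                         adjust = adjust)$exposure$p_value
    }
    derive_grouping(locus, pooled, dom_p, rec_p, rare_hom_threshold)
  })
  names(out) <- cohort$loci$rsid
  out
}

# ---- patterns ---------------------------------------------------------------

#' Construct a genotype-combination pattern
#'
#' @param slots Named character vector over the loci of one enzyme class,
#'   in metadata order; values `"1"` (group 1), `"2"` (group 2) or `NA`
#'   (wildcard).
#' @param enzyme_class Class label.
#' @return Object of class `combination_pattern`.
#' @export
combination_pattern <- function(slots, enzyme_class) {
  if (is.null(names(slots)) || any(!is.na(slots) & !slots %in% c("1", "2"))) {
    stop("combination_pattern: slots must be named and take values '1'/'2'/NA")
  }
  structure(list(slots = slots, enzyme_class = enzyme_class),
            class = "combination_pattern")
}

#' Render a pattern as its display string
#'
#' @param pattern A `combination_pattern`.
#' @param loci Locus-definition table (deletion loci render as P/N).
#' @return A string such as `"2/-/-/-/1"` or `"P/N/-/2/1"`.
#' @export
pattern_string <- function(pattern, loci) {
  vapply(names(pattern$slots), function(rs) {
    v <- pattern$slots[[rs]]
    if (is.na(v)) return("-")
    kind <- loci$kind[match(rs, loci$rsid)]
    if (identical(kind, "presence")) c("1" = "P", "2" = "N")[[v]] else v
  }, character(1)) |> paste(collapse = "/")
}

#' Parse a pattern display string
#'
#' @param string Pattern string with "/"-separated slots ("-" or the
#'   typographic minus for wildcards, "P"/"N" accepted for deletion loci).
#' @param enzyme_class Class whose loci the slots refer to.
#' @param loci Locus-definition table.
#' @return A [combination_pattern()].
#' @export
parse_pattern <- function(string, enzyme_class, loci) {
  class_loci <- loci$rsid[loci$enzyme_class == enzyme_class]
  parts <- strsplit(string, "/", fixed = TRUE)[[1]]
  if (length(parts) != length(class_loci)) {
    stop("pattern '", string, "' has ", length(parts), " slots; class ",
         enzyme_class, " has ", length(class_loci), " loci")
  }
  slots <- vapply(parts, function(p) {
    switch(p, "-" = , "−" = NA_character_,
           "P" = "1", "N" = "2", "1" = "1", "2" = "2",
           stop("invalid pattern slot: '", p, "'"))
  }, character(1))
  names(slots) <- class_loci
  combination_pattern(slots, enzyme_class)
}

# Logical carrier indicator over cohort rows: TRUE iff the subject's
# genotype lies in the named group at every constrained locus; NA if any
# required genotype is missing.
carrier_indicator <- function(cohort, pattern, groupings) {
  d <- cohort$data
  z <- rep(TRUE, nrow(d))
  for (rs in names(pattern$slots)) {
    v <- pattern$slots[[rs]]
    if (is.na(v)) next
    grp <- groupings[[rs]]
    if (is.null(grp)) stop("no grouping for pattern locus ", rs)
    members <- if (v == "1") grp$group1 else grp$group2
    g <- d[[rs]]
    z <- z & ifelse(is.na(g), NA, g %in% members)
  }
  z
}

#' Carrier counts for a combination pattern
#'
#' A subject carries the pattern iff, at every non-wildcard locus, their
#' genotype lies in the named group. Subjects missing a required genotype
#' are excluded from that pattern's analysis. The all-wildcard pattern is
#' vacuously carried by everyone.
#'
#' @param cohort A `cohort`.
#' @param pattern A `combination_pattern`.
#' @param groupings Named list from [derive_groupings()], covering every
#'   constrained locus.
#' @return A `data.frame` with one row per group (`case`, `control`):
#'   `carriers`, `eligible` (complete-case n), `frequency`
#'   (carriers/eligible).
#' @export
combination_carriers <- function(cohort, pattern, groupings) {
  z <- carrier_indicator(cohort, pattern, groupings)
  status <- cohort$data$status
  per_group <- function(s) {
    zz <- z[status == s]
    eligible <- sum(!is.na(zz))
    carriers <- sum(zz, na.rm = TRUE)
    c(carriers = carriers, eligible = eligible,
      frequency = if (eligible > 0) carriers / eligible else NA_real_)
  }
  rows <- rbind(case = per_group(1L), control = per_group(0L))
  data.frame(group = rownames(rows), rows, row.names = NULL)
}

#' Test one combination pattern for association with case status
#'
#' Logistic regression of case status on the pattern-carrier indicator,
#' adjusted for the requested covariates, on subjects with complete
#' genotypes at the constrained loci.
#'
#' @param cohort A `cohort`.
#' @param pattern A `combination_pattern` with at least one constrained
#'   locus.
#' @param groupings Named list from [derive_groupings()].
#' @param adjust Covariates (default age and sex).
#' @param sex Optional 0/1 stratum restriction; the sex covariate is then
#'   dropped.
#' @return List of class `combination_result`: `pattern`, `counts` (from
#'   [combination_carriers()]), the exposure slice (`or`, `ci_lower`,
#'   `ci_upper`, `p_value`), `separated`, `n`.
#' @export
test_pattern <- function(cohort, pattern, groupings,
                         adjust = c("age", "sex"), sex = NULL) {
  if (all(is.na(pattern$slots))) {
    stop("test_pattern: pattern must constrain at least one locus")
  }
  keep <- stratum_rows(cohort$data, "all", sex)
  if (!is.null(sex)) adjust <- setdiff(adjust, "sex")
  sub <- cohort$data[keep, ]
  sub_cohort <- list(data = sub, loci = cohort$loci)
  z <- carrier_indicator(sub_cohort, pattern, groupings)
  ok <- !is.na(z)
  d <- sub[ok, ]
  zz <- as.numeric(z[ok])
  counts <- combination_carriers(sub_cohort, pattern, groupings)
  covs <- if (length(adjust)) as.matrix(d[, adjust, drop = FALSE]) else NULL
  fit <- if (nrow(d) && length(unique(d$status)) == 2L) {
    fit_exposure(d$status, zz, covs, exposure_name = "carrier")
  } else NULL
  structure(list(pattern = pattern, counts = counts,
                 exposure = if (!is.null(fit)) fit$exposure else NULL,
                 separated = if (!is.null(fit)) fit$separated else TRUE,
                 fit = fit, sex = sex,
                 n = if (!is.null(fit)) fit$n else 0L),
            class = "combination_result")
}

result_p <- function(res) {
  if (is.null(res$exposure) || isTRUE(res$separated)) return(NA_real_)
  res$exposure$p_value
}

result_log_or <- function(res) {
  if (is.null(res$exposure)) return(NA_real_)
  res$exposure$estimate
}

#' Scan all genotype combinations within an enzyme class
#'
#' Enumerates every fully-constrained pattern over the k loci of the class
#' (2^k patterns), tests each with [test_pattern()], and flags
#' significance against the Bonferroni threshold `alpha / m`. Following
#' the study's convention, `m` defaults to the number of loci kept in the
#' cohort; set `m = 2^k` (or the total pattern count over all classes) for
#' a family defined by the scan itself.
#'
#' @param cohort A `cohort`.
#' @param enzyme_class `"CYP"`, `"esterase"` or `"GST"`.
#' @param groupings Named list from [derive_groupings()].
#' @param alpha Family-wise level (default 0.05).
#' @param m Bonferroni divisor (default: number of loci in the cohort).
#' @param adjust Covariates (default age and sex).
#' @return List of class `class_scan`: `results` (list of
#'   `combination_result`, sorted by ascending P; separation-flagged
#'   patterns last), `threshold`, `m`, `enzyme_class`.
#' @export
scan_class <- function(cohort, enzyme_class, groupings, alpha = 0.05,
                       m = NULL, adjust = c("age", "sex")) {
  class_loci <- cohort$loci$rsid[cohort$loci$enzyme_class == enzyme_class]
  k <- length(class_loci)
  if (k == 0L) stop("scan_class: no loci in class '", enzyme_class, "'")
  if (is.null(m)) m <- nrow(cohort$loci)
  threshold <- bonferroni(alpha, m)
  grid <- expand.grid(rep(list(c("1", "2")), k), stringsAsFactors = FALSE)
  results <- lapply(seq_len(nrow(grid)), function(i) {
    slots <- unlist(grid[i, ], use.names = FALSE)
    names(slots) <- class_loci
    res <- test_pattern(cohort, combination_pattern(slots, enzyme_class),
                        groupings, adjust = adjust)
    res$significant <- !is.na(result_p(res)) && result_p(res) < threshold
    res
  })
  ps <- vapply(results, result_p, numeric(1))
  results <- results[order(is.na(ps), ps)]
  structure(list(results = results, threshold = threshold, m = m,
                 alpha = alpha, enzyme_class = enzyme_class,
                 class_loci = class_loci),
            class = "class_scan")
}

# All patterns reachable from `pattern` by wildcarding exactly one
# currently-constrained locus, paired with the index of the locus removed.
wildcard_successors <- function(pattern) {
  constrained <- which(!is.na(pattern$slots))
  lapply(constrained, function(i) {
    slots <- pattern$slots
    slots[i] <- NA_character_
    list(pattern = combination_pattern(slots, pattern$enzyme_class),
         removed = i)
  })
}

#' Backward elimination from a fully-constrained pattern
#'
#' Greedy relaxation: starting from a fully-constrained pattern (normally
#' the smallest-P pattern of a class scan), each step evaluates every
#' pattern obtained by wildcarding exactly one constrained locus and moves
#' to the one with the smallest association P-value (ties broken by larger
#' absolute log odds ratio, then by lower locus index); the walk stops
#' when two constrained loci remain. The "core" pattern is the minimum-P
#' pattern along the path (ties go to the pattern with fewer constrained
#' loci).
#'
#' @param cohort A `cohort`.
#' @param start The starting `combination_pattern`, normally fully
#'   constrained (a scan winner); at least two loci must be constrained.
#'   A start with exactly two constrained loci is already terminal and
#'   yields a path of length one.
#' @param groupings Named list from [derive_groupings()].
#' @param adjust Covariates (default age and sex).
#' @return List of class `elimination_path`: `steps` (list of
#'   `combination_result` from start downwards), `core`
#'   (`combination_result`), `core_index`.
#' @export
backward_eliminate <- function(cohort, start, groupings,
                               adjust = c("age", "sex")) {
  if (sum(!is.na(start$slots)) < 2L) {
    stop("backward_eliminate: start pattern must constrain at least two ",
         "loci (fully constrained for a scan start)")
  }
  current <- start
  steps <- list(test_pattern(cohort, current, groupings, adjust = adjust))
  while (sum(!is.na(current$slots)) > 2L) {
    succ <- wildcard_successors(current)
    cand <- lapply(succ, function(s) {
      res <- test_pattern(cohort, s$pattern, groupings, adjust = adjust)
      list(res = res, removed = s$removed)
    })
    ps <- vapply(cand, function(x) result_p(x$res), numeric(1))
    lors <- vapply(cand, function(x) abs(result_log_or(x$res)), numeric(1))
    idx <- vapply(cand, function(x) x$removed, numeric(1))
    ord <- order(is.na(ps), ps, -lors, idx)
    best <- cand[[ord[1L]]]
    current <- best$res$pattern
    steps[[length(steps) + 1L]] <- best$res
  }
  ps <- vapply(steps, result_p, numeric(1))
  k <- vapply(steps, function(s) sum(!is.na(s$pattern$slots)), numeric(1))
  core_index <- order(is.na(ps), ps, k)[1L]
  structure(list(steps = steps, core = steps[[core_index]],
                 core_index = core_index),
            class = "elimination_path")
}

#' Sex-stratified re-analysis of an elimination path
#'
#' Re-tests every pattern visited by [backward_eliminate()] within each
#' sex, with age as the only covariate (sex is constant within a stratum).
#' Strata in which the fit degenerates (e.g. zero carriers) are returned
#' with the separation flag set rather than dropped.
#'
#' @param cohort A `cohort`.
#' @param path An `elimination_path`.
#' @param groupings Named list from [derive_groupings()].
#' @return A list with elements `male` and `female`, each a list of
#'   `combination_result` parallel to `path$steps`.
#' @export
stratified_results <- function(cohort, path, groupings) {
  per_sex <- function(s) {
    lapply(path$steps, function(step) {
      test_pattern(cohort, step$pattern, groupings, adjust = c("age", "sex"),
                   sex = s)
    })
  }
  list(male = per_sex(0L), female = per_sex(1L))
}

#' @export
print.combination_result <- function(x, ...) {
  cat(paste(ifelse(is.na(x$pattern$slots), "-", x$pattern$slots),
            collapse = "/"),
      sprintf(" [%s]", x$pattern$enzyme_class), "\n", sep = "")
  print(x$counts, row.names = FALSE, digits = 3)
  if (isTRUE(x$separated) || is.null(x$exposure)) {
    cat("  fit degenerate (separation or empty stratum); OR withheld\n")
  } else {
    cat(sprintf("  P = %.3g, OR = %.3f (95%% CI %.3f-%.3f)\n",
                x$exposure$p_value, x$exposure$or, x$exposure$ci_lower,
                x$exposure$ci_upper))
  }
  invisible(x)
}

#' @export
print.elimination_path <- function(x, ...) {
  cat("Backward-elimination path (", length(x$steps), " steps, core at step ",
      x$core_index, ")\n", sep = "")
  for (s in x$steps) print(s)
  invisible(x)
}
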