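#' Published genotype counts from the motivating study
#'
#' Per-locus genotype counts for the 527 Parkinson's disease cases and 499
#' controls of the motivating candidate-gene study, as printed in its
#' genotype/allele frequency table. For SNP loci the columns `g1`, `g2`,
#' `g3` are hom_ref / het / hom_alt counts (allele order as in
#' [study_loci()]); for deletion loci `g1`/`g2` are present/null and `g3`
#' is `NA`.
#'
#' @return A `data.frame` with columns `rsid`, `group` (`case`/`control`),
#'   `g1`, `g2`, `g3`.
#' @export
study_genotype_counts <- function() {
  read.delim(system.file("extdata", "pd_study_genotype_counts.tsv",
                         package = "xmsynergy"),
             sep = "\t", stringsAsFactors = FALSE)
}

#' Published dominant/recessive/additive model P-values
#'
#' Age/sex-adjusted P-values of the three genetic models for the 11 SNP
#' loci, as printed in the motivating study's genetic-model table. Used as
#' input when reconstructing the genotype dichotomization that the
#' combination analysis relies on.
#'
#' @return A `data.frame` with columns `rsid`, `dominant_p`, `recessive_p`,
#'   `additive_p`.
#' @export
study_model_pvalues <- function() {
  read.delim(system.file("extdata", "pd_study_model_pvalues.tsv",
                         package = "xmsynergy"),
             sep = "\t", stringsAsFactors = FALSE)
}

#' Published genotype-combination carrier counts
#'
#' Carrier counts per group for the backward-elimination paths reported by
#' the motivating study, one row per visited pattern (total cohort rows
#' only). Pattern strings use "/"-separated slots: "1"/"2" for the two
#' genotype groups, "P"/"N" for present/null at deletion loci, "-" for a
#' wildcarded locus.
#'
#' @return A `data.frame` with columns `enzyme_class`, `pattern`,
#'   `control_carriers`, `case_carriers`.
#' @export
study_combination_counts <- function() {
  read.delim(system.file("extdata", "pd_study_combination_counts.tsv",
                         package = "xmsynergy"),
             sep = "\t", stringsAsFactors = FALSE)
}

#' Expand per-group genotype counts into a synthetic pseudo-cohort
#'
#' Reconstructs a subject-level `cohort` whose per-locus marginal genotype
#' counts equal a published count table exactly. Because only marginal
#' counts are known, genotypes are assigned locus-by-locus in a fixed
#' deterministic order (no joint structure), sexes alternate within group
#' and ages are constant: the result is a synthetic stand-in suitable only
#' for count-level (unadjusted) arithmetic — frequency tables, allele
#' collapses, HWE and 2x2 odds ratios — never for covariate-adjusted or
#' multi-locus analyses.
#'
#' @param counts Count table in the layout of [study_genotype_counts()].
#' @param loci Locus-definition table covering every rsid in `counts`.
#' @param age Constant age assigned to every subject (default 60).
#' @return A [new_cohort()] object.
#' @export
expand_counts_cohort <- function(counts = study_genotype_counts(),
                                 loci = study_loci(), age = 60) {
  group_n <- vapply(c(case = "case", control = "control"), function(g) {
    sub <- counts[counts$group == g, ]
    n <- rowSums(sub[, c("g1", "g2", "g3")], na.rm = TRUE)
    if (length(unique(n)) != 1L) {
      stop("expand_counts_cohort: per-locus totals differ within group ", g)
    }
    unique(n)
  }, numeric(1))
  build_group <- function(g, status) {
    n <- group_n[[g]]
    d <- data.frame(subject_id = sprintf("%s%04d", toupper(substr(g, 1, 2)),
                                         seq_len(n)),
                    status = status, sex = rep_len(c(0L, 1L), n), age = age)
    for (i in seq_len(nrow(loci))) {
      locus <- loci[i, ]
      row <- counts[counts$rsid == locus$rsid & counts$group == g, ]
      if (nrow(row) != 1L) stop("no counts for ", locus$rsid, " in group ", g)
      k <- unlist(row[, c("g1", "g2", "g3")])
      k <- k[!is.na(k)]
      d[[locus$rsid]] <- rep(unname(locus_states(locus)), times = k)
    }
    d
  }
  new_cohort(rbind(build_group("case", 1L), build_group("control", 0L)), loci)
}

#' Published cohort demographics
#'
#' Group sizes, sex splits and age medians/IQRs of the motivating study's
#' cohort of 1,026 Han Chinese subjects.
#'
#' @return A list with `n_cases`, `n_controls`, `sex_counts` (matrix), and
#'   `age` (per-group median and IQR bounds in years).
#' @export
study_demographics <- function() {
  list(
    n_cases = 527L,
    n_controls = 499L,
    sex_counts = matrix(c(270L, 257L, 270L, 229L), nrow = 2L, byrow = TRUE,
                        dimnames = list(c("case", "control"),
                                        c("male", "female"))),
    age = list(case = c(median = 66, q1 = 59, q3 = 73),
               control = c(median = 58, q1 = 50, q3 = 68))
  )
}
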