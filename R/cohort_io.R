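#' @importFrom stats median quantile rnorm runif qnorm pnorm plogis rbinom
#'   setNames complete.cases binomial coef glm glm.fit logLik pchisq sd vcov
#'   IQR chisq.test ks.test wilcox.test
#' @importFrom utils read.delim write.table head modifyList
NULL

ENZYME_CLASSES <- c("CYP", "esterase", "GST")
MISSING_TOKEN <- "NA"

#' Read a locus-metadata document
#'
#' Parses a YAML locus-metadata file into a locus-definition table. Each
#' entry declares a polymorphism: its rsID (or gene symbol for deletion
#' loci), gene, enzyme class (one of CYP, esterase, GST), variant kind
#' (`snp` with an ordered allele pair, or `presence` for deletion loci
#' scored present/null). The order of entries fixes the slot order used in
#' combination-pattern strings; for SNP loci the second allele is the
#' effect allele (its homozygote is `hom_alt`).
#'
#' @param path Path to a YAML file with a top-level `loci:` list.
#' @return A `data.frame` of class `locus_set` with one row per locus and
#'   columns `rsid`, `gene`, `enzyme_class`, `kind`, `allele1`, `allele2`
#'   (alleles are `NA` for presence loci).
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("locus metadata file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$loci) || !length(doc$loci)) {
    stop("locus metadata must contain a non-empty 'loci' list: ", path)
  }
  rows <- lapply(doc$loci, function(x) {
    for (f in c("rsid", "gene", "enzyme_class", "kind")) {
      if (is.null(x[[f]])) stop("locus entry missing field '", f, "'")
    }
    if (!x$enzyme_class %in% ENZYME_CLASSES) {
      stop("locus ", x$rsid, ": enzyme_class must be one of ",
           paste(ENZYME_CLASSES, collapse = "/"), ", got '", x$enzyme_class, "'")
    }
    if (!x$kind %in% c("snp", "presence")) {
      stop("locus ", x$rsid, ": kind must be 'snp' or 'presence'")
    }
    a1 <- a2 <- NA_character_
    if (x$kind == "snp") {
      if (length(x$alleles) != 2L) {
        stop("locus ", x$rsid, ": snp kind requires exactly 2 alleles")
      }
      a1 <- as.character(x$alleles[[1]])
      a2 <- as.character(x$alleles[[2]])
      if (a1 == a2) stop("locus ", x$rsid, ": alleles must be distinct")
    }
    data.frame(rsid = x$rsid, gene = x$gene, enzyme_class = x$enzyme_class,
               kind = x$kind, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  if (anyDuplicated(loci$rsid)) {
    stop("duplicate rsid in locus metadata: ",
         paste(unique(loci$rsid[duplicated(loci$rsid)]), collapse = ", "))
  }
  class(loci) <- c("locus_set", "data.frame")
  loci
}

#' Genotype states valid for one locus
#'
#' @param locus One-row slice of a locus-definition table.
#' @return Named character vector of canonical genotype strings: for a SNP,
#'   `hom_ref`, `het`, `hom_alt` built from the ordered allele pair; for a
#'   presence locus, `present` and `null`.
#' @export
locus_states <- function(locus) {
  if (locus$kind == "presence") {
    return(c(present = "present", null = "null"))
  }
  c(hom_ref = paste0(locus$allele1, locus$allele1),
    het     = paste0(locus$allele1, locus$allele2),
    hom_alt = paste0(locus$allele2, locus$allele2))
}

# Canonicalize raw genotype tokens for one locus; "CT" == "TC" given allele
# order in the metadata. Returns NA for the missing sentinel; stops with the
# offending value for anything else. Idempotent on its own output.
normalize_genotype <- function(tokens, locus) {
  tokens <- as.character(tokens)
  out <- rep(NA_character_, length(tokens))
  miss <- is.na(tokens) | tokens == MISSING_TOKEN
  states <- locus_states(locus)
  if (locus$kind == "presence") {
    ok <- !miss & tokens %in% states
    out[ok] <- tokens[ok]
  } else {
    flipped_het <- paste0(locus$allele2, locus$allele1)
    ok <- !miss & (tokens %in% states | tokens == flipped_het)
    out[ok] <- ifelse(tokens[ok] == flipped_het, states[["het"]], tokens[ok])
  }
  bad <- !miss & !ok
  if (any(bad)) {
    stop("invalid genotype token(s) for locus ", locus$rsid, " (",
         if (locus$kind == "snp") paste0(locus$allele1, "/", locus$allele2)
         else "present/null",
         "): '", paste(unique(tokens[bad]), collapse = "', '"),
         "' at row(s) ", paste(head(which(bad), 5L), collapse = ", "))
  }
  out
}

#' Assemble a cohort object
#'
#' Bundles a validated subject table with its locus definitions. Genotype
#' columns are normalized to canonical states; every genotype column must be
#' declared in `loci` and every declared locus must have a column.
#'
#' @param data Subject `data.frame` with columns `subject_id`, `status`
#'   (1 = case, 0 = control), `sex` (0 = male, 1 = female), `age` (years),
#'   then one genotype column per rsid.
#' @param loci Locus-definition table from [read_loci()].
#' @return An object of class `cohort`: a list with elements `data` and
#'   `loci`.
#' @export
new_cohort <- function(data, loci) {
  required <- c("subject_id", "status", "sex", "age")
  if (!identical(names(data)[seq_along(required)], required)) {
    stop("cohort table must start with columns ",
         paste(required, collapse = ", "), "; got: ",
         paste(head(names(data), 4L), collapse = ", "))
  }
  geno_cols <- setdiff(names(data), required)
  undeclared <- setdiff(geno_cols, loci$rsid)
  if (length(undeclared)) {
    stop("genotype column(s) not declared in locus metadata: ",
         paste(undeclared, collapse = ", "))
  }
  absent <- setdiff(loci$rsid, geno_cols)
  if (length(absent)) {
    stop("locus declared in metadata but missing from cohort table: ",
         paste(absent, collapse = ", "))
  }
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) {
    stop("duplicate subject id(s): ",
         paste(unique(data$subject_id[duplicated(data$subject_id)]),
               collapse = ", "))
  }
  if (nrow(data)) {
    data$status <- as.integer(data$status)
    data$sex <- as.integer(data$sex)
    data$age <- as.numeric(data$age)
    if (!all(data$status %in% 0:1)) stop("status must be 0 (control) or 1 (case)")
    if (!all(data$sex %in% 0:1)) stop("sex must be 0 (male) or 1 (female)")
    if (any(is.na(data$age)) || any(data$age <= 0)) stop("age must be positive")
    for (i in seq_len(nrow(loci))) {
      rs <- loci$rsid[i]
      data[[rs]] <- normalize_genotype(data[[rs]], loci[i, ])
    }
  }
  # column order: required then metadata order
  data <- data[, c(required, loci$rsid), drop = FALSE]
  structure(list(data = data, loci = loci), class = "cohort")
}

#' Read a cohort table plus locus metadata
#'
#' Reads the canonical on-disk form: a UTF-8 tab-separated subject table
#' (header `subject_id`, `status`, `sex`, `age`, then one column per rsid;
#' missing genotypes as `NA`) and a YAML locus-metadata document. Genotype
#' tokens are normalized (unordered allele pairs for SNPs); any token other
#' than a valid state or the missing sentinel is rejected with the offending
#' locus and rows named.
#'
#' @param cohort_path Path to the subject TSV.
#' @param meta_path Path to the locus metadata YAML, or an already-parsed
#'   `locus_set`.
#' @return A [new_cohort()] object.
#' @export
read_cohort <- function(cohort_path, meta_path) {
  loci <- if (inherits(meta_path, "locus_set")) meta_path else read_loci(meta_path)
  if (!file.exists(cohort_path)) stop("cohort file not found: ", cohort_path)
  data <- read.delim(cohort_path, sep = "\t", header = TRUE,
                     colClasses = "character", na.strings = MISSING_TOKEN,
                     check.names = FALSE)
  new_cohort(data, loci)
}

#' Write a cohort table to TSV
#'
#' Inverse of [read_cohort()]; a write-then-read round trip reproduces the
#' cohort exactly (normalization is idempotent).
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort$data, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = MISSING_TOKEN)
  invisible(path)
}

#' Summarize cohort integrity
#'
#' Report-only validation: per-group subject counts, per-locus missingness
#' fractions and the observed age range. Never mutates or rejects its input;
#' degenerate (empty) cohorts yield zero counts.
#'
#' @param cohort A `cohort` object.
#' @return A list of class `cohort_validation` with elements `n_total`,
#'   `n_cases`, `n_controls`, `sex_counts` (cases/controls x male/female),
#'   `age_range`, and `missingness` (named fraction per locus).
#' @export
validate_cohort <- function(cohort) {
  d <- cohort$data
  n <- nrow(d)
  miss <- vapply(cohort$loci$rsid, function(rs) {
    if (n == 0L) 0 else mean(is.na(d[[rs]]))
  }, numeric(1))
  sex_counts <- matrix(0L, 2L, 2L,
                       dimnames = list(c("case", "control"), c("male", "female")))
  if (n) {
    sex_counts["case", ] <- c(sum(d$status == 1L & d$sex == 0L),
                              sum(d$status == 1L & d$sex == 1L))
    sex_counts["control", ] <- c(sum(d$status == 0L & d$sex == 0L),
                                 sum(d$status == 0L & d$sex == 1L))
  }
  structure(list(
    n_total = n,
    n_cases = if (n) sum(d$status == 1L) else 0L,
    n_controls = if (n) sum(d$status == 0L) else 0L,
    sex_counts = sex_counts,
    age_range = if (n) range(d$age) else c(NA_real_, NA_real_),
    missingness = miss
  ), class = "cohort_validation")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$data), " subjects (",
      sum(x$data$status == 1L), " cases / ", sum(x$data$status == 0L),
      " controls), ", nrow(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation\n")
  cat("  subjects: ", x$n_total, " (", x$n_cases, " cases / ",
      x$n_controls, " controls)\n", sep = "")
  cat("  sex (case M/F, control M/F): ",
      paste(t(x$sex_counts), collapse = " / "), "\n", sep = "")
  if (!any(is.na(x$age_range))) {
    cat("  age range: ", paste(round(x$age_range, 1), collapse = " - "), "\n",
        sep = "")
  }
  if (any(x$missingness > 0)) {
    m <- x$missingness[x$missingness > 0]
    cat("  missingness: ",
        paste(names(m), round(m, 3), sep = "=", collapse = ", "), "\n",
        sep = "")
  } else cat("  missingness: none\n")
  invisible(x)
}

#' Packaged locus metadata for the 13-polymorphism study panel
#'
#' @param path Override for the packaged `loci_13.yaml`.
#' @return A `locus_set` with 13 loci: 5 CYP, 3 esterase, 5 GST.
#' @export
study_loci <- function(path = system.file("extdata", "loci_13.yaml",
                                          package = "xmsynergy")) {
  read_loci(path)
}
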