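# Fixtures built in code: small locus sets and hand-written cohorts used
# across the suite.

make_loci <- function(rsid, gene = rsid, enzyme_class = "CYP", kind = "snp",
                      allele1 = "T", allele2 = "C") {
  df <- data.frame(rsid = rsid, gene = gene, enzyme_class = enzyme_class,
                   kind = kind, allele1 = ifelse(kind == "snp", allele1, NA),
                   allele2 = ifelse(kind == "snp", allele2, NA),
                   stringsAsFactors = FALSE)
  class(df) <- c("locus_set", "data.frame")
  df
}

# Two-locus panel: one T/C SNP, one deletion locus.
tiny_loci <- function() {
  make_loci(c("rsA", "gstX"), enzyme_class = c("CYP", "GST"),
            kind = c("snp", "presence"))
}

# Five hand-written subjects over tiny_loci(); includes an unordered "CT"
# token that must normalize to "TC".
tiny_cohort_df <- function() {
  data.frame(
    subject_id = paste0("s", 1:5),
    status = c(1L, 1L, 0L, 0L, 0L),
    sex = c(0L, 1L, 0L, 1L, 0L),
    age = c(61.5, 70, 55, 58, 63),
    rsA = c("TT", "CT", "TC", "CC", "TT"),
    gstX = c("present", "null", "present", "null", "null"),
    stringsAsFactors = FALSE)
}

tiny_cohort <- function() new_cohort(tiny_cohort_df(), tiny_loci())

# Deterministic dominant-split groupings for an arbitrary locus set.
dominant_groupings <- function(loci) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    derive_grouping(loci[i, ],
                    if (loci$kind[i] == "snp") c(50, 30, 20) else NULL,
                    dom_p = 0.5, rec_p = 0.9)
  })
  names(out) <- loci$rsid
  out
}

# A cohort whose genotypes are drawn independently per locus at HWE, with
# status assigned at random: a pure null for scan/elimination tests.
null_cohort <- function(loci, n_cases = 200, n_controls = 200, freq = 0.4,
                        seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  freq <- rep_len(freq, nrow(loci))
  d <- data.frame(subject_id = sprintf("n%04d", 1:n),
                  status = rep(c(1L, 0L), c(n_cases, n_controls)),
                  sex = rbinom(n, 1, 0.5),
                  age = round(runif(n, 40, 80), 1))
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    q <- freq[i]
    states <- unname(locus_states(locus))
    probs <- if (locus$kind == "snp") c((1 - q)^2, 2 * q * (1 - q), q^2)
             else c(1 - q, q)
    d[[locus$rsid]] <- sample(states, n, replace = TRUE, prob = probs)
  }
  new_cohort(d, loci)
}
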