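test_that("stratified genotype counts and allele collapse are exact", {
  cohort <- expand_counts_cohort()
  ctrl <- genotype_counts(cohort, "rs12441817", "control")
  expect_equal(unname(ctrl$counts), c(138L, 242L, 119L))
  case <- genotype_counts(cohort, "rs12441817", "case")
  expect_equal(unname(case$counts), c(150L, 280L, 97L))

  # allele collapse: allele1 = 2*hom_ref + het, allele2 = 2*hom_alt + het
  ac <- allele_counts(case)
  expect_equal(unname(ac$counts), c(580L, 474L))
  expect_equal(ac$n_total_alleles, 2L * case$n_total)
  expect_equal(sum(ac$freq), 1, tolerance = 1e-12)

  expect_equal(unname(allele_counts(genotype_table(c(0, 0, 0), "snp"))$counts),
               c(0L, 0L))
  expect_equal(unname(allele_counts(genotype_table(c(10, 0, 0), "snp"))$counts),
               c(20L, 0L))
  expect_error(allele_counts(genotype_table(c(5, 5), "presence")), "snp")

  # empty stratum: zero table, no crash
  males_only <- genotype_counts(tiny_cohort(), "rsA", "case", sex = 1L)
  expect_equal(genotype_counts(tiny_cohort(), "rsA", "control",
                               sex = NULL)$n_total, 3L)
  empty <- new_cohort(tiny_cohort_df()[0, ], tiny_loci())
  expect_equal(genotype_counts(empty, "rsA", "case")$n_total, 0L)
  expect_error(genotype_counts(tiny_cohort(), "rsA", "everyone"),
               "unknown stratum")
})

test_that("counts agree between simulator report and count functions", {
  sim <- simulate_cohort(default_config(seed = 1L))
  for (rs in c("rs762551", "GSTM1")) {
    expect_equal(sim$report$genotypes[[rs]]$case$counts,
                 genotype_counts(sim$cohort, rs, "case")$counts)
  }
})

test_that("HWE screening drops planted violations and keeps deletion loci", {
  loci <- make_loci(c("rs_ok1", "rs_ok2", "rs_bad", "gstD"),
                    enzyme_class = c("CYP", "CYP", "esterase", "GST"),
                    kind = c("snp", "snp", "snp", "presence"))
  cohort <- null_cohort(loci, n_cases = 300, n_controls = 300, seed = 8)
  # overwrite one locus with a gross heterozygote deficit
  set.seed(9)
  cohort$data$rs_bad <- sample(c("TT", "CC"), 600, replace = TRUE)
  scr <- hwe_screen(cohort)
  expect_equal(scr$keep, c(TRUE, TRUE, FALSE, TRUE))
  expect_false(scr$testable[scr$rsid == "gstD"])

  kept <- apply_screen(cohort, scr)
  expect_equal(nrow(kept$loci), 3L)
  expect_false("rs_bad" %in% names(kept$data))

  # all-HWE cohort keeps everything
  expect_true(all(hwe_screen(null_cohort(tiny_loci(), seed = 2))$keep))
})

test_that("model codings collapse genotypes as defined", {
  loci <- study_loci()
  rs <- loci[loci$rsid == "rs12441817", ]
  g <- c("TT", "TC", "CC", "TC")
  expect_equal(code_genotypes(g, rs, "dominant"), c(0, 1, 1, 1))
  expect_equal(code_genotypes(g, rs, "recessive"), c(0, 0, 1, 0))
  expect_equal(code_genotypes(g, rs, "additive"), c(0, 1, 2, 1))
  gm <- code_genotypes(g, rs, "genotypic")
  expect_equal(dim(gm), c(4L, 2L))
  gst <- loci[loci$rsid == "GSTM1", ]
  expect_equal(code_genotypes(c("present", "null"), gst, "dominant"), c(0, 1))
  expect_error(code_genotypes(c("present"), gst, "recessive"), "2-level")
})

test_that("unadjusted regression ORs equal the collapsed 2x2 cross-products", {
  cohort <- null_cohort(make_loci("rsQ"), n_cases = 250, n_controls = 250,
                        freq = 0.35, seed = 14)
  for (model in c("dominant", "recessive")) {
    res <- run_model(cohort, "rsQ", model, adjust = character(0))
    k_case <- genotype_counts(cohort, "rsQ", "case")$counts
    k_ctrl <- genotype_counts(cohort, "rsQ", "control")$counts
    exposed <- if (model == "dominant") function(k) k[["het"]] + k[["hom_alt"]]
               else function(k) k[["hom_alt"]]
    oracle <- or_2x2(exposed(k_case), sum(k_case) - exposed(k_case),
                     exposed(k_ctrl), sum(k_ctrl) - exposed(k_ctrl))
    expect_equal(log(res$exposure$or), oracle$log_or, tolerance = 1e-6)
  }
})

test_that("the five genetic models return coherent association results", {
  sim <- simulate_cohort(default_config(seed = 5L))
  cohort <- sim$cohort

  rec <- run_model(cohort, "rs12441817", "recessive")
  expect_s3_class(rec, "assoc_result")
  expect_true(rec$adjusted)
  expect_true(rec$exposure$p_value > 0 && rec$exposure$p_value <= 1)
  expect_true(rec$exposure$ci_lower < rec$exposure$or &&
                rec$exposure$or < rec$exposure$ci_upper)

  gen <- run_model(cohort, "rs12441817", "genotypic")
  expect_equal(gen$lrt_df, 2L)
  expect_true(gen$lrt_p > 0 && gen$lrt_p <= 1)
  expect_equal(nrow(gen$exposure), 2L)

  al <- run_model(cohort, "rs12441817", "allelic")
  expect_s3_class(al$allelic_unadjusted, "or_result")
  # the raw allele cross-product and the adjusted allele-dose OR agree in
  # direction on a null locus drawn from one population
  expect_true(is.finite(al$exposure$or))

  # deletion loci only support the 2-level coding
  dom <- run_model(cohort, "GSTM1", "dominant")
  expect_true(is.finite(dom$exposure$or))
})

test_that("locus_table carries the Bonferroni context of both analyses", {
  sim <- simulate_cohort(default_config(seed = 6L))
  tab <- locus_table(sim$cohort, models = c("dominant"), alpha = 0.05)
  expect_equal(tab$m_loci, 13L)
  expect_equal(tab$m_snp, 11L)
  expect_equal(round(tab$threshold_loci, 4), 0.0038)
  expect_equal(round(tab$threshold_models, 4), 0.0045)

  single <- null_cohort(make_loci("rs1"), seed = 3)
  t1 <- locus_table(single, models = "dominant")
  expect_equal(t1$threshold_loci, 0.05)
})

test_that("cohort_summary reproduces demographic contrasts", {
  # identical groups: no sex or age signal
  d <- tiny_cohort_df()
  d$status <- c(1L, 1L, 0L, 0L, 1L)
  twin <- rbind(d, transform(d, subject_id = paste0(subject_id, "b"),
                             status = 1L - status))
  twin <- new_cohort(twin, tiny_loci())
  s <- cohort_summary(twin)
  expect_equal(s$sex_p, 1, tolerance = 1e-9)
  expect_equal(s$age_p, 1, tolerance = 1e-9)

  # planted 8-year shift at n = 500/500 is decisively detected
  loci <- make_loci("rsS")
  big <- null_cohort(loci, n_cases = 500, n_controls = 500, seed = 4)
  big$data$age <- big$data$age + ifelse(big$data$status == 1L, 8, 0)
  expect_lt(cohort_summary(big)$age_p, 0.001)
})
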