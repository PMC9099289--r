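test_that("dichotomization rules reproduce the published groupings", {
  loci <- study_loci()
  counts <- study_genotype_counts()
  pooled <- function(rs) {
    k <- counts[counts$rsid == rs, c("g1", "g2", "g3")]
    colSums(k)
  }

  # rare-homozygote merge takes precedence over model choice: the PON2
  # SNP has pooled CC below 5% although its recessive P (0.094) is far
  # smaller than its dominant P (0.90)
  g <- derive_grouping(loci[loci$rsid == "rs12026", ], pooled("rs12026"),
                       dom_p = 0.90, rec_p = 0.094)
  expect_equal(g$rule, "rare_hom_merge")
  expect_equal(g$group1, "GG")
  expect_equal(sort(g$group2), sort(c("GC", "CC")))

  # common homozygote: smaller-P model decides (recessive here)
  g <- derive_grouping(loci[loci$rsid == "rs12441817", ],
                       pooled("rs12441817"), dom_p = 0.68, rec_p = 0.04)
  expect_equal(g$rule, "recessive_by_p")
  expect_equal(sort(g$group1), sort(c("TT", "TC")))
  expect_equal(g$group2, "CC")

  # ... and dominant when its P is smaller
  g <- derive_grouping(loci[loci$rsid == "rs156697", ], pooled("rs156697"),
                       dom_p = 0.049, rec_p = 0.16)
  expect_equal(g$rule, "dominant_by_p")
  expect_equal(g$group1, "AA")

  # ties go to dominant
  g <- derive_grouping(loci[loci$rsid == "rs156697", ], pooled("rs156697"),
                       dom_p = 0.2, rec_p = 0.2)
  expect_equal(g$rule, "dominant_by_p")

  # deletion loci keep present/null; P-values not needed
  g <- derive_grouping(loci[loci$rsid == "GSTM1", ], NULL)
  expect_equal(g$rule, "presence")
  expect_equal(g$group1, "present")

  # missing model Ps when the split is needed
  expect_error(derive_grouping(loci[loci$rsid == "rs12441817", ],
                               pooled("rs12441817")),
               "P-values required")
})

test_that("pattern strings parse and render with P/N and wildcards", {
  loci <- study_loci()
  p <- parse_pattern("P/N/-/2/1", "GST", loci)
  expect_equal(unname(p$slots), c("1", "2", NA, "2", "1"))
  expect_equal(names(p$slots),
               c("GSTM1", "GSTT1", "rs4925", "rs156697", "rs1695"))
  expect_equal(pattern_string(p, loci), "P/N/-/2/1")
  # the typographic minus used in print is accepted too
  expect_equal(parse_pattern("2/−/−/−/1", "CYP", loci)$slots,
               parse_pattern("2/-/-/-/1", "CYP", loci)$slots)
  expect_error(parse_pattern("1/2", "GST", loci), "5 loci")
  expect_error(parse_pattern("X/N/-/2/1", "GST", loci), "invalid pattern slot")
})

test_that("carrier counting matches a direct tally and partitions strata", {
  cohort <- tiny_cohort()
  groupings <- dominant_groupings(tiny_loci())

  # all-wildcard: vacuously carried by every subject
  allw <- combination_pattern(c(rsA = NA, gstX = NA), "CYP")
  cc <- combination_carriers(cohort, allw, groupings)
  expect_equal(cc$carriers, cc$eligible)
  expect_equal(sum(cc$carriers), 5)

  # one-locus pattern equals the hand tally: carriers of TC or CC among
  # cases are subjects s2 (CT -> TC); controls s3 (TC), s4 (CC)
  one <- combination_pattern(c(rsA = "2", gstX = NA), "CYP")
  cc <- combination_carriers(cohort, one, groupings)
  expect_equal(cc$carriers[cc$group == "case"], 1)
  expect_equal(cc$carriers[cc$group == "control"], 2)
  expect_equal(cc$frequency[cc$group == "control"], 2 / 3)

  # complementary one-locus patterns partition each stratum
  comp <- combination_pattern(c(rsA = "1", gstX = NA), "CYP")
  cc2 <- combination_carriers(cohort, comp, groupings)
  expect_equal(cc$carriers + cc2$carriers, cc$eligible)

  # a missing required genotype excludes the subject from that analysis
  d <- tiny_cohort_df(); d$rsA[1] <- NA
  cc3 <- combination_carriers(new_cohort(d, tiny_loci()), one, groupings)
  expect_equal(cc3$eligible[cc3$group == "case"], 1)

  expect_error(combination_carriers(cohort, one, groupings["gstX"]),
               "no grouping")
})

test_that("class scans enumerate all 2^k patterns and keep stratum partitions", {
  loci <- study_loci()
  sim <- simulate_cohort(default_config(seed = 12L))
  groupings <- derive_groupings(sim$cohort, model_p = study_model_pvalues())

  gst <- scan_class(sim$cohort, "GST", groupings)
  expect_length(gst$results, 32L)
  expect_equal(gst$m, 13L)

  est <- scan_class(sim$cohort, "esterase", groupings, m = 8L)
  expect_length(est$results, 8L)
  expect_equal(est$threshold, 0.05 / 8)
  for (grp in c("case", "control")) {
    carriers <- vapply(est$results, function(r) {
      r$counts$carriers[r$counts$group == grp]
    }, numeric(1))
    totals <- vapply(est$results, function(r) {
      r$counts$eligible[r$counts$group == grp]
    }, numeric(1))
    expect_equal(sum(carriers), unique(totals))
  }
  # results come back ordered by ascending P
  ps <- vapply(est$results, xmsynergy:::result_p, numeric(1))
  expect_true(!is.unsorted(ps[!is.na(ps)]))

  expect_error(scan_class(sim$cohort, "GST", groupings["GSTM1"]),
               "no grouping")
  expect_error(scan_class(tiny_cohort(), "esterase",
                          dominant_groupings(tiny_loci())), "no loci")
})

test_that("a strongly planted pattern tops the scan in most replicates", {
  loci <- make_loci(c("rsP1", "rsP2"), enzyme_class = "CYP")
  groupings <- dominant_groupings(loci)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      n_cases = 527, n_controls = 499, loci = loci,
      freq = c(rsP1 = 0.15, rsP2 = 0.15),
      planted = list(list(loci = list(rsP1 = c("TC", "CC"),
                                      rsP2 = c("TC", "CC")),
                          or = 0.35)),
      seed = 500L + r)
    sim <- simulate_cohort(cfg)
    sc <- scan_class(sim$cohort, "CYP", groupings)
    top <- sc$results[[1L]]$pattern$slots
    if (identical(unname(top), c("2", "2"))) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("backward elimination is greedy with a brute-force step oracle", {
  loci <- make_loci(c("rsE1", "rsE2", "rsE3"), enzyme_class = "esterase")
  groupings <- dominant_groupings(loci)
  cohort <- null_cohort(loci, n_cases = 300, n_controls = 300, freq = 0.3,
                        seed = 77)
  start <- combination_pattern(c(rsE1 = "2", rsE2 = "1", rsE3 = "2"),
                               "esterase")
  path <- backward_eliminate(cohort, start, groupings)

  # visits 3, then 2 constrained loci; stops at 2
  kcon <- vapply(path$steps, function(s) sum(!is.na(s$pattern$slots)),
                 numeric(1))
  expect_equal(kcon, c(3, 2))

  # greedy choice equals the exhaustive minimum over single-wildcard
  # successors of the start pattern
  succ_p <- vapply(xmsynergy:::wildcard_successors(start), function(s) {
    xmsynergy:::result_p(test_pattern(cohort, s$pattern, groupings))
  }, numeric(1))
  expect_equal(xmsynergy:::result_p(path$steps[[2L]]), min(succ_p))

  # carrier counts are non-decreasing along the path (wildcarding relaxes
  # the predicate)
  for (grp in c("case", "control")) {
    carriers <- vapply(path$steps, function(s) {
      s$counts$carriers[s$counts$group == grp]
    }, numeric(1))
    expect_true(all(diff(carriers) >= 0))
  }

  # core is the minimum-P pattern on the path
  ps <- vapply(path$steps, xmsynergy:::result_p, numeric(1))
  expect_equal(xmsynergy:::result_p(path$core), min(ps, na.rm = TRUE))

  # a 2-constrained start is already terminal
  start2 <- combination_pattern(c(rsE1 = "2", rsE2 = "1", rsE3 = NA),
                                "esterase")
  p2 <- backward_eliminate(cohort, start2, groupings)
  expect_length(p2$steps, 1L)
  expect_identical(p2$core$pattern$slots, start2$slots)

  expect_error(backward_eliminate(cohort,
                                  combination_pattern(c(rsE1 = NA, rsE2 = "1",
                                                        rsE3 = NA),
                                                      "esterase"),
                                  groupings),
               "at least two")

  # five-locus class: the path walks 5 -> 4 -> 3 -> 2 constrained loci
  loci5 <- make_loci(paste0("rsF", 1:5), enzyme_class = "GST")
  cohort5 <- null_cohort(loci5, n_cases = 250, n_controls = 250, freq = 0.45,
                         seed = 78)
  start5 <- combination_pattern(setNames(rep("1", 5), loci5$rsid), "GST")
  path5 <- backward_eliminate(cohort5, start5, dominant_groupings(loci5))
  expect_equal(vapply(path5$steps,
                      function(s) sum(!is.na(s$pattern$slots)), numeric(1)),
               c(5, 4, 3, 2))
})

test_that("sex-stratified re-analysis detects female-restricted effects", {
  loci <- make_loci(c("rsW1", "rsW2"), enzyme_class = "GST")
  groupings <- dominant_groupings(loci)
  wins <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    set.seed(900L + r)
    n <- 1000L
    d <- data.frame(subject_id = sprintf("w%04d", 1:n),
                    sex = rep(c(0L, 1L), n / 2),
                    age = round(runif(n, 45, 80), 1))
    for (rs in loci$rsid) {
      d[[rs]] <- sample(c("TT", "TC", "CC"), n, replace = TRUE,
                        prob = c(0.5, 0.4, 0.1))
    }
    carrier <- d$rsW1 != "TT" & d$rsW2 != "TT"
    # protective carrier effect in females only
    lp <- -0.1 + log(0.25) * carrier * (d$sex == 1L)
    d$status <- rbinom(n, 1, plogis(lp))
    cohort <- new_cohort(d[, c("subject_id", "status", "sex", "age",
                               loci$rsid)], loci)
    pat <- combination_pattern(c(rsW1 = "2", rsW2 = "2"), "GST")
    path <- list(steps = list(test_pattern(cohort, pat, groupings)))
    class(path) <- "elimination_path"
    strat <- stratified_results(cohort, path, groupings)
    pf <- xmsynergy:::result_p(strat$female[[1L]])
    pm <- xmsynergy:::result_p(strat$male[[1L]])
    if (!is.na(pf) && !is.na(pm) && pf < pm) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)

  # zero carriers in a stratum propagates the separation flag, not a crash
  cohort0 <- tiny_cohort()
  pat0 <- combination_pattern(c(rsA = "2", gstX = "2"), "GST")
  path0 <- list(steps = list(test_pattern(cohort0, pat0,
                                          dominant_groupings(tiny_loci()))))
  class(path0) <- "elimination_path"
  strat0 <- stratified_results(cohort0, path0,
                               dominant_groupings(tiny_loci()))
  expect_true(strat0$male[[1L]]$separated || strat0$female[[1L]]$separated)
})
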