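#!/usr/bin/env Rscript
# Dominant / recessive / log-additive genetic-model association for the
# SNP loci, age/sex-adjusted.

suppressPackageStartupMessages(library(xmsynergy))

cohort <- read_cohort("results/cohort.tsv",
                      system.file("extdata", "loci_13.yaml",
                                  package = "xmsynergy"))
kept <- apply_screen(cohort, hwe_screen(cohort))
tab <- locus_table(kept, models = c("dominant", "recessive", "additive"))
message("genetic models over ", tab$m_snp, " SNP loci; Bonferroni threshold ",
        signif(tab$threshold_models, 2))
t2 <- render_table(tab, "table2", loci = kept$loci)
write.table(t2, "results/genetic_models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
best <- t2[order(suppressWarnings(as.numeric(t2$p))), ][1, ]
message("smallest model P: ", best$rsid, " ", best$model, " (P = ", best$p,
        ", OR = ", best$or_ci, ")")
message("wrote results/genetic_models.tsv")
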