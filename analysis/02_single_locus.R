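#!/usr/bin/env Rscript
# Demographics, Hardy-Weinberg screening and the single-locus
# genotype/allele frequency analysis of the simulated cohort.

suppressPackageStartupMessages(library(xmsynergy))

cohort <- read_cohort("results/cohort.tsv",
                      system.file("extdata", "loci_13.yaml",
                                  package = "xmsynergy"))
print(cohort_summary(cohort))

screen <- hwe_screen(cohort)
message(sum(!screen$keep), " locus/loci removed by the HWE screen (",
        sum(screen$keep), " kept)")
write.table(screen, "results/hwe_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

kept <- apply_screen(cohort, screen)
tab <- locus_table(kept)
message("genotype/allele analysis over ", tab$m_loci,
        " kept loci; Bonferroni threshold ", signif(tab$threshold_loci, 2))
write.table(render_table(tab, "table1"), "results/single_locus.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/hwe_screen.tsv and results/single_locus.tsv")
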