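#!/usr/bin/env Rscript
# Positive-control run: plant the reported protective CYP core pattern
# (hom-alt at the CYP1A1 promoter SNP with GG+GC at the CYP2E1 SNP) at
# OR = 0.35 and show that the scan + elimination machinery recovers it.

suppressPackageStartupMessages(library(xmsynergy))

planted <- list(list(loci = list(rs12441817 = "CC",
                                 rs2070676 = c("GG", "GC")),
                     or = 0.35))
sim <- simulate_cohort(sim_config(planted = planted, seed = 11L))
message("planted carriers (case/control): ",
        sim$report$planted_carriers[[1]][["case"]], "/",
        sim$report$planted_carriers[[1]][["control"]])

kept <- apply_screen(sim$cohort, hwe_screen(sim$cohort))
groupings <- derive_groupings(kept)
sc <- scan_class(kept, "CYP", groupings)
path <- backward_eliminate(kept, sc$results[[1]]$pattern, groupings)
print(path)
core <- path$core
message("recovered core ", pattern_string(core$pattern, kept$loci),
        ": OR = ", round(core$exposure$or, 3),
        " (planted 0.35), P = ", signif(core$exposure$p_value, 2))
dir.create("results", showWarnings = FALSE)
write.table(render_table(list(CYP = path), "table3", loci = kept$loci),
            "results/planted_effect.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/planted_effect.tsv")
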