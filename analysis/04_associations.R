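#!/usr/bin/env Rscript
# Association analyses:
#  - maternal vitamin D status (T3, IOM categories) vs newborn
#    anthropometry, covariate-adjusted;
#  - the three genetic risk scores (dichotomized) vs 25(OH)D at T1, T3
#    and the change score, with the 9-test Bonferroni family;
#  - per-SNP dominant-model associations.

suppressPackageStartupMessages(library(vitdgrs))

cohort <- read_cohort("results/cohort", n_enrolled = 239, n_dropped = 53)

sa <- stage_status_anthro(cohort)
readr::write_tsv(sa$means, "results/status_anthro_means.tsv")
readr::write_tsv(sa$models, "results/status_anthro_models.tsv")
cat("Vitamin D status vs newborn anthropometry (adjusted GLM p):\n")
print(sa$models)

assoc <- stage_grs_association(cohort)
readr::write_tsv(assoc, "results/grs_association.tsv")
fam <- attr(assoc, "family")
cat(sprintf("\nGRS associations (%d tests, Bonferroni threshold %.3g):\n",
            fam$m, fam$threshold))
print(assoc[, c("scheme", "outcome", "n_low", "mean_low", "n_high",
                "mean_high", "p", "sig_bonferroni")])

per_snp <- stage_per_snp(cohort)
readr::write_tsv(per_snp, "results/per_snp_dominant.tsv")
hits <- per_snp[per_snp$p < 0.05, c("rsid", "outcome", "p")]
cat("\nPer-SNP dominant-model nominal hits:\n")
print(hits)
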