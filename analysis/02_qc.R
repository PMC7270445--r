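#!/usr/bin/env Rscript
# Per-SNP quality control: call rates, minor allele frequencies and
# Hardy-Weinberg equilibrium chi-square tests for the six-SNP panel.

suppressPackageStartupMessages(library(vitdgrs))

cohort <- read_cohort("results/cohort", n_enrolled = 239, n_dropped = 53)
qc <- snp_qc(cohort)
readr::write_tsv(qc, "results/snp_qc.tsv")

print(qc)
cat(sprintf("\nMAF range: %.2f-%.2f; all SNPs in HWE at alpha = 0.05: %s\n",
            min(qc$maf), max(qc$maf), all(qc$pass)))
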