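#!/usr/bin/env Rscript
# Stage 2: somatic filter cascade (VarScan2 thresholds with MuTect rescue in
# the 2-5% VAF window) plus the germline-evidence filter, with a full audit.

suppressPackageStartupMessages(library(apobecsig))
dir.create("results", showWarnings = FALSE)

calls <- read_variants("results/sim/calls.vcf", "vcf")
dec_somatic <- filter_snv_mouse(calls)
dec_germline <- filter_germline(calls)

audit <- filter_audit(dec_somatic)
cat(sprintf("somatic cascade: %d in -> %d pass, %d fail, %d error\n",
            audit$n_input, audit$n_pass, audit$n_fail, audit$n_error))
fails <- table(unlist(strsplit(dec_somatic$failed_rules[
  !dec_somatic$passed & !dec_somatic$error], ",")))
for (rule in names(fails)) cat(sprintf("  rule %-12s failed %d calls\n",
                                       rule, fails[[rule]]))

keep <- dec_somatic$passed & !dec_somatic$error &
  dec_germline$passed & !dec_germline$error
filtered <- calls[keep, , drop = FALSE]
write_variants(filtered, "results/filtered.vcf", "vcf")
write.table(dec_somatic, "results/filter_decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d variants retained as somatic -> results/filtered.vcf\n",
            nrow(filtered)))
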