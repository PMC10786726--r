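#!/usr/bin/env Rscript
# Stage 3: pyrimidine-oriented context classification and APOBEC context
# statistics (TCN/TCW fractions, clonal vs subclonal APOBEC counts).

suppressPackageStartupMessages(library(apobecsig))

ref <- read_fasta("results/sim/reference.fa")
filtered <- read_variants("results/filtered.vcf", "vcf")
ctx <- extract_context(ref, filtered)
write.table(ctx, "results/contexts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fr <- apobec_fractions(ctx)
cat(sprintf("context fractions over %d mutations: TCN %.3f, TCW %.3f (RTCW %.3f + YTCW %.3f)\n",
            fr$n_total, fr$frac_tcn, fr$frac_tcw, fr$frac_rtcw, fr$frac_ytcw))

cnt <- count_apobec_mutations(ctx, stratify_by_clonality = TRUE)
cat(sprintf("APOBEC-associated (TCN C>T/G): %d of %d\n",
            cnt$n_apobec, cnt$n_total))
print(cnt$by_clonality)

summary <- data.frame(metric = c("n_total", "n_apobec", "frac_tcn",
                                 "frac_tcw", "frac_rtcw", "frac_ytcw"),
                      value = c(cnt$n_total, cnt$n_apobec, fr$frac_tcn,
                                fr$frac_tcw, fr$frac_rtcw, fr$frac_ytcw))
write.table(summary, "results/context_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
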