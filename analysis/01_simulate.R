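#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream analyses consume.
# A 100 kb GC-balanced reference; a 500-SNV tumor drawn from a 0.2/0.1/0.7
# SBS2/SBS13/SBS5 mixture with caller evidence; a two-region copy-number
# profile with clonal and region-restricted events; and 8 paired
# pre-/post-treatment samples where each post sample gains a 50-mutation
# TCW burst (the APOBEC signal the later stages should find).

suppressPackageStartupMessages(library(apobecsig))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "17"))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sig <- read_signature_matrix(system.file("extdata", "signatures_synthetic.tsv",
                                         package = "apobecsig"))
spec <- sim_spec(seed = seed)

ref <- simulate_reference(spec$genome_length, spec$gc_fraction, seed = seed)
write_fasta(ref, file.path(out, "reference.fa"))

truth <- simulate_catalog(ref, sig, spec, sample_id = "tumor1")
calls <- simulate_caller_calls(truth, spec$evidence, seed = seed + 1L)
write_variants(calls, file.path(out, "calls.vcf"), "vcf")
cat(sprintf("simulated %d true variants; %d detected by at least one caller\n",
            nrow(truth), nrow(calls)))

seg <- simulate_multiregion_segments(spec, tumor_id = "tumor1")
write_segments(seg, file.path(out, "segments.tsv"))
gt <- attr(seg, "ground_truth")
cat(sprintf("planted copy-number events: %g Mb heterogeneous / %g Mb altered (ITH %.4f)\n",
            gt$heterogeneous_bp / 1e6, gt$altered_bp / 1e6, gt$ith))

cohort <- simulate_paired_cohort(ref, sig, sim_spec(n_mutations = 100,
                                                    seed = seed),
                                 burst = list(n_extra = 50, tcw_only = TRUE),
                                 n_patients = 8, seed = seed + 2L)
paired <- do.call(rbind, lapply(cohort, function(p) rbind(p$pre, p$post)))
write_variants(paired, file.path(out, "paired_cohort.tsv"), "tsv")
cat(sprintf("paired cohort: %d patients, 100 pre + 50 burst mutations each\n",
            length(cohort)))
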