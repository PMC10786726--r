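# Fixture builders shared across test files.

bundled_signatures <- function() {
  read_signature_matrix(system.file("extdata", "signatures_synthetic.tsv",
                                    package = "apobecsig"))
}

make_ref <- function(seq, contig = "chr1") {
  ref_store(stats::setNames(seq, contig))
}

# a single-variant table with sensible evidence defaults
one_variant <- function(pos, ref, alt, chrom = "chr1", ...) {
  variant_table(sample_id = "S1", chrom = chrom, pos = pos, ref = ref,
                alt = alt, ...)
}

# random call set with evidence spanning all filter boundaries
random_calls <- function(n, seed = 1) {
  set.seed(seed)
  depth <- sample(c(20:70, 29L, 30L, 50L), n, replace = TRUE)
  vaf <- sample(c(runif(n), 0.02, 0.05, 0.019, 0.049), n)
  alt <- pmin(depth, round(vaf * depth))
  somatic_p <- sample(c(runif(n, 0, 0.02), 0.01, 0.001, 0.0009), n)
  caller_pool <- c("varscan2", "mutect", "scalpel", "varscan2,mutect",
                   "varscan2,scalpel", "varscan2,mutect,scalpel", "mutect2")
  variant_table(
    sample_id = "S1", chrom = "chr1", pos = seq_len(n),
    ref = "C", alt = "T",
    vaf_tumor = vaf, depth_tumor = depth, alt_reads_tumor = alt,
    somatic_p = somatic_p,
    callers = sample(caller_pool, n, replace = TRUE),
    caller_pass = sample(c(TRUE, FALSE), n, replace = TRUE),
    alt_reads_normal = sample(c(0L, 3L, 5L, 6L, 10L), n, replace = TRUE),
    vaf_normal = sample(c(0, 0.005, 0.01, 0.011, 0.05), n, replace = TRUE),
    clonality = sample(c("clonal", "subclonal"), n, replace = TRUE)
  )
}
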