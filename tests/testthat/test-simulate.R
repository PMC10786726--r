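test_that("reference simulation is seed-deterministic with the target GC", {
  r1 <- simulate_reference(10000, 0.5, seed = 17)
  r2 <- simulate_reference(10000, 0.5, seed = 17)
  expect_identical(r1$seq, r2$seq)
  expect_false(identical(r1$seq, simulate_reference(10000, 0.5, seed = 18)$seq))

  gc_only <- simulate_reference(2000, 1.0, seed = 1)
  expect_true(grepl("^[GC]+$", gc_only$seq[[1]]))

  # observed GC within 3 binomial standard deviations of the target
  L <- 1e6; gc <- 0.4
  r <- simulate_reference(L, gc, seed = 7)
  obs <- sum(strsplit(r$seq[[1]], "")[[1]] %in% c("G", "C")) / L
  expect_lt(abs(obs - gc), 3 * sqrt(gc * (1 - gc) / L))
  expect_error(simulate_reference(500), ">= 1000")
})

test_that("catalog simulation matches its availability-weighted spectrum", {
  ref <- simulate_reference(2e5, 0.5, seed = 11)
  # a flat signature: sampling should follow trinucleotide availability
  flat <- matrix(1 / 96, nrow = 96, ncol = 1,
                 dimnames = list(catalog96_channels(), "S_flat"))
  spec <- sim_spec(n_mutations = 20000, signature_weights = c(S_flat = 1),
                   seed = 5)
  v <- simulate_catalog(ref, flat, spec)
  expect_equal(nrow(v), 20000)

  counts <- attr(v, "sampled_channel_counts")
  # availability of each channel's context on the simulated reference
  ctx <- extract_context(ref, v)
  # goodness of fit against availability-weighted uniform expectation
  chars <- strsplit(ref$seq[[1]], "")[[1]]
  tri <- paste0(chars[2:(length(chars) - 3)], chars[3:(length(chars) - 2)],
                chars[4:(length(chars) - 1)])
  pyr <- substr(tri, 2, 2) %in% c("C", "T")
  tri_pyr <- tri
  tri_pyr[!pyr] <- revcomp(tri[!pyr])
  avail <- table(factor(tri_pyr, levels = unique(channel_context())))
  p_exp <- as.numeric(avail[channel_context()])
  gof <- chisq.test(counts, p = p_exp / sum(p_exp))
  expect_gt(gof$p.value, 0.001)

  # rebuilding the 96-catalog from emitted variants reproduces the draws
  expect_identical(as.integer(build_catalog96(ctx)), as.integer(counts))
})

test_that("catalog simulation handles edge cases and is reproducible", {
  ref <- simulate_reference(5000, 0.5, seed = 2)
  sig <- bundled_signatures()
  spec0 <- sim_spec(n_mutations = 0, seed = 3)
  expect_equal(nrow(simulate_catalog(ref, sig, spec0)), 0)

  spec <- sim_spec(n_mutations = 300, seed = 3)
  v1 <- simulate_catalog(ref, sig, spec)
  v2 <- simulate_catalog(ref, sig, spec)
  expect_identical(v1, v2)

  # a channel with positive mass but no available site errors informatively
  at_only <- ref_store(c(chr1 = paste(rep("AT", 600), collapse = "")))
  expect_error(simulate_catalog(at_only, sig, spec), "no reference sites")
})

test_that("paired cohorts add a TCW-only APOBEC burst on top of the pre sample", {
  ref <- simulate_reference(50000, 0.5, seed = 21)
  sig <- bundled_signatures()
  spec <- sim_spec(n_mutations = 100, seed = 9)
  coh <- simulate_paired_cohort(ref, sig, spec,
                                burst = list(n_extra = 50, tcw_only = TRUE),
                                n_patients = 3, seed = 31)
  expect_length(coh, 3)
  for (p in coh) {
    key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
    expect_true(all(key(p$pre) %in% key(p$post)))
    expect_equal(nrow(p$post), nrow(p$pre) + 50)
    # the gained APOBEC-context count, per the context engine, is >= burst
    gain <- count_apobec_mutations(extract_context(ref, p$post))$n_apobec -
      count_apobec_mutations(extract_context(ref, p$pre))$n_apobec
    expect_gte(gain, 50)
  }
  none <- simulate_paired_cohort(ref, sig, spec, burst = list(n_extra = 0),
                                 n_patients = 1, seed = 31)
  expect_equal(none$P01$post$pos, none$P01$pre$pos)
})

test_that("multi-region copy-number simulation records exact ground truth", {
  mixed <- sim_spec(n_regions = 2, n_clonal_events = 4, n_subclonal_events = 2,
                    event_bp = 5e6, seed = 13)
  seg <- simulate_multiregion_segments(mixed, genome_bp = 1e8)
  gt <- attr(seg, "ground_truth")
  expect_equal(gt$altered_bp, 6 * 5e6)
  expect_equal(gt$heterogeneous_bp, 2 * 5e6)
  expect_equal(gt$ith, 1 / 3)

  clonal_only <- sim_spec(n_regions = 3, n_clonal_events = 5,
                          n_subclonal_events = 0, event_bp = 2e6, seed = 4)
  expect_equal(attr(simulate_multiregion_segments(clonal_only),
                    "ground_truth")$ith, 0)
  private_only <- sim_spec(n_regions = 3, n_clonal_events = 0,
                           n_subclonal_events = 5, event_bp = 2e6, seed = 4)
  expect_equal(attr(simulate_multiregion_segments(private_only),
                    "ground_truth")$ith, 1)
  too_big <- sim_spec(n_clonal_events = 30, n_subclonal_events = 0,
                      event_bp = 5e6, seed = 1)
  expect_error(simulate_multiregion_segments(too_big, genome_bp = 1e8),
               "exceeds the genome")
})

test_that("caller evidence simulation honors its model", {
  ref <- simulate_reference(3e5, 0.5, seed = 41)
  flat <- matrix(1 / 96, nrow = 96, ncol = 1,
                 dimnames = list(catalog96_channels(), "S_flat"))
  spec <- sim_spec(n_mutations = 10000, signature_weights = c(S_flat = 1),
                   clonal_fraction = 1, seed = 6)
  v <- simulate_catalog(ref, flat, spec)

  # detection saturating at vanishing VAF => every caller labels every call
  sure <- default_evidence_model(callers = list(varscan2 = 1e-9,
                                                mutect = 1e-9))
  calls <- simulate_caller_calls(v, sure, seed = 8)
  expect_equal(nrow(calls), nrow(v))
  expect_true(all(calls$callers == "varscan2,mutect"))
  expect_identical(calls, simulate_caller_calls(v, sure, seed = 8))

  # CLT bound: realized mean VAF close to the model mean (clonal 0.4)
  mu <- 0.4; conc <- sure$vaf_concentration; n <- nrow(calls)
  # Var(realized vaf) <= Var(beta) + E[1/depth]/4; bound with 3 s.e.
  se <- sqrt((mu * (1 - mu) / (conc + 1) + 1 / (4 * 50)) / n)
  expect_lt(abs(mean(calls$vaf_tumor) - mu), 3 * se)
})
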