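test_that("contexts match hand-worked examples on both strands", {
  ref <- make_ref("ATTCAAATG")  # deaminase substrate-like TCA site at pos 4
  cc <- extract_context(ref, one_variant(4, "C", "T"))
  expect_equal(cc$trinucleotide, "TCA")
  expect_equal(cc$pentanucleotide, "TTCAA")
  expect_false(cc$strand_flipped)
  expect_true(cc$is_c_to_t_or_g && cc$is_tcn && cc$is_tcw && cc$is_ytcw)
  expect_false(cc$is_rtcw)

  # purine reference base: G>A on plus strand ATGAA -> C>T in TTCAT
  ref2 <- make_ref("AATGAAT")
  cc2 <- extract_context(ref2, one_variant(4, "G", "A"))
  expect_true(cc2$strand_flipped)
  expect_equal(cc2$pentanucleotide, "TTCAT")
  expect_equal(cc2$trinucleotide, "TCA")
  expect_equal(cc2$substitution, "C>T")
  expect_true(cc2$is_tcw && cc2$is_ytcw)

  # C>A is not an APOBEC-class substitution: all flags false
  cc3 <- extract_context(ref, one_variant(4, "C", "A"))
  expect_false(cc3$is_c_to_t_or_g)
  expect_false(any(cc3$is_tcn, cc3$is_tcw, cc3$is_rtcw, cc3$is_ytcw))

  # no-context signals: window off the contig edge, N in window, non-SNV
  edge <- extract_context(ref, one_variant(2, "T", "A"))
  expect_false(edge$context_ok)
  refn <- make_ref("ATNCAAA")
  withn <- extract_context(refn, one_variant(4, "C", "T"))
  expect_false(withn$context_ok)
  indel <- extract_context(ref, one_variant(4, "C", "CT"))
  expect_true(indel$skipped)
  expect_equal(attr(withn, "n_no_context"), 1)
})

test_that("apobec fractions follow the all-mutations denominator", {
  # 10 classified mutations: 3 RTCW + 1 YTCW TCW C>T/G, 6 others
  seq <- paste0("AAA", "ATCAA", "GTCTA", "ATCAA", "CTCAA",  # 3 RTCW, 1 YTCW
                "ACCAA", "ACCAA", "GGCGG", "AATAA", "AATAA", "ATTAA", "AAA")
  ref <- make_ref(seq)
  pos <- 3 + 5 * (0:9) + 3  # center of each planted 5-mer
  refs <- substr(rep(seq, 10), pos, pos)
  alts <- c("T", "G", "T", "T", "T", "G", "T", "C", "C", "G")
  v <- variant_table("S1", "chr1", pos, refs, alts)
  cc <- extract_context(ref, v)
  fr <- apobec_fractions(cc)
  expect_equal(fr$frac_tcw, 0.4)
  expect_equal(fr$frac_rtcw, 0.3)
  expect_equal(fr$frac_ytcw, 0.1)
  expect_equal(fr$frac_rtcw + fr$frac_ytcw, fr$frac_tcw)

  # no C>T/G mutations at all -> all fractions zero
  v0 <- variant_table("S1", "chr1", pos[1:2], refs[1:2], c("A", "A"))
  fr0 <- apobec_fractions(extract_context(ref, v0))
  expect_equal(fr0$frac_tcw + fr0$frac_tcn, 0)

  # every mutation TCW C>T/G -> fraction 1
  v1 <- variant_table("S1", "chr1", rep(pos[1], 2), "C", c("T", "G"))
  expect_equal(apobec_fractions(extract_context(ref, v1))$frac_tcw, 1)

  expect_error(apobec_fractions(extract_context(ref, v[0, ])), "undefined")
})

test_that("apobec counts stratify by clonality and conserve totals", {
  ref <- make_ref(paste(rep("ATCAG", 40), collapse = ""))  # TCA sites
  pos <- 5 * (1:30) + 3  # C centers, clean flanks
  v <- variant_table("S1", "chr1", pos, "C",
                     c(rep("T", 6), rep("A", 24)),
                     clonality = c(rep("clonal", 2), rep("subclonal", 4),
                                   rep("clonal", 24)))
  cc <- extract_context(ref, v)
  res <- count_apobec_mutations(cc, stratify_by_clonality = TRUE)
  expect_equal(res$n_apobec, 6)
  expect_equal(unname(res$by_clonality["clonal", "APOBEC"]), 2)
  expect_equal(unname(res$by_clonality["subclonal", "APOBEC"]), 4)
  expect_equal(sum(res$by_clonality), res$n_total)

  expect_equal(count_apobec_mutations(cc[0, ])$n_apobec, 0)

  v_unk <- v; v_unk$clonality[1] <- "unknown"
  expect_error(count_apobec_mutations(extract_context(ref, v_unk),
                                      stratify_by_clonality = TRUE),
               "clonality unknown")
})

test_that("flags agree with a brute-force double-strand scanner", {
  ref <- simulate_reference(50000, 0.45, seed = 99)
  seq <- ref$seq[[1]]
  set.seed(100)
  pos <- sample(3:(nchar(seq) - 2), 1000)
  refb <- substr(rep(seq, 1000), pos, pos)
  alts <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                 character(1), USE.NAMES = FALSE)
  v <- variant_table("S1", "chr1", pos, refb, alts)
  cc <- extract_context(ref, v)
  for (i in seq_len(nrow(cc))) {
    oracle <- naive_context_flags(seq, pos[i], refb[i], alts[i])
    for (flag in names(oracle)) {
      expect_identical(cc[[flag]][i], oracle[[flag]],
                       label = paste(flag, "at", pos[i]))
    }
  }
  # partition: RTCW + YTCW = TCW, and TCW implies TCN
  expect_equal(sum(cc$is_rtcw) + sum(cc$is_ytcw), sum(cc$is_tcw))
  expect_true(all(!cc$is_tcw | cc$is_tcn))
})

test_that("classification is invariant under reference strand flip", {
  ref <- simulate_reference(5000, 0.5, seed = 23)
  seq <- ref$seq[[1]]
  L <- nchar(seq)
  flipped_ref <- make_ref(revcomp(seq))
  set.seed(24)
  pos <- sample(3:(L - 2), 200)
  refb <- substr(rep(seq, 200), pos, pos)
  alts <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                 character(1), USE.NAMES = FALSE)
  v <- variant_table("S1", "chr1", pos, refb, alts)
  v_flip <- variant_table("S1", "chr1", L - pos + 1,
                          revcomp(refb), revcomp(alts))
  cc <- extract_context(ref, v)
  cf <- extract_context(flipped_ref, v_flip)
  for (flag in c("is_c_to_t_or_g", "is_tcn", "is_tcw", "is_rtcw", "is_ytcw")) {
    expect_identical(cc[[flag]], cf[[flag]])
  }
  expect_identical(cc$trinucleotide, cf$trinucleotide)
})
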