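test_that("96-channel catalogs index channels correctly and conserve counts", {
  # C>T at ACA context: zero-based 16*2 + 0*4 + 0 = 32 -> R index 33
  ref <- make_ref("AAACAAA")
  cc <- extract_context(ref, one_variant(4, "C", "T"))
  cat96 <- build_catalog96(cc)
  expect_equal(unname(cat96[33]), 1L)
  expect_equal(sum(cat96), 1L)
  expect_equal(names(cat96)[33], "A[C>T]A")

  empty <- build_catalog96(cc[0, ])
  expect_equal(sum(empty), 0L)
  expect_length(empty, 96)

  v <- random_calls(60, seed = 5)
  refsim <- simulate_reference(5000, 0.5, seed = 5)
  v$pos <- sample(3:4998, 60)
  v$ref <- substr(rep(refsim$seq[[1]], 60), v$pos, v$pos)
  v$alt <- vapply(v$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
    USE.NAMES = FALSE)
  cc2 <- extract_context(refsim, v)
  expect_equal(sum(build_catalog96(cc2)), sum(cc2$context_ok & !cc2$skipped))
})

test_that("refitting recovers exact blends and applies the 6% cutoff", {
  sig <- bundled_signatures()
  # pure signature: weight 1
  pure <- round(1000 * sig[, "SBS13"]); names(pure) <- rownames(sig)
  f <- refit_signatures(pure, sig)
  expect_equal(unname(f$weights["SBS13"]), 1)
  expect_false(f$excluded)

  # exact 0.6/0.4 blend: within 0.02 of truth and 1e-3 of the NNLS oracle
  blend <- round(20000 * (0.6 * sig[, "SBS2"] + 0.4 * sig[, "SBS5"]))
  names(blend) <- rownames(sig)
  fb <- refit_signatures(blend, sig)
  expect_equal(unname(fb$weights[c("SBS2", "SBS5")]), c(0.6, 0.4),
               tolerance = 0.02)
  oracle <- nnls_weights(blend, sig)
  expect_lt(max(abs(fb$weights - oracle)), 1e-3)

  # a 5% third component falls below the cutoff and is zeroed + renormalized
  with5 <- 0.57 * sig[, "SBS2"] + 0.38 * sig[, "SBS5"] + 0.05 * sig[, "SBS13"]
  with5 <- round(50000 * with5); names(with5) <- rownames(sig)
  f5 <- refit_signatures(with5, sig, cutoff = 0.06)
  expect_equal(unname(f5$weights["SBS13"]), 0)
  expect_equal(sum(f5$weights), 1, tolerance = 1e-9)
  expect_equal(unname(f5$weights["SBS2"]), 0.6, tolerance = 0.01)
  expect_gt(unname(f5$raw_weights["SBS13"]), 0.02)  # present before cutoff

  # <10 mutations excluded
  few <- setNames(c(rep(0L, 95), 9L), rownames(sig))
  expect_true(refit_signatures(few, sig)$excluded)
  ten <- setNames(c(rep(0L, 95), 10L), rownames(sig))
  expect_false(refit_signatures(ten, sig)$excluded)
})

test_that("refit weights are scale-invariant and never fit worse than one signature", {
  sig <- bundled_signatures()
  set.seed(42)
  cat96 <- setNames(as.integer(rmultinom(1, 500,
                                         0.5 * sig[, "SBS2"] +
                                           0.5 * sig[, "SBS40"])),
                    rownames(sig))
  f1 <- refit_signatures(cat96, sig)
  f10 <- refit_signatures(cat96 * 10L, sig)
  expect_equal(f1$weights, f10$weights, tolerance = 1e-12)

  best_single <- max(vapply(colnames(sig), function(s) {
    w <- setNames(as.numeric(colnames(sig) == s), colnames(sig))
    obs <- as.numeric(cat96) / sum(cat96)
    sum(obs * sig %*% w) / sqrt(sum(obs^2) * sum((sig %*% w)^2))
  }, numeric(1)))
  expect_gte(f1$cosine_similarity, best_single - 1e-9)
})

test_that("burden, dominant signature and attribution follow their rules", {
  exp1 <- list(excluded = FALSE,
               weights = c(SBS2 = 0.3, SBS13 = 0.2, SBS5 = 0.5),
               n_mutations = 200)
  expect_equal(apobec_signature_burden(exp1, 200), 100)
  exp2 <- list(excluded = FALSE, weights = c(SBS1 = 0.4, SBS5 = 0.6),
               n_mutations = 100)
  expect_equal(apobec_signature_burden(exp2), 0)
  exp3 <- list(excluded = FALSE, weights = c(SBS2 = 0.6, SBS13 = 0.4),
               n_mutations = 123)
  expect_equal(apobec_signature_burden(exp3), 123)
  expect_error(apobec_signature_burden(list(excluded = TRUE)), "excluded")

  expect_equal(dominant_signature(
    list(excluded = FALSE, weights = c(SBS1 = 0.6, SBS2 = 0.4)))$signature,
    "SBS1")
  tie <- dominant_signature(
    list(excluded = FALSE, weights = c(SBS13 = 0.5, SBS2 = 0.5)))
  expect_equal(tie$signature, "SBS2")  # numeric-aware: 2 before 13
  expect_true(tie$tie)

  sig <- bundled_signatures()
  solo <- list(excluded = FALSE,
               weights = setNames(as.numeric(colnames(sig) == "SBS2"),
                                  colnames(sig)))
  att <- attribute_mutation_signature("T[C>T]A", solo, sig)
  expect_equal(unname(att$probabilities["SBS2"]), 1)

  two <- matrix(c(0.02, 0), 1, 2, dimnames = list(NULL, c("A", "B")))
  sig2 <- matrix(0, 96, 2, dimnames = list(catalog96_channels(), c("A", "B")))
  sig2[1, ] <- c(0.02, 0); sig2[2:96, 1] <- 0.98 / 95; sig2[2:96, 2] <- 1 / 95
  e2 <- list(excluded = FALSE, weights = c(A = 0.5, B = 0.5))
  a2 <- attribute_mutation_signature(1, e2, sig2)
  expect_equal(unname(a2$probabilities), c(1, 0))

  sig3 <- sig2; sig3[1, ] <- c(0.01, 0.03)
  e3 <- list(excluded = FALSE, weights = c(A = 0.75, B = 0.25))
  a3 <- attribute_mutation_signature(1, e3, sig3)
  expect_equal(unname(a3$probabilities), c(0.5, 0.5))
  expect_true(a3$tie)

  sig4 <- sig2; sig4[1, ] <- 0
  expect_error(attribute_mutation_signature(1, e2, sig4), "unattributable")
})

test_that("clonal/subclonal refits detect subclonal APOBEC enrichment", {
  sig <- bundled_signatures()
  ref <- simulate_reference(60000, 0.5, seed = 77)
  make_patient <- function(i) {
    clo <- simulate_catalog(ref, sig,
                            sim_spec(n_mutations = 120,
                                     signature_weights = c(SBS5 = 1),
                                     clonal_fraction = 1, seed = 200 + i),
                            sample_id = sprintf("P%d", i))
    sub <- simulate_catalog(ref, sig,
                            sim_spec(n_mutations = 120,
                                     signature_weights = c(SBS2 = 0.3,
                                                           SBS13 = 0.1,
                                                           SBS5 = 0.6),
                                     clonal_fraction = 0, seed = 300 + i),
                            sample_id = sprintf("P%d", i))
    extract_context(ref, rbind(clo, sub))
  }
  cohort <- setNames(lapply(1:8, make_patient), paste0("P", 1:8))
  res <- clonal_subclonal_apobec_diff(cohort, sig, alternative = "less")
  expect_true(all(res$per_patient$diff < 0))
  expect_true(res$test$exact)
  expect_equal(res$test$p_value, 1 / 256)

  # identical clonal and subclonal catalogs give diff 0
  same <- cohort[["P1"]]
  half <- nrow(same) / 2
  same$clonality <- rep(c("clonal", "subclonal"), half)
  # force identical mutation content in both compartments
  dup <- rbind(same, same)
  dup$clonality <- rep(c("clonal", "subclonal"), each = nrow(same))
  r0 <- clonal_subclonal_apobec_diff(list(P = dup), sig)
  expect_equal(r0$per_patient$diff, 0)

  # attribution mode agrees on the direction
  ra <- clonal_subclonal_apobec_diff(cohort[1:3], sig, mode = "attribution")
  expect_true(all(ra$per_patient$diff < 0))
})
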