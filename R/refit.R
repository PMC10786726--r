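#' Build a 96-channel mutation catalog
#'
#' @param calls output of [extract_context()] for one sample; calls without a
#'   valid context (N window, contig edge, non-SNV) are dropped and counted.
#' @param sample_id label stored with the catalog (defaults to the single
#'   sample id present in `calls`).
#' @return Integer vector of length 96 (names = [catalog96_channels()]), with
#'   attributes `sample_id` and `n_dropped`.
#' @export
build_catalog96 <- function(calls, sample_id = NULL) {
  cc <- .classified(calls)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(cc) > 0) cc$sample_id[1] else "unknown"
  }
  counts <- integer(96)
  if (nrow(cc) > 0) {
    tab <- tabulate(cc$channel, nbins = 96)
    counts <- as.integer(tab)
  }
  names(counts) <- catalog96_channels()
  attr(counts, "sample_id") <- sample_id
  attr(counts, "n_dropped") <-
    attr(calls, "n_no_context") %||% sum(!calls$skipped & !calls$context_ok)
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sse <- function(obs, rec) sum((obs - rec)^2)

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Refit signature exposures to a 96-channel catalog
#'
#' Forward-selection refit: the catalog is normalized to channel fractions,
#' the single signature minimizing the squared reconstruction error is taken
#' as seed, and weights are then iteratively re-optimized one signature at a
#' time with a bounded golden-section line search, stopping when the best
#' achievable error improvement becomes negligible (below 1e-9). After
#' convergence, weights below `cutoff` are zeroed once and the remainder is
#' renormalized to sum 1.
#'
#' Samples with fewer than `min_mutations` mutations are excluded (too few
#' mutations for reliable signature discrimination).
#'
#' @param catalog integer 96-vector (see [build_catalog96()]) or any
#'   nonnegative numeric 96-vector.
#' @param signatures 96 x n signature matrix from [read_signature_matrix()].
#' @param cutoff minimum reported contribution fraction (default 0.06).
#' @param min_mutations minimum catalog size (default 10).
#' @return List with `sample_id`, `excluded` (+ `exclusion_reason`),
#'   `weights` (named, sum to 1 when not excluded, each 0 or >= cutoff),
#'   `raw_weights` (pre-cutoff), `reconstruction_error` (sum of squared
#'   channel-fraction residuals), `cosine_similarity`, `n_mutations`.
#' @export
refit_signatures <- function(catalog, signatures, cutoff = 0.06,
                             min_mutations = 10) {
  if (length(catalog) != 96) stop("catalog must have 96 channels")
  if (!is.matrix(signatures) || nrow(signatures) != 96) {
    stop("signatures must be a 96 x n matrix")
  }
  if (!is.null(names(catalog)) &&
      !identical(names(catalog), rownames(signatures))) {
    stop("catalog and signature channel order disagree")
  }
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  sample_id <- attr(catalog, "sample_id") %||% "unknown"
  total <- sum(catalog)
  empty <- stats::setNames(rep(0, ncol(signatures)), colnames(signatures))
  if (total < min_mutations) {
    return(list(sample_id = sample_id, excluded = TRUE,
                exclusion_reason = sprintf("fewer than %d mutations (%d)",
                                           min_mutations, total),
                weights = empty, raw_weights = empty,
                reconstruction_error = NA_real_,
                cosine_similarity = NA_real_, n_mutations = total))
  }
  obs <- as.numeric(catalog) / total
  nsig <- ncol(signatures)
  w <- rep(0, nsig)
  # seed: best single signature, weight optimized on [0, 1]
  line_tol <- 1e-6
  seed_err <- vapply(seq_len(nsig), function(j) {
    stats::optimize(function(a) sse(obs, a * signatures[, j]),
                    c(0, 1), tol = line_tol)$objective
  }, numeric(1))
  j0 <- which.min(seed_err)
  w[j0] <- stats::optimize(function(a) sse(obs, a * signatures[, j0]),
                           c(0, 1), tol = line_tol)$minimum
  err <- sse(obs, signatures %*% w)
  for (it in seq_len(1000)) {
    best <- list(err = err, j = NA, a = NA)
    for (j in seq_len(nsig)) {
      rec_others <- signatures %*% w - signatures[, j] * w[j]
      opt <- stats::optimize(
        function(a) sse(obs, rec_others + a * signatures[, j]),
        c(0, 1), tol = line_tol)
      if (opt$objective < best$err) {
        best <- list(err = opt$objective, j = j, a = opt$minimum)
      }
    }
    if (is.na(best$j)) break
    w[best$j] <- best$a
    improvement <- err - best$err
    err <- best$err
    if (improvement < 1e-9) break
  }
  raw <- w / sum(w)
  names(raw) <- colnames(signatures)
  weights <- raw
  weights[weights < cutoff] <- 0
  if (sum(weights) == 0) {
    # everything fell below the cutoff; keep the largest raw weight
    weights[which.max(raw)] <- raw[which.max(raw)]
  }
  weights <- weights / sum(weights)
  rec <- as.numeric(signatures %*% weights)
  list(sample_id = sample_id, excluded = FALSE, exclusion_reason = NA_character_,
       weights = weights, raw_weights = raw,
       reconstruction_error = sse(obs, rec),
       cosine_similarity = cosine_sim(obs, rec),
       n_mutations = total)
}

#' APOBEC signature burden (SBS2 + SBS13 mutation count)
#'
#' @param exposure result of [refit_signatures()].
#' @param total_mutations total mutation count the exposures refer to
#'   (defaults to the catalog size recorded in `exposure`).
#' @param apobec_signatures names of the APOBEC signatures in the reference
#'   set.
#' @return (SBS2 weight + SBS13 weight) x total mutations, rounded half-up to
#'   an integer count.
#' @export
apobec_signature_burden <- function(exposure, total_mutations = NULL,
                                    apobec_signatures = c("SBS2", "SBS13")) {
  if (isTRUE(exposure$excluded)) {
    stop("sample excluded from refitting: APOBEC burden undefined")
  }
  if (is.null(total_mutations)) total_mutations <- exposure$n_mutations
  wt <- sum(exposure$weights[names(exposure$weights) %in% apobec_signatures])
  floor(wt * total_mutations + 0.5)
}

#' Dominant signature of a refitted sample
#'
#' The signature with the highest contribution. Ties are broken by
#' numeric-aware name ordering (SBS2 before SBS13) and flagged.
#'
#' @param exposure result of [refit_signatures()].
#' @return List with `signature`, `weight`, `tie` (logical).
#' @export
dominant_signature <- function(exposure) {
  if (isTRUE(exposure$excluded)) stop("sample excluded: no dominant signature")
  w <- exposure$weights
  if (all(w == 0)) stop("all weights zero")
  top <- max(w)
  cand <- names(w)[w == top]
  # numeric-aware ordering: split trailing number off the name
  num <- suppressWarnings(as.numeric(sub("^\\D*", "", cand)))
  ord <- order(sub("\\d+$", "", cand), num, cand)
  list(signature = cand[ord[1]], weight = top, tie = length(cand) > 1)
}

#' Per-mutation signature attribution
#'
#' Posterior probability that each active signature generated a mutation in a
#' given channel: P(s | channel) proportional to weight_s * profile_s[channel].
#'
#' @param channel channel index in 1..96 (or a channel label).
#' @param exposure result of [refit_signatures()].
#' @param signatures the signature matrix used for the refit.
#' @return List with `probabilities` (named, sum 1), `label` (argmax
#'   signature), `tie` (top probabilities equal within 1e-9).
#' @export
attribute_mutation_signature <- function(channel, exposure, signatures) {
  if (isTRUE(exposure$excluded)) stop("sample excluded: cannot attribute")
  if (is.character(channel)) channel <- match(channel, catalog96_channels())
  if (is.na(channel) || channel < 1 || channel > 96) stop("bad channel")
  lik <- exposure$weights * signatures[channel, names(exposure$weights)]
  if (sum(lik) == 0) {
    stop("channel has zero probability under every active signature: unattributable")
  }
  p <- lik / sum(lik)
  top <- max(p)
  cand <- names(p)[p >= top - 1e-9]
  num <- suppressWarnings(as.numeric(sub("^\\D*", "", cand)))
  ord <- order(sub("\\d+$", "", cand), num, cand)
  list(probabilities = p, label = cand[ord[1]], tie = length(cand) > 1)
}

#' Clonal-vs-subclonal APOBEC signature difference across a cohort
#'
#' For each patient, signatures are refitted separately on the clonal and the
#' subclonal mutation catalogs and the difference (clonal APOBEC weight -
#' subclonal APOBEC weight, APOBEC = SBS2 + SBS13) is taken; the cohort-level
#' p-value is a one-sided exact Wilcoxon signed-rank test of the differences
#' against zero (alternative: clonal less than subclonal, i.e. subclonal
#' enrichment).
#'
#' `mode = "attribution"` instead refits once per patient on all mutations and
#' attributes each mutation to its most likely signature
#' ([attribute_mutation_signature()]); the difference is then between the
#' clonal and subclonal fractions of APOBEC-attributed mutations.
#'
#' @param calls_by_patient named list of [extract_context()] outputs, one per
#'   patient, with clonality labels.
#' @param signatures signature matrix.
#' @param cutoff,min_mutations refit parameters (see [refit_signatures()]).
#' @param mode `"refit"` (default) or `"attribution"`.
#' @param alternative sidedness of the cohort test (default `"less"`).
#' @return List with `per_patient` (data.frame: patient, diff, flagged) and
#'   `test` (the cohort [wilcoxon_signed_rank_exact()] result over unflagged
#'   patients).
#' @export
clonal_subclonal_apobec_diff <- function(calls_by_patient, signatures,
                                         cutoff = 0.06, min_mutations = 10,
                                         mode = c("refit", "attribution"),
                                         alternative = "less") {
  mode <- match.arg(mode)
  apo <- c("SBS2", "SBS13")
  rows <- lapply(names(calls_by_patient), function(pid) {
    calls <- calls_by_patient[[pid]]
    cc <- .classified(calls)
    if (any(cc$clonality == "unknown")) {
      stop("patient ", pid, " has mutations without clonality labels")
    }
    clo <- calls[calls$clonality == "clonal", , drop = FALSE]
    sub <- calls[calls$clonality == "subclonal", , drop = FALSE]
    if (mode == "refit") {
      f_clo <- refit_signatures(build_catalog96(clo, pid), signatures,
                                cutoff, min_mutations)
      f_sub <- refit_signatures(build_catalog96(sub, pid), signatures,
                                cutoff, min_mutations)
      flagged <- f_clo$excluded || f_sub$excluded
      d <- if (flagged) NA_real_ else
        sum(f_clo$weights[apo]) - sum(f_sub$weights[apo])
    } else {
      fit <- refit_signatures(build_catalog96(calls, pid), signatures,
                              cutoff, min_mutations)
      flagged <- fit$excluded ||
        nrow(.classified(clo)) < min_mutations ||
        nrow(.classified(sub)) < min_mutations
      d <- NA_real_
      if (!flagged) {
        apo_frac <- function(part) {
          pc <- .classified(part)
          labs <- vapply(pc$channel, function(ch)
            attribute_mutation_signature(ch, fit, signatures)$label,
            character(1))
          mean(labs %in% apo)
        }
        d <- apo_frac(clo) - apo_frac(sub)
      }
    }
    data.frame(patient = pid, diff = d, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  per_patient <- do.call(rbind, rows)
  d_ok <- per_patient$diff[!per_patient$flagged]
  test <- if (length(d_ok) > 0 && any(d_ok != 0)) {
    wilcoxon_signed_rank_exact(d_ok, alternative = alternative)
  } else NULL
  list(per_patient = per_patient, test = test)
}
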