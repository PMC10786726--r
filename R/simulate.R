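#' Synthetic data generation
#'
#' Generators for every input the pipeline consumes: an i.i.d. reference
#' sequence, signature-mixture mutation catalogs placed at real reference
#' sites, paired pre-/post-treatment cohorts where the post sample adds an
#' APOBEC-context mutation burst, caller evidence (depths, alt reads, somatic
#' p-values, caller sets), and multi-region copy-number profiles with clonal
#' and region-restricted events. Every generator is bit-reproducible given its
#' seed, and restores the caller's RNG state.
#'
#' @name synthetic-data
NULL

#' Simulation specification
#'
#' Bundles the default study conditions used throughout: mutation catalogs of
#' 500 SNVs drawn from a 0.2/0.1/0.7 SBS2/SBS13/SBS5 mixture (an
#' APOBEC-active tumor with a clock-like background) on a 100 kb GC-balanced
#' reference, 70% clonal mutations, 2 tumor regions, and tumor sequencing
#' evidence around 60x depth.
#'
#' @param genome_length reference length in bp (>= 1000).
#' @param gc_fraction GC content of the i.i.d. reference.
#' @param n_mutations catalog size.
#' @param signature_weights named nonnegative weights summing to 1.
#' @param clonal_fraction Bernoulli probability of the "clonal" label.
#' @param n_regions number of tumor regions for copy-number simulation.
#' @param n_clonal_events,n_subclonal_events,event_bp copy-number event plan.
#' @param evidence caller evidence model (see [default_evidence_model()]).
#' @param seed integer seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(genome_length = 1e5, gc_fraction = 0.5,
                     n_mutations = 500,
                     signature_weights = c(SBS2 = 0.2, SBS13 = 0.1, SBS5 = 0.7),
                     clonal_fraction = 0.7, n_regions = 2,
                     n_clonal_events = 4, n_subclonal_events = 2,
                     event_bp = 5e6, evidence = default_evidence_model(),
                     seed = 17) {
  if (genome_length < 1000) stop("genome_length must be >= 1000")
  if (any(signature_weights < 0)) stop("signature weights must be >= 0")
  if (abs(sum(signature_weights) - 1) > 1e-9) {
    stop("signature weights must sum to 1")
  }
  if (n_mutations < 0) stop("n_mutations must be >= 0")
  structure(list(genome_length = genome_length, gc_fraction = gc_fraction,
                 n_mutations = n_mutations,
                 signature_weights = signature_weights,
                 clonal_fraction = clonal_fraction, n_regions = n_regions,
                 n_clonal_events = n_clonal_events,
                 n_subclonal_events = n_subclonal_events, event_bp = event_bp,
                 evidence = evidence, seed = seed),
            class = "sim_spec")
}

#' Simulate an i.i.d. reference sequence
#'
#' @param length sequence length (>= 1000 so context windows are plentiful).
#' @param gc_fraction target GC content; bases are drawn i.i.d. with
#'   P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2.
#' @param seed integer seed.
#' @param contig contig name (default "chr1").
#' @return A `ref_store` with one contig.
#' @export
simulate_reference <- function(length, gc_fraction = 0.5, seed = 17,
                               contig = "chr1") {
  if (length < 1000) stop("length must be >= 1000 for context extraction")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  ref_store(stats::setNames(seq, contig))
}

# index every position of a ref_store with a 5-mer window by its
# pyrimidine-oriented trinucleotide context (1..32) and strand orientation
.site_index <- function(ref) {
  ctx_levels <- unique(channel_context())  # 32 contexts, canonical order
  sites <- list()
  for (contig in names(ref$seq)) {
    chars <- strsplit(ref$seq[[contig]], "")[[1]]
    L <- length(chars)
    if (L < 5) next
    pos <- 3:(L - 2)
    five <- chars[pos - 1]; center <- chars[pos]; three <- chars[pos + 1]
    flipped <- center %in% c("A", "G")
    tri <- ifelse(flipped,
                  paste0(comp_base(three), comp_base(center), comp_base(five)),
                  paste0(five, center, three))
    ok <- !grepl("[^ACGT]", paste0(chars[pos - 2], tri, chars[pos + 2]))
    ctx <- match(tri, ctx_levels)
    keep <- ok & !is.na(ctx)
    sites[[contig]] <- data.frame(contig = contig, pos = pos[keep],
                                  context = ctx[keep], flipped = flipped[keep],
                                  stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, sites)
  attr(idx, "context_levels") <- ctx_levels
  idx
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Each mutation is drawn by (i) sampling one of the 96 channels from the
#' mixture spectrum reweighted by the reference's trinucleotide availability
#' (renormalized), then (ii) sampling a distinct reference site uniformly
#' among the sites carrying that channel's context on either strand;
#' purine-site mutations are emitted as the complementary substitution.
#' Clonality labels are Bernoulli(`clonal_fraction`).
#'
#' @param ref a `ref_store`.
#' @param signatures 96 x n signature matrix.
#' @param spec a [sim_spec()] (fields used: n_mutations, signature_weights,
#'   clonal_fraction, seed).
#' @param sample_id sample label for the emitted variants.
#' @return A variant data.frame with attribute `sampled_channel_counts`
#'   (the 96-vector of channel draws; rebuilding the catalog from the emitted
#'   variants reproduces it exactly).
#' @export
simulate_catalog <- function(ref, signatures, spec, sample_id = "S1") {
  w <- spec$signature_weights
  missing_sig <- setdiff(names(w), colnames(signatures))
  if (length(missing_sig) > 0) {
    stop("unknown signatures in weights: ", paste(missing_sig, collapse = ", "))
  }
  spectrum <- as.numeric(signatures[, names(w), drop = FALSE] %*% w)
  old <- local_rng(spec$seed)
  on.exit(restore_rng(old))
  idx <- .site_index(ref)
  avail <- tabulate(idx$context, nbins = 32)
  ctx_of_channel <- match(channel_context(), attr(idx, "context_levels"))
  p <- spectrum * avail[ctx_of_channel]
  zero <- spectrum > 0 & avail[ctx_of_channel] == 0
  if (any(zero)) {
    stop("no reference sites available for channel(s): ",
         paste(catalog96_channels()[zero], collapse = ", "))
  }
  empty <- variant_table(character(0), character(0), integer(0),
                         character(0), character(0))
  if (spec$n_mutations == 0) {
    attr(empty, "sampled_channel_counts") <-
      stats::setNames(integer(96), catalog96_channels())
    return(empty)
  }
  draws <- as.integer(stats::rmultinom(1, spec$n_mutations, p / sum(p)))
  alts <- channel_alt()
  rows <- list()
  for (ctx in 1:32) {
    chs <- which(ctx_of_channel == ctx)
    need <- sum(draws[chs])
    if (need == 0) next
    pool <- which(idx$context == ctx)
    if (length(pool) < need) {
      stop("context ", attr(idx, "context_levels")[ctx], " has ",
           length(pool), " sites but ", need, " mutations requested")
    }
    picked <- pool[sample.int(length(pool), need)]
    ch_per_mut <- rep(chs, draws[chs])
    site <- idx[picked, , drop = FALSE]
    alt_pyr <- alts[ch_per_mut]
    ref_base <- ifelse(site$flipped, comp_base(substr(
      attr(idx, "context_levels")[ctx], 2, 2)), substr(
      attr(idx, "context_levels")[ctx], 2, 2))
    alt_base <- ifelse(site$flipped, comp_base(alt_pyr), alt_pyr)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = site$contig, pos = site$pos, ref = ref_base, alt = alt_base,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  clonality <- ifelse(stats::rbinom(nrow(df), 1, spec$clonal_fraction) == 1,
                      "clonal", "subclonal")
  out <- variant_table(sample_id = sample_id, chrom = df$chrom, pos = df$pos,
                       ref = df$ref, alt = df$alt, callers = "simulated",
                       clonality = clonality)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sampled_channel_counts") <-
    stats::setNames(draws, catalog96_channels())
  out
}

#' Simulate a paired pre-/post-treatment cohort with an APOBEC burst
#'
#' For each patient the pre-treatment variants are drawn from `spec_pre`; the
#' post-treatment sample contains every pre-treatment variant plus `n_extra`
#' burst mutations. With `tcw_only = TRUE` (default) burst mutations are
#' placed at unused TCW sites (either strand) as C>T or C>G with the given
#' odds, emulating APOBEC mutagenesis acquired under therapy; burst mutations
#' are labeled subclonal.
#'
#' @param ref a `ref_store`.
#' @param signatures signature matrix.
#' @param spec_pre [sim_spec()] for the pre-treatment catalogs.
#' @param burst list with `n_extra` (default 50), `tcw_only` (default TRUE),
#'   `ct_cg_odds` (C>T : C>G odds, default 2).
#' @param n_patients number of pairs.
#' @param seed cohort seed; patient i uses seed + i for its pre catalog.
#' @return Named list (one element per patient) of lists with `pre` and
#'   `post` variant data.frames.
#' @export
simulate_paired_cohort <- function(ref, signatures, spec_pre,
                                   burst = list(n_extra = 50, tcw_only = TRUE,
                                                ct_cg_odds = 2),
                                   n_patients = 8, seed = 17) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  n_extra <- burst$n_extra %||% 50
  tcw_only <- burst$tcw_only %||% TRUE
  odds <- burst$ct_cg_odds %||% 2
  idx <- .site_index(ref)
  ctx_levels <- attr(idx, "context_levels")
  tcw_ctx <- match(c("TCA", "TCT"), ctx_levels)
  out <- list()
  for (i in seq_len(n_patients)) {
    spec_i <- spec_pre
    spec_i$seed <- seed + i
    pid <- sprintf("P%02d", i)
    pre <- simulate_catalog(ref, signatures, spec_i,
                            sample_id = paste0(pid, "_pre"))
    old <- local_rng(seed + 100000L + i)
    if (n_extra > 0) {
      pool_ctx <- if (tcw_only) tcw_ctx else seq_along(ctx_levels)
      pool <- which(idx$context %in% pool_ctx &
                      !(paste(idx$contig, idx$pos) %in%
                          paste(pre$chrom, pre$pos)))
      if (length(pool) < n_extra) {
        restore_rng(old)
        stop("insufficient unused TCW sites for the burst (",
             length(pool), " < ", n_extra, ")")
      }
      picked <- idx[pool[sample.int(length(pool), n_extra)], , drop = FALSE]
      alt_pyr <- ifelse(stats::runif(n_extra) < odds / (odds + 1), "T", "G")
      extra <- variant_table(
        sample_id = paste0(pid, "_post"), chrom = picked$contig,
        pos = picked$pos,
        ref = ifelse(picked$flipped, "G", "C"),
        alt = ifelse(picked$flipped, comp_base(alt_pyr), alt_pyr),
        callers = "simulated", clonality = "subclonal")
    } else {
      extra <- NULL
    }
    restore_rng(old)
    post <- pre
    post$sample_id <- paste0(pid, "_post")
    post <- rbind(post, extra)
    post <- post[order(post$chrom, post$pos), , drop = FALSE]
    rownames(post) <- NULL
    out[[pid]] <- list(pre = pre, post = post)
  }
  out
}

#' Simulate multi-region copy-number segments
#'
#' Plants `n_clonal_events` (same non-diploid copy number in every region) and
#' `n_subclonal_events` (altered in a strict subset of regions) on disjoint
#' intervals of `event_bp` each, on a synthetic genome of `genome_bp`, then
#' fills the rest of each region with baseline segments so all regions share
#' the genome extent.
#'
#' @param spec a [sim_spec()] (fields: n_regions, n_clonal_events,
#'   n_subclonal_events, event_bp, seed).
#' @param tumor_id tumor label.
#' @param genome_bp simulated genome size (default 100 Mb).
#' @param baseline_cn diploid baseline (default 2).
#' @return Segment data.frame (0-based half-open) with attributes
#'   `ground_truth`: list(heterogeneous_bp, altered_bp, ith).
#' @export
simulate_multiregion_segments <- function(spec, tumor_id = "T1",
                                          genome_bp = 1e8, baseline_cn = 2) {
  if (spec$n_regions < 2) stop("need n_regions >= 2")
  n_ev <- spec$n_clonal_events + spec$n_subclonal_events
  if (n_ev * spec$event_bp > genome_bp) {
    stop("requested event mass exceeds the genome")
  }
  old <- local_rng(spec$seed)
  on.exit(restore_rng(old))
  regions <- sprintf("R%d", seq_len(spec$n_regions))
  # evenly spaced disjoint event intervals
  gap <- (genome_bp - n_ev * spec$event_bp) / (n_ev + 1)
  starts <- round(gap + (seq_len(n_ev) - 1) * (spec$event_bp + gap))
  ends <- starts + spec$event_bp
  kind <- sample(rep(c("clonal", "subclonal"),
                     c(spec$n_clonal_events, spec$n_subclonal_events)))
  cn_states <- matrix(baseline_cn, nrow = spec$n_regions, ncol = n_ev)
  for (e in seq_len(n_ev)) {
    ev_cn <- sample(c(baseline_cn - 1, baseline_cn + 1, baseline_cn + 2), 1)
    if (kind[e] == "clonal") {
      cn_states[, e] <- ev_cn
    } else {
      k <- sample.int(spec$n_regions - 1, 1)  # strict subset, non-empty
      cn_states[sample.int(spec$n_regions, k), e] <- ev_cn
    }
  }
  rows <- list()
  for (ri in seq_len(spec$n_regions)) {
    bks <- sort(unique(c(0, starts, ends, genome_bp)))
    for (j in seq_len(length(bks) - 1)) {
      lo <- bks[j]; hi <- bks[j + 1]
      e <- which(starts <= lo & ends >= hi)
      cn <- if (length(e) == 1) cn_states[ri, e] else baseline_cn
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = tumor_id, region_id = regions[ri], chrom = "chr1",
        start = lo, end = hi, total_cn = cn, stringsAsFactors = FALSE)
    }
  }
  seg <- validate_segments(do.call(rbind, rows))
  het_bp <- sum(spec$event_bp *
                  (kind == "subclonal" |
                     apply(cn_states, 2, function(x) length(unique(x)) > 1)))
  alt_bp <- n_ev * spec$event_bp
  attr(seg, "ground_truth") <- list(
    heterogeneous_bp = het_bp, altered_bp = alt_bp,
    ith = if (alt_bp == 0) NA_real_ else het_bp / alt_bp)
  seg
}

#' Default caller evidence model
#'
#' Depths are Poisson around `depth_mean`; the latent VAF is Beta-distributed
#' with a clonality-specific mean (clonal tumors around 0.4, subclonal around
#' 0.15) and concentration `vaf_concentration`; alt reads are Binomial(depth,
#' VAF); somatic p-values of true somatic calls are Beta(0.5, 50) (small);
#' each caller detects a variant with probability `min(1, vaf / vaf50)`.
#'
#' @param depth_mean mean tumor depth (default 60).
#' @param vaf_mean named means per clonality label.
#' @param vaf_concentration Beta concentration (default 30).
#' @param callers named list: per caller, the VAF at which detection
#'   saturates (`vaf50`).
#' @return Evidence model list.
#' @export
default_evidence_model <- function(depth_mean = 60,
                                   vaf_mean = c(clonal = 0.4,
                                                subclonal = 0.15,
                                                unknown = 0.25),
                                   vaf_concentration = 30,
                                   callers = list(varscan2 = 0.02,
                                                  mutect = 0.03)) {
  list(depth_mean = depth_mean, vaf_mean = vaf_mean,
       vaf_concentration = vaf_concentration, callers = callers)
}

#' Simulate caller evidence for a set of true variants
#'
#' @param variants variant data.frame (e.g. from [simulate_catalog()]).
#' @param model evidence model (see [default_evidence_model()]).
#' @param seed integer seed.
#' @return The variants annotated with depth, alt reads, realized VAF,
#'   somatic p and detecting caller set; variants detected by no caller are
#'   dropped (attribute `n_dropped`).
#' @export
simulate_caller_calls <- function(variants, model = default_evidence_model(),
                                  seed = 17) {
  v <- validate_variants(variants)
  n <- nrow(v)
  if (n == 0) return(v)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  mu <- model$vaf_mean[v$clonality]
  conc <- model$vaf_concentration
  true_vaf <- stats::rbeta(n, mu * conc, (1 - mu) * conc)
  depth <- pmax(1L, stats::rpois(n, model$depth_mean))
  alt <- stats::rbinom(n, depth, true_vaf)
  v$depth_tumor <- as.integer(depth)
  v$alt_reads_tumor <- as.integer(alt)
  v$vaf_tumor <- alt / depth
  v$somatic_p <- stats::rbeta(n, 0.5, 50)
  v$alt_reads_normal <- 0L
  v$vaf_normal <- 0
  v$caller_pass <- TRUE
  det <- matrix(FALSE, n, length(model$callers))
  for (j in seq_along(model$callers)) {
    pdet <- pmin(1, true_vaf / model$callers[[j]])
    det[, j] <- stats::runif(n) < pdet
  }
  v$callers <- apply(det, 1, function(row) {
    paste(names(model$callers)[row], collapse = ",")
  })
  keep <- v$callers != ""
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "true_vaf_mean") <- mean(true_vaf)
  validate_variants(out)
}
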