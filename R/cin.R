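#' Copy-number intratumor heterogeneity and missegregation metrics
#'
#' @name cin-metrics
NULL

#' SCNA intratumor heterogeneity of a multi-region tumor
#'
#' All regions are overlaid into disjoint intervals of constant per-region
#' copy number (bases not covered by a segment take the baseline). A base is
#' *altered* when any region's copy number differs from the baseline, and
#' *heterogeneous* when, additionally, the regions do not all share the same
#' copy-number state there (the alteration is not present identically in
#' every region). The metric is heterogeneous bases / altered bases,
#' base-pair weighted across the genome.
#'
#' @param segments segment data.frame for one tumor (columns of
#'   [read_segments()]); coordinates 0-based half-open.
#' @param baseline_cn unaltered copy number (default 2).
#' @return List with `ith` (in \[0,1\]), `heterogeneous_bp`, `altered_bp`.
#'   Errors when fewer than 2 regions; `ith` is NA (undefined) when no base
#'   is altered.
#' @export
scna_ith <- function(segments, baseline_cn = 2) {
  s <- validate_segments(segments)
  if (length(unique(s$tumor_id)) != 1) stop("segments must be a single tumor")
  regions <- sort(unique(s$region_id))
  if (length(regions) < 2) stop("SCNA ITH needs at least 2 regions")
  het_bp <- 0
  alt_bp <- 0
  for (ch in unique(s$chrom)) {
    sc <- s[s$chrom == ch, , drop = FALSE]
    bks <- sort(unique(c(sc$start, sc$end)))
    if (length(bks) < 2) next
    lo <- bks[-length(bks)]
    hi <- bks[-1]
    width <- hi - lo
    # region x interval copy-number matrix, baseline where uncovered
    cn <- matrix(baseline_cn, nrow = length(regions), ncol = length(lo))
    for (ri in seq_along(regions)) {
      sr <- sc[sc$region_id == regions[ri], , drop = FALSE]
      for (si in seq_len(nrow(sr))) {
        cover <- lo >= sr$start[si] & hi <= sr$end[si]
        cn[ri, cover] <- sr$total_cn[si]
      }
    }
    altered <- colSums(cn != baseline_cn) > 0
    uniform <- apply(cn, 2, function(col) length(unique(col)) == 1)
    het <- altered & !uniform
    alt_bp <- alt_bp + sum(width[altered])
    het_bp <- het_bp + sum(width[het])
  }
  list(ith = if (alt_bp == 0) NA_real_ else het_bp / alt_bp,
       heterogeneous_bp = het_bp, altered_bp = alt_bp)
}

#' Group percentage of chromosome missegregation errors
#'
#' Per subject, percent = 100 * errors / anaphases, optionally divided by a
#' recombination efficiency (e.g. 0.82 when only 82% of cells express the
#' transgene), capped at 100. The group value is the harmonic mean of the
#' per-subject percentages.
#'
#' @param counts data.frame with columns `subject_id`, `errors` (lagging
#'   chromosomes + anaphase bridges), `anaphases`.
#' @param normalize_efficiency optional fraction in (0, 1\]; per-subject
#'   percentages are divided by it.
#' @param zero_policy the harmonic mean is undefined when any subject has
#'   zero errors: `"strict"` (default) errors out, `"pooled"` falls back to
#'   the pooled 100 * sum(errors) / sum(anaphases) with a warning.
#' @return List with `group_percent`, `per_subject` (data.frame with the
#'   normalized percentages), `method` ("harmonic" or "pooled").
#' @export
missegregation_percent <- function(counts, normalize_efficiency = NULL,
                                   zero_policy = c("strict", "pooled")) {
  zero_policy <- match.arg(zero_policy)
  need <- c("subject_id", "errors", "anaphases")
  if (!all(need %in% names(counts))) {
    stop("counts needs columns: ", paste(need, collapse = ", "))
  }
  if (any(counts$anaphases <= 0)) stop("anaphases must be positive")
  if (any(counts$errors < 0) || any(counts$errors > counts$anaphases)) {
    stop("errors must lie in [0, anaphases]")
  }
  if (!is.null(normalize_efficiency) &&
      (normalize_efficiency <= 0 || normalize_efficiency > 1)) {
    stop("normalize_efficiency must be in (0, 1]")
  }
  pct <- 100 * counts$errors / counts$anaphases
  if (!is.null(normalize_efficiency)) {
    pct <- pmin(100, pct / normalize_efficiency)
  }
  per_subject <- data.frame(subject_id = counts$subject_id, percent = pct,
                            stringsAsFactors = FALSE)
  if (any(pct == 0)) {
    if (zero_policy == "strict") {
      stop("harmonic mean undefined: subject(s) with zero errors (",
           paste(counts$subject_id[pct == 0], collapse = ", "),
           "); use zero_policy = \"pooled\"")
    }
    warning("zero-error subject: falling back to pooled errors/anaphases")
    pooled <- 100 * sum(counts$errors) / sum(counts$anaphases)
    if (!is.null(normalize_efficiency)) {
      pooled <- min(100, pooled / normalize_efficiency)
    }
    return(list(group_percent = pooled, per_subject = per_subject,
                method = "pooled"))
  }
  list(group_percent = length(pct) / sum(1 / pct), per_subject = per_subject,
       method = "harmonic")
}
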