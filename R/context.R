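#' Pyrimidine-oriented sequence context classification
#'
#' Every somatic SNV is oriented so that its reference base is a pyrimidine
#' (C or T): when the reference base is a purine, the substitution and its
#' sequence window are reverse-complemented. APOBEC-relevant classes are then
#' read off the tri-/pentanucleotide around the mutated base:
#' \describe{
#'   \item{TCN}{C>T or C>G at a cytosine preceded by T (any 3' base)}
#'   \item{TCW}{TCN with 3' base W = A or T}
#'   \item{RTCW}{TCW with 5' base R = A or G (APOBEC3B-preferred)}
#'   \item{YTCW}{TCW with 5' base Y = C or T (APOBEC3A-preferred)}
#' }
#' RTCW and YTCW partition TCW because the 5' base is always one of A/C/G/T.
#'
#' @name context-classes
NULL

#' Classify SNVs by tri- and pentanucleotide context
#'
#' @param ref a `ref_store` (see [read_fasta()]).
#' @param variants variant data.frame; non-SNV rows are marked `skipped`.
#' @return The variant table with added columns: `skipped` (non-SNV),
#'   `context_ok` (FALSE when the pentanucleotide window runs off the contig
#'   or contains N — such calls are excluded from all statistics and counted
#'   in the `n_no_context` attribute), `trinucleotide`, `pentanucleotide`
#'   (pyrimidine-oriented), `substitution` (e.g. "C>T"), `strand_flipped`,
#'   `channel` (1..96), and logical flags `is_c_to_t_or_g`, `is_tcn`,
#'   `is_tcw`, `is_rtcw`, `is_ytcw`.
#' @export
extract_context <- function(ref, variants) {
  v <- validate_variants(variants)
  n <- nrow(v)
  out <- v
  out$skipped <- !is_snv(v)
  out$context_ok <- logical(n)
  out$trinucleotide <- rep(NA_character_, n)
  out$pentanucleotide <- rep(NA_character_, n)
  out$substitution <- rep(NA_character_, n)
  out$strand_flipped <- rep(NA, n)
  out$channel <- rep(NA_integer_, n)
  for (flag in c("is_c_to_t_or_g", "is_tcn", "is_tcw", "is_rtcw", "is_ytcw")) {
    out[[flag]] <- rep(NA, n)
  }
  for (i in seq_len(n)) {
    if (out$skipped[i]) next
    penta <- fetch_context(ref, v$chrom[i], v$pos[i], k = 5)
    if (is.na(penta)) next
    center <- substr(penta, 3, 3)
    if (center != v$ref[i]) {
      stop("reference mismatch at ", v$chrom[i], ":", v$pos[i],
           ": variant ref ", v$ref[i], ", reference base ", center)
    }
    alt <- v$alt[i]
    flipped <- center %in% c("A", "G")
    if (flipped) {
      penta <- revcomp(penta)
      center <- substr(penta, 3, 3)
      alt <- comp_base(alt)
    }
    tri <- substr(penta, 2, 4)
    sub <- paste0(center, ">", alt)
    five2 <- substr(penta, 1, 1)   # base 5' of the trinucleotide
    five1 <- substr(penta, 2, 2)
    three1 <- substr(penta, 4, 4)
    ctog <- center == "C" && alt %in% c("T", "G")
    tcn <- ctog && five1 == "T"
    tcw <- tcn && three1 %in% c("A", "T")
    rtcw <- tcw && five2 %in% c("A", "G")
    ytcw <- tcw && five2 %in% c("C", "T")
    out$context_ok[i] <- TRUE
    out$trinucleotide[i] <- tri
    out$pentanucleotide[i] <- penta
    out$substitution[i] <- sub
    out$strand_flipped[i] <- flipped
    out$channel[i] <- channel_index(tri, sub)
    out$is_c_to_t_or_g[i] <- ctog
    out$is_tcn[i] <- tcn
    out$is_tcw[i] <- tcw
    out$is_rtcw[i] <- rtcw
    out$is_ytcw[i] <- ytcw
  }
  attr(out, "n_no_context") <- sum(!out$skipped & !out$context_ok)
  attr(out, "n_skipped") <- sum(out$skipped)
  out
}

# rows usable for context statistics
.classified <- function(calls) {
  calls[!calls$skipped & calls$context_ok, , drop = FALSE]
}

#' APOBEC context fractions for one sample
#'
#' Each fraction is the number of C>T/C>G mutations in the given context
#' divided by the total number of classified mutations in the sample (all
#' substitution classes).
#'
#' @param calls output of [extract_context()] for one sample.
#' @return List with `frac_tcn`, `frac_tcw`, `frac_rtcw`, `frac_ytcw` and the
#'   denominator `n_total`. `frac_rtcw + frac_ytcw == frac_tcw` always.
#' @export
apobec_fractions <- function(calls) {
  cc <- .classified(calls)
  n <- nrow(cc)
  if (n == 0) stop("no classified mutations: fractions undefined")
  list(
    frac_tcn = sum(cc$is_tcn) / n,
    frac_tcw = sum(cc$is_tcw) / n,
    frac_rtcw = sum(cc$is_rtcw) / n,
    frac_ytcw = sum(cc$is_ytcw) / n,
    n_total = n
  )
}

#' Count APOBEC-context mutations, optionally by clonality
#'
#' An APOBEC-associated mutation is a C>T or C>G substitution in a TCN
#' trinucleotide context.
#'
#' @param calls output of [extract_context()].
#' @param stratify_by_clonality when TRUE, also return the 2x2 breakdown
#'   \{clonal, subclonal\} x \{APOBEC, non-APOBEC\}; every classified call must
#'   then carry a clonal/subclonal label.
#' @return List with `n_total`, `n_apobec`, and (stratified) `by_clonality`,
#'   a 2x2 integer table whose entries sum to `n_total`.
#' @export
count_apobec_mutations <- function(calls, stratify_by_clonality = FALSE) {
  cc <- .classified(calls)
  res <- list(n_total = nrow(cc), n_apobec = sum(cc$is_tcn))
  if (stratify_by_clonality) {
    bad <- cc$clonality == "unknown"
    if (any(bad)) {
      stop("clonality unknown for ", sum(bad), " variant(s), e.g. ",
           cc$chrom[bad][1], ":", cc$pos[bad][1])
    }
    tab <- table(
      clonality = factor(cc$clonality, levels = c("clonal", "subclonal")),
      class = factor(ifelse(cc$is_tcn, "APOBEC", "non-APOBEC"),
                     levels = c("APOBEC", "non-APOBEC"))
    )
    res$by_clonality <- tab
  }
  res
}
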