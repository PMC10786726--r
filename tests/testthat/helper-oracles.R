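# Independent oracles, deliberately coded differently from the package paths.

# --- naive double-strand context scanner -------------------------------
# Enumerates APOBEC context patterns explicitly on both strands instead of
# reverse-complement normalization.
.oc_comp <- c(A = "T", C = "G", G = "C", T = "A")
.oc_rc <- function(s) paste(rev(.oc_comp[strsplit(s, "")[[1]]]), collapse = "")

naive_context_flags <- function(seq, pos, ref, alt) {
  L <- nchar(seq)
  if (pos < 3 || pos > L - 2) return(NULL)
  p5 <- substr(seq, pos - 2, pos + 2)
  if (grepl("[^ACGT]", p5)) return(NULL)
  stopifnot(substr(p5, 3, 3) == ref)
  tcn_pat <- paste0("T", "C", c("A", "C", "G", "T"))
  tcw_pat <- paste0("T", "C", c("A", "T"))
  rtcw_pat <- as.vector(outer(c("A", "G"), tcw_pat, paste0))
  ytcw_pat <- as.vector(outer(c("C", "T"), tcw_pat, paste0))
  flags <- list(is_c_to_t_or_g = FALSE, is_tcn = FALSE, is_tcw = FALSE,
                is_rtcw = FALSE, is_ytcw = FALSE)
  for (strand in c("+", "-")) {
    if (strand == "+") {
      penta <- p5; a <- alt
    } else {
      penta <- .oc_rc(p5); a <- unname(.oc_comp[alt])
    }
    if (substr(penta, 3, 3) != "C") next  # scan only cytosine-centered strand
    if (!a %in% c("T", "G")) { flags$is_c_to_t_or_g <- FALSE; next }
    flags$is_c_to_t_or_g <- TRUE
    tri <- substr(penta, 2, 4)
    tetra4 <- substr(penta, 1, 4)
    flags$is_tcn <- tri %in% tcn_pat
    flags$is_tcw <- tri %in% tcw_pat
    flags$is_rtcw <- tetra4 %in% rtcw_pat
    flags$is_ytcw <- tetra4 %in% ytcw_pat
  }
  # T-centered on both strands cannot happen; C>x with x not T/G:
  if (!flags$is_c_to_t_or_g) {
    flags <- list(is_c_to_t_or_g = FALSE, is_tcn = FALSE, is_tcw = FALSE,
                  is_rtcw = FALSE, is_ytcw = FALSE)
  }
  flags
}

# --- naive filter evaluators -------------------------------------------
naive_snv_mouse <- function(v) {
  if (anyNA(c(v$depth_tumor, v$alt_reads_tumor, v$vaf_tumor, v$somatic_p))) {
    return(NA)
  }
  has_mutect <- "mutect" %in% strsplit(v$callers, ",")[[1]]
  ok_vaf <- if (v$vaf_tumor >= 0.05) TRUE else
    if (v$vaf_tumor >= 0.02 && has_mutect) TRUE else FALSE
  v$depth_tumor >= 30 && v$alt_reads_tumor >= 5 && v$somatic_p < 0.01 && ok_vaf
}

naive_indel_mouse <- function(v) {
  if (anyNA(c(v$depth_tumor, v$alt_reads_tumor, v$vaf_tumor, v$somatic_p))) {
    return(NA)
  }
  cl <- strsplit(v$callers, ",")[[1]]
  ("scalpel" %in% cl) && ("varscan2" %in% cl) && v$somatic_p < 0.001 &&
    v$depth_tumor >= 50 && v$alt_reads_tumor >= 10 && v$vaf_tumor >= 0.02
}

naive_germline <- function(v) {
  if (anyNA(c(v$alt_reads_normal, v$vaf_normal))) return(NA)
  !(v$alt_reads_normal > 5 || v$vaf_normal > 0.01)
}

naive_wgs_cellline <- function(v) {
  if (anyNA(c(v$depth_tumor, v$alt_reads_tumor, v$vaf_tumor, v$caller_pass))) {
    return(NA)
  }
  v$caller_pass && v$depth_tumor > 30 && v$alt_reads_tumor >= 4 &&
    v$vaf_tumor > 0.05
}

# --- brute-force Mann-Whitney ------------------------------------------
# p by enumerating every group-1 labeling of the pooled sample
brute_mwu_two_sided <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  lo <- min(u_obs, n1 * length(y) - u_obs)
  min(1, 2 * mean(all_u <= lo))
}

# --- NNLS refit oracle --------------------------------------------------
nnls_weights <- function(catalog, signatures) {
  obs <- as.numeric(catalog) / sum(catalog)
  w <- pracma::lsqnonneg(signatures, obs)$x
  names(w) <- colnames(signatures)
  w / sum(w)
}
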