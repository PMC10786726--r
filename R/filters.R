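#' Post-caller somatic filter cascades
#'
#' Pure, auditable pass/fail rules applied to caller output. Threshold wording
#' maps to operators literally: "minimum X" / "at least X" mean `>= X`;
#' "over X" / "greater than X" / "more than X" mean strict `> X`; p-value
#' thresholds are strict `<`. Every decision names the rules it failed;
#' variants lacking the evidence a cascade needs get an error decision, never
#' a silent pass.
#'
#' @name filter-cascades
NULL

#' Caller label presets
#'
#' @return Named list mapping roles to caller labels for the supported
#'   presets: `"mouse-wes"` (VarScan2 primary, MuTect rescue, Scalpel+VarScan2
#'   for indels) and `"cellline-wgs"` (MuTect2).
#' @export
caller_presets <- function() {
  list(
    "mouse-wes" = list(primary = "varscan2", rescue = "mutect",
                       indel_primary = "varscan2", indel_second = "scalpel"),
    "cellline-wgs" = list(primary = "mutect2")
  )
}

has_caller <- function(callers, label) {
  vapply(strsplit(callers, ",", fixed = TRUE),
         function(x) label %in% trimws(x), logical(1))
}

.decision_frame <- function(variants, required, rule_fns) {
  v <- validate_variants(variants)
  n <- nrow(v)
  passed <- logical(n)
  failed_rules <- character(n)
  error <- logical(n)
  error_reason <- character(n)
  for (i in seq_len(n)) {
    miss <- required[vapply(required, function(col) is.na(v[[col]][i]),
                            logical(1))]
    if (length(miss) > 0) {
      error[i] <- TRUE
      error_reason[i] <- paste("missing evidence:", paste(miss, collapse = ", "))
      next
    }
    fails <- character(0)
    for (rule in names(rule_fns)) {
      if (!isTRUE(rule_fns[[rule]](v[i, , drop = FALSE]))) {
        fails <- c(fails, rule)
      }
    }
    passed[i] <- length(fails) == 0
    failed_rules[i] <- paste(fails, collapse = ",")
  }
  data.frame(sample_id = v$sample_id, chrom = v$chrom, pos = v$pos,
             ref = v$ref, alt = v$alt, passed = passed,
             failed_rules = failed_rules, error = error,
             error_reason = error_reason, stringsAsFactors = FALSE)
}

#' Mouse WES SNV filter
#'
#' Pass requires: tumor depth >= 30, alt reads >= 5, somatic p < 0.01, and
#' VAF >= 5%; calls with VAF in \[2%, 5%) are rescued only when the second
#' caller (MuTect) also detected them; VAF < 2% always fails.
#'
#' @param variants variant data.frame (VarScan2 evidence in the standard
#'   columns).
#' @param preset caller label preset name (see [caller_presets()]).
#' @return Decision data.frame: one row per variant with `passed`,
#'   `failed_rules` (comma list), `error`, `error_reason`.
#' @export
filter_snv_mouse <- function(variants, preset = "mouse-wes") {
  p <- caller_presets()[[preset]]
  .decision_frame(
    variants,
    required = c("depth_tumor", "alt_reads_tumor", "vaf_tumor", "somatic_p"),
    rule_fns = list(
      min_depth = function(v) v$depth_tumor >= 30,
      min_alt_reads = function(v) v$alt_reads_tumor >= 5,
      somatic_p = function(v) v$somatic_p < 0.01,
      min_vaf = function(v) v$vaf_tumor >= 0.05 ||
        (v$vaf_tumor >= 0.02 && has_caller(v$callers, p$rescue))
    )
  )
}

#' Mouse WES indel filter
#'
#' Pass requires detection by both Scalpel and VarScan2, VarScan2 somatic
#' p < 0.001, depth >= 50, alt reads >= 10 and VAF >= 2%.
#'
#' @inheritParams filter_snv_mouse
#' @return Decision data.frame (see [filter_snv_mouse()]).
#' @export
filter_indel_mouse <- function(variants, preset = "mouse-wes") {
  p <- caller_presets()[[preset]]
  .decision_frame(
    variants,
    required = c("depth_tumor", "alt_reads_tumor", "vaf_tumor", "somatic_p"),
    rule_fns = list(
      both_callers = function(v) has_caller(v$callers, p$indel_primary) &&
        has_caller(v$callers, p$indel_second),
      somatic_p = function(v) v$somatic_p < 0.001,
      min_depth = function(v) v$depth_tumor >= 50,
      min_alt_reads = function(v) v$alt_reads_tumor >= 10,
      min_vaf = function(v) v$vaf_tumor >= 0.02
    )
  )
}

#' Germline contamination filter
#'
#' A variant is removed when the matched germline sample shows more than 5
#' alternative reads or a normal VAF greater than 1% (both strict).
#'
#' @inheritParams filter_snv_mouse
#' @return Decision data.frame; `passed` means the variant is kept as somatic.
#' @export
filter_germline <- function(variants) {
  .decision_frame(
    variants,
    required = c("alt_reads_normal", "vaf_normal"),
    rule_fns = list(
      germline_alt_reads = function(v) !(v$alt_reads_normal > 5),
      germline_vaf = function(v) !(v$vaf_normal > 0.01)
    )
  )
}

#' Cell-line WGS SNV filter
#'
#' Pass requires the caller's own PASS status, depth over 30 (strict), at
#' least 4 alt reads, and VAF greater than 0.05 (strict).
#'
#' @inheritParams filter_snv_mouse
#' @return Decision data.frame (see [filter_snv_mouse()]).
#' @export
filter_wgs_cellline <- function(variants, preset = "cellline-wgs") {
  .decision_frame(
    variants,
    required = c("depth_tumor", "alt_reads_tumor", "vaf_tumor", "caller_pass"),
    rule_fns = list(
      caller_pass = function(v) isTRUE(v$caller_pass),
      min_depth = function(v) v$depth_tumor > 30,
      min_alt_reads = function(v) v$alt_reads_tumor >= 4,
      min_vaf = function(v) v$vaf_tumor > 0.05
    )
  )
}

#' Audit summary of a filter decision table
#'
#' @param decisions decision data.frame from one of the filter cascades.
#' @return List with `n_input`, `n_pass`, `n_fail`, `n_error`; the three
#'   outcome counts always sum to `n_input`.
#' @export
filter_audit <- function(decisions) {
  list(n_input = nrow(decisions),
       n_pass = sum(decisions$passed & !decisions$error),
       n_fail = sum(!decisions$passed & !decisions$error),
       n_error = sum(decisions$error))
}
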