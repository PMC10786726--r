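#' Somatic variant call tables
#'
#' Variants are plain data.frames with one row per somatic call. Coordinates
#' are 1-based inclusive (VCF convention). Columns:
#' \describe{
#'   \item{sample_id}{sample label}
#'   \item{chrom, pos, ref, alt}{locus and alleles; `pos >= 1`, `ref != alt`}
#'   \item{vaf_tumor}{variant allele frequency in the tumor, in \[0,1\] or NA}
#'   \item{depth_tumor, alt_reads_tumor}{read counts (NA allowed);
#'     `alt_reads_tumor <= depth_tumor` when both present}
#'   \item{somatic_p}{primary caller's somatic p-value, or NA}
#'   \item{callers}{comma-separated caller labels, non-empty}
#'   \item{caller_pass}{logical: did the call pass the caller's internal
#'     filter (VCF FILTER == PASS); NA when unknown}
#'   \item{alt_reads_normal, vaf_normal}{matched-normal evidence, NA allowed}
#'   \item{clonality}{"clonal", "subclonal" or "unknown"}
#' }
#'
#' @param sample_id,chrom,pos,ref,alt,vaf_tumor,depth_tumor,alt_reads_tumor,somatic_p,callers,caller_pass,alt_reads_normal,vaf_normal,clonality
#'   column values, recycled to a common length.
#' @return A validated variant data.frame.
#' @export
variant_table <- function(sample_id, chrom, pos, ref, alt,
                          vaf_tumor = NA_real_, depth_tumor = NA_integer_,
                          alt_reads_tumor = NA_integer_, somatic_p = NA_real_,
                          callers = "unknown", caller_pass = NA,
                          alt_reads_normal = NA_integer_,
                          vaf_normal = NA_real_, clonality = "unknown") {
  n <- max(length(sample_id), length(chrom), length(pos))
  if (length(chrom) == 0) n <- 0
  r <- function(x) if (n == 0) x[0] else rep_len(x, n)
  df <- data.frame(
    sample_id = r(as.character(sample_id)), chrom = r(as.character(chrom)),
    pos = r(as.integer(pos)), ref = r(as.character(ref)),
    alt = r(as.character(alt)),
    vaf_tumor = r(as.numeric(vaf_tumor)),
    depth_tumor = r(as.integer(depth_tumor)),
    alt_reads_tumor = r(as.integer(alt_reads_tumor)),
    somatic_p = r(as.numeric(somatic_p)), callers = r(as.character(callers)),
    caller_pass = r(as.logical(caller_pass)),
    alt_reads_normal = r(as.integer(alt_reads_normal)),
    vaf_normal = r(as.numeric(vaf_normal)),
    clonality = r(as.character(clonality)),
    stringsAsFactors = FALSE
  )
  validate_variants(df)
}

variant_columns <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "vaf_tumor", "depth_tumor",
    "alt_reads_tumor", "somatic_p", "callers", "caller_pass",
    "alt_reads_normal", "vaf_normal", "clonality")
}

#' Validate a variant table against its invariants
#'
#' Checks positions, allele distinctness, VAF ranges, read-count consistency
#' and clonality labels; stops with an informative error naming the first
#' offending row.
#'
#' @param variants a variant data.frame (see [variant_table()]).
#' @return the input, invisibly unchanged, if valid.
#' @export
validate_variants <- function(variants) {
  missing_cols <- setdiff(variant_columns(), names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0) {
      stop("invalid variant record (row ", bad[1], "): ", what, call. = FALSE)
    }
  }
  v <- variants
  fail(is.na(v$pos) | v$pos < 1, "pos must be >= 1")
  fail(v$ref == v$alt, "ref and alt alleles must differ")
  fail(!is.na(v$vaf_tumor) & (v$vaf_tumor < 0 | v$vaf_tumor > 1),
       "vaf_tumor outside [0,1]")
  fail(!is.na(v$vaf_normal) & (v$vaf_normal < 0 | v$vaf_normal > 1),
       "vaf_normal outside [0,1]")
  fail(!is.na(v$alt_reads_tumor) & !is.na(v$depth_tumor) &
         v$alt_reads_tumor > v$depth_tumor,
       "alt_reads_tumor exceeds depth_tumor")
  fail(!is.na(v$somatic_p) & (v$somatic_p < 0 | v$somatic_p > 1),
       "somatic_p outside [0,1]")
  fail(is.na(v$callers) | v$callers == "", "callers must be non-empty")
  fail(!v$clonality %in% c("clonal", "subclonal", "unknown"),
       "clonality must be clonal/subclonal/unknown")
  v
}

#' Is a variant a single-nucleotide substitution?
#'
#' @param variants a variant data.frame.
#' @return logical vector; TRUE where both alleles are single A/C/G/T bases.
#' @export
is_snv <- function(variants) {
  variants$ref %in% .BASES & variants$alt %in% .BASES
}

# canonical ordering used by all writers: chrom, pos, alt
order_variants <- function(variants) {
  variants[order(variants$chrom, variants$pos, variants$alt,
                 variants$sample_id), , drop = FALSE]
}
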