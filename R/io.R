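#' File formats
#'
#' The pipeline reads and writes: FASTA references (via Biostrings), a minimal
#' VCF 4.2 dialect for somatic calls, plain TSV variant/segment tables, and
#' COSMIC-style signature matrices (TSV, 96 channel rows x signature columns).
#'
#' VCF dialect: single-allele records after splitting; call evidence lives in
#' INFO keys `SAMPLE`, `DP`, `ALTR`, `VAF`, `SOMP` (somatic p), `CALLERS`
#' (comma list), `CLON` (clonality), `NALTR`/`NVAF` (matched normal); the
#' FILTER column carries the caller's own PASS status. Variant coordinates are
#' 1-based inclusive; segment tables are 0-based half-open.
#'
#' @name io-formats
NULL

# shortest decimal representation that round-trips through as.numeric
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

.parse_info <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read somatic variant calls
#'
#' @param path file path.
#' @param format `"vcf"` (minimal VCF 4.2 dialect, see [io-formats]) or
#'   `"tsv"` (the columns of [variant_table()]).
#' @return A validated variant data.frame. Multi-allelic VCF records are split
#'   into one row per alternate allele.
#' @export
read_variants <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    missing_cols <- setdiff(variant_columns(), names(df))
    if (length(missing_cols) > 0) {
      stop("variant TSV lacks columns: ", paste(missing_cols, collapse = ", "))
    }
    out <- variant_table(
      sample_id = df$sample_id, chrom = df$chrom, pos = as.integer(df$pos),
      ref = df$ref, alt = df$alt, vaf_tumor = num_or_na(df$vaf_tumor),
      depth_tumor = as.integer(num_or_na(df$depth_tumor)),
      alt_reads_tumor = as.integer(num_or_na(df$alt_reads_tumor)),
      somatic_p = num_or_na(df$somatic_p), callers = df$callers,
      caller_pass = as.logical(df$caller_pass),
      alt_reads_normal = as.integer(num_or_na(df$alt_reads_normal)),
      vaf_normal = num_or_na(df$vaf_normal), clonality = df$clonality
    )
    return(out)
  }
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF header (line 1): missing ##fileformat")
  }
  body_idx <- which(!startsWith(lines, "#"))
  header_idx <- which(startsWith(lines, "#CHROM"))
  if (length(header_idx) != 1) stop("malformed VCF: need one #CHROM line")
  rows <- list()
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF record at line ", i,
                            ": expected 8 fields, got ", length(f))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    info <- f[8]
    for (alt in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = .parse_info(info, "SAMPLE"),
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alt,
        vaf_tumor = num_or_na(.parse_info(info, "VAF")),
        depth_tumor = as.integer(num_or_na(.parse_info(info, "DP"))),
        alt_reads_tumor = as.integer(num_or_na(.parse_info(info, "ALTR"))),
        somatic_p = num_or_na(.parse_info(info, "SOMP")),
        callers = .parse_info(info, "CALLERS"),
        caller_pass = if (f[7] == ".") NA else identical(f[7], "PASS"),
        alt_reads_normal = as.integer(num_or_na(.parse_info(info, "NALTR"))),
        vaf_normal = num_or_na(.parse_info(info, "NVAF")),
        clonality = .parse_info(info, "CLON"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    v <- variant_table(character(0), character(0), integer(0),
                       character(0), character(0))
    return(v)
  }
  df <- do.call(rbind, rows)
  df$sample_id[is.na(df$sample_id)] <- "unknown"
  df$callers[is.na(df$callers)] <- "unknown"
  df$clonality[is.na(df$clonality)] <- "unknown"
  validate_variants(df)
}

#' Write somatic variant calls
#'
#' Records are written in a deterministic (chrom, pos, alt) order so identical
#' inputs always produce byte-identical files.
#'
#' @param variants validated variant data.frame.
#' @param path output file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  v <- order_variants(validate_variants(variants))
  if (format == "tsv") {
    out <- v
    for (col in c("vaf_tumor", "somatic_p", "vaf_normal")) {
      out[[col]] <- ifelse(is.na(v[[col]]), NA, fmt_num(v[[col]]))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Tumor read depth\">",
    "##INFO=<ID=ALTR,Number=1,Type=Integer,Description=\"Tumor alt read count\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Tumor variant allele frequency\">",
    "##INFO=<ID=SOMP,Number=1,Type=Float,Description=\"Primary caller somatic p-value\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Detecting callers\">",
    "##INFO=<ID=CLON,Number=1,Type=String,Description=\"Clonality label\">",
    "##INFO=<ID=NALTR,Number=1,Type=Integer,Description=\"Normal alt read count\">",
    "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Normal variant allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  info_field <- function(key, val) {
    ifelse(is.na(val) | val == ".", NA_character_, paste0(key, "=", val))
  }
  n <- nrow(v)
  body <- character(n)
  for (i in seq_len(n)) {
    parts <- c(
      info_field("SAMPLE", v$sample_id[i]),
      info_field("DP", v$depth_tumor[i]),
      info_field("ALTR", v$alt_reads_tumor[i]),
      info_field("VAF", fmt_num(v$vaf_tumor[i])),
      info_field("SOMP", fmt_num(v$somatic_p[i])),
      info_field("CALLERS", v$callers[i]),
      info_field("CLON", v$clonality[i]),
      info_field("NALTR", v$alt_reads_normal[i]),
      info_field("NVAF", fmt_num(v$vaf_normal[i]))
    )
    filt <- if (is.na(v$caller_pass[i])) "." else
      if (v$caller_pass[i]) "PASS" else "FAIL"
    body[i] <- paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                     filt, paste(parts[!is.na(parts)], collapse = ";"),
                     sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a COSMIC-style signature matrix
#'
#' @param path TSV whose first column holds the 96 channel labels in canonical
#'   order (see [catalog96_channels()]) and whose remaining columns are
#'   signature profiles.
#' @return Numeric 96 x n_signatures matrix, channel labels as rownames; every
#'   column sums to 1 (renormalized with a warning when off by more than 1e-6).
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 96) {
    stop("signature matrix must have 96 channel rows, found ", nrow(df))
  }
  labels <- df[[1]]
  if (!identical(labels, catalog96_channels())) {
    stop("signature matrix channel labels are not in canonical 96-channel order")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(mat) == 0) stop("signature matrix has no signature columns")
  storage.mode(mat) <- "double"
  rownames(mat) <- labels
  if (any(mat < 0)) stop("signature profiles must be nonnegative")
  sums <- colSums(mat)
  if (any(sums == 0)) stop("signature column sums to zero")
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    warning("renormalizing signature columns not summing to 1: ",
            paste(colnames(mat)[off], collapse = ", "))
  }
  sweep(mat, 2, sums, "/")
}

#' Read multi-region copy-number segment tables
#'
#' @param path TSV with columns tumor_id, region_id, chrom, start, end,
#'   total_cn; coordinates 0-based half-open.
#' @return Validated segment data.frame sorted by (tumor, region, chrom,
#'   start). Within each region, segments must be non-overlapping, and all
#'   regions of a tumor must share the same per-chromosome extent.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_segments(df)
}

#' @rdname read_segments
#' @param segments segment data.frame to validate.
#' @export
validate_segments <- function(segments) {
  need <- c("tumor_id", "region_id", "chrom", "start", "end", "total_cn")
  missing_cols <- setdiff(need, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  s <- segments
  s$start <- as.numeric(s$start); s$end <- as.numeric(s$end)
  s$total_cn <- as.integer(s$total_cn)
  if (any(s$start < 0) || any(s$end <= s$start)) {
    stop("segments need 0 <= start < end")
  }
  if (any(s$total_cn < 0)) stop("total_cn must be >= 0")
  s <- s[order(s$tumor_id, s$region_id, s$chrom, s$start), , drop = FALSE]
  rownames(s) <- NULL
  key <- interaction(s$tumor_id, s$region_id, s$chrom, drop = TRUE)
  for (grp in split(seq_len(nrow(s)), key)) {
    if (length(grp) > 1) {
      st <- s$start[grp]; en <- s$end[grp]
      if (any(st[-1] < en[-length(en)])) {
        stop("overlapping segments within region ",
             s$region_id[grp[1]], " of tumor ", s$tumor_id[grp[1]],
             " on ", s$chrom[grp[1]])
      }
    }
  }
  # all regions of a tumor must share the same per-chromosome extent
  for (tu in unique(s$tumor_id)) {
    st <- s[s$tumor_id == tu, , drop = FALSE]
    for (ch in unique(st$chrom)) {
      sc <- st[st$chrom == ch, , drop = FALSE]
      lo <- tapply(sc$start, sc$region_id, min)
      hi <- tapply(sc$end, sc$region_id, max)
      if (length(unique(lo)) > 1 || length(unique(hi)) > 1) {
        stop("regions of tumor ", tu, " disagree on the extent of ", ch)
      }
    }
  }
  s
}

#' Write a segment table (TSV, 0-based half-open)
#'
#' @param segments validated segment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  s <- validate_segments(segments)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a FASTA reference with k-mer context lookup
#'
#' @param path FASTA file; sequence is uppercased on load.
#' @return A `ref_store` object supporting [fetch_context()].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ref_store(stats::setNames(toupper(as.character(seqs)), names(seqs)))
}

#' Build a reference store from named character sequences
#'
#' @param sequences named character vector of uppercase DNA strings.
#' @return A `ref_store` object.
#' @export
ref_store <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("reference sequences must be named")
  }
  # keep only the first whitespace-delimited token of each FASTA header
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  structure(list(seq = toupper(sequences),
                 lengths = nchar(sequences)),
            class = "ref_store")
}

#' @export
print.ref_store <- function(x, ...) {
  cat("ref_store with", length(x$seq), "contig(s):",
      paste0(names(x$seq), " (", x$lengths, " bp)", collapse = ", "), "\n")
  invisible(x)
}

#' Fetch the k-mer centered on a position
#'
#' @param ref a `ref_store`.
#' @param chrom contig name.
#' @param pos 1-based center position.
#' @param k odd window size (3 or 5).
#' @return The k-mer string, or `NA` ("no context") when the window runs off
#'   the contig or contains N.
#' @export
fetch_context <- function(ref, chrom, pos, k = 3) {
  if (k %% 2 != 1) stop("k must be odd")
  if (!chrom %in% names(ref$seq)) stop("no such contig: ", chrom)
  flank <- (k - 1) / 2
  L <- ref$lengths[[chrom]]
  lo <- pos - flank
  hi <- pos + flank
  if (lo < 1 || hi > L) return(NA_character_)
  s <- substr(ref$seq[[chrom]], lo, hi)
  if (grepl("[^ACGT]", s)) return(NA_character_)
  s
}

#' Write a reference store to FASTA
#'
#' @param ref a `ref_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$seq), path, width = 70)
  invisible(path)
}
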