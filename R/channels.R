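#' 96-channel trinucleotide substitution machinery
#'
#' Single-base substitutions are classified into 96 channels: 6 pyrimidine
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking-base
#' combinations. Channel order is substitution-major with flanks alphabetical,
#' i.e. zero-based index = 16*sub + 4*five_prime + three_prime where bases are
#' coded A=0, C=1, G=2, T=3.
#'
#' @name channels96
NULL

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Channel labels for the 96 trinucleotide substitution classes
#'
#' @return Character vector of length 96 in canonical order, e.g. `"A[C>A]A"`,
#'   `"A[C>A]C"`, ... ending `"T[T>G]T"`.
#' @export
#' @examples
#' catalog96_channels()[33] # "A[C>T]A"
catalog96_channels <- function() {
  out <- character(96)
  for (s in seq_along(.SUBS)) {
    for (f in seq_along(.BASES)) {
      for (t in seq_along(.BASES)) {
        idx <- 16L * (s - 1L) + 4L * (f - 1L) + (t - 1L) + 1L
        out[idx] <- paste0(.BASES[f], "[", .SUBS[s], "]", .BASES[t])
      }
    }
  }
  out
}

#' Map trinucleotide context + substitution to a channel index
#'
#' @param trinucleotide 3-mers with a pyrimidine center (e.g. "TCA").
#' @param substitution substitution strings like "C>T" (ref must equal the
#'   trinucleotide center).
#' @return Integer channel indices in 1..96 (NA for invalid inputs).
#' @export
channel_index <- function(trinucleotide, substitution) {
  five <- match(substr(trinucleotide, 1, 1), .BASES) - 1L
  center <- substr(trinucleotide, 2, 2)
  three <- match(substr(trinucleotide, 3, 3), .BASES) - 1L
  sub <- match(substitution, .SUBS) - 1L
  bad <- is.na(five) | is.na(three) | is.na(sub) |
    center != substr(substitution, 1, 1)
  idx <- 16L * sub + 4L * five + three + 1L
  idx[bad] <- NA_integer_
  idx
}

#' Reverse-complement a DNA string (vectorized, base-level)
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(unname(.COMP[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# complement of single bases, vectorized
comp_base <- function(b) unname(.COMP[b])

#' The trinucleotide context (pyrimidine-oriented) of every channel
#'
#' @return Character vector of length 96: the 3-mer whose center is the
#'   reference pyrimidine of each channel, e.g. "ACA" for "A[C>A]A".
#' @export
channel_context <- function() {
  lab <- catalog96_channels()
  paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
}

# The alternate base of every channel
channel_alt <- function() substr(catalog96_channels(), 5, 5)
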