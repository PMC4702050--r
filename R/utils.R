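#' @importFrom data.table data.table setDT setorder rbindlist := .N .SD
#' @importFrom stats rpois setNames
#' @importFrom utils write.table read.table head
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "seq_", "count", "rpm", "pos", "strand", "chrom", "start", "end",
  "five_prime_pos", "mean_rpm", "peak_rank", "n_tags", "top_tag_rpm",
  "width", "library", "best_rpm", "rnk", "key_"
))

#' Reverse-complement a DNA string (character version)
#'
#' Thin wrapper over [Biostrings::reverseComplement()] working on plain
#' character vectors in the internal DNA alphabet (T, not U).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' Internally all sequences are kept DNA-side (T); report output is RNA-side
#' (U). Case is folded to upper.
#'
#' @param x character vector.
#' @return character vector.
#' @export
dna2rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna2rna
#' @export
rna2dna <- function(x) chartr("Uu", "Tt", toupper(x))

# 1-based inclusive span string for reports, from 0-based half-open
span_1based <- function(start0, end0) {
  sprintf("%d-%d", start0 + 1L, end0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
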