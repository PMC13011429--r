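# Sequence and coordinate helpers.
#
# Internal convention: every interval carried inside the package is 0-based
# half-open [start0, end0); every emitted or ingested file is 1-based
# inclusive (GFF3 / tblout norm).  The two helpers below are the only place
# the conversion happens.

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#'
#' @param start,end Numeric vectors of 1-based inclusive coordinates
#'   (`start <= end`).
#' @return A tibble with columns `start0` and `end0`.
#' @export
iv_from_1based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  tibble(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}

#' Convert internal 0-based half-open coordinates to 1-based inclusive
#'
#' @param start0,end0 Numeric vectors of 0-based half-open coordinates
#'   (`start0 < end0`).
#' @return A tibble with columns `start` and `end`.
#' @export
iv_to_1based <- function(start0, end0) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  tibble(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substring in 0-based half-open coordinates.
sub0 <- function(seq, start0, end0) {
  if (end0 <= start0) return("")
  substr(seq, start0 + 1L, end0)
}

# Validate a DNA string (uppercase T-alphabet plus N).
assert_dna <- function(seq, what = "sequence") {
  if (any(!grepl("^[ACGTN]*$", seq))) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(seq)
}

# Normalise raw sequence text: uppercase, RNA U -> DNA T.
normalise_dna <- function(seq) {
  chartr("Uu", "Tt", seq) |> toupper()
}

# Three-letter amino-acid codes keyed by the one-letter standard-code output.
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stop"
)

#' Amino acid decoded by an anticodon
#'
#' Translates the reverse complement of the anticodon with the standard
#' bacterial codon table.  The CAT anticodon (codon AUG) is chemically
#' ambiguous in bacteria -- it may belong to elongator Met, initiator fMet,
#' or lysidine-modified Ile2 -- so callers must resolve CAT identities from
#' intron-less homologs (see [assign_cau_identity()]); here it decodes to
#' "Met" with the ambiguity reported via the `cau` attribute of
#' [anticodon_of()].
#'
#' @param anticodon Character vector of 3-mers over `{A,C,G,T}` (DNA
#'   alphabet, 5'->3').
#' @return Character vector of 3-letter amino-acid codes.
#' @export
aa_from_anticodon <- function(anticodon) {
  stopifnot(all(nchar(anticodon) == 3L))
  assert_dna(anticodon, "anticodon")
  codon <- revcomp(anticodon)
  unname(AA3[Biostrings::GENETIC_CODE[codon]])
}
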