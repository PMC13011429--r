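# Short-sequence local alignment, emulating blastn-short behaviour: exact
# seed requirement plus Smith-Waterman scoring with blastn-short's documented
# defaults (match +1, mismatch -3, gap of length k costs 5 + 2k).  Raw
# scores rank hits; no E-value model is fitted because reference sets are
# small and fixed.

#' Default alignment parameters
#'
#' @param match,mismatch Per-column scores (blastn-short defaults +1/-3).
#' @param gap_open,gap_extend Affine gap penalties as positive costs; a gap
#'   of length k costs `gap_open + k * gap_extend`.
#' @param word_size Length of the exact seed both sequences must share for
#'   an alignment to be attempted (blastn-short default 7).
#' @return A named list of parameters.
#' @export
align_params <- function(match = 1, mismatch = -3, gap_open = 5,
                         gap_extend = 2, word_size = 7L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, word_size = as.integer(word_size))
}

align_submat <- function(params) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- params$match
  m["N", ] <- params$mismatch
  m[, "N"] <- params$mismatch
  m
}

has_seed <- function(query, subject, w) {
  nq <- nchar(query)
  ns <- nchar(subject)
  if (nq < w || ns < w) return(FALSE)
  qw <- unique(substring(query, 1:(nq - w + 1L), w:nq))
  sw <- unique(substring(subject, 1:(ns - w + 1L), w:ns))
  any(qw %in% sw)
}

#' Optimal local alignment of two short nucleotide sequences
#'
#' Smith-Waterman alignment with affine gaps.  Identity is the percentage of
#' aligned columns (gap columns included) that match; coverage is the
#' percentage of the query length spanned by the alignment.  Returns `NULL`
#' when the two sequences share no exact `word_size`-mer, mirroring the
#' seed requirement of a word-based search.
#'
#' @param query,subject DNA strings over `{A,C,G,T,N}`.
#' @param params Scoring parameters from [align_params()].
#' @return A one-row tibble with columns `score`, `identity`, `coverage`,
#'   `q_start0`, `q_end0`, `s_start0`, `s_end0` (0-based half-open), or
#'   `NULL` when no seeded alignment exists.
#' @export
local_align <- function(query, subject, params = align_params()) {
  query <- normalise_dna(query)
  subject <- normalise_dna(subject)
  if (nchar(query) == 0L || nchar(subject) == 0L) {
    stop("empty sequence in local_align", call. = FALSE)
  }
  assert_dna(query, "query")
  assert_dna(subject, "subject")
  if (!has_seed(query, subject, params$word_size)) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = align_submat(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  score <- as.numeric(Biostrings::score(aln))
  if (score <= 0) return(NULL)
  nmatch <- Biostrings::nmatch(aln)
  indel <- Biostrings::nindel(aln)
  ncol_aln <- as.numeric(nmatch + Biostrings::nmismatch(aln) +
    Biostrings::insertion(indel)[1L, "WidthSum"] +
    Biostrings::deletion(indel)[1L, "WidthSum"])
  qr <- aln@pattern@range
  sr <- aln@subject@range
  tibble(
    score = score,
    identity = 100 * nmatch / ncol_aln,
    coverage = 100 * IRanges::width(qr) / nchar(query),
    q_start0 = IRanges::start(qr) - 1L, q_end0 = IRanges::end(qr),
    s_start0 = IRanges::start(sr) - 1L, s_end0 = IRanges::end(sr)
  )
}

#' Rank a query against an intron-less tRNA reference set
#'
#' Aligns the query against every reference, keeps hits whose query coverage
#' strictly exceeds `min_coverage`, and ranks them by score (ties by
#' identity, then lexicographic subject id).  The subject's amino-acid and
#' anticodon labels are carried from the reference headers.
#'
#' @param query DNA string (typically a reconstructed mature tRNA).
#' @param reference_set Tibble from [read_trna_db()] / [trna_db()].
#' @param min_coverage Query-coverage threshold in percent (default 75;
#'   hits with coverage `<= min_coverage` are dropped).
#' @param params Scoring parameters from [align_params()].
#' @return A tibble of ranked hits with columns `subject_id`,
#'   `subject_amino_acid`, `subject_anticodon`, `score`, `identity`,
#'   `coverage`, `q_start0`, `q_end0`, `s_start0`, `s_end0`.
#' @export
search_db <- function(query, reference_set, min_coverage = 75,
                      params = align_params()) {
  empty <- tibble(
    subject_id = character(), subject_amino_acid = character(),
    subject_anticodon = character(), score = double(),
    identity = double(), coverage = double(),
    q_start0 = integer(), q_end0 = integer(),
    s_start0 = integer(), s_end0 = integer()
  )
  query <- normalise_dna(query)
  assert_dna(query, "query")
  if (nrow(reference_set) == 0L) return(empty)
  seeded <- map_lgl(reference_set$seq,
                    function(s) has_seed(query, s, params$word_size))
  if (!any(seeded)) return(empty)
  refs <- reference_set[seeded, ]
  # one vectorised call: references as patterns against the single query
  # subject (local alignment statistics are orientation-symmetric)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(refs$seq), subject = query,
    type = "local", substitutionMatrix = align_submat(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  score <- as.numeric(Biostrings::score(aln))
  nmatch <- Biostrings::nmatch(aln)
  indel <- Biostrings::nindel(aln)
  ncol_aln <- as.numeric(nmatch + Biostrings::nmismatch(aln) +
    Biostrings::insertion(indel)[, "WidthSum"] +
    Biostrings::deletion(indel)[, "WidthSum"])
  qr <- aln@subject@range   # aligned span on the query
  sr <- aln@pattern@range   # aligned span on the reference
  out <- tibble(
    subject_id = refs$id,
    subject_amino_acid = refs$amino_acid,
    subject_anticodon = refs$anticodon,
    score = score,
    identity = 100 * nmatch / ncol_aln,
    coverage = 100 * IRanges::width(qr) / nchar(query),
    q_start0 = IRanges::start(qr) - 1L, q_end0 = IRanges::end(qr),
    s_start0 = IRanges::start(sr) - 1L, s_end0 = IRanges::end(sr)
  )
  out |>
    filter(.data$score > 0, .data$coverage > .env$min_coverage) |>
    arrange(desc(.data$score), desc(.data$identity), .data$subject_id)
}
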