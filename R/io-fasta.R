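# FASTA ingestion for genomes and intron-less tRNA reference sets.

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and any RNA `U` is mapped to DNA `T`; `N` is
#' allowed.  Record ids are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path Path to a FASTA file of DNA sequences.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- normalise_dna(as.character(set))
  assert_dna(seqs, paste0("FASTA file ", path))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path, call. = FALSE)
  seqs <- unname(seqs)
  tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Read an intron-less tRNA reference database
#'
#' Headers must follow the dialect `>{id}|{amino_acid}|{anticodon}`, e.g.
#' `>ref001|Asn|GTT`.  The anticodon is stored in the DNA alphabet.
#'
#' @param path Path to the reference FASTA.
#' @return A tibble with columns `id`, `amino_acid`, `anticodon`, `seq`.
#' @export
read_trna_db <- function(path) {
  recs <- read_genome_fasta(path)
  parts <- str_split(recs$id, stringr::fixed("|"))
  bad <- map_int(parts, length) != 3L
  if (any(bad)) {
    stop("unparseable tRNA reference header(s): ",
         paste(head(recs$id[bad], 3L), collapse = ", "),
         " (expected id|amino_acid|anticodon)", call. = FALSE)
  }
  trna_db(
    id         = map_chr(parts, 1L),
    amino_acid = map_chr(parts, 2L),
    anticodon  = normalise_dna(map_chr(parts, 3L)),
    seq        = recs$seq
  )
}

#' Assemble a tRNA reference database tibble
#'
#' @param id,amino_acid,anticodon,seq Character vectors of equal length.
#' @return A tibble with one row per reference.
#' @export
trna_db <- function(id, amino_acid, anticodon, seq) {
  anticodon <- normalise_dna(anticodon)
  stopifnot(all(nchar(anticodon) == 3L))
  assert_dna(anticodon, "reference anticodon")
  assert_dna(seq <- normalise_dna(seq), "reference sequence")
  if (anyDuplicated(id)) stop("duplicate reference id", call. = FALSE)
  tibble(id = id, amino_acid = amino_acid, anticodon = anticodon, seq = seq)
}

#' Write a tRNA reference database to FASTA
#'
#' Inverse of [read_trna_db()]; headers use the `id|amino_acid|anticodon`
#' dialect.
#'
#' @param db Tibble as returned by [trna_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trna_db <- function(db, path) {
  set <- Biostrings::DNAStringSet(db$seq)
  names(set) <- paste(db$id, db$amino_acid, db$anticodon, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write genome records to FASTA
#'
#' @param genomes Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(genomes$seq)
  names(set) <- genomes$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
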