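# Emission of resolved calls: fixed-column TSV and paired GFF3 features
# (tRNA gene with an intron child).  Internal coordinates are 0-based
# half-open; both emitted formats are 1-based inclusive.

CALLS_TSV_COLS <- c(
  "call_id", "genome_id", "strand", "gene_start", "gene_end",
  "intron_start", "intron_end", "exon1_len", "trna_seq", "anticodon",
  "amino_acid", "intron_seq", "intron_class", "site", "top_homolog_id",
  "homolog_score", "homolog_identity", "homolog_coverage", "shift_a",
  "shift_b", "n_hypotheses", "cau_flag", "cau_resolved",
  "boundary_adjusted", "status", "truncated_context"
)

#' Write resolved calls to TSV
#'
#' Columns are fixed (see [read_calls_tsv()] for the inverse); gene and
#' intron coordinates are emitted 1-based inclusive.
#'
#' @param calls Calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  gene <- iv_to_1based(calls$gene_start0, calls$gene_end0)
  intron <- iv_to_1based(calls$intron_start0, calls$intron_end0)
  out <- calls |>
    mutate(gene_start = gene$start, gene_end = gene$end,
           intron_start = intron$start, intron_end = intron$end) |>
    select(dplyr::all_of(CALLS_TSV_COLS))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read resolved calls from TSV
#'
#' Inverse of [write_calls_tsv()]: converts the emitted 1-based inclusive
#' coordinates back to internal 0-based half-open ones, so a
#' write-then-read round trip is field-identical.
#'
#' @param path Path to a calls TSV.
#' @return A calls tibble.
#' @export
read_calls_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           anticodon = "c", amino_acid = "c", site = "c",
                           top_homolog_id = "c", status = "c"
                         ))
  if (nrow(raw) == 0L) return(empty_calls())
  gene <- iv_from_1based(raw$gene_start, raw$gene_end)
  intron <- iv_from_1based(raw$intron_start, raw$intron_end)
  raw |>
    mutate(gene_start0 = gene$start0, gene_end0 = gene$end0,
           intron_start0 = intron$start0, intron_end0 = intron$end0,
           exon1_len = as.integer(.data$exon1_len),
           shift_a = as.integer(.data$shift_a),
           shift_b = as.integer(.data$shift_b),
           n_hypotheses = as.integer(.data$n_hypotheses)) |>
    select(dplyr::all_of(names(empty_calls())))
}

#' Write resolved calls as GFF3
#'
#' Emits a `tRNA` gene feature per call with an `intron` child feature
#' (attributes carry the anticodon, amino acid, site and intron class),
#' 1-based inclusive coordinates per the GFF3 contract.
#'
#' @param calls Calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(calls, path) {
  if (nrow(calls) == 0L) {
    readr::write_lines("##gff-version 3", path)
    return(invisible(path))
  }
  gene <- GenomicRanges::GRanges(
    seqnames = calls$genome_id,
    ranges = IRanges::IRanges(start = calls$gene_start0 + 1L,
                              end = calls$gene_end0),
    strand = calls$strand
  )
  S4Vectors::mcols(gene) <- S4Vectors::DataFrame(
    source = "intronaut", type = "tRNA",
    ID = calls$call_id,
    anticodon = calls$anticodon, amino_acid = calls$amino_acid,
    site = calls$site, intron_class = NA_character_
  )
  intron <- GenomicRanges::GRanges(
    seqnames = calls$genome_id,
    ranges = IRanges::IRanges(start = calls$intron_start0 + 1L,
                              end = calls$intron_end0),
    strand = calls$strand
  )
  S4Vectors::mcols(intron) <- S4Vectors::DataFrame(
    source = "intronaut", type = "intron",
    ID = paste0(calls$call_id, ":intron"),
    Parent = calls$call_id,
    anticodon = NA_character_, amino_acid = NA_character_,
    site = calls$site, intron_class = calls$intron_class
  )
  gr <- c(gene, intron)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features back from a GFF3 file
#'
#' Companion to [write_gff3()] for round-trip checks: returns the feature
#' table with coordinates as printed (1-based inclusive).
#'
#' @param path Path to a GFF3 file.
#' @return A tibble (`seqid`, `type`, `start`, `end`, `strand`, `ID`,
#'   plus attribute columns when present).
#' @export
read_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  meta <- as_tibble(as.data.frame(S4Vectors::mcols(gr)))
  for (col in c("ID", "anticodon", "amino_acid", "site", "intron_class")) {
    if (col %in% names(meta)) out[[col]] <- as.character(meta[[col]])
  }
  out
}

#' Read external tRNA-with-intron predictions
#'
#' Consumes the documented TSV dialect for tFind/ARAGORN-style calls:
#' columns `genome_id`, `strand`, `intron_start`, `intron_end` (1-based
#' inclusive).
#'
#' @param path Path to the predictions TSV.
#' @return A tibble with internal 0-based half-open `intron_start0` /
#'   `intron_end0`.
#' @export
read_external_predictions <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("genome_id", "strand", "intron_start", "intron_end")
                %in% names(raw)))
  iv <- iv_from_1based(raw$intron_start, raw$intron_end)
  raw |>
    mutate(intron_start0 = iv$start0, intron_end0 = iv$end0) |>
    select("genome_id", "strand", "intron_start0", "intron_end0")
}
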