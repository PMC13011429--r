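# Parser for the Infernal cmsearch `--tblout` tabular dialect.
#
# Column layout (cmsearch orientation: target = genome, query = model):
#   1 target name  2 target acc  3 query name  4 query acc  5 mdl
#   6 mdl from     7 mdl to      8 seq from    9 seq to    10 strand
#  11 trunc       12 pass       13 gc         14 bias      15 score
#  16 E-value     17 inc        18.. description

#' Read covariance-model hits from an Infernal `--tblout` file
#'
#' Rows are filtered to `evalue < evalue_max`; minus-strand rows (where
#' `seq from > seq to`) are normalised so `start < stop` with the strand
#' recorded.  Malformed rows are skipped with a warning.  Coordinates are
#' kept 1-based inclusive as read from the file; convert with
#' [hits_as_candidates()] before resolution.
#'
#' @param path Path to a `--tblout` file.
#' @param evalue_max Strict upper bound on the reported E-value
#'   (default `1e-4`).
#' @return A tibble with columns `target_id`, `model`, `start`, `stop`,
#'   `strand`, `score`, `evalue` (possibly zero rows).
#' @export
read_cm_tblout <- function(path, evalue_max = 1e-4) {
  stopifnot(evalue_max > 0)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- tibble(
    target_id = character(), model = character(),
    start = integer(), stop = integer(), strand = character(),
    score = double(), evalue = double()
  )
  if (length(lines) == 0L) return(empty)
  rows <- map(lines, function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(f) < 17L) {
      warning("skipping malformed tblout row: ", substr(line, 1, 60),
              call. = FALSE)
      return(NULL)
    }
    from <- suppressWarnings(as.integer(f[8L]))
    to <- suppressWarnings(as.integer(f[9L]))
    score <- suppressWarnings(as.numeric(f[15L]))
    evalue <- suppressWarnings(as.numeric(f[16L]))
    if (anyNA(c(from, to, score, evalue)) || !f[10L] %in% c("+", "-")) {
      warning("skipping malformed tblout row: ", substr(line, 1, 60),
              call. = FALSE)
      return(NULL)
    }
    tibble(
      target_id = f[1L], model = f[3L],
      start = min(from, to), stop = max(from, to),
      strand = f[10L], score = score, evalue = evalue
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  filter(out, .data$evalue < .env$evalue_max)
}

#' Collapse redundant covariance-model hits at the same locus
#'
#' When the same genomic locus is reported by more than one model (e.g. the
#' generic group I model and a taxon-specific one), only the hit with the
#' higher score is retained.  "Same locus" means reciprocal overlap of at
#' least `overlap_frac` on the same target and strand; score ties are broken
#' by lower E-value, then leftmost start, so output is deterministic.
#'
#' @param hits Tibble as returned by [read_cm_tblout()].
#' @param overlap_frac Reciprocal-overlap fraction in `(0, 1]` defining the
#'   "same locus" (default `0.5`).
#' @return The surviving hits, sorted by `(target_id, start)`.
#' @export
dedup_hits <- function(hits, overlap_frac = 0.5) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1)
  if (nrow(hits) == 0L) return(hits)
  ord <- hits |>
    mutate(.row = row_number()) |>
    arrange(desc(.data$score), .data$evalue, .data$start, .data$.row)
  keep <- logical(0)
  kept <- ord[0, ]
  for (i in seq_len(nrow(ord))) {
    h <- ord[i, ]
    same <- kept$target_id == h$target_id & kept$strand == h$strand
    clash <- FALSE
    if (any(same)) {
      k <- kept[same, ]
      ov <- pmax(0L, pmin(k$stop, h$stop) - pmax(k$start, h$start) + 1L)
      w_h <- h$stop - h$start + 1L
      w_k <- k$stop - k$start + 1L
      clash <- any(ov / w_h >= overlap_frac & ov / w_k >= overlap_frac)
    }
    if (!clash) kept <- bind_rows(kept, h)
  }
  kept |>
    select(-".row") |>
    arrange(.data$target_id, .data$start)
}

#' Convert 1-based hit rows to internal 0-based intron candidates
#'
#' @param hits Tibble from [read_cm_tblout()] (after [dedup_hits()]).
#' @return A tibble with columns `genome_id`, `start0`, `end0`, `strand`,
#'   `source_model`, `score`, `evalue`.
#' @export
hits_as_candidates <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(
      genome_id = character(), start0 = integer(), end0 = integer(),
      strand = character(), source_model = character(),
      score = double(), evalue = double()
    ))
  }
  iv <- iv_from_1based(hits$start, hits$stop)
  tibble(
    genome_id = hits$target_id, start0 = iv$start0, end0 = iv$end0,
    strand = hits$strand, source_model = hits$model,
    score = hits$score, evalue = hits$evalue
  )
}

#' Write hits in Infernal `--tblout` layout
#'
#' Emits the 17-column cmsearch orientation so that synthetic hit tables
#' round-trip through [read_cm_tblout()].
#'
#' @param hits Tibble with columns `target_id`, `model`, `start`, `stop`,
#'   `strand`, `score`, `evalue` (1-based inclusive coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cm_tblout <- function(hits, path) {
  header <- "#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description"
  body <- character(0)
  if (nrow(hits) > 0L) {
    from <- ifelse(hits$strand == "+", hits$start, hits$stop)
    to <- ifelse(hits$strand == "+", hits$stop, hits$start)
    body <- sprintf(
      "%s - %s - cm 1 100 %d %d %s no 1 0.50 0.0 %.1f %.3g ! -",
      hits$target_id, hits$model, from, to, hits$strand,
      hits$score, hits$evalue
    )
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}
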