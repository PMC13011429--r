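# Host-gene classification of detected introns and homing-endonuclease
# annotation.  Evidence comes from externally produced hit tables (rRNA /
# tmRNA covariance-model hits, blastx-style protein homology, TnpB
# annotations) plus internal ORF detection; this module never runs the
# external searches itself.

overlap_any <- function(hits, lo, hi) {
  nrow(hits) > 0L && any(pmin(hits$end0, hi) > pmax(hits$start0, lo))
}

side_hits <- function(hits, intron, flank) {
  if (is.null(hits) || nrow(hits) == 0L) {
    empty <- tibble(genome_id = character(), model = character(),
                    subject_id = character(), start0 = integer(),
                    end0 = integer())
    return(list(up = empty, down = empty))
  }
  h <- filter(hits, .data$genome_id == intron$genome_id)
  up <- filter(h, pmin(.data$end0, intron$start0) >
                 pmax(.data$start0, intron$start0 - flank))
  down <- filter(h, pmin(.data$end0, intron$end0 + flank) >
                   pmax(.data$start0, intron$end0))
  list(up = up, down = down)
}

#' Classify the host locus of a detected intron
#'
#' Categories in priority order: `tRNA` (already established by the
#' boundary resolver) > `rRNA` > `tmRNA` > `CDS` > `IStron-like` >
#' `unknown`.  rRNA and tmRNA require model hits on both sides of the
#' intron within 1,000-nt flanks; CDS requires protein hits from the same
#' subject on both sides within 4,000-nt flanks; a TnpB annotation within
#' the CDS flank marks an IStron-like element.  tmRNA additionally accepts
#' partial evidence -- a full-length hit whose intron-facing end lies
#' within `tmrna_boundary_tol` of the intron boundary (the intron cutting
#' the tmRNA at its T loop truncates the model hit) plus a short
#' (`tmrna_fragment_min` to 39 nt) same-model fragment on the opposite
#' side; such calls are flagged "partial evidence".  When evidence
#' supports more than one category the higher-priority one wins and the
#' conflict is reported via `message()`.
#'
#' @param intron One-row tibble with `intron_id`, `genome_id`, `start0`,
#'   `end0`, and optionally `is_trna` (logical).
#' @param rrna_hits,tmrna_hits Tibbles (`genome_id`, `start0`, `end0`,
#'   `model`) of covariance-model hits.
#' @param cds_hits Tibble (`genome_id`, `start0`, `end0`, `subject_id`) of
#'   blastx-style protein hits.
#' @param tnpb_hits Tibble (`genome_id`, `start0`, `end0`) of TnpB-related
#'   gene annotations.
#' @param flank_rna,flank_cds Flank widths in nt (defaults 1,000 / 4,000).
#' @param tmrna_boundary_tol,tmrna_fragment_min Placeholder thresholds of
#'   the partial-tmRNA rule (defaults 30 / 20 nt); reported in the
#'   evidence string so downstream users can see they are heuristics.
#' @return A one-row tibble with `intron_id`, `category`, `evidence`.
#' @export
classify_host <- function(intron, rrna_hits = NULL, tmrna_hits = NULL,
                          cds_hits = NULL, tnpb_hits = NULL,
                          flank_rna = 1000L, flank_cds = 4000L,
                          tmrna_boundary_tol = 30L, tmrna_fragment_min = 20L) {
  stopifnot(nrow(intron) == 1L)
  is_trna <- "is_trna" %in% names(intron) && isTRUE(intron$is_trna)

  r <- side_hits(rrna_hits, intron, flank_rna)
  rrna_ok <- nrow(r$up) > 0L && nrow(r$down) > 0L

  t <- side_hits(tmrna_hits, intron, flank_rna)
  tmrna_ok <- FALSE
  tmrna_evidence <- NULL
  if (nrow(t$up) > 0L && nrow(t$down) > 0L) {
    w_up <- max(t$up$end0 - t$up$start0)
    w_down <- max(t$down$end0 - t$down$start0)
    if (min(w_up, w_down) >= 40L) {
      tmrna_ok <- TRUE
      tmrna_evidence <- "tmRNA model hits on both sides"
    } else {
      short_w <- min(w_up, w_down)
      if (w_up < w_down) {
        near_end_dist <- abs(intron$end0 - min(t$down$start0))
      } else {
        near_end_dist <- abs(intron$start0 - max(t$up$end0))
      }
      if (short_w >= tmrna_fragment_min &&
          near_end_dist <= tmrna_boundary_tol) {
        tmrna_ok <- TRUE
        tmrna_evidence <- paste0(
          "tmRNA (partial evidence): truncated hit within ",
          tmrna_boundary_tol, " nt of intron boundary + >=",
          tmrna_fragment_min, " nt fragment on opposite side")
      }
    }
  }

  cds_ok <- FALSE
  cds_subject <- NA_character_
  c2 <- side_hits(cds_hits, intron, flank_cds)
  if (nrow(c2$up) > 0L && nrow(c2$down) > 0L) {
    shared <- intersect(c2$up$subject_id, c2$down$subject_id)
    if (length(shared) > 0L) {
      cds_ok <- TRUE
      cds_subject <- sort(shared)[1L]
    }
  }

  istron_ok <- !is.null(tnpb_hits) && overlap_any(
    filter(tnpb_hits, .data$genome_id == intron$genome_id),
    intron$start0 - flank_cds, intron$end0 + flank_cds
  )

  satisfied <- c(
    tRNA = is_trna, rRNA = rrna_ok, tmRNA = tmrna_ok,
    CDS = cds_ok, `IStron-like` = istron_ok
  )
  if (sum(satisfied) > 1L) {
    message("intron ", intron$intron_id, ": evidence for multiple host ",
            "categories (", paste(names(satisfied)[satisfied],
                                  collapse = ", "),
            "); keeping highest priority")
  }
  category <- if (any(satisfied)) names(satisfied)[which(satisfied)[1L]]
              else "unknown"
  evidence <- switch(category,
    tRNA = "resolved tRNA call",
    rRNA = paste0("rRNA model hits on both sides (",
                  paste(unique(c(r$up$model, r$down$model)), collapse = ","),
                  ")"),
    tmRNA = tmrna_evidence,
    CDS = paste0("same-subject protein hits on both sides (", cds_subject,
                 ")"),
    `IStron-like` = "TnpB-related gene in vicinity",
    unknown = ""
  )
  tibble(intron_id = intron$intron_id, category = category,
         evidence = evidence)
}

#' Classify every intron in a table
#'
#' @param introns Tibble of intron rows (see [classify_host()]).
#' @param ... Hit tables and thresholds passed to [classify_host()].
#' @return A tibble with one classification row per intron.
#' @export
classify_hosts <- function(introns, ...) {
  bind_rows(map(seq_len(nrow(introns)),
                function(i) classify_host(introns[i, ], ...)))
}

#' Find open reading frames within an intron sequence
#'
#' Sense-strand only (introns are transcribed in the host gene's sense),
#' three frames, bacterial start codons ATG/GTG/TTG, standard stops.  Every
#' start-to-stop span of at least `min_len_nt` is reported; a frame's final
#' ORF may run to the intron end without a stop (`partial = TRUE`).  The
#' caller applies the length gate: ORFs are only sought in group I introns
#' longer than 500 bp (and in all group II introns) -- see
#' [scan_heg_orfs()].
#'
#' @param intron_seq DNA string.
#' @param min_len_nt Minimal ORF length in nt, stop codon included
#'   (default 300, i.e. at least 99 codons of protein).
#' @return A tibble sorted by decreasing length with columns `start0`,
#'   `end0`, `frame`, `length_nt`, `protein_len_aa`, `partial`.
#' @export
find_orfs <- function(intron_seq, min_len_nt = 300L) {
  intron_seq <- normalise_dna(intron_seq)
  assert_dna(intron_seq)
  L <- nchar(intron_seq)
  out <- list()
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3L
    if (n_codon < 1L) next
    pos <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(intron_seq, pos, pos + 2L)
    starts <- which(codons %in% c("ATG", "GTG", "TTG"))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (s in starts) {
      nxt <- stops[stops >= s]
      if (length(nxt) > 0L) {
        e <- nxt[1L]
        len <- (e - s + 1L) * 3L
        partial <- FALSE
      } else {
        e <- n_codon
        len <- (e - s + 1L) * 3L
        partial <- TRUE
      }
      if (len < min_len_nt) next
      out[[length(out) + 1L]] <- tibble(
        start0 = frame + 3L * (s - 1L),
        end0 = frame + 3L * e,
        frame = frame, length_nt = len,
        protein_len_aa = if (partial) len %/% 3L else len %/% 3L - 1L,
        partial = partial
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(start0 = integer(), end0 = integer(), frame = integer(),
                  length_nt = integer(), protein_len_aa = integer(),
                  partial = logical()))
  }
  arrange(res, desc(.data$length_nt), .data$start0)
}

#' Scan resolved calls for HEG-sized ORFs
#'
#' Applies the length rule -- group I introns are scanned only when longer
#' than `heg_len` (500 bp), group II introns always -- and runs
#' [find_orfs()] on each qualifying intron.
#'
#' @param calls Calls tibble with `call_id`, `intron_seq`, `intron_class`.
#' @param min_len_nt Minimal ORF length ([find_orfs()]).
#' @param heg_len Length gate for group I introns in bp (default 500).
#' @return A tibble of ORFs with `call_id` and `orf_id` prepended.
#' @export
scan_heg_orfs <- function(calls, min_len_nt = 300L, heg_len = 500L) {
  rows <- map(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    len <- nchar(cl$intron_seq)
    if (cl$intron_class == "groupI" && len <= heg_len) return(NULL)
    orfs <- find_orfs(cl$intron_seq, min_len_nt)
    if (nrow(orfs) == 0L) return(NULL)
    mutate(orfs,
           call_id = cl$call_id,
           orf_id = paste0(cl$call_id, ":orf", row_number()),
           .before = 1L)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(call_id = character(), orf_id = character(),
                  start0 = integer(), end0 = integer(), frame = integer(),
                  length_nt = integer(), protein_len_aa = integer(),
                  partial = logical()))
  }
  out
}

DOMAIN_FAMILIES <- c(
  PF03161 = "LAGLIDADG", PF11645 = "PD-(D/E)XK", PF01844 = "HNH",
  PF00078 = "reverse transcriptase", PF07727 = "reverse transcriptase"
)

domain_family <- function(accession, name) {
  acc <- sub("\\..*$", "", accession)
  fam <- unname(DOMAIN_FAMILIES[acc])
  rt <- !is.na(name) & grepl("RVT|reverse.?transcriptase", name,
                             ignore.case = TRUE)
  ifelse(!is.na(fam), fam, ifelse(rt, "reverse transcriptase",
                                  NA_character_))
}

#' Attach protein-domain labels to ORFs
#'
#' Joins a parsed hmmscan-style table to the ORF table, attaching for each
#' ORF the best (lowest E-value) domain with `E < evalue_max`.  Families
#' of interest -- LAGLIDADG (PF03161), PD-(D/E)XK (PF11645), HNH (PF01844)
#' and reverse transcriptase -- are flagged in a `family` column.  Rows
#' naming unknown ORF ids are skipped with a warning.
#'
#' @param orfs ORF tibble from [scan_heg_orfs()] (must carry `orf_id`).
#' @param domain_table Tibble with columns `orf_id`, `accession`, `name`,
#'   `evalue` (see [read_hmmscan_tblout()]).
#' @param evalue_max Domain E-value threshold (default 0.01).
#' @return `orfs` with columns `domain_accession`, `domain_name`,
#'   `domain_evalue`, `family` added (`NA` where nothing qualifies).
#' @export
attach_domains <- function(orfs, domain_table, evalue_max = 0.01) {
  unknown <- setdiff(unique(domain_table$orf_id), orfs$orf_id)
  if (length(unknown) > 0L) {
    warning("domain rows for unknown ORF id(s) skipped: ",
            paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  best <- domain_table |>
    filter(.data$evalue < .env$evalue_max,
           .data$orf_id %in% orfs$orf_id) |>
    group_by(.data$orf_id) |>
    arrange(.data$evalue, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    mutate(family = domain_family(.data$accession, .data$name)) |>
    select("orf_id", domain_accession = "accession",
           domain_name = "name", domain_evalue = "evalue", "family")
  left_join(orfs, best, by = "orf_id")
}

#' Read domain hits from an hmmscan `--tblout` file
#'
#' Parses the per-sequence table (target = domain model, query = ORF id)
#' into the tibble [attach_domains()] consumes.
#'
#' @param path Path to an hmmscan `--tblout` file.
#' @return A tibble with columns `orf_id`, `accession`, `name`, `evalue`,
#'   `score`.
#' @export
read_hmmscan_tblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- map(lines, function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(f) < 6L) {
      warning("skipping malformed hmmscan row", call. = FALSE)
      return(NULL)
    }
    tibble(orf_id = f[3L], accession = f[2L], name = f[1L],
           evalue = suppressWarnings(as.numeric(f[5L])),
           score = suppressWarnings(as.numeric(f[6L])))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(orf_id = character(), accession = character(),
                  name = character(), evalue = double(), score = double()))
  }
  out
}
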