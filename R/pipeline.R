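# Pipeline drivers binding the stages together.  These functions back the
# command-line front end (inst/cli/intronaut.R) but are ordinary tidyverse
# functions: paths in, tibbles out, files written under an output prefix.

#' Build a run configuration
#'
#' Collects every tunable threshold with its default.  Defaults marked (*)
#' are the survey protocol's stated values: e-value < 1e-4 (*), homolog
#' coverage > 75% (*), 400-bp context flanks (*), 1,000 / 4,000-nt
#' classification flanks (*), ORFs sought in group I introns > 500 bp (*),
#' domain E-value < 0.01 (*), phyla plotted at >= 20 genomes (*).
#'
#' @param ... Named overrides of any default below.
#' @return A named list of parameters (class `intronaut_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    genomes = NULL, hits = NULL, trna_db = NULL, out_prefix = "intronaut",
    out_dir = ".", predictions = NULL, calls = NULL, phylum_map = NULL,
    subgroup_scores = NULL, rrna_hits = NULL, tmrna_hits = NULL,
    cds_hits = NULL, tnpb_hits = NULL,
    evalue_max = 1e-4, min_coverage = 75, flank = 400L, window = 10L,
    overlap_frac = 0.5, min_intron_len = 50L, min_side_score = 12,
    orf_min = 300L, heg_len = 500L, domain_evalue = 0.01,
    min_genomes = 20L, jitter = 2L, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, dots)
  num <- c("evalue_max", "min_coverage", "flank", "window", "overlap_frac",
           "min_intron_len", "min_side_score", "orf_min", "heg_len",
           "domain_evalue", "min_genomes")
  bad <- num[map_lgl(num, function(k) !is.numeric(cfg[[k]]) ||
                       cfg[[k]] <= 0)]
  if (length(bad) > 0L) {
    stop("config threshold(s) must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "intronaut_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line, `#` comments allowed; values are
#' parsed as numbers where possible.  Command-line flags override file
#' values in the CLI front end.
#'
#' @param path Path to the config file.
#' @return An `intronaut_config` list.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- map(kv, function(x) {
    v <- trimws(x[2L])
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  do.call(run_config, setNames(vals, map_chr(kv, function(x) trimws(x[1L]))))
}

# Machine-readable parameter record written next to every run's outputs.
write_params <- function(config, path) {
  scalar <- keep(unclass(config), function(v) !is.null(v) &&
                   length(v) == 1L && !is.list(v))
  readr::write_lines(
    paste0(names(scalar), " = ", unlist(scalar)), path
  )
  invisible(path)
}

require_inputs <- function(config, keys) {
  for (k in keys) {
    v <- config[[k]]
    if (is.null(v)) stop("missing required input: ", k, call. = FALSE)
    if (is.character(v) && !file.exists(v)) {
      stop("input file not found (", k, "): ", v, call. = FALSE)
    }
  }
}

#' Run the detection pipeline
#'
#' Reads genomes, a covariance-model hit table and an intron-less tRNA
#' database; filters hits by e-value, deduplicates same-locus hits,
#' resolves group I candidates, finalises CAT-anticodon identities from
#' homologs, and writes `<prefix>.calls.tsv`, `<prefix>.gff3` and
#' `<prefix>.params.txt`.
#'
#' @param config An [run_config()] list with `genomes`, `hits`, `trna_db`
#'   set (paths) and `out_prefix`/`out_dir`.
#' @return A list with `status` (0 = calls written, 1 = no calls) and the
#'   calls tibble, invisibly.
#' @export
run_detect <- function(config) {
  require_inputs(config, c("genomes", "hits", "trna_db"))
  genomes <- read_genome_fasta(config$genomes)
  db <- read_trna_db(config$trna_db)
  hits <- read_cm_tblout(config$hits, config$evalue_max) |>
    dedup_hits(config$overlap_frac)
  candidates <- hits_as_candidates(hits) |>
    filter(.data$source_model != "RF00029")
  calls <- resolve_candidates(
    candidates, genomes, db,
    flank = config$flank, window = config$window,
    min_coverage = config$min_coverage,
    min_intron_len = config$min_intron_len,
    min_side_score = config$min_side_score
  )
  if (nrow(calls) > 0L) {
    calls <- bind_rows(map(seq_len(nrow(calls)), function(i) {
      if (isTRUE(calls$cau_flag[i])) {
        assign_cau_identity(calls[i, ], db, config$min_coverage)
      } else {
        calls[i, ]
      }
    }))
  }
  prefix <- file.path(config$out_dir, config$out_prefix)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  write_calls_tsv(calls, paste0(prefix, ".calls.tsv"))
  write_gff3(calls, paste0(prefix, ".gff3"))
  write_params(config, paste0(prefix, ".params.txt"))
  invisible(list(status = if (nrow(calls) > 0L) 0L else 1L, calls = calls))
}

#' Verify/correct external predictions in bulk
#'
#' Runs [adjust_external_call()] over a predictions TSV
#' ([read_external_predictions()]) and writes the adjusted calls.
#'
#' @param config An [run_config()] list with `genomes`, `predictions`,
#'   `trna_db` set.
#' @return As [run_detect()], invisibly.
#' @export
run_adjust <- function(config) {
  require_inputs(config, c("genomes", "predictions", "trna_db"))
  genomes <- read_genome_fasta(config$genomes)
  db <- read_trna_db(config$trna_db)
  preds <- read_external_predictions(config$predictions)
  calls <- bind_rows(map(seq_len(nrow(preds)), function(i) {
    adjust_external_call(preds[i, ], genomes, db,
                         flank = config$flank, window = config$window,
                         min_coverage = config$min_coverage,
                         min_intron_len = config$min_intron_len)
  }))
  if (nrow(calls) == 0L) calls <- empty_calls()
  prefix <- file.path(config$out_dir, config$out_prefix)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  write_calls_tsv(calls, paste0(prefix, ".adjusted.tsv"))
  write_params(config, paste0(prefix, ".params.txt"))
  invisible(list(status = if (nrow(calls) > 0L) 0L else 1L, calls = calls))
}

#' Classify host loci for a table of introns
#'
#' Reads a calls TSV plus whichever evidence tables are configured --
#' `rrna_hits` / `tmrna_hits` (Infernal `--tblout`), `cds_hits` (TSV with
#' `genome_id`, `subject_id`, `start`, `end`, 1-based inclusive) and
#' `tnpb_hits` (TSV with `genome_id`, `start`, `end`) -- and writes
#' `<prefix>.classification.tsv`.  Calls in the input are tRNA-hosted by
#' construction; the evidence tables serve the non-tRNA intron intervals
#' passed via an `introns` TSV (`intron_id`, `genome_id`, `start`, `end`).
#'
#' @param config An [run_config()] list; requires `calls` or an `introns`
#'   table under `predictions`.
#' @return A list with `status` and the classification tibble, invisibly.
#' @export
run_classify <- function(config) {
  require_inputs(config, "calls")
  calls <- read_calls_tsv(config$calls)
  introns <- tibble(
    intron_id = calls$call_id, genome_id = calls$genome_id,
    start0 = calls$intron_start0, end0 = calls$intron_end0,
    is_trna = TRUE
  )
  read_model_tbl <- function(key) {
    path <- config[[key]]
    if (is.null(path)) return(NULL)
    h <- read_cm_tblout(path, evalue_max = Inf)
    iv <- iv_from_1based(h$start, h$stop)
    tibble(genome_id = h$target_id, model = h$model,
           start0 = iv$start0, end0 = iv$end0)
  }
  read_iv_tsv <- function(key, extra = character()) {
    path <- config[[key]]
    if (is.null(path)) return(NULL)
    raw <- readr::read_tsv(path, show_col_types = FALSE)
    iv <- iv_from_1based(raw$start, raw$end)
    out <- tibble(genome_id = raw$genome_id, start0 = iv$start0,
                  end0 = iv$end0)
    for (col in extra) out[[col]] <- raw[[col]]
    out
  }
  cls <- classify_hosts(
    introns,
    rrna_hits = read_model_tbl("rrna_hits"),
    tmrna_hits = read_model_tbl("tmrna_hits"),
    cds_hits = read_iv_tsv("cds_hits", "subject_id"),
    tnpb_hits = read_iv_tsv("tnpb_hits")
  )
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  prefix <- file.path(config$out_dir, config$out_prefix)
  readr::write_tsv(cls, paste0(prefix, ".classification.tsv"))
  write_params(config, paste0(prefix, ".params.txt"))
  invisible(list(status = 0L, classification = cls))
}

#' Aggregate survey statistics from a calls table
#'
#' Builds the survey table and writes one TSV per summary:
#' `stats_retention.tsv`, `stats_positions.tsv`, `stats_lengths.tsv`,
#' `stats_subgroups.tsv`, `stats_copies.tsv`.
#'
#' @param config An [run_config()] list with `calls` and `phylum_map` set
#'   (paths); optionally `subgroup_scores` (TSV `intron_id`, `model`,
#'   `score`).
#' @return A list with `status` and the survey tibble, invisibly.
#' @export
run_stats <- function(config) {
  require_inputs(config, c("calls", "phylum_map"))
  calls <- read_calls_tsv(config$calls)
  pmap_tbl <- readr::read_tsv(config$phylum_map, show_col_types = FALSE)
  subgroups <- NULL
  if (!is.null(config$subgroup_scores)) {
    scores <- readr::read_tsv(config$subgroup_scores,
                              show_col_types = FALSE)
    subgroups <- assign_subgroup(scores, intron_ids = calls$call_id)
  }
  heg <- scan_heg_orfs(calls, config$orf_min, config$heg_len)
  survey <- build_survey(calls, pmap_tbl, subgroups = subgroups,
                         heg_calls = unique(heg$call_id))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  w <- function(x, f) readr::write_tsv(x, file.path(config$out_dir, f))
  w(retention_rate(survey, pmap_tbl, config$min_genomes),
    "stats_retention.tsv")
  w(position_matrix(survey), "stats_positions.tsv")
  w(tidy(length_histogram(survey, heg_len = config$heg_len)),
    "stats_lengths.tsv")
  w(count(survey, .data$subgroup), "stats_subgroups.tsv")
  w(copy_number_stats(survey), "stats_copies.tsv")
  write_params(config, file.path(config$out_dir, "stats.params.txt"))
  invisible(list(status = 0L, survey = survey))
}

#' Generate and write a synthetic survey
#'
#' Runs [make_survey()] under the config seed and writes `genomes.fna`,
#' `hits.tbl` (Infernal `--tblout` layout), `trna_db.fna`, `aragorn.tsv`,
#' `truth.tsv` and `phylum_map.tsv` into `out_dir`.  Fixed seed gives
#' byte-identical output.
#'
#' @param config An [run_config()] list (`seed`, `jitter`, `out_dir`).
#' @return A list with `status` and the survey object, invisibly.
#' @export
run_simulate <- function(config) {
  sim <- make_survey(config$seed, jitter = config$jitter)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  p <- function(f) file.path(config$out_dir, f)
  write_genome_fasta(sim$genomes, p("genomes.fna"))
  write_cm_tblout(sim$hits, p("hits.tbl"))
  write_trna_db(sim$trna_db, p("trna_db.fna"))
  ar <- iv_to_1based(sim$aragorn$start0, sim$aragorn$end0)
  readr::write_tsv(
    tibble(genome_id = sim$aragorn$genome_id, strand = sim$aragorn$strand,
           intron_start = ar$start, intron_end = ar$end),
    p("aragorn.tsv")
  )
  readr::write_tsv(sim$truth, p("truth.tsv"))
  readr::write_tsv(sim$phylum_map, p("phylum_map.tsv"))
  write_params(config, p("simulate.params.txt"))
  invisible(list(status = 0L, survey = sim))
}
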