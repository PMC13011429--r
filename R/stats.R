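# Survey statistics over resolved calls: subgroup assignment, per-phylum
# retention rates, per-genome copy numbers, insertion-position matrices and
# intron length distributions.

#' Assemble a survey table from calls and annotations
#'
#' One row per detected intron, joining phylum labels, host categories,
#' subgroup assignments and HEG flags onto the calls.
#'
#' @param calls Calls tibble ([resolve_candidates()]).
#' @param genome_phylum_map Tibble (`genome_id`, `phylum`).
#' @param classifications Optional tibble (`intron_id`, `category`) keyed
#'   by `call_id`; calls default to category `"tRNA"`.
#' @param subgroups Optional tibble (`intron_id`, `subgroup`).
#' @param heg_calls Optional character vector of `call_id`s carrying a
#'   homing-endonuclease ORF.
#' @return A survey tibble with columns `genome_id`, `phylum`, `intron_id`,
#'   `class`, `category`, `site`, `amino_acid`, `anticodon`, `length`,
#'   `subgroup`, `has_heg`.
#' @export
build_survey <- function(calls, genome_phylum_map, classifications = NULL,
                         subgroups = NULL, heg_calls = character()) {
  unmapped <- setdiff(unique(calls$genome_id), genome_phylum_map$genome_id)
  if (length(unmapped) > 0L) {
    stop("genome(s) missing from phylum map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out <- calls |>
    left_join(genome_phylum_map, by = "genome_id") |>
    mutate(
      intron_id = .data$call_id,
      class = .data$intron_class,
      length = nchar(.data$intron_seq),
      category = "tRNA",
      subgroup = "unassigned",
      has_heg = .data$call_id %in% heg_calls
    ) |>
    select("genome_id", "phylum", "intron_id", "class", "category",
           "site", "amino_acid", "anticodon", "length", "subgroup",
           "has_heg")
  if (!is.null(classifications)) {
    out <- out |>
      left_join(rename_cat(classifications), by = "intron_id") |>
      mutate(category = dplyr::coalesce(.data$category_new,
                                        .data$category)) |>
      select(-"category_new")
  }
  if (!is.null(subgroups)) {
    out <- out |>
      left_join(select(subgroups, "intron_id", subgroup_new = "subgroup"),
                by = "intron_id") |>
      mutate(subgroup = dplyr::coalesce(.data$subgroup_new,
                                        .data$subgroup)) |>
      select(-"subgroup_new")
  }
  out
}

rename_cat <- function(classifications) {
  select(classifications, "intron_id", category_new = "category")
}

#' Assign group I intron subgroups from covariance-model scores
#'
#' Each intron is assigned the subgroup whose model scored highest
#' (cmscan `--max`-style table); score ties break lexicographically by
#' model name (and are reported via `message()`); introns without any row
#' are `"unassigned"`.
#'
#' @param subgroup_score_table Tibble (`intron_id`, `model`, `score`).
#' @param intron_ids Optional character vector of all intron ids, so that
#'   introns absent from the score table get an explicit `"unassigned"`.
#' @return A tibble (`intron_id`, `subgroup`).
#' @export
assign_subgroup <- function(subgroup_score_table,
                            intron_ids = unique(subgroup_score_table$intron_id)) {
  best <- subgroup_score_table |>
    group_by(.data$intron_id) |>
    arrange(desc(.data$score), .data$model, .by_group = TRUE) |>
    mutate(.tie = n() > 1L & sum(.data$score == max(.data$score)) > 1L) |>
    slice(1L) |>
    ungroup()
  ties <- best$intron_id[best$.tie]
  if (length(ties) > 0L) {
    message("subgroup score tie broken lexicographically for: ",
            paste(ties, collapse = ", "))
  }
  tibble(intron_id = intron_ids) |>
    left_join(select(best, "intron_id", subgroup = "model"),
              by = "intron_id") |>
    mutate(subgroup = dplyr::coalesce(.data$subgroup, "unassigned"))
}

#' Per-phylum intron retention rates
#'
#' The retention rate is the number of genomes carrying at least one
#' intron of a class divided by the total number of genomes of that phylum
#' in the input set.  Phyla with fewer than `min_genomes` genomes are kept
#' in the full table but flagged `plotted = FALSE` (they are excluded from
#' the plotted summary).
#'
#' @param survey Survey tibble ([build_survey()]).
#' @param genome_phylum_map Tibble (`genome_id`, `phylum`) covering every
#'   screened genome (the denominator), not only genomes with introns.
#' @param min_genomes Minimal phylum size for plotting (default 20).
#' @param classes Intron classes to tabulate.
#' @return A tibble (`phylum`, `class`, `n_genomes`, `n_with_intron`,
#'   `rate`, `plotted`).
#' @export
retention_rate <- function(survey, genome_phylum_map, min_genomes = 20L,
                           classes = c("groupI", "groupII")) {
  unmapped <- setdiff(unique(survey$genome_id), genome_phylum_map$genome_id)
  if (length(unmapped) > 0L) {
    stop("genome(s) missing from phylum map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  totals <- count(genome_phylum_map, .data$phylum, name = "n_genomes")
  grid <- tidyr::expand_grid(phylum = totals$phylum, class = classes)
  with_introns <- survey |>
    distinct(.data$phylum, .data$class, .data$genome_id) |>
    count(.data$phylum, .data$class, name = "n_with_intron")
  grid |>
    left_join(totals, by = "phylum") |>
    left_join(with_introns, by = c("phylum", "class")) |>
    mutate(
      n_with_intron = dplyr::coalesce(.data$n_with_intron, 0L),
      rate = .data$n_with_intron / .data$n_genomes,
      plotted = .data$n_genomes >= min_genomes
    ) |>
    arrange(.data$phylum, .data$class)
}

#' Per-genome intron copy-number statistics
#'
#' Computed over genomes containing at least one intron of each class;
#' the standard deviation is the sample (n - 1) estimate, reported as 0
#' with `sd_degenerate = TRUE` when only one genome qualifies.
#'
#' @param survey Survey tibble.
#' @return A tibble (`class`, `n_genomes`, `mean`, `sd`, `median`,
#'   `sd_degenerate`); zero rows for an empty survey.
#' @export
copy_number_stats <- function(survey) {
  if (nrow(survey) == 0L) {
    return(tibble(class = character(), n_genomes = integer(),
                  mean = double(), sd = double(), median = double(),
                  sd_degenerate = logical()))
  }
  survey |>
    count(.data$class, .data$genome_id, name = "copies") |>
    group_by(.data$class) |>
    summarise(
      n_genomes = n(),
      mean = mean(.data$copies),
      sd = if (n() > 1L) sd(.data$copies) else 0,
      median = median(.data$copies),
      sd_degenerate = n() == 1L
    )
}

#' Insertion-position count matrix
#'
#' Counts tRNA-hosted introns by phylum, insertion site and amino acid;
#' the marginal sums conserve the total tRNA-intron count.
#'
#' @param survey Survey tibble.
#' @return A tibble (`phylum`, `site`, `amino_acid`, `n`).
#' @export
position_matrix <- function(survey) {
  survey |>
    filter(.data$category == "tRNA") |>
    count(.data$phylum, .data$site, .data$amino_acid, name = "n")
}

#' Intron length distribution with the HEG-eligibility flag
#'
#' Bins intron lengths and records which introns exceed the 500-bp
#' threshold above which group I introns can carry homing endonuclease
#' genes.
#'
#' @param survey Survey tibble.
#' @param binwidth Histogram bin width in bp (default 50).
#' @param heg_len HEG-eligibility threshold in bp (default 500).
#' @return An object of class `intron_length_dist`; use [tidy()] for the
#'   binned histogram and [glance()] for the summary (n, min, max, mean,
#'   `n_heg_eligible`).
#' @export
length_histogram <- function(survey, binwidth = 50L, heg_len = 500L) {
  lengths <- survey$length
  breaks <- if (length(lengths) > 0L) {
    seq(0L, (max(lengths) %/% binwidth + 1L) * binwidth, by = binwidth)
  } else {
    c(0L, binwidth)
  }
  counts <- if (length(lengths) > 0L) {
    tabulate(findInterval(lengths, breaks, left.open = FALSE),
             nbins = length(breaks) - 1L)
  } else {
    rep(0L, length(breaks) - 1L)
  }
  structure(
    list(
      histogram = tibble(
        bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
        count = counts
      ),
      lengths = lengths, heg_len = heg_len
    ),
    class = "intron_length_dist"
  )
}

#' @export
tidy.intron_length_dist <- function(x, ...) x$histogram

#' @export
glance.intron_length_dist <- function(x, ...) {
  tibble(
    n = length(x$lengths),
    min = if (length(x$lengths)) min(x$lengths) else NA_integer_,
    max = if (length(x$lengths)) max(x$lengths) else NA_integer_,
    mean = if (length(x$lengths)) mean(x$lengths) else NA_real_,
    n_heg_eligible = sum(x$lengths > x$heg_len)
  )
}

#' @export
print.intron_length_dist <- function(x, ...) {
  g <- glance(x)
  cat("intron length distribution: n =", g$n, ", range", g$min, "-", g$max,
      "bp, mean", round(g$mean, 1), "bp,", g$n_heg_eligible,
      "introns > ", x$heg_len, "bp (HEG-eligible)\n")
  invisible(x)
}
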