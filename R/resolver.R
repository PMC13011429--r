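# Splice-boundary resolution for group I intron candidates in tRNA genes.
#
# A covariance-model hit only approximately locates an intron.  The exact
# boundaries are recovered by enumerating every (a, b) pair near the hit
# that satisfies the group I splicing rules -- the 5' exon ends on a U
# (T in DNA), the intron ends on the omega-G, and the spliced product folds
# into a cloverleaf with the splice junction inside the 7-nt anticodon
# loop -- and then letting the top-scoring intron-less homolog arbitrate
# among the surviving boundary frames.  Shifting a boundary by two
# nucleotides typically converts the call into a different isoacceptor
# (e.g. Asn (GTT) at 35/36 versus a Thr-like (TGT) frame at 33/34), so the
# homolog database is the sole reliable arbiter between frames.

empty_calls <- function() {
  tibble(
    call_id = character(), genome_id = character(), strand = character(),
    gene_start0 = integer(), gene_end0 = integer(),
    intron_start0 = integer(), intron_end0 = integer(),
    exon1_len = integer(), trna_seq = character(), anticodon = character(),
    amino_acid = character(), intron_seq = character(),
    intron_class = character(), site = character(),
    top_homolog_id = character(), homolog_score = double(),
    homolog_identity = double(), homolog_coverage = double(),
    shift_a = integer(), shift_b = integer(), n_hypotheses = integer(),
    cau_flag = logical(), cau_resolved = logical(),
    boundary_adjusted = logical(), status = character(),
    truncated_context = logical()
  )
}

#' Extract strand-normalised genomic context around an intron candidate
#'
#' Pulls `flank` nucleotides on either side of the candidate interval and
#' reverse-complements minus-strand candidates so all downstream logic is
#' strand-free.  The returned object maps context coordinates back to
#' genome coordinates.
#'
#' @param candidate One-row tibble with columns `genome_id`, `start0`,
#'   `end0`, `strand` (internal 0-based half-open coordinates).
#' @param genomes Tibble from [read_genome_fasta()].
#' @param flank Nucleotides of context on each side (default 400).
#' @return A list with elements `ctx` (context sequence), `cand_start` /
#'   `cand_end` (candidate interval in context coordinates), `strand`,
#'   `truncated` (flag set when the candidate lies within `flank` of a
#'   contig end), and `to_genome(start0, end0)` mapping context intervals
#'   back to genome plus-strand coordinates.
#' @export
extract_context <- function(candidate, genomes, flank = 400L) {
  stopifnot(flank >= 0L, nrow(candidate) == 1L)
  gi <- match(candidate$genome_id, genomes$id)
  if (is.na(gi)) {
    stop("genome id not found: ", candidate$genome_id, call. = FALSE)
  }
  gseq <- genomes$seq[gi]
  L <- nchar(gseq)
  s <- max(0L, candidate$start0 - flank)
  e <- min(L, candidate$end0 + flank)
  truncated <- (candidate$start0 - flank) < 0L || (candidate$end0 + flank) > L
  ctx <- sub0(gseq, s, e)
  minus <- identical(candidate$strand, "-")
  if (minus) ctx <- revcomp(ctx)
  list(
    ctx = ctx,
    cand_start = if (minus) e - candidate$end0 else candidate$start0 - s,
    cand_end = if (minus) e - candidate$start0 else candidate$end0 - s,
    strand = candidate$strand,
    truncated = truncated,
    to_genome = if (minus) {
      function(start0, end0) c(e - end0, e - start0)
    } else {
      function(start0, end0) c(s + start0, s + end0)
    }
  )
}

#' Check for tRNA sequence on both sides of a candidate intron
#'
#' Aligns the upstream and downstream flanks of the candidate against the
#' intron-less reference set; a side counts as tRNA-bearing when its best
#' local alignment reaches `min_side_score` (comfortably above what two
#' unrelated sequences of these lengths produce under blastn-short scoring,
#' and below the score of a genuine exon fragment).
#'
#' @param context List from [extract_context()].
#' @param trna_db Reference set from [read_trna_db()].
#' @param min_side_score Minimal alignment score per side (default 12:
#'   under this scoring, unrelated 400-nt flanks top out around 10 while
#'   genuine exon fragments of ~90%-identity homologs score 16 or more).
#' @param params Alignment parameters ([align_params()]).
#' @return A one-row tibble with `ok`, `score_5p`, `score_3p`.
#' @export
flanking_trna_check <- function(context, trna_db, min_side_score = 12,
                                params = align_params()) {
  # one vectorised score-only alignment call per side (local alignment
  # scores are symmetric, so the references go in as patterns)
  side_score <- function(side_seq) {
    if (nchar(side_seq) < params$word_size) return(0)
    seeded <- map_lgl(trna_db$seq,
                      function(s) has_seed(side_seq, s, params$word_size))
    if (!any(seeded)) return(0)
    scores <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(trna_db$seq[seeded]),
      subject = side_seq, type = "local",
      substitutionMatrix = align_submat(params),
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE
    )
    max(0, scores)
  }
  s5 <- side_score(sub0(context$ctx, 0L, context$cand_start))
  s3 <- side_score(sub0(context$ctx, context$cand_end, nchar(context$ctx)))
  tibble(ok = s5 >= min_side_score && s3 >= min_side_score,
         score_5p = s5, score_3p = s3)
}

#' Enumerate candidate splice boundaries around a model hit
#'
#' Exhaustively scans every pair `(a, b)` with `a` within `window` of the
#' candidate start and `b` within `window` of the candidate end (0-based
#' half-open intron `[a, b)`), keeping pairs that satisfy the group I
#' rules: the context base before `a` is T (the 5'-exon terminal U), the
#' base before `b` is G (the omega-G), the intron is at least
#' `min_intron_len` nt, and the spliced product folds into a cloverleaf
#' with the splice junction on anticodon-loop positions 32-37.
#'
#' @param context List from [extract_context()], or a plain context string
#'   (then give `cand_start`/`cand_end`).
#' @param cand_start,cand_end Candidate interval in context coordinates;
#'   taken from `context` when it is an [extract_context()] result.
#' @param window Maximal boundary shift explored on each side (default 10).
#' @param min_intron_len Minimal intron length (default 50; the smallest
#'   group I catalytic cores are larger).
#' @return A tibble of boundary hypotheses with columns `a`, `b`, `site`,
#'   `loop_index`, `anticodon`, `mature_seq`, `gene_start_s`, `gene_end_s`
#'   (gene span in spliced-context coordinates), `n_pairs`, and list-column
#'   `fold`.  Zero rows when nothing qualifies.
#' @export
enumerate_boundaries <- function(context, cand_start = context$cand_start,
                                 cand_end = context$cand_end,
                                 window = 10L, min_intron_len = 50L) {
  stopifnot(window >= 0L)
  ctx <- if (is.list(context)) context$ctx else context
  L <- nchar(ctx)
  chars <- strsplit(ctx, "", fixed = TRUE)[[1L]]
  ci <- match(chars, c("A", "C", "G", "T", "N"))
  out <- list()
  for (a in (cand_start - window):(cand_start + window)) {
    if (a < 1L || a >= L) next
    if (chars[a] != "T") next        # context base at 0-based a-1
    for (b in (cand_end - window):(cand_end + window)) {
      if (b > L || b - a < min_intron_len) next
      if (chars[b] != "G") next      # context base at 0-based b-1
      si <- c(ci[seq_len(a)], if (b < L) ci[(b + 1L):L] else integer(0))
      p <- cl_fold_params_at_junction(si, a)
      if (is.null(p)) next
      spliced <- paste0(sub0(ctx, 0L, a), sub0(ctx, b, L))
      fold <- new_cloverleaf(spliced, p)
      i <- (a - 1L) - fold$loop_start0 + 1L
      out[[length(out) + 1L]] <- tibble(
        a = a, b = b,
        site = insertion_site_label(i), loop_index = i,
        anticodon = fold$anticodon,
        mature_seq = substr(spliced, fold$gene_start0 + 1L, fold$gene_end0),
        gene_start_s = fold$gene_start0, gene_end_s = fold$gene_end0,
        n_pairs = fold$n_pairs, fold = list(fold)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      a = integer(), b = integer(), site = character(),
      loop_index = integer(), anticodon = character(),
      mature_seq = character(), gene_start_s = integer(),
      gene_end_s = integer(), n_pairs = integer(), fold = list()
    ))
  }
  bind_rows(out)
}

# Score hypotheses against the homolog database and pick the winner by:
# (1) highest homolog alignment score, (2) anticodon equal to the top
# homolog's, (3) smallest total boundary shift, (4) leftmost a.
select_hypothesis <- function(hyps, trna_db, cand_start, cand_end,
                              min_coverage, params) {
  scored <- map(seq_len(nrow(hyps)), function(i) {
    top <- search_db(hyps$mature_seq[i], trna_db, min_coverage, params)
    if (nrow(top) == 0L) return(NULL)
    top <- top[1L, ]
    mutate(hyps[i, ],
      top_homolog_id = top$subject_id,
      homolog_score = top$score,
      homolog_identity = top$identity,
      homolog_coverage = top$coverage,
      homolog_amino_acid = top$subject_amino_acid,
      anticodon_match = .data$anticodon == top$subject_anticodon
    )
  })
  scored <- bind_rows(scored)
  if (nrow(scored) == 0L) return(NULL)
  scored |>
    mutate(total_shift = abs(.data$a - cand_start) + abs(.data$b - cand_end)) |>
    arrange(desc(.data$homolog_score), desc(.data$anticodon_match),
            .data$total_shift, .data$a) |>
    slice(1L)
}

col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

# Assemble a one-row ResolvedCall tibble from a winning hypothesis.
build_call <- function(hyp, context, candidate, n_hypotheses,
                       intron_class = "groupI", boundary_adjusted = FALSE,
                       status = "ok") {
  shift_len <- hyp$b - hyp$a
  gene_end_ctx <- hyp$gene_end_s + shift_len
  gene_iv <- context$to_genome(hyp$gene_start_s, gene_end_ctx)
  intron_iv <- context$to_genome(hyp$a, hyp$b)
  anticodon <- hyp$anticodon
  cau <- identical(anticodon, "CAT")
  # for CAT this provisional "Met" is finalised by assign_cau_identity()
  aa <- if (is.na(anticodon)) NA_character_ else aa_from_anticodon(anticodon)
  tibble(
    call_id = paste0(candidate$genome_id, ":", intron_iv[1L], "-",
                     intron_iv[2L], candidate$strand),
    genome_id = candidate$genome_id,
    strand = candidate$strand,
    gene_start0 = gene_iv[1L], gene_end0 = gene_iv[2L],
    intron_start0 = intron_iv[1L], intron_end0 = intron_iv[2L],
    exon1_len = hyp$a - hyp$gene_start_s,
    trna_seq = hyp$mature_seq,
    anticodon = anticodon,
    amino_acid = aa,
    intron_seq = sub0(context$ctx, hyp$a, hyp$b),
    intron_class = intron_class,
    site = hyp$site,
    top_homolog_id = col_or(hyp, "top_homolog_id", NA_character_),
    homolog_score = col_or(hyp, "homolog_score", NA_real_),
    homolog_identity = col_or(hyp, "homolog_identity", NA_real_),
    homolog_coverage = col_or(hyp, "homolog_coverage", NA_real_),
    shift_a = hyp$a - context$cand_start,
    shift_b = hyp$b - context$cand_end,
    n_hypotheses = n_hypotheses,
    cau_flag = cau,
    cau_resolved = FALSE,
    boundary_adjusted = boundary_adjusted,
    status = status,
    truncated_context = context$truncated
  )
}

#' Resolve a group I intron candidate into a tRNA call
#'
#' Runs the full boundary-resolution procedure for one covariance-model
#' candidate: extract 400-bp context (strand-normalised), require tRNA
#' sequence on both sides of the candidate, enumerate boundary hypotheses
#' under the U / omega-G / anticodon-loop rules, rank each surviving
#' hypothesis by its top-scoring intron-less homolog (query coverage
#' > `min_coverage`), and select the winner by homolog score, anticodon
#' agreement, minimal boundary shift, then leftmost start.
#'
#' @param candidate One-row tibble (`genome_id`, `start0`, `end0`,
#'   `strand`), e.g. a row of [hits_as_candidates()].
#' @param genomes Tibble from [read_genome_fasta()].
#' @param trna_db Intron-less reference set from [read_trna_db()].
#' @param flank,window,min_coverage,min_intron_len,min_side_score Tuning
#'   parameters; see [run_config()] for defaults and units.
#' @param params Alignment parameters ([align_params()]).
#' @return A one-row calls tibble (see [empty_calls()] for the column
#'   contract) or `NULL` when the flanking check fails or no hypothesis
#'   passes the homolog coverage threshold.
#' @export
resolve <- function(candidate, genomes, trna_db, flank = 400L, window = 10L,
                    min_coverage = 75, min_intron_len = 50L,
                    min_side_score = 12, params = align_params()) {
  context <- extract_context(candidate, genomes, flank)
  fc <- flanking_trna_check(context, trna_db, min_side_score, params)
  if (!fc$ok) return(NULL)
  hyps <- enumerate_boundaries(context, window = window,
                               min_intron_len = min_intron_len)
  if (nrow(hyps) == 0L) return(NULL)
  win <- select_hypothesis(hyps, trna_db, context$cand_start,
                           context$cand_end, min_coverage, params)
  if (is.null(win)) return(NULL)
  build_call(win, context, candidate, n_hypotheses = nrow(hyps))
}

#' Resolve a table of candidates
#'
#' Vectorised driver around [resolve()].  Candidates overlapping annotated
#' rRNA loci are skipped here (they are classified by [classify_host()]
#' instead, preventing double counting).
#'
#' @param candidates Tibble of candidate rows ([hits_as_candidates()]).
#' @param genomes,trna_db,... Passed to [resolve()].
#' @param rrna_loci Optional tibble (`genome_id`, `start0`, `end0`) of
#'   annotated rRNA genes to exclude.
#' @return A calls tibble (possibly zero rows).
#' @export
resolve_candidates <- function(candidates, genomes, trna_db,
                               rrna_loci = NULL, ...) {
  if (!is.null(rrna_loci) && nrow(candidates) > 0L) {
    keep <- map_lgl(seq_len(nrow(candidates)), function(i) {
      cc <- candidates[i, ]
      r <- filter(rrna_loci, .data$genome_id == cc$genome_id)
      !any(pmin(r$end0, cc$end0) > pmax(r$start0, cc$start0))
    })
    candidates <- candidates[keep, ]
  }
  calls <- map(seq_len(nrow(candidates)), function(i) {
    resolve(candidates[i, ], genomes, trna_db, ...)
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0L) empty_calls() else out
}

#' Resolve the amino acid of a CAT-anticodon call from homologs
#'
#' tRNAs with the CAT anticodon may be Met, initiator fMet, or
#' lysidine-modified Ile2; the distinction is not readable from the
#' anticodon, so the label is copied from the top-scoring CAT-anticodon
#' intron-less homolog.
#'
#' @param call One-row calls tibble with `anticodon == "CAT"`.
#' @param trna_db Reference set; its `amino_acid` labels distinguish Met /
#'   fMet / Ile2.
#' @param min_coverage,params As in [resolve()].
#' @return The call with `amino_acid` replaced by the homolog label and
#'   `cau_resolved = TRUE`, or labelled `"Met?"` with
#'   `cau_resolved = FALSE` when the database holds no CAT reference.
#' @export
assign_cau_identity <- function(call, trna_db, min_coverage = 75,
                                params = align_params()) {
  stopifnot(nrow(call) == 1L)
  if (!identical(call$anticodon, "CAT")) {
    stop("assign_cau_identity requires a CAT-anticodon call", call. = FALSE)
  }
  cat_db <- filter(trna_db, .data$anticodon == "CAT")
  if (nrow(cat_db) == 0L) {
    return(mutate(call, amino_acid = "Met?", cau_resolved = FALSE))
  }
  hits <- search_db(call$trna_seq, cat_db, min_coverage, params)
  if (nrow(hits) == 0L) {
    return(mutate(call, amino_acid = "Met?", cau_resolved = FALSE))
  }
  mutate(call, amino_acid = hits$subject_amino_acid[1L], cau_resolved = TRUE)
}

#' Verify or correct an externally predicted intron-containing tRNA
#'
#' Consumes a tFind/ARAGORN-style prediction (gene plus exon/intron
#' segmentation).  When the predicted mature anticodon matches the
#' top-scoring intron-less homolog (coverage > `min_coverage`) the call is
#' accepted as-is; otherwise boundaries are re-enumerated around the
#' predicted ones and re-selected with [resolve()]'s criteria.  When no
#' homolog clears the coverage threshold the prediction is returned with
#' status `"unverified"`.
#'
#' @param prediction One-row tibble with columns `genome_id`, `strand`,
#'   `intron_start0`, `intron_end0` (internal 0-based coordinates; see
#'   [read_external_predictions()] for the 1-based TSV dialect).
#' @param genomes,trna_db,flank,window,min_coverage,min_intron_len,params
#'   As in [resolve()].
#' @return A one-row calls tibble; `boundary_adjusted` records whether the
#'   external boundaries were moved.
#' @export
adjust_external_call <- function(prediction, genomes, trna_db, flank = 400L,
                                 window = 10L, min_coverage = 75,
                                 min_intron_len = 50L,
                                 params = align_params()) {
  stopifnot(nrow(prediction) == 1L)
  candidate <- tibble(
    genome_id = prediction$genome_id,
    start0 = prediction$intron_start0, end0 = prediction$intron_end0,
    strand = prediction$strand
  )
  context <- extract_context(candidate, genomes, flank)
  a <- context$cand_start
  b <- context$cand_end
  spliced <- paste0(sub0(context$ctx, 0L, a),
                    sub0(context$ctx, b, nchar(context$ctx)))
  fold <- cl_fold_at_junction(spliced, a)
  pred_hyp <- NULL
  if (!is.null(fold)) {
    i <- (a - 1L) - fold$loop_start0 + 1L
    pred_hyp <- tibble(
      a = a, b = b, site = insertion_site_label(i), loop_index = i,
      anticodon = fold$anticodon,
      mature_seq = substr(spliced, fold$gene_start0 + 1L, fold$gene_end0),
      gene_start_s = fold$gene_start0, gene_end_s = fold$gene_end0,
      n_pairs = fold$n_pairs, fold = list(fold)
    )
    top <- search_db(pred_hyp$mature_seq, trna_db, min_coverage, params)
    if (nrow(top) > 0L &&
        identical(top$subject_anticodon[1L], pred_hyp$anticodon)) {
      t1 <- top[1L, ]
      accepted <- mutate(pred_hyp,
        top_homolog_id = t1$subject_id, homolog_score = t1$score,
        homolog_identity = t1$identity, homolog_coverage = t1$coverage,
        homolog_amino_acid = t1$subject_amino_acid
      )
      return(build_call(accepted, context, candidate, n_hypotheses = 1L))
    }
  }
  hyps <- enumerate_boundaries(context, window = window,
                               min_intron_len = min_intron_len)
  if (nrow(hyps) > 0L) {
    win <- select_hypothesis(hyps, trna_db, context$cand_start,
                             context$cand_end, min_coverage, params)
    if (!is.null(win)) {
      adjusted <- !(win$a == a && win$b == b)
      return(build_call(win, context, candidate, n_hypotheses = nrow(hyps),
                        boundary_adjusted = adjusted))
    }
  }
  # no homolog above coverage: return the external call, unverified
  fallback <- pred_hyp %||% tibble(
    a = a, b = b, site = NA_character_, loop_index = NA_integer_,
    anticodon = NA_character_, mature_seq = spliced,
    gene_start_s = 0L, gene_end_s = nchar(spliced),
    n_pairs = NA_integer_, fold = list(NULL)
  )
  build_call(fallback, context, candidate, n_hypotheses = 0L,
             status = "unverified")
}

#' Call group II introns from ARAGORN / RF00029 overlap
#'
#' A tRNA intron region reported by ARAGORN becomes a group II candidate
#' when it overlaps a group II covariance-model hit on the same genome and
#' strand.  Boundaries are then set by homolog alignment rather than the
#' group I U / omega-G rules: every small boundary shift whose spliced
#' product folds is scored against the intron-less references and the best
#' alignment wins.  The splice junction is not restricted to the anticodon
#' loop, so the site may come out as `"D-loop"`.
#'
#' @param aragorn_introns Tibble (`genome_id`, `start0`, `end0`, `strand`)
#'   of ARAGORN-style tRNA intron intervals.
#' @param rf00029_hits Candidate tibble of group II model hits
#'   ([hits_as_candidates()]).
#' @param genomes,trna_db,flank,min_coverage,params As in [resolve()].
#' @param window Boundary-shift window for the alignment-guided adjustment
#'   (default 5).
#' @param min_intron_len Minimal intron length (default 50).
#' @return A calls tibble with `intron_class == "groupII"`.
#' @export
group2_trna_overlap <- function(aragorn_introns, rf00029_hits, genomes,
                                trna_db, flank = 400L, window = 5L,
                                min_coverage = 75, min_intron_len = 50L,
                                params = align_params()) {
  calls <- list()
  for (i in seq_len(nrow(aragorn_introns))) {
    ai <- aragorn_introns[i, ]
    h <- filter(rf00029_hits, .data$genome_id == ai$genome_id,
                .data$strand == ai$strand)
    if (!any(pmin(h$end0, ai$end0) > pmax(h$start0, ai$start0))) next
    context <- extract_context(ai, genomes, flank)
    # the external segmentation is trusted as long as the spliced product's
    # anticodon matches the top intron-less homolog; boundaries are only
    # re-set from alignment when homology disagrees
    asis <- g2_enumerate(context, 0L, min_intron_len)
    if (nrow(asis) == 1L) {
      top <- search_db(asis$mature_seq, trna_db, min_coverage, params)
      if (nrow(top) > 0L &&
          identical(top$subject_anticodon[1L], asis$anticodon)) {
        t1 <- top[1L, ]
        accepted <- mutate(asis,
          top_homolog_id = t1$subject_id, homolog_score = t1$score,
          homolog_identity = t1$identity, homolog_coverage = t1$coverage,
          homolog_amino_acid = t1$subject_amino_acid
        )
        calls[[length(calls) + 1L]] <-
          build_call(accepted, context, ai, n_hypotheses = 1L,
                     intron_class = "groupII")
        next
      }
    }
    hyps <- g2_enumerate(context, window, min_intron_len)
    if (nrow(hyps) == 0L) next
    win <- select_hypothesis(hyps, trna_db, context$cand_start,
                             context$cand_end, min_coverage, params)
    if (is.null(win)) {
      pred <- hyps |>
        mutate(total_shift = abs(.data$a - context$cand_start) +
                 abs(.data$b - context$cand_end)) |>
        arrange(.data$total_shift, .data$a) |>
        slice(1L)
      calls[[length(calls) + 1L]] <-
        build_call(pred, context, ai, n_hypotheses = nrow(hyps),
                   intron_class = "groupII", status = "unverified")
    } else {
      calls[[length(calls) + 1L]] <-
        build_call(win, context, ai, n_hypotheses = nrow(hyps),
                   intron_class = "groupII",
                   boundary_adjusted = !(win$a == context$cand_start &&
                                           win$b == context$cand_end))
    }
  }
  out <- bind_rows(calls)
  if (nrow(out) == 0L) empty_calls() else out
}

# Boundary hypotheses for the group II path: no U/G requirement, junction
# may fall anywhere in the folded gene (anticodon loop, D loop, ...).
g2_enumerate <- function(context, window, min_intron_len) {
  ctx <- context$ctx
  L <- nchar(ctx)
  ci <- seq_to_int(ctx)
  out <- list()
  for (a in (context$cand_start - window):(context$cand_start + window)) {
    if (a < 1L || a >= L) next
    for (b in (context$cand_end - window):(context$cand_end + window)) {
      if (b > L || b - a < min_intron_len) next
      si <- c(ci[seq_len(a)], if (b < L) ci[(b + 1L):L] else integer(0))
      j <- a - 1L
      lo <- max(0L, j - 150L)
      hi <- min(length(si), j + 150L)
      win <- si[(lo + 1L):hi]
      jw <- j - lo
      starts <- (jw - 45L):(jw + 45L)
      p <- cl_search(win, length(win), starts[starts >= 0L], full = FALSE)
      if (is.null(p)) next
      p$g0 <- p$g0 + lo
      p$l0 <- p$l0 + lo
      spliced <- paste0(sub0(ctx, 0L, a), sub0(ctx, b, L))
      fold <- new_cloverleaf(spliced, p)
      if (j < fold$gene_start0 || j >= fold$gene_end0) next
      site <- g2_site(fold, j)
      out[[length(out) + 1L]] <- tibble(
        a = a, b = b, site = site,
        loop_index = if (startsWith(site, "3")) {
          (j - fold$loop_start0) + 1L
        } else NA_integer_,
        anticodon = fold$anticodon,
        mature_seq = substr(spliced, fold$gene_start0 + 1L, fold$gene_end0),
        gene_start_s = fold$gene_start0, gene_end_s = fold$gene_end0,
        n_pairs = fold$n_pairs, fold = list(fold)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(a = integer(), b = integer(), site = character(),
                  loop_index = integer(), anticodon = character(),
                  mature_seq = character(), gene_start_s = integer(),
                  gene_end_s = integer(), n_pairs = integer(),
                  fold = list()))
  }
  bind_rows(out)
}

g2_site <- function(fold, j) {
  r <- fold$regions
  inside <- function(region) {
    row <- r[r$region == region, ]
    j >= row$start0 && j < row$end0
  }
  loop_i <- (j - fold$loop_start0) + 1L
  if (loop_i >= 1L && loop_i <= 6L) return(insertion_site_label(loop_i))
  if (inside("d_loop")) return("D-loop")
  "other"
}
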