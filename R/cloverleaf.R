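# Cloverleaf secondary-structure validation for candidate mature tRNAs.
#
# This is a lightweight structural stand-in for covariance-model validation:
# it enumerates canonical bacterial tRNA layouts and accepts a placement when
# every stem reaches its complementarity threshold (Watson-Crick or G:T
# wobble pairs).  Thresholds: acceptor stem >= 6/7, anticodon and T stems
# >= 4/5, D stem >= (k-1)/k for stem length k in {3,4}.  Loop sizes are
# fixed: anticodon and T loops exactly 7 nt, D loop 7-11 nt, variable region
# 3-23 nt, 1-2 nt between acceptor stem and D arm, 0-1 nt between D arm and
# anticodon arm, and up to 4 trailing nt (discriminator/CCA remnant).
# Production runs may substitute an external structure validator; everything
# downstream only consumes the anticodon-loop coordinates.

# Pairing lookup over the integer alphabet A=1 C=2 G=3 T=4 N=5.
CL_PAIR <- local({
  m <- matrix(FALSE, 5L, 5L)
  m[1L, 4L] <- m[4L, 1L] <- TRUE  # A:T
  m[2L, 3L] <- m[3L, 2L] <- TRUE  # C:G
  m[3L, 4L] <- m[4L, 3L] <- TRUE  # G:T wobble
  m
})

seq_to_int <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T", "N"))
}

# Count complementary pairs between a 5' arm starting at 0-based s5 and the
# reversed 3' arm starting at 0-based s3, both of length `len`.  Returns -1
# when an ambiguous base sits in either arm (N never pairs and invalidates
# the stem outright).
stem_score <- function(si, s5, s3, len) {
  a <- si[(s5 + 1L):(s5 + len)]
  b <- si[(s3 + len):(s3 + 1L)]
  if (anyNA(a) || anyNA(b) || any(a == 5L) || any(b == 5L)) return(-1L)
  sum(CL_PAIR[cbind(a, b)])
}

# Exhaustive layout search.  `loop_starts` are the candidate 0-based
# anticodon-loop starts; `full = TRUE` additionally requires the fold to
# cover the whole sequence (gene start 0, at most 4 trailing nt).
cl_search <- function(si, L, loop_starts, full) {
  best <- NULL
  for (l0 in sort(unique(loop_starts))) {
    if (l0 - 5L < 0L || l0 + 12L > L) next
    loop <- si[(l0 + 1L):(l0 + 7L)]
    if (anyNA(loop) || any(loop == 5L)) next
    acs <- stem_score(si, l0 - 5L, l0 + 7L, 5L)
    if (acs < 4L) next
    lefts <- list()
    for (sp1 in 1:2) for (k in 3:4) for (dl in 7:11) for (sp2 in 0:1) {
      g0 <- l0 - 5L - sp2 - (2L * k + dl) - sp1 - 7L
      if (g0 < 0L || (full && g0 != 0L)) next
      ds <- g0 + 7L + sp1
      dsc <- stem_score(si, ds, ds + k + dl, k)
      if (dsc < k - 1L) next
      lefts[[length(lefts) + 1L]] <-
        list(g0 = g0, sp1 = sp1, k = k, dl = dl, sp2 = sp2, dsc = dsc)
    }
    if (length(lefts) == 0L) next
    for (v in 3:23) {
      gend <- l0 + 36L + v
      trailing <- L - gend
      if (full) {
        if (trailing < 0L || trailing > 4L) next
      } else {
        if (gend > L) next
        trailing <- 0L
      }
      tstart <- l0 + 12L + v
      tsc <- stem_score(si, tstart, tstart + 12L, 5L)
      if (tsc < 4L) next
      acc3 <- l0 + 29L + v
      for (lf in lefts) {
        asc <- stem_score(si, lf$g0, acc3, 7L)
        if (asc < 6L) next
        total <- acs + lf$dsc + tsc + asc
        # ties: prefer a placement showing the invariant U33 (T at loop
        # position 2), then the leftmost anticodon loop (enumeration order)
        u33 <- as.integer(loop[2L] == 4L)
        if (is.null(best) || total > best$n_pairs ||
            (total == best$n_pairs && u33 > best$u33)) {
          best <- c(lf, list(
            l0 = l0, v = v, trailing = trailing,
            acs = acs, tsc = tsc, asc = asc, n_pairs = total, u33 = u33
          ))
        }
      }
    }
  }
  best
}

cl_regions <- function(p) {
  ds <- p$g0 + 7L + p$sp1
  l0 <- p$l0
  tibble(
    region = c(
      "acceptor_stem_5p", "spacer_1", "d_stem_5p", "d_loop", "d_stem_3p",
      "spacer_2", "anticodon_stem_5p", "anticodon_loop", "anticodon_stem_3p",
      "variable_region", "t_stem_5p", "t_loop", "t_stem_3p",
      "acceptor_stem_3p", "trailing"
    ),
    start0 = c(
      p$g0, p$g0 + 7L, ds, ds + p$k, ds + p$k + p$dl,
      l0 - 5L - p$sp2, l0 - 5L, l0, l0 + 7L,
      l0 + 12L, l0 + 12L + p$v, l0 + 17L + p$v, l0 + 24L + p$v,
      l0 + 29L + p$v, l0 + 36L + p$v
    ),
    end0 = c(
      p$g0 + 7L, p$g0 + 7L + p$sp1, ds + p$k, ds + p$k + p$dl,
      ds + 2L * p$k + p$dl, l0 - 5L, l0, l0 + 7L, l0 + 12L,
      l0 + 12L + p$v, l0 + 17L + p$v, l0 + 24L + p$v, l0 + 29L + p$v,
      l0 + 36L + p$v, l0 + 36L + p$v + p$trailing
    )
  )
}

new_cloverleaf <- function(seq, p) {
  structure(
    list(
      seq = seq,
      gene_start0 = p$g0,
      gene_end0 = p$l0 + 36L + p$v + p$trailing,
      total_len = p$l0 + 36L + p$v + p$trailing - p$g0,
      loop_start0 = p$l0,
      anticodon = substr(seq, p$l0 + 3L, p$l0 + 5L),
      n_pairs = p$n_pairs,
      regions = cl_regions(p)
    ),
    class = "cloverleaf"
  )
}

#' Fold a candidate mature tRNA into a cloverleaf
#'
#' Searches all canonical layout placements covering the whole sequence and
#' returns the one maximising the total number of Watson-Crick + G:T pairs
#' across the four stems (ties resolved to the leftmost anticodon loop), or
#' `NULL` when no placement satisfies the stem thresholds.  An ambiguous
#' base (`N`) inside any stem or the anticodon loop invalidates a placement.
#'
#' @param seq A DNA string over `{A,C,G,T,N}` of length 50-120.
#' @return A `cloverleaf` object or `NULL`.
#' @export
fold_cloverleaf <- function(seq) {
  seq <- normalise_dna(seq)
  assert_dna(seq)
  L <- nchar(seq)
  if (L < 50L || L > 120L) {
    stop("sequence length ", L, " outside the 50-120 nt tRNA range",
         call. = FALSE)
  }
  si <- seq_to_int(seq)
  best <- cl_search(si, L, loop_starts = 26:34, full = TRUE)
  if (is.null(best)) return(NULL)
  new_cloverleaf(seq, best)
}

# Fold the region around a splice junction inside a longer (already spliced)
# sequence.  `junction0` is the 0-based index of the first 3'-exon base, so
# the last 5'-exon base sits at junction0 - 1 and must land on anticodon-loop
# positions 32-37 (loop offsets 0-5).  Returns NULL when nothing folds.
cl_fold_at_junction <- function(seq, junction0) {
  p <- cl_fold_params_at_junction(seq_to_int(seq), junction0)
  if (is.null(p)) return(NULL)
  new_cloverleaf(seq, p)
}

# Same search on a pre-converted integer sequence, restricted to a window
# around the junction (a tRNA gene is at most ~100 nt, so nothing outside
# +-120 nt of the junction can belong to the fold).  Returns the placement
# parameters with absolute coordinates, or NULL.
cl_fold_params_at_junction <- function(si, junction0) {
  j <- junction0 - 1L
  lo <- max(0L, j - 120L)
  hi <- min(length(si), j + 120L)
  win <- si[(lo + 1L):hi]
  jw <- j - lo
  starts <- (jw - 5L):jw
  best <- cl_search(win, length(win), starts[starts >= 0L], full = FALSE)
  if (is.null(best)) return(NULL)
  best$g0 <- best$g0 + lo
  best$l0 <- best$l0 + lo
  best
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("cloverleaf fold: ", x$total_len, " nt, ", x$n_pairs, " stem pairs, ",
      "anticodon loop at [", x$loop_start0, ",", x$loop_start0 + 7L, "), ",
      "anticodon ", x$anticodon, "\n", sep = "")
  gene <- substr(x$seq, x$gene_start0 + 1L, x$gene_end0)
  db <- rep(".", x$total_len)
  for (i in seq_len(nrow(x$regions))) {
    r <- x$regions[i, ]
    if (r$end0 <= r$start0) next
    idx <- (r$start0 + 1L):r$end0 - x$gene_start0
    if (grepl("_5p$", r$region)) db[idx] <- "("
    if (grepl("_3p$", r$region)) db[idx] <- ")"
  }
  cat(gene, "\n", paste(db, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cloverleaf <- function(x, ...) {
  mutate(x$regions, length = .data$end0 - .data$start0)
}

#' @export
glance.cloverleaf <- function(x, ...) {
  tibble(
    total_len = x$total_len, n_pairs = x$n_pairs,
    loop_start0 = x$loop_start0, anticodon = x$anticodon
  )
}

#' Read the anticodon from a folded tRNA
#'
#' The anticodon occupies positions 3-5 of the 7-nt anticodon loop (tRNA
#' positions 34-36).  For the CAT anticodon the amino acid is chemically
#' ambiguous (Met, initiator fMet, or lysidine-modified Ile2) and must be
#' resolved against intron-less homologs ([assign_cau_identity()]); the
#' candidate set is carried in `aa_candidates`.
#'
#' @param fold A `cloverleaf` object from [fold_cloverleaf()].
#' @param seq The folded sequence; defaults to the one stored in `fold`.
#' @return A one-row tibble with columns `anticodon`, `amino_acid`,
#'   `cau_flag`, and list-column `aa_candidates`.
#' @export
anticodon_of <- function(fold, seq = fold$seq) {
  stopifnot(inherits(fold, "cloverleaf"))
  if (!identical(seq, fold$seq)) {
    stop("fold does not belong to this sequence", call. = FALSE)
  }
  ac <- substr(seq, fold$loop_start0 + 3L, fold$loop_start0 + 5L)
  cau <- identical(ac, "CAT")
  tibble(
    anticodon = ac,
    amino_acid = aa_from_anticodon(ac),
    cau_flag = cau,
    aa_candidates = list(if (cau) c("Met", "fMet", "Ile2")
                         else aa_from_anticodon(ac))
  )
}

#' Label an insertion site from its anticodon-loop index
#'
#' The 7-nt anticodon loop is numbered 32-38 with the anticodon at 34-36.
#' An intron whose 5' exon ends at loop index `i` (1-based, `i` in 1..6)
#' sits between positions `31 + i` and `32 + i`; e.g. index 4 gives
#' "35/36", the site between the second and third anticodon nucleotides.
#'
#' @param exon1_end_loop_index Integer vector with values in 1..6.
#' @return Character vector of site labels such as `"35/36"`.
#' @export
insertion_site_label <- function(exon1_end_loop_index) {
  i <- exon1_end_loop_index
  if (any(is.na(i)) || any(i < 1L | i > 6L) || any(i != as.integer(i))) {
    stop("insertion outside anticodon loop", call. = FALSE)
  }
  paste0(31L + as.integer(i), "/", 32L + as.integer(i))
}
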