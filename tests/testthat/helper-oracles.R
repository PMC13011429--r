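# Independent oracles used to cross-check the implementation.  These are
# deliberately naive re-implementations; they must stay independent of the
# code paths they validate.

# Quadratic Smith-Waterman with affine gaps: a gap of length k costs
# open + k * extend.  Returns the optimal local score only.
sw_oracle_score <- function(q, s, match = 1, mismatch = -3, open = 5,
                            extend = 2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(qc)
  m <- length(sc)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (qc[i] == sc[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + sub)
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                               X[i, j + 1L] - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                               Y[i + 1L, j] - extend)
      if (M[i + 1L, j + 1L] > best) best <- M[i + 1L, j + 1L]
    }
  }
  best
}

# Exhaustive boundary scan: every (a, b) in the window, rules checked via
# plain substring operations.
boundary_oracle <- function(ctx, cand_start, cand_end, window = 10L,
                            min_intron_len = 50L) {
  L <- nchar(ctx)
  rows <- list()
  for (a in seq(cand_start - window, cand_start + window)) {
    for (b in seq(cand_end - window, cand_end + window)) {
      if (a < 1L || a >= L || b > L || b - a < min_intron_len) next
      if (substr(ctx, a, a) != "T") next
      if (substr(ctx, b, b) != "G") next
      spliced <- paste0(substr(ctx, 1L, a), substr(ctx, b + 1L, L))
      fold <- intronaut:::cl_fold_at_junction(spliced, a)
      if (is.null(fold)) next
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, b = b,
        site = insertion_site_label(a - fold$loop_start0),
        anticodon = fold$anticodon, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(a = integer(), b = integer(), site = character(),
                      anticodon = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Naive per-frame ORF scan by codon walking.
orf_oracle <- function(seq, min_len = 300L) {
  L <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    p <- f + 1L
    starts <- integer(0)
    while (p + 2L <= L) {
      if (substr(seq, p, p + 2L) %in% c("ATG", "GTG", "TTG")) {
        starts <- c(starts, p)
      }
      p <- p + 3L
    }
    for (st in starts) {
      p <- st
      found_stop <- FALSE
      while (p + 2L <= L) {
        if (substr(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) {
          found_stop <- TRUE
          break
        }
        p <- p + 3L
      }
      end1 <- if (found_stop) p + 2L else p - 1L
      len <- end1 - st + 1L
      if (len >= min_len) {
        rows[[length(rows) + 1L]] <- data.frame(start0 = st - 1L,
                                                end0 = end1, frame = f)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start0 = integer(), end0 = integer(),
                      frame = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start0, out$end0), , drop = FALSE]
}

# Greedy-by-score hit dedup, written with plain loops.
dedup_oracle <- function(hits, frac = 0.5) {
  ord <- hits[order(-hits$score, hits$evalue, hits$start), , drop = FALSE]
  kept <- ord[0, , drop = FALSE]
  for (i in seq_len(nrow(ord))) {
    h <- ord[i, , drop = FALSE]
    clash <- FALSE
    for (j in seq_len(nrow(kept))) {
      k <- kept[j, , drop = FALSE]
      if (k$target_id != h$target_id || k$strand != h$strand) next
      ov <- max(0L, min(k$stop, h$stop) - max(k$start, h$start) + 1L)
      if (ov / (h$stop - h$start + 1L) >= frac &&
          ov / (k$stop - k$start + 1L) >= frac) {
        clash <- TRUE
      }
    }
    if (!clash) kept <- rbind(kept, h)
  }
  kept[order(kept$target_id, kept$start), , drop = FALSE]
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
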