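# Single-locus fixture builder: one planted intron-containing tRNA in a
# random background genome, with the matching candidate hit and homolog
# database.  This is the unit the recovery and trap-discrimination
# experiments run on.

#' Build a one-locus synthetic fixture
#'
#' Plants one intron-interrupted tRNA into a random background genome and
#' returns everything [resolve()] needs, plus the ground truth.  The
#' homolog database holds the intron-less version of the planted tRNA
#' degraded to `homolog_identity` (`db = "true"`), the mature product of
#' the alternative boundary frame two nucleotides upstream
#' (`db = "shifted"`, only meaningful for trap fixtures), or both.
#'
#' @param anticodon,site,length,trap,heg Passed to [make_trna()] /
#'   [insert_intron()].
#' @param seed Integer seed.
#' @param strand Strand the locus is planted on.
#' @param jitter Absolute hit-boundary jitter in nt applied to each end
#'   (sign drawn at random).
#' @param homolog_identity Reference identity (default 0.92).
#' @param db Which homolog references to include.
#' @param n_refs Independently degraded references per frame (default 2;
#'   real intron-less databases carry many homologs per tRNA family).
#' @param flank_len Background length on each side of the locus.
#' @return A list with `genomes`, `candidate` (one-row candidate tibble),
#'   `trna_db`, and `truth` (including the true intron boundaries in
#'   genome coordinates).
#' @export
make_fixture <- function(anticodon, site, length, seed, trap = FALSE,
                         heg = FALSE, strand = "+", jitter = 0L,
                         homolog_identity = 0.92,
                         db = c("true", "shifted", "both"),
                         n_refs = 2L, flank_len = 600L) {
  db <- match.arg(db)
  loop5 <- if (site == "32/33") "TT" else "CT"
  loop3 <- if (site == "37/38") "TA" else "AA"
  trna <- make_trna(anticodon, seed, loop5, loop3)
  planted <- insert_intron(trna, site, length, seed + 1L, trap = trap,
                           heg = heg)
  with_seed(seed + 2L, {
    left <- rand_dna(flank_len)
    right <- rand_dna(flank_len)
    locus <- if (strand == "-") revcomp(planted$pre_seq) else planted$pre_seq
    gseq <- paste0(left, locus, right)
    ls <- nchar(left)
    le <- ls + nchar(locus)
    if (strand == "+") {
      ia <- ls + planted$a_local
      ib <- ls + planted$b_local
    } else {
      ia <- le - planted$b_local
      ib <- le - planted$a_local
    }
    j1 <- if (jitter > 0L) sample(c(-1L, 1L), 1L) * sample.int(jitter, 1L)
          else 0L
    j2 <- if (jitter > 0L) sample(c(-1L, 1L), 1L) * sample.int(jitter, 1L)
          else 0L
    refs <- list()
    if (db %in% c("true", "both")) {
      for (r in seq_len(n_refs)) {
        refs[[length(refs) + 1L]] <-
          make_homolog_ref(trna, homolog_identity, seed + 2L + r,
                           id = paste0("true_ref_", r))
      }
    }
    if (db %in% c("shifted", "both")) {
      mat <- paste0(substr(planted$pre_seq, 1L, planted$a_local - 2L),
                    substr(planted$pre_seq, planted$b_local - 1L,
                           nchar(planted$pre_seq)))
      shifted <- list(seq = mat, loop_start0 = trna$loop_start0,
                      anticodon = substr(mat, trna$loop_start0 + 3L,
                                         trna$loop_start0 + 5L))
      shifted$amino_acid <- aa_from_anticodon(shifted$anticodon)
      for (r in seq_len(n_refs)) {
        refs[[length(refs) + 1L]] <-
          make_homolog_ref(shifted, homolog_identity, seed + 30L + r,
                           id = paste0("shifted_ref_", r))
      }
    }
    list(
      genomes = tibble(id = "FIX_1", seq = gseq, length = nchar(gseq)),
      candidate = tibble(
        genome_id = "FIX_1", start0 = ia + j1, end0 = ib + j2,
        strand = strand, source_model = "RF00028",
        score = 60, evalue = 1e-8
      ),
      trna_db = bind_rows(refs),
      truth = tibble(
        genome_id = "FIX_1", strand = strand,
        locus_start0 = ls, locus_end0 = le,
        intron_start0 = ia, intron_end0 = ib,
        site = site, anticodon = anticodon,
        amino_acid = aa_from_anticodon(anticodon),
        intron_len = length, trap = trap, heg = heg
      )
    )
  })
}
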