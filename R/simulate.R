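# Synthetic genomes with planted intron-containing tRNA loci and full
# ground-truth bookkeeping.  Everything the resolver, classifier and
# statistics modules consume can be generated here deterministically, so
# the whole pipeline is testable without any external download.

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Anticodons compatible with each insertion site: the loop base 5' of the
# cut must be T.  Positions 32, 33 and 37 lie outside the anticodon and are
# set by make_trna's loop flanks; positions 34-36 constrain the anticodon
# itself.  The paper-era site labels map to loop indices 1-6.
SITE_ANTICODONS <- list(
  "32/33" = c("GCC", "GGC"),          # loop flank position 32 set to T
  "33/34" = c("CAT", "GAA", "GTG"),   # invariant T33 precedes the cut
  "34/35" = c("TAA", "TGC", "TCT"),   # anticodon starts with T
  "35/36" = c("GTT", "GTC", "ATT"),   # anticodon has T at position 35
  "36/37" = c("CCT", "TCT", "GCT"),   # anticodon ends with T
  "37/38" = c("GCA", "TGG")           # loop flank position 37 set to T
)

#' Generate a synthetic tRNA gene accepted by the cloverleaf validator
#'
#' Builds a canonical 72-nt layout (7-bp acceptor stem, 2-nt spacer, 4-bp
#' D stem with 8-nt loop, 5-bp anticodon stem with the 7-nt loop, 5-nt
#' variable region, 5-bp T stem with 7-nt loop) with perfectly
#' complementary random stems and the requested anticodon at loop
#' positions 34-36, so the validator accepts it by construction.
#'
#' @param anticodon 3-mer over `{A,C,G,T}` (DNA alphabet).
#' @param seed Integer seed fixing the random stems.
#' @param loop5,loop3 The two loop bases before (positions 32-33) and
#'   after (37-38) the anticodon; defaults `"CT"` / `"AA"` give the
#'   invariant U33.
#' @return A list with `seq`, `loop_start0` (0-based anticodon-loop
#'   start), `anticodon`, `amino_acid`.
#' @export
make_trna <- function(anticodon, seed, loop5 = "CT", loop3 = "AA") {
  anticodon <- normalise_dna(anticodon)
  stopifnot(nchar(anticodon) == 3L, nchar(loop5) == 2L, nchar(loop3) == 2L)
  assert_dna(anticodon, "anticodon")
  with_seed(seed, {
    acc5 <- rand_dna(7L)
    spacer1 <- paste0("T", rand_dna(1L))
    dstem5 <- rand_dna(4L)
    dloop <- rand_dna(8L)
    spacer2 <- rand_dna(1L)
    acstem5 <- rand_dna(5L)
    acloop <- paste0(loop5, anticodon, loop3)
    var <- rand_dna(5L)
    tstem5 <- rand_dna(5L)
    tloop <- "TTCGAAT"
    seq <- paste0(
      acc5, spacer1,
      dstem5, dloop, revcomp(dstem5), spacer2,
      acstem5, acloop, revcomp(acstem5),
      var,
      tstem5, tloop, revcomp(tstem5),
      revcomp(acc5)
    )
    list(seq = seq, loop_start0 = 31L, anticodon = anticodon,
         amino_acid = aa_from_anticodon(anticodon))
  })
}

#' Plant an intron into a synthetic tRNA
#'
#' Inserts a random intron ending in the obligatory omega-G at the
#' requested anticodon-loop site.  The loop base 5' of the cut must be T
#' (the 5'-exon terminal U); an incompatible site/anticodon combination is
#' an error.  With `trap = TRUE` the intron ends in `GTG`, which -- with
#' the invariant T33 -- creates a second structurally valid boundary frame
#' two nucleotides upstream whose anticodon reads `TG` + the base at
#' position 36 (the classic Asn(GTT)@35/36 versus Thr(TGT)@33/34
#' ambiguity).  For non-trap introns the bases adjacent to both termini
#' are chosen so that no such alternative frame exists.  With
#' `heg = TRUE` the intron length is forced above 500 bp and a stop-free
#' ORF of at least 300 nt (ATG ... TAA) is planted.
#'
#' @param trna List from [make_trna()].
#' @param site Site label in `"32/33"` ... `"37/38"`.
#' @param length Intron length in nt (study-like range 184-894).
#' @param seed Integer seed.
#' @param trap,heg Flags described above.
#' @return A list with `pre_seq` (tRNA with intron), `a_local` / `b_local`
#'   (0-based intron boundaries within `pre_seq`), `site`, `anticodon`,
#'   `intron_len`, `trap`, `heg`.
#' @export
insert_intron <- function(trna, site, length, seed, trap = FALSE,
                          heg = FALSE) {
  stopifnot(site %in% names(SITE_ANTICODONS), length >= 50L,
            length <= 2000L)
  i <- as.integer(sub("/.*$", "", site)) - 31L
  a_local <- trna$loop_start0 + i
  before <- substr(trna$seq, a_local, a_local)
  if (before != "T") {
    stop("site ", site, " incompatible with this tRNA: position ",
         31L + i, " is ", before, ", need T before the cut", call. = FALSE)
  }
  with_seed(seed, {
    if (heg) length <- max(length, 600L)
    intron <- strsplit(rand_dna(length), "", fixed = TRUE)[[1L]]
    intron[length] <- "G"
    if (trap) {
      intron[length - 2L] <- "G"
      intron[length - 1L] <- "T"
    } else {
      # block alternative frames at -1/-2 (intron side)
      intron[length - 1L] <- sample(c("A", "C", "T"), 1L)
      intron[length - 2L] <- sample(c("A", "C", "T"), 1L)
    }
    # block alternative frames at +1/+2 (no T right after the 5' boundary)
    intron[1L] <- sample(c("A", "C", "G"), 1L)
    intron[2L] <- sample(c("A", "C", "G"), 1L)
    if (heg) {
      n_codons <- 108L
      body <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                             c("TAA", "TAG", "TGA")),
                     n_codons, replace = TRUE)
      orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
      off <- 20L
      intron[(off + 1L):(off + nchar(orf))] <-
        strsplit(orf, "", fixed = TRUE)[[1L]]
    }
    intron <- paste(intron, collapse = "")
    pre <- paste0(substr(trna$seq, 1L, a_local), intron,
                  substr(trna$seq, a_local + 1L, nchar(trna$seq)))
    list(pre_seq = pre, a_local = a_local, b_local = a_local + length,
         site = site, anticodon = trna$anticodon, intron_len = length,
         trap = trap, heg = heg)
  })
}

#' Derive an intron-less homolog reference from a planted tRNA
#'
#' Degrades the mature sequence to roughly the requested identity by
#' substituting bases only outside the anticodon triplet, so the
#' anticodon-match logic downstream stays exercised.
#'
#' @param trna List from [make_trna()].
#' @param identity Target sequence identity in `[0.5, 1]` (default 0.92).
#' @param seed Integer seed.
#' @param id Reference id.
#' @param amino_acid Label carried in the reference header (defaults to
#'   the decoded amino acid; set explicitly for CAT references to Met,
#'   fMet or Ile2).
#' @return A one-row tibble in the [trna_db()] layout.
#' @export
make_homolog_ref <- function(trna, identity = 0.92, seed, id,
                             amino_acid = trna$amino_acid) {
  stopifnot(identity >= 0.5, identity <= 1)
  with_seed(seed, {
    chars <- strsplit(trna$seq, "", fixed = TRUE)[[1L]]
    protected <- (trna$loop_start0 + 3L):(trna$loop_start0 + 5L)
    mutable <- setdiff(seq_along(chars), protected)
    n_mut <- round((1 - identity) * length(chars))
    if (n_mut > 0L) {
      at <- sample(mutable, n_mut)
      chars[at] <- map_chr(chars[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      })
    }
    trna_db(id = id, amino_acid = amino_acid, anticodon = trna$anticodon,
            seq = paste(chars, collapse = ""))
  })
}

#' Default per-phylum simulation profile
#'
#' Emulates the broad structure of the bacterial survey: one phylum with
#' strong 35/36 enrichment and no group II introns (Patescibacteria-like,
#' ~40% group I retention), one with the classical 33/34 / 34/35 / 36/37
#' sites plus group II introns (Cyanobacteriota-like), and one small,
#' sparse phylum that falls below the 20-genome plotting threshold.
#'
#' @return A tibble with one row per phylum; `site_probs` is a list-column
#'   of named site-probability vectors for group I insertions.
#' @export
default_phylum_profile <- function() {
  tibble(
    phylum = c("Patescibacteria", "Cyanobacteriota", "Bacillota"),
    n_genomes = c(25L, 22L, 10L),
    rate_groupI = c(0.4, 0.4, 0.1),
    rate_groupII = c(0, 0.2, 0.2),
    site_probs = list(
      c("35/36" = 0.7, "33/34" = 0.2, "36/37" = 0.1),
      c("33/34" = 0.4, "34/35" = 0.3, "36/37" = 0.3),
      c("33/34" = 0.5, "34/35" = 0.5)
    )
  )
}

# Intron lengths emulating the observed distribution: most introns a bit
# over the ~184-nt minimum with a thin tail to ~894 (mean ~257 bp).
sample_intron_len <- function(n) {
  pmin(894L, 184L + as.integer(round(stats::rexp(n, rate = 1 / 73))))
}

# Per-genome copy number for genomes that carry introns: mostly 1, with an
# overdispersed tail (survey-like mean 1.6, sd 1.7).
sample_copies <- function(n) {
  1L + stats::rnbinom(n, size = 0.157, mu = 0.6)
}

#' Simulate a genome survey with planted intron-containing tRNA loci
#'
#' Generates random-background genomes, plants intron-interrupted tRNA
#' genes according to the per-phylum profile (sites, classes, rates,
#' copy numbers), emits candidate hit tables with boundary jitter, an
#' intron-less homolog database (identity degraded only outside the
#' anticodon), ARAGORN-style intron intervals for the group II path, and a
#' truth table.  A self-consistency audit re-derives every truth record
#' from the emitted sequences at generation time.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param phylum_profile Profile tibble ([default_phylum_profile()]).
#' @param jitter Maximal per-boundary hit jitter in nt (default 2).
#' @param homolog_identity Reference identity (default 0.92).
#' @param decoys Number of unrelated decoy references added to the
#'   homolog database (default 4).
#' @return A list with tibbles `genomes`, `hits` (1-based tblout layout),
#'   `aragorn` (group II intron intervals, internal coordinates),
#'   `trna_db`, `truth`, and `phylum_map`.
#' @export
make_survey <- function(seed, phylum_profile = default_phylum_profile(),
                        jitter = 2L, homolog_identity = 0.92,
                        decoys = 4L) {
  with_seed(seed, {
    genomes <- list()
    truth <- list()
    hits <- list()
    aragorn <- list()
    refs <- list()
    phylum_map <- list()
    g_index <- 0L
    for (p in seq_len(nrow(phylum_profile))) {
      prof <- phylum_profile[p, ]
      sites <- prof$site_probs[[1L]]
      for (g in seq_len(prof$n_genomes)) {
        g_index <- g_index + 1L
        gid <- sprintf("SYN_%03d", g_index)
        phylum_map[[g_index]] <- tibble(genome_id = gid,
                                        phylum = prof$phylum)
        n_g1 <- if (runif(1L) < prof$rate_groupI) sample_copies(1L) else 0L
        n_g2 <- if (runif(1L) < prof$rate_groupII) sample_copies(1L) else 0L
        segs <- rand_dna(sample(600:1200, 1L))
        pos <- nchar(segs)
        for (k in seq_len(n_g1 + n_g2)) {
          class <- if (k <= n_g1) "groupI" else "groupII"
          site <- sample(names(sites), 1L, prob = sites)
          anticodon <- sample(SITE_ANTICODONS[[site]], 1L)
          lseed <- sample.int(1e7, 1L)
          loop5 <- if (site == "32/33") "TT" else "CT"
          loop3 <- if (site == "37/38") "TA" else "AA"
          aa_label <- if (anticodon == "CAT") {
            sample(c("Met", "fMet", "Ile2"), 1L)
          } else {
            aa_from_anticodon(anticodon)
          }
          trna <- make_trna(anticodon, lseed, loop5, loop3)
          ilen <- sample_intron_len(1L)
          planted <- insert_intron(trna, site, ilen, lseed + 1L)
          strand <- if (runif(1L) < 0.3) "-" else "+"
          locus_seq <- if (strand == "-") revcomp(planted$pre_seq)
                       else planted$pre_seq
          ls <- pos
          le <- pos + nchar(locus_seq)
          if (strand == "+") {
            ia <- ls + planted$a_local
            ib <- ls + planted$b_local
          } else {
            ia <- le - planted$b_local
            ib <- le - planted$a_local
          }
          spacer <- rand_dna(sample(600:1200, 1L))
          segs <- paste0(segs, locus_seq, spacer)
          pos <- nchar(segs)
          lid <- paste0(gid, ":", ia, "-", ib, strand)
          truth[[length(truth) + 1L]] <- tibble(
            locus_id = lid, genome_id = gid, phylum = prof$phylum,
            strand = strand, locus_start0 = ls, locus_end0 = le,
            intron_start0 = ia, intron_end0 = ib,
            site = planted$site, anticodon = planted$anticodon,
            amino_acid = aa_label,
            class = class, intron_len = planted$intron_len,
            trap = planted$trap, heg = planted$heg
          )
          j1 <- sample(-jitter:jitter, 1L)
          j2 <- sample(-jitter:jitter, 1L)
          if (class == "groupI") {
            hits[[length(hits) + 1L]] <- tibble(
              target_id = gid,
              model = sample(c("RF00028", "gpI_bact_tRNA"), 1L),
              start = ia + 1L + j1, stop = ib + j2, strand = strand,
              score = round(runif(1L, 40, 90), 1L),
              evalue = 10^-runif(1L, 5, 12)
            )
          } else {
            aragorn[[length(aragorn) + 1L]] <- tibble(
              genome_id = gid, start0 = ia, end0 = ib, strand = strand
            )
            hits[[length(hits) + 1L]] <- tibble(
              target_id = gid, model = "RF00029",
              start = ia + 1L + j1, stop = ib + j2, strand = strand,
              score = round(runif(1L, 40, 90), 1L),
              evalue = 10^-runif(1L, 5, 12)
            )
          }
          for (r in 1:2) {
            refs[[length(refs) + 1L]] <- make_homolog_ref(
              trna, homolog_identity, lseed + 2L + r,
              id = paste0("ref_", lid, "_", r),
              amino_acid = aa_label
            )
          }
        }
        genomes[[g_index]] <- tibble(id = gid, seq = segs,
                                     length = nchar(segs))
      }
    }
    for (d in seq_len(decoys)) {
      dec <- make_trna(sample(c("AAT", "CCG", "GGA", "TTG"), 1L),
                       sample.int(1e7, 1L))
      refs[[length(refs) + 1L]] <- trna_db(
        id = paste0("decoy_", d), amino_acid = dec$amino_acid,
        anticodon = dec$anticodon, seq = dec$seq
      )
    }
    out <- list(
      genomes = bind_rows(genomes),
      hits = bind_rows(hits),
      aragorn = if (length(aragorn)) bind_rows(aragorn) else
        tibble(genome_id = character(), start0 = integer(),
               end0 = integer(), strand = character()),
      trna_db = bind_rows(refs),
      truth = if (length(truth)) bind_rows(truth) else
        tibble(locus_id = character()),
      phylum_map = bind_rows(phylum_map)
    )
    audit_truth(out)
    out
  })
}

# Every truth record must be re-derivable from the emitted sequences:
# the strand-normalised locus substring minus the intron must fold back
# to a tRNA whose anticodon matches the record.
audit_truth <- function(survey) {
  tr <- survey$truth
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    g <- survey$genomes$seq[match(t$genome_id, survey$genomes$id)]
    locus <- sub0(g, t$locus_start0, t$locus_end0)
    if (t$strand == "-") locus <- revcomp(locus)
    a <- if (t$strand == "-") t$locus_end0 - t$intron_end0
         else t$intron_start0 - t$locus_start0
    intron <- substr(locus, a + 1L, a + t$intron_len)
    if (substr(intron, t$intron_len, t$intron_len) != "G") {
      stop("truth audit failed for ", t$locus_id, ": no terminal G")
    }
    mature <- paste0(substr(locus, 1L, a),
                     substr(locus, a + t$intron_len + 1L, nchar(locus)))
    fold <- fold_cloverleaf(mature)
    if (is.null(fold) || fold$anticodon != t$anticodon) {
      stop("truth audit failed for ", t$locus_id,
           ": spliced product does not refold")
    }
  }
  invisible(TRUE)
}

#' Simulate planted non-tRNA host loci for the classifier
#'
#' Generates one genome per fixture with an intron interval planted
#' mid-sequence and the hit-table evidence implied by the category:
#' rRNA / tmRNA model hits flanking both sides within 1,000 nt (half the
#' tmRNA fixtures exercise the partial-evidence rule), same-subject
#' protein hits on both sides within 4,000 nt for CDS, a one-sided TnpB
#' annotation for IStron-like, and no evidence for unknown.
#'
#' @param n_each Fixtures per category (default 20).
#' @param seed Integer seed.
#' @return A list with `introns`, `rrna_hits`, `tmrna_hits`, `cds_hits`,
#'   `tnpb_hits`, and `truth` (`intron_id`, `category`).
#' @export
make_locus_fixtures <- function(n_each = 20L, seed) {
  with_seed(seed, {
    categories <- c("rRNA", "tmRNA", "CDS", "IStron-like", "unknown")
    introns <- list(); rrna <- list(); tmrna <- list()
    cds <- list(); tnpb <- list(); truth <- list()
    idx <- 0L
    for (cat in categories) {
      for (k in seq_len(n_each)) {
        idx <- idx + 1L
        gid <- sprintf("HOST_%03d", idx)
        iid <- paste0(gid, ":intron")
        s <- 4500L
        e <- s + sample(200:800, 1L)
        introns[[idx]] <- tibble(intron_id = iid, genome_id = gid,
                                 start0 = s, end0 = e)
        truth[[idx]] <- tibble(intron_id = iid, category = cat)
        if (cat == "rRNA") {
          rrna[[length(rrna) + 1L]] <- tibble(
            genome_id = gid, model = "RF00177",
            start0 = s - sample(400:900, 1L), end0 = s - sample(5:50, 1L)
          )
          rrna[[length(rrna) + 1L]] <- tibble(
            genome_id = gid, model = "RF00177",
            start0 = e + sample(5:50, 1L), end0 = e + sample(400:900, 1L)
          )
        } else if (cat == "tmRNA") {
          off <- sample(5:100, 1L)
          down_width <- if (k %% 2L == 0L) sample(20:35, 1L)
                        else sample(60:200, 1L)
          tmrna[[length(tmrna) + 1L]] <- tibble(
            genome_id = gid, model = "RF00023",
            start0 = s - sample(150:300, 1L), end0 = s - sample(0:20, 1L)
          )
          tmrna[[length(tmrna) + 1L]] <- tibble(
            genome_id = gid, model = "RF00023",
            start0 = e + off, end0 = e + off + down_width
          )
        } else if (cat == "CDS") {
          subj <- sample(c("flagellin", "nrdA", "recA"), 1L)
          cds[[length(cds) + 1L]] <- tibble(
            genome_id = gid, subject_id = subj,
            start0 = s - sample(1500:3500, 1L),
            end0 = s - sample(100:1000, 1L)
          )
          cds[[length(cds) + 1L]] <- tibble(
            genome_id = gid, subject_id = subj,
            start0 = e + sample(100:1000, 1L),
            end0 = e + sample(1500:3500, 1L)
          )
        } else if (cat == "IStron-like") {
          tnpb[[length(tnpb) + 1L]] <- tibble(
            genome_id = gid,
            start0 = e + sample(200:2000, 1L),
            end0 = e + sample(2100:3900, 1L)
          )
        }
      }
    }
    empty_model <- tibble(genome_id = character(), model = character(),
                          start0 = integer(), end0 = integer())
    list(
      introns = bind_rows(introns),
      rrna_hits = if (length(rrna)) bind_rows(rrna) else empty_model,
      tmrna_hits = if (length(tmrna)) bind_rows(tmrna) else empty_model,
      cds_hits = if (length(cds)) bind_rows(cds) else
        tibble(genome_id = character(), subject_id = character(),
               start0 = integer(), end0 = integer()),
      tnpb_hits = if (length(tnpb)) bind_rows(tnpb) else
        tibble(genome_id = character(), start0 = integer(),
               end0 = integer()),
      truth = bind_rows(truth)
    )
  })
}
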