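test_that("FASTA reading normalises case and alphabet and enforces unique ids", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">g1 some description", "ACGTACGT", ">g2", "acguacgu"), f)
  recs <- read_genome_fasta(f)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$id, c("g1", "g2"))
  expect_equal(recs$length, c(8L, 8L))
  expect_equal(recs$seq[2], "ACGTACGT")  # lowercase and U both mapped

  dup <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">same", "ACGT", ">same", "AAAA"), dup)
  expect_error(read_genome_fasta(dup), "same")

  empty <- withr::local_tempfile(fileext = ".fna")
  writeLines(character(0), empty)
  expect_error(read_genome_fasta(empty), "empty")
})

test_that("tRNA reference headers parse into id/amino-acid/anticodon", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">r1|Asn|GTT", "ACGTACGTACGT", ">r2|fMet|CAU", "ACGTACGTACGA"), f)
  db <- read_trna_db(f)
  expect_equal(db$amino_acid, c("Asn", "fMet"))
  expect_equal(db$anticodon, c("GTT", "CAT"))  # RNA anticodon normalised

  bad <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">r1_Asn_GTT", "ACGT"), bad)
  expect_error(read_trna_db(bad), "unparseable")

  out <- withr::local_tempfile(fileext = ".fna")
  write_trna_db(db, out)
  expect_equal(read_trna_db(out), db)
})

tblout_line <- function(target, model, from, to, strand, score, evalue) {
  paste(target, "-", model, "-", "cm", 1, 100, from, to, strand, "no", 1,
        0.5, 0.0, score, evalue, "!", "-")
}

test_that("tblout parsing filters by e-value and normalises minus-strand rows", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment line",
    tblout_line("g1", "RF00028", 100, 400, "+", 55.0, 1e-6),
    tblout_line("g1", "RF00028", 900, 600, "-", 44.0, 1e-5),
    tblout_line("g2", "RF00028", 10, 300, "+", 12.0, 1e-3)
  ), f)
  hits <- read_cm_tblout(f, evalue_max = 1e-4)
  expect_equal(nrow(hits), 2L)                       # 1e-3 row filtered out
  minus <- hits[hits$strand == "-", ]
  expect_equal(c(minus$start, minus$stop), c(600L, 900L))

  empty <- withr::local_tempfile(fileext = ".tbl")
  writeLines("# only comments", empty)
  expect_equal(nrow(read_cm_tblout(empty)), 0L)

  mal <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("too few fields", tblout_line("g1", "m", 1, 50, "+", 5, 1e-9)),
             mal)
  expect_warning(h <- read_cm_tblout(mal), "malformed")
  expect_equal(nrow(h), 1L)
})

test_that("tblout e-value filter is strict and round-trips through the writer", {
  hits <- tibble::tibble(
    target_id = c("g1", "g1"), model = c("RF00028", "gpI_bact_tRNA"),
    start = c(100L, 700L), stop = c(400L, 950L), strand = c("+", "-"),
    score = c(51.5, 62.0), evalue = c(1e-6, 9.9e-5)
  )
  f <- withr::local_tempfile(fileext = ".tbl")
  write_cm_tblout(hits, f)
  back <- read_cm_tblout(f, evalue_max = 1e-4)
  expect_equal(back$start, hits$start)
  expect_equal(back$stop, hits$stop)
  expect_equal(back$strand, hits$strand)
  expect_true(all(back$evalue < 1e-4))
  # strictness: a hit at exactly the threshold is dropped
  at <- hits
  at$evalue <- c(1e-4, 1e-4)
  write_cm_tblout(at, f)
  expect_equal(nrow(read_cm_tblout(f, evalue_max = 1e-4)), 0L)
})

test_that("hit dedup keeps the higher score and matches the greedy oracle", {
  h <- function(start, stop, score, evalue = 1e-8, target = "g",
                strand = "+", model = "m") {
    tibble::tibble(target_id = target, model = model, start = start,
                   stop = stop, strand = strand, score = score,
                   evalue = evalue)
  }
  two <- dplyr::bind_rows(h(100, 400, 50), h(100, 400, 60))
  expect_equal(dedup_hits(two)$score, 60)

  disjoint <- dplyr::bind_rows(h(100, 400, 50), h(1000, 1300, 60))
  expect_equal(nrow(dedup_hits(disjoint)), 2L)

  # score tie broken by lower e-value
  tie <- dplyr::bind_rows(h(100, 400, 50, 1e-6), h(100, 400, 50, 1e-9))
  expect_equal(dedup_hits(tie)$evalue, 1e-9)

  # chains of overlapping hits equal the greedy-by-score oracle
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    starts <- cumsum(sample(20:120, n, replace = TRUE))
    hh <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      h(starts[i], starts[i] + sample(80:200, 1),
        score = sample(30:90, 1), evalue = 10^-sample(5:12, 1))
    }))
    got <- dedup_hits(hh, 0.5)
    want <- dedup_oracle(as.data.frame(hh), 0.5)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    # idempotence
    expect_equal(dedup_hits(got, 0.5), got)
  }
})

test_that("0-based/1-based interval conversion is a bijection", {
  set.seed(11)
  s0 <- sample(0:5000, 200, replace = TRUE)
  e0 <- s0 + sample(1:900, 200, replace = TRUE)
  one <- iv_to_1based(s0, e0)
  back <- iv_from_1based(one$start, one$end)
  expect_equal(back$start0, s0)
  expect_equal(back$end0, e0)
  # convention anchor: 0-based [100, 190) prints as 101..190
  expect_equal(unlist(iv_to_1based(100, 190)), c(start = 101L, end = 190L))
})

test_that("calls round-trip through TSV and GFF3 with the emitted 1-based convention", {
  fx <- make_fixture("GTT", "35/36", 200, seed = 301)
  call_p <- resolve(fx$candidate, fx$genomes, fx$trna_db)
  fxm <- make_fixture("GTC", "35/36", 220, seed = 302, strand = "-")
  call_m <- resolve(fxm$candidate, fxm$genomes, fxm$trna_db)
  calls <- dplyr::bind_rows(call_p, call_m)
  expect_equal(nrow(calls), 2L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_calls_tsv(calls, tsv)
  back <- read_calls_tsv(tsv)
  expect_equal(as.data.frame(back), as.data.frame(calls))

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(calls, gff)
  feats <- read_gff3_features(gff)
  expect_setequal(feats$type, c("tRNA", "intron"))
  introns <- feats[feats$type == "intron", ]
  expect_setequal(introns$start, calls$intron_start0 + 1L)
  expect_setequal(introns$end, calls$intron_end0)
  # minus-strand feature still has ascending coordinates
  m <- feats[feats$strand == "-", ]
  expect_true(all(m$start <= m$end))
  expect_true("-" %in% feats$strand)
})
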