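intron_row <- function(id = "i1", gid = "g", s = 5000L, e = 5400L,
                       is_trna = FALSE) {
  tibble::tibble(intron_id = id, genome_id = gid, start0 = s, end0 = e,
                 is_trna = is_trna)
}

model_hits <- function(gid, ivs, model = "RF00177") {
  dplyr::bind_rows(lapply(ivs, function(iv) {
    tibble::tibble(genome_id = gid, model = model, start0 = iv[1],
                   end0 = iv[2])
  }))
}

test_that("host classification follows the evidence rules and priorities", {
  it <- intron_row()
  # rRNA model hits on both sides within 1,000 nt
  rr <- model_hits("g", list(c(4200L, 4900L), c(5500L, 6200L)))
  expect_equal(classify_host(it, rrna_hits = rr)$category, "rRNA")
  # one-sided rRNA evidence is not enough
  expect_equal(classify_host(it, rrna_hits = rr[1, ])$category, "unknown")
  # hits outside the flank do not count
  far <- model_hits("g", list(c(3000L, 3900L), c(5500L, 6200L)))
  expect_equal(classify_host(it, rrna_hits = far)$category, "unknown")

  # TnpB gene 800 nt downstream, nothing else -> IStron-like
  tnpb <- tibble::tibble(genome_id = "g", start0 = 6200L, end0 = 7400L)
  got <- classify_host(it, tnpb_hits = tnpb)
  expect_equal(got$category, "IStron-like")

  # same-subject protein hits on both sides within 4,000 nt -> CDS
  cds <- tibble::tibble(genome_id = "g",
                        subject_id = c("flagellin", "flagellin"),
                        start0 = c(2000L, 6000L), end0 = c(3500L, 7500L))
  expect_equal(classify_host(it, cds_hits = cds)$category, "CDS")
  # different subjects on the two sides do not make a CDS
  mixed <- dplyr::mutate(cds, subject_id = c("flagellin", "recA"))
  expect_equal(classify_host(it, cds_hits = mixed)$category, "unknown")

  # no evidence at all
  expect_equal(classify_host(it)$category, "unknown")

  # resolved tRNA call outranks everything
  expect_equal(classify_host(intron_row(is_trna = TRUE),
                             rrna_hits = rr)$category |>
                 suppressMessages(), "tRNA")

  # conflicting both-sides evidence: higher priority wins, conflict logged
  expect_message(
    both <- classify_host(it, rrna_hits = rr, cds_hits = cds),
    "multiple host categories"
  )
  expect_equal(both$category, "rRNA")
})

test_that("tmRNA classification accepts full and partial (T-loop) evidence", {
  it <- intron_row()
  full <- model_hits("g", list(c(4300L, 4950L), c(5500L, 5800L)),
                     model = "RF00023")
  expect_equal(classify_host(it, tmrna_hits = full)$category, "tmRNA")

  # truncated hit ending at the intron boundary + short opposite fragment
  partial <- model_hits("g", list(c(4300L, 4990L), c(5600L, 5625L)),
                        model = "RF00023")
  got <- classify_host(it, tmrna_hits = partial)
  expect_equal(got$category, "tmRNA")
  expect_match(got$evidence, "partial evidence")

  # fragment too short, or boundary too far: not tmRNA
  tiny <- model_hits("g", list(c(4300L, 4990L), c(5600L, 5610L)),
                     model = "RF00023")
  expect_equal(classify_host(it, tmrna_hits = tiny)$category, "unknown")
  far <- model_hits("g", list(c(4300L, 4800L), c(5600L, 5625L)),
                    model = "RF00023")
  expect_equal(classify_host(it, tmrna_hits = far)$category, "unknown")
})

test_that("ORF finding matches a brute-force codon-walk oracle", {
  set.seed(211)
  for (i in 1:20) {
    seq <- rand_seq(sample(300:2000, 1))
    got <- find_orfs(seq, min_len_nt = 150L)
    want <- orf_oracle(seq, min_len = 150L)
    got_sorted <- got[order(got$start0, got$end0),
                      c("start0", "end0", "frame")]
    expect_equal(as.data.frame(got_sorted), want, ignore_attr = TRUE)
  }
  # no start codon, no ORFs
  expect_equal(nrow(find_orfs(strrep("CCC", 200))), 0L)
})

test_that("the HEG length gate scans only group I introns over 500 bp", {
  tr <- make_trna("GTT", seed = 221)
  short_i <- insert_intron(tr, "35/36", 400, seed = 222, heg = FALSE)
  long_i <- insert_intron(tr, "35/36", 600, seed = 223, heg = TRUE)
  calls <- tibble::tibble(
    call_id = c("short", "long", "g2short"),
    intron_seq = c(
      substr(short_i$pre_seq, short_i$a_local + 1, short_i$b_local),
      substr(long_i$pre_seq, long_i$a_local + 1, long_i$b_local),
      substr(short_i$pre_seq, short_i$a_local + 1, short_i$b_local)
    ),
    intron_class = c("groupI", "groupI", "groupII")
  )
  orfs <- scan_heg_orfs(calls)
  expect_false("short" %in% orfs$call_id)       # 400 bp group I: skipped
  expect_true("long" %in% orfs$call_id)         # planted ORF found
  expect_gte(max(orfs$length_nt[orfs$call_id == "long"]), 300L)
  # group II introns are scanned regardless of length (may find nothing)
  expect_true(all(orfs$length_nt >= 300L))
})

test_that("domain labels attach only below the E-value threshold", {
  tr <- make_trna("GTT", seed = 231)
  long_i <- insert_intron(tr, "35/36", 600, seed = 232, heg = TRUE)
  calls <- tibble::tibble(
    call_id = "c1",
    intron_seq = substr(long_i$pre_seq, long_i$a_local + 1,
                        long_i$b_local),
    intron_class = "groupI"
  )
  orfs <- scan_heg_orfs(calls)
  expect_gte(nrow(orfs), 1L)
  oid <- orfs$orf_id[1]
  domains <- tibble::tibble(
    orf_id = c(oid, oid, "ghost"),
    accession = c("PF01844.22", "PF03161.12", "PF01844.22"),
    name = c("HNH", "LAGLIDADG_1", "HNH"),
    evalue = c(1e-10, 0.5, 1e-10)
  )
  expect_warning(lab <- attach_domains(orfs, domains), "ghost")
  expect_equal(lab$family[lab$orf_id == oid], "HNH")
  expect_equal(lab$domain_evalue[lab$orf_id == oid], 1e-10)

  # above threshold only: nothing attaches
  weak <- tibble::tibble(orf_id = oid, accession = "PF01844",
                         name = "HNH", evalue = 0.5)
  lab2 <- attach_domains(orfs, weak)
  expect_true(all(is.na(lab2$family)))
  # empty table is fine
  lab3 <- attach_domains(orfs, weak[0, ])
  expect_true(all(is.na(lab3$family)))
})

test_that("hmmscan tblout rows parse into the domain table", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# hmmscan tblout",
    "HNH PF01844.22 c1:orf1 - 1e-12 45.2 0.1 1e-11 44.0 0.1 1 1 0 1 1 1 1 desc"
  ), f)
  tab <- read_hmmscan_tblout(f)
  expect_equal(tab$orf_id, "c1:orf1")
  expect_equal(tab$accession, "PF01844.22")
  expect_equal(tab$evalue, 1e-12)
})

test_that("every fixture intron gets exactly one category matching its truth", {
  fx <- make_locus_fixtures(n_each = 4L, seed = 241)
  got <- classify_hosts(fx$introns, rrna_hits = fx$rrna_hits,
                        tmrna_hits = fx$tmrna_hits, cds_hits = fx$cds_hits,
                        tnpb_hits = fx$tnpb_hits)
  expect_equal(nrow(got), nrow(fx$truth))
  expect_equal(anyDuplicated(got$intron_id), 0L)
  joined <- dplyr::left_join(got, fx$truth, by = "intron_id")
  expect_equal(joined$category.x, joined$category.y)
})
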