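test_that("context extraction is strand-aware with a coordinate round trip", {
  genomes <- tibble::tibble(id = "g", seq = rand_seq(2000), length = 2000L)
  cand <- tibble::tibble(genome_id = "g", start0 = 1000L, end0 = 1300L,
                         strand = "+")
  ctx <- extract_context(cand, genomes, flank = 400L)
  expect_equal(nchar(ctx$ctx), 1100L)
  expect_equal(c(ctx$cand_start, ctx$cand_end), c(400L, 700L))
  expect_false(ctx$truncated)
  expect_equal(ctx$to_genome(400L, 700L), c(1000L, 1300L))

  cand_m <- dplyr::mutate(cand, strand = "-")
  ctxm <- extract_context(cand_m, genomes, flank = 400L)
  expect_equal(ctxm$ctx, revcomp(ctx$ctx))
  expect_equal(ctxm$to_genome(ctxm$cand_start, ctxm$cand_end),
               c(1000L, 1300L))
  # round trip through arbitrary sub-intervals
  expect_equal(ctxm$to_genome(410L, 420L), c(1280L, 1290L))

  edge <- tibble::tibble(genome_id = "g", start0 = 50L, end0 = 350L,
                         strand = "+")
  ctxe <- extract_context(edge, genomes, flank = 400L)
  expect_true(ctxe$truncated)
  expect_equal(ctxe$cand_start, 50L)

  expect_error(extract_context(dplyr::mutate(cand, genome_id = "nope"),
                               genomes), "genome id not found")
})

test_that("flanking tRNA check requires exon sequence on both sides", {
  fx <- make_fixture("GTT", "35/36", 200, seed = 111)
  ctx <- extract_context(fx$candidate, fx$genomes)
  expect_true(flanking_trna_check(ctx, fx$trna_db)$ok)

  # intron planted in plain random sequence: no tRNA on either side
  rnd <- tibble::tibble(id = "r", seq = rand_seq(1500), length = 1500L)
  cand <- tibble::tibble(genome_id = "r", start0 = 600L, end0 = 800L,
                         strand = "+")
  rc <- flanking_trna_check(extract_context(cand, rnd), fx$trna_db)
  expect_false(rc$ok)

  # exon fragment on the 5' side only
  tr <- make_trna("GTT", seed = 112)
  one_sided <- tibble::tibble(
    id = "o",
    seq = paste0(rand_seq(500), substr(tr$seq, 1, 36), rand_seq(200),
                 rand_seq(500)),
    length = 1236L
  )
  cand1 <- tibble::tibble(genome_id = "o", start0 = 536L, end0 = 736L,
                          strand = "+")
  oc <- flanking_trna_check(extract_context(cand1, one_sided),
                            make_homolog_ref(tr, 1, 113, "ref"))
  expect_false(oc$ok)
  expect_gt(oc$score_5p, oc$score_3p)
})

test_that("boundary enumeration finds the planted frame and matches the exhaustive oracle", {
  fx <- make_fixture("GTC", "35/36", 184, seed = 121, jitter = 0)
  ctx <- extract_context(fx$candidate, fx$genomes)
  hyps <- enumerate_boundaries(ctx)
  planted <- hyps[hyps$a == ctx$cand_start & hyps$b == ctx$cand_end, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$site, "35/36")
  expect_equal(planted$anticodon, "GTC")

  oracle <- boundary_oracle(ctx$ctx, ctx$cand_start, ctx$cand_end)
  expect_equal(as.data.frame(hyps[, c("a", "b", "site", "anticodon")]),
               oracle, ignore_attr = TRUE)

  # non-tRNA context yields nothing
  set.seed(122)
  rnd_ctx <- rand_seq(1000)
  expect_equal(nrow(enumerate_boundaries(rnd_ctx, 400L, 600L)), 0L)
})

test_that("enlarging the window never removes a hypothesis", {
  fx <- make_fixture("GTT", "35/36", 250, seed = 131, jitter = 2)
  ctx <- extract_context(fx$candidate, fx$genomes)
  small <- enumerate_boundaries(ctx, window = 5L)
  big <- enumerate_boundaries(ctx, window = 10L)
  key <- function(h) paste(h$a, h$b)
  expect_true(all(key(small) %in% key(big)))
  expect_gte(nrow(big), nrow(small))
})

test_that("trap fixtures expose two competing frames resolved by the homolog db", {
  fx <- make_fixture("GTT", "35/36", 220, seed = 141, trap = TRUE,
                     db = "both")
  ctx <- extract_context(fx$candidate, fx$genomes)
  hyps <- enumerate_boundaries(ctx)
  expect_gte(nrow(hyps), 2L)
  expect_true(all(c("35/36", "33/34") %in% hyps$site))
  expect_equal(hyps$anticodon[hyps$site == "35/36"][1], "GTT")
  expect_equal(hyps$anticodon[hyps$site == "33/34" &
                                startsWith(hyps$anticodon, "TG")][1], "TGT")

  true_db <- fx$trna_db[startsWith(fx$trna_db$id, "true"), ]
  shifted_db <- fx$trna_db[startsWith(fx$trna_db$id, "shifted"), ]
  full <- resolve(fx$candidate, fx$genomes, true_db)
  expect_equal(c(full$site, full$anticodon), c("35/36", "GTT"))
  ablated <- resolve(fx$candidate, fx$genomes, shifted_db)
  expect_equal(c(ablated$site, ablated$anticodon), c("33/34", "TGT"))
})

test_that("resolve recovers planted calls on both strands with jitter", {
  for (cs in list(list(ac = "GTT", site = "35/36", strand = "+"),
                  list(ac = "GTC", site = "35/36", strand = "-"),
                  list(ac = "CAT", site = "33/34", strand = "+"),
                  list(ac = "CCT", site = "36/37", strand = "-"))) {
    fx <- make_fixture(cs$ac, cs$site, 300, seed = 151 + match(cs$ac,
                       c("GTT", "GTC", "CAT", "CCT")), jitter = 3,
                       strand = cs$strand)
    call <- resolve(fx$candidate, fx$genomes, fx$trna_db)
    expect_false(is.null(call))
    expect_equal(call$site, cs$site)
    expect_equal(call$anticodon, cs$ac)
    expect_equal(call$intron_start0, fx$truth$intron_start0)
    expect_equal(call$intron_end0, fx$truth$intron_end0)
    # excision/re-insertion round trip
    g <- fx$genomes$seq[1]
    gene <- substr(g, call$gene_start0 + 1, call$gene_end0)
    if (call$strand == "-") gene <- revcomp(gene)
    recon <- paste0(substr(call$trna_seq, 1, call$exon1_len),
                    call$intron_seq,
                    substr(call$trna_seq, call$exon1_len + 1,
                           nchar(call$trna_seq)))
    expect_identical(gene, recon)
  }
})

test_that("adjust_external_call accepts correct predictions and fixes shifted ones", {
  fx <- make_fixture("GTT", "35/36", 220, seed = 171, trap = TRUE,
                     db = "both")
  truth <- fx$truth
  correct <- tibble::tibble(genome_id = "FIX_1", strand = "+",
                            intron_start0 = truth$intron_start0,
                            intron_end0 = truth$intron_end0)
  true_db <- fx$trna_db[startsWith(fx$trna_db$id, "true"), ]
  acc <- adjust_external_call(correct, fx$genomes, true_db)
  expect_equal(c(acc$site, acc$anticodon, acc$status),
               c("35/36", "GTT", "ok"))
  expect_false(acc$boundary_adjusted)
  expect_equal(acc$intron_start0, truth$intron_start0)

  # the documented miscall: boundaries shifted two nucleotides upstream
  shifted <- dplyr::mutate(correct,
                           intron_start0 = intron_start0 - 2L,
                           intron_end0 = intron_end0 - 2L)
  fixed <- adjust_external_call(shifted, fx$genomes, true_db)
  expect_equal(c(fixed$site, fixed$anticodon), c("35/36", "GTT"))
  expect_true(fixed$boundary_adjusted)
  expect_equal(fixed$intron_start0, truth$intron_start0)

  # no usable homolog: call returned unverified
  decoy_db <- trna_db(id = "x", amino_acid = "Gly", anticodon = "GCC",
                      seq = rand_seq(72))
  unv <- adjust_external_call(shifted, fx$genomes, decoy_db)
  expect_equal(unv$status, "unverified")
})

test_that("CAT-anticodon identity is copied from the top CAT homolog", {
  fx <- make_fixture("CAT", "33/34", 260, seed = 181)
  call <- resolve(fx$candidate, fx$genomes, fx$trna_db)
  expect_true(call$cau_flag)
  tr <- make_trna("CAT", seed = 181)
  fmet_db <- make_homolog_ref(tr, 0.95, seed = 182, id = "f",
                              amino_acid = "fMet")
  got <- assign_cau_identity(call, fmet_db)
  expect_equal(got$amino_acid, "fMet")
  expect_true(got$cau_resolved)

  no_cat <- trna_db(id = "y", amino_acid = "Asn", anticodon = "GTT",
                    seq = rand_seq(72))
  unres <- assign_cau_identity(call, no_cat)
  expect_equal(unres$amino_acid, "Met?")
  expect_false(unres$cau_resolved)

  non_cat <- dplyr::mutate(call, anticodon = "GTT")
  expect_error(assign_cau_identity(non_cat, fmet_db), "CAT")
})

test_that("group II calls come from ARAGORN/RF00029 overlap with BLAST-set boundaries", {
  # anticodon-loop group II insertion
  tr <- make_trna("TAT", seed = 191)
  planted <- insert_intron(tr, "34/35", 150, seed = 192)
  left <- with_seed_helper(193, rand_seq(500))
  right <- with_seed_helper(194, rand_seq(500))
  gseq <- paste0(left, planted$pre_seq, right)
  genomes <- tibble::tibble(id = "G2", seq = gseq, length = nchar(gseq))
  ia <- 500L + planted$a_local
  ib <- 500L + planted$b_local
  aragorn <- tibble::tibble(genome_id = "G2", start0 = ia, end0 = ib,
                            strand = "+")
  rf29 <- tibble::tibble(genome_id = "G2", start0 = ia - 5L, end0 = ib + 5L,
                         strand = "+", source_model = "RF00029",
                         score = 50, evalue = 1e-9)
  db <- make_homolog_ref(tr, 0.95, seed = 195, id = "ref")
  calls <- group2_trna_overlap(aragorn, rf29, genomes, db)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$intron_class, "groupII")
  expect_equal(calls$site, "34/35")
  expect_equal(c(calls$intron_start0, calls$intron_end0), c(ia, ib))

  # no overlapping RF00029 hit: no call
  far <- dplyr::mutate(rf29, start0 = 10L, end0 = 60L)
  expect_equal(nrow(group2_trna_overlap(aragorn, far, genomes, db)), 0L)
})

test_that("a group II intron planted in the D loop is labelled D-loop", {
  tr <- make_trna("GTT", seed = 201)
  a_local <- 16L  # inside the D loop of the canonical layout
  intron <- with_seed_helper(202, rand_seq(140))
  pre <- paste0(substr(tr$seq, 1, a_local), intron,
                substr(tr$seq, a_local + 1, nchar(tr$seq)))
  gseq <- paste0(with_seed_helper(203, rand_seq(500)), pre,
                 with_seed_helper(204, rand_seq(500)))
  genomes <- tibble::tibble(id = "GD", seq = gseq, length = nchar(gseq))
  ia <- 500L + a_local
  ib <- ia + 140L
  aragorn <- tibble::tibble(genome_id = "GD", start0 = ia, end0 = ib,
                            strand = "+")
  rf29 <- tibble::tibble(genome_id = "GD", start0 = ia - 3L, end0 = ib + 3L,
                         strand = "+", source_model = "RF00029",
                         score = 50, evalue = 1e-9)
  db <- make_homolog_ref(tr, 0.95, seed = 205, id = "ref")
  calls <- group2_trna_overlap(aragorn, rf29, genomes, db)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$site, "D-loop")
  expect_equal(c(calls$intron_start0, calls$intron_end0), c(ia, ib))
})
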