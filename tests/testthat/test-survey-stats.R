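toy_survey <- function() {
  tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g3", "g4", "g5"),
    phylum = c("P1", "P1", "P1", "P1", "P2", "P2"),
    intron_id = paste0("i", 1:6),
    class = c("groupI", "groupI", "groupI", "groupII", "groupI", "groupI"),
    category = c("tRNA", "tRNA", "tRNA", "tRNA", "rRNA", "tRNA"),
    site = c("35/36", "33/34", "35/36", "34/35", "33/34", "36/37"),
    amino_acid = c("Asn", "fMet", "Asn", "Leu", "Phe", "Arg"),
    anticodon = c("GTT", "CAT", "GTT", "TAA", "GAA", "CCT"),
    length = c(184L, 300L, 894L, 420L, 620L, 210L),
    subgroup = "unassigned",
    has_heg = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
}

toy_map <- function() {
  tibble::tibble(
    genome_id = c(paste0("g", 1:3), sprintf("p1_%02d", 1:17),
                  "g4", "g5", sprintf("p2_%02d", 1:3)),
    phylum = c(rep("P1", 20), rep("P2", 5))
  )
}

test_that("subgroup assignment is argmax with lexicographic tie-breaking", {
  scores <- tibble::tibble(
    intron_id = c("i1", "i1", "i2", "i3", "i3"),
    model = c("IA", "IC", "IC", "IC", "IA"),
    score = c(80, 65, 70, 55, 55)
  )
  expect_message(got <- assign_subgroup(scores, intron_ids = paste0("i", 1:4)),
                 "tie")
  expect_equal(got$subgroup[got$intron_id == "i1"], "IA")   # argmax
  expect_equal(got$subgroup[got$intron_id == "i2"], "IC")   # single row
  expect_equal(got$subgroup[got$intron_id == "i3"], "IA")   # tie, lexicographic
  expect_equal(got$subgroup[got$intron_id == "i4"], "unassigned")
})

test_that("retention rates use the full phylum denominator and the plot threshold", {
  rr <- retention_rate(toy_survey(), toy_map(), min_genomes = 20L)
  p1_g1 <- rr[rr$phylum == "P1" & rr$class == "groupI", ]
  expect_equal(p1_g1$n_genomes, 20L)
  expect_equal(p1_g1$n_with_intron, 2L)       # g1 and g2
  expect_equal(p1_g1$rate, 0.1)
  expect_true(p1_g1$plotted)
  p2_g1 <- rr[rr$phylum == "P2" & rr$class == "groupI", ]
  expect_equal(p2_g1$rate, 2 / 5)
  expect_false(p2_g1$plotted)                 # 5 genomes < 20
  p2_g2 <- rr[rr$phylum == "P2" & rr$class == "groupII", ]
  expect_equal(p2_g2$rate, 0)                 # zero-intron class still 0.0
  expect_true(all(rr$rate >= 0 & rr$rate <= 1))

  expect_error(retention_rate(toy_survey(),
                              toy_map()[-1, ], min_genomes = 20L),
               "missing from phylum map.*g1")
})

test_that("copy-number statistics use the sample sd with a degenerate flag", {
  sv <- tibble::tibble(
    genome_id = c("a", "b", "c", "c", "c", "c", "d"),
    class = c(rep("groupI", 6), "groupII"),
    phylum = "P", intron_id = paste0("x", 1:7), category = "tRNA",
    site = "35/36", amino_acid = "Asn", anticodon = "GTT",
    length = 200L, subgroup = "unassigned", has_heg = FALSE
  )
  cs <- copy_number_stats(sv)
  g1 <- cs[cs$class == "groupI", ]
  expect_equal(g1$mean, 2)                     # copies {1, 1, 4}
  expect_equal(g1$median, 1)
  expect_equal(g1$sd, sd(c(1, 1, 4)))
  g2 <- cs[cs$class == "groupII", ]
  expect_equal(g2$sd, 0)                       # single genome
  expect_true(g2$sd_degenerate)
  expect_equal(nrow(copy_number_stats(toy_survey()[0, ])), 0L)
})

test_that("position matrix counts tRNA-hosted introns and conserves totals", {
  three <- toy_survey()[c(1, 1, 1), ]
  three$intron_id <- paste0("d", 1:3)
  pm3 <- position_matrix(three)
  expect_equal(nrow(pm3), 1L)
  expect_equal(pm3$n, 3L)

  sv <- toy_survey()
  pm <- position_matrix(sv)
  expect_equal(sum(pm$n), sum(sv$category == "tRNA"))
  # base-table oracle
  tr <- sv[sv$category == "tRNA", ]
  want <- as.data.frame(table(tr$phylum, tr$site, tr$amino_acid),
                        stringsAsFactors = FALSE)
  want <- want[want$Freq > 0, ]
  expect_equal(sum(pm$n), sum(want$Freq))
  expect_equal(nrow(pm), nrow(want))
})

test_that("length distribution reports range and HEG eligibility", {
  ld <- length_histogram(toy_survey())
  gl <- glance(ld)
  expect_equal(c(gl$min, gl$max), c(184L, 894L))
  expect_equal(gl$n_heg_eligible, 2L)          # lengths 894 and 620 exceed 500
  # oracle binning
  h <- tidy(ld)
  expect_equal(sum(h$count), nrow(toy_survey()))
  oracle <- table(cut(toy_survey()$length,
                      breaks = seq(0, 900, by = 50), right = TRUE))
  expect_equal(sum(h$count), sum(oracle))

  flat <- dplyr::mutate(toy_survey(), length = 200L)
  expect_equal(glance(length_histogram(flat))$n_heg_eligible, 0L)
})

test_that("survey statistics are identical after a TSV round trip", {
  sv <- toy_survey()
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sv, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(retention_rate(back, toy_map()),
               retention_rate(sv, toy_map()))
  expect_equal(copy_number_stats(back), copy_number_stats(sv))
  expect_equal(position_matrix(back), position_matrix(sv))
})

test_that("plot builders return ggplot objects", {
  sv <- toy_survey()
  expect_s3_class(plot_position_matrix(sv), "ggplot")
  expect_s3_class(plot_length_distribution(sv), "ggplot")
  expect_s3_class(plot_retention(retention_rate(sv, toy_map())), "ggplot")
})
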