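test_that("tRNAscan tables parse with strand normalization and flags", {
  fx <- simulate_trnascan_fixture(c(GCC = 3L, AAT = 1L), n_pseudo = 2L,
                                  n_truncated = 1L, minus_fraction = 0.5,
                                  seed = 4L)
  genes <- parse_trnascan(fx$path)
  expect_equal(nrow(genes), 7L)
  expect_equal(sum(genes$retained), 4L)
  expect_equal(sum(genes$pseudo), 2L)
  expect_equal(sum(genes$truncated), 1L)
  expect_true(all(genes$begin < genes$end))
  expect_true(all(genes$strand %in% c("+", "-")))
  # filtered-out + retained = parsed (copy conservation)
  expect_equal(sum(genes$retained) + sum(!genes$retained), nrow(genes))
})

test_that("malformed rows are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Name\ttRNA #\tBegin\tEnd\tType\tCodon\tB\tE\tScore\tNote",
               "--------\t------\t-----\t----\t----\t-----\t-----\t---\t-----\t------",
               "chr1\t1\t100\t172\tGly\tGCC\t0\t0\t55.0\t",
               "broken row"), path)
  expect_warning(genes <- parse_trnascan(path), "malformed")
  expect_equal(nrow(genes), 1L)
  expect_equal(attr(genes, "n_skipped"), 1L)
})

test_that("copy numbers summarize anticodons with planted truth", {
  fx <- simulate_trnascan_fixture(c(GCC = 3L, AAT = 1L), seed = 2L)
  summ <- copy_numbers(parse_trnascan(fx$path))
  expect_equal(summ$anticodon_counts[["GCC"]], 3L)
  expect_equal(summ$anticodon_counts[["AAT"]], 1L)
  expect_equal(summ$median_copies, 2)
  one <- copy_numbers(parse_trnascan(
    simulate_trnascan_fixture(c(TTT = 5L), n_pseudo = 0L,
                              n_truncated = 0L, seed = 3L)$path))
  expect_length(one$anticodon_counts, 1L)
})

test_that("anticodons map to codons by reverse complement (involution)", {
  expect_equal(anticodon_to_codon("GCC"), c(GCC = "GGC"),
               ignore_attr = TRUE)
  expect_equal(unname(anticodon_to_codon("AAT")), "ATT")
  trips <- apply(expand.grid(c("A", "C", "G", "T"),
                             c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")),
                 1, paste, collapse = "")
  back <- vapply(trips, function(x)
    unname(anticodon_to_codon(anticodon_to_codon(x))), character(1))
  expect_equal(unname(back), trips)
  expect_error(anticodon_to_codon("GXX"), "non-ACGT")
})

test_that("RAIT mirrors RSCU on anticodon copies", {
  # Thr (4 codons): anticodons AGT (codon ACT) and GGT (ACC), copies 6/2
  fx <- simulate_trnascan_fixture(c(AGT = 6L, GGT = 2L), n_pseudo = 0L,
                                  n_truncated = 0L, seed = 5L)
  summ <- copy_numbers(parse_trnascan(fx$path))
  r <- rait(summ)
  expect_equal(r$rait[r$anticodon == "AGT"], 3)   # 4 * 6 / 8
  expect_equal(r$rait[r$anticodon == "GGT"], 1)
  expect_equal(r$ending[r$anticodon == "AGT"], "W")  # codon ACT
  expect_equal(r$ending[r$anticodon == "GGT"], "S")  # codon ACC
  # equal copies within a family -> RAIT equals k/represented
  fx2 <- simulate_trnascan_fixture(c(TTC = 4L, CTC = 4L), n_pseudo = 0L,
                                   n_truncated = 0L, seed = 6L)
  r2 <- rait(copy_numbers(parse_trnascan(fx2$path)))
  # Glu has 2 codons, both represented equally
  expect_equal(r2$rait, c(1, 1))
  # family-mean identity: mean over represented = k / represented
  k <- 4; rep_n <- 2
  expect_equal(mean(r$rait), k / rep_n)
})

test_that("copy-weighted GC3 responds to outlier exclusion as hand-computed", {
  # codon equivalents: AGT -> ACT (W-ending), GCC -> GGC (S-ending)
  fx <- simulate_trnascan_fixture(c(AGT = 57L, GCC = 3L), n_pseudo = 0L,
                                  n_truncated = 0L, seed = 7L)
  summ <- copy_numbers(parse_trnascan(fx$path))
  expect_equal(trna_gc3(summ), 3 / 60)
  expect_equal(trna_gc3(summ, exclude = "AGT"), 1)
  expect_equal(trna_gc3(summ, weighted = FALSE), 1 / 2)
})

test_that("anticodons far above the copy-number fence are flagged outliers", {
  fx <- simulate_trnascan_fixture(c(AGT = 57L, GCC = 3L, AAT = 2L,
                                    GGT = 2L, TTC = 3L),
                                  n_pseudo = 0L, n_truncated = 0L,
                                  seed = 8L)
  summ <- copy_numbers(parse_trnascan(fx$path))
  expect_equal(summ$outliers, "AGT")
  expect_equal(summ$range_copies, c(2L, 57L))
})
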