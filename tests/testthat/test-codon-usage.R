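test_that("codon frequencies match a direct tally and exclude stops", {
  tab <- codon_frequencies(strrep("ATG", 100))
  expect_equal(tab$per_1000[tab$codon == "ATG"], 1000)
  expect_equal(sum(tab$count), 100L)

  tab61 <- codon_frequencies(paste(ORACLE_SENSE, collapse = ""))
  expect_equal(tab61$per_1000, rep(1000 / 61, 61))

  set.seed(3)
  cods <- sample(ORACLE_SENSE, 500, replace = TRUE)
  tab2 <- codon_frequencies(paste(cods, collapse = ""))
  hand <- table(factor(cods, levels = ORACLE_SENSE))
  expect_equal(tab2$count, as.integer(hand))

  # stop codons neither counted nor in the denominator
  tab3 <- codon_frequencies("ATGTAAATG")
  expect_equal(attr(tab3, "total_codons"), 2L)
  expect_equal(sum(codon_frequencies("TAATAGTGA")$count), 0L)
})

test_that("pooled per-1000 frequencies come from pooled counts", {
  t1 <- codon_frequencies(strrep("ATG", 10))
  t2 <- codon_frequencies(strrep("GGA", 30))
  pool <- pool_codon_usage(list(t1, t2))
  expect_equal(pool$per_1000[pool$codon == "ATG"], 250)
  expect_equal(pool$per_1000[pool$codon == "GGA"], 750)
})

test_that("RSCU equals family-size-scaled relative usage", {
  # Glu family (GAA/GAG) used 30/10
  tab <- codon_frequencies(paste(c(rep("GAA", 30), rep("GAG", 10)),
                                 collapse = ""))
  r <- rscu(tab)
  expect_equal(r$rscu[r$codon == "GAA"], 1.5)
  expect_equal(r$rscu[r$codon == "GAG"], 0.5)

  # equal usage of every family member -> all RSCU = 1
  r61 <- rscu(codon_frequencies(paste(rep(ORACLE_SENSE, 30),
                                      collapse = "")))
  expect_equal(r61$rscu, rep(1, 61))

  # 4-fold family used as a single codon
  tab4 <- codon_frequencies(strrep("GGA", 40))
  r4 <- rscu(tab4)
  expect_equal(r4$rscu[r4$codon == "GGA"], 4)
  expect_equal(r4$rscu[r4$codon %in% c("GGC", "GGG", "GGT")], rep(0, 3))
  expect_true("E" %in% attr(r4, "undefined_families"))

  # family RSCU sums equal family size whenever defined
  set.seed(8)
  tabr <- rscu(codon_frequencies(paste(sample(ORACLE_SENSE, 2000,
                                              TRUE), collapse = "")))
  sums <- tapply(tabr$rscu, tabr$aa, sum)
  sizes <- table(ORACLE_CODE[ORACLE_SENSE])
  expect_equal(as.numeric(sums[names(sizes)]), as.numeric(sizes))
})

test_that("observed ENC spans 20 to 61 and follows Wright's homozygosity", {
  expect_equal(enc_obs(codon_frequencies(paste(rep(ORACLE_SENSE, 50),
                                               collapse = ""))), 61)
  one_per_aa <- vapply(split(ORACLE_SENSE, ORACLE_CODE[ORACLE_SENSE]),
                       function(v) v[1], character(1))
  expect_equal(enc_obs(codon_frequencies(paste(rep(one_per_aa, 40),
                                               collapse = ""))), 20)
  # single 2-fold family with counts (3,1): F = (4*(9+1)/16 - 1)/3 = 0.5;
  # all class means imputed to 0.5 -> ENC = 2 + (9+1+5+3)/0.5 = 38
  counts <- stats::setNames(integer(61), ORACLE_SENSE)
  counts["GAA"] <- 3L; counts["GAG"] <- 1L
  expect_equal(enc_obs(counts), 38)
  # nothing estimable -> undefined
  counts0 <- stats::setNames(integer(61), ORACLE_SENSE)
  counts0["ATG"] <- 5L
  expect_true(is.na(enc_obs(counts0)))
})

test_that("observed ENC is scale-stable and decreases with concentration", {
  set.seed(11)
  cods <- sample(ORACLE_SENSE, 30000, replace = TRUE)
  counts <- table(factor(cods, levels = ORACLE_SENSE))
  counts <- stats::setNames(as.integer(counts), ORACLE_SENSE)
  e1 <- enc_obs(counts)
  e10 <- enc_obs(counts * 10L)
  expect_lt(abs(e1 - e10), 0.1)

  # nested tables concentrating usage within families
  fam <- split(ORACLE_SENSE, ORACLE_CODE[ORACLE_SENSE])
  mk <- function(w) {  # weight on the first codon of each family
    counts <- stats::setNames(numeric(61), ORACLE_SENSE)
    for (v in fam) {
      n <- length(v)
      counts[v] <- 300 * c(w, rep((1 - w) / max(n - 1, 1), n - 1))[1:n]
    }
    round(counts) + 1
  }
  encs <- vapply(c(0.25, 0.5, 0.75, 0.95), function(w) enc_obs(mk(w)),
                 numeric(1))
  expect_true(all(diff(encs) < 0))
})

test_that("expected ENC follows the composition curve with clamping", {
  expect_equal(enc_exp(0), 6 + 34 / 1.025^2)
  expect_equal(enc_exp(0.5), 61)   # unclamped value exceeds 61
  expect_equal(enc_exp(1), min(max(7 + 34 / (1 + 0.025^2), 20), 61))
  # Wright's classic constants
  expect_equal(enc_exp(0.5, enc_config(2, 29, 1)), 2.5 + 29 / 0.5)
  expect_error(enc_exp(1.2), "0, 1")
  expect_error(enc_exp(-0.1), "0, 1")
})

test_that("ENC difference is the normalized expected-minus-observed score", {
  expect_equal(enc_diff(50, 50), 0)
  expect_equal(enc_diff(50, 45), 0.1)
  expect_equal(enc_diff(50, 55), -0.1)
})

test_that("composition-only codon usage yields near-zero ENC difference", {
  # codons drawn per amino acid proportional to third-base composition;
  # at mid GC3 the clamped expectation curve sits at 61 and observed
  # ENC approaches it
  gen <- function(n, gc3, seed) {
    set.seed(seed)
    w <- ifelse(substr(ORACLE_SENSE, 3, 3) %in% c("G", "C"),
                gc3 / 2, (1 - gc3) / 2)
    aa <- ORACLE_CODE[ORACLE_SENSE]
    cods <- vapply(sample(unique(aa), n, replace = TRUE), function(a) {
      v <- ORACLE_SENSE[aa == a]
      sample(v, 1, prob = w[match(v, ORACLE_SENSE)])
    }, character(1))
    paste(cods, collapse = "")
  }
  for (g3 in c(0.45, 0.55)) {
    ed <- vapply(1:6, function(s) enc_record(gen(3000, g3, s))$enc_diff,
                 numeric(1))
    expect_lt(abs(mean(ed)), 0.02)
  }
})
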