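test_that("parsimony polarization follows the two-outgroup rules", {
  p <- polarize(c(rep("A", 19), "G"), "A", "A")
  expect_equal(p[c("status", "anc", "der", "i", "n")],
               list(status = "polarized", anc = "A", der = "G",
                    i = 1L, n = 20L))
  expect_equal(polarize(c(rep("A", 10), rep("G", 10)), "A", "G")$status,
               "unpolarized")
  p2 <- polarize(c(rep("A", 12), rep("G", 8)), "G", "G")
  expect_equal(p2$anc, "G")
  expect_equal(p2$i, 12L)   # derived = A
  # single outgroup suffices in relaxed mode only
  expect_equal(polarize(c("A", "A", "G"), "A", NA)$status, "polarized")
  expect_equal(polarize(c("A", "A", "G"), "A", NA,
                        relaxed = FALSE)$status, "unpolarized")
  # outgroup matching neither allele
  expect_equal(polarize(c("A", "A", "G"), "C", "C")$status,
               "unpolarized")
  expect_equal(polarize(rep("A", 5), "A", "A")$status, "monomorphic")
  # order invariance of the ingroup allele list
  set.seed(2)
  al <- c(rep("C", 14), rep("T", 6))
  for (r in 1:5) {
    expect_equal(polarize(sample(al), "C", "C")$i, 6L)
  }
})

test_that("polarized coding sites classify by degeneracy and mutation class", {
  c1 <- classify_site("GGA", 3, "A", "G")
  expect_equal(c1$degeneracy, 4L)
  expect_equal(c1$class, "WS")
  expect_true(c1$included)
  c2 <- classify_site("GGA", 1, "G", "A")
  expect_equal(c2$degeneracy, 0L)
  expect_equal(c2$class, "SW")
  c3 <- classify_site("GAA", 3, "A", "G")
  expect_equal(c3$degeneracy, 2L)
  expect_false(c3$included)
  expect_error(classify_site("GGA", 3, "G", "A"), "does not match")
})

test_that("spectra bin derived counts and preserve generator bookkeeping", {
  sites <- data.frame(degeneracy = 4L, class = "WS", i = c(1L, 1L, 2L))
  sfs <- build_sfs(sites, n = 4L, L_W = c(`4` = 100), L_S = c(`4` = 50))
  expect_equal(unname(sfs[["4"]]$sfs["WS", ]), c(2, 1, 0))
  expect_equal(sum(sfs[["4"]]$sfs[c("SW", "cons"), ]), 0)
  # i = 0 / i = n reassigned monomorphic (dropped)
  sites2 <- rbind(sites, data.frame(degeneracy = 4L, class = "WS",
                                    i = c(0L, 4L)))
  sfs2 <- build_sfs(sites2, n = 4L, L_W = c(`4` = 100),
                    L_S = c(`4` = 50))
  expect_equal(sum(sfs2[["4"]]$sfs), 3)
  # generator-planted spectrum round-trips exactly
  sim <- simulate_polymorphism(n_sites = 5e4, seed = 12)
  back <- build_sfs(cbind(sim$sites, degeneracy = 4L), n = 20L,
                    L_W = c(`4` = sim$truth$L_W),
                    L_S = c(`4` = sim$truth$L_S))
  expect_equal(back[["4"]]$sfs, sim$data$sfs)
})

test_that("expected SFS reduces to theta/i at B = 0 and is continuous there", {
  for (n in c(2L, 10L, 50L)) {
    expect_equal(expected_sfs(3.7, 0, n), 3.7 / seq_len(n - 1L))
  }
  # continuity across the analytic switch
  for (n in c(10L, 20L)) {
    e_small <- expected_sfs(1, 1e-6, n)
    expect_lt(max(abs(e_small - 1 / seq_len(n - 1L))), 1e-5)
  }
})

test_that("expected SFS matches independent quadrature oracles", {
  integrand <- function(x, i, n, B) {
    choose(n, i) * x^(i - 1) * (1 - x)^(n - i - 1) *
      (1 - exp(-B * (1 - x))) / (1 - exp(-B))
  }
  for (B in c(2, -1.3, 0.46)) {
    got <- expected_sfs(1, B, 10)
    adaptive <- vapply(1:9, function(i) {
      stats::integrate(integrand, 0, 1, i = i, n = 10, B = B,
                       rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(got, adaptive, tolerance = 1e-8)
    # fine-grid midpoint Riemann sum
    x <- (seq_len(2e5) - 0.5) / 2e5
    riemann <- vapply(1:9, function(i) mean(integrand(x, i, 10, B)),
                      numeric(1))
    expect_lt(max(abs(got - riemann) / riemann), 1e-6)
  }
})

test_that("neutral SFS is invariant under hypergeometric projection", {
  counts <- 1000 / seq_len(29)
  proj <- project_sfs(counts, 30L, 10L)
  # projected neutral spectrum stays proportional to 1/i
  expect_equal(proj / proj[1], (1 / seq_len(9)) / 1, tolerance = 1e-10)
})

test_that("model fit recovers the neutral null and planted parameters", {
  sim0 <- simulate_polymorphism(B = 0, lambda = 3, n_sites = 2e5,
                                seed = 71)
  fit0 <- fit_gbgc(sim0$data)
  expect_lt(abs(fit0$B), 0.1)
  boot0 <- bootstrap_fit(sim0$data, n_boot = 100L, seed = 5L)
  expect_true(boot0$ci$lower[boot0$ci$param == "B"] <= 0 &&
                boot0$ci$upper[boot0$ci$param == "B"] >= 0)
  expect_lt(abs(fit0$lambda - 3), 0.2)
})

test_that("median recovery bias is small at planted (B=0.5, lambda=3)", {
  est <- t(vapply(1:50, function(r) {
    sim <- simulate_polymorphism(B = 0.5, lambda = 3, n_sites = 1e5,
                                 seed = 900 + r)
    fit <- fit_gbgc(sim$data)
    c(fit$B, fit$lambda)
  }, numeric(2)))
  expect_lt(abs(stats::median(est[, 1]) - 0.5), 0.05)
  expect_lt(abs(stats::median(est[, 2]) - 3), 0.15)
})

test_that("doubling all counts doubles theta and leaves B and lambda fixed", {
  sim <- simulate_polymorphism(n_sites = 2e5, seed = 33)
  d <- sim$data
  d2 <- gbgc_data(2 * d$sfs["WS", ], 2 * d$sfs["SW", ],
                  2 * d$sfs["cons", ], 2 * d$L_W, 2 * d$L_S, d$n)
  f1 <- fit_gbgc(d)
  f2 <- fit_gbgc(d2)
  expect_equal(f2$B, f1$B, tolerance = 1e-4)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(unname(f2$theta / f1$theta), rep(2, 3), tolerance = 1e-3)
})

test_that("swapping the W->S and S->W classes flips the sign of B", {
  sim <- simulate_polymorphism(n_sites = 2e5, seed = 44)
  d <- sim$data
  swapped <- gbgc_data(d$sfs["SW", ], d$sfs["WS", ], d$sfs["cons", ],
                       L_W = d$L_S, L_S = d$L_W, n = d$n)
  f <- fit_gbgc(d)
  fs <- fit_gbgc(swapped)
  expect_equal(fs$B, -f$B, tolerance = 0.02)
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  sim <- simulate_polymorphism(n_sites = 5e4, theta0 = 0.02, seed = 3)
  b1 <- bootstrap_fit(sim$data, n_boot = 40L, seed = 17L)
  b2 <- bootstrap_fit(sim$data, n_boot = 40L, seed = 17L)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$boot, b2$boot)
  expect_equal(b1$n_failed, 0L)
})

test_that("VCF/FASTA/GFF fixtures round-trip into the identical site table", {
  sim <- simulate_polymorphism(n_sites = 400, theta0 = 0.02, seed = 3)
  for (minus in c(FALSE, TRUE)) {
    dir <- withr::local_tempdir()
    fx <- write_polymorphism_fixtures(sim$sites, n = 20L, dir = dir,
                                      minus_strand_gene = minus)
    rp <- read_polymorphism(fx$paths$vcf, fx$paths$fasta, fx$paths$gff,
                            fx$paths$outgroups)
    got <- rp$sites[order(rp$sites$pos), colnames(fx$expected)]
    rownames(got) <- NULL
    expect_equal(got, fx$expected, ignore_attr = TRUE)
    expect_equal(rp$n, 20L)
    expect_equal(rp$n_unpolarized, 0L)
  }
})

test_that("0-fold fixtures classify as 0-fold with the planted classes", {
  sim <- simulate_polymorphism(n_sites = 300, theta0 = 0.02,
                               gc = 0.451, B = 0.56, lambda = 2.73,
                               seed = 9)
  dir <- withr::local_tempdir()
  fx <- write_polymorphism_fixtures(sim$sites, n = 20L, dir = dir,
                                    degeneracy = 0L)
  rp <- read_polymorphism(fx$paths$vcf, fx$paths$fasta, fx$paths$gff,
                          fx$paths$outgroups)
  expect_true(all(rp$sites$degeneracy == 0L))
  expect_equal(sort(table(rp$sites$class), decreasing = TRUE),
               sort(table(fx$expected$class), decreasing = TRUE),
               ignore_attr = TRUE)
})
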