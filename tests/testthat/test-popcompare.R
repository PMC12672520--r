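test_that("build_table reconstructs reference counts by half-up rounding", {
  t1 <- build_table(4, 12, 0.5, 100)
  expect_equal(unname(t1), matrix(c(4L, 8L, 50L, 50L), 2, byrow = TRUE))
  expect_equal(unname(build_table(0, 10, 0, 100))[2, 1], 0L)
  expect_equal(unname(build_table(1, 10, 0.7818, 1000))[2, 1], 782L)
  expect_error(build_table(4, 12, 0.5, NA), class = "pharmscape_domain_error")
})

test_that("two-proportion Z matches the closed form and its chi-square identity", {
  tab <- matrix(c(40, 60, 60, 40), 2, byrow = TRUE)
  z <- two_proportion_z(tab)
  expect_equal(z$z, -2.828427, tolerance = 1e-6)
  expect_equal(z$p, 2 * pnorm(-abs(-0.2 / sqrt(0.5 * 0.5 * (2 / 100)))))
  chi <- chi_square_test(tab)
  expect_equal(chi$chi2, 8, tolerance = 1e-9)
  expect_equal(z$z^2, chi$chi2, tolerance = 1e-9)

  same <- matrix(c(30, 70, 30, 70), 2, byrow = TRUE)
  expect_equal(two_proportion_z(same), list(z = 0, p = 1))
  # degenerate pooled proportion
  expect_equal(two_proportion_z(matrix(c(0, 10, 0, 20), 2, byrow = TRUE)),
               list(z = 0, p = 1))
})

test_that("z^2 equals uncorrected Pearson chi-square on random tables", {
  set.seed(21)
  for (rep in 1:50) {
    tab <- matrix(sample(1:200, 4), 2)
    z <- two_proportion_z(tab)
    chi <- chi_square_test(tab, continuity_correction = FALSE)
    expect_equal(z$z^2, chi$chi2, tolerance = 1e-9)
    # Yates-corrected statistic never exceeds the uncorrected one
    expect_lte(chi_square_test(tab, TRUE)$chi2, chi$chi2 + 1e-12)
  }
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  tab <- matrix(c(3, 7, 5, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab), tolerance = 1e-9)
  # full enumeration gives 0.6499166...; 0.649914 is the rounded reference
  expect_equal(fisher_exact(tab), 0.649914, tolerance = 1e-5)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-9)
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)),
               class = "pharmscape_domain_error")

  # random small tables (N <= 40) against the enumeration oracle
  set.seed(9)
  for (rep in 1:100) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab), tolerance = 1e-9)
  }
})

test_that("odds ratio and Haldane zero-cell correction", {
  expect_equal(odds_ratio(matrix(c(40, 60, 60, 40), 2, byrow = TRUE))$or,
               1600 / 3600)
  expect_equal(odds_ratio(matrix(c(30, 70, 30, 70), 2, byrow = TRUE))$or, 1)
  corr <- odds_ratio(matrix(c(10, 0, 5, 5), 2, byrow = TRUE))
  expect_equal(corr$or, (10.5 * 5.5) / (0.5 * 5.5))
  expect_true(corr$defined)
  raw <- odds_ratio(matrix(c(10, 0, 5, 5), 2, byrow = TRUE),
                    zero_cell_correction = FALSE)
  expect_false(raw$defined)
  expect_true(is.na(raw$or))
  # CI brackets the point estimate
  ok <- odds_ratio(matrix(c(40, 60, 60, 40), 2, byrow = TRUE))
  expect_lt(ok$ci_low, ok$or)
  expect_gt(ok$ci_high, ok$or)
})

test_that("p-value adjustment: BH step-up and Bonferroni", {
  expect_equal(adjust_pvalues(c(0.005, 0.04, 0.5), "bh"),
               c(0.015, 0.06, 0.5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "pharmscape_domain_error")

  set.seed(2)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(adjust_pvalues(p, "bh"), oracle_bh(p), tolerance = 1e-12)
    # BH adjusted values are monotone in raw-p rank
    o <- order(p)
    expect_true(!is.unsorted(adjust_pvalues(p, "bh")[o]))
    # Bonferroni dominates raw p
    expect_true(all(adjust_pvalues(p, "bonferroni") >= p - 1e-15))
  }
})

test_that("significance banding follows the published tier scheme", {
  expect_equal(assign_band(0.01), "*")
  expect_equal(assign_band(1e-30), "**")
  expect_equal(assign_band(0.2), "ns")
  expect_equal(assign_band(1e-50), "***")
  expect_equal(assign_band(1e-60), "***")
  # gap-filling defaults: just above the *** cutoff is **, 0.05 itself is ns
  expect_equal(assign_band(1.0001e-50), "**")
  expect_equal(assign_band(0.05), "ns")
  expect_error(assign_band(0.01, bands = c("*" = 0.05, "**" = 1e-20)),
               class = "pharmscape_domain_error")
})

test_that("compare_landscape: equal frequencies are null, shifted loci rank first", {
  # exactly equal cohort and reference frequencies -> all three p = 1
  freqs <- tibble::tibble(
    gene = "G1", chrom = "1", pos = 100L, ref = "A", alt = "G", rsid = "rs1",
    consequence_class = "missense", AC = 30L, AN = 100L, AF = 0.3
  )
  reference <- tibble::tibble(
    chrom = "1", pos = 100L, ref = "A", alt = "G",
    population = "overall", AF = 0.3, AN = 100L
  )
  res <- compare_landscape(freqs, reference)$results
  expect_equal(res$p_z, 1)
  expect_equal(res$p_chi2, 1)
  expect_equal(res$p_fisher, 1)
  expect_equal(res$band, "ns")

  # synthetic 100-locus panel: the 10 shifted loci carry the smallest adjusted p
  set.seed(77)
  m <- 100; n_alleles <- 2000
  true_af <- rep(0.3, m)
  ref_af <- true_af; ref_af[1:10] <- 0.5
  ac <- rbinom(m, n_alleles, true_af)
  freqs2 <- tibble::tibble(
    gene = sprintf("G%d", 1:m), chrom = "1", pos = 1000L + 1:m,
    ref = "A", alt = "G", rsid = sprintf("rs%d", 1:m),
    consequence_class = "missense",
    AC = ac, AN = n_alleles, AF = ac / n_alleles
  )
  reference2 <- tibble::tibble(
    chrom = "1", pos = 1000L + 1:m, ref = "A", alt = "G",
    population = "overall", AF = ref_af, AN = 10000L
  )
  res2 <- compare_landscape(freqs2, reference2)$results
  top10 <- res2$gene[1:10]
  expect_setequal(top10, sprintf("G%d", 1:10))

  # cohort loci absent from the reference are reported separately
  freqs3 <- dplyr::bind_rows(freqs, dplyr::mutate(freqs, pos = 999L, gene = "G9"))
  res3 <- compare_landscape(freqs3, reference)
  expect_equal(res3$unmatched$gene, "G9")
  expect_error(compare_landscape(dplyr::mutate(freqs, pos = 1L), reference),
               class = "pharmscape_domain_error")
})
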