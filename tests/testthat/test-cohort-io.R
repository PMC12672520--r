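test_that("read_cohort builds the matrix and reports absent catalog loci", {
  rows <- catalog_row(
    gene = c("G1", "G2", "G3", "G4"),
    chrom = "1", pos = c(100L, 200L, 300L, 999L),
    ref = "A", alt = "G", rsid = c("rs1", "rs2", "rs3", "rs4")
  )
  cat <- load_catalog(write_catalog_fixture(rows))
  samples <- sprintf("S%d", 1:5)
  vcf <- write_vcf_lines(c(
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            c("0/0", "0/1", "1/1", "0/0", "./.")), collapse = "\t"),
    paste(c("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT",
            c("0/1", "0/1", "0/0", "0/0", "0/0")), collapse = "\t"),
    paste(c("1", "300", "rs3", "A", "G", ".", "PASS", ".", "GT",
            c("1/1", "1/1", "0/1", "./1", "0/0")), collapse = "\t")
  ), samples)
  gm <- read_cohort(vcf, cat)
  expect_equal(dim(gm$geno), c(5, 3))
  expect_equal(gm$missing_loci$rsid, "rs4")
  expect_equal(gm$geno[, 1], c(0L, 1L, 2L, 0L, NA))
  # half-call "./1" treated as missing
  expect_true(is.na(gm$geno[4, 3]))
})

test_that("multiallelic records are decomposed against the catalog allele", {
  cat <- load_catalog(write_catalog_fixture(
    catalog_row(gene = "G1", chrom = "1", pos = 100L, ref = "A", alt = "T",
                rsid = "rs1")
  ))
  vcf <- write_vcf_lines(
    paste(c("1", "100", "rs1", "A", "C,T", ".", "PASS", ".", "GT",
            c("1/2", "2/2", "0/1", "0/2", "0/0")), collapse = "\t"),
    sprintf("S%d", 1:5)
  )
  gm <- read_cohort(vcf, cat)
  # T is alt index 2: 1/2 -> dosage 1; 2/2 -> 2; 0/1 (the other alt) -> 0 but called
  expect_equal(gm$geno[, 1], c(1L, 2L, 0L, 1L, 0L))
})

test_that("chromosome name dialects are reconciled", {
  cat <- load_catalog(write_catalog_fixture(
    catalog_row(gene = "G1", chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  ))
  vcf <- write_vcf_lines(
    paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t"),
    "S1"
  )
  gm <- read_cohort(vcf, cat)
  expect_equal(ncol(gm$geno), 1)
  expect_equal(gm$geno[1, 1], 1L)
})

test_that("allele_frequencies matches hand counts and handles edge cases", {
  # {0/0 x3, 0/1 x2, 1/1 x1, missing x1} -> AN=12, AC=4, AF=1/3
  g <- matrix(c(0L, 0L, 0L, 1L, 1L, 2L, NA), ncol = 1)
  fr <- allele_frequencies(make_gm(g))
  expect_equal(fr$AN, 12L)
  expect_equal(fr$AC, 4L)
  expect_equal(fr$AF, 1 / 3)
  expect_equal(c(fr$f_hom_ref, fr$f_het, fr$f_hom_alt), c(1/2, 1/3, 1/6))

  # all hom-ref and all het
  fr0 <- allele_frequencies(make_gm(matrix(0L, 5, 1)))
  expect_equal(c(fr0$AC, fr0$AN, fr0$AF), c(0, 10, 0))
  fr5 <- allele_frequencies(make_gm(matrix(1L, 4, 1)))
  expect_equal(fr5$AF, 0.5)
  expect_equal(c(fr5$f_hom_ref, fr5$f_het, fr5$f_hom_alt), c(0, 1, 0))

  # zero called samples -> flagged NA
  frNA <- allele_frequencies(make_gm(matrix(NA_integer_, 3, 1)))
  expect_true(is.na(frNA$AF))
  expect_equal(frNA$AN, 0L)
})

test_that("AC/AN identities hold under random missingness and sample permutation", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:40, 1); m <- sample(1:6, 1)
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE), n, m)
    fr <- allele_frequencies(make_gm(g))
    expect_equal(fr$AC, fr$n_het + 2L * fr$n_hom_alt)
    expect_equal(fr$AN, 2L * (fr$n_hom_ref + fr$n_het + fr$n_hom_alt))
    called <- fr$n_hom_ref + fr$n_het + fr$n_hom_alt
    sums <- (fr$f_hom_ref + fr$f_het + fr$f_hom_alt)[called > 0]
    expect_equal(sums, rep(1, length(sums)))
    # permutation invariance in samples
    fr_perm <- allele_frequencies(make_gm(g[sample(n), , drop = FALSE]))
    expect_equal(fr_perm$AF, fr$AF)
  }
})

test_that("VCF write/read round-trip reproduces genotype codes", {
  set.seed(5)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), 10, 6)
  gm <- make_gm(g)
  path <- tempfile(fileext = ".vcf")
  write_genotype_vcf(gm, path)
  cat <- load_catalog(write_catalog_fixture(
    dplyr::mutate(gm$loci, drugs = "multiple", evidence_level = "",
                  is_hla_haplotype = FALSE)
  ))
  back <- read_cohort(path, cat)
  expect_equal(unname(back$geno), unname(g))
  expect_equal(back$sample_ids, gm$sample_ids)
})

test_that("classify_variants flags singletons and the rare/common split", {
  set.seed(3)
  # 100-sample cohort, chosen alt-allele counts
  acs <- c(1L, 1L, 2L, 3L, 30L)
  g <- sapply(acs, function(ac) {
    v <- integer(100)
    v[seq_len(ac)] <- 1L
    v
  })
  lab <- classify_variants(allele_frequencies(make_gm(g)), rare_threshold = 0.01)
  expect_equal(sum(lab$is_singleton), 2)
  # AFs are AC/200: 0.005, 0.005, 0.01, 0.015, 0.15; rare is strictly < 0.01
  expect_equal(lab$rarity, c("rare", "rare", "common", "common", "common"))
  expect_error(classify_variants(lab, rare_threshold = 0),
               class = "pharmscape_domain_error")
  # AF just below the threshold is rare by definition
  lab2 <- classify_variants(tibble::tibble(AC = 5L, AN = 1000L, AF = 0.005))
  expect_equal(lab2$rarity, "rare")
})

test_that("gene_summary tallies class counts and shares", {
  freqs <- tibble::tibble(
    gene = c("X", "X", "X", "Y", "Y", rep("Z", 5)),
    consequence_class = c(rep("missense", 3), "missense", "lof",
                          rep("missense", 4), "lof"),
    AF = 0.1, AC = 10L, AN = 100L
  )
  lab <- classify_variants(freqs)
  gs <- gene_summary(lab)
  x_mis <- gs[gs$gene == "X" & gs$consequence_class == "missense", ]
  expect_equal(x_mis$n, 3)
  expect_equal(x_mis$class_total, 8)
  expect_equal(x_mis$pct_of_class, 100 * 3 / 8)
  expect_error(gene_summary(lab, gene = "NOPE"),
               class = "pharmscape_domain_error")
})

test_that("format errors are raised for unusable VCFs", {
  cat <- load_catalog(write_catalog_fixture(catalog_row()))
  # VCF without samples/GT
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c("6", "31575254", ".", "G", "A", ".", "PASS", "."), collapse = "\t")
  ), path)
  expect_error(read_cohort(path, cat), class = "pharmscape_format_error")
})
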