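# Population comparison: cohort allele frequencies vs a reference table,
# via 2x2 allele-count contingency tables, three tests, odds ratios,
# multiple-testing adjustment and significance banding.

#' Read a reference-population frequency table
#'
#' Expected TSV columns: `chrom`, `pos`, `ref`, `alt`, `population`, `AF`,
#' `AN`. One row per (locus, population).
#'
#' @param path Path to the reference TSV.
#' @return A tibble.
#' @export
read_reference <- function(path) {
  ref <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      population = readr::col_character(), AF = readr::col_double(),
      AN = readr::col_integer()
    )
  )
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt", "population", "AF", "AN"),
                          names(ref))
  if (length(missing_cols) > 0) {
    stop_pharmscape(
      sprintf("reference TSV missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "pharmscape_schema_error"
    )
  }
  assert_prob(ref$AF, "reference AF")
  ref
}

#' Build the 2x2 allele-count table for one locus
#'
#' Cohort row is (AC, AN - AC). The reference provides a frequency, so its
#' alt count is reconstructed as `round(AF * AN)` (half-up), ref count
#' `AN - alt`.
#'
#' @param cohort_ac,cohort_an Cohort alt allele count and called allele number.
#' @param ref_af,ref_an Reference allele frequency and allele number.
#' @return Integer matrix `[[cohort_alt, cohort_ref], [ref_alt, ref_ref]]`.
#' @export
build_table <- function(cohort_ac, cohort_an, ref_af, ref_an) {
  if (is.na(ref_an) || ref_an <= 0) {
    stop_pharmscape(
      "reference AN is missing; supply a reference table with AN or set a default via ref_an",
      "pharmscape_domain_error"
    )
  }
  if (cohort_an <= 0) {
    stop_pharmscape("cohort AN must be positive", "pharmscape_domain_error")
  }
  ref_alt <- floor(ref_af * ref_an + 0.5)   # round half-up
  m <- matrix(as.integer(c(cohort_ac, cohort_an - cohort_ac,
                           ref_alt, ref_an - ref_alt)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("cohort", "reference"), c("alt", "ref")))
  m
}

#' Two-proportion Z-test (pooled variance, two-sided)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p`. When the pooled proportion is 0 or 1 the test is degenerate and
#' returns `z = 0`, `p = 1`.
#'
#' @param table 2x2 matrix as from [build_table()] (rows are groups,
#'   columns successes/failures).
#' @return List with `z` and `p`.
#' @export
two_proportion_z <- function(table) {
  n1 <- sum(table[1, ]); n2 <- sum(table[2, ])
  if (n1 == 0 || n2 == 0) {
    stop_pharmscape("both group totals must be > 0", "pharmscape_domain_error")
  }
  p1 <- table[1, 1] / n1
  p2 <- table[2, 1] / n2
  pooled <- (table[1, 1] + table[2, 1]) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    return(list(z = 0, p = 1))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Continuity (Yates) correction is off by default, which preserves the
#' identity z-squared = chi-square with the two-proportion Z-test.
#'
#' @param table 2x2 integer matrix.
#' @param continuity_correction Apply Yates correction (default `FALSE`).
#' @return List with `chi2` and `p`.
#' @export
chi_square_test <- function(table, continuity_correction = FALSE) {
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_pharmscape("chi-square test needs all margins > 0",
                    "pharmscape_domain_error")
  }
  res <- suppressWarnings(
    stats::chisq.test(table, correct = continuity_correction)
  )
  list(chi2 = unname(res$statistic), p = res$p.value)
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose point probability does not exceed the observed
#' one (ties at relative tolerance 1e-7, the standard convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  if (any(table < 0) || any(table != round(table))) {
    stop_pharmscape("Fisher's exact test needs non-negative integer cells",
                    "pharmscape_domain_error")
  }
  stats::fisher.test(table)$p.value
}

#' Odds ratio with 95% confidence interval
#'
#' `OR = (a d)/(b c)` on the 2x2 table. If any cell is zero and
#' `zero_cell_correction` is `TRUE`, 0.5 is added to every cell
#' (Haldane-Anscombe) before computing OR and CI. With correction disabled a
#' zero cell yields a flagged undefined result (`NA`s), not an error.
#'
#' @param table 2x2 matrix.
#' @param zero_cell_correction Apply the 0.5 correction (default `TRUE`).
#' @return List with `or`, `ci_low`, `ci_high`, `defined`.
#' @export
odds_ratio <- function(table, zero_cell_correction = TRUE) {
  t2 <- table
  if (any(table == 0)) {
    if (!zero_cell_correction) {
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  defined = FALSE))
    }
    t2 <- table + 0.5
  }
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       defined = TRUE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (FDR) or Bonferroni, preserving input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvals, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  assert_prob(pvals[!is.na(pvals)], "p-values")
  p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni")
}

#' Default significance bands
#'
#' The published banding scheme: `*` for p < 0.05, `**` for p < 1e-20,
#' `***` for p <= 1e-50, `ns` otherwise. The printed scheme leaves
#' (1e-20, 0.05) and (1e-50, 1e-49) unassigned; these defaults close the gaps
#' so banding is total.
#' @export
default_bands <- function() {
  c("***" = 1e-50, "**" = 1e-20, "*" = 0.05)
}

#' Assign a significance band to an adjusted p-value
#'
#' @param p_adjusted Adjusted p-value(s).
#' @param bands Named numeric vector of strictly increasing thresholds from
#'   most to least extreme tier; see [default_bands()]. The most extreme tier
#'   uses `<=`, the rest `<`.
#' @return Character tier(s): a band label or `"ns"`.
#' @export
assign_band <- function(p_adjusted, bands = default_bands()) {
  if (is.unsorted(bands, strictly = TRUE)) {
    stop_pharmscape("band thresholds must be strictly increasing from the most extreme tier",
                    "pharmscape_domain_error")
  }
  vapply(p_adjusted, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p <= bands[[1]]) return(names(bands)[1])
    for (i in seq_along(bands)[-1]) {
      if (p < bands[[i]]) return(names(bands)[i])
    }
    "ns"
  }, character(1))
}

#' Compare cohort allele frequencies against a reference population
#'
#' For every locus present in both the cohort frequency table and the
#' reference table (for the requested population): build the 2x2 allele-count
#' table, run chi-square, Fisher exact and two-proportion Z tests, compute the
#' odds ratio, adjust the chosen primary p-value over the whole tested family,
#' and assign a significance band.
#'
#' @param freqs Cohort frequency table from [allele_frequencies()] (loci with
#'   `AN == 0` are excluded automatically).
#' @param reference Reference tibble as from [read_reference()].
#' @param population Reference population label to compare against
#'   (default `"overall"`).
#' @param primary_test Which test supplies the p-value that is adjusted:
#'   `"z"` (default), `"chi2"` or `"fisher"`.
#' @param adjust `"bh"` (default) or `"bonferroni"`.
#' @param bands Band thresholds, see [assign_band()].
#' @param continuity_correction Yates correction for the chi-square test.
#' @param ref_an Default reference AN used where the table's `AN` is missing.
#' @return A list with `results` (tibble, one row per compared locus, sorted
#'   by adjusted p) and `unmatched` (cohort loci absent from the reference).
#' @export
compare_landscape <- function(freqs, reference,
                              population = "overall",
                              primary_test = c("z", "chi2", "fisher"),
                              adjust = c("bh", "bonferroni"),
                              bands = default_bands(),
                              continuity_correction = FALSE,
                              ref_an = NULL) {
  primary_test <- match.arg(primary_test)
  adjust <- match.arg(adjust)

  ref <- reference[reference$population == population, , drop = FALSE]
  ref$key <- locus_key(ref$chrom, ref$pos, ref$ref, ref$alt)
  usable <- freqs[!is.na(freqs$AF) & freqs$AN > 0, , drop = FALSE]
  usable$key <- locus_key(usable$chrom, usable$pos, usable$ref, usable$alt)
  usable <- usable[!duplicated(usable$key), , drop = FALSE]

  idx <- match(usable$key, ref$key)
  matched <- usable[!is.na(idx), , drop = FALSE]
  refm <- ref[idx[!is.na(idx)], , drop = FALSE]
  unmatched <- usable[is.na(idx), setdiff(names(usable), "key"), drop = FALSE]
  if (nrow(matched) == 0) {
    stop_pharmscape("no loci shared between cohort and reference table",
                    "pharmscape_domain_error")
  }
  refm$AN[is.na(refm$AN)] <- if (!is.null(ref_an)) as.integer(ref_an) else NA_integer_

  rows <- purrr::map(seq_len(nrow(matched)), function(i) {
    tab <- build_table(matched$AC[i], matched$AN[i], refm$AF[i], refm$AN[i])
    z <- two_proportion_z(tab)
    chi <- tryCatch(chi_square_test(tab, continuity_correction),
                    pharmscape_error = function(e) list(chi2 = NA_real_, p = NA_real_))
    pf <- fisher_exact(tab)
    orr <- odds_ratio(tab)
    tibble(
      p_chi2 = chi$p, chi2_stat = chi$chi2,
      p_fisher = pf,
      p_z = z$p, z_stat = z$z,
      odds_ratio = orr$or, or_ci_low = orr$ci_low, or_ci_high = orr$ci_high,
      or_defined = orr$defined
    )
  })
  stats_tbl <- dplyr::bind_rows(rows)
  p_primary <- switch(primary_test,
                      z = stats_tbl$p_z,
                      chi2 = stats_tbl$p_chi2,
                      fisher = stats_tbl$p_fisher)
  out <- dplyr::bind_cols(
    matched[, intersect(c("gene", "chrom", "pos", "ref", "alt", "rsid",
                          "consequence_class"), names(matched))],
    tibble(cohort_AF = matched$AF, cohort_AC = matched$AC,
           cohort_AN = matched$AN,
           ref_AF = refm$AF, ref_AN = refm$AN),
    stats_tbl,
    tibble(p_primary = p_primary)
  )
  out$p_adjusted <- adjust_pvalues(out$p_primary, adjust)
  out$band <- assign_band(out$p_adjusted, bands)
  out <- out[order(out$p_adjusted, out$p_primary), , drop = FALSE]
  list(results = out, unmatched = unmatched)
}
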