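# Gene-level cumulative allele probability (CAP) burden and the
# variants-per-participant functional score.

#' Cumulative allele probability for a set of variant allele frequencies
#'
#' `CAP = 1 - prod(1 - AF)^2` over the gene's variant allele set: the
#' probability that a diploid individual drawn from the population carries at
#' least one variant allele in the gene, assuming independent loci and
#' Hardy-Weinberg genotype proportions. An empty set scores 0; any AF of 1 is
#' absorbing (CAP = 1). The diploid exponent 2 is used for all loci,
#' including non-autosomal ones (logged limitation).
#'
#' @param afs Numeric vector of allele frequencies in `[0, 1]`.
#' @return CAP value in `[0, 1]`.
#' @examples
#' cap_score(c(0.1, 0.2))  # 1 - (0.81 * 0.64) = 0.4816
#' @export
cap_score <- function(afs) {
  if (length(afs) == 0) return(0)
  assert_prob(afs, "allele frequencies")
  1 - prod((1 - afs)^2)
}

#' Expected variant alleles carried per participant
#'
#' The "variants per participant" functional score: the expected count of
#' variant alleles a diploid participant carries across the gene's variant
#' set. With `per = "participant"` (default) this is `sum(2 * AF)`, which
#' equals total AC divided by cohort size; `per = "site"` gives the
#' per-variant-site alternative `sum(AF)`.
#'
#' @param afs Numeric vector of allele frequencies in `[0, 1]`.
#' @param per `"participant"` (default) or `"site"`.
#' @return Non-negative score.
#' @export
variants_per_participant <- function(afs, per = c("participant", "site")) {
  per <- match.arg(per)
  if (length(afs) == 0) return(0)
  assert_prob(afs, "allele frequencies")
  if (per == "participant") sum(2 * afs) else sum(afs)
}

#' Per-gene CAP burden for a variant class
#'
#' Collects, per gene, the catalog loci of the requested consequence class
#' observed in the cohort, and applies [cap_score()] and
#' [variants_per_participant()] to their cohort allele frequencies. Loci with
#' undefined AF (zero called samples) are excluded from the allele set and
#' reported separately. Genes with no qualifying variants score `cap = 0`,
#' `n_variants = 0`.
#'
#' @param freqs Cohort frequency table (from [allele_frequencies()]), which
#'   must carry `gene` and `consequence_class` columns (present when the
#'   genotype matrix was built from a catalog).
#' @param variant_class `"missense"`, `"lof"` or `"all_functional"`
#'   (missense plus lof).
#' @param genes Optional gene universe; defaults to all genes in `freqs`.
#' @param vpp_per Passed to [variants_per_participant()].
#' @return A list with `scores` (tibble `gene`, `variant_class`,
#'   `n_variants`, `cap`, `vpp`, ranked by descending CAP) and `excluded`
#'   (loci dropped for undefined AF).
#' @export
burden_by_gene <- function(freqs, variant_class = c("missense", "lof", "all_functional"),
                           genes = NULL, vpp_per = "participant") {
  variant_class <- match.arg(variant_class)
  classes <- switch(variant_class,
                    missense = "missense",
                    lof = "lof",
                    all_functional = c("missense", "lof"))
  if (!("consequence_class" %in% names(freqs))) {
    stop_pharmscape("frequency table lacks consequence_class; build it from a catalog",
                    "pharmscape_schema_error")
  }
  genes <- genes %||% sort(unique(freqs$gene))
  qualifying <- freqs[freqs$consequence_class %in% classes, , drop = FALSE]
  excluded <- qualifying[is.na(qualifying$AF), , drop = FALSE]
  qualifying <- qualifying[!is.na(qualifying$AF), , drop = FALSE]
  scores <- purrr::map(genes, function(g) {
    afs <- qualifying$AF[qualifying$gene == g]
    tibble(
      gene = g, variant_class = variant_class,
      n_variants = length(afs),
      cap = cap_score(afs),
      vpp = variants_per_participant(afs, per = vpp_per)
    )
  })
  scores <- dplyr::bind_rows(scores)
  scores <- scores[order(-scores$cap, scores$gene), , drop = FALSE]
  list(scores = scores, excluded = excluded)
}
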