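# Cohort genotype extraction: VCF -> genotype matrix for catalog loci.
# Parsing goes through VariantAnnotation; GT decoding and multiallelic
# decomposition against the catalog allele are done here.

new_genotype_matrix <- function(sample_ids, loci, geno, missing_loci) {
  stopifnot(nrow(geno) == length(sample_ids), ncol(geno) == nrow(loci))
  structure(
    list(sample_ids = sample_ids, loci = loci, geno = geno,
         missing_loci = missing_loci),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci (%d catalog loci absent from VCF)\n",
              length(x$sample_ids), nrow(x$loci), nrow(x$missing_loci)))
  invisible(x)
}

# Decode a vector of GT strings into alt-allele dosage for allele index k.
# Half-calls ("./1") and any call containing "." are treated as missing.
# Genotypes carrying a *different* alt allele stay called (dosage counts only
# allele k), implementing per-alt decomposition of multiallelic records.
decode_gt <- function(gt, k) {
  gt <- sub(":.*$", "", gt)           # GT is always first; drop other fields
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(a) {
    if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_integer_)
    sum(a == as.character(k))
  }, integer(1))
}

#' Read cohort genotypes at catalog loci from a VCF
#'
#' Streams a VCF v4.2 file (plain or bgzipped) through
#' [VariantAnnotation::readVcf()] and extracts one genotype-matrix column per
#' catalog locus found. Multiallelic records are decomposed so each alt allele
#' is matched independently against the catalog allele: a `1/2` genotype codes
#' as dosage 1 for either alt. Chromosome spellings `chr6` vs `6` are
#' reconciled automatically. Catalog loci absent from the VCF are returned in
#' the `missing_loci` table (the "not present in this population" case), not
#' an error.
#'
#' @param vcf_path Path to the cohort VCF.
#' @param catalog A curated `variant_catalog`.
#' @return A `genotype_matrix`: `sample_ids`, `loci` (tibble of matched
#'   catalog rows), `geno` (integer matrix samples x loci; entries 0/1/2 count
#'   alt alleles, `NA` = missing call) and `missing_loci`.
#' @export
read_cohort <- function(vcf_path, catalog) {
  if (nrow(catalog$entries) == 0) {
    stop_pharmscape("catalog is empty; nothing to extract",
                    "pharmscape_domain_error")
  }
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "cohort")
  if (!("GT" %in% names(VariantAnnotation::geno(vcf)))) {
    stop_pharmscape("VCF has no GT genotype field", "pharmscape_format_error")
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (ncol(gt) == 0) {
    stop_pharmscape("VCF contains zero samples", "pharmscape_format_error")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)

  entries <- catalog$entries
  # one matrix column per distinct (gene, locus); the same locus listed under
  # several drug associations collapses to one column
  cat_keys <- locus_key(entries$chrom, entries$pos, entries$ref, entries$alt)
  keep_rows <- !duplicated(paste(entries$gene, cat_keys))
  entries <- entries[keep_rows, , drop = FALSE]
  cat_keys <- cat_keys[keep_rows]
  # per-record decomposed keys: one per alt allele
  rec_idx <- rep(seq_along(chrom), lengths(alt_list))
  alt_idx <- unlist(lapply(lengths(alt_list), seq_len), use.names = FALSE)
  alts <- as.character(unlist(alt_list, use.names = FALSE))
  vcf_keys <- locus_key(chrom[rec_idx], pos[rec_idx], ref[rec_idx], alts)

  match_pos <- match(cat_keys, vcf_keys)
  found <- !is.na(match_pos)
  cols <- lapply(which(found), function(i) {
    m <- match_pos[i]
    decode_gt(gt[rec_idx[m], ], alt_idx[m])
  })
  geno <- if (length(cols)) {
    matrix(unlist(cols, use.names = FALSE), nrow = ncol(gt))
  } else {
    matrix(integer(0), nrow = ncol(gt), ncol = 0)
  }
  new_genotype_matrix(
    sample_ids = colnames(gt),
    loci = entries[found, , drop = FALSE],
    geno = geno,
    missing_loci = entries[!found, , drop = FALSE]
  )
}

#' Per-locus allele and genotype frequencies
#'
#' Missing genotypes are excluded from AN (site-level pairwise-complete
#' deletion, never imputed). Loci with zero called samples are flagged
#' (`AF = NA`) so downstream tests can exclude them.
#'
#' @param gm A `genotype_matrix`.
#' @return A tibble with one row per locus: locus identity columns plus
#'   `AC`, `AN`, `AF`, genotype counts `n_hom_ref`/`n_het`/`n_hom_alt`/
#'   `n_missing`, genotype frequencies over called samples
#'   `f_hom_ref`/`f_het`/`f_hom_alt`, and `n_samples`.
#' @export
allele_frequencies <- function(gm) {
  g <- gm$geno
  n_hom_ref <- colSums(g == 0L, na.rm = TRUE)
  n_het     <- colSums(g == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(g == 2L, na.rm = TRUE)
  n_missing <- colSums(is.na(g))
  called <- n_hom_ref + n_het + n_hom_alt
  AN <- 2L * called
  AC <- n_het + 2L * n_hom_alt
  AF <- ifelse(AN > 0, AC / AN, NA_real_)
  dplyr::bind_cols(
    gm$loci[, intersect(c("chrom", "pos", "ref", "alt", "rsid", "gene",
                          "consequence_class"), names(gm$loci))],
    tibble(
      AC = as.integer(AC), AN = as.integer(AN), AF = AF,
      n_hom_ref = as.integer(n_hom_ref), n_het = as.integer(n_het),
      n_hom_alt = as.integer(n_hom_alt), n_missing = as.integer(n_missing),
      f_hom_ref = ifelse(called > 0, n_hom_ref / called, NA_real_),
      f_het     = ifelse(called > 0, n_het / called, NA_real_),
      f_hom_alt = ifelse(called > 0, n_hom_alt / called, NA_real_),
      n_samples = length(gm$sample_ids)
    )
  )
}

#' Classify variants by rarity and singleton status
#'
#' A singleton is a variant observed on exactly one allele copy in the cohort
#' (AC = 1, defined on the whole cohort). A variant is `rare` when its cohort
#' AF is strictly below `rare_threshold`, else `common`.
#'
#' @param freqs Output of [allele_frequencies()].
#' @param rare_threshold AF cutoff in (0, 1); default 0.01.
#' @return `freqs` with `is_singleton` and `rarity` columns appended.
#' @export
classify_variants <- function(freqs, rare_threshold = 0.01) {
  if (!is.numeric(rare_threshold) || rare_threshold <= 0 || rare_threshold >= 1) {
    stop_pharmscape("rare_threshold must lie in (0, 1)",
                    "pharmscape_domain_error")
  }
  freqs %>%
    mutate(
      is_singleton = .data$AC == 1L,
      rarity = dplyr::if_else(.data$AF < rare_threshold, "rare", "common",
                              missing = NA_character_)
    )
}

#' Per-gene variant class summary
#'
#' Counts a gene's observed variants per consequence class and rarity, with
#' each class count's share of the module-wide class total.
#'
#' @param labelled Output of [classify_variants()] (must carry
#'   `consequence_class`).
#' @param gene Optional gene symbol to restrict to; must exist in `labelled`.
#' @return Tibble: `gene`, `consequence_class`, `n`, `n_rare`, `n_singleton`,
#'   `class_total`, `pct_of_class`.
#' @export
gene_summary <- function(labelled, gene = NULL) {
  if (!is.null(gene) && !(gene %in% labelled$gene)) {
    stop_pharmscape(sprintf("gene \"%s\" not present in frequency table", gene),
                    "pharmscape_domain_error")
  }
  totals <- labelled %>%
    group_by(.data$consequence_class) %>%
    summarise(class_total = dplyr::n(), .groups = "drop")
  out <- labelled %>%
    group_by(.data$gene, .data$consequence_class) %>%
    summarise(
      n = dplyr::n(),
      n_rare = sum(.data$rarity == "rare", na.rm = TRUE),
      n_singleton = sum(.data$is_singleton, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    left_join(totals, by = "consequence_class") %>%
    mutate(pct_of_class = 100 * .data$n / .data$class_total)
  if (!is.null(gene)) out <- out[out$gene == gene, , drop = FALSE]
  out
}

#' Write a frequency table to TSV
#'
#' Columns follow the standard frequency-report layout; `AF` is printed with
#' 6 significant digits.
#'
#' @param freqs Output of [classify_variants()] (or [allele_frequencies()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(freqs, path) {
  out <- freqs
  out$AF <- ifelse(is.na(out$AF), NA_character_,
                   formatC(out$AF, digits = 6, format = "g"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a genotype matrix to a minimal VCF v4.2 file
#'
#' Emits an unphased GT-only VCF. With `fixed_date = TRUE` the `##fileDate`
#' header is a constant string so identical inputs produce byte-identical
#' files (reproducibility contract of the simulator).
#'
#' @param gm A `genotype_matrix` (or compatible list with `sample_ids`,
#'   `loci`, `geno`).
#' @param path Output path (plain text).
#' @param fixed_date Use a constant `##fileDate` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, fixed_date = TRUE) {
  loci <- gm$loci
  g <- gm$geno
  date_str <- if (fixed_date) "20240101" else format(Sys.Date(), "%Y%m%d")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##fileDate=%s", date_str),
    "##source=pharmscape",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  ord <- order(norm_chrom(loci$chrom), loci$pos)
  gt_strings <- c("0/0", "0/1", "1/1")
  body <- vapply(ord, function(j) {
    codes <- g[, j]
    gts <- ifelse(is.na(codes), "./.", gt_strings[codes + 1L])
    id <- loci$rsid[j]
    paste(c(loci$chrom[j], loci$pos[j],
            if (nzchar(id)) id else ".",
            loci$ref[j], loci$alt[j], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
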