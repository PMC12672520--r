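# End-to-end orchestration: catalog curation -> cohort extraction ->
# frequencies/classification -> population comparison -> LD -> CAP burden,
# with per-stage TSV outputs and a machine-readable JSON run summary.

pipeline_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[pharmscape:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pharmacogenomic-landscape pipeline
#'
#' Executes every stage in order and writes one TSV per stage plus
#' `run_summary.json` into `out_dir`. All stages are deterministic, so
#' re-running with identical inputs reproduces byte-identical outputs.
#' Stage files: `01_catalog_curated.tsv`, `02_frequencies.tsv`,
#' `03_comparison.tsv`, `04_ld.tsv`, `05_cap.tsv`.
#'
#' @param vcf Path to the cohort VCF.
#' @param catalog Path to the catalog TSV.
#' @param reference Path to the reference-frequency TSV.
#' @param out_dir Output directory (created if needed).
#' @param drug Optional drug filter applied to the curated catalog.
#' @param rare_threshold AF cutoff for the rare/common call (default 0.01).
#' @param adjust Multiple-testing method, `"bh"` (default) or `"bonferroni"`.
#' @param primary_test `"z"` (default), `"chi2"` or `"fisher"`.
#' @param ref_population Reference population label (default `"overall"`).
#' @param ld_pairs `NULL` for all pairs (only run when the matrix has 2..200
#'   loci), or a two-column pair specification for [ld_matrix()].
#' @param quiet Suppress per-stage logging (default `FALSE`).
#' @return Invisibly, a list with all in-memory stage results plus `summary`
#'   (the JSON summary as a list) and `files` (paths written).
#' @export
run_pipeline <- function(vcf, catalog, reference, out_dir,
                         drug = NULL, rare_threshold = 0.01,
                         adjust = "bh", primary_test = "z",
                         ref_population = "overall", ld_pairs = NULL,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  cat_raw <- load_catalog(catalog)
  cur <- curate_catalog(cat_raw)
  cat_cur <- cur$catalog
  if (!is.null(drug)) cat_cur <- subset_by_drug(cat_cur, drug)
  pipeline_log(quiet, "catalog", "%d rows in, %d after curation (%d duplicates, %d HLA haplotypes removed)%s",
               nrow(cat_raw$entries), nrow(cat_cur$entries),
               cur$n_duplicates_removed, nrow(cur$hla_removed),
               if (is.null(drug)) "" else sprintf(", drug=%s", drug))
  cat_out <- cat_cur$entries
  cat_out$drugs <- vapply(cat_out$drugs, paste, character(1), collapse = ";")
  files$catalog <- file.path(out_dir, "01_catalog_curated.tsv")
  readr::write_tsv(cat_out, files$catalog, progress = FALSE)

  gm <- read_cohort(vcf, cat_cur)
  pipeline_log(quiet, "cohort", "%d samples, %d/%d catalog loci found (%d missing from VCF)",
               length(gm$sample_ids), nrow(gm$loci), nrow(cat_cur$entries),
               nrow(gm$missing_loci))

  freqs <- classify_variants(allele_frequencies(gm), rare_threshold)
  files$frequencies <- file.path(out_dir, "02_frequencies.tsv")
  write_frequency_tsv(freqs, files$frequencies)
  pipeline_log(quiet, "freq", "%d loci, %d singletons, %d rare",
               nrow(freqs), sum(freqs$is_singleton, na.rm = TRUE),
               sum(freqs$rarity == "rare", na.rm = TRUE))

  ref_tbl <- read_reference(reference)
  cmp <- compare_landscape(freqs, ref_tbl, population = ref_population,
                           primary_test = primary_test, adjust = adjust)
  files$comparison <- file.path(out_dir, "03_comparison.tsv")
  readr::write_tsv(cmp$results, files$comparison, progress = FALSE)
  n_sig <- sum(cmp$results$p_adjusted < 0.05, na.rm = TRUE)
  pipeline_log(quiet, "compare", "%d loci tested, %d significant after %s adjustment",
               nrow(cmp$results), n_sig, adjust)

  ld <- NULL
  n_loci <- nrow(gm$loci)
  if (!is.null(ld_pairs) || (n_loci >= 2 && n_loci <= 200)) {
    ld <- ld_matrix(gm, pairs = ld_pairs)
    files$ld <- file.path(out_dir, "04_ld.tsv")
    readr::write_tsv(ld, files$ld, progress = FALSE)
    pipeline_log(quiet, "ld", "%d pairs, max r2 = %s", nrow(ld),
                 format(suppressWarnings(max(ld$r2, na.rm = TRUE)), digits = 4))
  } else {
    pipeline_log(quiet, "ld", "skipped (%d loci and no explicit pairs)", n_loci)
  }

  caps <- dplyr::bind_rows(lapply(c("missense", "lof", "all_functional"),
                                  function(cl) burden_by_gene(freqs, cl)$scores))
  files$cap <- file.path(out_dir, "05_cap.tsv")
  readr::write_tsv(caps, files$cap, progress = FALSE)
  top_cap <- caps[caps$variant_class == "all_functional", , drop = FALSE]
  pipeline_log(quiet, "cap", "%d gene x class scores", nrow(caps))

  summary <- list(
    catalog = list(
      n_rows_loaded = nrow(cat_raw$entries),
      n_duplicates_removed = cur$n_duplicates_removed,
      n_hla_removed = nrow(cur$hla_removed),
      n_after_curation = nrow(cat_cur$entries)
    ),
    cohort = list(
      n_samples = length(gm$sample_ids),
      n_loci_found = nrow(gm$loci),
      n_loci_missing = nrow(gm$missing_loci)
    ),
    frequencies = list(
      n_singletons = sum(freqs$is_singleton, na.rm = TRUE),
      n_rare = sum(freqs$rarity == "rare", na.rm = TRUE)
    ),
    comparison = list(
      n_tested = nrow(cmp$results),
      n_unmatched = nrow(cmp$unmatched),
      n_significant_adjusted = n_sig,
      adjust = adjust, primary_test = primary_test
    ),
    ld = list(n_pairs = if (is.null(ld)) 0L else nrow(ld)),
    cap = list(
      top_genes = utils::head(top_cap$gene[order(-top_cap$cap)], 5)
    )
  )
  files$summary <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    catalog = cat_cur, genotype_matrix = gm, frequencies = freqs,
    comparison = cmp, ld = ld, cap = caps,
    summary = summary, files = files
  ))
}

#' Render a human-readable markdown report from pipeline stage outputs
#'
#' Produces a comparison table with significance bands, the LD table sorted
#' by r-squared, and the CAP ranking per variant class. Missing stage files
#' yield a warning block in place of the section rather than an error.
#'
#' @param out_dir Directory holding the stage TSVs written by
#'   [run_pipeline()].
#' @param path Optional file to write the markdown to.
#' @return The markdown report as a character vector of lines (invisibly if
#'   `path` is given).
#' @export
render_report <- function(out_dir, path = NULL) {
  md <- c("# Pharmacogenomic landscape report", "")
  fmt_num <- function(x, d = 4) ifelse(is.na(x), "NA", formatC(x, digits = d, format = "g"))
  tbl_md <- function(df) {
    hdr <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(hdr, sep, body)
  }

  cmp_file <- file.path(out_dir, "03_comparison.tsv")
  md <- c(md, "## Allele-frequency comparison", "")
  if (file.exists(cmp_file)) {
    cmp <- readr::read_tsv(cmp_file, show_col_types = FALSE, progress = FALSE)
    if (nrow(cmp) == 0) {
      md <- c(md, "no overlapping loci", "")
    } else {
      show <- utils::head(cmp, 25)
      df <- data.frame(
        gene = show$gene, locus = paste0(show$chrom, ":", show$pos),
        rsid = show$rsid,
        cohort_AF = fmt_num(show$cohort_AF), ref_AF = fmt_num(show$ref_AF),
        OR = fmt_num(show$odds_ratio), p_adj = fmt_num(show$p_adjusted, 3),
        band = show$band, check.names = FALSE
      )
      md <- c(md, tbl_md(df), "")
    }
  } else {
    md <- c(md, "> WARNING: comparison stage output missing", "")
  }

  ld_file <- file.path(out_dir, "04_ld.tsv")
  md <- c(md, "## Linkage disequilibrium (sorted by r2)", "")
  if (file.exists(ld_file)) {
    ld <- readr::read_tsv(ld_file, show_col_types = FALSE, progress = FALSE)
    show <- utils::head(ld[order(-ld$r2), ], 25)
    df <- data.frame(
      rsid1 = show$rsid1, rsid2 = show$rsid2,
      n = show$n_informative, D = fmt_num(show$D),
      D_prime = fmt_num(show$D_prime), r2 = fmt_num(show$r2),
      check.names = FALSE
    )
    md <- c(md, tbl_md(df), "")
  } else {
    md <- c(md, "> WARNING: LD stage output missing", "")
  }

  cap_file <- file.path(out_dir, "05_cap.tsv")
  md <- c(md, "## Cumulative allele probability (CAP) ranking", "")
  if (file.exists(cap_file)) {
    cap <- readr::read_tsv(cap_file, show_col_types = FALSE, progress = FALSE)
    for (cl in unique(cap$variant_class)) {
      sub <- cap[cap$variant_class == cl, ]
      sub <- utils::head(sub[order(-sub$cap), ], 10)
      md <- c(md, sprintf("### %s", cl), "",
              tbl_md(data.frame(gene = sub$gene, n_variants = sub$n_variants,
                                cap = fmt_num(sub$cap), vpp = fmt_num(sub$vpp),
                                check.names = FALSE)), "")
    }
  } else {
    md <- c(md, "> WARNING: CAP stage output missing", "")
  }

  if (!is.null(path)) {
    writeLines(md, path)
    return(invisible(md))
  }
  md
}
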