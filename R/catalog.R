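# Variant catalog: the curated drug-response variant list that drives every
# downstream stage (frequency extraction, population comparison, LD, burden).

CATALOG_COLUMNS <- c(
  "gene", "chrom", "pos", "ref", "alt", "rsid",
  "consequence_class", "drugs", "evidence_level", "is_hla_haplotype"
)

CONSEQUENCE_CLASSES <- c(
  "missense", "lof", "synonymous", "regulatory", "intronic",
  "utr", "upstream", "downstream", "other"
)

new_variant_catalog <- function(entries, provenance = character()) {
  structure(
    list(entries = entries, provenance = provenance),
    class = "variant_catalog"
  )
}

validate_catalog_entries <- function(entries) {
  if (any(entries$pos < 1L)) {
    stop_pharmscape("catalog positions must be 1-based (pos >= 1)",
                    "pharmscape_schema_error")
  }
  if (any(toupper(entries$ref) == toupper(entries$alt))) {
    stop_pharmscape("catalog rows with ref == alt are not valid variants",
                    "pharmscape_schema_error")
  }
  if (any(!nzchar(entries$chrom))) {
    stop_pharmscape("catalog chrom must be non-empty",
                    "pharmscape_schema_error")
  }
  bad_class <- setdiff(unique(entries$consequence_class), CONSEQUENCE_CLASSES)
  if (length(bad_class) > 0) {
    stop_pharmscape(
      sprintf("unknown consequence_class value(s): %s (allowed: %s)",
              paste(bad_class, collapse = ", "),
              paste(CONSEQUENCE_CLASSES, collapse = ", ")),
      "pharmscape_schema_error"
    )
  }
  invisible(entries)
}

#' Load a curated drug-response variant catalog from TSV
#'
#' The catalog is the curated list of pharmacogene variants with drug
#' associations and consequence classes that the whole pipeline is driven by.
#' The TSV must be tab-separated with a header row naming exactly the columns
#' `gene`, `chrom`, `pos`, `ref`, `alt`, `rsid`, `consequence_class`,
#' `drugs` (semicolon-separated drug names, e.g. `"etanercept;infliximab"` or
#' `"multiple"`), `evidence_level` and `is_hla_haplotype` (`true`/`false`).
#' Lines starting with `#` are ignored. Coordinates are 1-based, matching VCF.
#'
#' @param path Path to the catalog TSV file.
#' @return A `variant_catalog` object: a list with `entries` (a tibble, one
#'   row per catalog entry, row order preserved; `drugs` is a list-column of
#'   character vectors) and `provenance` (free-text notes).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("gene", "chrom", "pos", "ref", "alt", "rsid", "consequence_class",
#'         "drugs", "evidence_level", "is_hla_haplotype", sep = "\t"),
#'   paste("TNF", "6", "31575254", "G", "A", "rs1800629", "upstream",
#'         "etanercept", "2B", "false", sep = "\t")
#' ), tsv)
#' cat <- load_catalog(tsv)
#' nrow(cat$entries)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop_pharmscape(sprintf("catalog file not found: %s", path),
                    "pharmscape_io_error")
  }
  raw <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_pharmscape(
      sprintf("catalog TSV is missing mandatory column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "pharmscape_schema_error"
    )
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) & !is.na(raw$pos))
  if (length(bad) > 0) {
    stop_pharmscape(
      sprintf("unparseable pos value(s) in catalog row(s): %s (e.g. \"%s\")",
              paste(bad, collapse = ", "), raw$pos[bad[1]]),
      "pharmscape_row_error"
    )
  }
  hla <- tolower(trimws(raw$is_hla_haplotype)) %in% c("true", "t", "1", "yes")
  entries <- tibble(
    gene = raw$gene,
    chrom = raw$chrom,
    pos = pos,
    ref = toupper(raw$ref),
    alt = toupper(raw$alt),
    rsid = ifelse(is.na(raw$rsid), "", raw$rsid),
    consequence_class = tolower(raw$consequence_class),
    drugs = lapply(strsplit(raw$drugs, ";", fixed = TRUE),
                   function(d) sort(unique(tolower(trimws(d))))),
    evidence_level = ifelse(is.na(raw$evidence_level), "", raw$evidence_level),
    is_hla_haplotype = hla
  )
  validate_catalog_entries(entries)
  new_variant_catalog(entries, provenance = sprintf("loaded from %s", path))
}

# Duplicate key: coordinates plus the drug-association set, not rsid (rsids
# can be absent or merged; coordinates are the stable key).
catalog_dup_key <- function(entries) {
  paste(
    locus_key(entries$chrom, entries$pos, entries$ref, entries$alt),
    vapply(entries$drugs, function(d) paste(d, collapse = ";"), character(1)),
    sep = "|"
  )
}

#' Remove duplicate catalog entries
#'
#' Keeps the first occurrence of each (chrom, pos, ref, alt, drug-set) key.
#' The same locus listed under two different drug associations is *not* a
#' duplicate: both rows are retained as distinct associations.
#'
#' @param catalog A `variant_catalog`.
#' @return A `variant_catalog` with duplicates removed; the attribute
#'   `"n_duplicates_removed"` on the result records how many rows were dropped.
#' @export
dedupe_catalog <- function(catalog) {
  entries <- catalog$entries
  keep <- !duplicated(catalog_dup_key(entries))
  out <- new_variant_catalog(entries[keep, , drop = FALSE], catalog$provenance)
  attr(out, "n_duplicates_removed") <- sum(!keep)
  out
}

#' Drop HLA haplotype-defining rows from the catalog
#'
#' HLA haplotype variants (rows tagging a multi-locus haplotype rather than a
#' single sequence variant) cannot be treated as biallelic sites and are
#' removed before frequency analysis. Detection relies solely on the explicit
#' `is_hla_haplotype` column — never inferred from gene names, so legitimate
#' single variants inside the HLA region are untouched.
#'
#' @param catalog A `variant_catalog`.
#' @return A list with `catalog` (retained entries) and `removed` (a tibble of
#'   `gene`, `rsid` for each removed row).
#' @export
filter_hla_haplotypes <- function(catalog) {
  entries <- catalog$entries
  is_hla <- entries$is_hla_haplotype
  removed <- entries[is_hla, c("gene", "rsid")]
  kept <- new_variant_catalog(entries[!is_hla, , drop = FALSE],
                              catalog$provenance)
  list(catalog = kept, removed = removed)
}

#' Subset the catalog to one drug's associated variants
#'
#' @param catalog A `variant_catalog`.
#' @param drug Drug name (case-insensitive), e.g. `"etanercept"`.
#' @param multiple_matches_all If `TRUE` (default), entries tagged
#'   `"multiple"` (multi-TNFi associations) match every specific drug query.
#' @return A `variant_catalog` restricted to entries associated with `drug`.
#' @export
subset_by_drug <- function(catalog, drug, multiple_matches_all = TRUE) {
  entries <- catalog$entries
  drug <- tolower(drug)
  vocab <- sort(unique(unlist(entries$drugs)))
  if (nrow(entries) > 0 && !(drug %in% vocab)) {
    stop_pharmscape(
      sprintf("unknown drug \"%s\"; catalog drug vocabulary: %s",
              drug, paste(vocab, collapse = ", ")),
      "pharmscape_domain_error"
    )
  }
  hit <- vapply(entries$drugs, function(d) {
    drug %in% d || (multiple_matches_all && "multiple" %in% d)
  }, logical(1))
  new_variant_catalog(entries[hit, , drop = FALSE], catalog$provenance)
}

#' Run the full catalog curation: dedupe then drop HLA haplotypes
#'
#' @param catalog A `variant_catalog` as loaded.
#' @return A list with `catalog` (curated), `n_duplicates_removed`, and
#'   `hla_removed` (tibble of removed HLA haplotype rows).
#' @export
curate_catalog <- function(catalog) {
  dd <- dedupe_catalog(catalog)
  hla <- filter_hla_haplotypes(dd)
  list(
    catalog = hla$catalog,
    n_duplicates_removed = attr(dd, "n_duplicates_removed"),
    hla_removed = hla$removed
  )
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat(sprintf("<variant_catalog> %d entries, %d genes\n",
              nrow(x$entries), length(unique(x$entries$gene))))
  if (length(x$provenance)) cat("provenance:", x$provenance, "\n")
  print(x$entries, ...)
  invisible(x)
}
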