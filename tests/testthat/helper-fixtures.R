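# Programmatic fixtures: catalog tables, VCF snippets, genotype matrices.

catalog_row <- function(gene = "TNF", chrom = "6", pos = 31575254L,
                        ref = "G", alt = "A", rsid = "rs1800629",
                        consequence_class = "upstream", drugs = "etanercept",
                        evidence_level = "2B", is_hla_haplotype = FALSE) {
  tibble::tibble(gene = gene, chrom = chrom, pos = pos, ref = ref, alt = alt,
                 rsid = rsid, consequence_class = consequence_class,
                 drugs = drugs, evidence_level = evidence_level,
                 is_hla_haplotype = is_hla_haplotype)
}

write_catalog_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# A curation-scale catalog mirroring the published pipeline's bookkeeping:
# 161 distinct entries (across 111 genes is not required for the filter
# test), of which 10 rows in 7 distinct HLA genes are haplotype-tagged;
# optionally inflated with duplicated rows to a given total.
make_curation_fixture <- function(n_total = 161, n_hla = 10, n_hla_genes = 7,
                                  n_rows_with_dups = NULL) {
  n_plain <- n_total - n_hla
  plain <- catalog_row(
    gene = sprintf("GENE%03d", seq_len(n_plain)),
    chrom = as.character(1 + (seq_len(n_plain) %% 22)),
    pos = 1000L + 17L * seq_len(n_plain),
    ref = "A", alt = "G",
    rsid = sprintf("rs%d", 10000 + seq_len(n_plain)),
    consequence_class = rep(c("missense", "lof", "intronic", "upstream"),
                            length.out = n_plain),
    drugs = rep(c("etanercept", "adalimumab", "infliximab", "multiple"),
                length.out = n_plain)
  )
  hla_genes <- sprintf("HLA-%s", LETTERS[seq_len(n_hla_genes)])
  hla <- catalog_row(
    gene = rep(hla_genes, length.out = n_hla),
    chrom = "6",
    pos = 29900000L + 31L * seq_len(n_hla),
    ref = "C", alt = "T",
    rsid = sprintf("rs%d", 90000 + seq_len(n_hla)),
    consequence_class = "other",
    drugs = "multiple",
    is_hla_haplotype = TRUE
  )
  out <- dplyr::bind_rows(plain, hla)
  if (!is.null(n_rows_with_dups)) {
    extra <- n_rows_with_dups - nrow(out)
    dup_idx <- rep(seq_len(nrow(out)), length.out = extra)
    out <- dplyr::bind_rows(out, out[dup_idx, ])
  }
  out
}

# Build a genotype_matrix directly (no VCF round trip) for property tests.
make_gm <- function(geno, loci = NULL, sample_ids = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  loci <- loci %||% tibble::tibble(
    gene = sprintf("G%d", seq_len(m)), chrom = "1",
    pos = 100L + seq_len(m), ref = "A", alt = "G",
    rsid = sprintf("rs%d", seq_len(m)),
    consequence_class = "missense"
  )
  pharmscape:::new_genotype_matrix(
    sample_ids = sample_ids %||% sprintf("S%d", seq_len(n)),
    loci = loci, geno = geno,
    missing_loci = loci[0, ]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_vcf_lines <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

# A small default locus panel for simulator-driven tests.
panel_loci <- function(afs, chrom = "6",
                       classes = rep("missense", length(afs)),
                       genes = sprintf("G%d", seq_along(afs))) {
  tibble::tibble(
    gene = genes, chrom = chrom, pos = 10000L + 50L * seq_along(afs),
    ref = "A", alt = "G", rsid = sprintf("rs%d", seq_along(afs)),
    consequence_class = classes, drugs = "multiple",
    evidence_level = "2B", is_hla_haplotype = FALSE, af = afs
  )
}
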