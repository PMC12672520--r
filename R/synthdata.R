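# Seeded synthetic diploid cohorts with the statistical structure the
# pipeline assumes: Hardy-Weinberg genotypes at specified allele frequencies,
# configurable two-locus LD blocks, injected singletons and missingness, plus
# a shifted reference-frequency table for power / type-I experiments. The
# generator stands in for the access-controlled whole-genome cohort; its
# truth table retains the drawn haplotypes so estimators can be tested
# against known latent state.

#' Haplotype frequencies realizing target allele frequencies and correlation
#'
#' Inverse construction for the LD simulator: given alt-allele frequencies
#' `p`, `q` at two loci and a signed allele correlation `r`
#' (`r^2` is the usual LD measure), returns the unique haplotype frequencies
#' with `D = r * sqrt(p(1-p)q(1-q))`: `(pq + D, p(1-q) - D, (1-p)q - D,
#' (1-p)(1-q) + D)`. Combinations whose implied haplotype frequency would be
#' negative are infeasible and raise an error reporting the feasible range
#' of `r`.
#'
#' @param p,q Allele frequencies in (0, 1).
#' @param r Signed correlation, `|r| <= 1`.
#' @return A `haplotype_freqs` object.
#' @export
haplotype_freqs_from_targets <- function(p, q, r) {
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    stop_pharmscape("p and q must lie strictly inside (0, 1)",
                    "pharmscape_domain_error")
  }
  if (abs(r) > 1) {
    stop_pharmscape("|r| must be <= 1", "pharmscape_domain_error")
  }
  sd_prod <- sqrt(p * (1 - p) * q * (1 - q))
  D <- r * sd_prod
  h <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D, (1 - p) * (1 - q) + D)
  if (any(h < -1e-12)) {
    r_min <- max(-p * q, -(1 - p) * (1 - q)) / sd_prod
    r_max <- min(p * (1 - q), (1 - p) * q) / sd_prod
    stop_pharmscape(
      sprintf("infeasible (p=%g, q=%g, r=%g): feasible r range is [%.4f, %.4f]",
              p, q, r, r_min, r_max),
      "pharmscape_domain_error"
    )
  }
  h <- pmax(h, 0)
  haplotype_freqs(h[1], h[2], h[3], h[4])
}

#' Build a simulation configuration
#'
#' @param n_samples Cohort size (>= 1). The emulated study's scale is 14,387
#'   individuals; tests use smaller cohorts for speed.
#' @param loci Tibble of loci to simulate with columns `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `rsid`, `consequence_class`, `drugs` (semicolon
#'   string), `evidence_level`, and `af` (true alt-allele frequency).
#' @param ld_blocks Optional tibble with columns `locus1`, `locus2` (indices
#'   into `loci`) and `r` (signed target correlation); `p`/`q` are the two
#'   loci's `af` values. Loci may appear in at most one block.
#' @param n_singletons Number of extra singleton loci to inject (one
#'   heterozygous carrier each, chosen uniformly at random).
#' @param missing_rate Per-genotype independent missingness probability in
#'   `[0, 1)`.
#' @param seed RNG seed (integer).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples, loci, ld_blocks = NULL, n_singletons = 0L,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_samples >= 1)
  assert_prob(loci$af, "true allele frequencies")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_pharmscape("missing_rate must lie in [0, 1)", "pharmscape_domain_error")
  }
  if (!is.null(ld_blocks)) {
    idx <- c(ld_blocks$locus1, ld_blocks$locus2)
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > nrow(loci))) {
      stop_pharmscape("ld_blocks loci must be distinct valid indices into loci",
                      "pharmscape_domain_error")
    }
    if (any(abs(ld_blocks$r) > 1)) {
      stop_pharmscape("|r| must be <= 1 in ld_blocks", "pharmscape_domain_error")
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), loci = loci,
         ld_blocks = ld_blocks, n_singletons = as.integer(n_singletons),
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a diploid cohort VCF and its truth table
#'
#' Unlinked loci draw genotypes as binomial(2, AF) — Hardy-Weinberg
#' proportions. Loci inside an LD block draw two haplotypes per sample from
#' the block's haplotype-frequency distribution (from
#' [haplotype_freqs_from_targets()]) and derive both genotypes, so the target
#' r is realized in the latent haplotypes. Singleton loci get exactly one
#' heterozygous carrier before missingness. Missingness is applied last,
#' genotype-wise independent. Identical configurations (including the seed)
#' produce byte-identical VCFs: the file carries a fixed header date.
#'
#' @param config A `sim_config`.
#' @param vcf_path Output VCF path (plain text).
#' @return Invisibly, the truth table: list with `loci` (incl. singleton loci
#'   and `true_af`), `genotypes` (pre-missingness integer matrix), `blocks`
#'   (per-block true haplotype frequencies and `r2_true`), `haplotypes`
#'   (per-block list of two n-vectors of drawn haplotype codes 1..4 =
#'   AB/Ab/aB/ab), `singleton_carriers`, and the emitted `vcf_path`.
#' @export
simulate_cohort <- function(config, vcf_path) {
  set.seed(config$seed)
  n <- config$n_samples
  loci <- config$loci
  nl <- nrow(loci)
  geno <- matrix(0L, nrow = n, ncol = nl)

  in_block <- rep(FALSE, nl)
  blocks <- list()
  haplos <- list()
  if (!is.null(config$ld_blocks)) {
    for (b in seq_len(nrow(config$ld_blocks))) {
      i <- config$ld_blocks$locus1[b]
      j <- config$ld_blocks$locus2[b]
      r <- config$ld_blocks$r[b]
      hf <- haplotype_freqs_from_targets(loci$af[i], loci$af[j], r)
      probs <- c(hf$p_AB, hf$p_Ab, hf$p_aB, hf$p_ab)
      h1 <- sample.int(4L, n, replace = TRUE, prob = probs)
      h2 <- sample.int(4L, n, replace = TRUE, prob = probs)
      alt1 <- c(1L, 1L, 0L, 0L)
      alt2 <- c(1L, 0L, 1L, 0L)
      geno[, i] <- alt1[h1] + alt1[h2]
      geno[, j] <- alt2[h1] + alt2[h2]
      in_block[c(i, j)] <- TRUE
      blocks[[b]] <- tibble(
        locus1 = i, locus2 = j, r_target = r,
        p_AB = hf$p_AB, p_Ab = hf$p_Ab, p_aB = hf$p_aB, p_ab = hf$p_ab,
        r2_true = r^2
      )
      haplos[[b]] <- list(h1 = h1, h2 = h2)
    }
  }
  for (k in which(!in_block)) {
    geno[, k] <- rbinom(n, 2L, loci$af[k])
  }

  # singleton injection: synthetic loci on a dedicated contig, one het carrier
  singleton_carriers <- integer(0)
  if (config$n_singletons > 0) {
    s <- config$n_singletons
    base_pos <- 1000000L
    sing <- tibble(
      gene = sprintf("SINGLETON%02d", seq_len(s)),
      chrom = "22",
      pos = base_pos + seq_len(s),
      ref = "A", alt = "T",
      rsid = "",
      consequence_class = "missense",
      drugs = "multiple",
      evidence_level = "",
      is_hla_haplotype = FALSE,
      af = 1 / (2 * n)
    )
    keep <- intersect(names(loci), names(sing))
    loci <- dplyr::bind_rows(loci[, keep, drop = FALSE], sing[, keep, drop = FALSE])
    sg <- matrix(0L, nrow = n, ncol = s)
    singleton_carriers <- sample.int(n, s, replace = TRUE)
    for (k in seq_len(s)) sg[singleton_carriers[k], k] <- 1L
    geno <- cbind(geno, sg)
  }

  geno_full <- geno
  if (config$missing_rate > 0) {
    drop <- matrix(runif(length(geno)) < config$missing_rate,
                   nrow = nrow(geno))
    geno[drop] <- NA_integer_
  }

  sample_ids <- sprintf("S%05d", seq_len(n))
  if (!("rsid" %in% names(loci))) loci$rsid <- ""
  gm <- list(sample_ids = sample_ids, loci = loci, geno = geno)
  write_genotype_vcf(gm, vcf_path, fixed_date = TRUE)

  truth <- list(
    loci = dplyr::mutate(loci, true_af = .data$af),
    genotypes = geno_full,
    observed = geno,
    sample_ids = sample_ids,
    blocks = if (length(blocks)) dplyr::bind_rows(blocks) else NULL,
    haplotypes = haplos,
    singleton_carriers = singleton_carriers,
    vcf_path = vcf_path
  )
  invisible(truth)
}

#' Emit a reference-frequency table shifted from the simulated truth
#'
#' Builds the comparison-population table: per locus, `AF = true AF + shift`
#' at the given reference allele number. Loci with shift 0 are true nulls for
#' type-I-error experiments; shifted loci are true signals for power
#' experiments.
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param shifts Numeric vector of per-locus AF deltas, length 1 or
#'   `nrow(truth$loci)`.
#' @param ref_an Reference allele number (> 0).
#' @param population Population label (default `"overall"`).
#' @param path Optional TSV output path.
#' @return The reference tibble (written to `path` if given).
#' @export
simulate_reference <- function(truth, shifts = 0, ref_an = 10000L,
                               population = "overall", path = NULL) {
  loci <- truth$loci
  shifts <- rep(shifts, length.out = nrow(loci))
  af <- loci$true_af + shifts
  if (any(af < 0 | af > 1)) {
    stop_pharmscape("shift pushes a reference AF outside [0, 1]",
                    "pharmscape_domain_error")
  }
  ref <- tibble(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    population = population, AF = af, AN = as.integer(ref_an)
  )
  if (!is.null(path)) readr::write_tsv(ref, path, progress = FALSE)
  ref
}

#' Write a catalog TSV for simulated loci
#'
#' Serializes the simulator's locus table in the catalog schema so the
#' synthetic bundle can be fed through [load_catalog()] like real inputs.
#'
#' @param loci Locus tibble (as in [sim_config()]; `drugs` is the
#'   semicolon-joined string form).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(loci, path) {
  out <- tibble(
    gene = loci$gene, chrom = loci$chrom, pos = loci$pos,
    ref = loci$ref, alt = loci$alt,
    rsid = loci$rsid %||% "",
    consequence_class = loci$consequence_class %||% "other",
    drugs = if (is.list(loci$drugs)) {
      vapply(loci$drugs, paste, character(1), collapse = ";")
    } else loci$drugs %||% "multiple",
    evidence_level = loci$evidence_level %||% "",
    is_hla_haplotype = tolower(as.character(loci$is_hla_haplotype %||% FALSE))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
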