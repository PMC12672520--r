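# Pairwise linkage disequilibrium from unphased diploid genotypes.
# Two-locus haplotype frequencies are estimated by EM (only the double
# heterozygote has ambiguous phase) and D, D', r^2 derived from them.
# This is an owned re-implementation of the usual batch-LD tool step so the
# estimator is fully specified.

# Genotype-pair class probabilities implied by haplotype frequencies
# h = (AB, Ab, aB, ab) under random mating. Returns a 3x3 matrix indexed by
# (alt dosage locus1 + 1, alt dosage locus2 + 1), where allele "A"/"B" is the
# alt allele at each locus.
genotype_pair_probs <- function(h) {
  a1 <- c(1L, 1L, 0L, 0L)  # alt-allele at locus 1 carried by each haplotype
  a2 <- c(1L, 0L, 1L, 0L)
  pr <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      g1 <- a1[i] + a1[j]
      g2 <- a2[i] + a2[j]
      pr[g1 + 1L, g2 + 1L] <- pr[g1 + 1L, g2 + 1L] + h[i] * h[j]
    }
  }
  pr
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; A/B denote the
#' alt alleles) from unphased genotype dosage pairs. Phase is ambiguous only
#' for double heterozygotes; the E-step splits them between AB/ab and Ab/aB in
#' proportion to the current products of haplotype frequencies, the M-step
#' re-estimates. Initialization is at linkage equilibrium (p*q), which is
#' deterministic; homozygote classes break the symmetric double-het likelihood
#' ridge when present. The log-likelihood is non-decreasing by construction
#' and is recorded per iteration.
#'
#' @param g1,g2 Integer vectors of alt-allele dosages (0/1/2, `NA` missing) at
#'   the two loci; pairwise-complete samples are used.
#' @param tol Convergence threshold on the max absolute frequency change
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1000). Non-convergence is reported
#'   via `converged = FALSE`, never an error.
#' @return An object of class `haplotype_freqs`: list with `p_AB`, `p_Ab`,
#'   `p_aB`, `p_ab`, allele frequencies `p` (alt at locus 1) and `q` (alt at
#'   locus 2), `n_informative`, `em_iterations`, `converged`, `loglik`
#'   (per-iteration trace), and `defined` (`FALSE` for monomorphic loci,
#'   where LD is undefined).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[ok]); g2 <- as.integer(g2[ok])
  n <- length(g1)
  if (n < 2) {
    stop_pharmscape("need at least 2 samples called at both loci",
                    "pharmscape_domain_error")
  }
  # 3x3 table of genotype-pair counts
  cnt <- matrix(0, 3, 3)
  for (k in seq_len(n)) cnt[g1[k] + 1L, g2[k] + 1L] <- cnt[g1[k] + 1L, g2[k] + 1L] + 1
  p <- sum(g1) / (2 * n)
  q <- sum(g2) / (2 * n)
  res <- list(p = p, q = q, n_informative = n)
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    return(structure(
      c(list(p_AB = NA_real_, p_Ab = NA_real_, p_aB = NA_real_,
             p_ab = NA_real_), res,
        list(em_iterations = 0L, converged = TRUE, loglik = numeric(0),
             defined = FALSE)),
      class = "haplotype_freqs"
    ))
  }
  # Phase-known haplotype contributions: for any dosage pair other than the
  # (1,1) double het, at most one locus is heterozygous, so the two
  # haplotypes of the individual are determined.
  known <- matrix(0, nrow = 9, ncol = 4,
                  dimnames = list(NULL, c("AB", "Ab", "aB", "ab")))
  rowidx <- 0
  for (d1 in 0:2) for (d2 in 0:2) {
    rowidx <- rowidx + 1
    if (d1 == 1 && d2 == 1) next
    # haplotype alleles: alt copies at locus1 split as (1,1)/(1,0)/(0,0)
    h1a <- if (d1 == 2) c(1, 1) else if (d1 == 1) c(1, 0) else c(0, 0)
    h2a <- if (d2 == 2) c(1, 1) else if (d2 == 1) c(1, 0) else c(0, 0)
    # when one locus is het, the het allele pairs with both haplotypes of the
    # hom locus interchangeably -> assignment (sorted) is unique up to order
    for (m in 1:2) {
      hap <- paste0(if (h1a[m] == 1) "A" else "a", if (h2a[m] == 1) "B" else "b")
      hap <- chartr("ab", "ab", hap)
      col <- match(hap, c("AB", "Ab", "aB", "ab"))
      known[rowidx, col] <- known[rowidx, col] + 1
    }
  }
  counts_flat <- as.vector(t(matrix(cnt, 3, 3)))  # row-major (d1 outer)
  # fixed haplotype counts from phase-known classes
  fixed <- colSums(known * counts_flat)
  n_dh <- cnt[2, 2]  # double heterozygotes

  h <- c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))
  loglik <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    pr <- genotype_pair_probs(h)
    ll <- sum(counts_flat * log(ifelse(t(pr) > 0, t(pr), 1)))
    loglik <- c(loglik, ll)
    # E-step: split double hets between AB/ab and Ab/aB
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    exp_counts <- fixed +
      n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- exp_counts / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  h <- unname(h)
  structure(
    c(list(p_AB = h[1], p_Ab = h[2], p_aB = h[3], p_ab = h[4]),
      list(p = h[1] + h[2], q = h[1] + h[3], n_informative = n,
           em_iterations = iter, converged = converged, loglik = loglik,
           defined = TRUE)),
    class = "haplotype_freqs"
  )
}

#' Construct a haplotype-frequency object directly
#'
#' @param p_AB,p_Ab,p_aB,p_ab Haplotype frequencies (must be non-negative and
#'   sum to 1 within 1e-9).
#' @return A `haplotype_freqs` object.
#' @export
haplotype_freqs <- function(p_AB, p_Ab, p_aB, p_ab) {
  h <- c(p_AB, p_Ab, p_aB, p_ab)
  if (any(h < -1e-12) || abs(sum(h) - 1) > 1e-9) {
    stop_pharmscape("haplotype frequencies must be >= 0 and sum to 1",
                    "pharmscape_domain_error")
  }
  structure(
    list(p_AB = p_AB, p_Ab = p_Ab, p_aB = p_aB, p_ab = p_ab,
         p = p_AB + p_Ab, q = p_AB + p_aB,
         n_informative = NA_integer_, em_iterations = NA_integer_,
         converged = NA, loglik = numeric(0), defined = TRUE),
    class = "haplotype_freqs"
  )
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' `D = p_AB - p*q`; `D' = D / Dmax` with `Dmax = min(p(1-q), (1-p)q)` for
#' `D > 0` and `min(pq, (1-p)(1-q))` for `D < 0`; `r^2 = D^2 /
#' (p(1-p)q(1-q))`. Monomorphic loci (p or q in {0, 1}) yield a flagged
#' undefined result rather than an error.
#'
#' @param hap A `haplotype_freqs` object.
#' @return List with `D`, `D_prime`, `r2`, `defined`, plus pass-through
#'   fields `p`, `q`, `n_informative`, `em_iterations`, `converged`.
#' @export
ld_stats <- function(hap) {
  p <- hap$p; q <- hap$q
  base <- list(p = p, q = q, n_informative = hap$n_informative,
               em_iterations = hap$em_iterations, converged = hap$converged)
  if (!isTRUE(hap$defined) || p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    return(c(list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                  defined = FALSE), base))
  }
  D <- hap$p_AB - p * q
  if (D > 0) {
    dmax <- min(p * (1 - q), (1 - p) * q)
  } else if (D < 0) {
    dmax <- min(p * q, (1 - p) * (1 - q))
  } else {
    dmax <- NA_real_
  }
  d_prime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (p * (1 - p) * q * (1 - q))
  c(list(D = D, D_prime = d_prime, r2 = min(r2, 1), defined = TRUE), base)
}

#' Pairwise LD across a genotype matrix
#'
#' Runs [em_haplotype_freqs()] + [ld_stats()] for every requested locus pair
#' using pairwise-complete samples. A pair whose loci cannot be analysed
#' (missing locus, too few informative samples) produces an error row, and
#' the run continues.
#'
#' @param gm A `genotype_matrix`.
#' @param pairs Either `NULL` (all pairs) or a two-column matrix/data frame of
#'   locus indices or rsids.
#' @param tol,max_iter Passed to [em_haplotype_freqs()].
#' @return Tibble sorted by `r2` descending: `locus1`, `locus2`, `rsid1`,
#'   `rsid2`, `n_informative`, `D`, `D_prime`, `r2`, `converged`, `defined`,
#'   `error`.
#' @export
ld_matrix <- function(gm, pairs = NULL, tol = 1e-8, max_iter = 1000L) {
  nl <- nrow(gm$loci)
  keys <- locus_key(gm$loci$chrom, gm$loci$pos, gm$loci$ref, gm$loci$alt)
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(x, gm$loci$rsid)
    ifelse(is.na(i), match(x, keys), i)
  }
  if (is.null(pairs)) {
    if (nl < 2) {
      stop_pharmscape("need at least 2 loci for all-pairs LD",
                      "pharmscape_domain_error")
    }
    cmb <- utils::combn(nl, 2)
    i1 <- cmb[1, ]; i2 <- cmb[2, ]
  } else {
    pairs <- as.data.frame(pairs)
    i1 <- resolve(pairs[[1]])
    i2 <- resolve(pairs[[2]])
  }
  rows <- purrr::map(seq_along(i1), function(k) {
    a <- i1[k]; b <- i2[k]
    if (is.na(a) || is.na(b) || a < 1 || b < 1 || a > nl || b > nl) {
      return(tibble(locus1 = NA_character_, locus2 = NA_character_,
                    rsid1 = NA_character_, rsid2 = NA_character_,
                    n_informative = NA_integer_, D = NA_real_,
                    D_prime = NA_real_, r2 = NA_real_, converged = NA,
                    defined = FALSE, error = "locus not found in matrix"))
    }
    stats <- tryCatch({
      hap <- em_haplotype_freqs(gm$geno[, a], gm$geno[, b],
                                tol = tol, max_iter = max_iter)
      c(ld_stats(hap), list(error = NA_character_))
    }, pharmscape_error = function(e) {
      list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_, defined = FALSE,
           n_informative = NA_integer_, em_iterations = NA_integer_,
           converged = NA, error = conditionMessage(e))
    })
    tibble(
      locus1 = keys[a], locus2 = keys[b],
      rsid1 = gm$loci$rsid[a], rsid2 = gm$loci$rsid[b],
      n_informative = stats$n_informative %||% NA_integer_,
      D = stats$D, D_prime = stats$D_prime, r2 = stats$r2,
      converged = stats$converged %||% NA,
      defined = isTRUE(stats$defined),
      error = stats$error
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-ifelse(is.na(out$r2), -Inf, out$r2)), , drop = FALSE]
}
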