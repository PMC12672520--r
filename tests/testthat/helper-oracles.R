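# Independent oracles used to check package statistics. These deliberately
# avoid the code paths (and stats:: calls) they verify.

# Two-sided Fisher p by full hypergeometric enumeration over all tables with
# the observed margins, summing point probabilities <= observed (rel tol 1e-7).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  ks <- max(0, k - n2):min(m, k)
  probs <- choose(m, ks) * choose(n2, k - ks) / choose(m + n2, k)
  obs <- choose(m, a) * choose(n2, c) / choose(m + n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by hand: sort, p * m / i, enforce monotonicity
# from the largest rank down, cap at 1, return in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  ranked <- pmin(ranked, 1)
  out <- numeric(m)
  out[o] <- ranked
  out
}

# Genotype-pair class probabilities under random mating for haplotype
# frequencies h = (AB, Ab, aB, ab); independent re-derivation.
oracle_pair_probs <- function(h) {
  a1 <- c(1, 1, 0, 0); a2 <- c(1, 0, 1, 0)
  pr <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    pr[a1[i] + a1[j] + 1, a2[i] + a2[j] + 1] <-
      pr[a1[i] + a1[j] + 1, a2[i] + a2[j] + 1] + h[i] * h[j]
  }
  pr
}

# Brute-force haplotype-frequency MLE for tiny samples: coarse grid over the
# 3-simplex, then a local refinement around the best point. Returns r^2 at
# the maximizing haplotype frequencies.
oracle_ld_grid_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  loglik <- function(h) {
    pr <- oracle_pair_probs(h)
    sum(log(pmax(pr[cbind(g1 + 1, g2 + 1)], 1e-300)))
  }
  best <- NULL; best_ll <- -Inf
  scan <- function(centre, width, step) {
    sq <- seq(-width, width, by = step)
    for (d1 in sq) for (d2 in sq) for (d3 in sq) {
      h123 <- centre[1:3] + c(d1, d2, d3)
      h4 <- 1 - sum(h123)
      h <- c(h123, h4)
      if (any(h < -1e-12)) next
      h <- pmax(h, 0); h <- h / sum(h)
      ll <- loglik(h)
      if (ll > best_ll) { best_ll <<- ll; best <<- h }
    }
  }
  scan(centre = rep(0.25, 4), width = 0.25, step = 0.02)
  scan(centre = best, width = 0.02, step = 0.002)
  scan(centre = best, width = 0.002, step = 0.0002)
  scan(centre = best, width = 0.0002, step = 0.00002)
  h <- best
  p <- h[1] + h[2]; q <- h[1] + h[3]
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) return(NA_real_)
  D <- h[1] - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}

# Direct haplotype-frequency counting from simulator truth (phase known).
count_true_haplotypes <- function(truth, block = 1) {
  hp <- truth$haplotypes[[block]]
  tab <- tabulate(c(hp$h1, hp$h2), nbins = 4)
  tab / sum(tab)
}
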