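# Shared internal helpers: locus keys and chromosome-name normalization.

# Chromosome dialects ("chr6" vs "6") are reconciled by stripping any leading
# "chr" for matching only; user-facing output keeps the input spelling.
norm_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

# Canonical locus key used to join catalog, cohort and reference tables.
locus_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, toupper(ref), toupper(alt), sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pharmscape <- function(msg, class) {
  abort(msg, class = c(class, "pharmscape_error"))
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_pharmscape(
      sprintf("%s must lie in [0, 1]; got values outside that range.", what),
      "pharmscape_domain_error"
    )
  }
  invisible(x)
}
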