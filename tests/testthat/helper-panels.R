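# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately naive (per-locus loops, literal formula
# transcriptions) and never reuse package internals.

# Small panel from an explicit dosage matrix (samples x loci).
make_panel <- function(dosage, chrom = NULL, pos = NULL, pop = NULL) {
  L <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  loci <- data.frame(id = paste0("L", seq_len(L)), chrom = chrom,
                     pos = pos, ref = "A", alt = "T")
  samples <- paste0("S", seq_len(nrow(dosage)))
  if (!is.null(pop)) names(pop) <- samples
  genotype_panel(dosage, loci, population = pop, samples = samples)
}

# Literal per-locus transcription of the Weir-Cockerham (1984) two-level
# variance components for one biallelic locus: inputs are per-group
# called sample sizes, alt-allele frequencies and heterozygote fractions.
wc_components_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
    ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Group summaries for the oracle straight from a dosage matrix.
wc_oracle_from_dosage <- function(dosage, groups, locus) {
  g <- sort(unique(groups))
  n <- p <- h <- numeric(length(g))
  for (k in seq_along(g)) {
    x <- dosage[groups == g[k], locus]
    x <- x[!is.na(x)]
    n[k] <- length(x)
    p[k] <- sum(x) / (2 * length(x))
    h[k] <- mean(x == 1L)
  }
  wc_components_oracle(n, p, h)
}

# Default two-population simulation reused by several test files
# (small enough to keep the suite fast).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_panel(sim_config(
        n1 = 60, n2 = 70, n_loci = 600, n_selected = 10,
        missing_rate = 0.02, seed = 42))
    cache
  }
})
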