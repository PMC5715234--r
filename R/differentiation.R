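#' Weir-Cockerham FST variance components per locus
#'
#' For each locus, the two-level (population / individual) moment
#' estimator of Weir & Cockerham (1984) computed from per-population
#' alt-allele frequencies, observed heterozygote fractions, and called
#' sample sizes: among-population component `a`, among-individual
#' within-population component `b`, within-individual component `c`, and
#' `theta = a / (a + b + c)`. Per-locus theta can be negative (the
#' estimator is unbiased, not constrained); loci monomorphic across all
#' groups have undefined theta and are excluded from multilocus sums.
#'
#' @param panel a `genotype_panel`.
#' @param groups named vector sample id -> group label; defaults to the
#'   panel's population labels. Must define >= 2 groups.
#' @param loci optional locus ids / indices to restrict to.
#' @return Data frame, one row per locus: `id`, `chrom`, `pos`, `a`, `b`,
#'   `c`, `theta`, plus per-group `freq_<g>` and `n_<g>` columns.
#' @export
wc_fst <- function(panel, groups = NULL, loci = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(groups)) groups <- panel$population
  groups <- groups[panel$samples]
  glev <- sort(unique(groups[groups != "unassigned"]))
  if (length(glev) < 2L) stop("need >= 2 groups")
  if (!is.null(loci)) panel <- subset_panel(panel, loci = loci)
  r <- length(glev)
  L <- nrow(panel$loci)
  n_mat <- p_mat <- h_mat <- matrix(NA_real_, nrow = L, ncol = r,
                                    dimnames = list(NULL, glev))
  for (g in glev) {
    d <- panel$dosage[groups == g, , drop = FALSE]
    n <- colSums(!is.na(d))
    n_mat[, g] <- n
    p_mat[, g] <- colSums(d, na.rm = TRUE) / (2 * n)
    h_mat[, g] <- colSums(d == 1L, na.rm = TRUE) / n
  }
  ok <- rowSums(n_mat >= 2) == r & rowSums(is.na(p_mat)) == 0
  nbar <- rowMeans(n_mat)
  nc <- (r * nbar - rowSums(n_mat^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_mat * p_mat) / (r * nbar)
  s2 <- rowSums(n_mat * (p_mat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_mat * h_mat) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  mono <- pbar == 0 | pbar == 1
  theta[mono | !ok] <- NA_real_
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  out <- data.frame(id = panel$loci$id, chrom = panel$loci$chrom,
                    pos = panel$loci$pos, a = a, b = b, c = cc,
                    theta = theta, row.names = NULL)
  for (g in glev) {
    out[[paste0("freq_", g)]] <- p_mat[, g]
    out[[paste0("n_", g)]] <- n_mat[, g]
  }
  out
}

#' Multilocus Weir-Cockerham theta (ratio of sums)
#'
#' `sum(a) / sum(a + b + c)` over loci with defined theta — the standard
#' multilocus aggregate, which differs from the mean of per-locus ratios.
#'
#' @param fst data frame from [wc_fst()] (needs columns `a`, `b`, `c`,
#'   `theta`).
#' @return Single numeric theta.
#' @export
multilocus_fst <- function(fst) {
  use <- !is.na(fst$theta)
  if (!any(use)) stop("no locus with defined theta")
  sum(fst$a[use]) / sum(fst$a[use] + fst$b[use] + fst$c[use])
}

#' Two-level distance-based AMOVA
#'
#' Analysis of molecular variance on squared Euclidean distances between
#' dosage vectors (per-locus normalised over pairwise-complete loci).
#' Partitions variance among and within populations, reports Phi_ST =
#' sigma2_among / (sigma2_among + sigma2_within), and a permutation
#' P-value: the fraction of group-label permutations with Phi_ST at least
#' the observed value, with add-one correction.
#'
#' @param panel a `genotype_panel`.
#' @param groups named vector sample id -> group; defaults to panel
#'   populations ("unassigned" samples are dropped).
#' @param n_permutations default 1000; 0 skips the test.
#' @param seed optional integer seed for the permutations.
#' @return A list of class `amova_result`: `components` (data frame with
#'   sigma2 and percent for among/within), `phi_st`, `p_value`,
#'   `n_permutations`, `ss` (sums of squares), `df`.
#' @export
amova <- function(panel, groups = NULL, n_permutations = 1000, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(groups)) groups <- panel$population
  groups <- groups[panel$samples]
  keep <- groups != "unassigned" & !is.na(groups)
  if (length(unique(groups[keep])) < 2L) stop("need >= 2 groups")
  d <- panel$dosage[keep, , drop = FALSE]
  g <- factor(groups[keep])
  # squared distance = mean over pairwise-complete loci of (dosage diff)^2
  called <- !is.na(d)
  Lpair <- tcrossprod(called * 1)
  d0 <- d; d0[!called] <- 0
  # sum (a-b)^2 over loci called in both = sum a^2 + sum b^2 - 2 sum ab
  a2 <- (d0^2) %*% t(called * 1)
  ab <- tcrossprod(d0)
  D2 <- (a2 + t(a2) - 2 * ab) / Lpair
  if (any(!is.finite(D2))) stop("sample pair(s) share zero called loci")
  obs <- amova_phi(D2, g)
  p_value <- NA_real_
  perm_phi <- NULL
  if (n_permutations >= 1) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    perm_phi <- vapply(seq_len(n_permutations), function(i) {
      amova_phi(D2, sample(g))$phi
    }, numeric(1))
    p_value <- (1 + sum(perm_phi >= obs$phi)) / (1 + n_permutations)
  }
  sig_a <- max(obs$sigma_a, 0)
  sig_w <- max(obs$sigma_w, 0)
  components <- data.frame(
    source = c("among_populations", "within_populations"),
    df = c(obs$df_a, obs$df_w),
    sigma2 = c(obs$sigma_a, obs$sigma_w),
    percent = 100 * c(sig_a, sig_w) / (sig_a + sig_w))
  structure(list(components = components, phi_st = obs$phi,
                 p_value = p_value, n_permutations = n_permutations,
                 ss = c(among = obs$ss_a, within = obs$ss_w,
                        total = obs$ss_t),
                 df = c(among = obs$df_a, within = obs$df_w)),
            class = "amova_result")
}

# Variance components and Phi_ST from a squared-distance matrix and a
# grouping factor (Excoffier-style SS from pairwise squared distances).
amova_phi <- function(D2, g) {
  N <- nrow(D2)
  ut <- upper.tri(D2)
  ss_t <- sum(D2[ut]) / N
  ss_w <- 0
  n_g <- table(g)
  for (lev in levels(g)) {
    i <- which(g == lev)
    if (length(i) > 1L)
      ss_w <- ss_w + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
  }
  ss_a <- ss_t - ss_w
  r <- nlevels(g)
  df_a <- r - 1L
  df_w <- N - r
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  n0 <- (N - sum(n_g^2) / N) / df_a
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  phi <- sigma_a / (sigma_a + sigma_w)
  list(ss_t = ss_t, ss_w = ss_w, ss_a = ss_a, df_a = df_a, df_w = df_w,
       sigma_a = sigma_a, sigma_w = sigma_w, phi = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (distance-based, 2 levels)\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f", x$phi_st))
  if (!is.na(x$p_value))
    cat(sprintf("  (P = %.4g, %d permutations)", x$p_value,
                x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Sliding-window FST
#'
#' Aggregates per-locus Weir-Cockerham components into overlapping windows
#' tiling each chromosome from position 1 (window starts 1, 1+step,
#' 1+2*step, ...). A locus at position P belongs to every window
#' `[s, s+window)` with `s <= P < s+window`. Window theta is the ratio of
#' sums of components over member loci; windows without any defined locus
#' are omitted.
#'
#' @param fst data frame from [wc_fst()].
#' @param window window size in bp (default 100 kb).
#' @param step step size in bp (default 10 kb).
#' @return Data frame: `chrom`, `start`, `end` (half-open), `n_loci`,
#'   `theta`.
#' @export
sliding_window_fst <- function(fst, window = 1e5, step = 1e4) {
  stopifnot(window > 0, step > 0)
  fst <- fst[!is.na(fst$theta), , drop = FALSE]
  if (!nrow(fst)) stop("no locus with defined theta")
  pieces <- lapply(split(fst, fst$chrom), function(fc) {
    P <- fc$pos
    j_lo <- pmax(1L, floor((P - 1 - window) / step) + 2L)
    j_hi <- floor((P - 1) / step) + 1L
    reps <- j_hi - j_lo + 1L
    idx <- rep(seq_len(nrow(fc)), reps)
    wj <- unlist(lapply(seq_len(nrow(fc)),
                        function(i) seq(j_lo[i], j_hi[i])))
    key <- factor(wj)
    num <- tapply(fc$a[idx], key, sum)
    den <- tapply((fc$a + fc$b + fc$c)[idx], key, sum)
    nl <- tapply(idx, key, length)
    j <- as.integer(names(num))
    data.frame(chrom = fc$chrom[1],
               start = 1 + (j - 1) * step,
               end = 1 + (j - 1) * step + window,
               n_loci = as.integer(nl),
               theta = as.numeric(num / den),
               row.names = NULL)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Flag top-tail FST outlier windows
#'
#' Flags the windows whose theta is at least the k-th largest value, where
#' k = `ceiling(n * top_fraction)`; all windows tied with the cutoff value
#' are included, so ties can push the flagged count above k.
#'
#' @param windows data frame from [sliding_window_fst()].
#' @param top_fraction upper tail fraction (default 0.05).
#' @return The input with a logical `outlier` column and attribute
#'   `threshold`.
#' @export
outlier_windows <- function(windows, top_fraction = 0.05) {
  if (!nrow(windows)) stop("no windows")
  th <- windows$theta[!is.na(windows$theta)]
  k <- max(1L, ceiling(length(th) * top_fraction))
  cutoff <- sort(th, decreasing = TRUE)[k]
  windows$outlier <- !is.na(windows$theta) & windows$theta >= cutoff
  attr(windows, "threshold") <- cutoff
  windows
}
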