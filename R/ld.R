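#' Pairwise linkage disequilibrium (composite genotypic r-squared)
#'
#' r-squared is the squared Pearson correlation between dosage vectors over
#' pairwise-complete samples — the composite (genotypic) LD estimator, valid
#' for unphased genotypes and essentially equal to haplotype r-squared for
#' highly inbred material. Only pairs on the same chromosome are formed.
#'
#' @param panel a `genotype_panel`.
#' @param subset `NULL`, a population label, or sample ids.
#' @param max_distance keep only pairs at most this many bp apart
#'   (`NULL` = no limit).
#' @param maf_min loci with subset MAF below this are excluded (default 0,
#'   i.e. only monomorphic loci are skipped).
#' @param alpha significance level attached to the result (default 0.01).
#' @return Data frame: `locus_i`, `locus_j`, `chrom`, `distance` (bp),
#'   `r2`, `n` (pairwise-complete samples), `p_value`, `significant`.
#' @export
pairwise_r2 <- function(panel, subset = NULL, max_distance = NULL,
                        maf_min = 0, alpha = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- resolve_subset(panel, subset)
  d <- panel$dosage[idx, , drop = FALSE]
  af <- allele_frequencies(panel, subset)
  poly <- !is.na(af$maf) & af$maf > maf_min
  out <- list()
  for (ch in unique(panel$loci$chrom)) {
    li <- which(panel$loci$chrom == ch & poly)
    if (length(li) < 2L) next
    dd <- d[, li, drop = FALSE]
    pos <- panel$loci$pos[li]
    r <- suppressWarnings(stats::cor(dd, use = "pairwise.complete.obs"))
    called <- !is.na(dd)
    npair <- crossprod(called)  # pairwise-complete counts
    ut <- which(upper.tri(r), arr.ind = TRUE)
    dist_bp <- abs(pos[ut[, 1]] - pos[ut[, 2]])
    keep <- rep(TRUE, nrow(ut))
    if (!is.null(max_distance)) keep <- dist_bp <= max_distance
    ut <- ut[keep, , drop = FALSE]
    dist_bp <- dist_bp[keep]
    r2 <- r[ut]^2
    n <- npair[ut]
    out[[ch]] <- data.frame(
      locus_i = panel$loci$id[li[ut[, 1]]],
      locus_j = panel$loci$id[li[ut[, 2]]],
      chrom = ch, distance = dist_bp, r2 = r2, n = n,
      row.names = NULL)
  }
  if (!length(out))
    stop("fewer than two polymorphic loci on every chromosome")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # r2 can be NA when a locus is constant over the pairwise-complete subset
  res <- res[!is.na(res$r2), , drop = FALSE]
  res$p_value <- r2_significance(res$r2, res$n)
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res
}

#' Significance of an r-squared value
#'
#' Standard allelic-association approximation: `n * r2` is referred to a
#' 1-df chi-square distribution, where n is the pairwise-complete sample
#' count. Undefined (`NA`) for n < 3.
#'
#' @param r2 squared correlation(s).
#' @param n called sample count(s).
#' @return P-value vector.
#' @export
r2_significance <- function(r2, n) {
  p <- stats::pchisq(n * r2, df = 1, lower.tail = FALSE)
  p[n < 3] <- NA_real_
  p
}

#' LD decay profile and decay distance
#'
#' Bins pairs by physical distance, averages r-squared per bin, and locates
#' the decay distance at a threshold (default r2 = 0.1): the midpoint of
#' the first bin whose mean r-squared drops below the threshold and stays
#' below it in every later non-empty bin. The decay distance is therefore a
#' bin-resolution quantity.
#'
#' @param pairs output of [pairwise_r2()] (or any data frame with
#'   `distance` and `r2` columns).
#' @param threshold r-squared level defining decay (default 0.1).
#' @param bin_width bin width in bp (default 500 kb).
#' @return A list of class `ld_decay`: `profile` (data frame with
#'   `bin_start`, `bin_end`, `bin_mid`, `n_pairs`, `mean_r2`),
#'   `decay_distance` (bp, `NA` if the profile never crosses the
#'   threshold), `threshold`, `bin_width`, and `beyond_range` flag.
#' @export
ld_decay <- function(pairs, threshold = 0.1, bin_width = 5e5) {
  if (!nrow(pairs)) stop("no LD pairs supplied")
  stopifnot(all(c("distance", "r2") %in% names(pairs)))
  dmax <- max(pairs$distance)
  edges <- seq(0, by = bin_width, length.out = ceiling(dmax / bin_width) + 1L)
  if (edges[length(edges)] <= dmax) edges <- c(edges, dmax + bin_width)
  bin <- findInterval(pairs$distance, edges, rightmost.closed = FALSE)
  mean_r2 <- tapply(pairs$r2, bin, mean)
  n_pairs <- tapply(pairs$r2, bin, length)
  b <- as.integer(names(mean_r2))
  profile <- data.frame(
    bin_start = edges[b], bin_end = edges[b + 1L],
    bin_mid = (edges[b] + edges[b + 1L]) / 2,
    n_pairs = as.integer(n_pairs), mean_r2 = as.numeric(mean_r2),
    row.names = NULL)
  profile <- profile[order(profile$bin_start), , drop = FALSE]
  below <- profile$mean_r2 < threshold
  # first bin below threshold such that all later non-empty bins stay below
  stays <- rev(cumprod(rev(below))) == 1
  decay <- if (any(stays)) profile$bin_mid[which(stays)[1]] else NA_real_
  structure(list(profile = profile, decay_distance = decay,
                 threshold = threshold, bin_width = bin_width,
                 beyond_range = is.na(decay)),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay profile: ", nrow(x$profile), " bins of ",
      x$bin_width / 1000, " kb\n", sep = "")
  if (x$beyond_range) {
    cat("  decay distance at r2 =", x$threshold,
        ": beyond observed range\n")
  } else {
    cat("  decay distance at r2 = ", x$threshold, ": ",
        x$decay_distance / 1000, " kb\n", sep = "")
  }
  invisible(x)
}
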