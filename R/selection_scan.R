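#' Allele-frequency difference t test
#'
#' Tests the difference between subpopulation allele frequencies f1 and f2
#' with the pooled-frequency statistic
#' `t = (f1 - f2) / sqrt((1/(2 n1) + 1/(2 n2)) * fexp (1 - fexp))`,
#' `fexp = (f1 n1 + f2 n2) / (n1 + n2)`,
#' where n1, n2 are individual counts (alleles counted as 2n). Two-sided
#' P-values come from a Student t reference with `2 n1 + 2 n2 - 2` degrees
#' of freedom by default (a standard-normal reference is also available;
#' at hundreds of samples the two agree except in the far tail). Tails are
#' evaluated in log space, so `-log10(P)` stays finite and accurate far
#' beyond double-precision underflow (values above 300 are routine for
#' strongly diverged loci).
#'
#' When f1 = f2 (including both 0 or both 1, where the pooled variance is
#' zero) the statistic is 0 and P = 1.
#'
#' @param f1,f2 allele frequencies in the two subpopulations (vectorised).
#' @param n1,n2 subpopulation sample sizes in individuals.
#' @param df degrees of freedom for the t reference; default
#'   `2*n1 + 2*n2 - 2`.
#' @param reference `"t"` (default) or `"normal"`.
#' @return Data frame: `f1`, `f2`, `n1`, `n2`, `fexp`, `diff`, `abs_diff`,
#'   `t`, `p_value`, `neglog10_p`.
#' @export
allele_diff_test <- function(f1, f2, n1, n2, df = NULL,
                             reference = c("t", "normal")) {
  reference <- match.arg(reference)
  stopifnot(all(f1 >= 0 & f1 <= 1, na.rm = TRUE),
            all(f2 >= 0 & f2 <= 1, na.rm = TRUE),
            all(n1 >= 1), all(n2 >= 1))
  k <- max(length(f1), length(f2), length(n1), length(n2))
  f1 <- rep_len(f1, k); f2 <- rep_len(f2, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  fexp <- (f1 * n1 + f2 * n2) / (n1 + n2)
  v <- (1 / (2 * n1) + 1 / (2 * n2)) * fexp * (1 - fexp)
  tt <- (f1 - f2) / sqrt(v)
  degenerate <- v == 0
  if (any(degenerate & f1 != f2, na.rm = TRUE))
    stop("internal error: zero pooled variance with f1 != f2")
  tt[degenerate] <- 0
  if (is.null(df)) df <- 2 * n1 + 2 * n2 - 2
  log_p <- log(2) + if (reference == "t")
    stats::pt(-abs(tt), df = df, log.p = TRUE)
  else
    stats::pnorm(-abs(tt), log.p = TRUE)
  log_p[tt == 0] <- 0
  data.frame(f1 = f1, f2 = f2, n1 = n1, n2 = n2, fexp = fexp,
             diff = f1 - f2, abs_diff = abs(f1 - f2), t = tt,
             p_value = exp(log_p), neglog10_p = -log_p / log(10))
}

#' Population-specific alleles
#'
#' A locus carries a population-specific allele when one of its alleles has
#' frequency exactly zero in one subpopulation and a positive frequency in
#' the other, and the frequency difference is significant at `alpha` under
#' [allele_diff_test()]. Both alleles are examined (an alt allele absent
#' in group 2 and a ref allele absent in group 2 are both reportable).
#'
#' @param panel a `genotype_panel`.
#' @param group1,group2 population labels.
#' @param alpha significance cutoff (default 0.001).
#' @return Data frame of flagged loci: `id`, `chrom`, `pos`, `allele`
#'   (the specific allele's nucleotide), `carrier_group`, `freq_carrier`
#'   (the allele's frequency in the carrier group), `p_value`,
#'   `neglog10_p`.
#' @export
population_specific_alleles <- function(panel, group1, group2,
                                        alpha = 0.001) {
  stopifnot(inherits(panel, "genotype_panel"))
  af1 <- allele_frequencies(panel, group1)
  af2 <- allele_frequencies(panel, group2)
  n1 <- af1$n_called; n2 <- af2$n_called
  ok <- n1 > 0 & n2 > 0
  tst <- allele_diff_test(af1$alt_freq[ok], af2$alt_freq[ok],
                          n1[ok], n2[ok])
  loci <- panel$loci[ok, , drop = FALSE]
  f1 <- af1$alt_freq[ok]; f2 <- af2$alt_freq[ok]
  sig <- tst$p_value < alpha
  rows <- list()
  flag <- function(which_allele, carrier, fr, sel) {
    if (!any(sel)) return(NULL)
    data.frame(id = loci$id[sel], chrom = loci$chrom[sel],
               pos = loci$pos[sel],
               allele = which_allele[sel],
               carrier_group = carrier,
               freq_carrier = fr[sel],
               p_value = tst$p_value[sel],
               neglog10_p = tst$neglog10_p[sel],
               row.names = NULL)
  }
  # alt allele absent in one group, present in the other
  rows$alt1 <- flag(loci$alt, group1, f1, sig & f2 == 0 & f1 > 0)
  rows$alt2 <- flag(loci$alt, group2, f2, sig & f1 == 0 & f2 > 0)
  # ref allele (frequency 1 - alt) absent in one group
  rows$ref1 <- flag(loci$ref, group1, 1 - f1, sig & f2 == 1 & f1 < 1)
  rows$ref2 <- flag(loci$ref, group2, 1 - f2, sig & f1 == 1 & f2 < 1)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), chrom = character(),
                      pos = integer(), allele = character(),
                      carrier_group = character(),
                      freq_carrier = numeric(), p_value = numeric(),
                      neglog10_p = numeric())
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' EigenGWAS scan for loci driving population structure
#'
#' Three steps: (i) a genetic relationship matrix (GRM) from standardised
#' dosages, `z_il = (d_il - 2 p_l) / sqrt(2 p_l (1 - p_l))`, GRM =
#' `Z Z' / m`; (ii) its top eigenvalues and eigenvectors; (iii) a
#' per-locus simple linear regression of the focal eigenvector on dosage,
#' with chi-square = (slope / se)^2. The chi-squares are deflated by the
#' genomic-control inflation factor `lambda_gc = median(chisq) / 0.4549`
#' (0.4549 is the 1-df chi-square median), and corrected P-values (PGC)
#' come from the deflated statistics on 1 df, in log space.
#'
#' Missing dosages are mean-imputed; monomorphic loci are excluded.
#'
#' @param panel a `genotype_panel`.
#' @param k_top number of eigenpairs to compute (default 10).
#' @param focal_k eigenvector to scan against (default 1, the axis of
#'   strongest structure).
#' @param loco leave-one-chromosome-out association (default `TRUE`): the
#'   eigenvector regressed against each chromosome's loci is recomputed
#'   from all other chromosomes. Because the global eigenvector is fitted
#'   from the very loci being tested, the null median chi-square is
#'   otherwise inflated by the GRM's top eigenvalue (about
#'   `(1 + sqrt(n/m))^2` even without structure); LOCO removes that
#'   self-fitting term so lambda_gc is interpretable as structure.
#' @return A list of class `eigengwas_result`: `scan` (data frame: `id`,
#'   `chrom`, `pos`, `beta`, `chisq`, `p_value`, `pgc`, `neglog10_pgc`),
#'   `eigenvalues` (top k), `vectors` (samples x k), `lambda_gc`,
#'   `focal_k`, `n_loci`.
#' @export
eigengwas <- function(panel, k_top = 10, focal_k = 1, loco = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$samples) < 3L) stop("need at least 3 samples")
  stopifnot(focal_k >= 1, focal_k <= k_top)
  d <- panel$dosage
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  poly <- n_called > 0L & p > 0 & p < 1
  if (sum(poly) < 2L) stop("need at least 2 polymorphic loci")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- d
  mu <- 2 * p
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  z <- sweep(sweep(x, 2, mu), 2, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(z)
  zz <- tcrossprod(z)
  grm <- zz / m
  eg <- eigen(grm, symmetric = TRUE)
  k_top <- min(k_top, ncol(eg$vectors))
  vectors <- eg$vectors[, seq_len(k_top), drop = FALSE]
  ev <- eg$values[seq_len(k_top)]
  y_global <- vectors[, focal_k]
  n <- length(y_global)
  chroms <- panel$loci$chrom[poly]
  uniq_chrom <- unique(chroms)
  if (loco && length(uniq_chrom) < 2L) {
    warning("single chromosome: falling back to the global eigenvector")
    loco <- FALSE
  }
  # Per-locus regression of the focal eigenvector on (imputed) dosage.
  # With loco = TRUE the eigenvector used against each chromosome's loci
  # is recomputed from all OTHER chromosomes, so under the null the
  # response is independent of the tested locus (no PC self-fitting).
  regress_chunk <- function(cols, y) {
    xc <- sweep(x[, cols, drop = FALSE], 2,
                colMeans(x[, cols, drop = FALSE]))
    yc <- y - mean(y)
    sxx <- colSums(xc^2)
    sxy <- as.vector(crossprod(xc, yc))
    beta <- sxy / sxx
    rss <- sum(yc^2) - beta * sxy
    se2 <- rss / ((n - 2) * sxx)
    cbind(beta = beta, chisq = beta^2 / se2)
  }
  if (loco) {
    fit <- matrix(NA_real_, nrow = m, ncol = 2,
                  dimnames = list(NULL, c("beta", "chisq")))
    for (ch in uniq_chrom) {
      cols <- which(chroms == ch)
      zc <- z[, cols, drop = FALSE]
      grm_c <- (zz - tcrossprod(zc)) / (m - length(cols))
      eg_c <- eigen(grm_c, symmetric = TRUE)
      y_c <- eg_c$vectors[, focal_k]
      if (sum(y_c * y_global) < 0) y_c <- -y_c
      fit[cols, ] <- regress_chunk(cols, y_c)
    }
  } else {
    fit <- regress_chunk(seq_len(m), y_global)
  }
  beta <- fit[, "beta"]
  chisq <- fit[, "chisq"]
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  log_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE, log.p = TRUE)
  log_pgc <- stats::pchisq(chisq / lambda, df = 1, lower.tail = FALSE,
                           log.p = TRUE)
  scan <- data.frame(id = panel$loci$id[poly],
                     chrom = panel$loci$chrom[poly],
                     pos = panel$loci$pos[poly],
                     beta = beta, chisq = chisq,
                     p_value = exp(log_p), pgc = exp(log_pgc),
                     neglog10_pgc = -log_pgc / log(10),
                     row.names = NULL)
  dimnames(vectors) <- list(panel$samples, paste0("EV", seq_len(k_top)))
  structure(list(scan = scan, eigenvalues = ev, vectors = vectors,
                 lambda_gc = lambda, focal_k = focal_k, n_loci = m),
            class = "eigengwas_result")
}

#' @export
print.eigengwas_result <- function(x, ...) {
  cat("EigenGWAS scan: ", x$n_loci, " loci, focal eigenvector ",
      x$focal_k, "\n", sep = "")
  cat(sprintf("  lambda_GC = %.3f; top eigenvalues: %s\n", x$lambda_gc,
              paste(sprintf("%.2f", utils::head(x$eigenvalues, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Rank candidate loci under selection across the three statistics
#'
#' Merges per-locus FST, the allele-difference t scan, and the EigenGWAS
#' scan on their shared locus set, ranks each statistic (1 = strongest
#' signal), and orders loci by the best (minimum) of their three ranks,
#' breaking ties by (chrom, pos).
#'
#' @param fst data frame from [wc_fst()].
#' @param tscan data frame from [allele_diff_test()] with an `id` column
#'   (see [run_all()] for the assembled form), ranked by `neglog10_p`.
#' @param escan `eigengwas_result` (or its `scan` data frame), ranked by
#'   `chisq`.
#' @param top_n rows to return (default 10; `Inf` for all).
#' @return Data frame of candidates ordered by rank: `id`, `chrom`,
#'   `pos`, the three statistics, per-statistic ranks, `best_rank`,
#'   `rank`, and `consistent` (TRUE when the three ranks all fall within
#'   the returned top set size).
#' @export
rank_candidates <- function(fst, tscan, escan, top_n = 10) {
  if (inherits(escan, "eigengwas_result")) escan <- escan$scan
  ids <- Reduce(intersect, list(fst$id, tscan$id, escan$id))
  if (!length(ids)) stop("no shared loci across the three statistics")
  f <- fst[match(ids, fst$id), ]
  t_ <- tscan[match(ids, tscan$id), ]
  e <- escan[match(ids, escan$id), ]
  rk <- function(v) rank(-v, ties.method = "min", na.last = "keep")
  out <- data.frame(id = ids, chrom = f$chrom, pos = f$pos,
                    theta = f$theta,
                    abs_diff = t_$abs_diff, neglog10_p_t = t_$neglog10_p,
                    eigengwas_chisq = e$chisq,
                    neglog10_pgc = e$neglog10_pgc,
                    fst_rank = rk(f$theta),
                    t_rank = rk(t_$neglog10_p),
                    eigengwas_rank = rk(e$chisq),
                    row.names = NULL)
  out$best_rank <- pmin(out$fst_rank, out$t_rank, out$eigengwas_rank,
                        na.rm = TRUE)
  ord <- order(out$best_rank, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n <- min(top_n, nrow(out))
  out <- out[seq_len(n), , drop = FALSE]
  out$consistent <- out$fst_rank <= nrow(out) * 3 &
    out$t_rank <= nrow(out) * 3 & out$eigengwas_rank <= nrow(out) * 3
  rownames(out) <- NULL
  out
}

#' Annotate candidate loci with overlapping intervals
#'
#' Attaches every interval (half-open, `[start, end)`) containing a
#' candidate's position. Malformed intervals (end <= start) are skipped
#' with a warning.
#'
#' @param candidates data frame with `id`, `chrom`, `pos`.
#' @param annotations data frame with `chrom`, `start`, `end`, `label`
#'   (BED-like; or a path to such a TSV).
#' @return The candidates with an added `annotations` column
#'   (comma-joined labels, "" when none).
#' @export
interval_overlap <- function(candidates, annotations) {
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- utils::read.table(
      annotations, header = TRUE, sep = "\t", comment.char = "#",
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(annotations)))
  bad <- annotations$end <= annotations$start
  if (any(bad)) {
    warning(sum(bad), " malformed interval(s) skipped (end <= start)")
    annotations <- annotations[!bad, , drop = FALSE]
  }
  ann_by_chrom <- split(annotations, annotations$chrom)
  candidates$annotations <- vapply(seq_len(nrow(candidates)), function(i) {
    a <- ann_by_chrom[[as.character(candidates$chrom[i])]]
    if (is.null(a)) return("")
    hit <- a$start <= candidates$pos[i] & candidates$pos[i] < a$end
    paste(a$label[hit], collapse = ",")
  }, character(1))
  candidates
}
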