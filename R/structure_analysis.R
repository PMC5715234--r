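#' Principal component analysis of a genotype panel
#'
#' Missing dosages are mean-imputed per locus, the matrix is centered, and
#' (by default) each locus is scaled by `1/sqrt(p(1-p))` where p is the
#' alt-allele frequency — the normalisation that gives every locus equal
#' expected contribution under drift. Monomorphic loci are dropped. The
#' decomposition is deterministic up to axis sign; signs are fixed by
#' making each axis's largest-magnitude locus loading positive.
#'
#' @param panel a `genotype_panel`.
#' @param n_axes number of axes to return (default 10).
#' @param scaling `"patterson"` (default) or `"center_only"`.
#' @return An object of class `panel_pca`: list with `coords` (samples x
#'   axes), `eigenvalues` (all, non-increasing), `var_explained`
#'   (fractions, all axes), `loadings` (loci x axes), `scaling`.
#' @export
panel_pca <- function(panel, n_axes = 10,
                      scaling = c("patterson", "center_only")) {
  stopifnot(inherits(panel, "genotype_panel"))
  scaling <- match.arg(scaling)
  d <- panel$dosage
  if (nrow(d) < 2L) stop("need at least 2 samples")
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  poly <- n_called > 0L & p > 0 & p < 1
  if (sum(poly) < 2L) stop("need at least 2 polymorphic loci")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- d
  mu <- 2 * p
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, mu)
  if (scaling == "patterson") x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (n_axes > k_max) {
    warning("only ", k_max, " axes available; truncating")
    n_axes <- k_max
  }
  sv <- svd(x)
  eig <- sv$d^2 / (nrow(x) - 1L)
  ve <- sv$d^2 / sum(sv$d^2)
  coords <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  loadings <- sv$v[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(n_axes)) {
    s <- sign(loadings[which.max(abs(loadings[, k])), k])
    if (s < 0) {
      loadings[, k] <- -loadings[, k]
      coords[, k] <- -coords[, k]
    }
  }
  dimnames(coords) <- list(panel$samples, paste0("PC", seq_len(n_axes)))
  dimnames(loadings) <- list(panel$loci$id[poly],
                             paste0("PC", seq_len(n_axes)))
  structure(list(coords = coords, eigenvalues = eig, var_explained = ve,
                 loadings = loadings, scaling = scaling),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  k <- ncol(x$coords)
  cat("panel_pca: ", nrow(x$coords), " samples, ", k, " axes (",
      x$scaling, " scaling)\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(min(k, 5))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Evanno delta-K from cluster-model log-likelihoods
#'
#' Post-processes a table of replicate log-likelihoods L(K) from an
#' external model-based clustering run (e.g. STRUCTURE). For each interior
#' K, `delta_K = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K))`, with the
#' mean of the absolute second difference taken over replicates and the sd
#' over the replicates at K. The supported number of clusters is the K
#' maximising delta-K.
#'
#' @param loglik numeric matrix, replicates x K values; column names give
#'   the K values (defaults to 1..ncol).
#' @param strict error when sd(L(K)) is zero at an interior K (default
#'   `FALSE`, which yields `NA` there).
#' @return Data frame: `K`, `mean_L`, `sd_L`, `delta_K` (NA at the two
#'   boundary K), with attribute `best_K`.
#' @export
evanno_delta_k <- function(loglik, strict = FALSE) {
  loglik <- as.matrix(loglik)
  if (ncol(loglik) < 3L) stop("need at least 3 consecutive K values")
  if (nrow(loglik) < 2L) stop("need at least 2 replicates per K")
  Ks <- if (!is.null(colnames(loglik)))
    as.integer(colnames(loglik)) else seq_len(ncol(loglik))
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  mean_L <- colMeans(loglik)
  sd_L <- apply(loglik, 2, stats::sd)
  delta <- rep(NA_real_, length(Ks))
  for (i in seq(2L, length(Ks) - 1L)) {
    second_diff <- abs(loglik[, i + 1L] - 2 * loglik[, i] + loglik[, i - 1L])
    if (sd_L[i] == 0) {
      if (strict) stop("sd of L(K) is zero at K = ", Ks[i])
      next
    }
    delta[i] <- mean(second_diff) / sd_L[i]
  }
  out <- data.frame(K = Ks, mean_L = mean_L, sd_L = sd_L, delta_K = delta,
                    row.names = NULL)
  attr(out, "best_K") <- if (all(is.na(delta))) NA_integer_ else
    Ks[which.max(delta)]
  out
}

#' Cross-tabulate cluster assignments against origins
#'
#' Builds the cluster x origin contingency table and the percent of
#' samples concordant with the majority mapping (each cluster mapped to
#' its most frequent origin).
#'
#' @param assignments named vector, sample id -> cluster label.
#' @param origins named vector, sample id -> origin (population) label.
#' @return A list with `table` (cluster x origin counts) and
#'   `percent_concordant`.
#' @export
membership_crosstab <- function(assignments, origins) {
  ids <- names(assignments)
  if (is.null(ids) || is.null(names(origins)))
    stop("assignments and origins must be named by sample id")
  if (!setequal(ids, names(origins)))
    stop("assignments and origins cover different sample sets")
  origins <- origins[ids]
  tab <- table(cluster = as.character(assignments),
               origin = as.character(origins))
  concordant <- sum(apply(tab, 1, max))
  list(table = tab,
       percent_concordant = 100 * concordant / sum(tab))
}
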