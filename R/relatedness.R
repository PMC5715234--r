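#' Pairwise genetic distance matrix
#'
#' `rogers` is the Rogers distance computed from individual allele-frequency
#' vectors (dosage/2, i.e. 0, 0.5, 1 for the alt allele):
#' `D_ij = (1/L) * sum_l sqrt(0.5 * sum_a (p_ila - p_jla)^2)`.
#' `allele_sharing` is one minus the proportion of shared alleles,
#' `D_ij = 1 - shared/(2L)`. For biallelic loci the two definitions
#' coincide (both reduce to the mean absolute dosage difference divided
#' by 2); both tags are kept so the intent of an analysis is explicit.
#' L counts pairwise-complete loci; distances are means over those loci.
#'
#' @param panel a `genotype_panel`.
#' @param method `"rogers"` or `"allele_sharing"`.
#' @param strict error on sample pairs with zero shared called loci
#'   (default `TRUE`); otherwise such entries are `NA`.
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and attribute `method`.
#' @export
distance_matrix <- function(panel, method = c("rogers", "allele_sharing"),
                            strict = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  method <- match.arg(method)
  if (length(panel$samples) < 2L) stop("need at least 2 samples")
  x <- panel$dosage / 2
  # Both methods reduce to mean_l |x_i - x_j| with x in {0, .5, 1}.
  # Decompose each genotype into two haploid {0,1} indicators (h1 >= h2);
  # then |x_i - x_j| = 0.5 (|h1_i - h1_j| + |h2_i - h2_j|) exactly, and
  # each binary term vectorises across all pairs as crossproducts.
  called <- !is.na(x)
  L <- tcrossprod(called * 1)                  # pairwise-complete counts
  x0 <- x
  x0[!called] <- 0
  h1 <- (x0 >= 0.5) * 1
  h2 <- (x0 >= 1.0) * 1
  abs_sum <- 0.5 * (manhattan_masked(h1, called) +
                    manhattan_masked(h2, called))
  D <- abs_sum / L
  if (any(L == 0)) {
    if (strict) stop("sample pair(s) share zero called loci")
    D[L == 0] <- NA_real_
  }
  diag(D) <- 0
  dimnames(D) <- list(panel$samples, panel$samples)
  attr(D, "method") <- method
  D
}

# Pairwise sum over loci of |a_i - a_j| for a binary matrix `b`
# (samples x loci), restricted to loci where both rows are in `called`.
# For binary values |a-b| = a + b - 2ab, all terms expressible as
# crossproducts with the call mask.
manhattan_masked <- function(b, called) {
  bm <- b * called
  s_i <- bm %*% t(called)       # sum of a_i over loci called in both
  ab <- tcrossprod(bm)          # sum of a_i * a_j
  s_i + t(s_i) - 2 * ab
}

#' Loiselle marker-based kinship matrix
#'
#' Kinship between accessions i and j:
#' `K_ij = sum_l sum_a [(p_ila - p_la)(p_jla - p_la) + p_la(1-p_la)/(n_l - 1)]
#'          / sum_l sum_a p_la (1 - p_la)`
#' where `p_ila` is the allele frequency within individual i (dosage/2),
#' `p_la` the frequency in the reference sample (the full panel), and
#' `n_l` the number of non-missing alleles at locus l (2 x called
#' genotypes). Sums run over loci called in both members of a pair.
#' Negative pairwise values, indicating less relatedness than random pairs,
#' are truncated to zero after summation across loci.
#'
#' @param panel a `genotype_panel`.
#' @return A symmetric matrix with entries >= 0 and attribute
#'   `raw_negative_fraction` (share of off-diagonal pairs truncated).
#' @export
loiselle_kinship <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$samples) < 2L) stop("need at least 2 samples")
  d <- panel$dosage
  called <- !is.na(d)
  n_called <- colSums(called)
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  usable <- !is.na(p) & n_called >= 2L
  if (!any(usable & p > 0 & p < 1))
    stop("no polymorphic locus with >= 2 called genotypes")
  d <- d[, usable, drop = FALSE]
  called <- called[, usable, drop = FALSE]
  p <- p[usable]
  n_l <- 2 * colSums(called)
  pq <- p * (1 - p)
  # biallelic: sum_a (p_ia - p_a)(p_ja - p_a) = 2 (x_i - p)(x_j - p),
  # sum_a p_a(1-p_a) = 2 p (1-p)
  x <- sweep(d / 2, 2, p)        # x_i - p, NA where missing
  x[!called] <- 0
  num_cross <- 2 * tcrossprod(x)
  cm <- called * 1
  w_bias <- 2 * pq / (n_l - 1)
  num_bias <- cm %*% (w_bias * t(cm))
  denom <- cm %*% (2 * pq * t(cm))
  if (any(denom == 0))
    stop("sample pair(s) share no usable loci")
  K <- (num_cross + num_bias) / denom
  neg <- K < 0
  diag(neg) <- FALSE
  K[K < 0] <- 0
  dimnames(K) <- list(panel$samples, panel$samples)
  attr(K, "raw_negative_fraction") <-
    sum(neg[upper.tri(neg)]) / sum(upper.tri(neg))
  K
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths, a
#' known artifact of NJ on noisy distances, are clamped to zero with the
#' deficit transferred to the adjacent branch so path lengths through the
#' node are preserved.
#'
#' @param dist symmetric distance matrix with sample ids as dimnames.
#' @return An unrooted `phylo` tree (see [ape::nj()]); write with
#'   [ape::write.tree()] for newick output.
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("need at least 3 samples")
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (any(!is.finite(dist))) stop("non-finite distances")
  tree <- ape::nj(stats::as.dist(dist))
  # clamp negative edges, pushing the deficit onto an adjacent edge
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (!length(adj)) adj <- which(tree$edge[, 2] == tree$edge[e, 1])
    if (length(adj))
      tree$edge.length[adj[1]] <- tree$edge.length[adj[1]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Within- and between-group distance distributions
#'
#' @param dist symmetric distance matrix with sample ids as dimnames.
#' @param groups named vector mapping sample id to group label.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return A list with `summary` (data frame: set, n_pairs, mean, min, max)
#'   and `histograms` (named list of `hist` objects). Pair sets are each
#'   within-group set plus one pooled `between` set; a group of size 1
#'   yields an empty within set (n_pairs 0, NA moments).
#' @export
distance_distribution <- function(dist, groups, breaks = 20) {
  dist <- as.matrix(dist)
  ids <- rownames(dist)
  if (is.null(ids)) stop("distance matrix must carry sample ids")
  if (!all(ids %in% names(groups)))
    stop("groups must cover all samples in the distance matrix")
  g <- groups[ids]
  ut <- upper.tri(dist)
  pair_groups <- outer(g, g, function(a, b) ifelse(a == b, a, "between"))
  sets <- c(sort(unique(g)), "between")
  rows <- list(); hists <- list()
  for (s in sets) {
    v <- dist[ut & pair_groups == s]
    rows[[s]] <- data.frame(
      set = s, n_pairs = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_)
    if (length(v))
      hists[[s]] <- graphics::hist(v, breaks = breaks, plot = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(summary = out, histograms = hists)
}
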