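#' Per-locus diversity statistics
#'
#' For a biallelic locus with allele frequencies p and q = 1 - p estimated
#' from called genotypes:
#' gene diversity (expected heterozygosity) is `1 - (p^2 + q^2)`,
#' polymorphism information content is the Botstein biallelic reduction
#' `1 - (p^2 + q^2) - 2 p^2 q^2`, observed heterozygosity is the fraction
#' of called genotypes with dosage 1, and MAF is `min(p, q)`.
#'
#' Loci with no called genotype in the subset are flagged undefined
#' (`defined = FALSE`, statistics `NA`); monomorphic loci have all
#' statistics equal to 0.
#'
#' @param panel a `genotype_panel`.
#' @param subset `NULL`, a population label, or sample ids (see
#'   [allele_frequencies()]).
#' @return Data frame, one row per locus: `id`, `chrom`, `pos`, `maf`,
#'   `gene_diversity`, `het_obs`, `pic`, `call_rate`, `defined`.
#' @export
locus_stats <- function(panel, subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- resolve_subset(panel, subset)
  d <- panel$dosage[idx, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  q <- 1 - p
  gd <- 1 - (p^2 + q^2)
  pic <- gd - 2 * p^2 * q^2
  het <- colSums(d == 1L, na.rm = TRUE) / n_called
  het[n_called == 0L] <- NA_real_
  data.frame(id = panel$loci$id, chrom = panel$loci$chrom,
             pos = panel$loci$pos,
             maf = pmin(p, q), gene_diversity = gd, het_obs = het,
             pic = pic, call_rate = n_called / nrow(d),
             defined = n_called > 0L, row.names = NULL)
}

#' Biallelic PIC and gene diversity at a given allele frequency
#'
#' Convenience evaluators of the closed-form statistics used by
#' [locus_stats()]. At p = 0.5 PIC attains its biallelic maximum 0.375 and
#' gene diversity its maximum 0.5.
#'
#' @param p allele frequency (vectorised).
#' @return Numeric vector.
#' @export
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' @rdname pic_biallelic
#' @export
gene_diversity_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2)
}

#' Summarise diversity statistics per population group
#'
#' Computes, for each population and for the pooled (`combined`) sample,
#' the mean and observed range of each per-locus statistic. The combined
#' group is recomputed from the pooled genotypes, not averaged from the
#' subgroup summaries. Undefined loci (no called genotype in a group) are
#' excluded from that group's means and ranges.
#'
#' @param panel a `genotype_panel`.
#' @param groups population labels to summarise; default all labels present.
#' @param combined include a pooled-group row (default `TRUE`).
#' @param hist_breaks number of histogram bins retained per statistic for
#'   distribution plots (default 20).
#' @return A list with `summary` (long data frame: group, statistic, mean,
#'   min, max, n_defined) and `histograms` (named list of `hist` objects
#'   per group and statistic).
#' @export
panel_summary <- function(panel, groups = NULL, combined = TRUE,
                          hist_breaks = 20) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(groups)) groups <- sort(unique(panel$population))
  stat_names <- c("maf", "gene_diversity", "het_obs", "pic")
  group_sets <- lapply(groups, function(g) {
    if (!any(panel$population == g)) stop("empty group: ", g)
    g
  })
  names(group_sets) <- groups
  if (combined) group_sets <- c(group_sets,
                                list(combined = list(panel$samples)))
  rows <- list()
  hists <- list()
  for (g in names(group_sets)) {
    subset <- if (g == "combined") panel$samples else g
    st <- locus_stats(panel, subset = subset)
    st <- st[st$defined, , drop = FALSE]
    if (!nrow(st)) stop("no defined loci in group: ", g)
    for (s in stat_names) {
      v <- st[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, statistic = s, mean = mean(v),
        min = min(v), max = max(v), n_defined = length(v))
      hists[[paste(g, s, sep = ".")]] <-
        graphics::hist(v, breaks = hist_breaks, plot = FALSE)
    }
  }
  list(summary = do.call(rbind, rows), histograms = hists)
}
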