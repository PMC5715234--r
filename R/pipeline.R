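#' Analysis run configuration
#'
#' Bundles the thresholds of the full pipeline. Defaults are the standard
#' settings of the analysis: missingness filter 0.20, LD significance
#' alpha 0.01, LD decay threshold r2 = 0.1, 100 kb windows with 10 kb
#' steps, top 5% outlier windows, allele-difference significance 1e-6,
#' population-specific-allele alpha 0.001, top 10 candidates.
#'
#' @param max_missing,ld_alpha,ld_decay_threshold,ld_bin_width,window,step
#'   stage thresholds (see the stage functions).
#' @param top_fraction,t_alpha,specific_alpha,top_n more stage thresholds.
#' @param n_permutations AMOVA permutation count.
#' @param seed integer seed for seeded stages (AMOVA permutations).
#' @return A list of class `run_config`.
#' @export
run_config <- function(max_missing = 0.20, ld_alpha = 0.01,
                       ld_decay_threshold = 0.1, ld_bin_width = 5e5,
                       window = 1e5, step = 1e4, top_fraction = 0.05,
                       t_alpha = 1e-6, specific_alpha = 0.001,
                       top_n = 10, n_permutations = 1000, seed = 1L) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            ld_alpha > 0, ld_alpha < 1,
            ld_decay_threshold > 0, window > 0, step > 0,
            top_fraction > 0, top_fraction <= 1,
            t_alpha > 0, t_alpha < 1, specific_alpha > 0,
            specific_alpha < 1, top_n >= 1, n_permutations >= 0)
  structure(list(max_missing = max_missing, ld_alpha = ld_alpha,
                 ld_decay_threshold = ld_decay_threshold,
                 ld_bin_width = ld_bin_width, window = window, step = step,
                 top_fraction = top_fraction, t_alpha = t_alpha,
                 specific_alpha = specific_alpha, top_n = top_n,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full two-gene-pool analysis
#'
#' Executes, in order: missingness filter, per-group diversity summary,
#' pairwise LD and decay per group, Rogers distances (with
#' within/between distribution), Loiselle kinship, neighbor-joining tree,
#' PCA and cluster-vs-origin cross-tabulation, AMOVA, per-locus and
#' windowed Weir-Cockerham FST with outlier windows, the allele-difference
#' t scan, population-specific alleles, EigenGWAS, and the merged
#' candidate ranking. Every stage's table is written as TSV under
#' `out_dir` together with a run log of counts and thresholds.
#'
#' @param panel a `genotype_panel` (two population labels expected).
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param groups optional two population labels to compare (defaults to
#'   the two most frequent labels in the panel).
#' @param annotations optional BED-like interval data frame or path for
#'   candidate annotation.
#' @param ld_max_distance cap on LD pair distance in bp (`NULL` = none).
#' @return A list (invisibly when writing) with every stage result:
#'   `filter`, `diversity`, `ld`, `distance`, `kinship`, `tree`, `pca`,
#'   `crosstab`, `amova`, `fst`, `windows`, `tscan`, `specific`,
#'   `eigengwas`, `candidates`, `log`.
#' @export
run_all <- function(panel, config = run_config(), out_dir = NULL,
                    groups = NULL, annotations = NULL,
                    ld_max_distance = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(groups)) {
    tab <- sort(table(panel$population[panel$population != "unassigned"]),
                decreasing = TRUE)
    if (length(tab) < 2L) stop("panel must carry >= 2 population labels")
    groups <- names(tab)[1:2]
  }
  note("run_all: ", length(panel$samples), " samples x ",
       nrow(panel$loci), " loci; groups ", groups[1], " vs ", groups[2])

  fl <- stage("filter", filter_missingness(panel, config$max_missing))
  panel <- fl$panel
  note("filter: retained ", fl$report$n_retained_loci, "/",
       fl$report$n_input_loci, " loci (",
       sprintf("%.2f%%", fl$report$percent_retained), ")")

  div <- stage("diversity", panel_summary(panel, groups = groups))

  ld <- lapply(stats::setNames(groups, groups), function(g) stage("ld", {
    pairs <- pairwise_r2(panel, subset = g,
                         max_distance = ld_max_distance,
                         alpha = config$ld_alpha)
    decay <- ld_decay(pairs, threshold = config$ld_decay_threshold,
                      bin_width = config$ld_bin_width)
    note("ld[", g, "]: ", nrow(pairs), " pairs, ",
         sprintf("%.2f%%", 100 * mean(pairs$significant)),
         " significant at alpha=", config$ld_alpha)
    list(pairs = pairs, decay = decay)
  }))

  dist <- stage("distance", distance_matrix(panel, method = "rogers"))
  dist_dist <- stage("distance",
                     distance_distribution(dist, panel$population))
  kin <- stage("kinship", loiselle_kinship(panel))
  note("kinship: ", sprintf("%.2f%%", 100 *
       mean(kin[upper.tri(kin)] == 0)), " of pairs at zero")
  tree <- stage("tree", neighbor_joining(dist))

  pca <- stage("pca", panel_pca(panel))
  pc1_clusters <- ifelse(pca$coords[, 1] >= stats::median(pca$coords[, 1]),
                         "cluster1", "cluster2")
  crosstab <- stage("crosstab",
                    membership_crosstab(pc1_clusters, panel$population))
  note("crosstab: ", sprintf("%.2f%%", crosstab$percent_concordant),
       " concordant with origin")

  amv <- stage("amova", amova(panel, n_permutations = config$n_permutations,
                              seed = config$seed))
  note("amova: among-population ",
       sprintf("%.2f%%", amv$components$percent[1]),
       ", Phi_ST = ", sprintf("%.4f", amv$phi_st))

  fst <- stage("fst", wc_fst(panel))
  theta_ml <- multilocus_fst(fst)
  note("fst: multilocus theta = ", sprintf("%.4f", theta_ml))
  win <- stage("windows", outlier_windows(
    sliding_window_fst(fst, window = config$window, step = config$step),
    top_fraction = config$top_fraction))
  note("windows: ", nrow(win), " windows, ", sum(win$outlier), " outliers")

  af1 <- allele_frequencies(panel, groups[1])
  af2 <- allele_frequencies(panel, groups[2])
  tscan <- stage("tscan", {
    res <- allele_diff_test(af1$alt_freq, af2$alt_freq,
                            af1$n_called, af2$n_called)
    cbind(af1[c("id", "chrom", "pos")], res)
  })
  note("tscan: ", sum(tscan$p_value < config$t_alpha, na.rm = TRUE),
       " loci significant at P<", config$t_alpha)
  spec <- stage("specific",
                population_specific_alleles(panel, groups[1], groups[2],
                                            alpha = config$specific_alpha))
  eg <- stage("eigengwas", eigengwas(panel))
  note("eigengwas: lambda_GC = ", sprintf("%.3f", eg$lambda_gc))
  cand <- stage("candidates",
                rank_candidates(fst, tscan, eg, top_n = config$top_n))
  if (!is.null(annotations))
    cand <- stage("candidates", interval_overlap(cand, annotations))

  out <- list(filter = fl, diversity = div, ld = ld, distance = dist,
              distance_distribution = dist_dist, kinship = kin,
              tree = tree, pca = pca, crosstab = crosstab, amova = amv,
              fst = fst, multilocus_theta = theta_ml, windows = win,
              tscan = tscan, specific = spec, eigengwas = eg,
              candidates = cand, groups = groups, config = config,
              log = log_lines)
  if (!is.null(out_dir)) {
    write_report_bundle(out, out_dir)
    return(invisible(out))
  }
  out
}

# Write every stage table of a run_all() result as TSV under out_dir.
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$filter$report, "filter_report.tsv")
  w(res$diversity$summary, "diversity_summary.tsv")
  for (g in names(res$ld)) {
    w(res$ld[[g]]$pairs, paste0("ld_pairs_", g, ".tsv"))
    w(res$ld[[g]]$decay$profile, paste0("ld_decay_", g, ".tsv"))
  }
  utils::write.table(res$distance, file.path(out_dir, "rogers_distance.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(res$kinship, file.path(out_dir, "kinship.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  ape::write.tree(res$tree, file.path(out_dir, "nj_tree.nwk"))
  utils::write.table(res$pca$coords, file.path(out_dir, "pca_coords.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  w(as.data.frame(res$crosstab$table), "crosstab.tsv")
  w(res$amova$components, "amova.tsv")
  w(res$fst, "fst_per_locus.tsv")
  w(res$windows, "fst_windows.tsv")
  w(res$tscan, "allele_diff_scan.tsv")
  w(res$specific, "population_specific_alleles.tsv")
  w(res$eigengwas$scan, "eigengwas_scan.tsv")
  w(res$candidates, "candidates.tsv")
  writeLines(c(paste0("soypopdiv ", as.character(
    utils::packageVersion("soypopdiv"))), res$log),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
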