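#' Configuration for the two-population panel simulator
#'
#' Defaults emulate a two-gene-pool cultivar panel: 277 + 300 mostly
#' inbred diploids, 5,195 biallelic SNPs on 20 chromosomes, background
#' divergence at the estimated between-pool FST (0.1933), a minority of
#' strongly diverged (planted "selected") loci, a small admixed fraction,
#' and a low missing-call rate.
#'
#' @param n1,n2 diploid sample counts in the two populations.
#' @param n_loci number of biallelic loci.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (default 50 Mb, the
#'   scale of a soybean chromosome).
#' @param background_F Balding-Nichols divergence for ordinary loci.
#' @param n_selected number of planted strongly diverged loci.
#' @param selected_F divergence at planted loci (must exceed
#'   `background_F`).
#' @param inbreeding probability that a genotype is drawn as a fully
#'   inbred (homozygous) call; cultivated soybean lines are near-fully
#'   inbred (default 0.95).
#' @param admixed_fraction fraction of individuals whose locus-wise
#'   frequencies come from a 50/50 mixture of the two populations.
#' @param missing_rate independent missing-call rate.
#' @param seed integer seed; every stochastic draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n1 = 277, n2 = 300, n_loci = 5195, n_chrom = 20,
                       chrom_length_bp = 5e7, background_F = 0.1933,
                       n_selected = 50, selected_F = 0.8,
                       inbreeding = 0.95, admixed_fraction = 0.05,
                       missing_rate = 0.03, seed = 1L) {
  cfg <- list(n1 = n1, n2 = n2, n_loci = n_loci, n_chrom = n_chrom,
              chrom_length_bp = chrom_length_bp,
              background_F = background_F, n_selected = n_selected,
              selected_F = selected_F, inbreeding = inbreeding,
              admixed_fraction = admixed_fraction,
              missing_rate = missing_rate, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n1 >= 1, n2 >= 1, n_loci >= 1, n_chrom >= 1,
              chrom_length_bp > n_loci,
              background_F >= 0, background_F < 1,
              n_selected >= 0, n_selected < n_loci,
              inbreeding >= 0, inbreeding <= 1,
              admixed_fraction >= 0, admixed_fraction <= 1,
              missing_rate >= 0, missing_rate < 1)
    if (n_selected > 0 && selected_F <= background_F)
      stop("selected_F must exceed background_F")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-population SNP panel under the Balding-Nichols model
#'
#' Each locus gets an ancestral frequency `p ~ Uniform(0.05, 0.95)`; the
#' two population frequencies are independent draws from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` with locus-specific F (background, or
#' `selected_F` at planted loci), so F is exactly the expected FST of that
#' locus. Planted loci additionally condition the draw on a realized
#' between-population frequency gap above 0.5: they model selection toward
#' opposite alleles, whereas an unconditioned high-F pair of draws fixes
#' the same allele in both pools about half the time. Genotypes are drawn
#' as fully inbred calls (dosage
#' `2 * Bernoulli(p_pop)`) with probability `inbreeding` and as
#' Hardy-Weinberg calls (`Binomial(2, p_pop)`) otherwise. Admixed
#' individuals use the 50/50 mixture frequency at every locus but keep
#' their nominal population label (they are the cross-assigned samples).
#' Loci are placed uniformly at random on chromosomes and sorted by
#' position. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `panel` (a `genotype_panel`) and `truth`, itself a
#'   list of `loci` (per-locus: `id`, `p_ancestral`, `p1`, `p2`, `F`,
#'   `outlier`) and `samples` (per-sample: `id`, `population`,
#'   `ancestry1` — proportion of population-1 ancestry).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cf$seed)
  L <- cf$n_loci
  # positions: uniform on chromosomes, sorted, unique
  chrom <- sort(sample.int(cf$n_chrom, L, replace = TRUE))
  pos <- integer(L)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(cf$chrom_length_bp, length(i)))
  }
  chrom_lab <- as.character(chrom)
  # planted outlier loci
  outlier <- rep(FALSE, L)
  if (cf$n_selected > 0)
    outlier[sample.int(L, cf$n_selected)] <- TRUE
  Fl <- ifelse(outlier, cf$selected_F, cf$background_F)
  p_anc <- stats::runif(L, 0.05, 0.95)
  draw_pop_freq <- function(p, F) {
    out <- p
    i <- F > 0
    out[i] <- stats::rbeta(sum(i), p[i] * (1 - F[i]) / F[i],
                           (1 - p[i]) * (1 - F[i]) / F[i])
    out
  }
  p1 <- draw_pop_freq(p_anc, Fl)
  p2 <- draw_pop_freq(p_anc, Fl)
  # Planted loci model selection pulling the pools toward opposite
  # alleles. An unconditioned high-F Beta pair fixes the SAME allele about
  # half the time (no realized divergence), so planted draws are redrawn
  # until the realized frequency gap exceeds 0.5 — the strongly diverged
  # regime the planted class represents.
  if (any(outlier)) {
    for (l in which(outlier)) {
      tries <- 0L
      while (abs(p1[l] - p2[l]) <= 0.5 && tries < 1000L) {
        p1[l] <- draw_pop_freq(p_anc[l], Fl[l])
        p2[l] <- draw_pop_freq(p_anc[l], Fl[l])
        tries <- tries + 1L
      }
    }
  }
  n <- cf$n1 + cf$n2
  pop <- rep(c("pop1", "pop2"), c(cf$n1, cf$n2))
  samples <- sprintf("%s_%03d", pop, c(seq_len(cf$n1), seq_len(cf$n2)))
  admixed <- stats::runif(n) < cf$admixed_fraction
  ancestry1 <- ifelse(pop == "pop1", 1, 0)
  ancestry1[admixed] <- 0.5
  p_mix <- (p1 + p2) / 2
  dosage <- matrix(NA_integer_, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    pf <- if (admixed[i]) p_mix else if (pop[i] == "pop1") p1 else p2
    inbred <- stats::runif(L) < cf$inbreeding
    g <- integer(L)
    g[inbred] <- 2L * (stats::runif(sum(inbred)) < pf[inbred])
    g[!inbred] <- stats::rbinom(sum(!inbred), 2L, pf[!inbred])
    dosage[i, ] <- g
  }
  ref <- c("A", "C", "G", "T")[sample.int(4, L, replace = TRUE)]
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  loci <- data.frame(
    id = sprintf("snp%05d", seq_len(L)),
    chrom = chrom_lab, pos = pos, ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE)
  panel <- genotype_panel(dosage, loci,
                          population = stats::setNames(pop, samples),
                          samples = samples)
  if (cf$missing_rate > 0)
    panel <- inject_missingness(panel, cf$missing_rate,
                                seed = cf$seed + 1L)
  truth <- list(
    loci = data.frame(id = loci$id, chrom = chrom_lab, pos = pos,
                      p_ancestral = p_anc, p1 = p1, p2 = p2, F = Fl,
                      outlier = outlier, row.names = NULL),
    samples = data.frame(id = samples, population = pop,
                         ancestry1 = ancestry1, row.names = NULL))
  list(panel = panel, truth = truth, config = cf)
}

#' Set calls to missing at random
#'
#' Each call is independently set missing with probability `rate`.
#' Deterministic given `seed`.
#'
#' @param panel a `genotype_panel`.
#' @param rate missing probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The panel with missing calls injected.
#' @export
inject_missingness <- function(panel, rate, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  d <- panel$dosage
  mask <- stats::runif(length(d)) < rate
  d[mask] <- NA_integer_
  genotype_panel(d, panel$loci, population = panel$population,
                 samples = panel$samples)
}

#' Write a simulated fixture to disk
#'
#' Emits the panel as VCF + population TSV (via [write_panel()]) plus
#' per-locus and per-sample truth TSVs and a key=value record of the
#' generating configuration. [load_panel()] on the VCF round-trips.
#'
#' @param sim result of [simulate_panel()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "panel.vcf"),
    populations = file.path(out_dir, "populations.tsv"),
    truth_loci = file.path(out_dir, "truth_loci.tsv"),
    truth_samples = file.path(out_dir, "truth_samples.tsv"),
    config = file.path(out_dir, "sim_config.txt"))
  write_panel(sim$panel, paths["vcf"], paths["populations"])
  utils::write.table(sim$truth$loci, paths["truth_loci"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, paths["truth_samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0(names(sim$config), "=",
                    vapply(sim$config, format, character(1))),
             paths["config"])
  invisible(paths)
}
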