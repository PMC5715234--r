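#' Construct a genotype panel
#'
#' A `genotype_panel` is the central container of the package: a samples x
#' loci matrix of alt-allele dosages (0, 1, 2, or `NA` for a missing call)
#' together with locus coordinates and a population label per sample.
#'
#' @param dosage integer matrix, samples in rows, loci in columns. Missing
#'   calls are `NA` (never a numeric 0). Row names are sample ids, column
#'   names locus ids; if absent they are taken from `samples`/`loci`.
#' @param loci data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`. One row per column of `dosage`, same order.
#' @param population named character vector mapping sample id to population
#'   label. Samples absent from the map are labelled `"unassigned"`.
#' @param samples optional character vector of sample ids (defaults to
#'   `rownames(dosage)`).
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `loci`, `samples`, `population`.
#' @export
genotype_panel <- function(dosage, loci, population = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) samples <- rownames(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  needed <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols))
    stop("loci table lacks column(s): ", paste(missing_cols, collapse = ", "))
  loci <- loci[needed]
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  if (nrow(loci) != ncol(dosage))
    stop("dosage has ", ncol(dosage), " columns but loci table has ",
         nrow(loci), " rows")
  if (length(samples) != nrow(dosage))
    stop("dosage has ", nrow(dosage), " rows but ", length(samples),
         " sample ids given")
  if (anyDuplicated(loci$id))
    stop("locus ids are not unique")
  if (anyDuplicated(samples))
    stop("sample ids are not unique")
  if (any(loci$pos < 1L, na.rm = TRUE))
    stop("locus positions must be >= 1 (1-based)")
  if (any(loci$ref == loci$alt))
    stop("ref and alt allele identical at some locus")
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad))
    stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(samples, loci$id)
  pop <- rep("unassigned", length(samples))
  names(pop) <- samples
  if (!is.null(population)) {
    population <- vapply(population, as.character, character(1))
    known <- intersect(samples, names(population))
    pop[known] <- population[known]
  }
  structure(
    list(dosage = dosage, loci = loci, samples = samples, population = pop),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat("genotype_panel: ", length(x$samples), " samples x ",
      nrow(x$loci), " loci\n", sep = "")
  cat("  chromosomes: ", length(unique(x$loci$chrom)),
      "; missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  tab <- table(x$population)
  cat("  populations: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a panel by samples and/or loci
#'
#' @param panel a `genotype_panel`.
#' @param samples sample ids, logical or integer index (default: all).
#' @param loci locus ids, logical or integer index (default: all).
#' @return A new `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, loci = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(samples)) seq_along(panel$samples) else samples
  li <- if (is.null(loci)) seq_len(nrow(panel$loci)) else loci
  if (is.character(si)) si <- match(si, panel$samples)
  if (is.character(li)) li <- match(li, panel$loci$id)
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(li)) stop("unknown locus id in subset")
  genotype_panel(panel$dosage[si, li, drop = FALSE],
                 panel$loci[li, , drop = FALSE],
                 population = panel$population,
                 samples = panel$samples[si])
}

# Resolve a subset argument (NULL, population label, or sample id vector)
# to a vector of sample indices.
resolve_subset <- function(panel, subset) {
  if (is.null(subset)) return(seq_along(panel$samples))
  if (length(subset) == 1L && subset %in% panel$population) {
    return(which(panel$population == subset))
  }
  idx <- match(subset, panel$samples)
  if (anyNA(idx)) {
    if (length(subset) == 1L)
      stop("unknown population label or sample id: ", subset)
    stop("unknown sample id(s): ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  if (!length(idx)) stop("empty sample subset")
  idx
}
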