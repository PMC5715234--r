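#' Load a SNP genotype panel from VCF or a genotype table
#'
#' Reads diploid biallelic SNP genotypes into a [genotype_panel()]. VCF input
#' is parsed with \pkg{vcfR}; phased and unphased genotypes are treated
#' identically and dosage is the count of alt alleles. A genotype table is a
#' tab-delimited file with one row per locus, columns `id`, `chrom`, `pos`,
#' `ref`, `alt` followed by one column per sample; calls may be nucleotide
#' pairs ("AA", "AT", "TA"), slash/pipe pairs ("0/1", "1|0"), or dosages
#' (0/1/2); "NN", "--", "./.", "" and "NA" are missing.
#'
#' @param path path to the genotype file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"genotype_table"`.
#' @param populations either a path to a two-column TSV (sample, population)
#'   or a named character vector. Samples without an entry get a warning and
#'   the label `"unassigned"`.
#' @param multiallelic `"drop"` (default) removes records with more than one
#'   alternate allele; `"error"` aborts on them.
#' @return A `genotype_panel`.
#' @export
load_panel <- function(path, format = c("auto", "vcf", "genotype_table"),
                       populations = NULL, multiallelic = c("drop", "error")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "genotype_table"
  }
  pop <- read_population_map(populations)
  panel <- switch(format,
    vcf = read_panel_vcf(path, multiallelic),
    genotype_table = read_panel_table(path, multiallelic)
  )
  unknown <- setdiff(panel$samples, names(pop))
  if (!is.null(pop) && length(unknown))
    warning(length(unknown), " sample(s) absent from population map, ",
            "labelled 'unassigned'")
  genotype_panel(panel$dosage, panel$loci, population = pop,
                 samples = panel$samples)
}

read_population_map <- function(populations) {
  if (is.null(populations)) return(NULL)
  if (is.character(populations) && length(populations) == 1L &&
      file.exists(populations)) {
    tab <- utils::read.table(populations, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("sample", "population"))
    out <- tab$population
    names(out) <- tab$sample
    return(out)
  }
  if (is.null(names(populations)))
    stop("inline population map must be a named vector (sample -> label)")
  populations
}

read_panel_vcf <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt)
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !multi
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s) in ", path)
  }
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  loci <- data.frame(id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  dosage <- matrix(gt_string_to_dosage(as.vector(gt)),
                   nrow = nrow(gt), ncol = ncol(gt))
  dosage <- t(dosage)  # samples x loci
  rownames(dosage) <- colnames(gt)
  list(dosage = dosage, loci = loci, samples = colnames(gt))
}

# "0/1", "1|0", "0/0", "./.", NA -> alt-allele count or NA
gt_string_to_dosage <- function(g) {
  g <- sub(":.*$", "", g)
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g) & grepl("^[01][/|][01]$", g)
  out[ok] <- (g[ok] %in% c("0/1", "1/0", "0|1", "1|0")) * 1L +
    (g[ok] %in% c("1/1", "1|1")) * 2L
  hap <- !is.na(g) & g %in% c("0", "1")  # haploid-style call
  out[hap] <- 2L * (g[hap] == "1")
  out
}

read_panel_table <- function(path, multiallelic) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(tab)))
    stop("genotype table must begin with columns: ",
         paste(needed, collapse = ", "))
  samples <- setdiff(names(tab), needed)
  if (!length(samples)) stop("genotype table has no sample columns")
  multi <- grepl(",", tab$alt)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s) in ", path)
    tab <- tab[!multi, , drop = FALSE]
  }
  loci <- tab[needed]
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(tab),
                   dimnames = list(samples, loci$id))
  for (j in seq_len(nrow(tab))) {
    calls <- as.character(unlist(tab[j, samples], use.names = FALSE))
    dosage[, j] <- call_to_dosage(calls, loci$ref[j], loci$alt[j],
                                  line = j, path = path)
  }
  list(dosage = dosage, loci = loci, samples = samples)
}

# One locus worth of textual calls -> dosage vector.
call_to_dosage <- function(calls, ref, alt, line = NA, path = "") {
  out <- rep(NA_integer_, length(calls))
  calls <- trimws(calls)
  missing_codes <- c("NN", "--", "./.", ".|.", ".", "", "NA")
  is_missing <- is.na(calls) | calls %in% missing_codes
  numeric_like <- !is_missing & calls %in% c("0", "1", "2")
  out[numeric_like] <- as.integer(calls[numeric_like])
  gtlike <- !is_missing & grepl("^[01][/|][01]$", calls)
  out[gtlike] <- gt_string_to_dosage(calls[gtlike])
  pair <- !is_missing & !numeric_like & !gtlike & nchar(calls) == 2L
  if (any(pair)) {
    a1 <- substr(calls[pair], 1, 1)
    a2 <- substr(calls[pair], 2, 2)
    valid <- a1 %in% c(ref, alt) & a2 %in% c(ref, alt)
    if (any(!valid))
      stop("malformed genotype call '", calls[pair][!valid][1],
           "' at locus row ", line, " of ", path)
    out[pair] <- (a1 == alt) + (a2 == alt)
  }
  unparsed <- !is_missing & !numeric_like & !gtlike & nchar(calls) != 2L
  if (any(unparsed))
    stop("malformed genotype call '", calls[unparsed][1],
         "' at locus row ", line, " of ", path)
  out
}

#' Write a panel to disk
#'
#' Emits a minimal VCF v4.2 file (GT field only) plus a two-column
#' population TSV. `load_panel()` on the output reproduces the dosage
#' matrix, coordinates and labels exactly.
#'
#' @param panel a `genotype_panel`.
#' @param vcf_path output VCF path.
#' @param pop_path optional output population TSV path.
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, vcf_path, pop_path = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  loci <- panel$loci
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=soypopdiv",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  d <- t(panel$dosage)  # loci x samples
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  body <- paste(loci$chrom, loci$pos, loci$id, loci$ref, loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  if (!is.null(pop_path)) {
    utils::write.table(
      data.frame(sample = panel$samples,
                 population = unname(panel$population[panel$samples])),
      pop_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(c(vcf = vcf_path, populations = pop_path))
}

#' Remove loci with too many missing calls
#'
#' Drops every locus whose missing-call fraction is strictly greater than
#' `max_missing` (a locus at exactly the threshold is retained), mirroring
#' the convention of discarding markers with missing data in more than a
#' given share of accessions.
#'
#' @param panel a `genotype_panel`.
#' @param max_missing maximum tolerated missing fraction, default 0.20.
#' @return A list with elements `panel` (the filtered panel) and `report`,
#'   a one-row data frame with `n_input_loci`, `n_removed_loci`,
#'   `n_retained_loci`, `percent_retained`, plus attribute
#'   `missing_fraction` (per input locus).
#' @export
filter_missingness <- function(panel, max_missing = 0.20) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$loci) == 0L) stop("empty panel")
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(panel$dosage))
  keep <- miss <= max_missing
  report <- data.frame(
    n_input_loci = length(keep),
    n_removed_loci = sum(!keep),
    n_retained_loci = sum(keep),
    percent_retained = 100 * sum(keep) / length(keep)
  )
  attr(report, "missing_fraction") <- stats::setNames(miss, panel$loci$id)
  list(panel = subset_panel(panel, loci = which(keep)), report = report)
}

#' Per-locus allele frequencies over a sample subset
#'
#' Frequencies use non-missing calls only: alt frequency is the total alt
#' dosage divided by twice the number of called genotypes.
#'
#' @param panel a `genotype_panel`.
#' @param subset `NULL` (all samples), a population label, or a vector of
#'   sample ids.
#' @return Data frame with one row per locus: `id`, `chrom`, `pos`,
#'   `n_called` (genotypes), `alt_freq`, `maf`. Loci with no called
#'   genotype in the subset have `NA` frequencies.
#' @export
allele_frequencies <- function(panel, subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- resolve_subset(panel, subset)
  d <- panel$dosage[idx, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE) / (2 * n_called)
  alt[n_called == 0L] <- NA_real_
  data.frame(id = panel$loci$id, chrom = panel$loci$chrom,
             pos = panel$loci$pos, n_called = n_called,
             alt_freq = alt, maf = pmin(alt, 1 - alt),
             row.names = NULL)
}
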