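test_that("the allele-difference t statistic follows the printed formula", {
  # hand evaluation: f1=.8, f2=.2, n1=n2=100 -> fexp=.5, t=12
  r <- allele_diff_test(0.8, 0.2, 100, 100)
  expect_equal(r$fexp, 0.5)
  expect_equal(r$t, 12)
  expect_equal(r$diff, 0.6)
  # equal frequencies -> t = 0, P = 1 (also at the degenerate boundary)
  r0 <- allele_diff_test(c(0.3, 0, 1), c(0.3, 0, 1), 50, 60)
  expect_equal(r0$t, c(0, 0, 0))
  expect_equal(r0$p_value, c(1, 1, 1))
  expect_equal(r0$neglog10_p, c(0, 0, 0))
  # fexp sits between f1 and f2
  set.seed(14)
  f1 <- runif(50); f2 <- runif(50)
  rr <- allele_diff_test(f1, f2, 277, 300)
  expect_true(all(rr$fexp >= pmin(f1, f2) & rr$fexp <= pmax(f1, f2)))
})

test_that("t is antisymmetric and -log10 P increases with |f1 - f2|", {
  a <- allele_diff_test(0.7, 0.25, 277, 300)
  b <- allele_diff_test(0.25, 0.7, 300, 277)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
  # monotone in |f1-f2| at fixed fexp and n: move symmetrically about .5
  deltas <- seq(0.05, 0.45, by = 0.05)
  nl <- allele_diff_test(0.5 + deltas, 0.5 - deltas, 277, 300)$neglog10_p
  expect_true(all(diff(nl) > 0))
})

test_that("log-space tails match the arbitrary-precision oracle", {
  # frozen oracle: two-sided Student-t tail at df = 2*277 + 2*300 - 2,
  # computed with 60-digit arithmetic (regularized incomplete beta)
  df <- 2 * 277 + 2 * 300 - 2
  oracle_t <- c(`5` = 6.178958442, `12` = 30.61857243,
                `26` = 116.915163, `30` = 145.8679227)
  # construct (f1, f2) pairs with pooled fexp exactly 0.5 despite n1 != n2
  se <- sqrt((1 / (2 * 277) + 1 / (2 * 300)) * 0.25)
  for (tv in as.numeric(names(oracle_t))) {
    D <- tv * se
    r <- allele_diff_test(0.5 + 300 * D / 577, 0.5 - 277 * D / 577,
                          277, 300)
    expect_equal(r$t, tv, tolerance = 1e-9)
    expect_equal(r$neglog10_p, oracle_t[[as.character(tv)]],
                 tolerance = 1e-5)
  }
  # finite and monotone far beyond double-precision underflow
  nl <- allele_diff_test(c(0.9, 0.95, 0.99), c(0.1, 0.05, 0.01),
                         277, 300)$neglog10_p
  expect_true(all(is.finite(nl)))
  expect_true(all(diff(nl) > 0))
  expect_gt(max(nl), 140)  # the regime of strongly diverged loci
  # 1-df chi-square upper tail oracle (EigenGWAS PGC path)
  oracle_chisq <- c(`6.63` = 1.998806184, `100` = 22.81702341,
                    `500` = 110.0220297, `1600` = 349.1359765)
  for (x in as.numeric(names(oracle_chisq))) {
    nlp <- -pchisq(x, 1, lower.tail = FALSE, log.p = TRUE) / log(10)
    expect_equal(nlp, oracle_chisq[[as.character(x)]], tolerance = 1e-3)
  }
})

test_that("population-specific alleles require absence plus significance", {
  # carrier frequency high enough to clear alpha = 0.001
  n1 <- 277; n2 <- 300
  d <- matrix(0L, n1 + n2, 3)
  pop <- rep(c("CN", "US"), c(n1, n2))
  # locus 1: alt present in CN at ~0.094, absent in US
  d[1:52, 1] <- 1L
  # locus 2: alt is a singleton in CN -> fails the significance gate
  d[1, 2] <- 1L
  # locus 3: ref-allele specificity (alt fixed in US, not in CN)
  d[, 3] <- 2L
  d[1:52, 3] <- 1L
  p <- make_panel(d, pop = pop)
  hits <- population_specific_alleles(p, "CN", "US")
  expect_true("L1" %in% hits$id)
  expect_false("L2" %in% hits$id)
  expect_true("L3" %in% hits$id)
  l1 <- hits[hits$id == "L1", ]
  expect_equal(l1$carrier_group, "CN")
  expect_equal(l1$freq_carrier, 52 / (2 * 277), tolerance = 1e-12)
  # monomorphic locus in both groups is never flagged
  expect_false("L2" %in% hits$id)
  # singleton P-value really is above the gate
  pv <- allele_diff_test(1 / (2 * 277), 0, 277, 300)$p_value
  expect_gt(pv, 0.001)
})

test_that("EigenGWAS GRM is standardized and the scan finds planted loci", {
  # standardization identity: on a Hardy-Weinberg panel the GRM trace
  # (sum of all eigenvalues) is about n
  hwe <- simulate_panel(sim_config(n1 = 40, n2 = 40, n_loci = 500,
                                   background_F = 0, n_selected = 0,
                                   inbreeding = 0, admixed_fraction = 0,
                                   missing_rate = 0, seed = 23))
  full <- eigengwas(hwe$panel, k_top = 80)
  expect_equal(sum(full$eigenvalues), 80, tolerance = 0.1)
  sim <- shared_sim()
  eg <- eigengwas(sim$panel)
  expect_gt(eg$lambda_gc, 0)
  # focal eigenvector separates the populations by sign
  ev1 <- eg$vectors[, eg$focal_k]
  pop <- sim$panel$population
  side <- ev1 > 0
  concord <- max(mean(side == (pop == "pop1")),
                 mean(side == (pop == "pop2")))
  expect_gte(concord, 0.9)
  # planted loci dominate the smallest corrected P-values
  planted <- sim$truth$loci$id[sim$truth$loci$outlier]
  top <- eg$scan$id[order(eg$scan$pgc)][seq_len(2 * length(planted))]
  expect_gte(mean(planted %in% top), 0.8)
})

test_that("a majority of loci reach P < 1e-6 at study-scale divergence", {
  sim <- simulate_panel(sim_config(n1 = 277, n2 = 300, n_loci = 1200,
                                   background_F = 0.1933, n_selected = 0,
                                   missing_rate = 0, seed = 29))
  af1 <- allele_frequencies(sim$panel, "pop1")
  af2 <- allele_frequencies(sim$panel, "pop2")
  tst <- allele_diff_test(af1$alt_freq, af2$alt_freq,
                          af1$n_called, af2$n_called)
  expect_gt(mean(tst$p_value < 1e-6, na.rm = TRUE), 0.5)
})

test_that("lambda_GC is near 1 without structure", {
  sim <- simulate_panel(sim_config(n1 = 100, n2 = 100, n_loci = 2000,
                                   background_F = 0, n_selected = 0,
                                   admixed_fraction = 0, missing_rate = 0,
                                   seed = 17))
  eg <- eigengwas(sim$panel)
  expect_gt(eg$lambda_gc, 0.8)
  expect_lt(eg$lambda_gc, 1.2)
})

test_that("candidate ranking is deterministic with positional tie-breaks", {
  fst <- data.frame(id = c("a", "b", "c"), chrom = c("2", "1", "1"),
                    pos = c(10L, 500L, 20L), a = 1, b = 1, c = 0,
                    theta = c(0.9, 0.5, 0.5))
  tscan <- data.frame(id = c("a", "b", "c"), abs_diff = c(0.9, 0.6, 0.6),
                      neglog10_p = c(300, 100, 100))
  escan <- data.frame(id = c("a", "b", "c"), chisq = c(900, 200, 200),
                      neglog10_pgc = c(250, 60, 60))
  rc <- rank_candidates(fst, tscan, escan, top_n = 3)
  expect_equal(rc$id[1], "a")              # unanimous first
  expect_equal(rc$id[2:3], c("c", "b"))    # tie broken by (chrom, pos)
  expect_equal(rc$rank, 1:3)
})

test_that("FST and EigenGWAS ranks agree on simulated data", {
  sim <- shared_sim()
  fst <- wc_fst(sim$panel)
  eg <- eigengwas(sim$panel)
  shared <- intersect(fst$id[!is.na(fst$theta)], eg$scan$id)
  rho <- cor(rank(-fst$theta[match(shared, fst$id)]),
             rank(-eg$scan$chisq[match(shared, eg$scan$id)]),
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("interval overlap is half-open and matches brute force", {
  cand <- data.frame(id = c("a", "b", "c"), chrom = c("1", "1", "2"),
                     pos = c(100L, 150L, 75L))
  ann <- data.frame(chrom = c("1", "2", "1"), start = c(50L, 50L, 600L),
                    end = c(150L, 100L, 700L),
                    label = c("q1", "q2", "q3"))
  out <- interval_overlap(cand, ann)
  expect_equal(out$annotations, c("q1", "", "q2"))  # 150 excluded: half-open
  # random loci vs random intervals against an all-pairs double loop
  set.seed(19)
  cand2 <- data.frame(id = paste0("x", 1:60),
                      chrom = sample(c("1", "2"), 60, TRUE),
                      pos = sample.int(1000, 60))
  ann2 <- data.frame(chrom = sample(c("1", "2"), 30, TRUE),
                     start = sample.int(900, 30),
                     end = 0L, label = paste0("iv", 1:30))
  ann2$end <- ann2$start + sample.int(200, 30)
  got <- interval_overlap(cand2, ann2)
  for (i in seq_len(nrow(cand2))) {
    hits <- character()
    for (j in seq_len(nrow(ann2))) {
      if (cand2$chrom[i] == ann2$chrom[j] &&
          ann2$start[j] <= cand2$pos[i] && cand2$pos[i] < ann2$end[j])
        hits <- c(hits, ann2$label[j])
    }
    expect_equal(got$annotations[i], paste(hits, collapse = ","))
  }
  # malformed intervals skipped with a warning
  bad <- rbind(ann, data.frame(chrom = "1", start = 100L, end = 100L,
                               label = "degenerate"))
  expect_warning(interval_overlap(cand, bad), "malformed")
})
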