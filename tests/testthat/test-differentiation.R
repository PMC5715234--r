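test_that("W-C components match the brute-force transcription", {
  # 2 populations x 5 individuals, worked genotype table with a het and
  # a missing call
  d <- rbind(c(0L, 1L, 2L),
             c(0L, 1L, 2L),
             c(1L, 0L, 2L),
             c(0L, 0L, 1L),
             c(0L, NA, 2L),
             c(2L, 2L, 0L),
             c(2L, 1L, 0L),
             c(1L, 2L, 0L),
             c(2L, 2L, 1L),
             c(2L, 2L, NA))
  pop <- rep(c("A", "B"), each = 5)
  p <- make_panel(d, pop = pop)
  fst <- wc_fst(p)
  for (l in 1:3) {
    oracle <- wc_oracle_from_dosage(d, pop, l)
    expect_equal(fst$a[l], oracle[["a"]], tolerance = 1e-12)
    expect_equal(fst$b[l], oracle[["b"]], tolerance = 1e-12)
    expect_equal(fst$c[l], oracle[["c"]], tolerance = 1e-12)
    expect_equal(fst$theta[l], sum(oracle["a"]) / sum(oracle),
                 tolerance = 1e-12)
  }
})

test_that("theta hits the boundary cases", {
  # fixed difference: p1 = 1, p2 = 0, no heterozygotes -> theta = 1
  d <- rbind(matrix(2L, 4, 2), matrix(0L, 4, 2))
  p <- make_panel(d, pop = rep(c("A", "B"), each = 4))
  expect_equal(wc_fst(p)$theta, c(1, 1))
  # identical frequencies and heterozygosity, large n -> theta ~ 0
  set.seed(12)
  g <- as.integer(rbinom(400, 2, 0.4))
  d2 <- cbind(g, sample(g))
  p2 <- make_panel(d2, pop = rep(c("A", "B"), each = 200))
  expect_lt(abs(multilocus_fst(wc_fst(p2))), 0.02)
  # monomorphic across groups -> undefined
  d3 <- cbind(matrix(0L, 6, 1), matrix(c(0L, 1L), 6, 1))
  p3 <- make_panel(d3, pop = rep(c("A", "B"), each = 3))
  expect_true(is.na(wc_fst(p3)$theta[1]))
})

test_that("theta is invariant to group and allele relabeling", {
  sim <- shared_sim()
  p <- subset_panel(sim$panel, loci = 1:100)
  f1 <- wc_fst(p)
  swapped <- setNames(ifelse(p$population == "pop1", "pop2", "pop1"),
                      names(p$population))
  f2 <- wc_fst(p, groups = swapped)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
  d <- p$dosage
  d[, 1] <- 2L - d[, 1]
  f3 <- wc_fst(make_panel(d, chrom = p$loci$chrom, pos = p$loci$pos,
                          pop = unname(p$population)))
  expect_equal(f1$theta, f3$theta, tolerance = 1e-12)
})

test_that("multilocus theta is the ratio of sums, not the mean of ratios", {
  # locus 1: fixed difference; locus 2: weak divergence with heterozygotes
  # (unequal component denominators, so the two aggregates must differ)
  d <- cbind(c(0L, 0L, 0L, 2L, 2L, 2L), c(0L, 1L, 1L, 1L, 2L, 1L))
  p <- make_panel(d, pop = rep(c("A", "B"), each = 3))
  fst <- wc_fst(p)
  ml <- multilocus_fst(fst)
  by_hand_ratio_of_sums <- sum(fst$a) / sum(fst$a + fst$b + fst$c)
  expect_equal(ml, by_hand_ratio_of_sums)
  expect_false(isTRUE(all.equal(ml, mean(fst$theta))))
  expect_equal(multilocus_fst(fst[1, ]), fst$theta[1])
})

test_that("AMOVA percentages sum to 100 and Phi agrees with theta", {
  sim <- simulate_panel(sim_config(n1 = 60, n2 = 60, n_loci = 500,
                                   background_F = 0.19, n_selected = 0,
                                   inbreeding = 1, admixed_fraction = 0,
                                   missing_rate = 0, seed = 13))
  am <- amova(sim$panel, n_permutations = 99, seed = 1)
  expect_equal(sum(am$components$percent), 100)
  expect_lt(am$p_value, 0.05)
  theta <- multilocus_fst(wc_fst(sim$panel))
  expect_equal(am$phi_st, theta, tolerance = 0.01)
})

test_that("AMOVA permutation P is reproducible and seeded", {
  sim <- shared_sim()
  p <- subset_panel(sim$panel, samples = c(1:15, 101:115), loci = 1:100)
  a1 <- amova(p, n_permutations = 49, seed = 7)
  a2 <- amova(p, n_permutations = 49, seed = 7)
  expect_equal(a1$p_value, a2$p_value)
  a3 <- amova(p, n_permutations = 0)
  expect_true(is.na(a3$p_value))
})

test_that("window membership follows the half-open tiling from 1", {
  fst <- data.frame(id = "x", chrom = "1", pos = 95000L,
                    a = 1, b = 1, c = 0, theta = 0.5)
  win <- sliding_window_fst(fst, window = 1e5, step = 1e4)
  expect_equal(nrow(win), 10L)
  expect_equal(win$start, 1 + (0:9) * 1e4)
  expect_true(all(win$end - win$start == 1e5))
  expect_true(all(win$theta == 0.5))
  # boundary: pos = end is excluded (half-open)
  fst2 <- data.frame(id = "y", chrom = "1", pos = 100001L,
                     a = 1, b = 0, c = 0, theta = 1)
  win2 <- sliding_window_fst(fst2, window = 1e5, step = 1e4)
  expect_false(1 %in% win2$start)       # [1, 100001) excludes 100001
  expect_true(10001 %in% win2$start)
})

test_that("planted high-F loci surface in the top windows", {
  sim <- shared_sim()
  fst <- wc_fst(sim$panel)
  win <- outlier_windows(sliding_window_fst(fst))
  planted <- sim$truth$loci[sim$truth$loci$outlier, ]
  covered <- vapply(seq_len(nrow(planted)), function(i) {
    w <- win[win$chrom == planted$chrom[i] &
             win$start <= planted$pos[i] &
             planted$pos[i] < win$end, ]
    any(w$outlier)
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("the outlier tie rule includes all cutoff-tied windows", {
  w <- data.frame(chrom = "1", start = 1, end = 2,
                  n_loci = 1, theta = seq(0.01, 1, length.out = 100))
  expect_equal(sum(outlier_windows(w)$outlier), 5L)
  w2 <- w
  w2$theta <- seq(0.01, 0.5, length.out = 100)  # low background
  w2$theta[1:10] <- 0.99  # ties spanning the cutoff
  w2$theta[11:12] <- 1
  expect_gte(sum(outlier_windows(w2)$outlier), 5L)
  expect_equal(sum(outlier_windows(w2)$outlier), 12L)
  # doubling the fraction doubles the flags on distinct values
  expect_equal(sum(outlier_windows(w, 0.10)$outlier), 10L)
})
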