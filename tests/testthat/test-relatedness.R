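test_that("Rogers distance matches hand values on constructed genotypes", {
  # identical samples; opposite homozygotes; AA vs Aa at one locus
  d <- rbind(c(0L, 0L, 0L),
             c(0L, 0L, 0L),
             c(2L, 2L, 2L),
             c(1L, 0L, 0L))
  D <- distance_matrix(make_panel(d))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)          # opposite homozygotes at every locus
  expect_equal(D[1, 4], 0.5 / 3)    # sqrt(.5*(.25+.25)) = 0.5 at 1 of 3 loci
  d1 <- matrix(c(0L, 1L), nrow = 2)
  expect_equal(distance_matrix(make_panel(d1))[1, 2], 0.5)
  # allele_sharing coincides for biallelic data
  expect_equal(distance_matrix(make_panel(d), "allele_sharing"), D,
               ignore_attr = TRUE)
})

test_that("Rogers distance is a bounded semimetric on simulated panels", {
  sim <- shared_sim()
  p <- subset_panel(sim$panel, samples = 1:40)
  D <- distance_matrix(p)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diag(D) == 0))
  # triangle inequality on random triples
  set.seed(8)
  for (k in 1:50) {
    ijk <- sample(nrow(D), 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("kinship matches a brute-force transcription of the estimator", {
  sim <- shared_sim()
  p <- subset_panel(sim$panel, samples = c(1:6, 101:106), loci = 1:60)
  K <- loiselle_kinship(p)
  # naive per-pair loop, straight from the formula
  d <- p$dosage
  n_called <- colSums(!is.na(d))
  pl <- colSums(d, na.rm = TRUE) / (2 * n_called)
  use <- n_called >= 2 & !is.na(pl)
  kin_naive <- function(i, j) {
    num <- den <- 0
    for (l in which(use)) {
      if (is.na(d[i, l]) || is.na(d[j, l])) next
      xi <- d[i, l] / 2; xj <- d[j, l] / 2
      nl <- 2 * n_called[l]
      for (freq in c(pl[l], 1 - pl[l])) {   # both alleles
        pi_ <- if (freq == pl[l]) xi else 1 - xi
        pj_ <- if (freq == pl[l]) xj else 1 - xj
        num <- num + (pi_ - freq) * (pj_ - freq) +
          freq * (1 - freq) / (nl - 1)
        den <- den + freq * (1 - freq)
      }
    }
    max(num / den, 0)
  }
  for (pair in list(c(1, 2), c(1, 8), c(5, 12), c(3, 3))) {
    expect_equal(K[pair[1], pair[2]], kin_naive(pair[1], pair[2]),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(K))
  expect_true(all(K >= 0))
})

test_that("within-population kinship exceeds between-population kinship", {
  sim <- shared_sim()
  K <- loiselle_kinship(sim$panel)
  pop <- sim$panel$population
  same <- outer(pop, pop, "==")
  ut <- upper.tri(K)
  expect_gt(mean(K[ut & same]), mean(K[ut & !same]))
})

test_that("neighbor joining recovers additive trees", {
  # 4-taxon additive matrix with split (a,b)|(c,d); oracle enumerates the
  # three unrooted topologies via the four-point condition
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  # tree: a-1-x, b-2-x, x-3-y, c-4-y, d-5-y
  D["a", "b"] <- 1 + 2; D["a", "c"] <- 1 + 3 + 4; D["a", "d"] <- 1 + 3 + 5
  D["b", "c"] <- 2 + 3 + 4; D["b", "d"] <- 2 + 3 + 5; D["c", "d"] <- 4 + 5
  D <- D + t(D)
  sums <- c(ab_cd = D["a", "b"] + D["c", "d"],
            ac_bd = D["a", "c"] + D["b", "d"],
            ad_bc = D["a", "d"] + D["b", "c"])
  expect_equal(names(which.min(sums)), "ab_cd")  # oracle: true split
  tr <- neighbor_joining(D / 10)  # keep entries in [0,1]
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_true(ape::is.monophyletic(tr, c("c", "d")))
  # 3 taxa: branch lengths solve the three-point equations
  D3 <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  bl <- setNames(t3$edge.length[match(seq_len(3), t3$edge[, 2])],
                 t3$tip.label)
  expect_equal(bl[["x"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(bl[["y"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(bl[["z"]], (0.4 + 0.5 - 0.3) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3")
})

test_that("the NJ tree contains a split matching population labels", {
  sim <- shared_sim()
  D <- distance_matrix(sim$panel)
  tr <- neighbor_joining(D)
  pop <- sim$panel$population
  # some internal-edge bipartition separates the two populations for
  # >= 90% of samples
  internal <- which(tr$edge[, 2] > length(tr$tip.label))
  concord <- vapply(internal, function(e) {
    clade <- ape::extract.clade(tr, tr$edge[e, 2])$tip.label
    side <- names(which.max(table(pop[clade])))
    (sum(pop[clade] == side) +
       sum(pop[setdiff(tr$tip.label, clade)] != side)) / length(pop)
  }, numeric(1))
  expect_gte(max(concord), 0.90)
})

test_that("distance distributions partition all pairs", {
  sim <- shared_sim()
  p <- subset_panel(sim$panel, samples = c(1:10, 101:110))
  D <- distance_matrix(p)
  dd <- distance_distribution(D, p$population)
  n <- nrow(D)
  expect_equal(sum(dd$summary$n_pairs), n * (n - 1) / 2)
  expect_gt(dd$summary$mean[dd$summary$set == "between"],
            max(dd$summary$mean[dd$summary$set != "between"]))
  # histogram counts sum to pair counts
  for (s in dd$summary$set) {
    expect_equal(sum(dd$histograms[[s]]$counts),
                 dd$summary$n_pairs[dd$summary$set == s])
  }
  # single-member group yields an empty within set
  g <- setNames(c("solo", rep("rest", n - 1)), rownames(D))
  dd2 <- distance_distribution(D, g)
  expect_equal(dd2$summary$n_pairs[dd2$summary$set == "solo"], 0L)
})
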