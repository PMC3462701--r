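test_that("locus heterozygosity matches direct formula arithmetic", {
  expect_equal(locus_heterozygosity(c(a = 40)), 0)  # monomorphic
  expect_equal(locus_heterozygosity(c(a = 20, b = 20)), (40 / 39) * 0.5,
               tolerance = 1e-12)
  # four equifrequent alleles, large n: tends to 1 - 4 (1/4)^2 = 0.75
  big <- locus_heterozygosity(rep(1e6, 4))
  expect_equal(big, 0.75, tolerance = 1e-5)
  expect_equal(locus_heterozygosity(c(30, 10), unbiased = FALSE),
               1 - (0.75^2 + 0.25^2), tolerance = 1e-12)
  expect_true(is.na(locus_heterozygosity(integer(0))))
  expect_error(locus_heterozygosity(c(10, 10), n_genotyped = 7), "twice")
})

test_that("heterozygosity is invariant to allele relabeling", {
  set.seed(14)
  for (i in 1:20) {
    cnt <- rmultinom(1, 40, prob = runif(5))[, 1]
    names(cnt) <- 1:5
    relab <- cnt[sample(5)]
    names(relab) <- 1:5
    expect_equal(locus_heterozygosity(cnt), locus_heterozygosity(relab),
                 tolerance = 1e-12)
  }
})

test_that("population diversity matches hand-tabulated allele counting", {
  # printed 5-individual fixture, 2 loci, incl. one missing genotype
  info <- data.frame(id = paste0("i", 1:5), population = "M1",
                     habitat = "marine")
  a1 <- cbind(LocA = c(1L, 1L, 2L, 3L, 1L), LocB = c(2L, 2L, 2L, NA, 2L))
  a2 <- cbind(LocA = c(1L, 2L, 2L, 3L, 2L), LocB = c(2L, 1L, 2L, NA, 2L))
  g <- genotype_dataset(info, a1, a2)
  d <- population_diversity(g)
  # LocA alleles: 1 x4, 2 x4, 3 x2 of 10; unbiased correction 10/9
  pA <- c(4, 4, 2) / 10
  hA <- (10 / 9) * (1 - sum(pA^2))
  # LocB alleles over 4 genotyped individuals: 1 x1, 2 x7 of 8
  pB <- c(1, 7) / 8
  hB <- (8 / 7) * (1 - sum(pB^2))
  expect_equal(d$locus_h$H_E[d$locus_h$locus == "LocA"], hA,
               tolerance = 1e-12)
  expect_equal(d$locus_h$H_E[d$locus_h$locus == "LocB"], hB,
               tolerance = 1e-12)
  expect_equal(d$locus_h$n[d$locus_h$locus == "LocB"], 4)
  expect_equal(d$pop_summary$mean_h, mean(c(hA, hB)), tolerance = 1e-12)
})

test_that("identical homozygotes give zero diversity", {
  info <- data.frame(id = paste0("i", 1:4), population = "P1",
                     habitat = "pond")
  a <- cbind(LocA = rep(2L, 4), LocB = rep(5L, 4))
  d <- population_diversity(genotype_dataset(info, a, a))
  expect_equal(d$pop_summary$mean_h, 0)
})

test_that("unbiased estimator recovers 2pq under HWE sampling", {
  set.seed(27)
  n <- 20
  est <- replicate(2000, {
    k <- rbinom(1, 2 * n, 0.3)
    locus_heterozygosity(c(k, 2 * n - k))
  })
  expect_equal(mean(est), 2 * 0.3 * 0.7, tolerance = 0.01)
})

test_that("estimator is consistent on simulated HWE genotypes", {
  set.seed(41)
  n <- 200
  a1 <- cbind(L1 = sample(1:2, n, TRUE))
  a2 <- cbind(L1 = sample(1:2, n, TRUE))
  info <- data.frame(id = as.character(1:n), population = "M1",
                     habitat = "marine")
  d <- population_diversity(genotype_dataset(info, a1, a2))
  expect_equal(d$pop_summary$mean_h, 0.5, tolerance = 0.05)
})

test_that("habitat standardization equalizes habitat means exactly", {
  v <- c(M1 = 0.52, M2 = 0.64, P1 = 0.20, P2 = 0.40)
  hab <- c(M1 = "marine", M2 = "marine", P1 = "pond", P2 = "pond")
  s <- habitat_standardize(v, hab)
  expect_equal(as.numeric(tapply(s, hab, mean)), c(0.44, 0.44),
               tolerance = 1e-12)
  # idempotence
  expect_equal(habitat_standardize(s, hab), s, tolerance = 1e-12)
  # within-habitat differences and rank order preserved exactly
  expect_equal(s["M2"] - s["M1"], c(M2 = 0.12), tolerance = 1e-12)
  expect_equal(s["P2"] - s["P1"], c(P2 = 0.20), tolerance = 1e-12)
  # single habitat / all-equal: unchanged
  v1 <- c(A = 0.3, B = 0.5)
  expect_equal(habitat_standardize(v1, c(A = "pond", B = "pond")), v1)
  v2 <- c(M1 = 0.4, P1 = 0.4)
  expect_equal(habitat_standardize(v2, c(M1 = "marine", P1 = "pond")), v2)
  expect_error(habitat_standardize(c(X = 1), c(Y = "pond")),
               "without habitat")
})
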