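test_that("DA screen: no flags on perfectly symmetric data, per-cell t", {
  left <- matrix(rep(c(5L, 9L), each = 20), 20, 2,
                 dimnames = list(NULL, c("t1", "t2")))
  ds <- make_bilateral(left, left, population = rep("M1", 20),
                       habitat = rep("marine", 20))
  out <- da_screen(ds)
  expect_true(all(!out$flagged))
  expect_true(all(is.na(out$t)))  # zero variance: t undefined, not flagged
  expect_equal(attr(out, "summary")$n_tested, 0)
})

test_that("DA screen t/p agree with stats::t.test on a nondegenerate cell", {
  set.seed(5)
  left <- matrix(rpois(40, 10), 20, 2, dimnames = list(NULL, c("t1", "t2")))
  right <- left + matrix(sample(c(-1L, 0L, 1L, 2L), 40, TRUE), 20, 2)
  ds <- make_bilateral(left, pmax(right, 0L),
                       population = rep("M1", 20),
                       habitat = rep("marine", 20))
  out <- da_screen(ds)
  d <- (ds$left - ds$right)[, "t1"]
  tt <- t.test(d, mu = 0)
  expect_equal(out$t[out$trait == "t1"], unname(tt$statistic),
               tolerance = 1e-12)
  expect_equal(out$p[out$trait == "t1"], tt$p.value, tolerance = 1e-12)
})

test_that("DA screen detects a 2-sigma directional shift at n = 20", {
  sig <- 0.5
  delta <- 2 * sig * sqrt(2)  # two SDs of the signed side difference
  shift <- matrix(0, 8, 12, dimnames = list(
    c(paste0("M", 1:4), paste0("P", 1:4)), default_traits()))
  shift["P1", "DH"] <- delta
  cfg <- simulation_config(sigma_di = c(marine = sig, pond = sig),
                           da_shift = shift, seed = 17)
  out <- da_screen(simulate_counts(cfg))
  cell <- out[out$population == "P1" & out$trait == "DH", ]
  expect_true(cell$flagged)
  expect_lt(cell$p, 0.001)
})

test_that("dip statistic reproduces hand-derivable exact values", {
  expect_equal(dip_statistic(c(0, 1)), 0.25)          # two equal atoms
  expect_equal(dip_statistic(c(rep(0, 5), rep(1, 15))), 5 / 40)
  expect_equal(dip_statistic(rep(3, 10)), 0)           # degenerate
  expect_equal(dip_statistic(1:10), 1 / 20, tolerance = 1e-6)
  expect_equal(dip_statistic(1:4), 1 / 8, tolerance = 1e-6)
  set.seed(8)
  x <- rnorm(30)
  d <- dip_statistic(x)
  expect_gte(d, 1 / 60 - 1e-6)
  expect_lte(d, 0.25 + 1e-6)
})

test_that("dip separates bimodal from unimodal samples", {
  set.seed(9)
  d_uni <- replicate(60, dip_statistic(rnorm(20)))
  d_bi <- replicate(60, dip_statistic(c(rnorm(10, -3, 0.3),
                                        rnorm(10, 3, 0.3))))
  expect_gt(median(d_bi), 1.4 * median(d_uni))
  # dip-test false positive rate under a unimodal null stays near alpha
  p_null <- replicate(150, dip_test(rnorm(20))$p_value)
  expect_lte(mean(p_null < 0.05), 0.08)
})

test_that("AS screen flags an antisymmetric mixture and not pure FA", {
  delta <- matrix(0, 8, 12, dimnames = list(
    c(paste0("M", 1:4), paste0("P", 1:4)), default_traits()))
  delta["P2", "IO"] <- 3
  cfg <- simulation_config(sigma_di = c(marine = 0.3, pond = 0.3),
                           antisym_delta = delta, seed = 23)
  out <- as_screen(simulate_counts(cfg))
  cell <- out[out$population == "P2" & out$trait == "IO", ]
  expect_true(cell$flagged)
  expect_lt(cell$excess_kurtosis, -1)
})

test_that("AS screen reports constant-difference cells as degenerate", {
  left <- matrix(rep(c(5L, 9L), each = 12), 12, 2,
                 dimnames = list(NULL, c("t1", "t2")))
  ds <- make_bilateral(left, left, population = rep("M1", 12),
                       habitat = rep("marine", 12))
  out <- as_screen(ds)
  expect_true(all(is.na(out$excess_kurtosis)))
  expect_true(all(!out$flagged))
})

test_that("repeatability is 1 for identical recounts, ~0 for shuffled", {
  cfg <- simulation_config(recount_error_prob = 0, seed = 31)
  ds <- simulate_counts(cfg)
  out <- repeatability(ds)
  expect_equal(out$R, rep(1, 12))
  expect_true(all(out$p == 0))
  # shuffled recounts: second-session differences unrelated to the first
  set.seed(99)
  perm <- sample(nrow(ds$info))
  ds2 <- bilateral_dataset(ds$info, ds$left, ds$right,
                           ds$left[perm, ], ds$right[perm, ])
  out2 <- repeatability(ds2)
  expect_true(all(abs(out2$R) < 0.3))
})

test_that("repeatability matches an aov-based ICC on a perturbed fixture", {
  set.seed(12)
  left <- matrix(rpois(40, 12), 20, 2, dimnames = list(NULL, c("t1", "t2")))
  right <- left + matrix(sample(-1:1, 40, TRUE), 20, 2)
  left2 <- left; right2 <- right
  left2[1, ] <- left2[1, ] + 1L  # one individual's diff perturbed by +1
  ds <- make_bilateral(left, pmax(right, 0L), population = rep("M1", 20),
                       habitat = rep("marine", 20),
                       left2 = left2, right2 = pmax(right2, 0L))
  out <- repeatability(ds)
  for (tr in c("t1", "t2")) {
    d1 <- (ds$left - ds$right)[, tr]
    d2 <- (ds$left2 - ds$right2)[, tr]
    long <- data.frame(y = c(d1, d2), ind = factor(rep(1:20, 2)))
    ms <- anova(aov(y ~ ind, data = long))
    R_oracle <- (ms["ind", "Mean Sq"] - ms["Residuals", "Mean Sq"]) /
      (ms["ind", "Mean Sq"] + ms["Residuals", "Mean Sq"])
    expect_equal(out$R[out$trait == tr], R_oracle, tolerance = 1e-10)
    expect_gt(out$R[out$trait == tr], 0)
    expect_lt(out$R[out$trait == tr], 1)
  }
  expect_warning(repeatability(simulate_counts(
    simulation_config(seed = 1))[c("info", "left", "right", "trait_names")] |>
      (\(x) bilateral_dataset(x$info, x$left, x$right))()),
    "no recounts")
})
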