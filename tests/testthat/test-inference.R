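test_that("spearman_pair handles monotone and constant inputs", {
  x <- 1:6
  expect_equal(spearman_pair(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_pair(x, rev(x))$rho, -1)
  r <- spearman_pair(x, rep(1, 6))
  expect_true(is.na(r$rho) && r$method == "undefined")
  expect_error(spearman_pair(1:5, 1:4), "paired")
  expect_error(spearman_pair(c(1, NA, 3, 4), c(1, 2, 3, 4)), "missing")
})

test_that("exact permutation p at n = 5 matches full 120-term enumeration", {
  set.seed(55)
  for (i in 1:4) {
    x <- rnorm(5)
    y <- sample(c(rnorm(4), x[2]))  # allow occasional ties in ranks
    sp <- spearman_pair(x, y)
    expect_equal(sp$method, "exact_permutation")
    all_r <- enumerate_perm_rho(x, y)
    expect_equal(sp$p, mean(abs(all_r) >= abs(sp$rho) - 1e-10),
                 tolerance = 1e-12)
    sp1 <- spearman_pair(x, y, sidedness = "one_sided")
    brute1 <- if (sp1$rho >= 0) mean(all_r >= sp1$rho - 1e-10)
              else mean(all_r <= sp1$rho + 1e-10)
    expect_equal(sp1$p, brute1, tolerance = 1e-12)
  }
})

test_that("exact p at n = 8 agrees with a random-permutation oracle", {
  x <- 1:8
  y <- c(8, 7, 6, 5, 4, 2, 3, 1)  # reversed with one swap
  sp <- spearman_pair(x, y)
  expect_equal(sp$method, "exact_permutation")
  set.seed(77)
  rx <- rank(x); ry <- rank(y)
  mc <- replicate(10000, abs(cor(rx, sample(ry))) >= abs(sp$rho) - 1e-10)
  # exact value must sit inside the Monte-Carlo binomial interval
  ci <- binom.test(sum(mc), length(mc))$conf.int
  expect_gte(sp$p, ci[1])
  expect_lte(sp$p, ci[2])
})

test_that("fa_glmm with no between-population variance reproduces the
           fixed-effects type III ANOVA", {
  set.seed(61)
  n_per <- 10
  info <- data.frame(
    population = rep(c("M1", "M2", "P1", "P2"), each = n_per),
    habitat = rep(c("marine", "pond"), each = 2 * n_per),
    sex = rep(c("male", "female"), 2 * n_per))
  e <- rnorm(4 * n_per)
  # remove population-mean deviations so the REML variance component is 0
  e <- e - ave(e, info$population) + ave(e, info$habitat)
  y <- 2 + 3 * (info$habitat == "pond") + 0.5 * (info$sex == "male") + e
  rep_ <- fa_glmm(y, info, eliminate = FALSE, random_test = "none",
                  ls_means = FALSE)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ habitat * sex, data = info)
  oracle <- car::Anova(fit, type = "III")
  for (tm in c("habitat", "sex", "habitat:sex")) {
    expect_equal(rep_$terms$statistic[rep_$terms$term == tm],
                 oracle[tm, "F value"], tolerance = 1e-6)
  }
})

test_that("backward elimination respects the term hierarchy", {
  set.seed(71)
  for (i in 1:5) {
    cfg <- simulation_config(n_populations_per_habitat = 2,
                             n_individuals = 12, seed = 100 + i)
    ds <- simulate_counts(cfg)
    am <- suppressWarnings(asymmetry_matrix(ds))
    het <- setNames(runif(4, 0.2, 0.8), unique(ds$info$population))
    r <- fa_glmm(am$csra, am$info, heterozygosity = het,
                 random_test = "none", ls_means = FALSE)
    kept <- r$terms$term[r$terms$statistic_name == "F"]
    path <- r$elimination_path$term
    # a term is retained xor eliminated, never both
    expect_length(intersect(kept, path), 0)
    expect_setequal(union(kept, path),
                    c("habitat", "sex", "het", "habitat:sex", "habitat:het"))
    # main effects never leave before interactions containing them
    if ("habitat:sex" %in% kept)
      expect_true(all(c("habitat", "sex") %in% kept))
    if ("habitat:het" %in% kept)
      expect_true(all(c("habitat", "het") %in% kept))
    for (mn in c("habitat", "sex", "het")) {
      ints <- grep(":", union(kept, path), value = TRUE)
      ints <- ints[grepl(mn, ints)]
      if (mn %in% path && length(ints)) {
        ipos <- match(intersect(path, ints), path)
        expect_true(all(ipos < match(mn, path)))
      }
    }
  }
})

test_that("p-values are invariant to population relabeling", {
  cfg <- simulation_config(n_populations_per_habitat = 2,
                           n_individuals = 15, seed = 83)
  ds <- simulate_counts(cfg)
  am <- suppressWarnings(asymmetry_matrix(ds))
  r1 <- fa_glmm(am$csra, am$info, random_test = "none", ls_means = FALSE,
                eliminate = FALSE)
  info2 <- am$info
  relab <- c(M1 = "Zeta", M2 = "Alpha", P1 = "Kappa", P2 = "Beta")
  info2$population <- unname(relab[info2$population])
  r2 <- fa_glmm(am$csra, info2, random_test = "none", ls_means = FALSE,
                eliminate = FALSE)
  expect_equal(r1$terms$p, r2$terms$p, tolerance = 1e-8)
})

test_that("het_glmm refuses degenerate designs", {
  lh <- data.frame(population = rep(c("M1", "M2", "P1", "P2"), each = 1),
                   locus = "L1", H_E = c(0.5, 0.6, 0.2, 0.3),
                   habitat = rep(c("marine", "pond"), each = 2))
  expect_error(het_glmm(lh), "2 loci")
  lh2 <- data.frame(population = rep(c("M1", "P1"), each = 3),
                    locus = rep(paste0("L", 1:3), 2),
                    H_E = runif(6),
                    habitat = rep(c("marine", "pond"), each = 3))
  expect_error(het_glmm(lh2), "2 populations per habitat")
})

test_that("het GLM post hoc isolates a low-diversity population", {
  set.seed(19)
  pops <- c(paste0("M", 1:4), paste0("P", 1:4))
  lh <- expand.grid(population = pops, locus = paste0("L", 1:23),
                    stringsAsFactors = FALSE)
  lh$H_E <- pmin(pmax(rnorm(nrow(lh), 0.6, 0.12), 0), 1)
  low <- lh$population == "P3"  # one near-monomorphic population
  lh$H_E[low] <- abs(rnorm(sum(low), 0.02, 0.02))
  r <- het_glm_posthoc(lh)
  expect_lt(r$terms$p[r$terms$term == "population"], 0.001)
  others <- setdiff(pops, "P3")
  expect_true(all(r$posthoc["P3", others] < 0.05))
  # structural properties of the p matrix
  expect_equal(r$posthoc, t(r$posthoc))
  expect_equal(unname(diag(r$posthoc)), rep(1, 8))
  # two statistically identical populations are rarely separated
  expect_gt(min(r$posthoc[others, others][upper.tri(diag(7))]), 0.001)
})

test_that("sra_manova flags habitat and follows up per trait", {
  cfg <- simulation_config(sigma_di = calibrate_di_ratio(3), seed = 3)
  am <- suppressWarnings(asymmetry_matrix(simulate_counts(cfg)))
  r <- sra_manova(am)
  hab <- r$terms[r$terms$term == "habitat", ]
  expect_equal(hab$statistic_name, "Wilks_lambda")
  expect_lt(hab$p, 0.001)
  uni <- r$terms[grepl("^habitat\\[", r$terms$term), ]
  expect_equal(nrow(uni), 12)
  expect_gte(sum(uni$p < 0.05), 10)
})

test_that("sra_manova drops linearly dependent traits with a warning", {
  cfg <- simulation_config(n_populations_per_habitat = 2,
                           n_individuals = 20, seed = 29)
  am <- suppressWarnings(asymmetry_matrix(simulate_counts(cfg)))
  dup <- am$sra[, rep("PP", 4)]
  colnames(dup) <- paste0("copy", 1:4)
  fake <- list(info = am$info, sra = cbind(am$sra[, 1:3], dup),
               retained_traits = c(colnames(am$sra)[1:3],
                                   paste0("copy", 1:4)))
  expect_warning(r <- sra_manova(fake), "rank-deficient")
  expect_lt(length(r$traits_used), 7)
})
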