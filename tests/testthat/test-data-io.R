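test_that("count table round-trips field-exactly, including recounts", {
  cfg <- simulation_config(n_populations_per_habitat = 2, n_individuals = 5,
                           seed = 11)
  ds <- simulate_counts(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(ds, f)
  back <- read_count_table(f)
  expect_identical(back$info, ds$info)
  expect_identical(back$left, ds$left)
  expect_identical(back$right, ds$right)
  expect_identical(back$left2, ds$left2)
  expect_identical(back$right2, ds$right2)
  expect_identical(back$trait_names, ds$trait_names)
})

test_that("a two-row table with 12 traits parses into 2 individuals", {
  left <- matrix(5L, 2, 12, dimnames = list(NULL, default_traits()))
  ds <- make_bilateral(left, left, population = c("M1", "P1"),
                       habitat = c("marine", "pond"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(ds, f)
  back <- read_count_table(f)
  expect_equal(nrow(back$info), 2)
  expect_equal(back$trait_names, default_traits())
})

test_that("invalid counts and headers produce named errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,population,habitat,sex,PP_L,PP_R",
               "a,M1,marine,male,-1,2"), f)
  expect_error(read_count_table(f), "negative count")
  writeLines(c("id,population,habitat,sex,PP_L,PP_R",
               "a,M1,marine,male,1.5,2"), f)
  expect_error(read_count_table(f), "whole numbers")
  writeLines(c("id,population,habitat,PP_L,PP_R",
               "a,M1,marine,1,2"), f)
  expect_error(read_count_table(f), "sex")
  writeLines(c("id,population,habitat,sex,PP_L,PP_R",
               "a,M1,marine,male,1,2",
               "b,M1,pond,male,1,2"), f)
  expect_error(read_count_table(f), "more than one habitat")
})

test_that("a 160-row 8-population design reads back as 8 populations", {
  cfg <- simulation_config(seed = 4)  # 4 + 4 populations x 20 individuals
  ds <- simulate_counts(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(ds, f)
  back <- read_count_table(f)
  expect_equal(nrow(back$info), 160)
  expect_equal(length(unique(back$info$population)), 8)
  expect_equal(sort(unique(back$info$habitat)), c("marine", "pond"))
})

test_that("genepop fixture parses: blocks, loci and missing codes", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(genepop_fixture_lines(), f)
  g <- read_genotypes(f, dialect = "genepop")
  expect_equal(nrow(g$info), 6)
  expect_equal(g$locus_names, c("LocA", "LocB"))
  expect_equal(unique(g$info$population), c("Pop1", "Pop2"))
  # 000000 -> both alleles missing at that locus
  expect_true(is.na(g$a1[3, "LocB"]) && is.na(g$a2[3, "LocB"]))
  expect_equal(unname(g$a1[1, "LocA"]), 1L)
  expect_equal(unname(g$a2[1, "LocB"]), 3L)
})

test_that("genotype table round-trips and genepop re-reads identically", {
  cfg <- simulation_config(n_populations_per_habitat = 2, n_individuals = 4,
                           n_loci = 23, seed = 9)
  g <- simulate_genotypes(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, f, dialect = "table")
  back <- read_genotypes(f, dialect = "table")
  expect_identical(back$info, g$info)
  expect_identical(back$a1, g$a1)
  expect_identical(back$a2, g$a2)
  expect_equal(length(back$locus_names), 23)
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genotypes(g, f2, dialect = "genepop")
  hab <- setNames(g$info$habitat, g$info$population)
  back2 <- read_genotypes(f2, dialect = "genepop",
                          pop_habitat = hab,
                          pop_names = unique(g$info$population))
  expect_identical(back2$a1, g$a1)
  expect_identical(back2$a2, g$a2)
  expect_identical(back2$info$population, g$info$population)
})

test_that("unknown dialect and malformed allele columns error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,population,LocA_1,LocA_2,LocB_1",
               "a,M1,1,2,1"), f)
  expect_error(read_genotypes(f, dialect = "table"), "odd number")
  expect_error(read_genotypes(f, dialect = "vcf"), "dialect")
})

test_that("write_report writes one CSV per stage plus a manifest", {
  d <- withr::local_tempdir()
  out <- write_report(list(a = data.frame(x = 1:2),
                           b = data.frame(y = c(0.5, 2.25))),
                      d, manifest = list(seed = 1))
  expect_true(file.exists(file.path(d, "a.csv")))
  expect_true(file.exists(file.path(d, "b.csv")))
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  # empty report: manifest only
  d2 <- withr::local_tempdir()
  write_report(list(), d2)
  expect_equal(list.files(d2), "manifest.yaml")
})
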