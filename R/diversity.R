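#' Expected heterozygosity at one locus
#'
#' Nei's gene diversity from sample allele counts. The default unbiased
#' (small-sample corrected) estimator is
#' \deqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_k p_k^2\right)}
#' with `p_k` the sample allele frequencies and `n` the number of genotyped
#' individuals, matching the "gene diversity" convention of standard
#' population-genetics software. A monomorphic locus has diversity 0.
#'
#' @param allele_counts named (or unnamed) non-negative integer vector of
#'   allele counts at the locus.
#' @param n_genotyped number of genotyped diploid individuals; defaults to
#'   `sum(allele_counts)/2`.
#' @param unbiased apply the `2n/(2n-1)` correction (default `TRUE`).
#' @return Expected heterozygosity, or `NA` when no individual is genotyped.
#' @export
locus_heterozygosity <- function(allele_counts, n_genotyped = NULL,
                                 unbiased = TRUE) {
  allele_counts <- allele_counts[!is.na(allele_counts)]
  total <- sum(allele_counts)
  if (is.null(n_genotyped)) n_genotyped <- total / 2
  if (n_genotyped == 0 || total == 0) return(NA_real_)
  if (total != 2 * n_genotyped)
    stop("allele counts must sum to twice the number of genotyped individuals")
  p <- allele_counts / total
  h <- 1 - sum(p^2)
  if (unbiased) h <- h * (2 * n_genotyped) / (2 * n_genotyped - 1)
  h
}

#' Per-locus and per-population expected heterozygosity
#'
#' Tabulates alleles cell-wise (per locus within population, missing
#' genotypes excluded per cell) and applies [locus_heterozygosity()], then
#' averages over loci within populations. Standard errors are reported both
#' across loci within a population and across populations within a habitat.
#'
#' @param genotypes a [genotype_dataset()].
#' @param unbiased passed to [locus_heterozygosity()].
#' @return An object of class `diversity_table`: list with
#'   `locus_h` (data frame: `population`, `locus`, `n`, `H_E`),
#'   `pop_summary` (data frame: `population`, `habitat`, `mean_h`,
#'   `se_across_loci`, `n_loci`) and `habitat_summary` (data frame:
#'   `habitat`, `mean_h`, `se_across_populations`, `n_populations`;
#'   only populations with a habitat label contribute).
#' @export
population_diversity <- function(genotypes, unbiased = TRUE) {
  stopifnot(inherits(genotypes, "genotype_dataset"))
  pops <- unique(genotypes$info$population)
  loci <- genotypes$locus_names
  locus_h <- do.call(rbind, lapply(pops, function(p) {
    sel <- genotypes$info$population == p
    do.call(rbind, lapply(seq_along(loci), function(j) {
      a <- c(genotypes$a1[sel, j], genotypes$a2[sel, j])
      a <- a[!is.na(a)]
      n <- length(a) / 2
      h <- if (n == 0) NA_real_ else
        locus_heterozygosity(table(a), n_genotyped = n, unbiased = unbiased)
      data.frame(population = p, locus = loci[j], n = n, H_E = h)
    }))
  }))
  rownames(locus_h) <- NULL
  hab_of <- tapply(genotypes$info$habitat, genotypes$info$population,
                   function(h) h[1])
  pop_summary <- do.call(rbind, lapply(pops, function(p) {
    h <- locus_h$H_E[locus_h$population == p]
    h <- h[!is.na(h)]
    data.frame(population = p, habitat = unname(hab_of[p]),
               mean_h = mean(h),
               se_across_loci = stats::sd(h) / sqrt(length(h)),
               n_loci = length(h))
  }))
  rownames(pop_summary) <- NULL
  with_hab <- pop_summary[!is.na(pop_summary$habitat), ]
  habitat_summary <- if (nrow(with_hab)) {
    do.call(rbind, lapply(split(with_hab, with_hab$habitat), function(g) {
      data.frame(habitat = g$habitat[1], mean_h = mean(g$mean_h),
                 se_across_populations =
                   stats::sd(g$mean_h) / sqrt(nrow(g)),
                 n_populations = nrow(g))
    }))
  } else NULL
  if (!is.null(habitat_summary)) rownames(habitat_summary) <- NULL
  structure(list(locus_h = locus_h, pop_summary = pop_summary,
                 habitat_summary = habitat_summary),
            class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, ...) {
  cat("Expected heterozygosity (Nei gene diversity)\n")
  print(x$pop_summary, row.names = FALSE)
  if (!is.null(x$habitat_summary)) {
    cat("\nHabitat means:\n")
    print(x$habitat_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Standardize population values to a common habitat mean
#'
#' Removes the between-habitat mean difference from population-level values
#' by shifting each habitat to the unweighted grand mean over populations:
#' `x - habitat_mean + grand_mean`. Within-habitat differences and rank
#' order are preserved exactly, and the operation is idempotent. Used to ask
#' whether an across-population correlation survives once the habitat
#' contrast is removed.
#'
#' @param pop_values named numeric vector of per-population values.
#' @param habitat_of named character vector mapping population to habitat.
#' @return Named numeric vector of standardized values; every habitat's mean
#'   equals the grand mean.
#' @export
habitat_standardize <- function(pop_values, habitat_of) {
  if (is.null(names(pop_values)))
    stop("pop_values must be named by population")
  hab <- habitat_of[names(pop_values)]
  if (any(is.na(hab)))
    stop("population(s) without habitat label: ",
         paste(names(pop_values)[is.na(hab)], collapse = ", "))
  grand <- mean(pop_values)
  hm <- tapply(as.numeric(pop_values), as.character(hab), mean)
  stats::setNames(
    as.numeric(pop_values) - as.numeric(hm[as.character(hab)]) + grand,
    names(pop_values))
}
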