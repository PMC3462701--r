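#' Spearman rank correlation with exact small-sample permutation p
#'
#' Computes Spearman's rho on average ranks. For `n <= exact_max_n` the
#' p-value is exact: the full permutation null distribution of
#' `S = sum(rank(x) * rank(y))` is computed by dynamic programming over
#' subsets of assigned ranks (equivalent to enumerating all `n!`
#' permutations, ties handled through half-integer average ranks). Larger
#' samples use the usual t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, no missing values.
#' @param sidedness `"two_sided"` (default) or `"one_sided"`; the one-sided
#'   p is taken in the direction of the observed statistic.
#' @param exact_max_n largest n for which the exact permutation null is
#'   enumerated.
#' @return An object of class `correlation_result`: list with `rho`, `p`,
#'   `n`, `sidedness`, `method` (`"exact_permutation"`,
#'   `"t_approximation"`, or `"undefined"` when an input is constant, in
#'   which case `rho` and `p` are `NA`).
#' @export
spearman_pair <- function(x, y, sidedness = c("two_sided", "one_sided"),
                          exact_max_n = 10) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) stop("x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  res <- function(rho, p, method)
    structure(list(rho = rho, p = p, n = n, sidedness = sidedness,
                   method = method), class = "correlation_result")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(res(NA_real_, NA_real_, "undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    null_rho <- .spearman_null_rho(rx, ry)
    tot <- sum(null_rho$count)
    p <- if (sidedness == "two_sided") {
      sum(null_rho$count[abs(null_rho$rho) >= abs(rho) - 1e-10]) / tot
    } else if (rho >= 0) {
      sum(null_rho$count[null_rho$rho >= rho - 1e-10]) / tot
    } else {
      sum(null_rho$count[null_rho$rho <= rho + 1e-10]) / tot
    }
    return(res(rho, p, "exact_permutation"))
  }
  tv <- rho * sqrt((n - 2) / (1 - rho^2))
  p1 <- stats::pt(-abs(tv), n - 2)
  p <- if (sidedness == "two_sided") 2 * p1 else p1
  res(rho, p, "t_approximation")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d, %s, %s)\n",
              x$rho, x$p, x$n, x$sidedness, x$method))
  invisible(x)
}

# exact permutation null of rho via subset DP on S = sum rx_i * ry_perm(i):
# ranks doubled to integers (handles half-integer average ranks); the DP
# state is the set of used y-ranks, holding a dense count vector over the
# achievable partial sums, so adding one product is a constant shift.
# Equivalent to enumerating all n! permutations; O(2^n * n * maxS) work.
.spearman_null_rho <- function(rx, ry) {
  n <- length(rx)
  a <- as.integer(round(2 * rx))
  b <- as.integer(round(2 * ry))
  maxS <- sum(sort(a) * sort(b))
  nbit <- 2L^n
  counts <- vector("list", nbit)
  counts[[1]] <- c(1, numeric(maxS))  # index s+1 holds count of sum s
  popcount <- integer(nbit)
  for (mask in 1:(nbit - 1))
    popcount[mask + 1] <- popcount[bitwShiftR(mask, 1) + 1] +
      bitwAnd(mask, 1L)
  for (mask in 0:(nbit - 2)) {
    cur <- counts[[mask + 1]]
    if (is.null(cur)) next
    i <- popcount[mask + 1] + 1L  # next x position to assign
    nz <- which(cur != 0)
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0) next
      add <- a[i] * b[j]
      nm <- mask + bit
      tgt <- counts[[nm + 1]]
      if (is.null(tgt)) tgt <- numeric(maxS + 1)
      tgt[nz + add] <- tgt[nz + add] + cur[nz]
      counts[[nm + 1]] <- tgt
    }
    counts[[mask + 1]] <- NA  # free memory
  }
  final <- counts[[nbit]]
  nz <- which(final != 0)
  S <- (nz - 1) / 4  # undo the x2 scaling of both rank sets
  mx <- mean(rx); my <- mean(ry)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  rho <- (S - n * mx * my) / ((n - 1) * sx * sy)
  list(rho = rho, count = final[nz])
}

#' Population-level asymmetry vs heterozygosity, raw and habitat-standardized
#'
#' The two-step correlation analysis that separates an across-habitat
#' confound from a genuine within-habitat association: Spearman correlation
#' of population mean composite asymmetry against (i) raw population mean
#' heterozygosity and (ii) heterozygosity standardized to a common mean
#' across habitats ([habitat_standardize()]). If asymmetry tracks
#' heterozygosity only because both differ by habitat, the raw correlation
#' is strong and the standardized one collapses toward zero.
#'
#' @param asym an `asymmetry_matrix` (per-individual composite values and
#'   population labels).
#' @param diversity a `diversity_table` with habitat labels.
#' @param sidedness passed to [spearman_pair()].
#' @return List with `raw` and `standardized` `correlation_result`s and
#'   `table`, the per-population values used (population, habitat,
#'   mean_csra, mean_h, std_h).
#' @export
fa_het_correlation_stage <- function(asym, diversity,
                                     sidedness = c("two_sided",
                                                   "one_sided")) {
  sidedness <- match.arg(sidedness)
  csra_pop <- tapply(asym$csra, asym$info$population,
                     function(v) mean(v, na.rm = TRUE))
  ps <- diversity$pop_summary
  if (any(is.na(ps$habitat)))
    stop("diversity table has population(s) without habitat label")
  common <- intersect(names(csra_pop), ps$population)
  if (length(common) < 4)
    stop("need at least 4 populations shared between asymmetry and ",
         "genotype data")
  h <- stats::setNames(ps$mean_h, ps$population)[common]
  hab <- stats::setNames(ps$habitat, ps$population)[common]
  fa <- csra_pop[common]
  sh <- habitat_standardize(h, hab)
  raw <- spearman_pair(fa, h, sidedness = sidedness)
  std <- spearman_pair(fa, sh, sidedness = sidedness)
  list(raw = raw, standardized = std,
       table = data.frame(population = common, habitat = unname(hab),
                          mean_csra = unname(fa), mean_h = unname(h),
                          std_h = unname(sh)))
}
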