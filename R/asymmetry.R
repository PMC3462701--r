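#' Relative asymmetry of a bilateral count pair
#'
#' The unsigned left-right difference scaled by trait size,
#' \deqn{RA = |L - R| / ((L + R)/2),}
#' so that a one-count difference weighs heavily in a trait counted in ones
#' or twos but negligibly in a trait counted in the hundreds. The signed
#' difference `L - R` is deliberately not taken here: it is kept separately
#' for the directional-asymmetry and antisymmetry screens.
#'
#' @param left,right non-negative integer counts (vectorized).
#' @param zero_pair policy for the degenerate `L = R = 0` pair: `"zero"`
#'   (default) reads symmetric absence of the structure as perfect symmetry
#'   and returns 0 with a warning; `"missing"` returns `NA`.
#' @return Numeric vector of RA values in `[0, 2]`; `NA` where either count
#'   is missing.
#' @export
relative_asymmetry <- function(left, right, zero_pair = c("zero", "missing")) {
  zero_pair <- match.arg(zero_pair)
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(left != floor(left), na.rm = TRUE) ||
      any(right != floor(right), na.rm = TRUE))
    stop("counts must be whole numbers")
  ra <- abs(left - right) / ((left + right) / 2)
  zz <- !is.na(left) & !is.na(right) & left == 0 & right == 0
  if (any(zz)) {
    if (zero_pair == "zero") {
      warning(sum(zz), " zero/zero count pair(s): RA set to 0 ",
              "(symmetric absence); use zero_pair = 'missing' to drop")
      ra[zz] <- 0
    } else {
      ra[zz] <- NA_real_
    }
  }
  ra
}

#' Standardize relative asymmetry per trait
#'
#' Divides each individual's RA by the trait's mean RA taken over all
#' individuals pooled across populations and habitats, putting traits with
#' different baseline asymmetry on a common scale (mean 1 per trait). Traits
#' whose mean RA is zero carry no asymmetry information and are dropped with
#' a warning.
#'
#' @param ra_matrix numeric matrix (individuals x traits) of RA values;
#'   `NA` allowed.
#' @param pooling `"pooled"` (default) computes each trait mean over all
#'   individuals; `"per_population"` standardizes within populations and
#'   requires `populations`.
#' @param populations character vector of population labels, used only for
#'   `pooling = "per_population"`.
#' @return List with `sra` (matrix), `trait_mean_ra` (named vector of the
#'   per-trait means used) and `retained_traits`.
#' @export
standardize_ra <- function(ra_matrix, pooling = c("pooled", "per_population"),
                           populations = NULL) {
  pooling <- match.arg(pooling)
  ra_matrix <- as.matrix(ra_matrix)
  if (nrow(ra_matrix) == 0 || all(is.na(ra_matrix)))
    stop("no RA values to standardize")
  tm <- colMeans(ra_matrix, na.rm = TRUE)
  retained <- colnames(ra_matrix)[!is.na(tm) & tm > 0]
  dropped <- setdiff(colnames(ra_matrix), retained)
  if (length(dropped))
    warning("trait(s) with zero mean RA dropped from the composite: ",
            paste(dropped, collapse = ", "))
  if (pooling == "pooled") {
    sra <- sweep(ra_matrix, 2, tm, "/")
  } else {
    if (is.null(populations) || length(populations) != nrow(ra_matrix))
      stop("per-population standardization needs one population label per row")
    sra <- ra_matrix
    for (p in unique(populations)) {
      rows <- populations == p
      pm <- colMeans(ra_matrix[rows, , drop = FALSE], na.rm = TRUE)
      sra[rows, ] <- sweep(ra_matrix[rows, , drop = FALSE], 2, pm, "/")
    }
  }
  sra[, dropped] <- NA_real_
  list(sra = sra, trait_mean_ra = tm, retained_traits = retained)
}

#' Composite standardized relative asymmetry for one individual
#'
#' Sums the standardized relative asymmetry values across the retained
#' traits, weighting every trait equally. With complete data the population
#' mean of the composite equals the number of retained traits (each SRA
#' column has mean 1).
#'
#' @param sra_row named numeric vector of SRA values for one individual.
#' @param retained_traits traits entering the composite.
#' @param missing policy when some retained traits are `NA`: `"rescale"`
#'   (default) multiplies the observed sum by
#'   `n_retained / n_observed` so composites stay comparable across
#'   individuals; `"complete"` returns `NA` unless all retained traits are
#'   observed.
#' @return A single non-negative number, or `NA` if no retained trait is
#'   observed.
#' @export
composite_index <- function(sra_row, retained_traits,
                            missing = c("rescale", "complete")) {
  missing <- match.arg(missing)
  v <- sra_row[retained_traits]
  obs <- !is.na(v)
  if (!any(obs)) return(NA_real_)
  if (missing == "complete" && !all(obs)) return(NA_real_)
  s <- sum(v[obs])
  if (missing == "rescale") s <- s * length(v) / sum(obs)
  s
}

#' Full asymmetry index chain for a dataset
#'
#' Computes signed differences, relative asymmetry (RA), trait-standardized
#' RA (SRA) and the per-individual composite (CSRA) in one pass.
#'
#' @param dataset a [bilateral_dataset()].
#' @param zero_pair passed to [relative_asymmetry()].
#' @param missing passed to [composite_index()].
#' @param pooling passed to [standardize_ra()].
#' @return An object of class `asymmetry_matrix`: list with `info`,
#'   `signed_diff`, `ra`, `sra` (matrices), `trait_mean_ra`,
#'   `retained_traits` and `csra` (named by individual id).
#' @export
asymmetry_matrix <- function(dataset, zero_pair = c("zero", "missing"),
                             missing = c("rescale", "complete"),
                             pooling = c("pooled", "per_population")) {
  stopifnot(inherits(dataset, "bilateral_dataset"))
  zero_pair <- match.arg(zero_pair)
  missing <- match.arg(missing)
  pooling <- match.arg(pooling)
  sd_ <- dataset$left - dataset$right
  ra <- matrix(relative_asymmetry(dataset$left, dataset$right,
                                  zero_pair = zero_pair),
               nrow = nrow(sd_), dimnames = dimnames(sd_))
  std <- standardize_ra(ra, pooling = pooling,
                        populations = dataset$info$population)
  csra <- apply(std$sra, 1, composite_index,
                retained_traits = std$retained_traits, missing = missing)
  names(csra) <- dataset$info$id
  structure(
    list(info = dataset$info, signed_diff = sd_, ra = ra, sra = std$sra,
         trait_mean_ra = std$trait_mean_ra,
         retained_traits = std$retained_traits, csra = csra,
         policies = list(zero_pair = zero_pair, missing = missing,
                         pooling = pooling)),
    class = "asymmetry_matrix")
}

#' @export
print.asymmetry_matrix <- function(x, ...) {
  cat("Asymmetry matrix (RA/SRA/CSRA)\n")
  cat("  individuals     :", nrow(x$info), "\n")
  cat("  retained traits :", length(x$retained_traits), "\n")
  cat("  mean CSRA       :", sprintf("%.3f", mean(x$csra, na.rm = TRUE)), "\n")
  invisible(x)
}
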