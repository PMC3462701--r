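#' Directional-asymmetry screen
#'
#' For every population x trait cell, tests the signed left-right differences
#' against a zero mean with a two-sided one-sample t-test. Under pure
#' fluctuating asymmetry the signed differences are centred on zero and about
#' a fraction `alpha` of cells flag by chance; a substantially larger flagged
#' fraction indicates directional asymmetry. No multiple-testing correction
#' is applied: the flagged fraction itself is the quantity compared with the
#' nominal level.
#'
#' @param dataset a [bilateral_dataset()].
#' @param alpha flagging level.
#' @return Data frame with one row per cell: `population`, `trait`, `n`,
#'   `mean_diff`, `t`, `df`, `p`, `flagged`. Cells with zero variance get
#'   `NA` statistics and are not flagged. The attribute `"summary"` holds
#'   the cell count, the number flagged and the flagged fraction (degenerate
#'   cells excluded from the denominator).
#' @export
da_screen <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "bilateral_dataset"), alpha > 0, alpha < 1)
  d <- dataset$left - dataset$right
  pops <- unique(dataset$info$population)
  traits <- dataset$trait_names
  rows <- vector("list", length(pops) * length(traits))
  r <- 0L
  for (p in pops) {
    sel <- dataset$info$population == p
    for (j in seq_along(traits)) {
      x <- d[sel, j]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n < 2) next
      r <- r + 1L
      m <- mean(x)
      s <- stats::sd(x)
      if (s == 0) {
        rows[[r]] <- data.frame(population = p, trait = traits[j], n = n,
                                mean_diff = m, t = NA_real_, df = n - 1L,
                                p = NA_real_, flagged = FALSE)
      } else {
        tv <- m / (s / sqrt(n))
        pv <- 2 * stats::pt(-abs(tv), df = n - 1)
        rows[[r]] <- data.frame(population = p, trait = traits[j], n = n,
                                mean_diff = m, t = tv, df = n - 1L, p = pv,
                                flagged = pv < alpha)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  rownames(out) <- NULL
  usable <- sum(!is.na(out$p))
  attr(out, "summary") <- list(
    n_cells = nrow(out), n_tested = usable, n_flagged = sum(out$flagged),
    flagged_fraction = if (usable > 0) sum(out$flagged) / usable else NA_real_,
    alpha = alpha)
  out
}

#' Antisymmetry screen
#'
#' Antisymmetry (one side consistently larger, but which side varies between
#' individuals) produces a platykurtic or bimodal distribution of signed
#' left-right differences. This screen formalizes the usual visual check:
#' a population x trait cell is flagged when the excess kurtosis of the
#' signed differences falls below `kurtosis_threshold`, or when Hartigan's
#' dip test rejects unimodality at `alpha`. The dip test needs a minimum
#' sample; smaller cells are screened on kurtosis alone. Note the kurtosis
#' arm with the default threshold is deliberately sensitive at n ~ 20
#' (its chance trigger rate under a normal is around 10%), so flags are
#' advisory prompts for inspection, not formal rejections.
#'
#' @param dataset a [bilateral_dataset()].
#' @param kurtosis_threshold excess-kurtosis flag threshold (default -1.0;
#'   an exact two-point antisymmetric mixture has excess kurtosis -2).
#' @param alpha dip-test flagging level.
#' @param min_n_dip smallest cell size for which the dip test is run.
#' @return Data frame with one row per cell: `population`, `trait`, `n`,
#'   `excess_kurtosis`, `dip`, `dip_p`, `flagged`. Cells with zero variance
#'   get `NA` statistics and are not flagged.
#' @export
as_screen <- function(dataset, kurtosis_threshold = -1.0, alpha = 0.05,
                      min_n_dip = 8) {
  stopifnot(inherits(dataset, "bilateral_dataset"))
  d <- dataset$left - dataset$right
  pops <- unique(dataset$info$population)
  traits <- dataset$trait_names
  rows <- list()
  for (p in pops) {
    sel <- dataset$info$population == p
    for (j in seq_along(traits)) {
      x <- d[sel, j]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n < 2) next
      if (stats::sd(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, trait = traits[j], n = n,
          excess_kurtosis = NA_real_, dip = NA_real_, dip_p = NA_real_,
          flagged = FALSE)
        next
      }
      k2 <- e1071::kurtosis(x, type = 2)
      if (n >= min_n_dip) {
        dt <- dip_test(x)
        dip <- dt$statistic; dip_p <- dt$p_value
      } else {
        dip <- NA_real_; dip_p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, trait = traits[j], n = n,
        excess_kurtosis = k2, dip = dip, dip_p = dip_p,
        flagged = (k2 < kurtosis_threshold) ||
          (!is.na(dip_p) && dip_p < alpha))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_cells = nrow(out), n_flagged = sum(out$flagged),
    kurtosis_threshold = kurtosis_threshold, alpha = alpha)
  out
}

#' Repeatability of signed left-right differences
#'
#' Quantifies counting error by the one-way intraclass correlation of the
#' signed difference between two independent counting sessions, with
#' individuals as groups:
#' \deqn{R = (MS_B - MS_W) / (MS_B + MS_W)}
#' for two sessions, with the ANOVA F-test p-value (`F = MS_B / MS_W` on
#' `n - 1`, `n` degrees of freedom). Identical recounts give R = 1 exactly;
#' recounts unrelated to the first counts give R near 0.
#'
#' @param dataset a [bilateral_dataset()] carrying recounts.
#' @return Data frame with one row per trait: `trait`, `n`, `R`, `F`, `p`.
#'   Empty (no-recount) input yields an empty table with a warning.
#' @export
repeatability <- function(dataset) {
  stopifnot(inherits(dataset, "bilateral_dataset"))
  if (is.null(dataset$left2)) {
    warning("dataset has no recounts; repeatability not estimable")
    return(data.frame(trait = character(0), n = integer(0), R = numeric(0),
                      F = numeric(0), p = numeric(0)))
  }
  d1 <- dataset$left - dataset$right
  d2 <- dataset$left2 - dataset$right2
  traits <- dataset$trait_names
  out <- lapply(seq_along(traits), function(j) {
    ok <- !is.na(d1[, j]) & !is.na(d2[, j])
    n <- sum(ok)
    if (n < 2)
      return(data.frame(trait = traits[j], n = n, R = NA_real_,
                        F = NA_real_, p = NA_real_))
    y1 <- as.numeric(d1[ok, j]); y2 <- as.numeric(d2[ok, j])
    gm <- (y1 + y2) / 2
    msw <- sum((y1 - gm)^2 + (y2 - gm)^2) / n
    msb <- 2 * sum((gm - mean(gm))^2) / (n - 1)
    if (msw == 0 && msb == 0) {
      # no variation anywhere: perfectly repeatable constant differences
      return(data.frame(trait = traits[j], n = n, R = 1, F = Inf, p = 0))
    }
    if (msw == 0) {
      return(data.frame(trait = traits[j], n = n, R = 1, F = Inf, p = 0))
    }
    R <- (msb - msw) / (msb + msw)
    Fv <- msb / msw
    p <- stats::pf(Fv, df1 = n - 1, df2 = n, lower.tail = FALSE)
    data.frame(trait = traits[j], n = n, R = R, F = Fv, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
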