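#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical distribution function and any unimodal distribution function
#' (convex below the mode, concave above it, with an atom allowed at the
#' mode). Large values indicate bimodality/multimodality; for a bilateral
#' trait, a bimodal signed left-right difference is the signature of
#' antisymmetry rather than fluctuating asymmetry.
#'
#' The statistic is computed from the definition: for a candidate distance
#' `d`, a unimodal CDF fits the ECDF within `d` if and only if, for some
#' placement of the mode, a nondecreasing convex function threads the
#' left-hand band, a concave one the right-hand band, and the two can be
#' joined monotonically at the mode (where the CDF may jump). The least
#' feasible `d` is found by bisection, so the result is exact to `tol`.
#'
#' @param x numeric vector (ties allowed).
#' @param tol bisection tolerance on the returned distance.
#' @return The dip statistic, a number in `[0, 0.25]`. A sample whose ECDF
#'   is itself unimodal (e.g. all values identical) has dip 0; `1/(2n)` is
#'   the minimum for `n` distinct values.
#' @export
dip_statistic <- function(x, tol = 1e-8) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) stop("no data")
  tab <- table(x)
  t_ <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  k <- length(t_)
  if (k == 1) return(0)
  if (k == 2) return(min(cnt) / (2 * n))  # two atoms p, 1-p: dip = min/2
  C <- cumsum(cnt)
  l <- C / n            # point lower anchor: band lower edge is l - d
  u <- (C - cnt) / n    # left-limit anchor: band upper edge is u + d
  lo <- 0
  hi <- 0.26
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.dip_feasible(t_, l, u, mid)) hi <- mid else lo <- mid
  }
  hi
}

# Left sweep: nondecreasing convex function through bands [lb, ub] at
# abscissae t_. E[j] is the tightest convex lower bound at point j induced
# by earlier band edges (chords from an upper edge through a later lower
# edge, extended); feas[j] says the prefix 1..j is threadable; Lmin[j] is
# the least achievable value at point j.
.dip_sweep <- function(t_, lb, ub) {
  k <- length(t_)
  E <- rep(-Inf, k)
  s <- rep(0, k)
  for (j in 2:k) {
    i <- seq_len(j - 1)
    s[j] <- max(0, (lb[j] - ub[i]) / (t_[j] - t_[i]))
    E[j] <- max(lb[i] + s[i] * (t_[j] - t_[i]))
  }
  feas <- cumprod(c(TRUE, E[-1] <= ub[-1] + 1e-12) &
                    (lb <= ub + 1e-12)) > 0
  list(E = E, feas = feas, Lmin = pmax(lb, E))
}

.dip_feasible <- function(t_, l, u, d) {
  k <- length(t_)
  tol <- 1e-12
  lb <- pmax(l - d, 0)
  ub <- pmin(u + d, 1)
  left <- .dip_sweep(t_, lb, ub)
  # right side mapped to a left sweep via the symmetry G -> 1 - G(-t)
  right <- .dip_sweep(-rev(t_), rev(1 - ub), rev(1 - lb))
  ridx <- function(kk) k - kk + 1
  # mode strictly between points m and m+1 (m = 0: all-concave;
  # m = k: all-convex)
  for (m in 0:k) {
    okL <- if (m == 0) TRUE else left$feas[m]
    if (!okL) next
    okR <- if (m == k) TRUE else right$feas[ridx(m + 1)]
    if (!okR) next
    e1 <- if (m == 0) 0 else left$Lmin[m]
    s2 <- if (m == k) 1 else 1 - right$Lmin[ridx(m + 1)]
    if (e1 <= s2 + tol) return(TRUE)
  }
  # mode at data point kk: the CDF may jump there, so the point's value band
  # relaxes to [l - d, l + d] and the left limit only needs to fit under
  # u + d while respecting convex propagation (E) from the prefix
  for (kk in seq_len(k)) {
    okL <- if (kk == 1) TRUE else left$feas[kk - 1]
    if (!okL) next
    pos <- ridx(kk)
    okR <- if (pos == 1) TRUE else
      (right$feas[pos - 1] &&
         right$E[pos] <= rev(1 - lb)[pos] + tol)
    if (!okR) next
    e_prev <- if (kk == 1) 0 else left$Lmin[kk - 1]
    e1 <- max(0, e_prev, left$E[kk], u[kk] - d)  # least left-limit value
    if (e1 > min(u[kk] + d, 1) + tol) next
    s2 <- min(min(l[kk] + d, 1), 1 - right$E[pos])  # max value after jump
    if (e1 <= s2 + tol) return(TRUE)
  }
  FALSE
}

#' Dip test of unimodality
#'
#' Monte-Carlo p-value for [dip_statistic()] against the uniform null (the
#' classical least-favourable unimodal reference). Null tables are simulated
#' once per sample size with a fixed internal seed and memoized, so p-values
#' are deterministic and the caller's RNG state is untouched.
#'
#' @param x numeric vector.
#' @param n_null number of null replicates for the reference table.
#' @return List with `statistic`, `p_value` and `n`.
#' @export
dip_test <- function(x, n_null = 500) {
  x <- x[!is.na(x)]
  n <- length(x)
  d <- dip_statistic(x)
  null <- .dip_null_table(n, n_null)
  p <- (1 + sum(null >= d - 1e-10)) / (length(null) + 1)
  list(statistic = d, p_value = p, n = n)
}

.dip_cache <- new.env(parent = emptyenv())

.dip_null_table <- function(n, n_null) {
  key <- paste0("n", n, "_B", n_null)
  if (!is.null(.dip_cache[[key]])) return(.dip_cache[[key]])
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(104729L + n)  # fixed internal seed: tables are reproducible
  tab <- vapply(seq_len(n_null),
                function(i) dip_statistic(stats::runif(n), tol = 1e-6),
                numeric(1))
  .dip_cache[[key]] <- tab
  tab
}
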