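#' One-way GLM on heterozygosity with Fisher LSD post hoc tests
#'
#' Fixed-effect one-way analysis of locus-wise expected heterozygosity with
#' population as the factor, followed by all pairwise Fisher LSD
#' comparisons: unadjusted t tests on the pooled ANOVA error term.
#'
#' @param diversity a `diversity_table` or a data frame with columns
#'   `population`, `locus`, `H_E`.
#' @param alpha significance level recorded in the report.
#' @return A `model_report` whose `posthoc` element is the symmetric matrix
#'   of pairwise p-values (unit diagonal) and `posthoc_t` the matrix of t
#'   statistics.
#' @export
het_glm_posthoc <- function(diversity, alpha = 0.05) {
  lh <- if (inherits(diversity, "diversity_table")) diversity$locus_h
        else as.data.frame(diversity)
  lh <- lh[!is.na(lh$H_E), ]
  pops <- unique(lh$population)
  if (length(pops) < 2) stop("design error: at least 2 populations required")
  if (length(unique(lh$locus)) < 2)
    stop("design error: at least 2 loci required")
  f <- factor(lh$population, levels = pops)
  fit <- stats::lm(H_E ~ f, data = data.frame(H_E = lh$H_E, f = f))
  a <- stats::anova(fit)
  mse <- a["Residuals", "Mean Sq"]
  dfe <- a["Residuals", "Df"]
  means <- tapply(lh$H_E, f, mean)
  ns <- tapply(lh$H_E, f, length)
  k <- length(pops)
  pmat <- matrix(1, k, k, dimnames = list(pops, pops))
  tmat <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      tv <- (means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      pv <- 2 * stats::pt(-abs(tv), dfe)
      tmat[i, j] <- tv; tmat[j, i] <- -tv
      pmat[i, j] <- pv; pmat[j, i] <- pv
    }
  }
  tt <- data.frame(model = "het_glm", term = "population",
                   statistic_name = "F", statistic = a["f", "F value"],
                   df_num = a["f", "Df"], df_den = dfe,
                   p = a["f", "Pr(>F)"], retained = TRUE)
  lsm <- data.frame(model = "het_glm", level = names(means),
                    estimate = as.numeric(means),
                    se = sqrt(mse / as.numeric(ns)))
  rep <- .model_report("het_glm_posthoc", tt, lsm,
                       data.frame(term = character(0),
                                  p_at_drop = numeric(0)),
                       fit, singular = FALSE)
  rep$posthoc <- pmat
  rep$posthoc_t <- tmat
  rep$alpha <- alpha
  rep
}

# -- type III multivariate tests on an explicitly built full-rank design --
# population nested within habitat cannot be expressed through a factor
# contrast matrix (the nested block spans the habitat column), so the
# design matrix is assembled by hand: intercept | habitat (sum contrasts) |
# sex | habitat:sex | within-habitat population contrasts. Wilks' lambda
# uses det(E)/det(E+H) with Rao's F approximation.

.sum_contrast_cols <- function(f, prefix) {
  f <- droplevels(f)
  L <- nlevels(f)
  if (L < 2) return(NULL)
  C <- stats::contr.sum(L)
  M <- C[as.integer(f), , drop = FALSE]
  colnames(M) <- paste0(prefix, seq_len(L - 1))
  M
}

.nested_design <- function(info, include_sex = TRUE) {
  habitat <- factor(info$habitat)
  population <- factor(info$population)
  sex <- factor(info$sex)
  blocks <- list(`(Intercept)` = matrix(1, nrow(info), 1))
  Xh <- .sum_contrast_cols(habitat, "habitat")
  if (is.null(Xh)) stop("design error: two habitats are required")
  blocks$habitat <- Xh
  include_sex <- include_sex && nlevels(droplevels(sex)) >= 2
  if (include_sex) {
    Xs <- .sum_contrast_cols(sex, "sex")
    blocks$sex <- Xs
    Xhs <- do.call(cbind, lapply(seq_len(ncol(Xh)), function(a)
      Xh[, a] * Xs))
    colnames(Xhs) <- paste0("habitat:sex", seq_len(ncol(Xhs)))
    blocks$`habitat:sex` <- Xhs
  }
  nest <- NULL
  for (h in levels(habitat)) {
    sel <- habitat == h
    ph <- droplevels(population[sel])
    if (nlevels(ph) < 2) next
    C <- stats::contr.sum(nlevels(ph))
    M <- matrix(0, nrow(info), nlevels(ph) - 1)
    M[sel, ] <- C[as.integer(ph), , drop = FALSE]
    colnames(M) <- paste0("pop(", h, ")", seq_len(ncol(M)))
    nest <- cbind(nest, M)
  }
  if (!is.null(nest)) blocks$`population(habitat)` <- nest
  blocks
}

.rao_f <- function(lambda, p, q, v) {
  # Rao's F approximation for Wilks' lambda with p responses, q hypothesis
  # df and v error df
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- v - (p - q + 1) / 2
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  ls <- lambda^(1 / s)
  Fv <- (1 - ls) / ls * df2 / df1
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Multivariate GLM on per-trait standardized asymmetry
#'
#' Type III multivariate tests (Wilks' lambda, Rao F approximation) of
#' habitat, sex, habitat x sex and population nested within habitat -- all
#' fixed, since multivariate models admit no random factor -- on the matrix
#' of per-trait standardized relative asymmetry values. When the
#' multivariate habitat test is significant, univariate per-trait habitat F
#' tests are reported. Heterozygosity is deliberately absent from this
#' model (it is population-level, and population is in the design).
#'
#' @param asym an `asymmetry_matrix` from [asymmetry_matrix()], or a list
#'   with elements `sra` (matrix) and `info`.
#' @param alpha level used to decide whether univariate follow-ups are
#'   reported.
#' @return A `model_report` with Wilks' lambda rows per multivariate term
#'   and, below them, univariate habitat F rows per trait (term
#'   `habitat[<trait>]`) when triggered.
#' @export
sra_manova <- function(asym, alpha = 0.05) {
  info <- asym$info
  Y <- asym$sra[, asym$retained_traits, drop = FALSE]
  keep <- stats::complete.cases(Y)
  Y <- Y[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  # drop linearly dependent response columns (rank-deficient SSCP)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  qrY <- qr(Yc)
  if (qrY$rank < ncol(Y)) {
    bad <- colnames(Y)[qrY$pivot[-seq_len(qrY$rank)]]
    warning("rank-deficient response: dropping trait(s) ",
            paste(bad, collapse = ", "))
    Y <- Y[, setdiff(colnames(Y), bad), drop = FALSE]
  }
  blocks <- .nested_design(info)
  X <- do.call(cbind, blocks)
  if (nrow(Y) < ncol(Y) + ncol(X))
    stop("design error: need at least as many individuals as traits plus ",
         "design degrees of freedom")
  fit_sscp <- function(Xm) {
    q <- qr(Xm)
    crossprod(qr.resid(q, Y))
  }
  E <- fit_sscp(X)
  v <- nrow(Y) - qr(X)$rank
  p <- ncol(Y)
  terms <- setdiff(names(blocks), "(Intercept)")
  tt <- do.call(rbind, lapply(terms, function(tm) {
    Xr <- do.call(cbind, blocks[setdiff(names(blocks), tm)])
    H <- fit_sscp(Xr) - E
    q <- ncol(blocks[[tm]])
    lambda <- det(E) / det(E + H)
    rf <- .rao_f(lambda, p, q, v)
    data.frame(model = "sra_manova", term = tm,
               statistic_name = "Wilks_lambda", statistic = lambda,
               df_num = rf$df1, df_den = rf$df2, p = rf$p, retained = TRUE)
  }))
  hab_p <- tt$p[tt$term == "habitat"]
  uni <- NULL
  if (length(hab_p) && !is.na(hab_p) && hab_p < alpha) {
    Xr <- do.call(cbind, blocks[setdiff(names(blocks), "habitat")])
    qf <- qr(X); qr_ <- qr(Xr)
    rss_f <- colSums(qr.resid(qf, Y)^2)
    rss_r <- colSums(qr.resid(qr_, Y)^2)
    qh <- ncol(blocks$habitat)
    Fv <- ((rss_r - rss_f) / qh) / (rss_f / v)
    uni <- data.frame(model = "sra_manova",
                      term = paste0("habitat[", colnames(Y), "]"),
                      statistic_name = "F", statistic = Fv, df_num = qh,
                      df_den = v, p = stats::pf(Fv, qh, v,
                                                lower.tail = FALSE),
                      retained = TRUE)
  }
  out <- .model_report("sra_manova", rbind(tt, uni), NULL,
                       data.frame(term = character(0),
                                  p_at_drop = numeric(0)),
                       NULL, singular = FALSE)
  out$traits_used <- colnames(Y)
  out
}
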