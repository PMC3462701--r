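#' @importFrom lmerTest lmer
NULL

# -- internal: REML criterion for a one-random-intercept model, written out
# directly so the observed information of the variance components (and hence
# an SPSS-style Wald Z for the random effect) can be computed.
.reml_nll <- function(vb, ve, y, X, g) {
  n <- length(y)
  p <- ncol(X)
  Zi <- outer(g, levels(g), "==") * 1
  V <- vb * tcrossprod(Zi) + diag(ve, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(1e10)
  beta <- backsolve(chX, forwardsolve(t(chX), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  0.5 * (logdetV + 2 * sum(log(diag(chX))) + sum(r * Vi_r) +
           (n - p) * log(2 * pi))
}

# Wald Z for the random-intercept variance: estimate / asymptotic SE from
# the numerically differentiated REML information. Returns NA (with a
# boundary flag) for singular fits, where the Wald statistic is undefined.
.random_wald_z <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  vb <- vc$vcov[1]
  ve <- stats::sigma(model)^2
  y <- stats::model.response(stats::model.frame(model))
  X <- lme4::getME(model, "X")
  g <- droplevels(as.factor(model@flist[[1]]))
  if (vb < 1e-8 * ve) {
    return(list(var = vb, se = NA_real_, z = NA_real_, p = NA_real_,
                boundary = TRUE))
  }
  H <- pracma::hessian(function(th) .reml_nll(th[1], th[2], y, X, g),
                       c(vb, ve))
  cv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cv) || cv[1, 1] <= 0) {
    return(list(var = vb, se = NA_real_, z = NA_real_, p = NA_real_,
                boundary = TRUE))
  }
  se <- sqrt(cv[1, 1])
  z <- vb / se
  list(var = vb, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       boundary = FALSE)
}

# term hierarchy helpers -------------------------------------------------

.term_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

.droppable_terms <- function(terms) {
  ints <- terms[.term_order(terms) > 1]
  if (length(ints)) return(ints)
  terms
}

.mixed_formula <- function(terms, random) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste0("y ~ ", rhs, " + (1 | ", random, ")"))
}

# backward elimination on Satterthwaite type III F tests: interactions are
# candidates first; a main effect only becomes droppable once every
# interaction containing it is gone
.fit_eliminate <- function(dat, terms, random, alpha, eliminate) {
  path <- data.frame(term = character(0), p_at_drop = numeric(0))
  repeat {
    # near-boundary variance fits are legitimate here (exchangeable
    # populations); muffle the Hessian-eigenvalue chatter they produce
    m <- withCallingHandlers(
      suppressMessages(
        lmerTest::lmer(.mixed_formula(terms, random), data = dat,
                       REML = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         check.conv.grad = "ignore",
                         check.conv.hess = "ignore"))),
      warning = function(w) {
        if (grepl("eigenvalue|converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!eliminate || !length(terms)) break
    a <- stats::anova(m, type = 3)
    pv <- a[["Pr(>F)"]]
    names(pv) <- rownames(a)
    cand <- intersect(.droppable_terms(terms), names(pv))
    if (!length(cand)) break
    worst <- cand[which.max(pv[cand])]
    if (pv[worst] < alpha) break
    path <- rbind(path, data.frame(term = worst, p_at_drop = pv[worst]))
    terms <- setdiff(terms, worst)
  }
  list(model = m, terms = terms, path = path)
}

.model_report <- function(model_name, terms_tab, ls_means, path, fit,
                          singular) {
  structure(list(model = model_name, terms = terms_tab, ls_means = ls_means,
                 elimination_path = path, fit = fit, singular = singular),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Model report:", x$model, "\n")
  print(x$terms, row.names = FALSE)
  if (!is.null(x$ls_means) && nrow(x$ls_means)) {
    cat("\nLeast-squares means:\n")
    print(x$ls_means, row.names = FALSE)
  }
  if (!is.null(x$elimination_path) && nrow(x$elimination_path)) {
    cat("\nEliminated terms (in order):\n")
    print(x$elimination_path, row.names = FALSE)
  }
  if (isTRUE(x$singular))
    cat("\nNote: random-effect variance at boundary (singular fit)\n")
  invisible(x)
}

#' Mixed model on the composite asymmetry index
#'
#' Fits the composite standardized relative asymmetry with habitat and sex
#' as fixed factors, population-level heterozygosity as a covariate, the
#' habitat x sex and habitat x heterozygosity interactions, and population
#' nested within habitat as a random intercept (populations are uniquely
#' labelled, so the random intercept on population is the nested effect).
#' Estimation is by REML; fixed effects are tested with type III F tests
#' using Satterthwaite denominator degrees of freedom, and non-significant
#' terms are removed by backward elimination (interactions before the main
#' effects they contain). The random variance is tested with a Wald Z.
#'
#' @param csra numeric vector of per-individual composite indices.
#' @param info data frame with one row per individual: `population`,
#'   `habitat`, `sex`.
#' @param heterozygosity optional named numeric vector of population mean
#'   heterozygosity (names = populations); omit to fit without the
#'   covariate.
#' @param alpha retention threshold for backward elimination.
#' @param eliminate set `FALSE` to keep the full model.
#' @param ls_means compute habitat least-squares means (via emmeans).
#' @param random_test `"wald"` (default), or `"none"` to skip the
#'   variance-component test (useful in simulations).
#' @return A `model_report`: term table (F, Satterthwaite df, p; Wald Z row
#'   for the random effect), habitat LS means with SE, and the elimination
#'   path.
#' @export
fa_glmm <- function(csra, info, heterozygosity = NULL, alpha = 0.05,
                    eliminate = TRUE, ls_means = TRUE,
                    random_test = c("wald", "none")) {
  random_test <- match.arg(random_test)
  stopifnot(length(csra) == nrow(info))
  dat <- data.frame(y = as.numeric(csra),
                    habitat = factor(info$habitat),
                    sex = factor(info$sex),
                    population = factor(info$population))
  dat <- dat[!is.na(dat$y), ]
  .check_mixed_design(dat)
  terms <- c("habitat")
  if (nlevels(droplevels(dat$sex)) >= 2) {
    terms <- c(terms, "sex", "habitat:sex")
  }
  if (!is.null(heterozygosity)) {
    dat$het <- as.numeric(heterozygosity[as.character(dat$population)])
    if (any(is.na(dat$het)))
      stop("heterozygosity missing for population(s): ",
           paste(unique(dat$population[is.na(dat$het)]), collapse = ", "))
    terms <- c(terms, "het", "habitat:het")
  }
  .run_mixed("fa_glmm", dat, terms, alpha, eliminate, ls_means, random_test)
}

#' Mixed model on locus-wise heterozygosity
#'
#' Tests for a habitat effect on genetic diversity with locus-specific
#' expected heterozygosity as the response, habitat as the fixed factor and
#' population (nested within habitat) as a random intercept.
#'
#' @param diversity a `diversity_table` from [population_diversity()], or a
#'   data frame with columns `population`, `locus`, `H_E` plus a habitat
#'   label per population (column `habitat`).
#' @param habitat_of optional named vector mapping population to habitat
#'   (required if `diversity` does not carry habitat labels).
#' @inheritParams fa_glmm
#' @return A `model_report`.
#' @export
het_glmm <- function(diversity, habitat_of = NULL, alpha = 0.05,
                     eliminate = FALSE, random_test = c("wald", "none")) {
  random_test <- match.arg(random_test)
  lh <- .locus_h_frame(diversity, habitat_of)
  if (length(unique(lh$locus)) < 2)
    stop("design error: at least 2 loci are required")
  dat <- data.frame(y = lh$H_E, habitat = factor(lh$habitat),
                    population = factor(lh$population))
  dat <- dat[!is.na(dat$y), ]
  .check_mixed_design(dat)
  .run_mixed("het_glmm", dat, "habitat", alpha, eliminate,
             ls_means = TRUE, random_test)
}

.run_mixed <- function(model_name, dat, terms, alpha, eliminate, ls_means,
                       random_test) {
  fe <- .fit_eliminate(dat, terms, "population", alpha, eliminate)
  m <- fe$model
  singular <- lme4::isSingular(m, tol = 1e-5)
  tt <- if (length(fe$terms)) {
    a <- stats::anova(m, type = 3)
    data.frame(model = model_name, term = rownames(a),
               statistic_name = "F", statistic = a$`F value`,
               df_num = a$NumDF, df_den = a$DenDF, p = a$`Pr(>F)`,
               retained = TRUE)
  } else {
    data.frame(model = character(0), term = character(0),
               statistic_name = character(0), statistic = numeric(0),
               df_num = numeric(0), df_den = numeric(0), p = numeric(0),
               retained = logical(0))
  }
  if (random_test == "wald") {
    wz <- .random_wald_z(m)
    tt <- rbind(tt, data.frame(
      model = model_name, term = "population(habitat)",
      statistic_name = "Z", statistic = wz$z, df_num = NA_real_,
      df_den = NA_real_, p = wz$p, retained = TRUE))
    singular <- singular || wz$boundary
  }
  lsm <- NULL
  if (ls_means && "habitat" %in% fe$terms) {
    em <- suppressMessages(as.data.frame(
      emmeans::emmeans(m, "habitat", lmer.df = "satterthwaite")))
    lsm <- data.frame(model = model_name, level = as.character(em$habitat),
                      estimate = em$emmean, se = em$SE)
  }
  path <- fe$path
  if (nrow(path)) path <- cbind(model = model_name, path)
  .model_report(model_name, tt, lsm, path, m, singular)
}

.check_mixed_design <- function(dat) {
  tab <- table(unique(dat[, c("population", "habitat")])$habitat)
  if (length(tab) < 2)
    stop("design error: two habitats are required")
  if (any(tab < 2))
    stop("design error: at least 2 populations per habitat are required")
  invisible(TRUE)
}

.locus_h_frame <- function(diversity, habitat_of = NULL) {
  if (inherits(diversity, "diversity_table")) {
    lh <- diversity$locus_h
    hab <- stats::setNames(diversity$pop_summary$habitat,
                           diversity$pop_summary$population)
  } else {
    lh <- as.data.frame(diversity)
    hab <- if ("habitat" %in% names(lh))
      stats::setNames(lh$habitat, lh$population) else NULL
  }
  if (!is.null(habitat_of)) hab <- habitat_of
  if (is.null(hab)) stop("habitat labels are required")
  lh$habitat <- unname(hab[as.character(lh$population)])
  if (any(is.na(lh$habitat)))
    stop("population(s) without habitat label in diversity input")
  lh
}
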