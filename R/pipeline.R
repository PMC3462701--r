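#' Pipeline configuration
#'
#' Either file inputs (`counts`, optionally `genotypes`) or a
#' [simulation_config()] — exactly one of the two.
#'
#' @param counts path to a wide count CSV (see [read_count_table()]).
#' @param genotypes optional path to a genotype file.
#' @param genotype_dialect dialect for `genotypes`.
#' @param simulation a [simulation_config()] used instead of file input.
#' @param alpha screening/retention level.
#' @param zero_pair,missing_csra policies passed to [asymmetry_matrix()].
#' @param sidedness passed to the correlation stage.
#' @param strict_screens abort asymmetry inference if more than
#'   `max_da_fraction` of cells show directional asymmetry.
#' @param max_da_fraction tolerated flagged fraction in strict mode.
#' @param out output directory for [write_report()], or `NULL` to skip
#'   writing.
#' @param seed integer seed recorded in the manifest (and forwarded to the
#'   simulator when simulating).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, genotypes = NULL,
                            genotype_dialect = "table",
                            simulation = NULL,
                            alpha = 0.05,
                            zero_pair = "zero", missing_csra = "rescale",
                            sidedness = "two_sided",
                            strict_screens = FALSE, max_da_fraction = 0.10,
                            out = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(counts))
    stop("exactly one of file input (counts=) or simulation= must be given")
  structure(list(counts = counts, genotypes = genotypes,
                 genotype_dialect = genotype_dialect,
                 simulation = simulation, alpha = alpha,
                 zero_pair = zero_pair, missing_csra = missing_csra,
                 sidedness = sidedness, strict_screens = strict_screens,
                 max_da_fraction = max_da_fraction, out = out,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full asymmetry analysis pipeline
#'
#' Stage order is fixed: repeatability (when recounts exist), the
#' directional-asymmetry and antisymmetry screens (which must precede any
#' fluctuating-asymmetry inference), the RA/SRA/CSRA index chain, expected
#' heterozygosity (when genotypes exist), then the inference battery:
#' mixed model on the composite index, multivariate GLM on per-trait SRA,
#' mixed model and one-way GLM + Fisher LSD on heterozygosity, and the
#' raw vs habitat-standardized correlation stage. Diversity-dependent
#' stages are skipped with a notice when no genotypes are supplied.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A list of class `pipeline_result` holding every stage's output;
#'   written to `config$out` as CSV tables plus a manifest when set.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  log_ <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_ <<- c(log_, msg)
    say(msg)
  }
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    note("stage simulate: generating counts and genotypes (seed ",
         config$seed, ")")
    dataset <- simulate_counts(sim)
    genotypes <- simulate_genotypes(sim)
  } else {
    note("stage read: ", config$counts)
    dataset <- read_count_table(config$counts)
    genotypes <- if (!is.null(config$genotypes))
      read_genotypes(config$genotypes, dialect = config$genotype_dialect,
                     pop_habitat = stats::setNames(dataset$info$habitat,
                                                   dataset$info$population))
    else NULL
    if (is.null(genotypes))
      note("stage diversity: skipped (no genotype input)")
  }
  rep_tab <- if (!is.null(dataset$left2)) {
    note("stage repeatability")
    repeatability(dataset)
  } else {
    note("stage repeatability: skipped (no recounts)")
    NULL
  }
  note("stage DA screen")
  da <- da_screen(dataset, alpha = config$alpha)
  das <- attr(da, "summary")
  note(sprintf("  %d/%d cells flagged (%.1f%%)", das$n_flagged,
               das$n_tested, 100 * das$flagged_fraction))
  if (config$strict_screens &&
      !is.na(das$flagged_fraction) &&
      das$flagged_fraction > config$max_da_fraction)
    stop("stage DA screen: flagged fraction ",
         sprintf("%.1f%%", 100 * das$flagged_fraction),
         " exceeds strict-mode limit; asymmetry is not interpretable as FA")
  note("stage AS screen")
  as_tab <- as_screen(dataset, alpha = config$alpha)
  note("stage index chain (RA/SRA/CSRA)")
  asym <- withCallingHandlers(
    asymmetry_matrix(dataset, zero_pair = config$zero_pair,
                     missing = config$missing_csra),
    warning = function(w) {
      note("  note: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  div <- fa_mixed <- manova_rep <- het_mixed <- het_fixed <- corr <- NULL
  if (!is.null(genotypes)) {
    note("stage diversity")
    div <- population_diversity(genotypes)
  }
  note("stage fa_glmm")
  het_by_pop <- if (!is.null(div))
    stats::setNames(div$pop_summary$mean_h, div$pop_summary$population)
  else NULL
  fa_mixed <- fa_glmm(asym$csra, asym$info, heterozygosity = het_by_pop,
                      alpha = config$alpha)
  if (nrow(fa_mixed$elimination_path))
    note("  eliminated: ",
         paste(fa_mixed$elimination_path$term, collapse = ", "))
  note("stage sra_manova")
  manova_rep <- withCallingHandlers(
    sra_manova(asym, alpha = config$alpha),
    warning = function(w) {
      note("  note: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!is.null(div)) {
    note("stage het_glmm")
    het_mixed <- het_glmm(div)
    note("stage het_glm_posthoc")
    het_fixed <- het_glm_posthoc(div)
    note("stage correlation (raw vs habitat-standardized)")
    corr <- fa_het_correlation_stage(asym, div,
                                     sidedness = config$sidedness)
  } else {
    note("stage het_glmm/het_glm_posthoc/correlation: skipped ",
         "(no genotype input)")
  }
  result <- structure(
    list(dataset = dataset, genotypes = genotypes, repeatability = rep_tab,
         da_screen = da, as_screen = as_tab, asymmetry = asym,
         diversity = div, fa_glmm = fa_mixed, sra_manova = manova_rep,
         het_glmm = het_mixed, het_glm_posthoc = het_fixed,
         correlation = corr, log = log_, config = config),
    class = "pipeline_result")
  if (!is.null(config$out)) {
    write_report(.report_tables(result), config$out,
                 manifest = list(seed = config$seed,
                                 alpha = config$alpha,
                                 zero_pair = config$zero_pair,
                                 missing_csra = config$missing_csra,
                                 sidedness = config$sidedness,
                                 simulated = !is.null(config$simulation),
                                 log = log_))
  }
  result
}

.report_tables <- function(res) {
  asym <- res$asymmetry
  index_tab <- data.frame(asym$info, csra = unname(asym$csra))
  sra_tab <- data.frame(id = asym$info$id, as.data.frame(asym$sra),
                        check.names = FALSE)
  models <- rbind(res$fa_glmm$terms, res$sra_manova$terms,
                  if (!is.null(res$het_glmm)) res$het_glmm$terms,
                  if (!is.null(res$het_glm_posthoc))
                    res$het_glm_posthoc$terms)
  lsm <- rbind(res$fa_glmm$ls_means,
               if (!is.null(res$het_glmm)) res$het_glmm$ls_means)
  corr_tab <- if (!is.null(res$correlation)) {
    rbind(
      data.frame(analysis = "raw",
                 rho = res$correlation$raw$rho, p = res$correlation$raw$p,
                 n = res$correlation$raw$n,
                 method = res$correlation$raw$method),
      data.frame(analysis = "habitat_standardized",
                 rho = res$correlation$standardized$rho,
                 p = res$correlation$standardized$p,
                 n = res$correlation$standardized$n,
                 method = res$correlation$standardized$method))
  } else NULL
  list(csra = index_tab, sra = sra_tab, da_screen = res$da_screen,
       as_screen = res$as_screen, repeatability = res$repeatability,
       diversity = if (!is.null(res$diversity)) res$diversity$locus_h,
       diversity_populations = if (!is.null(res$diversity))
         res$diversity$pop_summary,
       models = models, ls_means = lsm, correlations = corr_tab,
       elimination = res$fa_glmm$elimination_path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("fluctasym pipeline result\n")
  cat("  individuals:", nrow(x$dataset$info), " populations:",
      length(unique(x$dataset$info$population)), "\n")
  das <- attr(x$da_screen, "summary")
  cat(sprintf("  DA screen: %d/%d cells flagged (%.1f%%)\n",
              das$n_flagged, das$n_tested, 100 * das$flagged_fraction))
  cat("  mean CSRA:", sprintf("%.2f", mean(x$asymmetry$csra, na.rm = TRUE)),
      "over", length(x$asymmetry$retained_traits), "retained traits\n")
  if (!is.null(x$fa_glmm)) {
    hab <- x$fa_glmm$terms[x$fa_glmm$terms$term == "habitat", ]
    if (nrow(hab))
      cat(sprintf("  habitat effect on CSRA: F(%.0f, %.1f) = %.2f, p = %.3g\n",
                  hab$df_num, hab$df_den, hab$statistic, hab$p))
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("  FA~H correlation: raw rho = %.3f (p = %.3g), ",
                x$correlation$raw$rho, x$correlation$raw$p))
    cat(sprintf("standardized rho = %.3f (p = %.3g)\n",
                x$correlation$standardized$rho,
                x$correlation$standardized$p))
  }
  invisible(x)
}
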