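#' Bilateral meristic trait dataset
#'
#' Container for per-individual left/right integer counts of bilateral
#' meristic traits (e.g. neuromast numbers per lateral-line segment,
#' posterior lateral plates), together with the design labels used by the
#' downstream models: population, habitat (marine vs pond) and sex.
#' An optional second counting session per individual supports
#' repeatability estimation.
#'
#' @param info data frame with columns `id`, `population`, `habitat`
#'   (`"marine"` or `"pond"`), `sex` (`"male"`, `"female"` or `"unknown"`);
#'   one row per individual.
#' @param left,right integer matrices (individuals x traits) of side counts;
#'   column names are the trait names. `NA` marks an explicitly missing
#'   count.
#' @param left2,right2 optional matrices of the same shape holding the
#'   second counting session; rows without a recount are all-`NA`.
#'
#' @return An object of class `bilateral_dataset`: a list with elements
#'   `info`, `left`, `right`, `left2`, `right2` and `trait_names`.
#' @export
bilateral_dataset <- function(info, left, right, left2 = NULL, right2 = NULL) {
  stopifnot(is.data.frame(info))
  need <- c("id", "population", "habitat", "sex")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("info is missing mandatory column(s): ", paste(miss, collapse = ", "))
  left <- as.matrix(left); right <- as.matrix(right)
  if (!identical(dim(left), dim(right)))
    stop("left and right count matrices must have identical dimensions")
  if (nrow(left) != nrow(info))
    stop("count matrices must have one row per individual")
  traits <- colnames(left)
  if (is.null(traits) || !identical(traits, colnames(right)))
    stop("left/right matrices must share identical trait column names")
  .check_counts(left, "left"); .check_counts(right, "right")
  if (!is.null(left2) || !is.null(right2)) {
    if (is.null(left2) || is.null(right2))
      stop("recounts require both left2 and right2")
    left2 <- as.matrix(left2); right2 <- as.matrix(right2)
    if (!identical(dim(left2), dim(left)) || !identical(dim(right2), dim(right)))
      stop("recount matrices must match the first-count dimensions")
    colnames(left2) <- traits; colnames(right2) <- traits
    .check_counts(left2, "left2"); .check_counts(right2, "right2")
  }
  bad_hab <- setdiff(unique(as.character(info$habitat)), c("marine", "pond"))
  if (length(bad_hab))
    stop("habitat must be 'marine' or 'pond'; found: ",
         paste(bad_hab, collapse = ", "))
  bad_sex <- setdiff(unique(as.character(info$sex)),
                     c("male", "female", "unknown"))
  if (length(bad_sex))
    stop("sex must be 'male', 'female' or 'unknown'; found: ",
         paste(bad_sex, collapse = ", "))
  map <- unique(info[, c("population", "habitat")])
  dup <- map$population[duplicated(map$population)]
  if (length(dup))
    stop("population mapped to more than one habitat: ",
         paste(unique(dup), collapse = ", "))
  info$id <- as.character(info$id)
  info$population <- as.character(info$population)
  info$habitat <- as.character(info$habitat)
  info$sex <- as.character(info$sex)
  rownames(info) <- NULL
  structure(
    list(info = info,
         left = .int_matrix(left), right = .int_matrix(right),
         left2 = if (is.null(left2)) NULL else .int_matrix(left2),
         right2 = if (is.null(right2)) NULL else .int_matrix(right2),
         trait_names = traits),
    class = "bilateral_dataset")
}

.check_counts <- function(m, what) {
  v <- m[!is.na(m)]
  if (length(v) == 0) return(invisible(TRUE))
  if (!is.numeric(v)) stop(what, " counts must be numeric integers")
  if (any(v != floor(v))) {
    idx <- which(!is.na(m) & m != floor(m), arr.ind = TRUE)[1, ]
    stop("non-integer count in ", what, " at row ", idx[1],
         ", trait '", colnames(m)[idx[2]], "': counts are meristic and ",
         "must be whole numbers")
  }
  if (any(v < 0)) {
    idx <- which(!is.na(m) & m < 0, arr.ind = TRUE)[1, ]
    stop("negative count in ", what, " at row ", idx[1],
         ", trait '", colnames(m)[idx[2]], "'")
  }
  invisible(TRUE)
}

.int_matrix <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' @export
print.bilateral_dataset <- function(x, ...) {
  cat("Bilateral meristic dataset\n")
  cat("  individuals :", nrow(x$info), "\n")
  cat("  traits      :", length(x$trait_names), "(",
      paste(utils::head(x$trait_names, 6), collapse = ", "),
      if (length(x$trait_names) > 6) ", ..." else "", ")\n", sep = " ")
  cat("  populations :", length(unique(x$info$population)), "\n")
  cat("  habitats    :", paste(sort(unique(x$info$habitat)), collapse = ", "), "\n")
  if (!is.null(x$left2))
    cat("  recounts    :", sum(apply(!is.na(x$left2), 1, any)), "individuals\n")
  invisible(x)
}

#' Multilocus codominant genotype dataset
#'
#' Container for two-allele integer calls per locus per individual, plus
#' population (and, when known, habitat) labels. Missing genotypes are `NA`
#' on both allele matrices.
#'
#' @param info data frame with columns `id`, `population` and optionally
#'   `habitat` (`NA` allowed when the habitat assignment is not carried by
#'   the genotype file, e.g. Genepop input).
#' @param a1,a2 integer matrices (individuals x loci) of allele labels
#'   (positive integers); column names are the locus names.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(info, a1, a2) {
  stopifnot(is.data.frame(info))
  if (!all(c("id", "population") %in% names(info)))
    stop("info must contain columns id and population")
  if (is.null(info$habitat)) info$habitat <- NA_character_
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (nrow(a1) != nrow(info))
    stop("allele matrices must have one row per individual")
  loci <- colnames(a1)
  if (is.null(loci) || !identical(loci, colnames(a2)))
    stop("allele matrices must share identical locus column names")
  for (m in list(a1, a2)) {
    v <- m[!is.na(m)]
    if (length(v) && (any(v != floor(v)) || any(v <= 0)))
      stop("allele labels must be positive integers (0 codes missing on input)")
  }
  # a genotype is missing as a unit: if one allele is NA, both are
  na <- is.na(a1) | is.na(a2)
  a1[na] <- NA; a2[na] <- NA
  info$id <- as.character(info$id)
  info$population <- as.character(info$population)
  info$habitat <- as.character(info$habitat)
  rownames(info) <- NULL
  structure(
    list(info = info, a1 = .int_matrix(a1), a2 = .int_matrix(a2),
         locus_names = loci),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Multilocus genotype dataset\n")
  cat("  individuals :", nrow(x$info), "\n")
  cat("  loci        :", length(x$locus_names), "\n")
  cat("  populations :", length(unique(x$info$population)), "\n")
  cat("  missing     :",
      sprintf("%.1f%%", 100 * mean(is.na(x$a1))), "of genotypes\n")
  invisible(x)
}

#' Default trait names
#'
#' The twelve bilateral traits scored in the motivating study system:
#' posterior lateral plates (PP) and eleven lateral-line neuromast lines of
#' the nine-spined stickleback head and trunk.
#'
#' @return Character vector of length 12.
#' @export
default_traits <- function() {
  c("PP", "DH", "IO", "M", "MPrL", "MPrU", "N", "Ot", "PO", "Pr",
    "Pr-c", "SO-c")
}
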