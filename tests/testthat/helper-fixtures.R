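# in-code fixtures shared across test files

# small bilateral dataset from explicit count matrices
make_bilateral <- function(left, right, population, habitat,
                           sex = NULL, left2 = NULL, right2 = NULL) {
  n <- nrow(left)
  if (is.null(sex)) sex <- rep("unknown", n)
  info <- data.frame(id = sprintf("ind%02d", seq_len(n)),
                     population = population, habitat = habitat, sex = sex,
                     stringsAsFactors = FALSE)
  bilateral_dataset(info, left, right, left2, right2)
}

# two populations x three individuals x two loci, hand-written Genepop text
genepop_fixture_lines <- function() {
  c("toy genepop fixture",
    "LocA",
    "LocB",
    "Pop",
    "a1 , 0101 0203",
    "a2 , 0102 0202",
    "a3 , 0101 000000",
    "Pop",
    "b1 , 0202 0303",
    "b2 , 0201 0303",
    "b3 , 0202 0301")
}

# independent brute-force recomputation of the full index chain with plain
# loops; deliberately shares no code with the package implementation
brute_csra <- function(left, right) {
  n <- nrow(left); Tn <- ncol(left)
  ra <- matrix(NA_real_, n, Tn)
  for (i in seq_len(n)) for (j in seq_len(Tn)) {
    L <- left[i, j]; R <- right[i, j]
    if (is.na(L) || is.na(R)) next
    ra[i, j] <- if (L == 0 && R == 0) 0 else abs(L - R) / ((L + R) / 2)
  }
  means <- numeric(Tn)
  for (j in seq_len(Tn)) means[j] <- mean(ra[, j], na.rm = TRUE)
  keep <- which(means > 0)
  csra <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; nobs <- 0
    for (j in keep) {
      if (!is.na(ra[i, j])) {
        acc <- acc + ra[i, j] / means[j]
        nobs <- nobs + 1
      }
    }
    csra[i] <- if (nobs == 0) NA_real_ else acc * length(keep) / nobs
  }
  csra
}

# literal enumeration of all n! rank permutations (oracle for the exact
# Spearman permutation p); only usable for tiny n
enumerate_perm_rho <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rx <- rank(x); ry <- rank(y)
  vapply(perms(seq_along(y)), function(p) stats::cor(rx, ry[p]), numeric(1))
}
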