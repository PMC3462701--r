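#' Read a wide-format bilateral count table
#'
#' Expects a UTF-8, comma-delimited table with a header row naming `id`,
#' `population`, `habitat`, `sex`, then `<trait>_L` / `<trait>_R` column
#' pairs, optionally followed by `<trait>_L2` / `<trait>_R2` recount pairs.
#' Counts must be non-negative whole numbers; empty cells are explicit
#' missing values.
#'
#' @param path path to the CSV file.
#' @param dialect table layout; only `"wide"` is defined.
#' @return A [bilateral_dataset()] with row order preserved.
#' @export
read_count_table <- function(path, dialect = "wide") {
  dialect <- match.arg(dialect, "wide")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("id", "population", "habitat", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  cols <- setdiff(names(df), need)
  l1 <- grep("_L$", cols, value = TRUE)
  traits <- sub("_L$", "", l1)
  if (!length(traits)) stop("no <trait>_L count columns found")
  r1 <- paste0(traits, "_R")
  miss_r <- setdiff(r1, cols)
  if (length(miss_r))
    stop("count table is missing mandatory column(s): ",
         paste(miss_r, collapse = ", "))
  grab <- function(cn) {
    m <- as.matrix(df[, cn, drop = FALSE])
    storage.mode(m) <- "numeric"
    colnames(m) <- traits
    m
  }
  left <- grab(paste0(traits, "_L"))
  right <- grab(r1)
  left2 <- right2 <- NULL
  l2 <- paste0(traits, "_L2"); r2 <- paste0(traits, "_R2")
  if (any(l2 %in% cols) || any(r2 %in% cols)) {
    if (!all(c(l2, r2) %in% cols))
      stop("recount columns must be present as complete _L2/_R2 pairs ",
           "for every trait")
    left2 <- grab(l2); right2 <- grab(r2)
  }
  bilateral_dataset(df[, need], left, right, left2, right2)
}

#' Write a bilateral count table
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces `x` field-exactly.
#'
#' @param dataset a [bilateral_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "bilateral_dataset"))
  tr <- dataset$trait_names
  out <- dataset$info
  for (j in seq_along(tr)) {
    out[[paste0(tr[j], "_L")]] <- dataset$left[, j]
    out[[paste0(tr[j], "_R")]] <- dataset$right[, j]
  }
  if (!is.null(dataset$left2)) {
    for (j in seq_along(tr)) {
      out[[paste0(tr[j], "_L2")]] <- dataset$left2[, j]
      out[[paste0(tr[j], "_R2")]] <- dataset$right2[, j]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read multilocus genotypes
#'
#' Two dialects are supported. `"genepop"`: a title line, locus names (one
#' per line or comma-separated), then population blocks separated by lines
#' reading `Pop`; individual lines are `id , g g g ...` with each genotype a
#' concatenation of two 2- or 3-digit allele codes; `0`/`00`/`000` codes a
#' missing allele. `"table"`: a CSV with columns `id`, `population`,
#' optionally `habitat`, then `<locus>_1` / `<locus>_2` allele pairs.
#'
#' @param path input file path.
#' @param dialect `"genepop"` or `"table"`.
#' @param pop_habitat optional named character vector mapping population
#'   name to habitat, used to fill habitat labels absent from Genepop files.
#' @param pop_names optional character vector of population names for
#'   Genepop blocks (default `Pop1`, `Pop2`, ...).
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("genepop", "table"),
                           pop_habitat = NULL, pop_names = NULL) {
  if (length(dialect) == 1 && !dialect %in% c("genepop", "table"))
    stop("unknown genotype dialect: ", dialect)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "table") {
    return(.read_genotype_table(path))
  }
  .read_genepop(path, pop_habitat, pop_names)
}

.read_genotype_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!all(c("id", "population") %in% names(df)))
    stop("genotype table must contain columns id and population")
  meta <- intersect(c("id", "population", "habitat"), names(df))
  cols <- setdiff(names(df), meta)
  if (length(cols) %% 2 != 0)
    stop("odd number of allele columns (", length(cols),
         "): loci must come as <locus>_1/<locus>_2 pairs")
  a1c <- grep("_1$", cols, value = TRUE)
  loci <- sub("_1$", "", a1c)
  a2c <- paste0(loci, "_2")
  if (!all(a2c %in% cols) || length(c(a1c, a2c)) != length(cols))
    stop("allele columns must be complete <locus>_1/<locus>_2 pairs")
  grab <- function(cn) {
    m <- as.matrix(df[, cn, drop = FALSE])
    storage.mode(m) <- "numeric"
    m[!is.na(m) & m == 0] <- NA  # 0 codes missing
    colnames(m) <- loci
    m
  }
  info <- df[, meta, drop = FALSE]
  if (is.null(info$habitat)) info$habitat <- NA_character_
  genotype_dataset(info, grab(a1c), grab(a2c))
}

.read_genepop <- function(path, pop_habitat = NULL, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]  # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' separator found")
  loci <- unlist(strsplit(paste(body[seq_len(first_pop - 1)], collapse = ","),
                          ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names before first 'Pop' line")
  pop_starts <- which(is_pop)
  n_pops <- length(pop_starts)
  if (is.null(pop_names)) pop_names <- paste0("Pop", seq_len(n_pops))
  if (length(pop_names) != n_pops)
    stop("pop_names must have one entry per Genepop population block")
  ids <- pops <- character(0)
  g1 <- g2 <- NULL
  bounds <- c(pop_starts, length(body) + 1)
  for (b in seq_len(n_pops)) {
    block <- body[seq(bounds[b] + 1, bounds[b + 1] - 1)]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) != 2)
        stop("malformed Genepop individual line: ", ln)
      id <- trimws(parts[1])
      codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(codes) != length(loci))
        stop("individual '", id, "' has ", length(codes),
             " genotypes for ", length(loci), " loci")
      w <- unique(nchar(codes))
      if (!all(w %in% c(4L, 6L)))
        stop("Genepop genotype codes must be 4 or 6 digits; got width(s) ",
             paste(w, collapse = ", "), " for individual '", id, "'")
      half <- nchar(codes) / 2
      x1 <- as.integer(substr(codes, 1, half))
      x2 <- as.integer(substr(codes, half + 1, 2 * half))
      x1[x1 == 0] <- NA; x2[x2 == 0] <- NA
      ids <- c(ids, id); pops <- c(pops, pop_names[b])
      g1 <- rbind(g1, x1); g2 <- rbind(g2, x2)
    }
  }
  dimnames(g1) <- list(NULL, loci); dimnames(g2) <- list(NULL, loci)
  habitat <- if (is.null(pop_habitat)) NA_character_ else
    unname(pop_habitat[pops])
  info <- data.frame(id = ids, population = pops, habitat = habitat,
                     stringsAsFactors = FALSE)
  genotype_dataset(info, g1, g2)
}

#' Write multilocus genotypes
#'
#' Genepop output uses 3-digit allele codes (the canonical form here; 2-digit
#' codes are accepted on input) with missing alleles coded `000`.
#'
#' @param genotypes a [genotype_dataset()].
#' @param path output file path.
#' @param dialect `"genepop"` or `"table"`.
#' @param title title line for Genepop output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path,
                            dialect = c("genepop", "table"),
                            title = "fluctasym genotype export") {
  stopifnot(inherits(genotypes, "genotype_dataset"))
  dialect <- match.arg(dialect)
  if (dialect == "table") {
    out <- genotypes$info
    for (j in seq_along(genotypes$locus_names)) {
      lc <- genotypes$locus_names[j]
      a1 <- genotypes$a1[, j]; a2 <- genotypes$a2[, j]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      out[[paste0(lc, "_1")]] <- a1
      out[[paste0(lc, "_2")]] <- a2
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    return(invisible(path))
  }
  code <- function(a) sprintf("%03d", ifelse(is.na(a), 0L, a))
  lines <- c(title, genotypes$locus_names)
  for (p in unique(genotypes$info$population)) {
    lines <- c(lines, "Pop")
    rows <- which(genotypes$info$population == p)
    for (i in rows) {
      g <- paste0(code(genotypes$a1[i, ]), code(genotypes$a2[i, ]))
      lines <- c(lines, paste0(genotypes$info$id[i], " , ",
                               paste(g, collapse = " ")))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write pipeline report tables
#'
#' Serializes a collection of result tables as one CSV per stage plus a YAML
#' run manifest (config, seed, package version). Re-running with the same
#' config and seed reproduces the tables byte-identically; no timestamps are
#' written.
#'
#' @param reports named list of data frames (or objects with an
#'   `as.data.frame` method); names become file names.
#' @param path output directory, created if needed.
#' @param manifest named list stored in `manifest.yaml` (e.g. config, seed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(reports, path, manifest = list()) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stop("cannot create output directory: ", path)
  }
  written <- character(0)
  for (nm in names(reports)) {
    tab <- reports[[nm]]
    if (is.null(tab)) next
    tab <- as.data.frame(tab)
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(.format_num(tab), f, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    written <- c(written, f)
  }
  manifest <- c(manifest,
                list(package = "fluctasym",
                     version = as.character(utils::packageVersion("fluctasym")),
                     tables = names(reports)))
  mf <- file.path(path, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(c(written, mf))
}

# fixed-precision numeric formatting so report files are locale-independent
# and byte-stable across runs
.format_num <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 10,
                                               format = "g")
  }
  df
}
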