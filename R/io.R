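#' @name shmctm-io
#' @title Readers and writers for pipeline tables
#'
#' @description All tabular artifacts travel as tab-separated text with a
#' header row; gene sets as GMT; configurations as YAML. These helpers pin
#' the column conventions so every stage can be run standalone from files.
NULL

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read per-cancer DEG tables
#'
#' One file per cancer, `deg_<cancer>.tsv`, columns `cancer`, `cell_type`,
#' `gene`, `log2fc`, `adj_p`.
#'
#' @param deg_tables Named list of DEG data frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths (or, for the reader, the list).
#' @export
write_deg_tables <- function(deg_tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(deg_tables))
  for (i in seq_along(deg_tables)) {
    paths[i] <- file.path(dir, sprintf("deg_%s.tsv", names(deg_tables)[i]))
    write_tsv(deg_tables[[i]], paths[i])
  }
  invisible(paths)
}

#' @rdname write_deg_tables
#' @export
read_deg_tables <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^deg_.*\\.tsv$", full.names = TRUE))
  out <- lapply(paths, read_tsv)
  names(out) <- sub("^deg_(.*)\\.tsv$", "\\1", basename(paths))
  out
}

#' Write / read the regulatory prior matrix
#'
#' TSV with ligand rows (first column `ligand`) and gene columns.
#'
#' @param prior Numeric ligand x gene matrix.
#' @param path File path.
#' @return Invisibly the path; the reader returns the matrix.
#' @export
write_prior <- function(prior, path) {
  df <- data.frame(ligand = rownames(prior), prior, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$ligand
  storage.mode(m) <- "double"
  m
}

#' Write / read a cohort
#'
#' Two files: `<prefix>_matrix.tsv` (samples x features, first column
#' `sample`) and `<prefix>_samples.tsv` (annotation). Missing abundances
#' are written as `NA`.
#'
#' @param x A [cohort()] object.
#' @param prefix Path prefix.
#' @param assay Assay label used when reading back.
#' @return Invisibly the paths; the reader returns a `cohort`.
#' @export
write_cohort <- function(x, prefix) {
  stopifnot(inherits(x, "cohort"))
  m <- data.frame(sample = x$samples$sample, x$abundance, check.names = FALSE)
  p1 <- paste0(prefix, "_matrix.tsv")
  p2 <- paste0(prefix, "_samples.tsv")
  write_tsv(m, p1)
  write_tsv(x$samples, p2)
  invisible(c(p1, p2))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix, assay = c("expression", "protein")) {
  assay <- match.arg(assay)
  m <- read_tsv(paste0(prefix, "_matrix.tsv"))
  samples <- read_tsv(paste0(prefix, "_samples.tsv"))
  ab <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(ab) <- "double"
  cohort(ab, samples, assay = assay)
}

#' Write / read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name <tab> description <tab> genes...`.
#'
#' @param sets Named list of character vectors (the writer), or a path
#'   (the reader).
#' @param path File path.
#' @param descriptions Optional character vector of set descriptions.
#' @return The reader returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg A [sim_config()] object.
#' @param path File path.
#' @return The reader returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
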