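#' Read an arrayed-screen well table together with its reagent library
#'
#' Loads per-well luminescence measurements (tab-separated, one row per well)
#' and the dsRNA reagent library that maps reagent identifiers to target
#' genes, validates both, and joins them into a `screen_dataset`.
#'
#' The well table must have columns `plate_id`, `row` (letters A-P), `col`
#' (1-24), `reagent_id` (empty for control/edge wells), `raw_signal`
#' (non-negative relative luminescence; empty = missing, never imputed),
#' `condition`, and `replicate`. The library table must have columns
#' `reagent_id` (unique), `gene_id`, `gene_symbol`, and `sublibrary`.
#'
#' @param path path to the tab-separated well table.
#' @param library_path path to the tab-separated reagent library.
#' @param conditions optional character vector of allowed condition labels;
#'   `NULL` accepts any label found in the file.
#' @return An object of class `screen_dataset`: a list with elements
#'   `wells` (data frame of well measurements) and `library` (reagent
#'   library data frame).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 20), seed = 1)
#' td <- tempfile(); dir.create(td)
#' paths <- write_screen_data(sim$dataset, file.path(td, "wells.tsv"),
#'                            file.path(td, "library.tsv"))
#' ds <- read_screen_data(paths$wells, paths$library)
#' nrow(ds$wells)
#' @export
read_screen_data <- function(path, library_path, conditions = NULL) {
  wells <- read_tsv(path, "screen well table")
  lib <- read_reagent_library(library_path)
  check_columns(wells, c("plate_id", "row", "col", "reagent_id",
                         "raw_signal", "condition", "replicate"),
                "screen well table")
  wells$plate_id <- as.character(wells$plate_id)
  wells$row <- as.character(wells$row)
  wells$col <- as.integer(wells$col)
  wells$reagent_id <- as.character(wells$reagent_id)
  wells$raw_signal <- as.numeric(wells$raw_signal)
  wells$condition <- as.character(wells$condition)
  wells$replicate <- as.integer(wells$replicate)
  screen_dataset(wells, lib, conditions = conditions)
}

#' Read a dsRNA reagent library table
#'
#' @param library_path path to a tab-separated table with columns
#'   `reagent_id`, `gene_id`, `gene_symbol`, `sublibrary`.
#' @return Validated reagent library data frame.
#' @export
read_reagent_library <- function(library_path) {
  lib <- read_tsv(library_path, "reagent library")
  check_columns(lib, c("reagent_id", "gene_id", "gene_symbol", "sublibrary"),
                "reagent library")
  validate_reagent_library(lib)
}

validate_reagent_library <- function(lib) {
  lib$reagent_id <- as.character(lib$reagent_id)
  lib$gene_id <- as.character(lib$gene_id)
  dup <- unique(lib$reagent_id[duplicated(lib$reagent_id)])
  if (length(dup) > 0L) {
    stop_format("reagent library: duplicate reagent_id(s): %s",
                paste(utils::head(dup, 10L), collapse = ", "))
  }
  if (anyNA(lib$reagent_id) || anyNA(lib$gene_id)) {
    stop_format("reagent library: reagent_id and gene_id must be non-missing")
  }
  lib
}

#' Construct and validate a screen dataset
#'
#' @param wells data frame of per-well measurements.
#' @param library reagent library data frame.
#' @param conditions optional allowed condition labels.
#' @return `screen_dataset` object.
#' @export
screen_dataset <- function(wells, library, conditions = NULL) {
  library <- validate_reagent_library(library)
  if (any(wells$raw_signal < 0, na.rm = TRUE)) {
    stop_format("screen well table: raw_signal must be non-negative")
  }
  bad_row <- !(wells$row %in% PLATE_ROWS)
  if (any(bad_row)) {
    stop_format("screen well table: invalid plate row(s): %s",
                paste(unique(wells$row[bad_row]), collapse = ", "))
  }
  if (any(!(wells$col %in% PLATE_COLS))) {
    stop_format("screen well table: plate columns must be integers 1-24")
  }
  if (!is.null(conditions)) {
    bad <- setdiff(unique(wells$condition), conditions)
    if (length(bad) > 0L) {
      stop_format("screen well table: unknown condition label(s): %s",
                  paste(bad, collapse = ", "))
    }
  }
  key <- paste(wells$plate_id, wells$condition, wells$replicate,
               wells$row, wells$col)
  if (anyDuplicated(key)) {
    stop_format("screen well table: duplicate well coordinates within a plate replicate")
  }
  has_reagent <- !is.na(wells$reagent_id) & nzchar(wells$reagent_id)
  unknown <- setdiff(unique(wells$reagent_id[has_reagent]), library$reagent_id)
  if (length(unknown) > 0L) {
    stop_format("screen well table: reagent_id(s) absent from library: %s",
                paste(utils::head(unknown, 10L), collapse = ", "))
  }
  structure(list(wells = wells, library = library),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  conds <- table(x$wells$condition[!duplicated(
    paste(x$wells$plate_id, x$wells$condition, x$wells$replicate))])
  cat("screen_dataset:", nrow(x$wells), "wells,",
      nrow(x$library), "reagents,",
      length(unique(x$library$gene_id)), "genes\n")
  cat("plate replicates per condition:\n")
  print(conds)
  invisible(x)
}

#' Write a screen dataset to tab-separated files
#'
#' @param dataset `screen_dataset` object.
#' @param path output path for the well table.
#' @param library_path output path for the reagent library.
#' @return Invisibly, a list with the two paths.
#' @export
write_screen_data <- function(dataset, path, library_path) {
  stopifnot(inherits(dataset, "screen_dataset"))
  write_tsv(dataset$wells, path)
  write_tsv(dataset$library, library_path)
  invisible(list(wells = path, library = library_path))
}

#' Read a gene-by-sample FPKM table with its sample sheet
#'
#' The FPKM file's first column must be `gene_id`; every remaining column
#' name must appear exactly once as a `sample_id` in the sample sheet, which
#' carries `sample_id`, `genotype`, `treatment`, and `replicate` columns.
#' Genes whose values are missing in every sample are dropped with a
#' warning; negative values are a validation error.
#'
#' @param path path to the tab-separated FPKM matrix.
#' @param meta_path path to the tab-separated sample sheet.
#' @return An object of class `expression_table`: list with `fpkm` (numeric
#'   matrix, genes x samples) and `meta` (sample sheet data frame).
#' @export
read_fpkm_table <- function(path, meta_path) {
  df <- read_tsv(path, "FPKM table")
  meta <- read_tsv(meta_path, "sample sheet")
  check_columns(meta, c("sample_id", "genotype", "treatment", "replicate"),
                "sample sheet")
  if (names(df)[1] != "gene_id") {
    stop_format("FPKM table: first column must be 'gene_id'")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(df$gene_id)
  expression_table(mat, meta)
}

#' Construct and validate an expression table
#'
#' @param fpkm numeric matrix of FPKM values, genes in rows, samples in
#'   columns (column names = sample ids).
#' @param meta sample sheet data frame (`sample_id`, `genotype`,
#'   `treatment`, `replicate`).
#' @return `expression_table` object.
#' @export
expression_table <- function(fpkm, meta) {
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta[, c("genotype", "treatment", "replicate")])) {
    stop_format("sample sheet: (genotype, treatment, replicate) must be unique")
  }
  missing_meta <- setdiff(colnames(fpkm), meta$sample_id)
  if (length(missing_meta) > 0L) {
    stop_format("FPKM table: sample column(s) without metadata: %s",
                paste(missing_meta, collapse = ", "))
  }
  if (any(fpkm < 0, na.rm = TRUE)) {
    stop_format("FPKM table: negative values are not allowed")
  }
  all_na <- rowSums(!is.na(fpkm)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropping %d gene(s) with all-missing FPKM values",
                    sum(all_na)), call. = FALSE)
    fpkm <- fpkm[!all_na, , drop = FALSE]
  }
  meta <- meta[match(colnames(fpkm), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(fpkm = fpkm, meta = meta), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$fpkm), "genes x", ncol(x$fpkm), "samples\n")
  cat("conditions:",
      paste(unique(paste(x$meta$genotype, x$meta$treatment, sep = " / ")),
            collapse = "; "), "\n")
  invisible(x)
}

#' Write an expression table to tab-separated files
#'
#' @param table `expression_table` object.
#' @param path output path for the FPKM matrix.
#' @param meta_path output path for the sample sheet.
#' @return Invisibly, a list with the two paths.
#' @export
write_fpkm_table <- function(table, path, meta_path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(gene_id = rownames(table$fpkm), table$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(table$meta, meta_path)
  invisible(list(fpkm = path, meta = meta_path))
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id`, `description`, then one or more member gene ids. Duplicate
#' members within a set are removed; a line with fewer than three fields is
#' a parse error reported with its line number.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors of
#'   member gene ids, with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_format("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop_format("GMT parse error at line %d: expected set_id, description and >=1 member", i)
    }
    ids[i] <- fields[1]
    desc[i] <- fields[2]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  names(sets) <- ids
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member gene ids per set).
#' @param descriptions optional character vector of set descriptions.
#' @return `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_format("gene sets must be named")
  }
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    stop_format("gene set(s) with no members: %s",
                paste(names(sets)[empty], collapse = ", "))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  structure(sets, descriptions = descriptions %||% names(sets),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets `gene_set_collection` object.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene-score table
#'
#' @param gene_scores gene-score data frame as produced by
#'   [aggregate_to_genes()] or [score_screen()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_gene_scores <- function(gene_scores, path) {
  write_tsv(gene_scores, path)
}

#' Read a gene-score table
#'
#' @param path path to a tab-separated gene-score table with at least
#'   `gene_id`, `condition`, `direction`, and `tier` columns.
#' @return Gene-score data frame.
#' @export
read_gene_scores <- function(path) {
  df <- read_tsv(path, "gene-score table")
  check_columns(df, c("gene_id", "condition", "direction", "tier"),
                "gene-score table")
  df
}
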