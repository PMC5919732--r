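`%||%` <- function(a, b) if (is.null(a)) b else a

# percentages are reported as integer percent, rounded half-up (round() is
# round-half-even and would give 0.5 -> 0)
round_half_up <- function(x) floor(x + 0.5)

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_format("%s: missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

read_tsv <- function(path, what = path) {
  if (!file.exists(path)) stop_format("%s: file not found: %s", what, path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
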