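# ---------------------------------------------------------------------------
# Deterministic TSV serialization and run manifests. Numbers are written in
# decimal notation with 12 significant digits; infinite log-weights use the
# literal tokens -inf / inf so tables round-trip exactly.
# ---------------------------------------------------------------------------

.format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) return("NA")
      if (v == -Inf) return("-inf")
      if (v == Inf) return("inf")
      formatC(v, digits = 12, format = "g")
    }, character(1))
    out
  } else as.character(x)
}

#' Write a data frame as a deterministic TSV table
#'
#' @param rows a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  cells <- vapply(rows, .format_cell, character(nrow(rows)))
  if (nrow(rows) == 1L) cells <- matrix(cells, 1L)
  if (nrow(rows) == 0L) cells <- matrix(character(0), 0L, ncol(rows))
  lines <- c(paste(names(rows), collapse = "\t"),
             apply(cells, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' Columns that parse fully as numbers (including the `-inf`/`inf` tokens)
#' are returned numeric.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    w <- v
    w[v == "-inf"] <- "-Inf"
    w[v == "inf"] <- "Inf"
    num <- suppressWarnings(as.numeric(w))
    if (!anyNA(num[!(w %in% "NA")])) df[[j]] <- num
  }
  df
}

# write a plain-text run manifest next to a command's outputs
.write_manifest <- function(dir, command, config, seed, outputs) {
  lines <- c(
    paste0("command: ", command),
    paste0("config: ", config %||% "(none)"),
    paste0("seed: ", seed %||% "(none)"),
    paste0("package_version: ", as.character(utils::packageVersion("sensegain"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "outputs:",
    paste0("  - ", outputs))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(file.path(dir, "manifest.txt"))
}
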