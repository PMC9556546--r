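#' Read a key = value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' and blank lines ignored.  Values are parsed as numeric vectors
#' (comma-separated), logicals (`true`/`false`), or strings.
#'
#' @param path Path to the configuration file.
#' @return Named list of parsed values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <-
      if (!anyNA(num)) num
      else if (length(parts) == 1L && tolower(parts) %in% c("true", "false"))
        tolower(parts) == "true"
      else parts
  }
  out
}

#' Write a configuration file
#'
#' @param config Named list (numeric vectors, logicals or strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else paste(as.character(v), collapse = ", ")
  }, character(1))
  writeLines(paste(names(config), fmt, sep = " = "), path)
  invisible(path)
}

# TSV with '# key: value' provenance header lines
write_tsv_provenance <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm,
                       paste(as.character(provenance[[nm]]), collapse = ", ")),
               con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read any of the package's tab-separated outputs
#'
#' Skips `#`-prefixed provenance headers.
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv_file <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

read_tsv <- read_tsv_file

#' Read and write marker-genotype and depth-window tables
#'
#' Tab-separated schemas: markers as (`sample`, `chromosome`, `position`,
#' `col_reads`, `ler_reads`); depth windows as (`sample`, `chromosome`,
#' `start`, `end`, `depth`).  `#`-prefixed header lines are ignored on read
#' and used for provenance on write.
#'
#' @param x Table to write.
#' @param path File path.
#' @param provenance Optional named list for the header.
#' @return Readers return the parsed data frame; writers return `path`
#'   invisibly.
#' @export
write_marker_table <- function(x, path, provenance = list()) {
  write_tsv_provenance(x, path, provenance)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- read_tsv(path)
  need <- c("sample", "chromosome", "position", "col_reads", "ler_reads")
  if (!all(need %in% names(df)))
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname write_marker_table
#' @export
write_depth_windows <- function(x, path, provenance = list()) {
  write_tsv_provenance(x, path, provenance)
}

#' @rdname write_marker_table
#' @export
read_depth_windows <- function(path) {
  df <- read_tsv(path)
  need <- c("sample", "chromosome", "start", "end", "depth")
  if (!all(need %in% names(df)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read and write a karyotype table
#'
#' Tab-separated columns `chromosome`, `sc_length_um`, `genomic_length_mb`.
#' @param x A [karyotype()] (writer) or file path (reader).
#' @param path File path.
#' @return The karyotype, or `path` invisibly.
#' @export
write_karyotype <- function(x, path) {
  stopifnot(inherits(x, "karyotype"))
  write_tsv_provenance(as.data.frame(x), path)
}

#' @rdname write_karyotype
#' @export
read_karyotype <- function(path) {
  df <- read_tsv(path)
  karyotype(df$chromosome, df$sc_length_um, df$genomic_length_mb)
}
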