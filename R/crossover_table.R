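#' Construct a crossover table
#'
#' The common currency of the analysis stages: one row per crossover, with
#' the sample (gamete/plant) it was observed in, the chromosome, the point
#' position in Mb, and optionally the flanking-marker interval in bp and the
#' origin of the call.  Rows are sorted by sample, chromosome and position.
#'
#' @param sample Sample identifiers.
#' @param chromosome Chromosome identifiers.
#' @param position_mb Crossover point positions (Mb).
#' @param interval_start_bp,interval_end_bp Optional interval bounds (bp,
#'   0-based half-open); `start < end` where present.
#' @param origin Optional origin tag, e.g. `"bivalent"`, `"chromatid"` or
#'   `"called"`.
#' @param karyotype Optional [karyotype()]; if given, positions are checked
#'   against chromosome bounds.
#' @return A data frame of class `crossover_table`.
#' @export
crossover_table <- function(sample, chromosome, position_mb,
                            interval_start_bp = NA_real_,
                            interval_end_bp = NA_real_,
                            origin = NA_character_, karyotype = NULL) {
  n <- length(sample)
  recycle <- function(v) if (length(v) == 1L && n != 1L) rep(v, n) else v
  tab <- data.frame(sample = as.character(sample),
                    chromosome = as.character(chromosome),
                    position_mb = as.numeric(position_mb),
                    interval_start_bp = as.numeric(recycle(interval_start_bp)),
                    interval_end_bp = as.numeric(recycle(interval_end_bp)),
                    origin = as.character(recycle(origin)),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(tab$position_mb)) || any(tab$position_mb < 0))
    stop("crossover positions must be finite and non-negative")
  has_iv <- !is.na(tab$interval_start_bp) & !is.na(tab$interval_end_bp)
  if (any(tab$interval_start_bp[has_iv] >= tab$interval_end_bp[has_iv]))
    stop("interval start must be less than interval end")
  if (!is.null(karyotype)) {
    i <- match(tab$chromosome, karyotype$chromosome)
    if (anyNA(i)) stop("crossover on a chromosome absent from the karyotype")
    if (any(tab$position_mb > karyotype$genomic_length_mb[i]))
      stop("crossover position beyond chromosome end")
  }
  tab <- tab[order(tab$sample, tab$chromosome, tab$position_mb), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("crossover_table", "data.frame")
  tab
}

empty_crossover_table <- function() {
  crossover_table(character(0), character(0), numeric(0))
}

#' Write or read a crossover table as tab-separated text
#'
#' Files carry `#`-prefixed provenance header lines (written as
#' `# key: value`) followed by a header row and one row per crossover.
#'
#' @param tab A `crossover_table`.
#' @param path File path.
#' @param provenance Optional named list recorded in the header.
#' @return `write_crossover_table()` returns `path` invisibly;
#'   `read_crossover_table()` returns a `crossover_table`.
#' @export
write_crossover_table <- function(tab, path, provenance = list()) {
  stopifnot(inherits(tab, "crossover_table"))
  write_tsv_provenance(tab, path, provenance)
}

#' @rdname write_crossover_table
#' @export
read_crossover_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  crossover_table(df$sample, df$chromosome, df$position_mb,
                  df$interval_start_bp, df$interval_end_bp, df$origin)
}
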