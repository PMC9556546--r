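#' Sliding-window Col allele frequencies
#'
#' Aggregates per-marker allele read counts of a BC1 marker-genotype table
#' into sliding windows (default 50 kb window, 25 kb step).  Windows with no
#' reads are flagged uninformative rather than given a frequency of zero
#' (absence of markers is not evidence of the Ler allele).
#'
#' @param markers Data frame with columns `sample`, `chromosome`, `position`
#'   (bp, 1-based), `col_reads`, `ler_reads`.
#' @param chrom_lengths_bp Named vector of chromosome lengths (bp), or a
#'   [karyotype()] (genomic lengths converted from Mb).
#' @param window,step Window and step sizes in bp, both positive.
#' @return Data frame of class `window_af`: `sample`, `chromosome`, `start`,
#'   `end` (bp, 0-based half-open), `col_reads`, `ler_reads`, `af` (Col
#'   allele frequency; `NA` when uninformative), `informative`.
#' @export
window_allele_freq <- function(markers, chrom_lengths_bp, window = 50000,
                               step = 25000) {
  if (window <= 0) stop("'window' must be positive")
  if (step <= 0) stop("'step' must be positive")
  need <- c("sample", "chromosome", "position", "col_reads", "ler_reads")
  if (!all(need %in% names(markers)))
    stop("'markers' needs columns: ", paste(need, collapse = ", "))
  if (any(markers$col_reads < 0) || any(markers$ler_reads < 0))
    stop("read counts must be non-negative")
  if (inherits(chrom_lengths_bp, "karyotype")) {
    chrom_lengths_bp <- stats::setNames(
      round(chrom_lengths_bp$genomic_length_mb * 1e6),
      chrom_lengths_bp$chromosome)
  }
  out <- list()
  for (sm in unique(markers$sample)) {
    for (ch in names(chrom_lengths_bp)) {
      len <- chrom_lengths_bp[[ch]]
      starts <- seq(0, len, by = step)
      starts <- starts[starts < len]
      ends <- pmin(starts + window, len)
      sub <- markers[markers$sample == sm & markers$chromosome == ch, ]
      sub <- sub[order(sub$position), ]
      if (nrow(sub) && is.unsorted(sub$position, strictly = TRUE))
        stop("marker positions must be strictly increasing within a chromosome")
      # cumulative sums + interval lookup: counts in [start, end)
      ccum <- c(0, cumsum(sub$col_reads))
      lcum <- c(0, cumsum(sub$ler_reads))
      lo <- findInterval(starts, sub$position - 0.5)   # markers with pos > start
      hi <- findInterval(ends - 0.5, sub$position - 0.5)
      ncol_ <- ccum[hi + 1L] - ccum[lo + 1L]
      nler <- lcum[hi + 1L] - lcum[lo + 1L]
      tot <- ncol_ + nler
      out[[length(out) + 1L]] <- data.frame(
        sample = sm, chromosome = ch, start = starts, end = ends,
        col_reads = ncol_, ler_reads = nler,
        af = ifelse(tot > 0, ncol_ / tot, NA_real_),
        informative = tot > 0, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("window_af", "data.frame")
  res
}

#' Call crossovers from window allele frequencies
#'
#' Informative windows are classified homozygous-Col (`af >= hom_min`),
#' heterozygous (`het_min <= af <= het_max`) or ambiguous; ambiguous and
#' uninformative windows are skipped without breaking state.  Runs of at
#' least `min_run` consecutive classified windows in the same state form
#' confident blocks (with the default 25 kb step, the default of 4 windows
#' demands about 125 kb of consistent evidence, which suppresses blip
#' blocks at transition zones and in sparse-marker stretches), and every transition between consecutive confident
#' blocks of different state yields one crossover call.  The call interval
#' spans from the start of the last window of the left block to the end of
#' the first window of the right block (with dense error-free markers this
#' interval always contains the true breakpoint); the point position is
#' drawn uniformly within the interval (seed R's generator for
#' reproducibility).  Calls with overlapping intervals are merged.
#'
#' @param win_af A `window_af` table from [window_allele_freq()].
#' @param hom_min Minimum Col allele frequency of a homozygous-Col window.
#' @param het_min,het_max Col allele frequency band of heterozygous windows.
#' @param min_run Minimum number of consecutive classified windows forming a
#'   confident block.
#' @return Data frame of class `co_calls`: `sample`, `chromosome`,
#'   `interval_start`, `interval_end` (bp, 0-based half-open), `point` (bp),
#'   `type` (`"col_to_het"` or `"het_to_col"`).  A sample/chromosome with
#'   only ambiguous windows contributes no calls and raises a warning.
#' @export
call_crossovers <- function(win_af, hom_min = 0.95, het_min = 0.25,
                            het_max = 0.75, min_run = 4) {
  stopifnot(inherits(win_af, "data.frame"))
  calls <- list()
  for (sm in unique(win_af$sample)) {
    for (ch in unique(win_af$chromosome[win_af$sample == sm])) {
      sub <- win_af[win_af$sample == sm & win_af$chromosome == ch, ]
      sub <- sub[order(sub$start), ]
      inf <- sub[sub$informative, ]
      if (!nrow(inf)) next
      state <- ifelse(inf$af >= hom_min, "col",
                      ifelse(inf$af >= het_min & inf$af <= het_max, "het", NA))
      cls <- inf[!is.na(state), ]
      st <- state[!is.na(state)]
      if (!nrow(cls)) {
        warning(sprintf("sample %s, %s: all windows ambiguous; no calls", sm, ch))
        next
      }
      r <- rle(st)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      conf <- which(r$lengths >= min_run)
      if (length(conf) < 2L) next
      for (q in seq_len(length(conf) - 1L)) {
        a <- conf[q]; b <- conf[q + 1L]
        if (r$values[a] == r$values[b]) next
        left_win <- cls[ends_idx[a], ]
        right_win <- cls[starts_idx[b], ]
        calls[[length(calls) + 1L]] <- data.frame(
          sample = sm, chromosome = ch,
          interval_start = left_win$start, interval_end = right_win$end,
          type = paste0(r$values[a], "_to_", r$values[b]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) {
    out <- data.frame(sample = character(0), chromosome = character(0),
                      interval_start = numeric(0), interval_end = numeric(0),
                      point = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("co_calls", "data.frame")
    return(out)
  }
  out <- do.call(rbind, calls)
  # merge calls whose intervals overlap (double-reported transitions)
  merged <- list()
  for (key in unique(paste(out$sample, out$chromosome, sep = "\r"))) {
    sub <- out[paste(out$sample, out$chromosome, sep = "\r") == key, ]
    sub <- sub[order(sub$interval_start), ]
    keep <- sub[1, ]
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      if (sub$interval_start[i] <= keep$interval_end[nrow(keep)]) {
        keep$interval_end[nrow(keep)] <-
          max(keep$interval_end[nrow(keep)], sub$interval_end[i])
      } else keep <- rbind(keep, sub[i, ])
    }
    merged[[length(merged) + 1L]] <- keep
  }
  out <- do.call(rbind, merged)
  out$point <- floor(runif(nrow(out), out$interval_start, out$interval_end))
  out <- out[order(out$sample, out$chromosome, out$interval_start),
             c("sample", "chromosome", "interval_start", "interval_end",
               "point", "type")]
  rownames(out) <- NULL
  class(out) <- c("co_calls", "data.frame")
  out
}

#' Convert crossover calls to a crossover table
#'
#' @param calls A `co_calls` data frame from [call_crossovers()].
#' @param karyotype A [karyotype()] (for position validation).
#' @return A [crossover_table()] with positions in Mb and the call intervals
#'   carried along.
#' @export
calls_to_crossover_table <- function(calls, karyotype = NULL) {
  crossover_table(calls$sample, calls$chromosome, calls$point / 1e6,
                  calls$interval_start, calls$interval_end,
                  origin = "called", karyotype = karyotype)
}

#' Sample quality control
#'
#' A sample fails if its mean sequencing depth is below `min_depth` (low
#' coverage) or if more than `max_contam_frac` of its informative windows
#' have a Col allele frequency inside `contam_range` (potential
#' contamination; in a clean backcross, windows are either heterozygous,
#' around 0.5, or homozygous Col, near 1, so an excess in between indicates
#' mixed material).
#'
#' @param win_af A `window_af` table covering the samples to check.
#' @param depths Named numeric vector of mean depths (x) per sample, or a
#'   data frame with columns `sample` and `depth`.
#' @param min_depth Depth threshold (x).
#' @param contam_range Col allele frequency range flagging contamination.
#' @param max_contam_frac Maximum tolerated fraction of windows in
#'   `contam_range`.
#' @return Data frame: `sample`, `depth`, `contam_frac`, `pass`, `reason`
#'   (`"pass"`, `"low_coverage"` or `"contamination"`).
#' @export
qc_samples <- function(win_af, depths, min_depth = 0.1,
                       contam_range = c(0.8, 0.9), max_contam_frac = 0.05) {
  if (is.data.frame(depths))
    depths <- stats::setNames(depths$depth, depths$sample)
  samples <- unique(win_af$sample)
  res <- lapply(samples, function(sm) {
    d <- depths[[sm]]
    if (is.null(d) || is.na(d)) stop(sprintf("no depth given for sample %s", sm))
    af <- win_af$af[win_af$sample == sm & win_af$informative]
    cf <- if (length(af))
      mean(af >= contam_range[1] & af <= contam_range[2]) else 0
    reason <- if (d < min_depth) "low_coverage"
              else if (cf > max_contam_frac) "contamination"
              else "pass"
    data.frame(sample = sm, depth = d, contam_frac = cf,
               pass = reason == "pass", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Screen samples for aneuploidy from window sequencing depths
#'
#' For each sample, every chromosome pair is compared by a two-sided
#' Mann-Whitney test on its 100 kb window depths; p-values are adjusted by
#' Benjamini-Hochberg across the pairs of that sample.  A chromosome is
#' flagged when, against the majority of the other chromosomes, it shows a
#' median fold change above `fold_threshold` (gain; below its reciprocal for
#' loss) together with an adjusted p-value below `p_threshold`.  The
#' p-value cut is applied to the adjusted value (the stricter reading); set
#' `adjust_first = FALSE` to threshold raw p-values instead.
#'
#' @param depth_windows Data frame: `sample`, `chromosome`, `start`, `end`,
#'   `depth` (window depths in x; windows should tile each chromosome
#'   without overlap, 100 kb by convention).
#' @param fold_threshold Minimum median fold change (> 1) to call a gain.
#' @param p_threshold Maximum (adjusted) p-value.
#' @param min_windows Minimum windows per chromosome; chromosomes below it
#'   make the sample's screen unreliable.
#' @param adjust_first Logical; apply `p_threshold` to FDR-adjusted p-values
#'   (default) or to raw ones.
#' @return An object of class `aneuploidy_screen`: list with `calls`
#'   (flagged sample/chromosome rows with `direction` and `median_fold`),
#'   `pairs` (all pairwise tests), `unreliable` (samples with too few
#'   windows).
#' @export
aneuploidy_screen <- function(depth_windows, fold_threshold = 1.2,
                              p_threshold = 1e-20, min_windows = 20,
                              adjust_first = TRUE) {
  need <- c("sample", "chromosome", "depth")
  if (!all(need %in% names(depth_windows)))
    stop("'depth_windows' needs columns: ", paste(need, collapse = ", "))
  if (any(depth_windows$depth < 0)) stop("depths must be non-negative")
  pair_rows <- list()
  call_rows <- list()
  unreliable <- character(0)
  for (sm in unique(depth_windows$sample)) {
    sub <- depth_windows[depth_windows$sample == sm, ]
    chroms <- unique(sub$chromosome)
    if (length(chroms) < 2L) {
      unreliable <- c(unreliable, sm)
      next
    }
    d <- split(sub$depth, factor(sub$chromosome, chroms))
    if (any(lengths(d) < min_windows)) {
      unreliable <- c(unreliable, sm)
      next
    }
    ij <- utils::combn(length(chroms), 2L)
    p <- numeric(ncol(ij))
    fold <- numeric(ncol(ij))
    for (q in seq_len(ncol(ij))) {
      x <- d[[ij[1L, q]]]; y <- d[[ij[2L, q]]]
      p[q] <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      fold[q] <- median(x) / median(y)
    }
    padj <- p.adjust(p, method = "fdr")
    p_used <- if (adjust_first) padj else p
    pr <- data.frame(sample = sm, chrom_a = chroms[ij[1L, ]],
                     chrom_b = chroms[ij[2L, ]], median_fold = fold,
                     p = p, p_adj = padj, stringsAsFactors = FALSE)
    pair_rows[[length(pair_rows) + 1L]] <- pr
    for (k in seq_along(chroms)) {
      ch <- chroms[k]
      rows_a <- which(ij[1L, ] == k)
      rows_b <- which(ij[2L, ] == k)
      f <- c(fold[rows_a], 1 / fold[rows_b])         # fold of ch vs other
      pu <- c(p_used[rows_a], p_used[rows_b])
      gain <- f > fold_threshold & pu < p_threshold
      loss <- f < 1 / fold_threshold & pu < p_threshold
      npairs <- length(f)
      if (sum(gain) > npairs / 2 || sum(loss) > npairs / 2) {
        dir <- if (sum(gain) > npairs / 2) "gain" else "loss"
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          sample = sm, chromosome = ch, direction = dir,
          median_fold = median(f), max_p = max(pu[if (dir == "gain") gain else loss]),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_calls <- data.frame(sample = character(0), chromosome = character(0),
                            direction = character(0), median_fold = numeric(0),
                            max_p = numeric(0), stringsAsFactors = FALSE)
  out <- list(calls = if (length(call_rows)) do.call(rbind, call_rows)
                      else empty_calls,
              pairs = if (length(pair_rows)) do.call(rbind, pair_rows)
                      else NULL,
              unreliable = unreliable)
  class(out) <- "aneuploidy_screen"
  out
}

#' @export
print.aneuploidy_screen <- function(x, ...) {
  ns <- if (is.null(x$pairs)) 0L else length(unique(x$pairs$sample))
  cat(sprintf("aneuploidy screen: %d samples tested, %d flagged call(s)\n",
              ns, nrow(x$calls)))
  if (nrow(x$calls)) print(x$calls, row.names = FALSE)
  if (length(x$unreliable))
    cat("unreliable (too few windows):", paste(x$unreliable, collapse = ", "), "\n")
  invisible(x)
}
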