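#' Distances between crossovers on two-crossover chromosomes
#'
#' For every (sample, chromosome) combination carrying exactly two
#' crossovers, emits the distance between them; chromosomes with any other
#' crossover count contribute nothing.
#'
#' @param tab A [crossover_table()].
#' @return Data frame with columns `chromosome`, `sample`, `distance_mb`.
#' @export
two_co_distances <- function(tab) {
  stopifnot(inherits(tab, "crossover_table"))
  if (!nrow(tab))
    return(data.frame(chromosome = character(0), sample = character(0),
                      distance_mb = numeric(0), stringsAsFactors = FALSE))
  splits <- split(tab$position_mb, list(tab$sample, tab$chromosome),
                  drop = TRUE, sep = "\r")
  two <- splits[lengths(splits) == 2L]
  if (!length(two))
    return(data.frame(chromosome = character(0), sample = character(0),
                      distance_mb = numeric(0), stringsAsFactors = FALSE))
  meta <- do.call(rbind, strsplit(names(two), "\r", fixed = TRUE))
  out <- data.frame(chromosome = meta[, 2L], sample = meta[, 1L],
                    distance_mb = vapply(two, function(p) abs(p[2L] - p[1L]),
                                         numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chromosome, out$sample), , drop = FALSE]
}

#' Permutation null for inter-crossover distances
#'
#' Builds the distance distribution expected without interference: for each
#' chromosome, all crossover positions observed on two-crossover chromosomes
#' in the whole population are pooled and the distances between all possible
#' position pairs (across and within samples) are computed.  The pooled set
#' is then downsampled so each chromosome's share matches its share of the
#' observed two-crossover dataset.
#'
#' @param tab A [crossover_table()].
#' @param n_total Approximate size of the downsampled null (distances are
#'   apportioned across chromosomes by their observed two-crossover sample
#'   share, capped at the number of available pairs).
#' @return An object of class `distance_null`: data frame with columns
#'   `chromosome` and `distance_mb`; attribute `downsample` records the
#'   per-chromosome sizes.  Uses R's global generator; seed with
#'   [set.seed()] for reproducibility.
#' @export
permutation_null <- function(tab, n_total = 10000) {
  obs <- two_co_distances(tab)
  if (!nrow(obs))
    stop("no chromosome with exactly two crossovers in any sample")
  splits <- split(tab$position_mb, list(tab$sample, tab$chromosome),
                  drop = TRUE, sep = "\r")
  two <- splits[lengths(splits) == 2L]
  chrom_of <- vapply(strsplit(names(two), "\r", fixed = TRUE),
                     `[`, character(1), 2L)
  share <- table(obs$chromosome)
  share <- share / sum(share)
  dists <- lapply(names(share), function(ch)
    as.numeric(stats::dist(unlist(two[chrom_of == ch], use.names = FALSE))))
  names(dists) <- names(share)
  # largest total for which every chromosome can still supply its share
  avail <- vapply(dists, length, integer(1))
  n_eff <- min(n_total, floor(min(avail / as.numeric(share))))
  pieces <- lapply(names(share), function(ch) {
    d <- dists[[ch]]
    take <- min(length(d), max(1L, round(n_eff * share[[ch]])))
    data.frame(chromosome = ch,
               distance_mb = if (take < length(d)) sample(d, take) else d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "downsample") <- vapply(pieces, nrow, integer(1))
  names(attr(out, "downsample")) <- names(share)
  class(out) <- c("distance_null", "data.frame")
  out
}

#' Two-sided Mann-Whitney comparison of distance distributions
#'
#' Compares observed inter-crossover distances with a no-interference null.
#' Uses exact enumeration of the rank-sum distribution when both groups have
#' at most 8 values, and the normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param observed Numeric vector of observed distances, or the data frame
#'   from [two_co_distances()].
#' @param null A `distance_null` (or numeric vector) of null distances.
#' @return The two-sided p-value.
#' @export
compare_distance_distributions <- function(observed, null) {
  x <- if (is.data.frame(observed)) observed$distance_mb else observed
  y <- if (is.data.frame(null)) null$distance_mb else null
  if (!length(x) || !length(y)) stop("both distance sets must be non-empty")
  mann_whitney_2s(x, y)
}

# Two-sided Mann-Whitney U; exact enumeration for small groups (handles ties
# through midranks), otherwise normal approximation with tie correction.
mann_whitney_2s <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (max(n1, n2) <= 8L) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n1)])
    idx <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[idx], nrow = n1))
    mu <- n1 * (n1 + n2 + 1) / 2
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(min(1, p))
  }
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                correct = TRUE)$p.value)
}

#' Coefficient-of-coincidence curve
#'
#' Each chromosome is divided into `n_intervals` equal-Mb intervals.  For
#' every interval pair (i < j) the coefficient of coincidence is the
#' observed frequency of samples carrying a crossover in both intervals
#' divided by the product of the single-interval frequencies (presence
#' indicators: at least one crossover per interval).  Pairs whose expected
#' co-occurrence is zero are undefined and omitted.  Values near 1 mean no
#' interference; values below 1 at short distances are the signature of
#' crossover interference.
#'
#' @param tab A [crossover_table()].
#' @param karyotype A [karyotype()] providing genomic lengths.
#' @param n_intervals Number of equal intervals per chromosome (>= 2).
#' @param exclude Chromosome identifiers excluded from the analysis (the
#'   hybrid analyses conventionally drop chromosome 4, which carries a
#'   transgene-associated translocation and an inversion).
#' @param samples Sample universe used for the frequencies.  Defaults to the
#'   samples recorded by [simulate_population()], or the distinct samples in
#'   `tab`.  Supply explicitly if some samples carry zero crossovers and are
#'   otherwise invisible.
#' @return An object of class `coc_curve`: list with `pairs` (one row per
#'   chromosome and interval pair: `chromosome`, `i`, `j`, `distance_mb`,
#'   `coc`) and `curve` (mean CoC per inter-interval separation across
#'   chromosomes: `separation`, `distance_mb`, `coc`, `n_pairs`).
#' @export
coc_curve <- function(tab, karyotype, n_intervals = 13, exclude = NULL,
                      samples = NULL) {
  stopifnot(inherits(tab, "crossover_table"), inherits(karyotype, "karyotype"))
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 2L) stop("'n_intervals' must be at least 2")
  if (is.null(samples))
    samples <- attr(tab, "samples") %||% unique(tab$sample)
  kar <- karyotype[!karyotype$chromosome %in% exclude, , drop = FALSE]
  tab2 <- tab[!tab$chromosome %in% exclude, , drop = FALSE]
  if (!nrow(tab2)) stop("crossover table is empty after exclusions")
  ns <- length(samples)
  pair_rows <- list()
  for (k in seq_len(nrow(kar))) {
    ch <- kar$chromosome[k]
    len <- kar$genomic_length_mb[k]
    w <- len / n_intervals
    sub <- tab2[tab2$chromosome == ch, , drop = FALSE]
    # presence matrix: samples x intervals
    pres <- matrix(FALSE, ns, n_intervals)
    if (nrow(sub)) {
      iv <- pmin(n_intervals, floor(sub$position_mb / w) + 1L)
      si <- match(sub$sample, samples)
      ok <- !is.na(si)
      pres[cbind(si[ok], iv[ok])] <- TRUE
    }
    f <- colMeans(pres)
    ij <- utils::combn(n_intervals, 2L)
    fij <- vapply(seq_len(ncol(ij)), function(q)
      mean(pres[, ij[1L, q]] & pres[, ij[2L, q]]), numeric(1))
    expected <- f[ij[1L, ]] * f[ij[2L, ]]
    coc <- ifelse(expected > 0, fij / expected, NA_real_)
    pair_rows[[k]] <- data.frame(chromosome = ch, i = ij[1L, ], j = ij[2L, ],
                                 separation = ij[2L, ] - ij[1L, ],
                                 distance_mb = (ij[2L, ] - ij[1L, ]) * w,
                                 coc = coc, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  defined <- pairs[!is.na(pairs$coc), , drop = FALSE]
  if (!nrow(defined)) stop("all interval pairs have zero expected co-occurrence")
  curve <- do.call(rbind, lapply(split(defined, defined$separation), function(d)
    data.frame(separation = d$separation[1L],
               distance_mb = mean(d$distance_mb),
               coc = mean(d$coc), n_pairs = nrow(d))))
  rownames(curve) <- NULL
  out <- list(pairs = pairs, curve = curve[order(curve$separation), ],
              n_intervals = n_intervals, n_samples = ns)
  class(out) <- "coc_curve"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coc_curve <- function(x, ...) {
  cat(sprintf("CoC curve: %d intervals, %d samples; mean CoC over defined pairs = %.3f\n",
              x$n_intervals, x$n_samples, mean(x$pairs$coc, na.rm = TRUE)))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.coc_curve <- function(x, ...) {
  plot(x$curve$distance_mb, x$curve$coc, type = "b",
       xlab = "inter-interval distance (Mb)", ylab = "CoC",
       ylim = c(0, max(1.2, x$curve$coc)), ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Crossover count summaries
#'
#' Per-chromosome mean crossover counts, the Pearson correlation of the mean
#' count with genomic length, the matrix of between-chromosome count
#' correlations across samples (crossover covariation), and per-sample
#' totals.
#'
#' @param tab A [crossover_table()].
#' @param karyotype A [karyotype()].
#' @param samples Sample universe (see [coc_curve()]).
#' @return An object of class `co_summary`: list with `per_chromosome`
#'   (chromosome, genomic_length_mb, mean_count), `length_correlation`
#'   (Pearson r, with attribute `reliable` FALSE when fewer than 3
#'   chromosomes), `count_correlations` (matrix), `per_sample` (sample,
#'   total).
#' @export
co_count_summaries <- function(tab, karyotype, samples = NULL) {
  stopifnot(inherits(tab, "crossover_table"), inherits(karyotype, "karyotype"))
  if (!nrow(tab)) stop("crossover table is empty")
  if (is.null(samples))
    samples <- attr(tab, "samples") %||% unique(tab$sample)
  counts <- matrix(0L, length(samples), nrow(karyotype),
                   dimnames = list(samples, karyotype$chromosome))
  t2 <- tab[tab$sample %in% samples & tab$chromosome %in% karyotype$chromosome, ]
  if (nrow(t2)) {
    tt <- table(factor(t2$sample, samples),
                factor(t2$chromosome, karyotype$chromosome))
    counts[] <- as.integer(tt)
  }
  mean_counts <- colMeans(counts)
  r <- if (nrow(karyotype) >= 2L &&
           isTRUE(stats::sd(mean_counts) > 0) &&
           isTRUE(stats::sd(karyotype$genomic_length_mb) > 0))
    cor(mean_counts, karyotype$genomic_length_mb) else NA_real_
  attr(r, "reliable") <- nrow(karyotype) >= 3L
  cc <- if (nrow(counts) >= 3L && ncol(counts) >= 2L)
    suppressWarnings(cor(counts)) else NULL
  out <- list(per_chromosome = data.frame(
                chromosome = karyotype$chromosome,
                genomic_length_mb = karyotype$genomic_length_mb,
                mean_count = as.numeric(mean_counts),
                stringsAsFactors = FALSE),
              length_correlation = r,
              count_correlations = cc,
              per_sample = data.frame(sample = samples,
                                      total = as.integer(rowSums(counts)),
                                      stringsAsFactors = FALSE))
  class(out) <- "co_summary"
  out
}

#' @export
print.co_summary <- function(x, ...) {
  print(x$per_chromosome, row.names = FALSE)
  cat(sprintf("Pearson r (mean count vs genomic length): %.3f%s\n",
              x$length_correlation,
              if (!attr(x$length_correlation, "reliable"))
                " (fewer than 3 chromosomes; unreliable)" else ""))
  if (!is.null(x$count_correlations)) {
    off <- x$count_correlations[upper.tri(x$count_correlations)]
    cat(sprintf("between-chromosome count correlations: range [%.3f, %.3f]\n",
                min(off), max(off)))
  }
  invisible(x)
}

#' Sliding-window crossover density profile
#'
#' Windows of `window_mb` tile each chromosome with step `step_mb`; each
#' window's crossover count is normalised by the number of samples.
#'
#' @param tab A [crossover_table()].
#' @param karyotype A [karyotype()].
#' @param window_mb Window size (Mb), > 0.
#' @param step_mb Step size (Mb), > 0.
#' @param samples Sample universe (see [coc_curve()]).
#' @return Data frame with columns `chromosome`, `start_mb`, `end_mb`
#'   (0-based half-open), `count`, `density` (crossovers per sample).
#' @export
co_density_profile <- function(tab, karyotype, window_mb = 1, step_mb = 0.05,
                               samples = NULL) {
  stopifnot(inherits(tab, "crossover_table"), inherits(karyotype, "karyotype"))
  if (window_mb <= 0) stop("'window_mb' must be positive")
  if (step_mb <= 0) stop("'step_mb' must be positive")
  if (is.null(samples))
    samples <- attr(tab, "samples") %||% unique(tab$sample)
  ns <- max(1L, length(samples))
  out <- lapply(seq_len(nrow(karyotype)), function(k) {
    len <- karyotype$genomic_length_mb[k]
    starts <- seq(0, len, by = step_mb)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_mb, len)
    pos <- tab$position_mb[tab$chromosome == karyotype$chromosome[k]]
    cnt <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos < ends[i]), numeric(1))
    data.frame(chromosome = karyotype$chromosome[k], start_mb = starts,
               end_mb = ends, count = cnt, density = cnt / ns,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
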