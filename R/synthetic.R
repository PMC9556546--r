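#' Specification of a synthetic BC1 sequencing population
#'
#' Describes the synthetic stand-in for a backcross (BC1) sequencing
#' population: hybrid Col/Ler gametes backcrossed to Col, genotyped at
#' biallelic markers by shallow sequencing.  Gamete genotypes consist of
#' Col-homozygous and Col/Ler-heterozygous blocks delimited by the true
#' crossovers; Ler-homozygous states never occur in a backcross to Col.
#'
#' @param n_samples Number of samples (>= 1).
#' @param genotype A [genotype_spec()] used when crossovers are drawn from a
#'   model.
#' @param karyotype A [karyotype()].
#' @param marker_density Markers per kb (e.g. 0.1 = one marker per 10 kb).
#' @param mean_depth Mean sequencing depth per marker (x).
#' @param error_rate Per-read genotyping error (allele flip) rate in [0, 1).
#' @param masks Optional data frame (`chromosome`, `start`, `end` in bp) of
#'   recombination-suppressed intervals (e.g. pericentromeres); generated
#'   breakpoints never fall inside a mask.
#' @param trisomy Optional list(`fraction`, `chromosome`, `het_centromere`):
#'   a fraction of samples carries an extra copy of one chromosome (1.5x
#'   depth); with `het_centromere = TRUE` the two non-recombinant
#'   centromeric copies are Col and Ler (meiosis I nondisjunction), giving a
#'   Col allele frequency near 2/3 there.
#' @return A list of class `synthetic_population_spec`.
#' @export
synthetic_population_spec <- function(n_samples, genotype, karyotype,
                                      marker_density = 0.1, mean_depth = 1,
                                      error_rate = 0, masks = NULL,
                                      trisomy = NULL) {
  if (!is.numeric(n_samples) || n_samples < 1) stop("'n_samples' must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("'error_rate' must be in [0, 1)")
  if (marker_density <= 0) stop("'marker_density' must be positive")
  if (mean_depth <= 0) stop("'mean_depth' must be positive")
  stopifnot(inherits(karyotype, "karyotype"))
  if (!is.null(masks)) {
    if (!all(c("chromosome", "start", "end") %in% names(masks)))
      stop("'masks' needs columns chromosome, start, end")
    i <- match(masks$chromosome, karyotype$chromosome)
    if (anyNA(i)) stop("mask on a chromosome absent from the karyotype")
    if (any(masks$start < 0) ||
        any(masks$end > karyotype$genomic_length_mb[i] * 1e6))
      stop("mask outside chromosome bounds")
  }
  if (!is.null(trisomy)) {
    if (is.null(trisomy$fraction) || is.null(trisomy$chromosome))
      stop("'trisomy' needs elements fraction and chromosome")
    trisomy$het_centromere <- isTRUE(trisomy$het_centromere)
  }
  spec <- list(n_samples = as.integer(n_samples), genotype = genotype,
               karyotype = karyotype, marker_density = marker_density,
               mean_depth = mean_depth, error_rate = error_rate,
               masks = masks, trisomy = trisomy)
  class(spec) <- "synthetic_population_spec"
  spec
}

#' Generate a marker map
#'
#' Marker positions are drawn uniformly along each chromosome, sorted and
#' deduplicated; the expected count is `density * length`.
#'
#' @param karyotype A [karyotype()].
#' @param marker_density Markers per kb.
#' @return Data frame: `chromosome`, `position` (bp, 1-based, strictly
#'   increasing within each chromosome).
#' @export
generate_marker_map <- function(karyotype, marker_density = 0.1) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (marker_density <= 0) stop("'marker_density' must be positive")
  out <- lapply(seq_len(nrow(karyotype)), function(k) {
    len_bp <- round(karyotype$genomic_length_mb[k] * 1e6)
    n <- round(marker_density * len_bp / 1000)
    pos <- sort(unique(ceiling(runif(n) * len_bp)))
    data.frame(chromosome = karyotype$chromosome[k], position = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

in_mask <- function(pos_bp, chrom, masks) {
  if (is.null(masks)) return(rep(FALSE, length(pos_bp)))
  hit <- rep(FALSE, length(pos_bp))
  for (i in which(masks$chromosome == chrom))
    hit <- hit | (pos_bp >= masks$start[i] & pos_bp < masks$end[i])
  hit
}

# draw one chromatid's breakpoints (bp) for a chromosome, respecting masks
draw_breakpoints <- function(spec, chrom_idx, max_tries = 1000) {
  kar <- spec$karyotype
  ch <- kar$chromosome[chrom_idx]
  len_mb <- kar$genomic_length_mb[chrom_idx]
  gt <- spec$genotype
  for (try in seq_len(max_tries)) {
    pos_mb <-
      if (gt$zyp1) {
        lam <- zyp1_lambda(gt, kar)
        simulate_zyp1_chromatid(len_mb, lam[chrom_idx])
      } else {
        prm <- coarsening_params(y = gt$y)
        biv <- simulate_bivalent_cos(kar$sc_length_um[chrom_idx], prm)
        map_sc_to_genome(bivalent_to_chromatid(biv),
                         kar$sc_length_um[chrom_idx], len_mb)
      }
    bp <- round(pos_mb * 1e6)
    if (!any(in_mask(bp, ch, spec$masks))) return(bp)
  }
  stop("could not draw breakpoints outside the masks")
}

#' Generate a BC1 marker-genotype population with planted crossovers
#'
#' Produces, per sample, a chromatid genotype (Col-homozygous vs
#' heterozygous blocks delimited by the true crossover breakpoints) and
#' per-marker read counts: the total is Poisson at the mean depth, split
#' between the Col and Ler alleles according to the genotype, with each read
#' flipped at the genotyping error rate.  When a trisomy is specified, the
#' first `round(fraction * n_samples)` samples carry three copies of the
#' trisomic chromosome (1.5x marker depth; allele frequencies follow the
#' three-copy dosage).
#'
#' @param spec A [synthetic_population_spec()].
#' @param co_source Either `"model"` (default; breakpoints drawn from the
#'   genotype's model, masks respected) or a [crossover_table()] of explicit
#'   truth crossovers (positions in Mb).
#' @return A list of class `synthetic_population`: `markers` (the
#'   marker-genotype table), `truth` (a [crossover_table()] of planted
#'   breakpoints), `marker_map`, `trisomic_samples`, `depths` (realised mean
#'   read depth per sample).
#' @export
generate_population_markers <- function(spec, co_source = "model") {
  stopifnot(inherits(spec, "synthetic_population_spec"))
  kar <- spec$karyotype
  map <- generate_marker_map(kar, spec$marker_density)
  ids <- sprintf("bc1_%04d", seq_len(spec$n_samples))
  n_tri <- if (is.null(spec$trisomy)) 0L
           else round(spec$trisomy$fraction * spec$n_samples)
  tri_samples <- ids[seq_len(n_tri)]
  explicit <- inherits(co_source, "crossover_table")
  if (!explicit && !identical(co_source, "model"))
    stop("'co_source' must be \"model\" or a crossover_table")
  err <- spec$error_rate

  marker_rows <- vector("list", spec$n_samples)
  truth_rows <- vector("list", spec$n_samples)
  depth_real <- numeric(spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    per_chrom_m <- vector("list", nrow(kar))
    per_chrom_t <- vector("list", nrow(kar))
    for (k in seq_len(nrow(kar))) {
      ch <- kar$chromosome[k]
      len_bp <- round(kar$genomic_length_mb[k] * 1e6)
      bp <- if (explicit) {
        v <- round(co_source$position_mb[co_source$sample == ids[s] &
                                           co_source$chromosome == ch] * 1e6)
        if (any(v < 0) || any(v > len_bp))
          stop("explicit crossover outside chromosome bounds")
        sort(v)
      } else draw_breakpoints(spec, k)
      pos <- map$position[map$chromosome == ch]
      # gamete haplotype: blocks alternate between Col and Ler at breakpoints
      start_col <- runif(1) < 0.5
      seg <- findInterval(pos, bp)              # 0..length(bp)
      hap_col <- (seg %% 2L == 0L) == start_col
      trisomic_here <- ids[s] %in% tri_samples &&
        identical(ch, spec$trisomy$chromosome)
      if (trisomic_here) {
        # three copies: gamete pair (complementary if MI nondisjunction,
        # duplicated if MII) plus the Col backcross parent
        hap2_col <- if (spec$trisomy$het_centromere) !hap_col else hap_col
        k_col <- hap_col + hap2_col + 1L         # Col copies out of 3
        p_col <- (k_col / 3) * (1 - err) + ((3 - k_col) / 3) * err
        n_reads <- rpois(length(pos), 1.5 * spec$mean_depth)
      } else {
        p_col <- ifelse(hap_col, 1 - err, 0.5)
        n_reads <- rpois(length(pos), spec$mean_depth)
      }
      n_col <- rbinom(length(pos), n_reads, p_col)
      per_chrom_m[[k]] <- data.frame(sample = ids[s], chromosome = ch,
                                     position = pos, col_reads = n_col,
                                     ler_reads = n_reads - n_col,
                                     stringsAsFactors = FALSE)
      if (length(bp))
        per_chrom_t[[k]] <- data.frame(sample = ids[s], chromosome = ch,
                                       position_mb = bp / 1e6,
                                       stringsAsFactors = FALSE)
    }
    mm <- do.call(rbind, per_chrom_m)
    depth_real[s] <- mean(mm$col_reads + mm$ler_reads)
    marker_rows[[s]] <- mm
    tt <- per_chrom_t[!vapply(per_chrom_t, is.null, logical(1))]
    if (length(tt)) truth_rows[[s]] <- do.call(rbind, tt)
  }
  markers <- do.call(rbind, marker_rows)
  tr <- truth_rows[!vapply(truth_rows, is.null, logical(1))]
  truth <- if (length(tr)) {
    td <- do.call(rbind, tr)
    crossover_table(td$sample, td$chromosome, td$position_mb,
                    origin = "truth", karyotype = kar)
  } else empty_crossover_table()
  attr(truth, "samples") <- ids
  out <- list(markers = markers, truth = truth, marker_map = map,
              trisomic_samples = tri_samples,
              depths = stats::setNames(depth_real, ids))
  class(out) <- "synthetic_population"
  out
}

#' Generate window sequencing-depth profiles
#'
#' Emulates 100 kb window depth output: each window's depth is a scaled
#' Poisson draw around the mean (granularity `1/reads_per_x`), and trisomic
#' chromosomes are scaled by 1.5.
#'
#' @param spec A [synthetic_population_spec()].
#' @param window_bp Window size (bp); windows tile each chromosome without
#'   overlap.
#' @param reads_per_x Poisson intensity per 1x of depth per window (controls
#'   the noise level; 100 corresponds to ~100 reads per 100 kb window at 1x).
#' @return Data frame: `sample`, `chromosome`, `start`, `end`, `depth`.
#' @export
generate_depth_profile <- function(spec, window_bp = 100000, reads_per_x = 100) {
  stopifnot(inherits(spec, "synthetic_population_spec"))
  kar <- spec$karyotype
  ids <- sprintf("bc1_%04d", seq_len(spec$n_samples))
  n_tri <- if (is.null(spec$trisomy)) 0L
           else round(spec$trisomy$fraction * spec$n_samples)
  tri_samples <- ids[seq_len(n_tri)]
  out <- list()
  for (s in seq_along(ids)) {
    for (k in seq_len(nrow(kar))) {
      ch <- kar$chromosome[k]
      len <- round(kar$genomic_length_mb[k] * 1e6)
      starts <- seq(0, len - 1, by = window_bp)
      ends <- pmin(starts + window_bp, len)
      scale <- if (ids[s] %in% tri_samples &&
                   identical(ch, spec$trisomy$chromosome)) 1.5 else 1
      lam <- spec$mean_depth * scale * reads_per_x * (ends - starts) / window_bp
      depth <- rpois(length(starts), lam) / reads_per_x
      out[[length(out) + 1L]] <- data.frame(
        sample = ids[s], chromosome = ch, start = starts, end = ends,
        depth = depth, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
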