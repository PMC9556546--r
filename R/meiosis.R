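#' Simulate crossover designation on one bivalent
#'
#' Runs the full coarsening pipeline for a single synaptonemal complex:
#' initialisation, explicit-Euler integration for `duration`, and
#' designation of foci above the MLH1 threshold.
#'
#' @param sc_length_um SC length (micrometre).
#' @param params A [coarsening_params()] object (its `y` encodes the
#'   genotype's HEI10 dosage).
#' @param duration Integration time (s); defaults to `params$duration`.
#' @return Numeric vector of designated focus positions (micrometre,
#'   ascending) on the bivalent.
#' @examples
#' set.seed(1)
#' simulate_bivalent_cos(12, coarsening_params(y = 2))
#' @export
simulate_bivalent_cos <- function(sc_length_um, params = coarsening_params(),
                                  duration = params$duration) {
  st <- init_sc_state(sc_length_um, params)
  st <- simulate_coarsening(st, params, duration)
  designate_foci(st, params$m_thresh)$position
}

#' Thin bivalent crossovers to one chromatid
#'
#' Each crossover on a bivalent involves two of the four chromatids, so a
#' transmitted chromatid carries each crossover independently with
#' probability one half.
#'
#' @param positions Crossover positions on the bivalent (any units).
#' @return The retained subset, in the original order.
#' @export
bivalent_to_chromatid <- function(positions) {
  if (!length(positions)) return(positions)
  positions[runif(length(positions)) < 0.5]
}

#' Map an SC position to a genomic position
#'
#' Assumes a linear relation between position along the SC (micrometre) and
#' genomic position (Mb).
#'
#' @param position_um Position(s) on the SC, in `[0, sc_length_um]`.
#' @param sc_length_um SC length (micrometre).
#' @param genomic_length_mb Chromosome genomic length (Mb).
#' @return Genomic position(s) in Mb.
#' @examples
#' map_sc_to_genome(15, 60, 30)  # 7.5 Mb
#' @export
map_sc_to_genome <- function(position_um, sc_length_um, genomic_length_mb) {
  if (any(position_um < 0) || any(position_um > sc_length_um))
    stop("position outside [0, sc_length_um]")
  position_um / sc_length_um * genomic_length_mb
}

#' Simulate one chromatid under the zyp1 (no-SC) null model
#'
#' Without a synaptonemal complex crossovers do not interfere: their number
#' per chromatid is Poisson and their positions are i.i.d. uniform along the
#' chromosome.
#'
#' @param genomic_length_mb Chromosome genomic length (Mb).
#' @param lambda Mean number of crossovers per chromatid (>= 0).
#' @return Sorted crossover positions (Mb); possibly empty.
#' @export
simulate_zyp1_chromatid <- function(genomic_length_mb, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("'lambda' must be a single non-negative number")
  n <- rpois(1L, lambda)
  sort(runif(n, 0, genomic_length_mb))
}

#' Simulate a population of meioses
#'
#' For coarsening genotypes, each cell simulates one bivalent per chromosome
#' (independent SCs), records the total number of designated (MLH1-positive)
#' foci, samples one transmitted chromatid set by 50% thinning, and maps
#' positions linearly to Mb.  For `zyp1` genotypes, chromatid crossover
#' counts are Poisson and positions uniform; the per-cell focus count is the
#' sum of bivalent-level Poisson draws with twice the chromatid mean.
#' All randomness flows from R's global generator ([set.seed()] for
#' reproducibility); cells are simulated sequentially, so results do not
#' depend on any batching of the work.
#'
#' @param genotype A [genotype_spec()].
#' @param karyotype A [karyotype()].
#' @param n_cells Number of cells (meioses) to simulate, >= 1.
#' @param params A [coarsening_params()]; its `y` is overridden by the
#'   genotype's dosage factor for coarsening genotypes.
#' @return An object of class `meiosis_population`: list with
#'   `focus_counts` (per-cell designated-focus totals, the MLH1 prediction),
#'   `crossovers` (a [crossover_table()] of transmitted chromatid sets, one
#'   sample per cell), `genotype`, and `karyotype`.
#' @examples
#' set.seed(1)
#' kar <- arabidopsis_karyotype("female")
#' gt <- genotype_presets("zyp1_hei10oe_hybrid", "female")
#' pop <- simulate_population(gt, kar, n_cells = 50)
#' mean(pop$focus_counts)
#' @export
simulate_population <- function(genotype, karyotype, n_cells,
                                params = coarsening_params()) {
  stopifnot(inherits(genotype, "genotype_spec"),
            inherits(karyotype, "karyotype"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("'n_cells' must be at least 1")
  n_cells <- as.integer(n_cells)
  ids <- sprintf("cell_%04d", seq_len(n_cells))
  nchrom <- nrow(karyotype)
  counts <- integer(n_cells)
  rows <- vector("list", n_cells)

  if (genotype$zyp1) {
    lam <- zyp1_lambda(genotype, karyotype)
    # bivalent-level focus counts: Poisson with twice the chromatid mean
    counts <- as.integer(rowSums(matrix(
      rpois(n_cells * nchrom, rep(2 * lam, each = n_cells)), n_cells)))
    # chromatid crossovers, drawn cell by cell per chromosome but assembled
    # as flat vectors (results identical to the per-cell construction)
    nco <- matrix(rpois(n_cells * nchrom, rep(lam, each = n_cells)), n_cells)
    total <- sum(nco)
    sample_v <- rep(rep(ids, nchrom), as.vector(nco))
    chrom_v <- rep(karyotype$chromosome, colSums(nco))
    pos_v <- runif(total, 0,
                   rep(rep(karyotype$genomic_length_mb, colSums(nco))))
    all_rows <- data.frame(sample = sample_v, chromosome = chrom_v,
                           position_mb = pos_v, stringsAsFactors = FALSE)
  } else {
    params$y <- genotype$y
    for (cell in seq_len(n_cells)) {
      tot <- 0L
      sub <- vector("list", nchrom)
      for (k in seq_len(nchrom)) {
        biv <- simulate_bivalent_cos(karyotype$sc_length_um[k], params)
        tot <- tot + length(biv)
        chr <- bivalent_to_chromatid(biv)
        sub[[k]] <- map_sc_to_genome(chr, karyotype$sc_length_um[k],
                                     karyotype$genomic_length_mb[k])
      }
      counts[cell] <- tot
      nk <- lengths(sub)
      rows[[cell]] <- data.frame(sample = rep(ids[cell], sum(nk)),
                                 chromosome = rep(karyotype$chromosome, nk),
                                 position_mb = unlist(sub),
                                 stringsAsFactors = FALSE)
    }
    all_rows <- do.call(rbind, rows)
  }
  tab <- crossover_table(all_rows$sample, all_rows$chromosome,
                         all_rows$position_mb, origin = "chromatid",
                         karyotype = karyotype)
  attr(tab, "samples") <- ids
  out <- list(focus_counts = counts, crossovers = tab,
              genotype = genotype, karyotype = karyotype)
  class(out) <- "meiosis_population"
  out
}

#' @export
print.meiosis_population <- function(x, ...) {
  cat(sprintf("meiosis population: genotype %s (%s), %d cells\n",
              x$genotype$name, x$genotype$sex, length(x$focus_counts)))
  cat(sprintf("  mean designated foci per cell: %.2f\n", mean(x$focus_counts)))
  cat(sprintf("  mean crossovers per transmitted chromatid set: %.2f\n",
              nrow(x$crossovers) / length(x$focus_counts)))
  invisible(x)
}
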