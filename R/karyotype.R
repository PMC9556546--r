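#' Define a karyotype
#'
#' A karyotype records, per chromosome, the synaptonemal-complex length used
#' by the coarsening simulation and the genomic length used to place
#' crossovers on the physical map.
#'
#' @param chromosome Character vector of unique chromosome identifiers
#'   (1 to 5 chromosomes).
#' @param sc_length_um Positive SC lengths (micrometre).
#' @param genomic_length_mb Positive genomic lengths (Mb).
#' @return A data frame of class `karyotype`.
#' @examples
#' karyotype(c("Chr1", "Chr2"), c(24, 21), c(30.4, 19.7))
#' @export
karyotype <- function(chromosome, sc_length_um, genomic_length_mb) {
  chromosome <- as.character(chromosome)
  if (anyDuplicated(chromosome)) stop("chromosome identifiers must be unique")
  n <- length(chromosome)
  if (n < 1L || n > 5L) stop("1 to 5 chromosomes supported")
  if (length(sc_length_um) != n || length(genomic_length_mb) != n)
    stop("lengths of 'sc_length_um' and 'genomic_length_mb' must match 'chromosome'")
  if (any(!is.finite(sc_length_um)) || any(sc_length_um <= 0) ||
      any(!is.finite(genomic_length_mb)) || any(genomic_length_mb <= 0))
    stop("all lengths must be positive and finite")
  k <- data.frame(chromosome = chromosome, sc_length_um = sc_length_um,
                  genomic_length_mb = genomic_length_mb,
                  stringsAsFactors = FALSE)
  class(k) <- c("karyotype", "data.frame")
  k
}

#' Default Arabidopsis karyotype
#'
#' Five chromosomes with TAIR10-scale genomic lengths.  The SC lengths are
#' configuration values, not measured ones: per-chromosome SC lengths are
#' only available in graphical form in the cytology literature, so the
#' defaults here are plausible working values for a female meiocyte
#' (24, 21, 17, 15, 19 micrometre) with male SCs scaled by the measured
#' male:female total-length factor of 1.6.  Replace them with your own
#' measurements for quantitative work.
#'
#' @param sex `"female"` or `"male"`.
#' @param sc_scale Extra multiplicative factor applied to all SC lengths.
#' @return A [karyotype()].
#' @examples
#' arabidopsis_karyotype("male")
#' @export
arabidopsis_karyotype <- function(sex = c("female", "male"), sc_scale = 1) {
  sex <- match.arg(sex)
  sc <- c(24, 21, 17, 15, 19)
  if (sex == "male") sc <- sc * 1.6
  karyotype(paste0("Chr", 1:5), sc * sc_scale,
            c(30.4, 19.7, 23.5, 18.6, 27.0))
}

#' Define a genotype for whole-cell simulation
#'
#' Non-`zyp1` genotypes are simulated with the coarsening model and are
#' characterised by the HEI10 dosage factor `y`.  `zyp1` genotypes (no
#' synaptonemal complex, hence no interference) are simulated by the
#' Poisson/uniform null: the number of crossovers per chromatid is Poisson
#' and positions are i.i.d. uniform along the chromosome.  The Poisson means
#' can be given per chromosome, or as a single per-chromatid-set total that
#' is apportioned proportionally to genomic length (matching the observed
#' correlation of crossover count with chromosome size).
#'
#' @param name Genotype label.
#' @param y Dosage factor (> 0); required unless `zyp1 = TRUE`.
#' @param zyp1 Logical; `TRUE` selects the Poisson/uniform null model.
#' @param sex `"female"` or `"male"` label.
#' @param poisson_means Optional named numeric vector of per-chromosome
#'   Poisson means (crossovers per chromatid), used when `zyp1 = TRUE`.
#' @param poisson_total Optional total mean crossovers per chromatid set,
#'   apportioned by genomic length when `poisson_means` is not given.
#' @return An object of class `genotype_spec`.
#' @examples
#' genotype_spec("wt_hybrid_female", y = 1.5, sex = "female")
#' genotype_spec("zyp1_hei10oe_female", zyp1 = TRUE, sex = "female",
#'               poisson_total = 19.6)
#' @export
genotype_spec <- function(name, y = NULL, zyp1 = FALSE,
                          sex = c("female", "male"),
                          poisson_means = NULL, poisson_total = NULL) {
  sex <- match.arg(sex)
  if (!zyp1) {
    if (is.null(y) || !is.numeric(y) || length(y) != 1L || !is.finite(y) || y <= 0)
      stop("non-zyp1 genotypes need a single positive dosage factor 'y'")
  } else {
    if (is.null(poisson_means) && is.null(poisson_total))
      stop("zyp1 genotypes need 'poisson_means' or 'poisson_total'")
    if (!is.null(poisson_means) && any(poisson_means < 0))
      stop("Poisson means must be non-negative")
    if (!is.null(poisson_total) &&
        (!is.numeric(poisson_total) || length(poisson_total) != 1L ||
         poisson_total < 0))
      stop("'poisson_total' must be a single non-negative number")
  }
  g <- list(name = as.character(name), y = y, zyp1 = isTRUE(zyp1), sex = sex,
            poisson_means = poisson_means, poisson_total = poisson_total)
  class(g) <- "genotype_spec"
  g
}

#' @export
print.genotype_spec <- function(x, ...) {
  if (x$zyp1) {
    lam <- if (!is.null(x$poisson_means))
      paste(signif(x$poisson_means, 3), collapse = ", ")
    else sprintf("total %g apportioned by genomic length", x$poisson_total)
    cat(sprintf("genotype %s (%s): zyp1 Poisson/uniform null, lambda = %s\n",
                x$name, x$sex, lam))
  } else {
    cat(sprintf("genotype %s (%s): coarsening model, dosage y = %g\n",
                x$name, x$sex, x$y))
  }
  invisible(x)
}

#' Built-in genotype presets
#'
#' Dosage factors for the coarsening model: `y = 2` (wild-type Col), 6
#' (HEI10-overexpressor heterozygous, Col), 8 (homozygous, Col), 1.5
#' (wild-type Col/Ler hybrid) and 5.5 (HEI10-overexpressor heterozygous,
#' hybrid).  For `zyp1` genotypes the per-chromatid-set Poisson totals are
#' taken from the sequenced hybrid populations: 19.6 (female) and 14.7
#' (male) for `zyp1` combined with HEI10 overexpression; for `zyp1` alone
#' the totals are derived from the reported fold changes over wild type
#' (2.3-fold female, 1.5-fold male on wild-type means of 3.06 and 4.74).
#'
#' @param name Optional preset name; if omitted, the full preset table is
#'   returned.
#' @param sex `"female"` or `"male"` (zyp1 presets differ by sex only through
#'   their Poisson totals; coarsening presets only through the karyotype they
#'   are paired with).
#' @return A `genotype_spec`, or a data frame listing all presets.
#' @examples
#' genotype_presets()
#' genotype_presets("hybrid_wt", "male")
#' @export
genotype_presets <- function(name = NULL, sex = c("female", "male")) {
  sex <- match.arg(sex)
  tab <- data.frame(
    name = c("col_wt", "col_hei10oe_het", "col_hei10oe_homo",
             "hybrid_wt", "hybrid_hei10oe_het",
             "zyp1_hybrid", "zyp1_hei10oe_hybrid"),
    model = c(rep("coarsening", 5), rep("zyp1", 2)),
    y = c(2, 6, 8, 1.5, 5.5, NA, NA),
    poisson_total_female = c(NA, NA, NA, NA, NA, 7.0, 19.6),
    poisson_total_male = c(NA, NA, NA, NA, NA, 7.1, 14.7),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  i <- match(name, tab$name)
  if (is.na(i)) stop(sprintf("unknown genotype preset '%s'", name))
  if (tab$model[i] == "coarsening")
    genotype_spec(name, y = tab$y[i], sex = sex)
  else
    genotype_spec(name, zyp1 = TRUE, sex = sex,
                  poisson_total = if (sex == "female")
                    tab$poisson_total_female[i] else tab$poisson_total_male[i])
}

# per-chromosome Poisson means for a zyp1 genotype on a given karyotype
zyp1_lambda <- function(genotype, karyotype) {
  stopifnot(inherits(genotype, "genotype_spec"), genotype$zyp1)
  if (!is.null(genotype$poisson_means)) {
    lam <- genotype$poisson_means
    if (!is.null(names(lam))) {
      miss <- setdiff(karyotype$chromosome, names(lam))
      if (length(miss))
        stop("missing Poisson means for: ", paste(miss, collapse = ", "))
      lam <- lam[karyotype$chromosome]
    } else if (length(lam) != nrow(karyotype)) {
      stop("'poisson_means' must be named or match the karyotype length")
    }
    return(unname(lam))
  }
  genotype$poisson_total * karyotype$genomic_length_mb /
    sum(karyotype$genomic_length_mb)
}
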