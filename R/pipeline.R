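#' Run an analysis pipeline stage
#'
#' Binds the package's stages into reproducible, file-to-file runs.  The
#' configuration (a named list or the path of a `key = value` file, see
#' [read_config()]) selects a subcommand:
#'
#' * `simulate` — coarsening (or `zyp1`) population for a genotype preset:
#'   writes `mlh1_counts.tsv` and `crossovers.tsv`.
#' * `synth` — synthetic BC1 marker population with planted crossovers:
#'   writes `markers.tsv`, `truth.tsv`, `depth_windows.tsv`.
#' * `call` — sliding-window crossover calling (+ QC) from a marker table:
#'   writes `calls.tsv`, `qc.tsv`, `called_crossovers.tsv`.
#' * `stats` — interference statistics from a crossover table: writes
#'   `two_co_distances.tsv`, `null_distances.tsv`, `mw_test.tsv`,
#'   `coc_curve.tsv`, `density.tsv`, `count_summary.tsv`.
#' * `aneuploidy` — depth-based screen from a depth-window table: writes
#'   `aneuploidy_calls.tsv`, `aneuploidy_pairs.tsv`.
#' * `reproduce` — a scaled-down end-to-end experiment: simulates the
#'   configured genotypes, and writes the focus-count table, CoC curves and
#'   two-crossover distance tables per genotype.
#'
#' Configuration keys shared by stages: `subcommand`, `seed`, `genotype`
#' (preset name), `sex`, `n_cells`, `n_samples`, `marker_density`,
#' `mean_depth`, `error_rate`, `markers` / `crossovers` / `depths` (input
#' paths), `exclude` (chromosomes dropped from interference statistics).
#' Every output carries a provenance header recording the subcommand, seed
#' and parameters.  One global seed drives the whole run.
#'
#' @param config Named list or path to a configuration file.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; overrides `config$seed`.
#' @return Invisibly, the vector of files written.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  if (!is.list(config)) stop("'config' must be a list or a file path")
  sub <- config$subcommand
  if (is.null(sub)) stop("config is missing 'subcommand'")
  valid <- c("simulate", "zyp1-null", "synth", "call", "stats", "aneuploidy",
             "reproduce")
  if (!sub %in% valid)
    stop(sprintf("unknown subcommand '%s' (expected one of: %s)", sub,
                 paste(valid, collapse = ", ")))
  seed <- as.integer(seed %||% config$seed %||% 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  message(sprintf("[meiocross] stage %s (seed %d) -> %s", sub, seed, out_dir))
  written <- switch(sub,
    "simulate" = ,
    "zyp1-null" = stage_simulate(config, out_dir, seed),
    "synth" = stage_synth(config, out_dir, seed),
    "call" = stage_call(config, out_dir, seed),
    "stats" = stage_stats(config, out_dir, seed),
    "aneuploidy" = stage_aneuploidy(config, out_dir, seed),
    "reproduce" = stage_reproduce(config, out_dir, seed))
  invisible(written)
}

cfg_get <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) {
    message(sprintf("[meiocross]   using default %s = %s", key,
                    paste(default, collapse = ", ")))
    default
  } else v
}

cfg_karyotype <- function(config) {
  if (!is.null(config$karyotype)) read_karyotype(config$karyotype)
  else arabidopsis_karyotype(cfg_get(config, "sex", "female"))
}

cfg_genotype <- function(config) {
  genotype_presets(cfg_get(config, "genotype", "hybrid_wt"),
                   cfg_get(config, "sex", "female"))
}

stage_simulate <- function(config, out_dir, seed) {
  kar <- cfg_karyotype(config)
  gt <- cfg_genotype(config)
  n_cells <- cfg_get(config, "n_cells", 100)
  pop <- simulate_population(gt, kar, n_cells)
  prov <- list(stage = "simulate", seed = seed, genotype = gt$name,
               sex = gt$sex, n_cells = n_cells)
  f1 <- file.path(out_dir, "mlh1_counts.tsv")
  write_tsv_provenance(data.frame(cell = sprintf("cell_%04d", seq_len(n_cells)),
                                  mlh1_foci = pop$focus_counts), f1, prov)
  f2 <- file.path(out_dir, "crossovers.tsv")
  write_crossover_table(pop$crossovers, f2, prov)
  c(f1, f2)
}

stage_synth <- function(config, out_dir, seed) {
  kar <- cfg_karyotype(config)
  gt <- cfg_genotype(config)
  spec <- synthetic_population_spec(
    n_samples = cfg_get(config, "n_samples", 20),
    genotype = gt, karyotype = kar,
    marker_density = cfg_get(config, "marker_density", 0.1),
    mean_depth = cfg_get(config, "mean_depth", 2),
    error_rate = cfg_get(config, "error_rate", 0))
  pop <- generate_population_markers(spec)
  depth <- generate_depth_profile(spec)
  prov <- list(stage = "synth", seed = seed, genotype = gt$name,
               n_samples = spec$n_samples)
  f1 <- file.path(out_dir, "markers.tsv")
  write_marker_table(pop$markers, f1, prov)
  f2 <- file.path(out_dir, "truth.tsv")
  write_crossover_table(pop$truth, f2, prov)
  f3 <- file.path(out_dir, "depth_windows.tsv")
  write_depth_windows(depth, f3, prov)
  c(f1, f2, f3)
}

stage_call <- function(config, out_dir, seed) {
  path <- config$markers
  if (is.null(path)) stop("stage 'call' needs config key 'markers' (input path)")
  if (!file.exists(path)) stop(sprintf("marker table not found: %s", path))
  markers <- read_marker_table(path)
  kar <- cfg_karyotype(config)
  wa <- window_allele_freq(markers, kar,
                           window = cfg_get(config, "window", 50000),
                           step = cfg_get(config, "step", 25000))
  depths <- tapply(markers$col_reads + markers$ler_reads, markers$sample, mean)
  qc <- qc_samples(wa, stats::setNames(as.numeric(depths), names(depths)))
  keep <- qc$sample[qc$pass]
  calls <- call_crossovers(wa[wa$sample %in% keep, ])
  prov <- list(stage = "call", seed = seed, input = path)
  f1 <- file.path(out_dir, "calls.tsv")
  write_tsv_provenance(calls, f1, prov)
  f2 <- file.path(out_dir, "qc.tsv")
  write_tsv_provenance(qc, f2, prov)
  f3 <- file.path(out_dir, "called_crossovers.tsv")
  tab <- calls_to_crossover_table(calls, kar)
  attr(tab, "samples") <- keep
  write_crossover_table(tab, f3, prov)
  c(f1, f2, f3)
}

stage_stats <- function(config, out_dir, seed) {
  path <- config$crossovers
  if (is.null(path)) stop("stage 'stats' needs config key 'crossovers' (input path)")
  if (!file.exists(path)) stop(sprintf("crossover table not found: %s", path))
  tab <- read_crossover_table(path)
  if (!nrow(tab)) stop("crossover table is empty; nothing to analyse")
  kar <- cfg_karyotype(config)
  exclude <- config$exclude
  prov <- list(stage = "stats", seed = seed, input = path,
               exclude = exclude %||% "none")
  obs <- two_co_distances(tab)
  nul <- permutation_null(tab)
  pval <- compare_distance_distributions(obs, nul)
  coc <- coc_curve(tab, kar, exclude = exclude)
  dens <- co_density_profile(tab, kar)
  summ <- co_count_summaries(tab, kar)
  f <- character(0)
  f[1] <- file.path(out_dir, "two_co_distances.tsv")
  write_tsv_provenance(obs, f[1], prov)
  f[2] <- file.path(out_dir, "null_distances.tsv")
  write_tsv_provenance(as.data.frame(nul), f[2], prov)
  f[3] <- file.path(out_dir, "mw_test.tsv")
  write_tsv_provenance(data.frame(n_observed = nrow(obs), n_null = nrow(nul),
                                  p_value = pval), f[3], prov)
  f[4] <- file.path(out_dir, "coc_curve.tsv")
  write_tsv_provenance(coc$curve, f[4], prov)
  f[5] <- file.path(out_dir, "density.tsv")
  write_tsv_provenance(dens, f[5], prov)
  f[6] <- file.path(out_dir, "count_summary.tsv")
  write_tsv_provenance(summ$per_chromosome, f[6], prov)
  f
}

stage_aneuploidy <- function(config, out_dir, seed) {
  path <- config$depths
  if (is.null(path)) stop("stage 'aneuploidy' needs config key 'depths' (input path)")
  if (!file.exists(path)) stop(sprintf("depth table not found: %s", path))
  depth <- read_depth_windows(path)
  scr <- aneuploidy_screen(depth)
  prov <- list(stage = "aneuploidy", seed = seed, input = path)
  f1 <- file.path(out_dir, "aneuploidy_calls.tsv")
  write_tsv_provenance(scr$calls, f1, prov)
  f2 <- file.path(out_dir, "aneuploidy_pairs.tsv")
  write_tsv_provenance(scr$pairs %||% data.frame(), f2, prov)
  c(f1, f2)
}

stage_reproduce <- function(config, out_dir, seed) {
  genotypes <- cfg_get(config, "genotypes",
                       c("hybrid_wt", "zyp1_hei10oe_hybrid"))
  sexes <- cfg_get(config, "sexes", c("female", "male"))
  n_cells <- cfg_get(config, "n_cells", 20)
  files <- character(0)
  counts <- list()
  for (g in genotypes) for (sx in sexes) {
    gt <- genotype_presets(g, sx)
    kar <- arabidopsis_karyotype(sx)
    pop <- simulate_population(gt, kar, n_cells)
    tag <- paste(g, sx, sep = "_")
    counts[[tag]] <- data.frame(genotype = g, sex = sx,
                                mean_mlh1 = mean(pop$focus_counts),
                                mean_cos_per_chromatid_set =
                                  nrow(pop$crossovers) / n_cells)
    prov <- list(stage = "reproduce", seed = seed, genotype = g, sex = sx,
                 n_cells = n_cells)
    fx <- file.path(out_dir, sprintf("crossovers_%s.tsv", tag))
    write_crossover_table(pop$crossovers, fx, prov)
    files <- c(files, fx)
    coc <- try(coc_curve(pop$crossovers, kar, exclude = "Chr4"), silent = TRUE)
    if (!inherits(coc, "try-error")) {
      fc <- file.path(out_dir, sprintf("coc_curve_%s.tsv", tag))
      write_tsv_provenance(coc$curve, fc, prov)
      files <- c(files, fc)
    }
    d <- two_co_distances(pop$crossovers)
    fd <- file.path(out_dir, sprintf("two_co_distances_%s.tsv", tag))
    write_tsv_provenance(d, fd, prov)
    files <- c(files, fd)
  }
  f0 <- file.path(out_dir, "focus_counts.tsv")
  write_tsv_provenance(do.call(rbind, counts), f0,
                       list(stage = "reproduce", seed = seed,
                            n_cells = n_cells))
  c(f0, files)
}
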