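# Shared fixtures built in code.

# A 2-chromosome karyotype keeps caller tests fast.
small_karyotype <- function() {
  karyotype(c("Chr1", "Chr2"), c(24, 17), c(30, 20))
}

one_chrom_karyotype <- function(len_mb = 30, sc_um = 24) {
  karyotype("Chr1", sc_um, len_mb)
}

# Crossover table from a list: names are samples, each element a named list
# of chromosome -> positions (Mb).
co_table <- function(lst, karyotype = NULL) {
  rows <- do.call(rbind, lapply(names(lst), function(sm) {
    per <- lst[[sm]]
    do.call(rbind, lapply(names(per), function(ch)
      if (length(per[[ch]]))
        data.frame(sample = sm, chromosome = ch, position_mb = per[[ch]],
                   stringsAsFactors = FALSE)))
  }))
  tab <- crossover_table(rows$sample, rows$chromosome, rows$position_mb,
                         karyotype = karyotype)
  attr(tab, "samples") <- names(lst)
  tab
}

# zyp1-style chromatid population on one chromosome: Poisson counts,
# uniform positions (the no-interference reference used by several tests).
null_population <- function(n, lambda, len_mb = 30, chrom = "Chr1") {
  ids <- sprintf("s%05d", seq_len(n))
  cnt <- rpois(n, lambda)
  tab <- crossover_table(rep(ids, cnt), rep(chrom, sum(cnt)),
                         runif(sum(cnt), 0, len_mb))
  attr(tab, "samples") <- ids
  tab
}

# Synthetic BC1 population with explicit planted breakpoints.
# `breaks` is a list (one element per sample, generator sample ids
# bc1_0001, ...) of named lists chromosome -> positions (Mb).
planted_population <- function(breaks, karyotype, marker_density = 0.1,
                               mean_depth = 10, error_rate = 0) {
  ids <- sprintf("bc1_%04d", seq_along(breaks))
  rows <- do.call(rbind, lapply(seq_along(breaks), function(i) {
    per <- breaks[[i]]
    do.call(rbind, lapply(names(per), function(ch)
      if (length(per[[ch]]))
        data.frame(sample = ids[i], chromosome = ch, position_mb = per[[ch]],
                   stringsAsFactors = FALSE)))
  }))
  truth <- if (is.null(rows)) empty_truth(karyotype)
           else crossover_table(rows$sample, rows$chromosome, rows$position_mb,
                                karyotype = karyotype)
  gt <- genotype_spec("fixture", zyp1 = TRUE, poisson_total = 1)  # unused here
  spec <- synthetic_population_spec(length(breaks), gt, karyotype,
                                    marker_density = marker_density,
                                    mean_depth = mean_depth,
                                    error_rate = error_rate)
  generate_population_markers(spec, co_source = truth)
}

empty_truth <- function(karyotype) {
  crossover_table(character(0), character(0), numeric(0),
                  karyotype = karyotype)
}

# Independent reference Euler step used by the oracle-equivalence test:
# a plain R reimplementation of one explicit Euler step, written directly
# from the update rules (nearest-node sinks, flux-form no-flux ends).
reference_euler <- function(c0, x, M, L, D, Lambda, alpha, c0_eq,
                            duration, dt_safety) {
  n <- length(c0)
  dx <- L / (n - 1)
  node <- pmin(pmax(floor(x / dx + 0.5), 0), n - 1) + 1  # 1-based
  kmax <- if (length(node)) max(table(node)) else 0
  dt0 <- dx^2 / (2 * D)
  if (kmax > 0) dt0 <- min(dt0, dx / (Lambda * kmax))
  dt0 <- dt0 * dt_safety
  nsteps <- ceiling(duration / dt0)
  dt <- duration / nsteps
  r <- D * dt / dx^2
  cc <- c0
  for (s in seq_len(nsteps)) {
    ceq <- c0_eq * M / (1 + M * sqrt(sqrt(M)))
    dM <- dt * Lambda * (cc[node] - ceq)
    dM <- ifelse(M + dM < 0, -M, dM)
    dc <- numeric(n)
    for (i in seq_along(node)) dc[node[i]] <- dc[node[i]] - dM[i] / dx
    M <- M + dM
    cn <- cc
    cn[1] <- cc[1] + r * (cc[2] - cc[1]) + dc[1]
    for (j in 2:(n - 1))
      cn[j] <- cc[j] + r * ((cc[j - 1] + cc[j + 1]) - 2 * cc[j]) + dc[j]
    cn[n] <- cc[n] + r * (cc[n - 1] - cc[n]) + dc[n]
    cc <- cn
  }
  list(c = cc, M = M, dt = dt, n_steps = nsteps)
}
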