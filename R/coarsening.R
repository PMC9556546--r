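#' Physical and numerical parameters of the HEI10 coarsening model
#'
#' Bundles every constant of the coarsening dynamics: HEI10 diffuses along
#' the synaptonemal complex (SC) with diffusivity `D` and is exchanged
#' between the SC pool and discrete foci at rate `Lambda`; a focus of amount
#' `M` is in equilibrium with the local concentration
#' `c_eq(M) = c0_eq * M / (1 + M^(1 + alpha))`, so large foci (on the
#' decreasing branch of `c_eq`) drain the pool and grow at the expense of
#' small ones.  The dosage factor `y` scales the initial HEI10 load
#' (`m_init_base`, `sigma_init_base`, `c_init_base`) to represent genotypes
#' with different HEI10 expression levels.
#'
#' @param D Diffusivity of HEI10 along the SC (micrometre^2/s).
#' @param Lambda Exchange rate between SC and foci (micrometre/s).
#' @param alpha Dimensionless exponent of the equilibrium concentration.
#' @param c0_eq Base equilibrium concentration (a.u./micrometre).
#' @param y Dosage factor scaling the initial HEI10 amounts (dimensionless).
#'   Defaults to the wild-type Col value 2; other presets are listed in
#'   [genotype_presets()].
#' @param m_init_base Mean initial focus amount at `y = 1` (a.u.).
#' @param sigma_init_base Standard deviation of initial focus amounts at
#'   `y = 1` (a.u.).
#' @param c_init_base Initial SC concentration at `y = 1` (a.u./micrometre).
#' @param focus_density Initial density of foci along the SC (foci/micrometre).
#' @param duration Default integration time (s); 36000 s = 10 h, the
#'   approximate duration of pachytene.
#' @param n_grid Number of grid nodes spanning `[0, L]` inclusive.
#' @param m_thresh Threshold amount above which a focus is assumed to recruit
#'   MLH1 and become a class I crossover site (a.u.).
#' @param dt_safety Safety factor applied to the explicit-Euler stability
#'   limit `min(dx^2/(2 D), dx/(Lambda k_max))`, where `k_max` is the largest
#'   number of foci sharing a grid node.
#'
#' @return An object of class `coarsening_params` (a named list).
#' @examples
#' p <- coarsening_params()
#' p
#' coarsening_params(y = 8)$y
#' @export
coarsening_params <- function(D = 1.1, Lambda = 2.1, alpha = 0.25, c0_eq = 1.35,
                              y = 2, m_init_base = 3.4, sigma_init_base = 1.1,
                              c_init_base = 1.4, focus_density = 4,
                              duration = 36000, n_grid = 50, m_thresh = 3,
                              dt_safety = 0.25) {
  p <- list(D = D, Lambda = Lambda, alpha = alpha, c0_eq = c0_eq, y = y,
            m_init_base = m_init_base, sigma_init_base = sigma_init_base,
            c_init_base = c_init_base, focus_density = focus_density,
            duration = duration, n_grid = as.integer(n_grid),
            m_thresh = m_thresh, dt_safety = dt_safety)
  for (nm in c("D", "Lambda", "c0_eq", "y", "m_init_base", "sigma_init_base",
               "c_init_base", "focus_density", "m_thresh", "dt_safety")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  if (!is.numeric(p$alpha) || length(p$alpha) != 1L || p$alpha < 0)
    stop("'alpha' must be a single non-negative number")
  if (p$duration < 0) stop("'duration' must be non-negative")
  if (p$n_grid < 3L) stop("'n_grid' must be at least 3")
  if (p$dt_safety > 1) stop("'dt_safety' must not exceed 1 (Euler stability)")
  class(p) <- "coarsening_params"
  p
}

#' Read coarsening parameters from a key = value configuration file
#'
#' Any subset of the [coarsening_params()] arguments may appear as
#' `key = value` lines (units as documented there); missing keys keep their
#' defaults and unknown keys are an error.
#'
#' @param path Path to the configuration file (see [read_config()]).
#' @return A validated [coarsening_params()] object.
#' @export
coarsening_params_from_config <- function(path) {
  cfg <- read_config(path)
  known <- names(formals(coarsening_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown coarsening parameter(s) in config: ",
         paste(bad, collapse = ", "))
  do.call(coarsening_params, cfg)
}

#' @export
print.coarsening_params <- function(x, ...) {
  cat("HEI10 coarsening parameters\n")
  cat(sprintf("  D = %g um^2/s, Lambda = %g um/s, alpha = %g, c0_eq = %g a.u./um\n",
              x$D, x$Lambda, x$alpha, x$c0_eq))
  cat(sprintf("  dosage y = %g  (M_init = %g, sigma = %g a.u.; c_init = %g a.u./um)\n",
              x$y, x$y * x$m_init_base, x$y * x$sigma_init_base,
              x$y * x$c_init_base))
  cat(sprintf("  %g foci/um, duration %g s, %d grid nodes, M_thresh = %g a.u., dt_safety = %g\n",
              x$focus_density, x$duration, x$n_grid, x$m_thresh, x$dt_safety))
  invisible(x)
}

#' Equilibrium concentration of a focus
#'
#' The local SC concentration at which a focus of amount `M` neither grows
#' nor shrinks, `c_eq(M) = c0_eq * M / (1 + M^(1 + alpha))`.  The function
#' rises for small `M`, peaks, and decreases for large `M`; the decreasing
#' branch is what drives coarsening (bigger foci pull the shared pool below
#' the equilibrium level of smaller ones).
#'
#' @param M Focus amount(s), a.u.; must be non-negative.
#' @param params A [coarsening_params()] object.
#' @return Equilibrium concentration(s), a.u./micrometre.
#' @examples
#' equilibrium_concentration(1, coarsening_params(c0_eq = 1.35, alpha = 0.25))
#' @export
equilibrium_concentration <- function(M, params = coarsening_params()) {
  if (any(!is.finite(M)) || any(M < 0))
    stop("focus amounts must be finite and non-negative")
  params$c0_eq * M / (1 + M^(1 + params$alpha))
}

#' Initialise the state of one synaptonemal complex
#'
#' The SC starts with a uniform concentration `y * c_init_base` and
#' `N = round(focus_density * L)` foci.  Focus positions are i.i.d. uniform
#' on `[0, L]` (set `positions = "equal"` for deterministic equal spacing);
#' amounts are drawn from a normal distribution with mean `y * m_init_base`
#' and sd `y * sigma_init_base`, truncated to mean +/- 3 sd by redrawing.
#' Randomness is taken from R's global generator, so results are reproducible
#' with [set.seed()].
#'
#' @param L SC length (micrometre), positive.
#' @param params A [coarsening_params()] object.
#' @param positions `"random"` (default) or `"equal"` spacing of initial foci.
#' @return An object of class `sc_state`: a list with elements `L`, `c`
#'   (concentrations at the `n_grid` nodes), `foci_x` (positions, sorted),
#'   `foci_M` (amounts), and `t` (elapsed time, s).
#' @examples
#' set.seed(1)
#' st <- init_sc_state(30, coarsening_params())
#' length(st$foci_x)  # 120 foci at 4 per micrometre
#' @export
init_sc_state <- function(L, params = coarsening_params(),
                          positions = c("random", "equal")) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("SC length 'L' must be a single positive number")
  positions <- match.arg(positions)
  N <- as.integer(round(params$focus_density * L))
  x <- if (positions == "random") sort(runif(N, 0, L))
       else (seq_len(N) - 0.5) * (L / N)
  m_mean <- params$y * params$m_init_base
  m_sd <- params$y * params$sigma_init_base
  M <- rtruncnorm(N, m_mean, m_sd, m_mean - 3 * m_sd, m_mean + 3 * m_sd)
  state <- list(L = L, c = rep(params$y * params$c_init_base, params$n_grid),
                foci_x = x, foci_M = M, t = 0)
  class(state) <- "sc_state"
  state
}

# truncated-normal sampling by rejection: draws outside [lo, hi] are redrawn
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

validate_sc_state <- function(state) {
  stopifnot(inherits(state, "sc_state"))
  if (length(state$foci_x) != length(state$foci_M))
    stop("focus positions and amounts differ in length")
  if (any(state$foci_M < 0) || any(state$c < 0))
    stop("negative concentration or focus amount in state")
  if (length(state$foci_x) && (min(state$foci_x) < 0 || max(state$foci_x) > state$L))
    stop("focus position outside [0, L]")
  invisible(state)
}

#' Advance the coarsening dynamics by explicit Euler integration
#'
#' Integrates the coupled focus-growth/diffusion-exchange equations with
#' no-flux boundaries on the fixed `n_grid` discretisation.  Each focus
#' exchanges with its nearest grid node; the point exchange is discretised so
#' that total HEI10 (`dx * sum(c) + sum(M)`) is conserved to floating-point
#' accuracy.  The time step is `dt_safety * min(dx^2/(2D), dx/(Lambda k_max))`
#' rounded so an integer number of steps covers `duration` exactly.
#'
#' @param state An `sc_state` from [init_sc_state()].
#' @param params A [coarsening_params()] object.
#' @param duration Integration time (s); defaults to `params$duration`.
#' @return The advanced `sc_state`; attributes `dt` and `n_steps` record the
#'   step actually used.
#' @seealso [designate_foci()]
#' @export
simulate_coarsening <- function(state, params = coarsening_params(),
                                duration = params$duration) {
  validate_sc_state(state)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration < 0)
    stop("'duration' must be a single non-negative number")
  if (length(state$c) != params$n_grid)
    stop("state grid size does not match params$n_grid")
  res <- .euler_coarsen(state$c, state$foci_x, state$foci_M, state$L,
                        params$D, params$Lambda, params$alpha, params$c0_eq,
                        duration, params$dt_safety)
  state$c <- res$c
  state$foci_M <- res$M
  state$t <- state$t + duration
  attr(state, "dt") <- res$dt
  attr(state, "n_steps") <- res$n_steps
  state
}

#' Total amount of HEI10 in a state
#'
#' `dx * sum(c) + sum(M)`, the quantity conserved by the dynamics.
#' @param state An `sc_state`.
#' @return Total HEI10 (a.u.).
#' @export
total_hei10 <- function(state) {
  dx <- state$L / (length(state$c) - 1)
  dx * sum(state$c) + sum(state$foci_M)
}

#' Designate crossover-promoting foci
#'
#' Foci whose amount strictly exceeds `m_thresh` are assumed to recruit MLH1
#' and mature into class I crossover sites.
#'
#' @param state An `sc_state` (normally after [simulate_coarsening()]).
#' @param m_thresh Threshold amount (a.u.).
#' @return A data frame with columns `position` (micrometre, ascending) and
#'   `amount` (a.u.); zero rows if no focus exceeds the threshold.
#' @export
designate_foci <- function(state, m_thresh = 3) {
  validate_sc_state(state)
  keep <- which(state$foci_M > m_thresh)
  out <- data.frame(position = state$foci_x[keep], amount = state$foci_M[keep])
  out[order(out$position), , drop = FALSE]
}

#' @export
print.sc_state <- function(x, ...) {
  cat(sprintf("SC state: L = %g um, %d grid nodes, %d foci, t = %g s\n",
              x$L, length(x$c), length(x$foci_x), x$t))
  cat(sprintf("  total HEI10 = %.6g a.u.; focus amounts %s\n", total_hei10(x),
              if (length(x$foci_M))
                sprintf("[%.3g, %.3g]", min(x$foci_M), max(x$foci_M))
              else "(none)"))
  invisible(x)
}

#' @export
plot.sc_state <- function(x, m_thresh = NULL, ...) {
  grid_x <- seq(0, x$L, length.out = length(x$c))
  plot(grid_x, x$c, type = "l", xlab = "position on SC (um)",
       ylab = "HEI10 (a.u./um  |  a.u.)", ...)
  if (length(x$foci_x))
    segments(x$foci_x, 0, x$foci_x, x$foci_M, col = "firebrick")
  if (!is.null(m_thresh)) abline(h = m_thresh, lty = 3)
  invisible(x)
}

#' Write an SC state snapshot as delimited text
#'
#' Writes two tab-separated files, `<prefix>_grid.tsv` (node position,
#' concentration) and `<prefix>_foci.tsv` (focus position, amount).
#'
#' @param state An `sc_state`.
#' @param prefix Path prefix for the two output files.
#' @return Invisibly, the two file paths.
#' @export
write_sc_state <- function(state, prefix) {
  validate_sc_state(state)
  grid_x <- seq(0, state$L, length.out = length(state$c))
  fg <- paste0(prefix, "_grid.tsv")
  ff <- paste0(prefix, "_foci.tsv")
  write.table(data.frame(position_um = grid_x, concentration = state$c),
              fg, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(position_um = state$foci_x, amount = state$foci_M),
              ff, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fg, ff))
}
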