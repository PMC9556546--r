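test_that("equilibrium concentration follows the closed form and its shape", {
  p <- coarsening_params(c0_eq = 1.35, alpha = 0.25)
  expect_identical(equilibrium_concentration(0, p), 0)
  p1 <- coarsening_params(c0_eq = 1.35, alpha = 0.25)
  expect_equal(equilibrium_concentration(1, coarsening_params(c0_eq = 1, alpha = 0.25)),
               0.5)
  # closed-form evaluation at M = 1: 1.35 * 1 / (1 + 1)
  expect_equal(equilibrium_concentration(1, p1), 0.675)
  # decreasing branch: larger foci have lower equilibrium concentration
  expect_lt(equilibrium_concentration(10, p1), equilibrium_concentration(2, p1))
  # vectorised and continuous at 0
  expect_equal(equilibrium_concentration(c(0, 1e-12), p1)[2], 1.35e-12,
               tolerance = 1e-6)
  expect_error(equilibrium_concentration(-1, p1), "non-negative")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(coarsening_params(D = 0), "positive")
  expect_error(coarsening_params(Lambda = -1), "positive")
  expect_error(coarsening_params(alpha = -0.1), "non-negative")
  expect_error(coarsening_params(n_grid = 2), "at least 3")
  expect_error(coarsening_params(dt_safety = 1.5), "stability")
})

test_that("initial state has the documented density, scaling and bounds", {
  set.seed(101)
  p <- coarsening_params(y = 2)
  st <- init_sc_state(30, p)
  expect_s3_class(st, "sc_state")
  expect_length(st$foci_x, 120)            # 4 foci per um on 30 um
  expect_equal(st$c, rep(2 * 1.4, p$n_grid))
  # truncation bounds for y = 2: [2*3.4 - 3*2*1.1, 2*3.4 + 3*2*1.1]
  expect_true(all(st$foci_M >= 0.2 - 1e-12 & st$foci_M <= 13.4 + 1e-12))
  expect_true(all(st$foci_x >= 0 & st$foci_x <= 30))
  expect_error(init_sc_state(0, p), "positive")

  set.seed(7); a <- init_sc_state(20, p)
  set.seed(7); b <- init_sc_state(20, p)
  expect_identical(a, b)                   # reproducible given seed

  eq <- init_sc_state(10, p, positions = "equal")
  expect_equal(diff(eq$foci_x), rep(10 / 40, 39))
})

test_that("uniform concentration with no foci is a fixed point", {
  p <- coarsening_params()
  st <- structure(list(L = 10, c = rep(2.8, p$n_grid),
                       foci_x = numeric(0), foci_M = numeric(0), t = 0),
                  class = "sc_state")
  out <- simulate_coarsening(st, p, 600)
  expect_equal(out$c, rep(2.8, p$n_grid), tolerance = 1e-12)
  expect_error(simulate_coarsening(st, p, -5), "non-negative")
})

test_that("duration zero is a no-op and time is tracked", {
  set.seed(3)
  p <- coarsening_params()
  st <- init_sc_state(12, p)
  out <- simulate_coarsening(st, p, 0)
  expect_identical(out$c, st$c)
  expect_identical(out$foci_M, st$foci_M)
  out2 <- simulate_coarsening(st, p, 60)
  expect_equal(out2$t, 60)
})

test_that("total HEI10 is conserved and nothing goes negative", {
  set.seed(21)
  p <- coarsening_params(y = 2)
  st <- init_sc_state(15, p)
  tot0 <- total_hei10(st)
  out <- simulate_coarsening(st, p, 7200)
  expect_lt(abs(total_hei10(out) - tot0) / tot0, 1e-8)
  expect_true(all(out$c >= 0))
  expect_true(all(out$foci_M >= 0))
})

test_that("flux limiting keeps shrinking foci at exactly zero, conserving mass", {
  # start with an empty SC and two foci below threshold: they must dissolve
  # toward the (low) shared pool without ever going negative
  p <- coarsening_params()
  st <- structure(list(L = 10, c = rep(0, p$n_grid),
                       foci_x = c(2.5, 7.5), foci_M = c(0.05, 4), t = 0),
                  class = "sc_state")
  tot0 <- total_hei10(st)
  out <- simulate_coarsening(st, p, 3600)
  expect_true(all(out$foci_M >= 0))
  expect_true(all(out$c >= 0))
  expect_lt(abs(total_hei10(out) - tot0) / tot0, 1e-8)
})

test_that("five-node two-focus integration matches an independent R oracle", {
  # brute-force step-by-step recomputation, 10 Euler steps
  p <- coarsening_params(n_grid = 5)
  c0 <- c(1.2, 0.8, 1.0, 1.1, 0.9)
  x <- c(2.4, 7.1); M <- c(4, 6); L <- 10
  dt0 <- min((L / 4)^2 / (2 * p$D), (L / 4) / p$Lambda) * p$dt_safety
  duration <- 10 * dt0 * 0.999  # ceil() gives exactly 10 steps
  ref <- reference_euler(c0, x, M, L, p$D, p$Lambda, p$alpha, p$c0_eq,
                         duration, p$dt_safety)
  st <- structure(list(L = L, c = c0, foci_x = x, foci_M = M, t = 0),
                  class = "sc_state")
  out <- simulate_coarsening(st, p, duration)
  expect_identical(attr(out, "n_steps"), 10)
  expect_equal(out$c, ref$c, tolerance = 0)
  expect_equal(out$foci_M, ref$M, tolerance = 0)
})

test_that("reflecting the system about L/2 mirrors the final state exactly", {
  p <- coarsening_params()
  L <- 14
  x <- c(1.3, 4.2, 9.7, 12.1)       # distinct host nodes
  M <- c(5, 7, 6, 4.5)
  st <- structure(list(L = L, c = rep(p$y * p$c_init_base, p$n_grid),
                       foci_x = x, foci_M = M, t = 0), class = "sc_state")
  stm <- structure(list(L = L, c = rep(p$y * p$c_init_base, p$n_grid),
                        foci_x = rev(L - x), foci_M = rev(M), t = 0),
                   class = "sc_state")
  a <- simulate_coarsening(st, p, 1800)
  b <- simulate_coarsening(stm, p, 1800)
  expect_identical(a$foci_M, rev(b$foci_M))
  expect_identical(a$c, rev(b$c))
})

test_that("coarsening is winner-takes-more: the larger focus grows", {
  # two foci on the decreasing branch of c_eq, symmetric positions, 10 h
  p <- coarsening_params(y = 2)
  st <- structure(list(L = 10, c = rep(p$y * p$c_init_base, p$n_grid),
                       foci_x = c(3, 7), foci_M = c(8, 6), t = 0),
                  class = "sc_state")
  out <- simulate_coarsening(st, p, 36000)
  expect_gt(out$foci_M[1], 8)
  expect_lt(out$foci_M[2], 6)
})

test_that("focus designation applies a strict threshold, ordered by position", {
  st <- structure(list(L = 10, c = rep(1, 50),
                       foci_x = c(8, 2, 5), foci_M = c(5, 2, 3), t = 0),
                  class = "sc_state")
  d <- designate_foci(st, 3)
  expect_equal(nrow(d), 1L)                # 3 is not > 3
  expect_equal(d$position, 8)
  st$foci_M <- c(0, 0, 0)
  expect_equal(nrow(designate_foci(st, 3)), 0L)
  st$foci_M <- c(0.2, 0.1, 0.4)
  d2 <- designate_foci(st, 0)
  expect_equal(d2$position, c(2, 5, 8))    # all returned, sorted
})

test_that("refining the grid to 100 nodes rarely changes the designated count", {
  p50 <- coarsening_params(y = 2)
  p100 <- coarsening_params(y = 2, n_grid = 100)
  n_diff <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    st <- init_sc_state(24, p50)
    st100 <- st
    st100$c <- rep(p50$y * p50$c_init_base, 100)
    a <- nrow(designate_foci(simulate_coarsening(st, p50, 36000), 3))
    b <- nrow(designate_foci(simulate_coarsening(st100, p100, 36000), 3))
    if (a != b) n_diff <- n_diff + 1L
  }
  # designated counts are small integers decided by close coarsening races,
  # so occasional +/-1 flips under refinement are expected; measured rate
  # is ~8% of seeds at these parameters
  expect_lte(n_diff, 2L)
})

test_that("state snapshots round-trip as delimited text", {
  set.seed(5)
  st <- init_sc_state(8, coarsening_params())
  files <- write_sc_state(st, file.path(tempdir(), "snap"))
  g <- read.table(files[1], header = TRUE, sep = "\t")
  f <- read.table(files[2], header = TRUE, sep = "\t")
  expect_equal(g$concentration, st$c)
  expect_equal(f$position_um, st$foci_x)
  expect_equal(f$amount, st$foci_M)
})
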