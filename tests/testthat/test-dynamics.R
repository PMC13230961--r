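test_that("symmetric division probability saturates and is braked by DCs", {
  expect_equal(division_probability(0, 0), 0)
  expect_equal(division_probability(0, 1e9), 1, tolerance = 1e-8)
  expect_equal(division_probability(0, 1, eta = 1, psi = 0.5), 0.5)
  expect_error(division_probability(-1, 1), "non-negative")
  a <- seq(0, 10, by = 0.1)
  expect_true(all(diff(division_probability(2, a)) > 0))    # rises with Wnt
  D <- seq(0, 10, by = 0.1)
  expect_true(all(diff(division_probability(D, 2)) < 0))    # braked by DCs
  expect_true(all(division_probability(D, 1e6) < 1))
})

test_that("dedifferentiation switch is centered at m0 and saturates at q0", {
  expect_equal(dedifferentiation_rate(0.05), 40 / 2)
  expect_equal(dedifferentiation_rate(1e6), 40, tolerance = 1e-12)
  expect_equal(dedifferentiation_rate(-1e6), 0, tolerance = 1e-12)
  m <- seq(0, 0.3, by = 0.005)
  expect_true(all(diff(dedifferentiation_rate(m)) > 0))
})

test_that("model right-hand side respects the invariant submanifolds", {
  p <- model_params()
  # extinction submanifold: only the microRNA equation is active
  d0 <- csc_rhs(0, c(0, 0, 0, 0.7), c(0, 0.7), p, NULL)
  expect_equal(unname(d0[1:3]), c(0, 0, 0))
  expect_equal(unname(d0[4]), p$gamma - p$alpha * 0.7)
  # a = 0 is invariant for any S
  da <- csc_rhs(0, c(0.5, 0.1, 0, 0.2), c(0.1, 0.2), p, NULL)
  expect_identical(unname(da[3]), 0)
  expect_error(csc_rhs(0, c(-0.1, 0, 0, 0), c(0, 0), p, NULL),
               "non-negative")
  # therapy off before t_start, on after
  th <- therapy_schedule("225Ac", 20, t_start = 5)
  st <- c(0.1, 0.01, 0.05, 0.5); dl <- c(0.01, 0.5)
  off <- csc_rhs(4.99, st, dl, p, th)
  on <- csc_rhs(5.0, st, dl, p, th)
  expect_equal(unname(off[1] - on[1]), p$upsilon * th$R_imm * st[1])
  expect_equal(unname(off[2] - on[2]), p$theta * th$R_imm * st[2])
})

test_that("integrator reproduces closed-form subcases at RK4 order", {
  # microRNA pure decay: gamma = 0 gives m(t) = m(0) exp(-alpha t)
  p <- model_params(gamma = 0, q0 = 0, tau = 0, upsilon = 0, theta = 0)
  errs <- sapply(c(0.02, 0.01), function(dt) {
    tr <- simulate_csc(p, history = c(0, 0, 0, 1), t_end = 1, dt = dt)
    abs(tr$states[nrow(tr$states), "m"] - exp(-p$alpha * 1))
  })
  expect_lt(errs[2], 1e-10)
  expect_gt(errs[1] / errs[2], 12)   # ~16x for a 4th-order method
  expect_lt(errs[1] / errs[2], 20)

  # stem-cell pure decay: a = 0, q0 = 0 -> S(t) = S0 exp(-eps t)
  p2 <- model_params(q0 = 0, tau = 0)
  errs2 <- sapply(c(0.02, 0.01), function(dt) {
    tr <- simulate_csc(p2, history = c(0.038, 0.001, 0, 0.5), t_end = 2,
                       dt = dt)
    abs(tr$states[nrow(tr$states), "S"] - 0.038 * exp(-p2$epsilon * 2))
  })
  expect_lt(errs2[2], 1e-10)
  expect_gt(errs2[1] / errs2[2], 12)
  expect_lt(errs2[1] / errs2[2], 20)
})

test_that("delay machinery is consistent with the undelayed limit", {
  # with q0 = 0 the delayed term is absent: tau > 0 must match tau = 0
  p0 <- model_params(q0 = 0, tau = 0)
  p1 <- model_params(q0 = 0, tau = 0.5)
  h <- c(0.04, 0.002, 0.01, 0.8)
  t0 <- simulate_csc(p0, history = h, t_end = 3, dt = 0.01)
  t1 <- simulate_csc(p1, history = h, t_end = 3, dt = 0.01)
  expect_equal(t1$states, t0$states, tolerance = 1e-12)
  # under-resolved delay warns
  expect_warning(simulate_csc(model_params(tau = 0.01), t_end = 0.1,
                              dt = 0.01), "under-resolved")
})

test_that("integrator agrees with an independent adaptive DDE solver", {
  skip_if_not_installed("deSolve")
  p <- model_params(tau = 0.8)
  th <- therapy_schedule("177Lu", 30, t_start = 1.0)
  h <- default_initial_state(p)
  ours <- simulate_csc(p, th, history = h, t_end = 4, dt = 0.0025)

  dede_rhs <- function(t, y, parms) {
    lag <- if (t <= p$tau) h else deSolve::lagvalue(t - p$tau)
    R <- if (t >= 1.0) th$R_imm else 0
    pr <- division_probability(y[2], y[3], p$eta, p$psi)
    qd <- dedifferentiation_rate(lag[4], p$q0, p$m0, p$sigma)
    qi <- dedifferentiation_rate(y[4], p$q0, p$m0, p$sigma)
    list(c((2 * pr - 1) * p$epsilon * y[1] + qd * lag[2] -
             p$upsilon * R * y[1],
           2 * (1 - pr) * p$epsilon * y[1] - (p$d + qi) * y[2] -
             p$theta * R * y[2],
           y[3] * (p$beta * y[1] * y[3] / (1 + y[3]) - p$alpha),
           p$gamma * exp(-y[1] / p$S0) - p$alpha * y[4]))
  }
  ref <- deSolve::dede(unname(h), seq(0, 4, by = 0.1), dede_rhs, NULL,
                       atol = 1e-10, rtol = 1e-10)
  ours_at <- state_at(ours, seq(0, 4, by = 0.1))
  expect_equal(max(abs(ours_at - ref[, 2:5])), 0, tolerance = 1e-6)
})

test_that("trajectories stay non-negative and respond to therapy", {
  p <- model_params()
  tr0 <- simulate_csc(p, t_end = 12, dt = 0.01)
  expect_true(all(tr0$states >= -1e-12))
  # a(0) = 0 stays exactly zero
  trz <- simulate_csc(p, history = c(0.038, 0.001, 0, 1.2), t_end = 2,
                      dt = 0.01)
  expect_true(all(trz$states[, "a"] == 0))
  # stronger coupling, smaller stem-cell burden at any post-onset time
  Rs <- c(0, 0.05, 0.1, 0.2, 0.4)
  finals <- sapply(Rs, function(R) {
    th <- therapy_schedule("225Ac", 1, t_start = 8.8964, R_imm = R)
    tr <- simulate_csc(p, th, t_end = 12, dt = 0.01)
    state_at(tr, c(10, 11, 12))[, "S"]
  })
  for (i in seq_len(nrow(finals))) {
    expect_true(all(diff(finals[i, ]) < 0))
  }
})

test_that("closed-form equilibria satisfy their defining balances", {
  p <- model_params()   # d = 36.5, q0 = 40
  eq <- equilibria(p)
  expect_equal(unname(eq$E1$state[1:3]), c(0, 0, 0))
  expect_identical(eq$E1$residual, 0)
  expect_lt(eq$E2$residual, 1e-8)
  expect_true(eq$E2$valid)
  expect_lt(eq$E3$residual, 1e-8)
  # Wnt-balance identity of the printed forms
  e3 <- eq$E3$state
  expect_equal(p$beta * e3["S"] * e3["a"] / (1 + e3["a"]), c(S = p$alpha),
               tolerance = 1e-14)
  # a3 agrees with a one-dimensional root-finder on the division balance
  g <- function(a) {
    S <- p$alpha * (1 + a) / (p$beta * a)
    2 * division_probability(S / p$d, a, p$eta, p$psi) - 1
  }
  a3_root <- stats::uniroot(g, c(0.5, 2), tol = 1e-14)$root
  expect_equal(unname(e3["a"]), a3_root, tolerance = 1e-10)
  # supplied microRNA level shifts the controlled branch as printed
  eq2 <- equilibria(p, m2 = 0.2)
  expect_equal(unname(eq2$E2$state["S"]),
               -p$S0 * log(p$alpha * 0.2 / p$gamma))
  # m2 above the production/degradation ratio invalidates the branch
  eq_bad <- equilibria(p, m2 = 4)
  expect_false(eq_bad$E2$valid)
})

test_that("eradication time is found on decaying trajectories", {
  # synthetic exponential decay via the pure-decay submodel
  p <- model_params(q0 = 0, tau = 0)
  tr <- simulate_csc(p, history = c(1, 0.001, 0, 0.5), t_end = 5, dt = 0.01)
  et <- eradication_time(tr, "S", threshold = exp(-2))
  expect_equal(et, 2, tolerance = 0.02)
  # never-eradicated trajectory
  expect_true(is.na(eradication_time(tr, "S", threshold = 1e-12)))
  # lower threshold cannot be reached earlier
  expect_gte(eradication_time(tr, "S", threshold = exp(-3)), et)
})

test_that("percent reduction reproduces the reference-table drops", {
  expect_equal(percent_reduction(0.4, 0.4), 0)
  expect_error(percent_reduction(0, 1), "positive")
  expect_error(percent_reduction(1, -1), "non-negative")
  ref <- reference_concentrations()
  before <- ref[ref$t_year == 9.006, ]
  after <- ref[ref$t_year == 9.796 & ref$r0_gy_per_year == 20, ]
  red_S <- round(percent_reduction(before$S, after$S), 2)
  red_D <- round(percent_reduction(before$D, after$D), 2)
  names(red_S) <- names(red_D) <- before$radionuclide
  expect_equal(red_S[["225Ac"]], 80.08)
  expect_equal(red_S[["90Y"]], 51.21)
  expect_equal(red_D[["90Y"]], 50.61)
})

test_that("trajectory round-trips through the CSV writer", {
  skip_if_not_installed("jsonlite")
  p <- model_params(tau = 0, q0 = 0)
  tr <- simulate_csc(p, t_end = 0.5, dt = 0.01)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f, paste0(f, ".json"))))
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(back$data$S, unname(tr$states[, "S"]))
  expect_identical(back$data$t_year, tr$times)
  expect_equal(back$meta$params$d, p$d)
})
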