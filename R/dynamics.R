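#' Parameters of the delayed cancer stem cell model
#'
#' The dynamical system tracks four concentrations: cancer stem cells `S`,
#' differentiated cancer cells `D`, Wnt-beta-catenin pathway proteins `a`
#' and microRNAs `m`.  Time is in years.  Differentiated cells dedifferentiate
#' back into stem cells at a microRNA-gated rate `q(m)` acting with a delay
#' `tau` (the DC-to-CSC conversion time); symmetric stem-cell division is
#' promoted by Wnt signalling and braked by the differentiated population
#' through `p(D, a)`.
#'
#' `q0 > d` is expected (dedifferentiation can outpace differentiated-cell
#' death); a warning is issued otherwise.
#'
#' @param eta Wnt feedback strength, mm^3/molecule.
#' @param psi differentiated-cell brake intensity, mm^3/cell.
#' @param epsilon CSC mitotic rate, 1/year.
#' @param q0 maximum dedifferentiation rate, 1/year.
#' @param tau DC-to-CSC conversion delay, years.
#' @param m0 minimal microRNA concentration, molecule/mm^3.
#' @param sigma microRNA sensitivity scale, molecule/mm^3.
#' @param upsilon CSC radio-kill rate, 1/year.
#' @param d differentiated-cell death rate, 1/year.
#' @param theta DC radio-kill rate, 1/year (set above `upsilon`: DCs are less
#'   radioresistant than CSCs).
#' @param alpha protein/molecule degradation rate.
#' @param beta Wnt self-renewal aggressiveness, mm^3/(cell year).
#' @param gamma maximum microRNA production, molecule/(mm^3 year).
#' @param S0 minimal CSC concentration, cell/mm^3.
#' @return list of class `model_params`.
#' @export
model_params <- function(eta = 1, psi = 0.5, epsilon = 1, q0 = 40,
                         tau = 8.8964, m0 = 0.05, sigma = 0.05,
                         upsilon = 25, d = 36.5, theta = 50,
                         alpha = 0.3, beta = 1, gamma = 1, S0 = 0.038) {
  p <- list(eta = eta, psi = psi, epsilon = epsilon, q0 = q0, tau = tau,
            m0 = m0, sigma = sigma, upsilon = upsilon, d = d, theta = theta,
            alpha = alpha, beta = beta, gamma = gamma, S0 = S0)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x < 0,
                 logical(1)))) {
    stop("all model parameters must be single non-negative numbers",
         call. = FALSE)
  }
  stopifnot(sigma > 0, S0 > 0)
  if (q0 > 0 && q0 <= d) {
    warning("'q0' <= 'd': dedifferentiation cannot outpace differentiated-",
            "cell death; the controlled equilibrium branch degenerates",
            call. = FALSE)
  }
  structure(p, class = "model_params")
}

#' Probability of symmetric stem-cell division
#'
#' `p(D, a) = eta a / ((1 + eta a)(1 + psi D))`: increasing in the Wnt
#' signal `a`, braked by the differentiated population `D`; always in
#' `[0, 1)`.
#'
#' @param D differentiated-cell concentration, cell/mm^3 (>= 0).
#' @param a Wnt-beta-catenin concentration, molecule/mm^3 (>= 0).
#' @param eta,psi feedback strengths, see [model_params()].
#' @return probability in `[0, 1)`.
#' @export
division_probability <- function(D, a, eta = 1, psi = 0.5) {
  if (any(D < 0) || any(a < 0)) stop("'D' and 'a' must be non-negative",
                                     call. = FALSE)
  eta * a / ((1 + eta * a) * (1 + psi * D))
}

#' Microstate-gated dedifferentiation rate
#'
#' `q(m) = q0/2 (1 + tanh((m - m0)/sigma))`: a smooth switch that is `q0/2`
#' at the minimal microRNA concentration `m0`, saturates at `q0` for high
#' microRNA levels, and vanishes for low ones.
#'
#' @param m microRNA concentration, molecule/mm^3 (the model evaluates it at
#'   the delayed time `t - tau` in the stem-cell equation).
#' @param q0,m0,sigma see [model_params()].
#' @return rate in `(0, q0)`, 1/year.
#' @export
dedifferentiation_rate <- function(m, q0 = 40, m0 = 0.05, sigma = 0.05) {
  stopifnot(sigma > 0)
  q0 / 2 * (1 + tanh((m - m0) / sigma))
}

#' Therapy schedule for the dynamical model
#'
#' Computes the radioimmunotherapy coupling `R_imm` from the linear-quadratic
#' stack and records when it switches on.  `R_imm` enters the model as a
#' time-constant multiplier of the kill terms `upsilon R_imm S` and
#' `theta R_imm D` from `t_start` onward (mode `"constant"`, canonical);
#' mode `"dose-rate"` instead scales the kill by the instantaneous dose-rate
#' profile, `alpha_c r(t - t_start) RE`.
#'
#' @param radionuclide registry name, [radionuclide()] or
#'   [effective_times()] object.
#' @param r0 extrapolated initial dose rate.
#' @param r0_unit `"Gy/year"` (scenario convention, default) or `"Gy/day"`.
#' @param t_start therapy start time, years.  Defaults to the model delay
#'   `tau` when coupled through [simulate_csc()]; pass explicitly here.
#' @param lq an [lq_params()] object.
#' @param oer_value oxygen enhancement ratio applied in the BED (1 = oxygen-
#'   free).
#' @param R_imm optional direct override of the coupling constant
#'   (bypasses the radiobiology stack).
#' @param mode `"constant"` or `"dose-rate"` (see Details).
#' @param days_per_year unit bridge factor.
#' @return list of class `therapy_schedule`.
#' @examples
#' therapy_schedule("225Ac", r0 = 20, t_start = 8.8964)
#' @export
therapy_schedule <- function(radionuclide = "225Ac", r0 = 0,
                             r0_unit = c("Gy/year", "Gy/day"),
                             t_start = 8.8964, lq = lq_params(),
                             oer_value = 1, R_imm = NULL,
                             mode = c("constant", "dose-rate"),
                             days_per_year = 365) {
  r0_unit <- match.arg(r0_unit); mode <- match.arg(mode)
  stopifnot(t_start >= 0)
  sched <- dose_schedule(radionuclide, r0, r0_unit, days_per_year)
  if (is.null(R_imm)) R_imm <- rit_rate(sched, lq, oer_value)
  stopifnot(R_imm >= 0)
  structure(list(sched = sched, t_start = t_start, R_imm = R_imm,
                 lq = lq, oer_value = oer_value, mode = mode,
                 days_per_year = days_per_year),
            class = "therapy_schedule")
}

#' @export
print.therapy_schedule <- function(x, ...) {
  cat(sprintf("<therapy_schedule %s>  r0 = %.4g Gy/day,  t_start = %.4g y,  R_imm = %.4g (%s)\n",
              x$sched$times$name, x$sched$r0, x$t_start, x$R_imm, x$mode))
  invisible(x)
}

# coupling value at time t (years); 0 before therapy start
therapy_coupling <- function(therapy, t) {
  if (is.null(therapy) || t < therapy$t_start) return(0)
  if (therapy$mode == "constant") return(therapy$R_imm)
  # dose-rate resolved variant: alpha_c * r(t - t_start) * RE, with t in days
  td <- years_to_days(t - therapy$t_start, therapy$days_per_year)
  RE <- relative_effectiveness(therapy$sched, therapy$lq, therapy$oer_value)
  therapy$lq$alpha_c * dose_rate(td, therapy$sched) * RE
}

#' Right-hand side of the delayed tumor model
#'
#' Evaluates the four coupled equations at state `(S, D, a, m)` given the
#' delayed values `D(t - tau)` and `m(t - tau)`.  The dedifferentiation
#' influx into the stem-cell pool uses the delayed pair
#' `q(m(t - tau)) D(t - tau)`, while the outflux from the differentiated
#' pool uses the instantaneous `q(m)` — the asymmetry is part of the model.
#' The radio-kill terms `upsilon R_imm S` and `theta R_imm D` act only once
#' therapy is on.
#'
#' @param t time, years.
#' @param state numeric vector `c(S, D, a, m)`, non-negative.
#' @param delayed numeric vector `c(D_delayed, m_delayed)`.
#' @param params a [model_params()] object.
#' @param therapy a [therapy_schedule()] or `NULL` (therapy-free).
#' @return numeric vector `d(S, D, a, m)/dt`.
#' @export
csc_rhs <- function(t, state, delayed, params, therapy = NULL) {
  if (any(state < 0) || any(delayed < 0)) {
    stop("'state' and 'delayed' must be non-negative", call. = FALSE)
  }
  S <- state[1]; D <- state[2]; a <- state[3]; m <- state[4]
  Dd <- delayed[1]; md <- delayed[2]
  R <- therapy_coupling(therapy, t)
  p  <- division_probability(D, a, params$eta, params$psi)
  qd <- dedifferentiation_rate(md, params$q0, params$m0, params$sigma)
  qi <- dedifferentiation_rate(m,  params$q0, params$m0, params$sigma)
  c(S = (2 * p - 1) * params$epsilon * S + qd * Dd - params$upsilon * R * S,
    D = 2 * (1 - p) * params$epsilon * S - (params$d + qi) * D -
        params$theta * R * D,
    a = a * (params$beta * S * a / (1 + a) - params$alpha),
    m = params$gamma * exp(-S / params$S0) - params$alpha * m)
}

#' Default initial state near the controlled equilibrium
#'
#' Small perturbation of the Wnt-inactive equilibrium branch:
#' `S(0) = S0`, `D(0) = S(0)/d`, `a(0) = 0.01` and the microRNA level at its
#' quasi-stationary value `m(0) = gamma/alpha * exp(-S(0)/S0)`.
#'
#' @param params a [model_params()] object.
#' @return named numeric state vector `c(S, D, a, m)`.
#' @export
default_initial_state <- function(params = model_params()) {
  S <- params$S0
  c(S = S, D = S / params$d, a = 0.01,
    m = params$gamma / params$alpha * exp(-S / params$S0))
}

#' Integrate the delayed tumor model
#'
#' Fixed-step classical fourth-order Runge-Kutta with cubic Hermite dense
#' output (method of steps).  Delayed values `D(t - tau)` and `m(t - tau)`
#' are read from the stored dense interpolant; for `t - tau` before the
#' start time the history function is used.  With `tau = 0` the scheme
#' degrades to plain RK4 on the ordinary system.  Therapy switches on at the
#' first step boundary at or after `t_start`.
#'
#' @param params a [model_params()] object.
#' @param therapy a [therapy_schedule()] or `NULL`.  If its `t_start` is
#'   `NULL` it defaults to the delay `tau`.
#' @param history constant history: a state vector `c(S, D, a, m)` used on
#'   `[t0 - tau, t0]`, or a function of time returning such a vector.
#'   Defaults to [default_initial_state()].
#' @param t_end final time, years (> `t0`).
#' @param dt fixed step, years.
#' @param t0 start time, years.
#' @return object of class `csc_trajectory`: list with `times`, `states`
#'   (matrix with columns S, D, a, m), `derivs` (stored right-hand sides for
#'   dense output) and metadata (`params`, `therapy`, `dt`, `history`).
#' @examples
#' tr <- simulate_csc(model_params(tau = 0, q0 = 0), t_end = 1, dt = 0.01)
#' head(as.data.frame(tr))
#' @export
simulate_csc <- function(params = model_params(), therapy = NULL,
                         history = default_initial_state(params),
                         t_end = 16, dt = 0.01, t0 = 0) {
  stopifnot(t_end > t0, dt > 0)
  tau <- params$tau
  if (tau > 0 && dt > tau / 2) {
    warning("step 'dt' exceeds tau/2: the delay is under-resolved",
            call. = FALSE)
  }
  hist_fun <- if (is.function(history)) {
    history
  } else {
    h <- as.numeric(history); function(t) h
  }
  n <- ceiling((t_end - t0) / dt - 1e-9)
  times <- t0 + (0:n) * dt

  Y <- matrix(NA_real_, n + 1L, 4L,
              dimnames = list(NULL, c("S", "D", "a", "m")))
  F <- matrix(NA_real_, n + 1L, 4L)

  # dense cubic-Hermite lookup over completed steps 1..i (node indices)
  lookup <- function(s, i) {
    if (s <= t0) return(hist_fun(s))
    # node-exact queries bypass interpolation (and pending derivative rows)
    kk <- round((s - t0) / dt)
    if (abs(s - (t0 + kk * dt)) < 1e-9 * dt && kk + 1L <= i + 1L &&
        !anyNA(Y[kk + 1L, ])) {
      return(Y[kk + 1L, ])
    }
    k <- floor((s - t0) / dt + 1e-12)
    if (k >= i) k <- i - 1L
    # back off to the last fully available interval (only reachable when
    # the delay is under-resolved, tau < 2 dt)
    while (k >= 0L && (anyNA(Y[k + 2L, ]) || anyNA(F[k + 2L, ]))) {
      k <- k - 1L
    }
    if (k < 0L) return(hist_fun(t0))
    th <- (s - (t0 + k * dt)) / dt
    y0 <- Y[k + 1L, ]; y1 <- Y[k + 2L, ]
    f0 <- F[k + 1L, ]; f1 <- F[k + 2L, ]
    (1 + 2 * th) * (1 - th)^2 * y0 + th * (1 - th)^2 * dt * f0 +
      th^2 * (3 - 2 * th) * y1 + th^2 * (th - 1) * dt * f1
  }

  # therapy acts from the first step boundary >= t_start
  if (!is.null(therapy)) {
    idx <- which(times >= therapy$t_start - 1e-12)
    t_on <- if (length(idx)) times[idx[1L]] else Inf
    therapy_eff <- therapy
    therapy_eff$t_start <- t_on
  } else {
    therapy_eff <- NULL
  }

  delayed_at <- function(s, i, stage_state) {
    if (tau == 0) return(pmax(stage_state[c(2L, 4L)], 0))
    v <- lookup(s, i)
    pmax(v[c(2L, 4L)], 0)  # guard against tiny interpolation overshoot
  }

  # therapy is constant over each step: all four stages of a step see the
  # regime of the step's start node, so the kill switch enters exactly at a
  # step boundary without contaminating the preceding step
  therapy_for <- function(t_node) {
    if (is.null(therapy_eff) || t_node < therapy_eff$t_start - 1e-12) {
      return(NULL)
    }
    therapy_eff
  }

  y <- as.numeric(hist_fun(t0))
  Y[1L, ] <- y
  F[1L, ] <- csc_rhs(t0, y, delayed_at(t0 - tau, 0L, y), params,
                     therapy_for(t0))

  for (i in seq_len(n)) {
    t_i <- times[i]; y <- Y[i, ]
    th_step <- therapy_for(t_i)
    d1 <- delayed_at(t_i - tau, i - 1L, y)
    k1 <- csc_rhs(t_i, pmax(y, 0), d1, params, th_step)
    y2 <- pmax(y + dt / 2 * k1, 0)
    d2 <- delayed_at(t_i + dt / 2 - tau, i - 1L, y2)
    k2 <- csc_rhs(t_i + dt / 2, y2, d2, params, th_step)
    y3 <- pmax(y + dt / 2 * k2, 0)
    d3 <- delayed_at(t_i + dt / 2 - tau, i - 1L, y3)
    k3 <- csc_rhs(t_i + dt / 2, y3, d3, params, th_step)
    y4 <- pmax(y + dt * k3, 0)
    d4 <- delayed_at(t_i + dt - tau, i - 1L, y4)
    k4 <- csc_rhs(t_i + dt, y4, d4, params, th_step)
    y_new <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y_new))) {
      stop(sprintf("integration failure: non-finite state at t = %.4f",
                   times[i + 1L]), call. = FALSE)
    }
    if (any(y_new < -1e-12)) {
      warning(sprintf("negative excursion at t = %.4f (min %.3g): the step ",
                      times[i + 1L], min(y_new)),
              "size may be too coarse", call. = FALSE)
    }
    Y[i + 1L, ] <- y_new
    dn <- delayed_at(times[i + 1L] - tau, i, y_new)
    F[i + 1L, ] <- csc_rhs(times[i + 1L], pmax(y_new, 0), dn, params,
                           therapy_for(times[i + 1L]))
  }

  structure(list(times = times, states = Y, derivs = F, params = params,
                 therapy = therapy_eff, dt = dt, t0 = t0,
                 history = hist_fun),
            class = "csc_trajectory")
}

#' Interpolate a trajectory at arbitrary times
#'
#' Queries the cubic Hermite dense output of [simulate_csc()] (the same
#' interpolant the integrator uses for its own delayed lookups).
#'
#' @param traj a `csc_trajectory`.
#' @param t numeric vector of times within the integration range.
#' @return matrix with one row per time and columns S, D, a, m.
#' @export
state_at <- function(traj, t) {
  stopifnot(inherits(traj, "csc_trajectory"))
  rng <- range(traj$times)
  if (any(t < rng[1] - 1e-12) || any(t > rng[2] + 1e-12)) {
    stop("'t' outside the trajectory range", call. = FALSE)
  }
  dt <- traj$dt; t0 <- traj$t0
  out <- t(vapply(t, function(s) {
    k <- min(max(floor((s - t0) / dt + 1e-12), 0), length(traj$times) - 2L)
    th <- (s - (t0 + k * dt)) / dt
    y0 <- traj$states[k + 1L, ]; y1 <- traj$states[k + 2L, ]
    f0 <- traj$derivs[k + 1L, ]; f1 <- traj$derivs[k + 2L, ]
    (1 + 2 * th) * (1 - th)^2 * y0 + th * (1 - th)^2 * dt * f0 +
      th^2 * (3 - 2 * th) * y1 + th^2 * (th - 1) * dt * f1
  }, numeric(4)))
  colnames(out) <- c("S", "D", "a", "m")
  out
}

#' Equilibria of the therapy-free model
#'
#' Closed-form equilibrium branches of the delayed system without
#' radioimmunotherapy:
#' * `E1 = (0, 0, 0, m1)` — tumor-free; `m1` defaults to the stationary
#'   microRNA level `gamma/alpha`.
#' * `E2 = (S2, D2, 0, m2)` — Wnt-inactive controlled state, with
#'   `S2 = -S0 log(alpha m2 / gamma)` and `D2 = S2/d`.  The microRNA level
#'   `m2` defaults to the value balancing dedifferentiation against
#'   differentiated-cell death, `q(m2) = epsilon d` (requires `q0 > d`);
#'   any `m2 < gamma/alpha` may be supplied.
#' * `E3` — Wnt-active aggressive state from the closed form for `a3`
#'   (valid in the dedifferentiation-silent regime `q(m3) ~ 0`), with
#'   `S3 = alpha (1 + a3)/(beta a3)`, `D3 = S3/d`,
#'   `m3 = gamma/alpha exp(-S3/S0)`.
#'
#' Each point is annotated with the residual of its defining steady-state
#' conditions (`residual`) and, for reference, the full right-hand-side
#' norm (`rhs_residual`) which for `E3` retains the neglected
#' dedifferentiation influx.
#'
#' @param params a [model_params()] object (therapy-free interpretation).
#' @param m1,m2 optional microRNA levels for the first two branches.
#' @return list with components `E1`, `E2`, `E3`; each a list with `state`,
#'   `residual`, `rhs_residual` and validity flags.
#' @export
equilibria <- function(params = model_params(), m1 = NULL, m2 = NULL) {
  p <- params
  rhs_norm <- function(st) {
    max(abs(csc_rhs(0, pmax(st, 0), pmax(st[c(2, 4)], 0), p, NULL)))
  }

  # E1: extinction; S=D=a=0 makes the first three equations vanish exactly
  if (is.null(m1)) m1 <- p$gamma / p$alpha
  e1 <- c(S = 0, D = 0, a = 0, m = m1)
  res1 <- max(abs(csc_rhs(0, e1, e1[c(2, 4)], p, NULL)[1:3]))

  # E2: Wnt-inactive; default m2 balances q(m2) = epsilon * d
  e2_valid <- TRUE; e2_note <- NULL
  if (is.null(m2)) {
    arg <- 2 * p$epsilon * p$d / p$q0 - 1
    if (p$q0 > p$epsilon * p$d && abs(arg) < 1) {
      m2 <- p$m0 + p$sigma * atanh(arg)
    } else {
      m2 <- p$gamma / (2 * p$alpha)
      e2_valid <- FALSE
      e2_note <- "q0 <= epsilon*d: no balancing microRNA level exists"
    }
  }
  S2 <- -p$S0 * log(p$alpha * m2 / p$gamma)
  if (m2 >= p$gamma / p$alpha) {
    e2_valid <- FALSE
    e2_note <- c(e2_note, "m2 >= gamma/alpha: S2 <= 0")
  }
  e2 <- c(S = S2, D = S2 / p$d, a = 0, m = m2)
  res2 <- if (all(e2 >= 0)) rhs_norm(e2) else NA_real_

  # E3: Wnt-active closed form
  w <- p$psi * p$alpha / (p$d * p$beta)
  a3_warn <- w >= 1
  a3 <- (1 + w * (1 + p$eta)) / (2 * p$eta * (1 - w)) *
    (1 + sqrt(1 + 4 * w * p$eta * (1 - w) / (1 + w * (1 + p$eta))^2))
  S3 <- p$alpha * (1 + a3) / (p$beta * a3)
  D3 <- S3 / p$d
  m3 <- p$gamma / p$alpha * exp(-S3 / p$S0)
  e3 <- c(S = S3, D = D3, a = a3, m = m3)
  # defining conditions of the closed form (dedifferentiation-silent regime)
  res3 <- max(abs(c(
    2 * division_probability(D3, a3, p$eta, p$psi) - 1,   # stem-cell balance
    p$beta * S3 * a3 / (1 + a3) - p$alpha,                # Wnt balance
    2 * (1 - division_probability(D3, a3, p$eta, p$psi)) * p$epsilon * S3 -
      p$d * D3,                                           # DC balance, q -> 0
    p$gamma * exp(-S3 / p$S0) - p$alpha * m3              # microRNA balance
  )))

  list(
    E1 = list(state = e1, residual = res1, rhs_residual = rhs_norm(e1)),
    E2 = list(state = e2, residual = res2, rhs_residual = res2,
              valid = e2_valid, note = e2_note),
    E3 = list(state = e3, residual = res3, rhs_residual = rhs_norm(e3),
              branch_warning = a3_warn)
  )
}

#' First time a trajectory component falls and stays below a threshold
#'
#' Operationalizes "eradication": the earliest trajectory time from which
#' the chosen component remains below `threshold` until the end of the
#' simulation.
#'
#' @param traj a `csc_trajectory`.
#' @param component `"S"` or `"D"`.
#' @param threshold positive concentration threshold.
#' @return time in years, or `NA` if the component never stays below.
#' @export
eradication_time <- function(traj, component = c("S", "D"), threshold) {
  component <- match.arg(component)
  stopifnot(threshold > 0)
  x <- traj$states[, component]
  below <- x < threshold
  if (!any(below)) return(NA_real_)
  # last index above threshold; eradication starts just after it
  last_above <- max(which(!below), 0L)
  if (last_above >= length(x)) return(NA_real_)
  traj$times[last_above + 1L]
}

#' Percent reduction between two concentrations
#'
#' `100 (1 - c_after / c_before)`, the reporting convention for
#' concentration drops across a treatment interval.  Full precision is
#' returned; round for display.
#'
#' @param c_before concentration before (> 0).
#' @param c_after concentration after (>= 0).
#' @return percent reduction (vectorized).
#' @examples
#' round(percent_reduction(0.0338857, 0.0067512), 2)   # 80.08
#' @export
percent_reduction <- function(c_before, c_after) {
  if (any(c_before <= 0)) stop("'c_before' must be positive", call. = FALSE)
  if (any(c_after < 0)) stop("'c_after' must be non-negative", call. = FALSE)
  100 * (1 - c_after / c_before)
}
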