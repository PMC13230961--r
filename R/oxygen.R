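#' Parameters of the oxygen reaction-diffusion field
#'
#' Oxygen partial pressure on a square tumor domain obeys
#' `dP/dt = -C_max P/(k + P) (S + D) + D_O2 Laplacian(P)` with Dirichlet
#' boundary `P = P_c` (capillary supply at the rim).  Time is in seconds —
#' oxygen equilibrates on a much faster scale than the cell populations —
#' and space in mm on the centered domain `[-l/2, l/2]^2`.
#'
#' The explicit scheme requires the diffusion number
#' `D_O2 * dt / dx^2 <= 0.25`; the defaults give `5e-4`.
#'
#' @param D_O2 oxygen diffusion coefficient, mm^2/s.
#' @param C_max maximum metabolic consumption, mmHg mm^3 / (cell s).
#' @param k partial pressure at half-maximal metabolism, mmHg.
#' @param P_c capillary boundary pressure, mmHg.
#' @param l domain width, mm.
#' @param dx grid spacing, mm (`l/dx` must be integral).
#' @param dt time step, s.
#' @param cell_density total cell concentration `S + D`, cell/mm^3
#'   (scalar, or a full `(l/dx + 1)^2` matrix for a spatially varying
#'   density).
#' @return list of class `oxygen_params`.
#' @export
oxygen_params <- function(D_O2 = 0.002, C_max = 15, k = 2.5, P_c = 40,
                          l = 20, dx = 0.2, dt = 0.01, cell_density = 1) {
  stopifnot(D_O2 > 0, C_max > 0, k > 0, P_c > 0, l > 0, dx > 0, dt > 0,
            all(cell_density >= 0))
  n <- l / dx
  if (abs(n - round(n)) > 1e-9) {
    stop("'l/dx' must be an integer number of cells", call. = FALSE)
  }
  s <- D_O2 * dt / dx^2
  if (s > 0.25) {
    stop(sprintf("stability number D_O2*dt/dx^2 = %.3g exceeds 0.25; ", s),
         "reduce 'dt' or coarsen 'dx'", call. = FALSE)
  }
  structure(list(D_O2 = D_O2, C_max = C_max, k = k, P_c = P_c, l = l,
                 dx = dx, dt = dt, cell_density = cell_density,
                 n_nodes = as.integer(round(n)) + 1L),
            class = "oxygen_params")
}

#' Grid node coordinates of the oxygen domain
#'
#' @param params an [oxygen_params()] object.
#' @return numeric vector of node coordinates on `[-l/2, l/2]`.
#' @export
oxygen_grid <- function(params) {
  seq(-params$l / 2, params$l / 2, by = params$dx)
}

#' Initial oxygen pressure field
#'
#' A small deterministic ripple on the capillary pressure,
#' `P(x, y, 0) = P_c + 0.1 cos((x^2 + y^2 - 55) pi)
#'             - 0.01 sin((x^2 + y^2 + 91) pi)` (the `"additive"` reading;
#' the `"nested"` variant places the sine term inside the cosine argument).
#' The radially symmetric perturbation seeds the circular depletion
#' patterns of the consumption-diffusion dynamics.  The boundary ring is
#' overwritten with `P_c`.
#'
#' @inheritParams oxygen_grid
#' @param perturbed logical; `FALSE` gives the uniform field `P_c`.
#' @param reading `"additive"` (canonical) or `"nested"` grouping of the
#'   perturbation terms.
#' @return object of class `pressure_field`: the pressure matrix with
#'   attributes `params`, `time` (s) and `coords`.
#' @export
initial_pressure_field <- function(params = oxygen_params(),
                                   perturbed = TRUE,
                                   reading = c("additive", "nested")) {
  reading <- match.arg(reading)
  xs <- oxygen_grid(params)
  n <- params$n_nodes
  if (perturbed) {
    r2 <- outer(xs^2, xs^2, "+")
    P <- if (reading == "additive") {
      params$P_c + 0.1 * cos((r2 - 55) * pi) - 0.01 * sin((r2 + 91) * pi)
    } else {
      params$P_c + 0.1 * cos((r2 - 55) * pi - 0.01 * sin((r2 + 91) * pi))
    }
  } else {
    P <- matrix(params$P_c, n, n)
  }
  P[1, ] <- params$P_c; P[n, ] <- params$P_c
  P[, 1] <- params$P_c; P[, n] <- params$P_c
  structure(P, params = params, time = 0, coords = xs,
            class = c("pressure_field", "matrix", "array"))
}

#' Michaelis-Menten oxygen consumption rate
#'
#' `C_max * P_o / (k + P_o) * (S + D)`: half-maximal at `P_o = k`,
#' saturating at `C_max * (S + D)`.
#'
#' @param P_o oxygen partial pressure, mmHg (vector or matrix, >= 0).
#' @inheritParams oxygen_grid
#' @return consumption (sink) rate, mmHg/s.
#' @export
oxygen_consumption <- function(P_o, params = oxygen_params()) {
  if (any(P_o < 0)) stop("'P_o' must be non-negative", call. = FALSE)
  params$C_max * P_o / (params$k + P_o) * params$cell_density
}

# 5-point Laplacian on the interior, zero on the Dirichlet ring
laplacian5 <- function(M, dx) {
  n <- nrow(M)
  L <- matrix(0, n, n)
  i <- 2:(n - 1)
  L[i, i] <- (M[i - 1, i] + M[i + 1, i] + M[i, i - 1] + M[i, i + 1] -
                4 * M[i, i]) / dx^2
  L
}

#' Integrate the oxygen reaction-diffusion field
#'
#' Explicit time stepping (classical RK4 by default, forward Euler
#' available) on the 5-point Laplacian semi-discretization.  The Dirichlet
#' ring is re-imposed after every stage and every step.  With zero cell
#' density the uniform capillary pressure is an exact steady state and is
#' preserved to machine precision.
#'
#' @inheritParams oxygen_grid
#' @param t_end final time, s.
#' @param init optional initial `pressure_field`; defaults to
#'   [initial_pressure_field()] with the perturbed ripple.
#' @param snapshot_times optional times (s) at which to keep intermediate
#'   fields (snapped to step boundaries).
#' @param method `"rk4"` (default) or `"euler"`.
#' @return the final `pressure_field`; if `snapshot_times` were requested,
#'   the attribute `snapshots` holds a named list of intermediate fields.
#' @examples
#' p <- oxygen_params(l = 20, dx = 1, cell_density = 0)
#' f <- simulate_oxygen(p, t_end = 0.5)
#' range(f)   # exactly 40
#' @export
simulate_oxygen <- function(params = oxygen_params(), t_end,
                            init = NULL, snapshot_times = NULL,
                            method = c("rk4", "euler")) {
  method <- match.arg(method)
  stopifnot(t_end >= 0)
  if (is.null(init)) init <- initial_pressure_field(params)
  P <- unclass(init); attributes(P) <- list(dim = dim(init))
  n <- params$n_nodes
  stopifnot(nrow(P) == n, ncol(P) == n)
  dt <- params$dt; dx <- params$dx
  dens <- params$cell_density

  clamp_bc <- function(M) {
    M[1, ] <- params$P_c; M[n, ] <- params$P_c
    M[, 1] <- params$P_c; M[, n] <- params$P_c
    M
  }
  rhs <- function(M) {
    R <- -params$C_max * M / (params$k + M) * dens +
      params$D_O2 * laplacian5(M, dx)
    R[1, ] <- 0; R[n, ] <- 0; R[, 1] <- 0; R[, n] <- 0
    R
  }

  nsteps <- round(t_end / dt)
  snaps <- list()
  snap_idx <- if (is.null(snapshot_times)) integer(0) else
    unique(pmin(pmax(round(snapshot_times / dt), 0L), nsteps))
  wrap <- function(M, t) structure(M, params = params, time = t,
                                   coords = oxygen_grid(params),
                                   class = c("pressure_field", "matrix",
                                             "array"))
  if (0L %in% snap_idx) snaps[["0"]] <- wrap(P, 0)

  for (i in seq_len(nsteps)) {
    if (method == "rk4") {
      k1 <- rhs(P)
      k2 <- rhs(clamp_bc(P + dt / 2 * k1))
      k3 <- rhs(clamp_bc(P + dt / 2 * k2))
      k4 <- rhs(clamp_bc(P + dt * k3))
      P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      P <- P + dt * rhs(P)
    }
    P <- clamp_bc(P)
    if (min(P) < -1e-9) {
      stop(sprintf("negative oxygen pressure (%.3g) at t = %.4g s",
                   min(P), i * dt), call. = FALSE)
    }
    if (i %in% snap_idx) snaps[[format(i * dt)]] <- wrap(P, i * dt)
  }

  out <- wrap(P, nsteps * dt)
  if (length(snaps)) attr(out, "snapshots") <- snaps
  out
}

#' @export
print.pressure_field <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<pressure_field>  %dx%d nodes, l = %g mm, t = %g s\n",
              nrow(x), ncol(x), p$l, attr(x, "time")))
  cat(sprintf("  interior mean = %.4f mmHg, min = %.4f, max = %.4f\n",
              mean(x[2:(nrow(x) - 1), 2:(ncol(x) - 1)]), min(x), max(x)))
  invisible(x)
}

#' @export
plot.pressure_field <- function(x, ...) {
  xs <- attr(x, "coords")
  graphics::image(xs, xs, unclass(x), xlab = "x [mm]", ylab = "y [mm]",
                  main = sprintf("oxygen pressure, t = %g s",
                                 attr(x, "time")),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Summaries of an oxygen pressure field
#'
#' Interior mean and minimum pressure (the Dirichlet ring is excluded from
#' the interior mean; `mean_all` includes it), the per-node OER histogram
#' in both orientations (node counts binned by OER, and mean OER binned by
#' pressure), and the unit-normalized empirical pressure density consumed by
#' [surviving_fraction()].
#'
#' @param field a `pressure_field`.
#' @param oer_pars an [oer_params()] object.
#' @param oer_bins,pressure_bins number of histogram bins.
#' @return list with `mean_interior`, `mean_all`, `min`, `max`,
#'   `oer_histogram` (data.frame: bin edges and node counts),
#'   `pressure_by_oer` (data.frame: mean pressure per OER bin),
#'   `pressure_density` (list `breaks`, `masses` summing to 1).
#' @export
field_summaries <- function(field, oer_pars = oer_params(),
                            oer_bins = 20, pressure_bins = 20) {
  stopifnot(inherits(field, "pressure_field"))
  n <- nrow(field)
  interior <- field[2:(n - 1), 2:(n - 1)]
  vals <- as.numeric(field)
  o <- oer(vals, oer_pars)

  ob <- seq(min(o), max(o), length.out = oer_bins + 1)
  if (ob[1] == ob[length(ob)]) ob <- ob[1] + c(-5e-7, 5e-7) * max(1, abs(ob[1]))
  oc <- cut(o, ob, include.lowest = TRUE)
  oer_histogram <- data.frame(
    oer_bin_left = ob[-length(ob)], oer_bin_right = ob[-1],
    count = as.integer(table(oc))
  )
  pressure_by_oer <- data.frame(
    oer_bin_left = ob[-length(ob)], oer_bin_right = ob[-1],
    mean_pressure = as.numeric(tapply(vals, oc, mean))
  )

  pb <- seq(min(vals), max(vals), length.out = pressure_bins + 1)
  if (pb[1] == pb[length(pb)]) pb <- pb[1] + c(-5e-7, 5e-7) * max(1, abs(pb[1]))
  pc <- cut(vals, pb, include.lowest = TRUE)
  masses <- as.integer(table(pc))
  pressure_density <- list(breaks = pb, masses = masses / sum(masses))

  list(mean_interior = mean(interior), mean_all = mean(vals),
       min = min(vals), max = max(vals),
       oer_histogram = oer_histogram, pressure_by_oer = pressure_by_oer,
       pressure_density = pressure_density)
}

#' Write a pressure field as plain matrix text
#'
#' Node-ordered, row-major plain text with a comment header carrying the
#' grid metadata (`l`, `dx`, `t`).
#'
#' @param field a `pressure_field`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_field <- function(field, file) {
  p <- attr(field, "params")
  hdr <- sprintf("# pressure_field l=%g dx=%g t=%g", p$l, p$dx,
                 attr(field, "time"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(unclass(field), digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}
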