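#' One-at-a-time local sensitivity analysis
#'
#' Each parameter is perturbed individually by a relative `delta` (default
#' +0.1 percent) while all others stay at their nominal values, and the
#' normalized finite-difference elasticity
#' `index_i = ((Y(p_i (1 + delta)) - Y(p)) / Y(p)) / delta`
#' is reported.  Positive (negative) indices mean the output increases
#' (decreases) with the parameter.  One model evaluation per parameter plus
#' one nominal evaluation.
#'
#' Zero-valued nominal parameters cannot be perturbed relatively and are
#' skipped with a message; parameters whose perturbed output is non-finite
#' are flagged and excluded from the ranking.
#'
#' @param model function taking a full named parameter vector and returning
#'   a scalar output.
#' @param params named numeric vector of nominal values.
#' @param delta relative perturbation (default `0.001` = +0.1 percent).
#' @param difference `"forward"` (canonical) or `"central"`.
#' @param perturb names of the parameters to perturb (default: all); the
#'   others stay fixed at their nominal values.
#' @return object of class `oat_sensitivity`: a data.frame with columns
#'   `parameter`, `nominal`, `perturbed`, `output_nominal`,
#'   `output_perturbed`, `index`, ordered by decreasing `|index|` with an
#'   alphabetical tie-break.  Attribute `excluded` lists flagged parameters.
#' @examples
#' oat_sensitivity(function(p) p[["x"]]^2 * p[["y"]], c(x = 2, y = 3))
#' @export
oat_sensitivity <- function(model, params, delta = 0.001,
                            difference = c("forward", "central"),
                            perturb = names(params)) {
  difference <- match.arg(difference)
  stopifnot(is.function(model), is.numeric(params), length(params) > 0,
            !is.null(names(params)), all(nzchar(names(params))), delta > 0,
            all(perturb %in% names(params)))
  Y0 <- model(params)
  if (!is.finite(Y0)) stop("output not finite at the nominal point",
                           call. = FALSE)
  zero <- intersect(perturb, names(params)[params == 0])
  if (length(zero)) {
    message("skipping zero-valued parameter(s): ",
            paste(zero, collapse = ", "))
  }
  use <- setdiff(perturb, zero)
  rows <- lapply(use, function(nm) {
    pp <- params; pp[nm] <- params[nm] * (1 + delta)
    Yp <- model(pp)
    if (difference == "central") {
      pm <- params; pm[nm] <- params[nm] * (1 - delta)
      Ym <- model(pm)
      idx <- ((Yp - Ym) / Y0) / (2 * delta)
    } else {
      idx <- ((Yp - Y0) / Y0) / delta
    }
    data.frame(parameter = nm, nominal = unname(params[nm]),
               perturbed = unname(pp[nm]), output_nominal = Y0,
               output_perturbed = Yp, index = idx)
  })
  out <- do.call(rbind, rows)
  bad <- out$parameter[!is.finite(out$index)]
  out <- out[is.finite(out$index), , drop = FALSE]
  out <- out[order(-abs(out$index), out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = bad, delta = delta, difference = difference,
            class = c("oat_sensitivity", "data.frame"))
}

#' @export
print.oat_sensitivity <- function(x, digits = 10, ...) {
  cat(sprintf("One-at-a-time sensitivity (delta = %+g, %s difference)\n",
              attr(x, "delta"), attr(x, "difference")))
  tab <- sensitivity_table(x, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  if (length(attr(x, "excluded"))) {
    cat("excluded (non-finite output):",
        paste(attr(x, "excluded"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.oat_sensitivity <- function(x, ...) {
  graphics::barplot(rev(x$index), names.arg = rev(x$parameter), horiz = TRUE,
                    las = 1, xlab = "normalized sensitivity index", ...)
  invisible(x)
}

#' Two-column ranked sensitivity table
#'
#' The reporting layout: parameter and signed index to `digits` decimals,
#' sorted by decreasing absolute index (alphabetical tie-break, inherited
#' from the report ordering).
#'
#' @param report an [oat_sensitivity()] result.
#' @param digits decimals in the formatted index column.
#' @return data.frame with columns `parameter` and `index` (character,
#'   signed fixed-point).
#' @export
sensitivity_table <- function(report, digits = 10) {
  stopifnot(inherits(report, "oat_sensitivity"))
  data.frame(parameter = report$parameter,
             index = sprintf(paste0("%+.", digits, "f"), report$index))
}

#' Sensitivity scenario for the delayed tumor model
#'
#' Builds the `(model, params)` pair analysed in the dynamical-model
#' sensitivity study: the output is the final CSC concentration `S(t_end)`
#' with therapy initiated at `t = tau`.  The parameter vector mixes the
#' pharmacokinetic root quantities (`Tp`, `Tb`, `Tu`) with the derived
#' effective half-times (`Te`, `Teu`): perturbing a root propagates through
#' the harmonic combination, while perturbing a derived time bypasses the
#' propagation for that entry (detected by comparison with the nominal
#' derived value — exact under one-at-a-time perturbation).
#'
#' @param radionuclide registry name (default `"225Ac"`).
#' @param r0 extrapolated initial dose rate in Gy/year.
#' @param t_end final simulation time, years.
#' @param dt integration step, years.
#' @param params a [model_params()] object supplying the dynamical
#'   nominal values.
#' @param lq an [lq_params()] object.
#' @return list with `model` (function of a named vector) and `params`
#'   (named nominal vector), ready for [oat_sensitivity()].
#' @examples
#' sc <- csc_sensitivity_scenario()
#' names(sc$params)
#' @export
csc_sensitivity_scenario <- function(radionuclide = "225Ac", r0 = 50,
                                     t_end = 16, dt = 0.01,
                                     params = model_params(),
                                     lq = lq_params()) {
  ph <- get_radionuclide(radionuclide)
  tm0 <- effective_times(ph)
  nominal <- c(
    Tp = ph$Tp, Tb = ph$Tb, Tu = ph$Tu, Te = tm0$Te, Teu = tm0$Teu,
    r0 = r0, alpha_c = lq$alpha_c, beta_c = lq$beta_c, T_mu = lq$T_mu,
    upsilon = params$upsilon, theta = params$theta,
    eta = params$eta, psi = params$psi, epsilon = params$epsilon,
    q0 = params$q0, tau = params$tau, m0 = params$m0, sigma = params$sigma,
    d = params$d, alpha = params$alpha, beta = params$beta,
    gamma = params$gamma, S0 = params$S0
  )
  model <- function(p) {
    # roots unless a derived half-time was itself the perturbed entry
    Te  <- if (p[["Te"]]  != nominal[["Te"]])  p[["Te"]]
           else p[["Tp"]] * p[["Tb"]] / (p[["Tp"]] + p[["Tb"]])
    Teu <- if (p[["Teu"]] != nominal[["Teu"]]) p[["Teu"]]
           else p[["Tp"]] * p[["Tu"]] / (p[["Tp"]] + p[["Tu"]])
    tms <- structure(list(Te = Te, Teu = Teu, tau_e = Te - Teu,
                          name = radionuclide), class = "effective_times")
    lqp <- lq_params(p[["alpha_c"]], p[["beta_c"]], p[["T_mu"]])
    mp <- model_params(eta = p[["eta"]], psi = p[["psi"]],
                       epsilon = p[["epsilon"]], q0 = p[["q0"]],
                       tau = p[["tau"]], m0 = p[["m0"]],
                       sigma = p[["sigma"]], upsilon = p[["upsilon"]],
                       d = p[["d"]], theta = p[["theta"]],
                       alpha = p[["alpha"]], beta = p[["beta"]],
                       gamma = p[["gamma"]], S0 = p[["S0"]])
    th <- therapy_schedule(tms, r0 = p[["r0"]], r0_unit = "Gy/year",
                           t_start = p[["tau"]], lq = lqp)
    tr <- simulate_csc(mp, th, t_end = t_end, dt = dt)
    tr$states[nrow(tr$states), "S"]
  }
  list(model = model, params = nominal)
}

#' Sensitivity scenario for the oxygen field
#'
#' The output is the mean tumor oxygen pressure at `t_end` seconds at cell
#' density `S + D` (default 1 cell/mm^3).  The default output is the domain
#' mean including the capillary boundary ring — the convention under which
#' the three metabolic/transport elasticities take their reference values
#' (about -1.73 for `C_max`, +0.16 for `k`, +0.003 for `D_O2`); interior-
#' only and center-node variants are available.
#'
#' @param t_end final time, s.
#' @param cell_density total cell concentration, cell/mm^3.
#' @param output `"mean_all"` (default), `"mean_interior"` or `"center"`.
#' @param perturbed_ic logical; start from the rippled initial condition
#'   (default) or the uniform field.
#' @param base an [oxygen_params()] object supplying grid/step settings.
#' @return list with `model` and `params` (named vector `C_max`, `k`,
#'   `D_O2`), ready for [oat_sensitivity()].
#' @export
oxygen_sensitivity_scenario <- function(t_end = 2, cell_density = 1,
                                        output = c("mean_all",
                                                   "mean_interior",
                                                   "center"),
                                        perturbed_ic = TRUE,
                                        base = oxygen_params()) {
  output <- match.arg(output)
  nominal <- c(C_max = base$C_max, k = base$k, D_O2 = base$D_O2)
  model <- function(p) {
    pars <- oxygen_params(D_O2 = p[["D_O2"]], C_max = p[["C_max"]],
                          k = p[["k"]], P_c = base$P_c, l = base$l,
                          dx = base$dx, dt = base$dt,
                          cell_density = cell_density)
    f <- simulate_oxygen(pars, t_end = t_end,
                         init = initial_pressure_field(pars,
                                                       perturbed = perturbed_ic))
    n <- nrow(f)
    switch(output,
           mean_all = mean(f),
           mean_interior = mean(f[2:(n - 1), 2:(n - 1)]),
           center = f[(n + 1) %/% 2, (n + 1) %/% 2])
  }
  list(model = model, params = nominal)
}
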