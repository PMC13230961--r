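#' Linear-quadratic radiosensitivity parameters
#'
#' @param alpha_c linear radiosensitivity, 1/Gy.
#' @param beta_c quadratic radiosensitivity, 1/Gy^2.
#' @param T_mu sublethal-damage repair half-time, days.
#' @return list of class `lq_params`.  `alpha_c/beta_c` carries units of Gy.
#' @export
lq_params <- function(alpha_c = 0.46, beta_c = 0.30, T_mu = 0.062) {
  stopifnot(alpha_c > 0, beta_c > 0, T_mu > 0)
  structure(list(alpha_c = alpha_c, beta_c = beta_c, T_mu = T_mu),
            class = "lq_params")
}

#' Oxygen enhancement ratio parameters
#'
#' @param OER_max maximum oxygen enhancement ratio under full anoxia
#'   (dimensionless, >= 1).
#' @param K_m oxygen partial pressure at which the OER reaches half its
#'   maximum effect, mmHg.
#' @return list of class `oer_params`.
#' @export
oer_params <- function(OER_max = 3, K_m = 3.28) {
  stopifnot(OER_max >= 1, K_m > 0)
  structure(list(OER_max = OER_max, K_m = K_m), class = "oer_params")
}

#' Repopulation parameters for the biologically effective dose
#'
#' Used only when the overall treatment time `T` exceeds the repopulation
#' kick-off time `T_k`; then a term `ln(2) (T - T_k) / (alpha_c T_d)` is
#' subtracted from the BED.
#'
#' @param T overall treatment time, days.
#' @param T_k repopulation kick-off time, days.
#' @param T_d proliferation doubling time, days.
#' @return list of class `repop_params`.
#' @export
repop_params <- function(T, T_k, T_d) {
  stopifnot(T >= 0, T_k >= 0, T_d >= 0)
  structure(list(T = T, T_k = T_k, T_d = T_d), class = "repop_params")
}

#' Tumor clonogen burden
#'
#' @param varsigma clonogen concentration, cells/mm^3.
#' @param V tumor volume, mm^3.
#' @return list of class `tumor_burden` with the initial clonogen number
#'   `N = varsigma * V`.
#' @examples
#' tumor_burden(0.004576, 1e5)$N   # 457.6 clonogens
#' @export
tumor_burden <- function(varsigma, V) {
  stopifnot(varsigma >= 0, V >= 0)
  structure(list(varsigma = varsigma, V = V, N = varsigma * V),
            class = "tumor_burden")
}

#' Dose schedule for a protracted radioimmunotherapy administration
#'
#' Combines the extrapolated initial dose rate `r0` with the effective
#' uptake/clearance half-times of a radionuclide.  `r0` may be given in
#' Gy/day or Gy/year; it is stored internally in Gy/day.
#'
#' @param radionuclide a [radionuclide()] object, an [effective_times()]
#'   object, or a registry name such as `"225Ac"`.
#' @param r0 extrapolated initial dose rate (>= 0).
#' @param r0_unit unit of `r0`, `"Gy/day"` (default) or `"Gy/year"`.
#' @param days_per_year conversion factor for the year-based unit.
#' @return list of class `dose_schedule` with fields `r0` (Gy/day) and
#'   `times` (an `effective_times` object).
#' @examples
#' dose_schedule("90Y", r0 = 2)
#' dose_schedule("225Ac", r0 = 20, r0_unit = "Gy/year")
#' @export
dose_schedule <- function(radionuclide, r0, r0_unit = c("Gy/day", "Gy/year"),
                          days_per_year = 365) {
  times <- if (inherits(radionuclide, "effective_times")) {
    radionuclide
  } else if (inherits(radionuclide, "radionuclide")) {
    effective_times(radionuclide)
  } else {
    effective_times(get_radionuclide(radionuclide))
  }
  r0d <- r0_per_day(r0, match.arg(r0_unit), days_per_year)
  structure(list(r0 = r0d, times = times), class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("<dose_schedule %s>  r0 = %.4g Gy/day,  Te = %.4f d,  Teu = %.4f d\n",
              x$times$name, x$r0, x$times$Te, x$times$Teu))
  invisible(x)
}

#' Tumor dose rate of a biexponential uptake/clearance curve
#'
#' `r(t) = r0 (2^(-t/Te) - 2^(-t/Teu))`: the dose rate rises from zero as
#' activity is taken up by the tumor, peaks, and decays to zero as it is
#' cleared.  Non-negative for all `t >= 0` because `Te > Teu`.
#'
#' @param t time since administration, days (vectorized, >= 0).
#' @param sched a [dose_schedule()].
#' @return dose rate in Gy/day.
#' @examples
#' s <- dose_schedule("131I", r0 = 2)
#' dose_rate(c(0, 1, 2, 5), s)
#' @export
dose_rate <- function(t, sched) {
  stopifnot(inherits(sched, "dose_schedule"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  with(sched$times, sched$r0 * (2^(-t / Te) - 2^(-t / Teu)))
}

#' Peak of the dose-rate curve
#'
#' Closed-form maximizer of the biexponential dose rate: the stationary
#' point of `r(t)` is `t* = log(Te/Teu) / (log(2) (1/Teu - 1/Te))`.
#'
#' @inheritParams dose_rate
#' @return named numeric vector `c(t = t_peak, r = r_peak)` (days, Gy/day);
#'   `c(0, 0)` by convention when `r0 = 0`.
#' @examples
#' peak_dose_rate(dose_schedule("177Lu", r0 = 2))   # r ~ 0.608 Gy/day
#' @export
peak_dose_rate <- function(sched) {
  stopifnot(inherits(sched, "dose_schedule"))
  if (sched$r0 == 0) return(c(t = 0, r = 0))
  tm <- sched$times
  t_peak <- log(tm$Te / tm$Teu) / (log(2) * (1 / tm$Teu - 1 / tm$Te))
  c(t = t_peak, r = dose_rate(t_peak, sched))
}

#' Total absorbed dose for complete decay
#'
#' Integrating the biexponential dose rate over all time gives
#' `D = r0 * tau_e / log(2)` with `tau_e = Te - Teu` the effective time.
#'
#' @inheritParams dose_rate
#' @return total dose in Gy.
#' @export
total_dose <- function(sched) {
  stopifnot(inherits(sched, "dose_schedule"))
  sched$r0 * sched$times$tau_e / log(2)
}

#' Dose-protraction factor of the linear-quadratic model
#'
#' Closed-form time factor combining the repair half-time `T_mu` with the
#' effective uptake and clearance half-times.  It converts the protracted
#' biexponential irradiation into the quadratic-damage dose equivalent:
#' the relative effectiveness is `RE = 1 + r0 * Lambda / (log(2) *
#' (alpha_c/beta_c) * OER)`.  The expression has poles at `T_mu = Te` and
#' `T_mu = Teu`; those configurations are rejected.
#'
#' @param T_mu repair half-time, days.
#' @param times an [effective_times()] object.
#' @param tol pole-detection tolerance on `|T_mu - Te|`, `|T_mu - Teu|`.
#' @return protraction factor Lambda, days.
#' @examples
#' protraction_factor(0.062, effective_times(get_radionuclide("225Ac")))
#' @export
protraction_factor <- function(T_mu, times, tol = 1e-9) {
  stopifnot(inherits(times, "effective_times"), T_mu > 0)
  Te <- times$Te; Teu <- times$Teu
  if (abs(T_mu - Te) < tol || abs(T_mu - Teu) < tol) {
    stop("singular configuration: 'T_mu' coincides with an effective ",
         "half-time", call. = FALSE)
  }
  2 * T_mu^4 * (Te - Teu) / ((T_mu^2 - Te^2) * (T_mu^2 - Teu^2)) +
    2 * Te * Teu * T_mu / (Te^2 - Teu^2) *
      (Te / (T_mu - Te) + Teu / (T_mu - Teu)) -
    T_mu / (Te - Teu) * (Te^2 / (T_mu - Te) + Teu^2 / (T_mu - Teu))
}

#' Relative effectiveness per unit dose
#'
#' `RE = 1 + r0 * Lambda / (log(2) * (alpha_c/beta_c) * OER)` with the
#' `"alpha-beta"` convention (the dimensionally consistent form used by the
#' oxygen-modified BED).  The `"plain"` convention drops the
#' `(alpha_c/beta_c) * OER` divisor and is retained for comparison with the
#' bare protraction formula.
#'
#' @inheritParams dose_rate
#' @param lq an [lq_params()] object.
#' @param oer_value oxygen enhancement ratio at the point of interest
#'   (>= 1; use 1 for the oxygen-free case).
#' @param convention `"alpha-beta"` (default) or `"plain"`.
#' @return relative effectiveness, dimensionless, >= 1.
#' @export
relative_effectiveness <- function(sched, lq = lq_params(), oer_value = 1,
                                   convention = c("alpha-beta", "plain")) {
  convention <- match.arg(convention)
  stopifnot(inherits(sched, "dose_schedule"), inherits(lq, "lq_params"),
            all(oer_value >= 1))
  lam <- protraction_factor(lq$T_mu, sched$times)
  div <- if (convention == "alpha-beta") (lq$alpha_c / lq$beta_c) * oer_value else 1
  1 + sched$r0 * lam / (log(2) * div)
}

#' Oxygen enhancement ratio at a given oxygen partial pressure
#'
#' `OER(P_o) = OER_max (P_o + K_m) / (OER_max P_o + K_m)`: equals `OER_max`
#' under full anoxia and decreases monotonically to 1 as oxygenation
#' improves.
#'
#' @param P_o oxygen partial pressure, mmHg (vectorized, >= 0).
#' @param pars an [oer_params()] object.
#' @return dimensionless OER in `[1, OER_max]`.
#' @examples
#' oer(0)      # 3
#' oer(3.28)   # 1.5 (half-effect pressure)
#' oer(40)     # ~1.053, near-normoxic
#' @export
oer <- function(P_o, pars = oer_params()) {
  stopifnot(inherits(pars, "oer_params"))
  if (any(P_o < 0)) stop("'P_o' must be non-negative", call. = FALSE)
  pars$OER_max * (P_o + pars$K_m) / (pars$OER_max * P_o + pars$K_m)
}

#' Biologically effective dose of a protracted administration
#'
#' `BED = (D / OER) * RE(r0, OER)` where `D` is the total dose and `RE` the
#' relative effectiveness; when repopulation parameters are supplied and the
#' treatment time exceeds the kick-off time, `log(2) (T - T_k) /
#' (alpha_c T_d)` is subtracted.
#'
#' @inheritParams relative_effectiveness
#' @param repop optional [repop_params()]; omit (default) to use the
#'   no-repopulation branch.
#' @return BED in Gy.
#' @export
bed <- function(sched, lq = lq_params(), oer_value = 1, repop = NULL) {
  stopifnot(all(oer_value >= 1))
  D  <- total_dose(sched)
  RE <- relative_effectiveness(sched, lq, oer_value)
  out <- D / oer_value * RE
  if (!is.null(repop) && repop$T > repop$T_k) {
    if (repop$T_d == 0) {
      stop("'T_d' must be positive when repopulation is active", call. = FALSE)
    }
    out <- out - log(2) * (repop$T - repop$T_k) / (lq$alpha_c * repop$T_d)
  }
  out
}

#' Radioimmunotherapy coupling constant
#'
#' `R_imm = alpha_c * BED` (no-repopulation branch).  This dimensionless
#' scalar multiplies the radio-kill terms of the dynamical tumor model and
#' is the exponent of the surviving fraction.
#'
#' @inheritParams bed
#' @return dimensionless coupling R_imm >= 0.
#' @export
rit_rate <- function(sched, lq = lq_params(), oer_value = 1) {
  lq$alpha_c * bed(sched, lq, oer_value)
}

#' Surviving fraction of clonogens under protracted irradiation
#'
#' `SF = exp(-alpha_c * BED(P_o, r0))`.  With a scalar `P_o` the oxygen
#' density is a point mass; with `density` supplied the survival is averaged
#' over an oxygen-pressure distribution,
#' `SF = integral f(P_o) exp(-alpha_c BED(P_o, r0)) dP_o`.
#' `density` may be a function (unit-normalized pdf on `[0, Inf)`) or an
#' empirical histogram `list(breaks =, masses =)` such as the pressure
#' density exported by [field_summaries()].
#'
#' @inheritParams bed
#' @param P_o oxygen partial pressure, mmHg (point-mass case).
#' @param oer_pars an [oer_params()] object.
#' @param density optional oxygen-pressure density (see Details).
#' @param norm_tol tolerance on the density normalization check.
#' @return surviving fraction in (0, 1].
#' @examples
#' s <- dose_schedule("225Ac", r0 = 2)
#' surviving_fraction(s, P_o = 40)
#' surviving_fraction(s, density = list(breaks = c(1, 40), masses = 1))
#' @export
surviving_fraction <- function(sched, lq = lq_params(), P_o = NULL,
                               oer_pars = oer_params(), density = NULL,
                               norm_tol = 1e-6) {
  sf_point <- function(p) exp(-lq$alpha_c * bed(sched, lq, oer(p, oer_pars)))
  if (is.null(density)) {
    if (is.null(P_o)) stop("supply either 'P_o' or 'density'", call. = FALSE)
    return(sf_point(P_o))
  }
  if (is.function(density)) {
    tot <- stats::integrate(density, 0, Inf, rel.tol = 1e-9)$value
    if (abs(tot - 1) > norm_tol) {
      stop(sprintf("density integrates to %.6g, not 1", tot), call. = FALSE)
    }
    return(stats::integrate(function(p) density(p) * sf_point(p), 0, Inf,
                            rel.tol = 1e-9)$value)
  }
  # empirical histogram: breaks (length nb + 1) and bin masses (length nb)
  breaks <- density$breaks; masses <- density$masses
  stopifnot(length(breaks) == length(masses) + 1L)
  if (abs(sum(masses) - 1) > norm_tol) {
    stop(sprintf("histogram masses sum to %.6g, not 1", sum(masses)),
         call. = FALSE)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sum(masses * sf_point(mids))
}

#' Poisson tumor control probability
#'
#' `TCP = exp(-N * SF)` where `N` is the initial clonogen number and `SF`
#' the surviving fraction: the probability that no clonogen survives.
#'
#' @inheritParams surviving_fraction
#' @param burden a [tumor_burden()] object.
#' @return probability in `[0, 1]`.
#' @export
tcp <- function(sched, lq = lq_params(), burden, P_o = NULL,
                oer_pars = oer_params(), density = NULL) {
  stopifnot(inherits(burden, "tumor_burden"))
  sf <- surviving_fraction(sched, lq, P_o = P_o, oer_pars = oer_pars,
                           density = density)
  exp(-burden$N * sf)
}

#' Dose-response table over radionuclides and dose rates
#'
#' Long-format table of total dose, relative effectiveness, BED, surviving
#' fraction and TCP over a grid of extrapolated initial dose rates, for each
#' requested radionuclide, at a fixed oxygen partial pressure.
#'
#' @param radionuclides character vector of registry names.
#' @param r0 numeric grid of dose rates.
#' @param r0_unit unit of `r0`.
#' @param P_o oxygen partial pressure, mmHg (use large values for normoxia).
#' @param lq an [lq_params()] object.
#' @param oer_pars an [oer_params()] object; set `P_o` and
#'   `apply_oer = FALSE` jointly to reproduce oxygen-free curves.
#' @param burden a [tumor_burden()] object for the TCP column.
#' @param apply_oer logical; `FALSE` evaluates the oxygen-free stack
#'   (OER fixed at 1).
#' @return `data.frame` with columns `radionuclide`, `r0_gy_per_day`,
#'   `P_o_mmHg`, `D_gy`, `RE`, `BED_gy`, `SF`, `TCP`.
#' @export
dose_response_table <- function(radionuclides = names(radionuclide_registry()),
                                r0, r0_unit = c("Gy/day", "Gy/year"),
                                P_o = 40, lq = lq_params(),
                                oer_pars = oer_params(),
                                burden = tumor_burden(0.004576, 1e5),
                                apply_oer = TRUE) {
  r0_unit <- match.arg(r0_unit)
  if (!length(r0)) stop("'r0' grid must be non-empty", call. = FALSE)
  rows <- lapply(radionuclides, function(nm) {
    do.call(rbind, lapply(r0, function(r) {
      s <- dose_schedule(nm, r, r0_unit)
      ov <- if (apply_oer) oer(P_o, oer_pars) else 1
      D <- total_dose(s)
      RE <- relative_effectiveness(s, lq, ov)
      B <- bed(s, lq, ov)
      SF <- exp(-lq$alpha_c * B)
      data.frame(radionuclide = nm, r0_gy_per_day = s$r0, P_o_mmHg = P_o,
                 D_gy = D, RE = RE, BED_gy = B, SF = SF,
                 TCP = exp(-burden$N * SF))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smallest dose rate on a grid reaching tumor control
#'
#' Reports the smallest grid `r0` whose TCP is at least `1 - threshold`
#' (the crossing criterion for "TCP reaches 1" on a response curve).
#'
#' @param tab a [dose_response_table()] for a single radionuclide.
#' @param threshold TCP shortfall tolerated, default `1e-3`.
#' @return dose rate in Gy/day, or `NA` if the grid never crosses.
#' @export
tcp_crossing <- function(tab, threshold = 1e-3) {
  stopifnot(length(unique(tab$radionuclide)) == 1L)
  ok <- tab$TCP >= 1 - threshold
  if (!any(ok)) return(NA_real_)
  min(tab$r0_gy_per_day[ok])
}
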