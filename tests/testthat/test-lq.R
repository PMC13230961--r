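test_that("dose rate follows the biexponential uptake/clearance curve", {
  s <- dose_schedule("90Y", r0 = 2)
  expect_equal(dose_rate(0, s), 0)            # uptake starts from zero
  expect_error(dose_rate(-0.1, s), "non-negative")
  expect_equal(dose_rate(2.424, s), 0.2552, tolerance = 1e-3)
  # non-negative and vanishing at long times
  tt <- seq(0, 60, by = 0.05)
  expect_true(all(dose_rate(tt, s) >= 0))
  expect_lt(dose_rate(60, s), 1e-8)

  i131 <- dose_schedule("131I", r0 = 2)
  expect_equal(max(dose_rate(seq(0, 30, by = 1e-3), i131)), 0.4362,
               tolerance = 1e-3)
})

test_that("closed-form dose-rate peak matches numeric maximization", {
  for (nm in names(radionuclide_registry())) {
    s <- dose_schedule(nm, r0 = 2)
    pk <- peak_dose_rate(s)
    num <- stats::optimize(function(t) dose_rate(t, s),
                           c(0, 20 * s$times$Te), maximum = TRUE,
                           tol = 1e-12)
    # the stationary point is better conditioned through the derivative
    h <- 1e-5
    t_root <- stats::uniroot(function(t) (dose_rate(t + h, s) -
                                            dose_rate(t - h, s)) / (2 * h),
                             c(0.1, 20 * s$times$Te), tol = 1e-12)$root
    expect_equal(unname(pk["t"]), t_root, tolerance = 1e-8)
    expect_equal(unname(pk["r"]), num$objective, tolerance = 1e-10)
    # dominates a fine grid
    expect_gte(pk["r"], max(dose_rate(seq(0, 20 * s$times$Te,
                                          length.out = 2000), s)))
  }
  expect_equal(peak_dose_rate(dose_schedule("90Y", 0)), c(t = 0, r = 0))
})

test_that("total dose equals the full-decay integral of the dose rate", {
  expect_equal(total_dose(dose_schedule("131I", 0)), 0)
  ac <- dose_schedule("225Ac", r0 = 2)
  expect_equal(total_dose(ac), 2 * (4.8718 - 2.4242) / log(2),
               tolerance = 1e-4)
  for (nm in names(radionuclide_registry())) {
    for (r0 in c(0.1, 2, 10)) {
      s <- dose_schedule(nm, r0)
      quad <- stats::integrate(function(t) dose_rate(t, s), 0,
                               50 * s$times$Te, rel.tol = 1e-10)$value
      expect_rel_equal(total_dose(s), quad, 1e-6)
    }
  }
})

test_that("protraction factor matches the LQ double-integral oracle", {
  for (nm in names(radionuclide_registry())) {
    tms <- effective_times(get_radionuclide(nm))
    expect_rel_equal(protraction_factor(0.062, tms),
                     lambda_quadrature(0.062, tms), 1e-5)
  }
  ac <- effective_times(get_radionuclide("225Ac"))
  expect_equal(round(protraction_factor(0.062, ac), 4), 0.0208)
  i131 <- effective_times(get_radionuclide("131I"))
  expect_equal(round(protraction_factor(0.062, i131), 4), 0.0181)
  # instant repair kills the protraction correction
  expect_lt(protraction_factor(1e-5, ac), 1e-4)
  # pole rejection
  expect_error(protraction_factor(ac$Te, ac), "singular")
})

test_that("relative effectiveness scales with dose rate and oxygen", {
  lq <- lq_params()
  expect_equal(relative_effectiveness(dose_schedule("90Y", 0), lq), 1)
  ac <- dose_schedule("225Ac", r0 = 2)
  lam <- protraction_factor(lq$T_mu, ac$times)
  expect_equal(relative_effectiveness(ac, lq, 1),
               1 + 2 * lam / (log(2) * (0.46 / 0.30)))
  # better oxygenation shrinks the protraction boost toward 1
  re1 <- relative_effectiveness(ac, lq, 1)
  re2 <- relative_effectiveness(ac, lq, 2)
  expect_lt(re2, re1)
  expect_gte(re2, 1)
  # monotone in r0
  res <- sapply(c(0.5, 1, 2, 4), function(r)
    relative_effectiveness(dose_schedule("225Ac", r), lq))
  expect_true(all(diff(res) > 0))
  # plain convention drops the alpha/beta divisor
  expect_equal(relative_effectiveness(ac, lq, convention = "plain"),
               1 + 2 * lam / log(2))
})

test_that("the oxygen enhancement ratio has the saturating form", {
  expect_equal(oer(0), 3)                          # full anoxia
  expect_equal(oer(3.28), 2 * 3 / (3 + 1))          # half-effect = 1.5
  expect_equal(oer(40), 3 * 43.28 / 123.28)        # ~1.0532
  expect_error(oer(-1), "non-negative")
  pp <- seq(0, 100, by = 0.5)
  expect_true(all(diff(oer(pp)) < 0))              # strictly decreasing
  expect_gt(min(oer(pp)), 1)
  custom <- oer_params(OER_max = 2.5, K_m = 5)
  expect_equal(oer(0, custom), 2.5)
  expect_equal(oer(5, custom), 2 * 2.5 / 3.5)
})

test_that("BED composes total dose, RE and oxygen, with repopulation branch", {
  lq <- lq_params()
  expect_equal(bed(dose_schedule("131I", 0), lq), 0)
  ac <- dose_schedule("225Ac", r0 = 2)
  # oxygen-free branch: BED = D * RE, hence R_imm = alpha_c * BED
  expect_equal(bed(ac, lq), total_dose(ac) * relative_effectiveness(ac, lq))
  expect_equal(rit_rate(ac, lq), lq$alpha_c * bed(ac, lq))
  # oxygenated: dose divided by OER, RE damped by OER
  ov <- oer(40)
  expect_equal(bed(ac, lq, ov),
               total_dose(ac) / ov * relative_effectiveness(ac, lq, ov))
  # repopulation subtracts only when treatment outlasts the kick-off
  rp <- repop_params(T = 30, T_k = 10, T_d = 3)
  expect_equal(bed(ac, lq, repop = rp),
               bed(ac, lq) - log(2) * 20 / (0.46 * 3))
  expect_equal(bed(ac, lq, repop = repop_params(T = 5, T_k = 10, T_d = 3)),
               bed(ac, lq))
  expect_error(bed(ac, lq, repop = repop_params(T = 30, T_k = 10, T_d = 0)),
               "T_d")
})

test_that("R_imm grows with dose rate and with the effective time", {
  lq <- lq_params()
  expect_equal(rit_rate(dose_schedule("90Y", 0), lq), 0)
  rs <- sapply(c(0.5, 1, 2, 4, 8), function(r)
    rit_rate(dose_schedule("177Lu", r), lq))
  expect_true(all(diff(rs) > 0))
  # longer effective time -> larger total dose -> larger coupling
  expect_gt(rit_rate(dose_schedule("225Ac", 2), lq),
            rit_rate(dose_schedule("90Y", 2), lq))
})

test_that("surviving fraction decreases with dose rate and oxygenation", {
  lq <- lq_params()
  expect_equal(surviving_fraction(dose_schedule("90Y", 0), lq, P_o = 40), 1)
  for (nm in names(radionuclide_registry())) {
    s <- dose_schedule(nm, r0 = 2)
    expect_lt(surviving_fraction(s, lq, P_o = 40),
              surviving_fraction(s, lq, P_o = 1))
  }
  expect_lt(surviving_fraction(dose_schedule("225Ac", 2), lq, P_o = 10),
            surviving_fraction(dose_schedule("90Y", 2), lq, P_o = 10))
  sf <- surviving_fraction(dose_schedule("131I", 3), lq, P_o = 20)
  expect_gt(sf, 0); expect_lt(sf, 1)
})

test_that("density-averaged survival collapses and bounds correctly", {
  lq <- lq_params()
  s <- dose_schedule("177Lu", r0 = 2)
  # a one-bin histogram is a point mass at the bin midpoint
  pm <- list(breaks = c(25 - 1e-9, 25 + 1e-9), masses = 1)
  expect_equal(surviving_fraction(s, lq, density = pm),
               surviving_fraction(s, lq, P_o = 25), tolerance = 1e-8)
  # uniform density on [1, 40] lies between the endpoint survivals
  unif <- function(p) stats::dunif(p, 1, 40)
  sfu <- surviving_fraction(s, lq, density = unif)
  expect_gt(sfu, surviving_fraction(s, lq, P_o = 40))
  expect_lt(sfu, surviving_fraction(s, lq, P_o = 1))
  # histogram quadrature agrees with Monte-Carlo sampling of the histogram
  set.seed(42)
  breaks <- seq(1, 40, length.out = 14)
  masses <- diff(pbeta((breaks - 1) / 39, 2, 2))
  masses <- masses / sum(masses)
  hist_sf <- surviving_fraction(s, lq, density = list(breaks = breaks,
                                                      masses = masses))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  draws <- sample(mids, 2e5, replace = TRUE, prob = masses)
  mc_sf <- mean(surviving_fraction(s, lq, P_o = draws))
  expect_equal(hist_sf, mc_sf, tolerance = 1e-3)
  # non-normalized densities are rejected
  expect_error(surviving_fraction(s, lq, density = list(breaks = breaks,
                                                        masses = masses * 2)),
               "sum to")
})

test_that("TCP is the Poisson no-survivor probability", {
  lq <- lq_params()
  s <- dose_schedule("225Ac", r0 = 2)
  b <- tumor_burden(0.004576, 1e5)
  expect_equal(b$N, 457.6)
  expect_equal(tcp(s, lq, tumor_burden(0, 1), P_o = 40), 1)
  # bit-for-bit composition with the same surviving fraction
  sf <- surviving_fraction(s, lq, P_o = 40)
  expect_identical(tcp(s, lq, b, P_o = 40), exp(-457.6 * sf))
  # enormous dose rates control the tumor
  expect_gt(tcp(dose_schedule("225Ac", 50), lq, b, P_o = 40), 1 - 1e-6)
  # more clonogens, less control
  expect_lt(tcp(s, lq, tumor_burden(0.01, 1e5), P_o = 40),
            tcp(s, lq, b, P_o = 40))
})

test_that("dose-response table is consistent with the scalar operations", {
  lq <- lq_params()
  one <- dose_response_table("131I", r0 = 2, P_o = 40)
  expect_equal(nrow(one), 1L)
  s <- dose_schedule("131I", 2)
  expect_equal(one$BED_gy, bed(s, lq, oer(40)))
  expect_equal(one$SF, surviving_fraction(s, lq, P_o = 40))
  expect_equal(one$TCP, tcp(s, lq, tumor_burden(0.004576, 1e5), P_o = 40))

  tab <- dose_response_table(r0 = seq(0.5, 6, by = 0.5), P_o = 40)
  # BED hierarchy at each fixed dose rate
  for (r in unique(tab$r0_gy_per_day)) {
    sl <- tab[tab$r0_gy_per_day == r, ]
    expect_equal(sl$radionuclide[order(-sl$BED_gy)],
                 c("225Ac", "177Lu", "131I", "90Y"))
  }
  # TCP non-decreasing along the dose-rate grid
  for (nm in unique(tab$radionuclide)) {
    expect_true(all(diff(tab$TCP[tab$radionuclide == nm]) >= 0))
  }
  expect_error(dose_response_table(r0 = numeric(0)), "non-empty")
  # crossing helper finds the first controlled dose rate
  ac <- tab[tab$radionuclide == "225Ac", ]
  cr <- tcp_crossing(ac)
  if (!is.na(cr)) expect_gte(ac$TCP[ac$r0_gy_per_day == cr], 1 - 1e-3)
})

test_that("outputs are invariant under the year/day round trip of r0", {
  lq <- lq_params()
  a <- dose_schedule("177Lu", r0 = 2, r0_unit = "Gy/day")
  b <- dose_schedule("177Lu", r0 = 2 * 365, r0_unit = "Gy/year")
  expect_equal(a$r0, b$r0)
  expect_equal(bed(a, lq), bed(b, lq))
  expect_equal(rit_rate(a, lq, oer(20)), rit_rate(b, lq, oer(20)))
})
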