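# Independent numeric oracles used to pin closed-form results.

# Protraction factor via the LQ dose-protraction double integral:
# RE - 1 = 2/(D (a/b)) int_0^inf r(t) int_0^t r(t') exp(-mu (t - t')) dt' dt
# with r(t) biexponential; the inner integral is taken analytically, the
# outer numerically.  Lambda follows from RE - 1 = r0 Lambda / (ln2 (a/b)).
lambda_quadrature <- function(T_mu, times, r0 = 1) {
  mu <- log(2) / T_mu
  le <- log(2) / times$Te
  lu <- log(2) / times$Teu
  inner <- function(t) {
    r0 * ((exp(-le * t) - exp(-mu * t)) / (mu - le) -
            (exp(-lu * t) - exp(-mu * t)) / (mu - lu))
  }
  f <- function(t) r0 * (exp(-le * t) - exp(-lu * t)) * inner(t)
  I <- stats::integrate(f, 0, Inf, rel.tol = 1e-11)$value
  2 * log(2)^2 * I / (r0^2 * times$tau_e)
}

# 0-D consumption-only oxygen oracle: with diffusion negligible the pressure
# at density 1 satisfies k ln P + P = k ln P0 + P0 - C_max t; solved by
# root bracketing.
oxygen_pointwise_oracle <- function(t, P0 = 40, C_max = 15, k = 2.5) {
  target <- k * log(P0) + P0 - C_max * t
  stats::uniroot(function(p) k * log(p) + p - target,
                 c(1e-12, P0), tol = 1e-13)$root
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected) / abs(expected), rel_tol)
}
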