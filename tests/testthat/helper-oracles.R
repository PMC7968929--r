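# Closed-form oracles for steady states of the three-repressor model,
# derived independently of the package solver by solving the scalar
# fixed-point equations by hand (quadratic roots / short fixed-point
# chains). All assume k_L = k_C = 1, delta = 1.

# LacI fixed point when its supply is (1 + boost) * P_lac activity and
# I1 = 0:  L = (1 + boost) * (1 - L / (K + L))  =>  quadratic in L.
oracle_L_selfrepressed <- function(K, boost = 0) {
  s <- 1 + boost
  # L^2 + (K - s + s... expand: L(K+L) = s(K+L) - sL => L^2 + KL - sK = 0
  (-K + sqrt(K^2 + 4 * s * K)) / 2
}

# P_lac activity at that fixed point.
oracle_aP <- function(K, boost = 0) {
  L <- oracle_L_selfrepressed(K, boost)
  1 - L / (K + L)
}

# Four-state cI vector for the all-forward TLC arrangement (junction rates
# mu1 = T->L, mu2 = L->C), assembled state by state from the closed forms.
oracle_cI_TLC <- function(K, mu1, mu2) {
  # no inducer: L = (1+mu1) aP, T = aP, cI = A_C(T) + mu2 aP
  a0 <- oracle_aP(K, boost = mu1)
  T0 <- a0
  c(none = (1 - T0 / (K + T0)) + mu2 * a0,
    IPTG = K / (K + 1) + mu2 * 1,
    aTc  = 1 + mu2 * a0,
    both = 1 + mu2 * 1)
}

# mu = 0 decoupled cI vector, identical for every arrangement.
oracle_cI_mu0 <- function(K) {
  L <- oracle_L_selfrepressed(K)
  c(none = K / (K + L), IPTG = K / (K + 1), aTc = 1, both = 1)
}

# Long-time integration of the exported rhs with deSolve, independent of the
# package's steady-state solvers.
integrate_to_ss <- function(a, env, params, t_max = 1e4) {
  f <- function(t, y, p) list(as.numeric(readthru::grn_rhs(y, a, env, params)))
  sol <- deSolve::lsoda(c(0, 0, 0), times = c(0, t_max), func = f,
                        rtol = 1e-12, atol = 1e-12)
  as.numeric(sol[nrow(sol), 2:4])
}

fixture_observed <- function() {
  f <- observed_fixtures()
  f[is.na(f$variant), c("label", "phenotype")]
}
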