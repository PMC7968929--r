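p_fit <- model_params(K = 0.1, mu = 0.6)

test_that("promoter activity follows the subtractive repression form", {
  p <- model_params(K = 0.1)
  # full induction or no repressor: constitutive rate
  expect_equal(promoter_activity("P_lac", 5, 1, p), 1)
  expect_equal(promoter_activity("P_lac", 0, 0, p), 1)
  expect_equal(promoter_activity("P_tet", 0, 0, p), 1)
  # half-occupancy at R = K
  expect_equal(promoter_activity("P_lac", 0.1, 0, p), 0.5)
  # clamped at zero when the constitutive rate is knocked out
  p0 <- model_params(K = 0.1, k_C = 0)
  expect_equal(promoter_activity("P_tet", 1, 0, p0), 0)
  expect_error(promoter_activity("P_lac", -1, 0, p), "non-negative")
})

test_that("read-through requires an upstream same-orientation neighbour", {
  p <- model_params(mu = 0.5)
  act <- c(0.7, 0.5, 0.3)  # slot activities

  # all-forward TLC: slot1 has no upstream; L gains from T, C from L
  rchi <- readthrough_inputs(parse_label("TLC"), act, p)
  expect_equal(unname(rchi["tetR"]), 0)
  expect_equal(unname(rchi["lacI"]), 0.5 * 0.7)
  expect_equal(unname(rchi["cI"]), 0.5 * 0.5)

  # T_rCL: cI (slot 2, forward) has a reversed upstream neighbour -> 0;
  # tetR (slot 1, reverse) reads from slot 2 only if slot 2 were reversed
  rchi2 <- readthrough_inputs(parse_label("T_rCL"), act, p)
  expect_equal(unname(rchi2["cI"]), 0)
  expect_equal(unname(rchi2["tetR"]), 0)
  expect_equal(unname(rchi2["lacI"]), 0.5 * act[2])

  # mu = 0 silences every junction
  p0 <- model_params(mu = 0)
  expect_true(all(readthrough_inputs(parse_label("TLC"), act, p0) == 0))
})

test_that("rhs vanishes at analytic fixed points and drives trajectories toward them", {
  a <- parse_label("TLC")
  p0 <- model_params(K = 0.1, mu = 0)
  env_iptg <- inducer_states()[2, ]

  # induced, decoupled: dL/dt = 1 - L, zero exactly at L = 1
  d <- grn_rhs(c(1, 0.5, 0.2), a, env_iptg, p0)
  expect_equal(unname(d["dL"]), 0)

  ss <- steady_state(a, env_iptg, p_fit)
  d2 <- grn_rhs(c(ss$L, ss$T, ss$C), a, env_iptg, p_fit)
  expect_lt(max(abs(d2)), 1e-9)

  # crude forward-Euler from the origin shrinks the residual norm
  x <- c(0, 0, 0)
  n0 <- max(abs(grn_rhs(x, a, env_iptg, p_fit)))
  for (i in 1:200) x <- pmax(0, x + 0.05 * grn_rhs(x, a, env_iptg, p_fit))
  expect_lt(max(abs(grn_rhs(x, a, env_iptg, p_fit))), n0 / 100)

  expect_error(grn_rhs(c(-1, 0, 0), a, env_iptg, p_fit), "non-negative")
})

test_that("steady states match closed-form oracles", {
  envs <- inducer_states()

  # both inducers, mu = 0: all repression lifted -> (1, 1, 1)
  for (a in enumerate_arrangements(TRUE)[c(1, 17, 33)]) {
    ss <- steady_state(a, envs[4, ], model_params(K = 0.1, mu = 0))
    expect_equal(c(ss$L, ss$T, ss$C), c(1, 1, 1), tolerance = 1e-9)
  }

  # IPTG only, no read-through into cI: C = K/(K+1) with L = T = 1
  ss <- steady_state(parse_label("CLT"), envs[2, ],
                     model_params(K = 0.1, mu = 0))
  expect_equal(c(ss$L, ss$T, ss$C), c(1, 1, 0.1 / 1.1), tolerance = 1e-9)

  # TLC with read-through, IPTG only: L gains mu, C = K/(K+1) + mu
  ss2 <- steady_state(parse_label("TLC"), envs[2, ],
                      model_params(K = 0.1, mu = 0.3))
  expect_equal(c(ss2$L, ss2$T, ss2$C), c(1.3, 1, 0.1 / 1.1 + 0.3),
               tolerance = 1e-9)
})

test_that("truth tables match the hand-derived state-by-state solutions", {
  # mu = 0 decouples the cassette: one vector for every arrangement
  expected0 <- oracle_cI_mu0(0.1)
  for (a in enumerate_arrangements(TRUE)[c(5, 23, 42)]) {
    tt <- truth_table(a, model_params(K = 0.1, mu = 0))
    expect_equal(tt$cI, expected0, tolerance = 1e-8)
  }
  expect_equal(unname(expected0["none"]), 0.2702, tolerance = 1e-3)

  tt_fit <- truth_table(parse_label("TLC"), p_fit)
  expect_equal(tt_fit$cI, oracle_cI_TLC(0.1, 0.6, 0.6), tolerance = 1e-8)
  expect_equal(unname(tt_fit$cI), c(0.4442, 0.6909, 1.1324, 1.6),
               tolerance = 1e-3)

  # cI leading: no read-through into cI; T = 1.6 under IPTG
  tt_clt <- truth_table(parse_label("CLT"), p_fit)
  expect_equal(unname(tt_clt$cI["IPTG"]), 0.1 / 1.7, tolerance = 1e-8)
  expect_true(all(tt_fit$table$converged))
})

test_that("steady state is independent of the starting point", {
  set.seed(11)
  envs <- inducer_states()
  arrs <- enumerate_arrangements(TRUE)
  for (i in 1:20) {
    a <- arrs[[sample.int(48, 1)]]
    env <- envs[sample.int(4, 1), ]
    p <- model_params(K = 10^stats::runif(1, -3, 1),
                      mu = stats::runif(1))
    ref <- steady_state(a, env, p)
    for (j in 1:5) {
      ss <- steady_state(a, env, p, init = stats::runif(3, 0, 3))
      expect_lt(max(abs(c(ss$L - ref$L, ss$T - ref$T, ss$C - ref$C))), 1e-6)
    }
  }
})

test_that("Newton route agrees with independent long-time integration", {
  set.seed(7)
  envs <- inducer_states()
  arrs <- enumerate_arrangements(TRUE)
  for (i in 1:10) {
    a <- arrs[[sample.int(48, 1)]]
    env <- envs[sample.int(4, 1), ]
    p <- model_params(K = 10^stats::runif(1, -3, 1), mu = stats::runif(1))
    ss <- steady_state(a, env, p)
    expect_lt(max(abs(c(ss$L, ss$T, ss$C) - integrate_to_ss(a, env, p))),
              1e-8)
    sso <- steady_state(a, env, p, method = "ode")
    expect_lt(max(abs(c(ss$L - sso$L, ss$T - sso$T, ss$C - sso$C))), 1e-8)
  }
})

test_that("steady-state cI is non-decreasing in the junction rate into cI", {
  a <- parse_label("TLC")
  envs <- inducer_states()
  for (s in 1:4) {
    prev <- -Inf
    for (m in seq(0, 1, by = 0.1)) {
      v <- apply_variant(a, p_fit, "terminator_swap", junction = 2,
                         spec = terminator("Tvar", m))
      ss <- steady_state(v$arrangement, envs[s, ], v$params)
      expect_gte(ss$C + 1e-12, prev)
      prev <- ss$C
    }
  }
})

test_that("P_tet -10 knockout keeps IPTG response but removes aTc repression", {
  a <- parse_label("TLC")
  v <- apply_variant(a, p_fit, "ptet_minus10")
  expect_equal(v$params$k_C, 0)

  tt <- truth_table(a, p_fit)
  tt10 <- truth_table(v$arrangement, v$params)

  # without its own promoter, cI comes from read-through alone
  expect_equal(unname(tt10$cI["IPTG"]), 0.6, tolerance = 1e-8)
  lab <- classify_model(tt$cI, p_fit$tau)
  lab10 <- classify_model(tt10$cI, p_fit$tau)
  expect_identical(lab, "NOR")
  expect_identical(lab10, "NOT_IPTG")
  # IPTG-containing states stay OFF exactly as in the unmutated strain,
  # aTc alone no longer switches the output OFF
  expect_identical(logic_bits(lab)[c(2, 4)], logic_bits(lab10)[c(2, 4)])
  expect_false(logic_bits(lab)[3] == logic_bits(lab10)[3])
  expect_error(apply_variant(a, p_fit, "no_such_variant"), "unknown variant")
})

test_that("terminator swaps reshape the phenotype as their rate dictates", {
  a <- parse_label("TLC")
  # strong double terminator: revert to the mu = 0 (ab initio) prediction
  v0 <- apply_variant(a, p_fit, "terminator_swap", junction = 2,
                      spec = terminator("T1T2", 0))
  expect_identical(classify_model(truth_table(v0$arrangement, v0$params)$cI,
                                  p_fit$tau),
                   "NOT_aTc")

  # tandem terminators: product rate gives intermediate cI
  single <- apply_variant(a, p_fit, "terminator_swap", junction = 2,
                          spec = terminator("Tw", 0.5))
  dbl <- apply_variant(a, p_fit, "double_terminator", junction = 2,
                       spec = terminator("Tw", 0.5),
                       spec2 = terminator("Tw2", 0.5))
  expect_equal(dbl$arrangement$junctions[[2]]$readthrough_rate, 0.25)
  env <- inducer_states()[2, ]
  c_zero <- steady_state(v0$arrangement, env, v0$params)$C
  c_dbl <- steady_state(dbl$arrangement, env, dbl$params)$C
  c_single <- steady_state(single$arrangement, env, single$params)$C
  expect_true(c_zero < c_dbl && c_dbl < c_single)
})

test_that("IPTG dose-response curves are monotone and depressed by upstream read-through", {
  conc <- c(0, 1, 5, 10, 20, 50, 100, 200, 500, 1000, 1e5)
  c0 <- lac_induction_curve(0, iptg_concentrations = conc)
  c5 <- lac_induction_curve(0.5, iptg_concentrations = conc)
  c9 <- lac_induction_curve(0.9, iptg_concentrations = conc)

  # non-decreasing in concentration; endpoints bound the curve
  for (curve in list(c0, c5, c9)) {
    expect_true(all(diff(curve$output) >= -1e-12))
    expect_equal(curve$occupancy[1], 0)
    expect_gt(curve$occupancy[length(conc)], 0.99)
  }
  # more upstream read-through -> more LacI -> lower mid-range output
  mid <- conc > 0 & conc < 1e5
  expect_true(all(c5$output[mid] < c0$output[mid]))
  expect_true(all(c9$output[mid] < c5$output[mid]))
})
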