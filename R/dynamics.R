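#' Model parameters for the three-repressor read-through model
#'
#' The model reduces to two free parameters: the half-repression point `K`
#' (shared by P_lac and P_tet) and the read-through rate `mu` of a default T1
#' junction. Rates are dimensionless; the constitutive rates and the
#' degradation rate are fixed at 1, and the output threshold `tau` at 2/5.
#' The defaults for `K` and `mu` are a representative point of the
#' grid-search-admissible region (see [grid_search()]).
#'
#' @param k_L Constitutive rate of the P_lac-driven units (lacI and tetR).
#' @param k_C Constitutive rate of the P_tet-driven unit (cI).
#' @param delta First-order degradation/dilution rate.
#' @param K Half-repression point (K_L = K_T = K), must be > 0.
#' @param mu Default junction read-through rate in \[0, 1\].
#' @param tau Output threshold on normalized cI, in (0, 1).
#' @return An object of class `model_params`.
#' @export
model_params <- function(k_L = 1, k_C = 1, delta = 1, K = 0.1, mu = 0.6,
                         tau = 2 / 5) {
  stopifnot(k_L >= 0, k_C >= 0, delta > 0, K > 0)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1], got ", mu)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1), got ", tau)
  structure(list(k_L = k_L, k_C = k_C, delta = delta, K = K, mu = mu,
                 tau = tau),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> k_L=%g k_C=%g delta=%g K=%g mu=%g tau=%g\n",
    x$k_L, x$k_C, x$delta, x$K, x$mu, x$tau))
  invisible(x)
}

#' Canonical inducer states
#'
#' The four binary inducer environments, in the fixed canonical order used
#' throughout: none, IPTG only, aTc only, both. `I1` is the IPTG input acting
#' on P_lac, `I2` the aTc input acting on P_tet.
#'
#' @return Data frame with columns `state`, `I1`, `I2`.
#' @export
inducer_states <- function() {
  data.frame(state = c("none", "IPTG", "aTc", "both"),
             I1 = c(0, 1, 0, 1),
             I2 = c(0, 0, 1, 1),
             stringsAsFactors = FALSE)
}

#' Promoter activity under repression and induction
#'
#' Activity is the constitutive rate minus a saturable repression term,
#' clamped at zero: `max(0, k - (1 - I) * R / (K + R))`. At full induction
#' (`I = 1`) or zero repressor the promoter runs at `k`; at `R = K` and
#' `I = 0` the repression term is at half strength.
#'
#' @param promoter `"P_lac"` or `"P_tet"`.
#' @param repressor_conc Concentration of the cognate repressor (LacI for
#'   P_lac, TetR for P_tet); must be >= 0.
#' @param inducer_value Cognate inducer occupancy in \[0, 1\] (I1 for P_lac,
#'   I2 for P_tet).
#' @param params A [model_params()] object.
#' @return Transcription rate (dimensionless, >= 0).
#' @export
promoter_activity <- function(promoter, repressor_conc, inducer_value,
                              params = model_params()) {
  promoter <- match.arg(promoter, c("P_lac", "P_tet"))
  if (any(repressor_conc < 0)) {
    stop("repressor concentration must be non-negative")
  }
  stopifnot(all(inducer_value >= 0), all(inducer_value <= 1))
  k <- if (promoter == "P_lac") params$k_L else params$k_C
  pmax(0, k - (1 - inducer_value) *
         repressor_conc / (params$K + repressor_conc))
}

# Gene indices used in state vectors: 1 = lacI (L), 2 = tetR (T), 3 = cI (C).
GENE_ORDER <- c("lacI", "tetR", "cI")

# Compile an arrangement into a per-gene adjacency map: for each gene, the
# gene index of its immediately upstream same-orientation neighbour (0 if
# none) and the raw read-through rate of the junction crossed (NA = model mu).
# Read-through does not chain past one junction: the upstream contribution is
# always the neighbour's own-promoter activity.
compile_arrangement <- function(a) {
  validate_arrangement(a)
  up <- integer(3)
  mu_raw <- rep(NA_real_, 3)
  has_up <- logical(3)
  for (i in 1:3) {
    fwd <- a$slots$orientation[i] == "forward"
    u <- if (fwd) i - 1L else i + 1L          # slot transcribed into slot i
    if (u < 1L || u > 3L) next
    if (a$slots$orientation[u] != a$slots$orientation[i]) next
    g <- match(a$slots$gene[i], GENE_ORDER)
    up[g] <- match(a$slots$gene[u], GENE_ORDER)
    mu_raw[g] <- a$junctions[[min(i, u)]]$readthrough_rate
    has_up[g] <- TRUE
  }
  list(up = up, mu_raw = mu_raw, has_up = has_up)
}

# Own-promoter activities by gene index given state x = c(L, T, C).
gene_activities <- function(x, I1, I2, params) {
  a_plac <- max(0, params$k_L - (1 - I1) * x[1] / (params$K + x[1]))
  a_ptet <- max(0, params$k_C - (1 - I2) * x[2] / (params$K + x[2]))
  c(a_plac, a_plac, a_ptet)
}

#' Read-through production terms for an arrangement
#'
#' For each gene B with an immediately upstream, same-orientation neighbour A
#' (upstream in B's own transcription direction: the slot to the left for a
#' forward unit, to the right for a reverse unit), the read-through input is
#' `mu_junction * A'`, where `A'` is A's own-promoter activity. Convergent or
#' divergent neighbours contribute zero, and read-through does not chain
#' across two junctions.
#'
#' @param a An [arrangement()].
#' @param activities_by_slot Numeric length-3 vector of own-promoter
#'   activities of the slots, in slot order.
#' @param params A [model_params()]; junction rates of `NA` resolve to
#'   `params$mu`.
#' @return Named numeric vector of read-through inputs for `lacI`, `tetR`,
#'   `cI`.
#' @export
readthrough_inputs <- function(a, activities_by_slot,
                               params = model_params()) {
  stopifnot(length(activities_by_slot) == 3L, all(activities_by_slot >= 0))
  cmp <- compile_arrangement(a)
  mu <- ifelse(is.na(cmp$mu_raw), params$mu, cmp$mu_raw)
  act_by_gene <- numeric(3)
  act_by_gene[match(a$slots$gene, GENE_ORDER)] <- activities_by_slot
  rchi <- ifelse(cmp$has_up, mu * act_by_gene[pmax(cmp$up, 1L)], 0)
  names(rchi) <- GENE_ORDER
  rchi
}

# Steady-state residual F(x) = production - delta * x for compiled inputs.
ss_residual_fn <- function(cmp, mu, I1, I2, params) {
  force(cmp); force(mu)
  function(x) {
    act <- gene_activities(x, I1, I2, params)
    rchi <- c(0, 0, 0)
    for (g in 1:3) if (cmp$has_up[g]) rchi[g] <- mu[g] * act[cmp$up[g]]
    act + rchi - params$delta * x
  }
}

#' Time derivatives of the repressor concentrations
#'
#' The right-hand side of the model: for each gene, own-promoter activity
#' plus read-through input minus first-order degradation,
#' `dX/dt = A'_X + rchi_X - delta * X`.
#'
#' @param state Numeric vector `c(L, T, C)` of LacI, TetR, CI concentrations,
#'   all >= 0.
#' @param a An [arrangement()].
#' @param env One row of [inducer_states()] (or any list with `I1`, `I2`).
#' @param params A [model_params()].
#' @return Named numeric vector of derivatives `(dL, dT, dC)`.
#' @export
grn_rhs <- function(state, a, env, params = model_params()) {
  stopifnot(length(state) == 3L)
  if (any(state < 0)) stop("state must be non-negative")
  cmp <- compile_arrangement(a)
  mu <- ifelse(is.na(cmp$mu_raw), params$mu, cmp$mu_raw)
  f <- ss_residual_fn(cmp, mu, env$I1, env$I2, params)
  d <- f(as.numeric(state))
  names(d) <- c("dL", "dT", "dC")
  d
}

# Damped Newton iteration on F(x) = 0 with a numeric Jacobian, confined to
# the non-negative orthant. Returns list(x, residual, converged, iter).
newton_solve <- function(f, x0, tol = 1e-10, max_iter = 200L) {
  x <- x0
  fx <- f(x)
  for (iter in seq_len(max_iter)) {
    res <- max(abs(fx))
    if (res < tol) {
      return(list(x = x, residual = res, converged = TRUE, iter = iter))
    }
    J <- matrix(0, 3, 3)
    for (i in 1:3) {
      h <- 1e-7 * (1 + abs(x[i]))
      xp <- x
      xp[i] <- xp[i] + h
      J[, i] <- (f(xp) - fx) / h
    }
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) dx <- -fx  # singular Jacobian: fall back to relaxation
    lambda <- 1
    repeat {
      xn <- pmax(0, x + lambda * dx)
      fn <- f(xn)
      if (max(abs(fn)) < max(abs(fx)) || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-10 && max(abs(fn)) >= max(abs(fx))) {
      return(list(x = x, residual = max(abs(fx)), converged = FALSE,
                  iter = iter))
    }
    x <- xn
    fx <- fn
  }
  list(x = x, residual = max(abs(fx)), converged = max(abs(fx)) < tol,
       iter = max_iter)
}

#' Steady state of the network in one inducer environment
#'
#' Computes the fixed point of [grn_rhs()]. The default `"newton"` method is
#' a damped Newton root-finder started from the origin. Method `"ode"` is the
#' reference route: stiff-safe integration (deSolve) from the origin to
#' `t_max`, followed by one Newton polish from the integrator's endpoint;
#' both routes agree to high accuracy (a tested property of the package).
#' Non-convergence is flagged, never silent.
#'
#' @param a An [arrangement()].
#' @param env One row of [inducer_states()].
#' @param params A [model_params()].
#' @param method `"newton"` (fast root-finder) or `"ode"`
#'   (integrate-then-polish reference).
#' @param tol Convergence tolerance on the max-norm of the residual.
#' @param t_max Integration horizon for `method = "ode"`.
#' @param init Initial concentrations, default the origin.
#' @return An object of class `steady_state`: list with `L`, `T`, `C`,
#'   `residual`, `converged`, `method`.
#' @export
steady_state <- function(a, env, params = model_params(),
                         method = c("newton", "ode"), tol = 1e-10,
                         t_max = 1e4, init = c(0, 0, 0)) {
  method <- match.arg(method)
  cmp <- compile_arrangement(a)
  mu <- ifelse(is.na(cmp$mu_raw), params$mu, cmp$mu_raw)
  f <- ss_residual_fn(cmp, mu, env$I1, env$I2, params)
  x0 <- pmax(0, as.numeric(init))

  if (method == "ode") {
    deriv <- function(t, y, p) list(f(y))
    sol <- deSolve::lsoda(y = x0, times = c(0, t_max), func = deriv,
                          rtol = 1e-12, atol = 1e-12)
    x0 <- pmax(0, as.numeric(sol[nrow(sol), 2:4]))
  }
  ns <- newton_solve(f, x0, tol = tol)
  if (!ns$converged && method == "newton") {
    # rare fallback: hand the hard case to the integrator route
    return(steady_state(a, env, params, method = "ode", tol = tol,
                        t_max = t_max, init = init))
  }
  structure(list(L = ns$x[1], T = ns$x[2], C = ns$x[3],
                 residual = ns$residual, converged = ns$converged,
                 method = method),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> L=%.6g T=%.6g C=%.6g (residual %.2e, %s)\n",
              x$L, x$T, x$C, x$residual,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Truth table of steady-state cI levels over the four inducer states
#'
#' Solves the model in the four canonical environments and collects the raw
#' steady-state cI concentrations (normalization and thresholding happen in
#' [classify_model()]).
#'
#' @inheritParams steady_state
#' @return An object of class `truth_table`: list with `table` (one row per
#'   state: `state`, `I1`, `I2`, `L`, `T`, `C`, `residual`, `converged`) and
#'   `cI` (named numeric vector in canonical state order).
#' @export
truth_table <- function(a, params = model_params(),
                        method = c("newton", "ode")) {
  method <- match.arg(method)
  envs <- inducer_states()
  rows <- vector("list", nrow(envs))
  for (i in seq_len(nrow(envs))) {
    ss <- steady_state(a, envs[i, ], params, method = method)
    rows[[i]] <- data.frame(state = envs$state[i], I1 = envs$I1[i],
                            I2 = envs$I2[i], L = ss$L, T = ss$T, C = ss$C,
                            residual = ss$residual,
                            converged = ss$converged,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!all(tab$converged)) {
    warning("non-converged steady state for arrangement ", a$label)
  }
  cI <- tab$C
  names(cI) <- tab$state
  structure(list(arrangement = a$label, table = tab, cI = cI),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> ", x$arrangement, "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Lean inner loop for grid searches: 4-state cI vector from a compiled
# arrangement, Newton route only, origin start. Falls back to the integrator
# via steady_state() if Newton stalls (not observed in practice).
fast_cI <- function(cmp, params, a = NULL) {
  I1s <- c(0, 1, 0, 1)
  I2s <- c(0, 0, 1, 1)
  mu <- ifelse(is.na(cmp$mu_raw), params$mu, cmp$mu_raw)
  cI <- numeric(4)
  for (s in 1:4) {
    f <- ss_residual_fn(cmp, mu, I1s[s], I2s[s], params)
    ns <- newton_solve(f, c(0, 0, 0))
    if (!ns$converged && !is.null(a)) {
      env <- inducer_states()[s, ]
      ss <- steady_state(a, env, params, method = "ode")
      ns$x <- c(ss$L, ss$T, ss$C)
    }
    cI[s] <- ns$x[3]
  }
  names(cI) <- c("none", "IPTG", "aTc", "both")
  cI
}

#' Apply a genetic variant to the model inputs
#'
#' Variants modify the arrangement or the parameters without touching the
#' network topology:
#' \describe{
#'   \item{`ptet_minus10`}{Inactivating -10 mutation of P_tet: sets `k_C = 0`
#'     so cI has no own-promoter production, while read-through into cI is
#'     untouched.}
#'   \item{`terminator_swap`}{Replaces the terminator at `junction` (1 or 2)
#'     with `spec`.}
#'   \item{`double_terminator`}{Places `spec` and `spec2` in tandem at
#'     `junction`; read-through rates multiply.}
#' }
#'
#' @param a An [arrangement()].
#' @param params A [model_params()].
#' @param variant Variant name (see Details).
#' @param junction Junction index (1 = slots 1-2, 2 = slots 2-3).
#' @param spec,spec2 [terminator()] specs for the terminator variants.
#' @return List with modified `arrangement` and `params`.
#' @export
apply_variant <- function(a, params = model_params(), variant,
                          junction = NULL, spec = NULL, spec2 = NULL) {
  validate_arrangement(a)
  switch(variant,
    ptet_minus10 = {
      params$k_C <- 0
    },
    terminator_swap = {
      stopifnot(junction %in% 1:2, inherits(spec, "terminator_spec"))
      a$junctions[[junction]] <- spec
    },
    double_terminator = {
      stopifnot(junction %in% 1:2)
      a$junctions[[junction]] <- double_terminator(spec, spec2,
                                                   mu = params$mu)
    },
    stop("unknown variant: '", variant, "'")
  )
  list(arrangement = a, params = params)
}

#' P_lac output along an IPTG dose-response, with upstream read-through
#'
#' Continuous-induction extension of the model for a minimal one-repressor
#' network: IPTG concentration maps to fractional LacI inactivation through a
#' Hill function, LacI supply is its own-promoter production plus a
#' read-through contribution from an upstream gene, and the reported output
#' is the resulting P_lac activity. A weaker upstream terminator (larger
#' `mu_upstream`) supplies more LacI and lowers the output at intermediate
#' IPTG.
#'
#' @param mu_upstream Read-through rate of the terminator upstream of lacI,
#'   in \[0, 1\].
#' @param upstream_activity Transcription rate of the upstream gene (default
#'   1, a constitutively transcribed neighbour).
#' @param iptg_concentrations Numeric vector of IPTG concentrations (uM),
#'   >= 0.
#' @param dose_params List with Hill coefficient `hill` and `EC50` (uM) of
#'   the IPTG occupancy curve. The defaults (h = 2, EC50 = 100 uM) are
#'   package choices for this extension, not fitted values.
#' @param params A [model_params()].
#' @return Data frame with columns `iptg`, `occupancy`, `lacI`, `output`.
#' @export
lac_induction_curve <- function(mu_upstream, upstream_activity = 1,
                                iptg_concentrations,
                                dose_params = list(hill = 2, EC50 = 100),
                                params = model_params()) {
  stopifnot(mu_upstream >= 0, mu_upstream <= 1,
            all(iptg_concentrations >= 0), upstream_activity >= 0)
  h <- dose_params$hill
  ec <- dose_params$EC50
  r <- mu_upstream * upstream_activity
  out <- lapply(iptg_concentrations, function(conc) {
    I1 <- if (conc == 0) 0 else conc^h / (conc^h + ec^h)
    # scalar fixed point L = k_L - (1-I1) L/(K+L) + r  (positive quadratic
    # root; the clamp never binds for k_L >= repression term)
    b <- params$K - (params$k_L + r) + (1 - I1)
    cc <- -(params$k_L + r) * params$K
    L <- (-b + sqrt(b^2 - 4 * cc)) / 2
    data.frame(iptg = conc, occupancy = I1, lacI = L,
               output = promoter_activity("P_lac", L, I1, params))
  })
  do.call(rbind, out)
}
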