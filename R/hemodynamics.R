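#' Carreau shear-thinning viscosity parameters
#'
#' Literature blood values (zero-shear viscosity 0.056 Pa s, infinite-shear
#' viscosity 0.0035 Pa s, relaxation time 3.313 s, power index 0.3568).
#' These are generic rheology constants, user-configurable.
#'
#' @param mu0 zero-shear viscosity, Pa s.
#' @param mu_inf infinite-shear viscosity, Pa s.
#' @param lambda relaxation time, s.
#' @param n power-law index.
#' @return list of class `carreau_params`.
#' @export
carreau_params <- function(mu0 = 0.056, mu_inf = 0.0035,
                           lambda = 3.313, n = 0.3568) {
  stopifnot(mu0 > 0, mu_inf > 0, mu_inf <= mu0, lambda >= 0)
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, n = n),
            class = "carreau_params")
}

#' Carreau effective viscosity
#'
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}}
#' Monotonically non-increasing in shear rate for n < 1 and bounded in
#' \eqn{[\mu_\infty, \mu_0]}. Vectorized over `shear_rate`.
#'
#' @param shear_rate shear rate(s), 1/s, >= 0.
#' @param params a [carreau_params()] set.
#' @return dynamic viscosity, Pa s.
#' @export
effective_viscosity <- function(shear_rate, params = carreau_params()) {
  if (any(shear_rate < 0)) stop_input("shear_rate must be >= 0")
  params$mu_inf + (params$mu0 - params$mu_inf) *
    (1 + (params$lambda * shear_rate)^2)^((params$n - 1) / 2)
}

#' Simulation configuration
#'
#' Physical and numerical settings of the transient simulation protocol:
#' four cardiac cycles are simulated, spheres are injected during the
#' first, and three more cycles let most spheres exit the domain. The
#' default time step is 2e-3 s and gravity acts with magnitude 9.8 m/s^2
#' (patient recumbent: along -z in the model frame).
#'
#' @param cardiac_period cardiac period, s.
#' @param n_cycles number of simulated cardiac cycles (>= 1).
#' @param dt time step, s; must satisfy `dt < cardiac_period / 10`.
#' @param gravity gravity vector, m/s^2.
#' @param blood_density blood density, kg/m^3.
#' @param viscosity Carreau parameter set.
#' @param seed integer seed used by the transport stage.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(cardiac_period = 1.0, n_cycles = 4,
                              dt = 2e-3, gravity = c(0, 0, -9.8),
                              blood_density = 1060,
                              viscosity = carreau_params(), seed = NULL) {
  check_scalar(cardiac_period, "cardiac_period", min = 0, strict_min = TRUE)
  check_scalar(n_cycles, "n_cycles", min = 1, integer = TRUE)
  check_scalar(dt, "dt", min = 0, strict_min = TRUE)
  if (dt >= cardiac_period / 10)
    stop_input("dt must be < cardiac_period / 10")
  stopifnot(length(gravity) == 3, blood_density > 0,
            inherits(viscosity, "carreau_params"))
  structure(list(cardiac_period = cardiac_period, n_cycles = n_cycles,
                 dt = dt, gravity = as.numeric(gravity),
                 blood_density = blood_density, viscosity = viscosity,
                 seed = seed),
            class = "simulation_config")
}

#' Pulsatile inlet waveform
#'
#' Truncated Fourier pulse: `mean_flow * (1 + sum_k a_k sin(2 pi k t / T +
#' phi_k))`. The cycle average equals `mean_flow` exactly for any harmonic
#' amplitudes because each harmonic integrates to zero over a full period.
#' Default amplitudes (0.35, 0.15) keep the waveform strictly positive; if
#' the supplied parameters allow negative instantaneous flow a warning is
#' raised (once, at evaluation).
#'
#' @param t time(s), s (vectorized).
#' @param mean_flow cycle-mean flow rate, ml/min.
#' @param params list with `period` (s), `rel_amp` (harmonic amplitudes as
#'   fractions of the mean) and `phase` (radians); see [waveform_params()].
#' @return instantaneous flow rate, ml/min.
#' @export
inlet_waveform <- function(t, mean_flow, params = waveform_params()) {
  if (mean_flow < 0) stop_input("mean_flow must be >= 0")
  if (sum(abs(params$rel_amp)) > 1)
    warning("waveform parameters allow negative instantaneous flow",
            call. = FALSE)
  w <- rep(1, length(t))
  for (k in seq_along(params$rel_amp))
    w <- w + params$rel_amp[k] *
      sin(2 * pi * k * t / params$period + params$phase[k])
  mean_flow * w
}

#' @rdname inlet_waveform
#' @param period cardiac period, s.
#' @param rel_amp relative harmonic amplitudes (0 for a constant inflow).
#' @param phase harmonic phases, radians (recycled to match `rel_amp`).
#' @export
waveform_params <- function(period = 1.0, rel_amp = c(0.35, 0.15),
                            phase = c(0, pi / 3)) {
  stopifnot(period > 0, length(rel_amp) >= 0)
  list(period = period, rel_amp = rel_amp,
       phase = rep_len(if (length(phase)) phase else 0,
                       length(rel_amp)))
}

#' Solve the network flow split
#'
#' In the reduced-order (0D) closure the per-outlet flows are boundary
#' conditions, so the flow in any branch is the inlet waveform scaled by
#' the sum of the flow fractions of the outlets downstream of that branch.
#' Mass is conserved at every bifurcation and every instant by
#' construction.
#'
#' @param tree an `arterial_tree`.
#' @param bcs outlet BC table from [outlet_flow_rates()]; its outlets must
#'   coincide with the tree's.
#' @param wave_params waveform parameter list ([waveform_params()]); the
#'   period should equal the simulation cardiac period.
#' @return object of class `flow_field`: the tree, per-branch downstream
#'   flow fractions, the inlet mean flow (ml/min) and the waveform
#'   parameters. Use [branch_flow()] / [velocity_profile()] to evaluate.
#' @export
solve_branch_flows <- function(tree, bcs, wave_params = waveform_params()) {
  stopifnot(inherits(tree, "arterial_tree"))
  if (!setequal(bcs$outlet_id, tree$outlet_ids))
    stop_input("outlet ids of tree and boundary conditions differ")
  frac <- stats::setNames(rep(0, nrow(tree$nodes)), tree$nodes$id)
  frac[bcs$outlet_id] <- bcs$flow_fraction
  # accumulate leaf fractions rootwards; deepest ids are the longest,
  # so processing by decreasing id length visits daughters before parents
  ord <- order(nchar(tree$nodes$id), decreasing = TRUE)
  for (i in ord) {
    p <- tree$nodes$parent_id[i]
    if (!is.na(p)) frac[p] <- frac[p] + frac[tree$nodes$id[i]]
  }
  structure(list(tree = tree, fractions = frac,
                 mean_inlet_ml_min = inlet_flow_rate(bcs),
                 wave_params = wave_params),
            class = "flow_field")
}

#' Evaluate branch flow over time
#'
#' @param field a `flow_field`.
#' @param branch_id branch id.
#' @param t time(s), s.
#' @return flow rate in the branch, ml/min (vectorized over `t`).
#' @export
branch_flow <- function(field, branch_id, t) {
  if (!branch_id %in% names(field$fractions))
    stop_input("unknown branch: ", branch_id)
  field$fractions[[branch_id]] *
    inlet_waveform(t, field$mean_inlet_ml_min, field$wave_params)
}

#' Quasi-steady laminar (Poiseuille) velocity profile
#'
#' Axial velocity at radial position r and time t:
#' \eqn{u(r,t) = 2 U(t) (1 - (r/R)^2)} with bulk velocity
#' \eqn{U(t) = Q(t) / (\pi R^2)}. Satisfies no-slip at the wall and
#' recovers Q(t) as the cross-sectional flux integral.
#'
#' @param field a `flow_field`.
#' @param branch_id branch id.
#' @param r radial position(s), m, in `[0, R]`.
#' @param t time, s.
#' @return axial velocity, m/s.
#' @export
velocity_profile <- function(field, branch_id, r, t) {
  nd <- field$tree$nodes
  R <- nd$radius_m[nd$id == branch_id]
  if (!length(R)) stop_input("unknown branch: ", branch_id)
  if (any(r < 0) || any(r > R))
    stop_input("r must lie in [0, R] with R = ", R)
  Q <- branch_flow(field, branch_id, t) * ML_MIN_TO_M3_S
  U <- Q / (pi * R^2)
  2 * U * (1 - (r / R)^2)
}

#' Export a per-branch flow time series
#'
#' Tabulates (and optionally writes) `branch_id, t_s, flow_ml_min` on the
#' simulation time grid.
#'
#' @param field a `flow_field`.
#' @param config a [simulation_config()].
#' @param path optional CSV path.
#' @return the time-series data.frame, invisibly if written.
#' @export
flow_time_series <- function(field, config, path = NULL) {
  tt <- seq(0, config$n_cycles * config$cardiac_period, by = config$dt)
  ids <- field$tree$nodes$id
  out <- do.call(rbind, lapply(ids, function(b)
    data.frame(branch_id = b, t_s = tt,
               flow_ml_min = branch_flow(field, b, tt),
               stringsAsFactors = FALSE)))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
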