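#' Microsphere properties
#'
#' Resin microsphere defaults: diameter 32 micrometres, density
#' 1600 kg/m^3 (typical literature values for resin spheres;
#' configurable).
#'
#' @param diameter sphere diameter, m.
#' @param density sphere density, kg/m^3.
#' @return list of class `microsphere_properties`.
#' @export
microsphere_properties <- function(diameter = 32e-6, density = 1600) {
  check_scalar(diameter, "diameter", min = 0, strict_min = TRUE)
  check_scalar(density, "density", min = 0, strict_min = TRUE)
  structure(list(diameter = diameter, density = density),
            class = "microsphere_properties")
}

#' Flux-weighted positions on a circular cross-section
#'
#' Samples points over a disc of radius `R` with density proportional to
#' the local Poiseuille axial velocity (flux weighting): the radial CDF is
#' \eqn{F(r) = 2(r/R)^2 - (r/R)^4}, inverted in closed form.
#'
#' @param n number of points.
#' @param R disc radius, m.
#' @return n x 2 matrix of (x, y) positions.
#' @export
sample_flux_positions <- function(n, R) {
  u <- stats::runif(n)
  r <- R * sqrt(1 - sqrt(1 - u))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# Normalized Poiseuille flux fraction through the half-plane {x > d} of the
# unit disc. Antiderivative of (1 - x^2)^{3/2}:
#   G(x) = (x (5 - 2 x^2) sqrt(1 - x^2) + 3 asin(x)) / 8,  total = 3 pi / 8.
flux_fraction_above <- function(d) {
  d <- pmin(pmax(d, -1), 1)
  G <- function(x) (x * (5 - 2 * x^2) * sqrt(pmax(1 - x^2, 0)) +
                      3 * asin(x)) / 8
  (G(1) - G(d)) / (3 * pi / 8)
}

# Chord offset d* (units of parent radius) such that the Poiseuille flux
# through {x > d*} equals f1; plain bisection to 1e-10.
partition_threshold <- function(f1) {
  stopifnot(f1 >= 0, f1 <= 1)
  if (f1 >= 1) return(-1)
  if (f1 <= 0) return(1)
  lo <- -1; hi <- 1
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (flux_fraction_above(mid) > f1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Assign a particle at a bifurcation to a daughter branch
#'
#' Reduced-order surrogate for the streamline split at a bifurcation: the
#' parent cross-section is partitioned by a chord perpendicular to the
#' projection of the daughter-separation axis, placed so that the
#' Poiseuille flux through the daughter-1 side equals its flow fraction
#' `f1`. The particle goes to the daughter whose region contains its
#' cross-sectional position; with flux-weighted particle positions the
#' expected split therefore equals the flow split.
#'
#' @param cross_position 2-vector (or n x 2 matrix) of cross-sectional
#'   position(s), m, in the parent (e1, e2) basis.
#' @param parent_radius parent vessel radius, m.
#' @param daughter_dirs 2 x 3 matrix of daughter unit directions.
#' @param fractions daughter flow fractions (f1, f2), summing to 1.
#' @param parent_dir parent unit direction (defines the cross basis).
#' @return integer vector of chosen daughters (1 or 2).
#' @export
bifurcation_assignment <- function(cross_position, parent_radius,
                                   daughter_dirs, fractions,
                                   parent_dir = c(1, 0, 0)) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_input("daughter flow fractions must sum to 1")
  cp <- if (is.matrix(cross_position)) cross_position else
    matrix(cross_position, ncol = 2)
  if (any(sqrt(rowSums(cp^2)) > parent_radius + 1e-12))
    stop_input("cross_position outside the lumen")
  ax <- bifurcation_axis(parent_dir, daughter_dirs[1, ], daughter_dirs[2, ])
  dstar <- partition_threshold(fractions[1])
  x <- (cp[, 1] * ax[1] + cp[, 2] * ax[2]) / parent_radius
  ifelse(x > dstar, 1L, 2L)
}

# Unit 2-vector (in the parent cross basis) of the daughter-separation
# axis; falls back to the fixed reference axis when the daughters project
# onto (anti)parallel directions.
bifurcation_axis <- function(parent_dir, d1, d2) {
  b <- cross_basis(parent_dir)
  v <- d1 - d2
  a <- c(sum(v * b$e1), sum(v * b$e2))
  na <- sqrt(sum(a^2))
  if (na < 1e-12) {
    warning("degenerate daughter directions; using reference axis",
            call. = FALSE)
    return(c(1, 0))
  }
  a / na
}

#' Injection schedule for one infusion
#'
#' Spheres are injected during the first cardiac cycle: release times are
#' uniform over `[0, cardiac_period)`, initial cross positions uniform
#' over the catheter lumen disc (centred at the tip offset), and the
#' initial velocity is the injection velocity along the vessel axis.
#'
#' @param n_particles number of spheres (>= 1).
#' @param catheter a [catheter_placement()].
#' @param tree the `arterial_tree` holding the catheter.
#' @param cardiac_period cardiac period, s.
#' @param seed integer seed.
#' @return data.frame `release_time_s`, `cross_x_m`, `cross_y_m`,
#'   `axial_m`, `v_axial_m_s`, with attribute `vessel_id`.
#' @export
injection_schedule <- function(n_particles, catheter, tree,
                               cardiac_period = 1.0, seed = NULL) {
  check_scalar(n_particles, "n_particles", min = 1, integer = TRUE)
  nd <- tree$nodes
  i <- match(catheter$vessel_id, nd$id)
  if (is.na(i)) stop_input("catheter vessel not in tree: ",
                           catheter$vessel_id)
  R <- nd$radius_m[i]
  if (catheter$catheter_inner_radius >= R)
    stop_input("catheter lumen does not fit inside the vessel")
  off <- catheter$radial_offset_fraction * (R - catheter$catheter_inner_radius)
  ctr <- off * c(cos(catheter$azimuth), sin(catheter$azimuth))
  with_seed(seed, {
    rel <- stats::runif(n_particles, 0, cardiac_period)
    rr <- catheter$catheter_inner_radius * sqrt(stats::runif(n_particles))
    th <- stats::runif(n_particles, 0, 2 * pi)
    out <- data.frame(
      release_time_s = rel,
      cross_x_m = ctr[1] + rr * cos(th),
      cross_y_m = ctr[2] + rr * sin(th),
      axial_m = catheter$axial_fraction * nd$length_m[i],
      v_axial_m_s = catheter$injection_velocity)
    attr(out, "vessel_id") <- catheter$vessel_id
    out
  })
}

#' Advance one microsphere by one time step (scalar reference update)
#'
#' Semi-implicit (drag-implicit) Euler update of Newton's second law with
#' Stokes drag, gravity and buoyancy:
#' \deqn{m \frac{dv}{dt} = 3\pi\mu d (u - v) + (\rho_p - \rho_f) V_p g,}
#' i.e. \eqn{v' = (v + \Delta t (u/\tau + b)) / (1 + \Delta t/\tau)} with
#' relaxation time \eqn{\tau = \rho_p d^2 / (18\mu)} and specific buoyant
#' force \eqn{b = (1 - \rho_f/\rho_p) g}. The fixed point in still fluid
#' is the Stokes terminal velocity \eqn{(\rho_p-\rho_f) g d^2 / (18\mu)}.
#' Positions advance by `velocity * dt`; the cross position is clamped to
#' the wall bound (spheres slide along the wall, no deposition).
#'
#' All vectors are in the branch-local frame (axial, cross-1, cross-2).
#'
#' @param state list with `axial_position` (m), `cross_position`
#'   (2-vector, m), `velocity` (3-vector, m/s).
#' @param dt time step, s.
#' @param u_fluid local fluid velocity, 3-vector, m/s.
#' @param config a [simulation_config()] (supplies blood density).
#' @param props [microsphere_properties()].
#' @param mu local dynamic viscosity, Pa s.
#' @param gravity_local gravity in the branch-local frame, m/s^2.
#' @param radius vessel radius for the wall clamp, m (Inf to disable).
#' @return updated state list.
#' @export
step_particle <- function(state, dt, u_fluid, config, props, mu,
                          gravity_local = c(0, 0, 0), radius = Inf) {
  if (any(!is.finite(c(state$velocity, state$cross_position,
                       state$axial_position))))
    stop("non-finite particle state", call. = FALSE)
  tau <- props$density * props$diameter^2 / (18 * mu)
  b <- (1 - config$blood_density / props$density) * gravity_local
  v <- (state$velocity + dt * (u_fluid / tau + b)) / (1 + dt / tau)
  ax <- state$axial_position + v[1] * dt
  cp <- state$cross_position + v[2:3] * dt
  rmax <- radius - props$diameter / 2
  r <- sqrt(sum(cp^2))
  if (is.finite(rmax) && r > rmax) cp <- cp * (rmax / r)
  list(axial_position = ax, cross_position = cp, velocity = v)
}

#' Run the microsphere transport simulation
#'
#' Releases `n_particles` spheres per the injection schedule during the
#' first cardiac cycle and advances them through the network for
#' `config$n_cycles` cardiac cycles with time step `config$dt` (the
#' protocol: injection in cycle one, three more cycles so that most
#' spheres exit). Within a branch, spheres follow the local quasi-steady
#' Poiseuille velocity with Stokes drag, gravity and buoyancy (one-way
#' coupling); at a bifurcation the daughter is chosen by the
#' flux-partition rule of [bifurcation_assignment()], after which the
#' cross position is re-seeded flux-weighted in the daughter (the
#' "remixing" closure; see the package vignette). Spheres that exit an
#' outlet are frozen and tallied; spheres still in transit at the end are
#' counted as resident and excluded from the distribution numerator.
#'
#' @param tree an `arterial_tree`.
#' @param field `flow_field` from [solve_branch_flows()].
#' @param catheter a [catheter_placement()], or `NULL` with
#'   `flux_release = TRUE` to release spheres flux-weighted across the
#'   root inlet (the flow-split oracle configuration).
#' @param config a [simulation_config()].
#' @param props [microsphere_properties()].
#' @param n_particles number of spheres.
#' @param seed integer seed (overrides `config$seed`).
#' @param exit_threshold warn if the exit fraction falls below this
#'   (default 0.95).
#' @param flux_release release spheres flux-weighted at the root inlet
#'   with the local fluid velocity (neutral oracle mode).
#' @return object of class `transport_result`: `injected`, named
#'   per-outlet `exits`, `resident`, `exit_fraction`, `seed`.
#' @export
run_transport <- function(tree, field, catheter, config,
                          props = microsphere_properties(),
                          n_particles = 10000, seed = NULL,
                          exit_threshold = 0.95, flux_release = FALSE) {
  check_scalar(n_particles, "n_particles", min = 1, integer = TRUE)
  n_particles <- as.integer(n_particles)
  seed <- seed %||% config$seed
  nd <- tree$nodes
  nb <- nrow(nd)
  idx <- stats::setNames(seq_len(nb), nd$id)

  # per-branch geometry, gravity projections, daughter partition data
  Rv <- nd$radius_m; Lv <- nd$length_m
  dirm <- cbind(nd$dir_x, nd$dir_y, nd$dir_z)
  g <- config$gravity
  g_ax <- numeric(nb); g_c1 <- numeric(nb); g_c2 <- numeric(nb)
  d1i <- rep(NA_integer_, nb); d2i <- rep(NA_integer_, nb)
  dstar <- rep(NA_real_, nb); ax1 <- rep(NA_real_, nb); ax2 <- rep(NA_real_, nb)
  dts <- tree_daughters(tree)
  for (i in seq_len(nb)) {
    bb <- cross_basis(dirm[i, ])
    g_ax[i] <- sum(g * dirm[i, ]); g_c1[i] <- sum(g * bb$e1)
    g_c2[i] <- sum(g * bb$e2)
    kids <- dts[[nd$id[i]]]
    if (!is.null(kids) && length(kids) >= 1) {
      d1i[i] <- idx[[kids[1]]]
      if (length(kids) == 2) {
        d2i[i] <- idx[[kids[2]]]
        fr <- field$fractions[kids]
        f1 <- if (sum(fr) > 0) fr[1] / sum(fr) else 0.5
        dstar[i] <- partition_threshold(f1)
        a <- bifurcation_axis(dirm[i, ], dirm[d1i[i], ], dirm[d2i[i], ])
        ax1[i] <- a[1]; ax2[i] <- a[2]
      }
    }
  }
  frac <- field$fractions[nd$id]
  outlet_idx <- which(nd$is_outlet)

  with_seed(seed, {
    # initial particle state
    if (flux_release) {
      ri <- idx[[tree$root_id]]
      pos <- sample_flux_positions(n_particles, Rv[ri] - props$diameter / 2)
      branch <- rep(ri, n_particles)
      s <- rep(0, n_particles)
      cx <- pos[, 1]; cy <- pos[, 2]
      vax <- rep(0, n_particles)  # relaxes to local fluid in the first steps
      rel <- stats::runif(n_particles, 0, config$cardiac_period)
    } else {
      sched <- injection_schedule(n_particles, catheter, tree,
                                  config$cardiac_period, seed = NULL)
      branch <- rep(idx[[attr(sched, "vessel_id")]], n_particles)
      s <- sched$axial_m
      cx <- sched$cross_x_m; cy <- sched$cross_y_m
      vax <- sched$v_axial_m_s
      rel <- sched$release_time_s
    }
    vcx <- numeric(n_particles); vcy <- numeric(n_particles)
    status <- rep(0L, n_particles)        # 0 pending 1 transit 2 exited
    exit_at <- rep(NA_integer_, n_particles)

    visc <- config$viscosity
    beta <- 1 - config$blood_density / props$density
    n_steps <- ceiling(config$n_cycles * config$cardiac_period / config$dt)
    dt <- config$dt

    for (k in seq_len(n_steps)) {
      t <- (k - 1) * dt
      status[status == 0L & rel <= t] <- 1L
      act <- which(status == 1L)
      if (!length(act)) {
        if (!any(status == 0L)) break else next
      }
      bi <- branch[act]
      Qin <- inlet_waveform(t, field$mean_inlet_ml_min,
                            field$wave_params) * ML_MIN_TO_M3_S
      U <- Qin * frac[bi] / (pi * Rv[bi]^2)
      rr <- sqrt(cx[act]^2 + cy[act]^2)
      u_ax <- 2 * U * (1 - (rr / Rv[bi])^2)
      mu <- effective_viscosity(8 * abs(U) / (2 * Rv[bi]), visc)
      tau <- props$density * props$diameter^2 / (18 * mu)
      fdt <- dt / tau
      vax[act] <- (vax[act] + dt * (u_ax / tau + beta * g_ax[bi])) / (1 + fdt)
      vcx[act] <- (vcx[act] + dt * beta * g_c1[bi]) / (1 + fdt)
      vcy[act] <- (vcy[act] + dt * beta * g_c2[bi]) / (1 + fdt)
      s[act] <- s[act] + vax[act] * dt
      cx[act] <- cx[act] + vcx[act] * dt
      cy[act] <- cy[act] + vcy[act] * dt
      # wall clamp
      rmax <- Rv[bi] - props$diameter / 2
      rr <- sqrt(cx[act]^2 + cy[act]^2)
      ov <- rr > rmax
      if (any(ov)) {
        sc <- rmax[ov] / rr[ov]
        cx[act[ov]] <- cx[act[ov]] * sc
        cy[act[ov]] <- cy[act[ov]] * sc
      }
      # branch crossings (may cascade through short branches)
      repeat {
        cross <- act[status[act] == 1L & s[act] >= Lv[branch[act]]]
        if (!length(cross)) break
        for (grp in split(cross, branch[cross])) {
          b <- branch[grp[1]]
          if (nd$is_outlet[b]) {
            status[grp] <- 2L
            exit_at[grp] <- b
            next
          }
          over <- s[grp] - Lv[b]
          if (is.na(d2i[b])) {
            nb2 <- rep(d1i[b], length(grp))
          } else {
            xq <- (cx[grp] * ax1[b] + cy[grp] * ax2[b]) / Rv[b]
            nb2 <- ifelse(xq > dstar[b], d1i[b], d2i[b])
          }
          branch[grp] <- nb2
          s[grp] <- pmax(over, 0)
          # remix: re-seed flux-weighted in the daughter cross-section
          pos <- sample_flux_positions(length(grp), 1)
          rad <- Rv[nb2] - props$diameter / 2
          cx[grp] <- pos[, 1] * rad
          cy[grp] <- pos[, 2] * rad
          vcx[grp] <- 0; vcy[grp] <- 0
        }
      }
    }

    exited <- which(status == 2L)
    exits <- stats::setNames(integer(length(outlet_idx)),
                             nd$id[outlet_idx])
    if (length(exited)) {
      tb <- table(nd$id[exit_at[exited]])
      exits[names(tb)] <- as.integer(tb)
    }
    exits <- exits[sort(names(exits))]
    resident <- n_particles - sum(exits)
    ef <- sum(exits) / n_particles
    if (ef < exit_threshold)
      warning(sprintf("exit fraction %.3f below threshold %.2f",
                      ef, exit_threshold), call. = FALSE)
    structure(list(injected = n_particles, exits = exits,
                   resident = resident, exit_fraction = ef,
                   seed = seed,
                   n_cycles = config$n_cycles, dt = config$dt),
              class = "transport_result")
  })
}

#' @export
print.transport_result <- function(x, ...) {
  cat("transport_result:", x$injected, "spheres injected,",
      sum(x$exits), "exited (", format(100 * x$exit_fraction, digits = 4),
      "% ),", x$resident, "resident\n")
  invisible(x)
}

#' Write a transport result as JSON
#'
#' @param result a `transport_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_transport_json <- function(result, path) {
  jsonlite::write_json(
    list(injected = result$injected, exits = as.list(result$exits),
         resident = result$resident, exit_fraction = result$exit_fraction,
         seed = result$seed, n_cycles = result$n_cycles, dt = result$dt),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
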