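test_that("injection schedule: timing, centring, determinism, lumen check", {
  tr <- fixture_bifurcation_tree()
  cath <- catheter_placement("b", injection_velocity = 0.6)
  sch <- injection_schedule(1000, cath, tr, cardiac_period = 1, seed = 4)
  expect_identical(nrow(sch), 1000L)
  expect_true(all(sch$release_time_s >= 0 & sch$release_time_s < 1))
  expect_true(all(sch$v_axial_m_s == 0.6))
  # centred catheter: mean cross position -> 0 (SE of a disc ~ r/2/sqrt(n))
  expect_lt(abs(mean(sch$cross_x_m)), 3 * cath$catheter_inner_radius /
              2 / sqrt(1000))
  expect_lt(abs(mean(sch$cross_y_m)), 3 * cath$catheter_inner_radius /
              2 / sqrt(1000))
  # all starting points inside the catheter lumen around the tip centre
  expect_true(all(sqrt(sch$cross_x_m^2 + sch$cross_y_m^2) <=
                    cath$catheter_inner_radius + 1e-15))
  expect_identical(sch, injection_schedule(1000, cath, tr, 1, seed = 4))

  fat <- catheter_placement("b", catheter_inner_radius = 5e-3)
  expect_error(injection_schedule(10, fat, tr, 1, seed = 1),
               class = "resim_input_error")
})

test_that("particle step: equilibrium, Stokes settling, streamline following", {
  cfg <- simulation_config()
  props <- microsphere_properties()
  mu <- 0.0035

  # neutral buoyancy, v = u: exact equilibrium
  cfgN <- cfg; u <- c(0.2, 0.01, -0.02)
  st <- list(axial_position = 0, cross_position = c(0, 0), velocity = u)
  prN <- microsphere_properties(density = cfg$blood_density)
  st2 <- step_particle(st, 2e-3, u, cfgN, prN, mu,
                       gravity_local = c(3, -2, 9))
  expect_equal(st2$velocity, u, tolerance = 1e-12)

  # still fluid: terminal velocity within 0.1% of the Stokes closed form
  vt <- (props$density - cfg$blood_density) * 9.8 * props$diameter^2 /
    (18 * mu)
  st <- list(axial_position = 0, cross_position = c(0, 0),
             velocity = c(0, 0, 0))
  for (i in 1:200)
    st <- step_particle(st, 1e-4, c(0, 0, 0), cfg, props, mu,
                        gravity_local = c(9.8, 0, 0))
  expect_lt(abs(st$velocity[1] - vt), 1e-3 * vt)

  # axial flow, neutral buoyancy: cross position constant, axial = u dt
  st <- list(axial_position = 0, cross_position = c(1e-4, -2e-4),
             velocity = c(0.15, 0, 0))
  st3 <- step_particle(st, 2e-3, c(0.15, 0, 0), cfgN, prN, mu)
  expect_equal(st3$cross_position, st$cross_position)
  expect_equal(st3$axial_position, 0.15 * 2e-3, tolerance = 1e-12)

  st$velocity <- c(NaN, 0, 0)
  expect_error(step_particle(st, 2e-3, c(0, 0, 0), cfg, props, mu),
               "non-finite")
})

test_that("bifurcation assignment follows the flux partition rule", {
  dirs <- fixture_bifurcation_tree()$nodes
  dd <- as.matrix(dirs[2:3, c("dir_x", "dir_y", "dir_z")])
  R <- 2e-3

  # f1 = 1: everything to daughter 1
  pos <- with_fixed_seed(1, sample_flux_positions(500, R))
  expect_true(all(bifurcation_assignment(pos, R, dd, c(1, 0)) == 1L))

  # f1 = 0.5, symmetric daughters: split by the sign of the axis coordinate
  ch <- bifurcation_assignment(pos, R, dd, c(0.5, 0.5))
  # the projected separation axis is -e1, so daughter 1 collects the
  # negative-e1 half of the disc
  expect_true(all((ch == 1L) == (pos[, 1] < 0) | abs(pos[, 1]) < 1e-12))

  # Monte-Carlo: flux-weighted positions split in the flow fractions
  n <- 1e5
  pos <- with_fixed_seed(42, sample_flux_positions(n, R))
  for (f1 in c(0.2, 0.5, 0.8)) {
    got <- mean(bifurcation_assignment(pos, R, dd, c(f1, 1 - f1)) == 1L)
    expect_lt(abs(got - f1), 3 * sqrt(f1 * (1 - f1) / n))
  }

  expect_error(bifurcation_assignment(c(3e-3, 0), R, dd, c(0.5, 0.5)),
               class = "resim_input_error")
  expect_error(bifurcation_assignment(c(0, 0), R, dd, c(0.5, 0.4)),
               class = "resim_input_error")
  # degenerate (identical) daughter directions fall back with a warning
  expect_warning(
    bifurcation_assignment(c(1e-4, 0), R, dd[c(1, 1), ], c(0.5, 0.5)),
    "degenerate")
})

test_that("single-vessel domain sends every sphere to its outlet", {
  tr <- fixture_single_branch_tree()
  bcs <- bcs_from_fractions(tr, 1)
  fld <- solve_branch_flows(tr, bcs)
  cath <- catheter_placement("b", axial_fraction = 0.1)
  res <- run_transport(tr, fld, cath, fast_config(), n_particles = 500,
                       seed = 3)
  expect_identical(unname(res$exits["b"]), 500L)
  expect_identical(res$resident, 0L)
  expect_identical(res$exit_fraction, 1)
})

test_that("transport conserves particles and is deterministic", {
  tr <- generate_tree(4, 2e-3, asymmetry = 0.8, seed = 2)
  frs <- with_fixed_seed(2, { x <- stats::runif(8); x / sum(x) })
  fld <- solve_branch_flows(tr, bcs_from_fractions(tr, frs))
  cath <- catheter_placement(tr$root_id)
  r1 <- run_transport(tr, fld, cath, fast_config(), n_particles = 2000,
                      seed = 11)
  r2 <- run_transport(tr, fld, cath, fast_config(), n_particles = 2000,
                      seed = 11)
  expect_identical(r1$exits, r2$exits)
  expect_identical(sum(r1$exits) + r1$resident, r1$injected)
})

test_that("flow-split limit: neutral spheres, flux release match flow fractions", {
  n <- 1e4
  tr <- fixture_bifurcation_tree()
  for (f1 in c(0.35, 0.6)) {
    fld <- solve_branch_flows(tr, bcs_from_fractions(tr, c(f1, 1 - f1)))
    res <- run_transport(tr, fld, NULL, drain_config(),
                         props = neutral_props(), n_particles = n,
                         seed = 5, flux_release = TRUE)
    expect_gte(res$exit_fraction, 0.999)
    got <- res$exits[["b1"]] / sum(res$exits)
    expect_lt(abs(got - f1), 3 * sqrt(f1 * (1 - f1) / n))
  }
})

test_that("catheter radial offset shifts the split monotonically to the near daughter", {
  # symmetric bifurcation in the x-y plane; daughter-1 side of the
  # partition axis corresponds to azimuth = pi (see bifurcation geometry).
  # A wide release cloud (lumen 0.3 R) probes the partition without
  # saturating at the first offset step.
  tr <- fixture_bifurcation_tree()
  fld <- solve_branch_flows(tr, bcs_from_fractions(tr, c(0.5, 0.5)))
  n <- 1e4
  share <- vapply(c(0, 0.4, 0.8), function(off) {
    cath <- catheter_placement("b", radial_offset_fraction = off,
                               azimuth = pi, catheter_inner_radius = 6e-4)
    res <- run_transport(tr, fld, cath, drain_config(),
                         props = neutral_props(), n_particles = n, seed = 9)
    res$exits[["b1"]] / sum(res$exits)
  }, numeric(1))
  expect_true(all(diff(share) > 0))
  expect_gt(share[3] - share[1], 3 * sqrt(0.25 / n))
})

test_that("halving the time step leaves outlet fractions within binomial error", {
  tr <- generate_tree(3, 2e-3, asymmetry = 0.9, seed = 6)
  frs <- c(0.3, 0.3, 0.2, 0.2)
  fld <- solve_branch_flows(tr, bcs_from_fractions(tr, frs))
  n <- 1e4
  cfgA <- simulation_config(cardiac_period = 0.5, dt = 4e-3,
                            gravity = c(0, 0, -9.8))
  cfgB <- simulation_config(cardiac_period = 0.5, dt = 2e-3,
                            gravity = c(0, 0, -9.8))
  cath <- catheter_placement(tr$root_id)
  fa <- run_transport(tr, fld, cath, cfgA, n_particles = n, seed = 21)
  fb <- run_transport(tr, fld, cath, cfgB, n_particles = n, seed = 21)
  pa <- fa$exits / sum(fa$exits); pb <- fb$exits / sum(fb$exits)
  expect_true(all(abs(pa - pb) < 3 * sqrt(pmax(pa * (1 - pa), 0.01) / n)))
})

test_that("low exit fraction raises the protocol warning", {
  tr <- fixture_bifurcation_tree()
  fld <- solve_branch_flows(tr, bcs_from_fractions(tr, c(0.5, 0.5)))
  cath <- catheter_placement("b")
  # one short cycle at a tiny flow: most spheres cannot drain
  slow <- bcs_from_fractions(tr, c(0.5, 0.5), total_ml_min = 0.05)
  flds <- solve_branch_flows(tr, slow)
  cfg <- simulation_config(cardiac_period = 0.5, n_cycles = 1, dt = 4e-3)
  expect_warning(
    res <- run_transport(tr, flds, cath, cfg, n_particles = 200, seed = 2),
    "exit fraction")
  expect_identical(sum(res$exits) + res$resident, res$injected)
})

test_that("transport result JSON is written with counts and seed", {
  tr <- fixture_single_branch_tree()
  fld <- solve_branch_flows(tr, bcs_from_fractions(tr, 1))
  res <- run_transport(tr, fld, catheter_placement("b"), fast_config(),
                       n_particles = 50, seed = 1)
  f <- tempfile(fileext = ".json")
  write_transport_json(res, f)
  doc <- jsonlite::read_json(f)
  expect_identical(doc$injected, 50L)
  expect_identical(doc$seed, 1L)
  expect_identical(doc$exits$b, 50L)
})
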