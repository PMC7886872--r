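# Fixtures are built in code; no binary data.

# Minimal hand-built tree: root along +x with two daughters at +/- `angle`
# in the x-y plane (symmetric Murray radii so the validator passes).
fixture_bifurcation_tree <- function(root_radius = 2e-3, angle = 30,
                                     lambda = 8) {
  th <- angle * pi / 180
  rd <- root_radius * 2^(-1 / 3)
  nodes <- data.frame(
    id = c("b", "b1", "b2"),
    parent_id = c(NA, "b", "b"),
    length_m = lambda * c(root_radius, rd, rd),
    radius_m = c(root_radius, rd, rd),
    dir_x = c(1, cos(th), cos(th)),
    dir_y = c(0, sin(th), -sin(th)),
    dir_z = c(0, 0, 0),
    is_outlet = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, root_id = "b", outlet_ids = c("b1", "b2"),
                 murray_exponent = 3),
            class = "arterial_tree")
}

# Degenerate single-vessel tree (the root is the only outlet).
fixture_single_branch_tree <- function(radius = 2e-3, lambda = 8) {
  nodes <- data.frame(
    id = "b", parent_id = NA_character_,
    length_m = lambda * radius, radius_m = radius,
    dir_x = 1, dir_y = 0, dir_z = 0, is_outlet = TRUE,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, root_id = "b", outlet_ids = "b",
                 murray_exponent = 3),
            class = "arterial_tree")
}

# Outlet BC table with prescribed fractions (one pseudo-segment per outlet
# unless a segment map is given).
bcs_from_fractions <- function(tree, fractions, total_ml_min = 60,
                               segments = NULL) {
  outs <- tree$outlet_ids
  stopifnot(length(fractions) == length(outs),
            abs(sum(fractions) - 1) < 1e-12)
  data.frame(outlet_id = outs,
             segment = segments %||% paste0("S", seq_along(outs)),
             flow_ml_min = total_ml_min * fractions,
             flow_fraction = fractions,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mid-rank oracle: rank = (# smaller) + (1 + # equal) / 2,
# then the Pearson formula on the ranks (independent of the package path)
brute_midrank <- function(x)
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
brute_spearman <- function(a, b) {
  ra <- brute_midrank(a); rb <- brute_midrank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Short, fast transport configuration (protocol shape preserved: release
# over the first cycle + extra cycles to drain; scaled down for test time).
fast_config <- function(gravity = c(0, 0, -9.8), seed = NULL,
                        n_cycles = 4, cardiac_period = 0.5, dt = 4e-3) {
  simulation_config(cardiac_period = cardiac_period, n_cycles = n_cycles,
                    dt = dt, gravity = gravity, seed = seed)
}

neutral_props <- function() microsphere_properties(density = 1060)

# Long-drain configuration for the flow-split oracle tests: the split
# property is protocol-independent, but near-wall spheres crawl (Poiseuille
# velocity -> 0 at the wall), and residents correlate with low-flow
# outlets; extra cycles let essentially all spheres exit so the exit tally
# is an unbiased estimate of the split.
drain_config <- function(gravity = c(0, 0, 0), cardiac_period = 0.5,
                         dt = 4e-3, n_cycles = 24) {
  simulation_config(cardiac_period = cardiac_period, n_cycles = n_cycles,
                    dt = dt, gravity = gravity)
}

# transport_result stub for the activity-mapping unit tests
fake_result <- function(exits, resident = 0) {
  structure(list(injected = sum(exits) + resident,
                 exits = exits, resident = resident,
                 exit_fraction = sum(exits) / (sum(exits) + resident),
                 seed = NA), class = "transport_result")
}
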