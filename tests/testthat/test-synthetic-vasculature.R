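test_that("symmetric depth-2 tree obeys Murray's law exactly", {
  tr <- generate_tree(depth = 2, root_radius = 2e-3, asymmetry = 1, seed = 1)
  expect_length(tr$outlet_ids, 2L)
  rd <- tr$nodes$radius_m[tr$nodes$id != "b"]
  expect_equal(rd, rep(2e-3 * 2^(-1 / 3), 2), tolerance = 1e-12)
})

test_that("tree generation is deterministic under a fixed seed", {
  a <- generate_tree(4, 2e-3, seed = 7)
  b <- generate_tree(4, 2e-3, seed = 7)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_tree_json(a, f1); write_tree_json(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(
    generate_tree(4, 2e-3, seed = 8)$nodes$dir_y, a$nodes$dir_y))
})

test_that("generated trees satisfy all structural invariants", {
  for (seed in 1:10) {
    asym <- c(1, 0.7)[seed %% 2 + 1]
    tr <- generate_tree(depth = 4, root_radius = 1.5e-3,
                        asymmetry = asym, seed = seed)
    expect_true(validate_tree(tr))
    nd <- tr$nodes
    expect_length(tr$outlet_ids, 8L)
    # Murray residual at every bifurcation
    kids <- split(nd$radius_m, nd$parent_id)
    for (p in names(kids)) {
      rp <- nd$radius_m[nd$id == p]
      expect_lt(abs(rp^3 - sum(kids[[p]]^3)), 1e-6 * rp^3)
    }
    # radii decrease root-to-leaf along every path
    for (o in tr$outlet_ids) {
      node <- o
      while (!is.na(nd$parent_id[nd$id == node])) {
        p <- nd$parent_id[nd$id == node]
        expect_lt(nd$radius_m[nd$id == node], nd$radius_m[nd$id == p])
        node <- p
      }
    }
    # unit directions
    expect_equal(sqrt(nd$dir_x^2 + nd$dir_y^2 + nd$dir_z^2),
                 rep(1, nrow(nd)), tolerance = 1e-9)
  }
})

test_that("invalid tree arguments are rejected", {
  expect_error(generate_tree(1, 2e-3), class = "resim_input_error")
  expect_error(generate_tree(3, -1), class = "resim_input_error")
  expect_error(generate_tree(3, 2e-3, asymmetry = 0),
               class = "resim_input_error")
})

test_that("tree JSON round-trips exactly", {
  tr <- generate_tree(4, 2e-3, asymmetry = 0.8, seed = 11)
  f <- tempfile(fileext = ".json")
  write_tree_json(tr, f)
  tr2 <- read_tree_json(f)
  expect_equal(tr2$nodes, tr$nodes)
  expect_identical(tr2$outlet_ids, tr$outlet_ids)
  expect_identical(tr2$root_id, tr$root_id)
})

test_that("node positions chain parent end to daughter start", {
  tr <- fixture_bifurcation_tree()
  pos <- tree_node_positions(tr)
  expect_equal(pos["b", ], c(x = 0, y = 0, z = 0))
  expect_equal(unname(pos["b1", ]),
               c(tr$nodes$length_m[1], 0, 0))
  expect_identical(pos["b1", ], pos["b2", ])
})

test_that("liver phantom respects envelopes, determinism and degenerate n_tumors", {
  ph0 <- generate_liver_phantom(0, seed = 5)
  expect_true(all(ph0$segments$tumor_volume_ml == 0))
  expect_identical(nrow(ph0$tumors), 0L)

  a <- generate_liver_phantom(3, seed = 9)
  b <- generate_liver_phantom(3, seed = 9)
  expect_identical(a, b)

  # seed sweep: all drawn values inside the stated envelopes
  for (seed in 1:1000) {
    ph <- generate_liver_phantom(seed %% 4, seed = seed)
    expect_true(all(ph$segments$healthy_volume_ml >= 0 &
                      ph$segments$healthy_volume_ml <= 400))
    expect_true(all(ph$perfusion$k1_ml_min_ml >= 0.02 &
                      ph$perfusion$k1_ml_min_ml <= 0.12))
    if (nrow(ph$tumors)) {
      tot <- tapply(ph$tumors$volume_ml, ph$tumors$tumor_id, sum)
      expect_true(all(tot >= 0 & tot <= 70))
      expect_true(all(ph$tumors$k2_ml_min_ml >= 0.35 &
                        ph$tumors$k2_ml_min_ml <= 1.30))
      # per-tumor shares sum to the tumor volume
      expect_true(all(ph$tumors$volume_ml >= 0))
    }
    expect_identical(ph$segments$segment, paste0("S", 1:8))
  }
})

test_that("outlet-to-segment mapping is a seeded surjection", {
  ph <- generate_liver_phantom(1, seed = 2)
  tr8 <- generate_tree(4, 2e-3, seed = 3)   # 8 outlets
  m8 <- map_outlets_to_segments(tr8, ph$segments, seed = 1)
  expect_setequal(m8$outlet_id, tr8$outlet_ids)
  expect_setequal(m8$segment, ph$segments$segment)  # bijection at 8/8

  tr16 <- generate_tree(5, 2e-3, seed = 3)  # 16 outlets
  m16 <- map_outlets_to_segments(tr16, ph$segments, seed = 1)
  cnt <- table(m16$segment)
  expect_true(all(cnt >= 1))
  expect_identical(sum(cnt), 16L)
  expect_identical(m16, map_outlets_to_segments(tr16, ph$segments, seed = 1))

  # zero-volume segment may receive no outlets; positive ones all do
  segs <- ph$segments
  segs$healthy_volume_ml[1] <- 0
  segs$tumor_volume_ml[1] <- 0
  m <- map_outlets_to_segments(tr8, segs, seed = 4)
  expect_true(all(segs$segment[-1] %in% m$segment))

  tr2 <- generate_tree(2, 2e-3, seed = 1)
  expect_error(map_outlets_to_segments(tr2, ph$segments, seed = 1),
               class = "resim_input_error")
})

test_that("synthetic observation: identity at zero noise, clamped and renormalized", {
  truth <- setNames(c(40, 30, 20, 10), paste0("S", 1:4))
  expect_identical(as.numeric(synthesize_observed_distribution(truth, 0)),
                   as.numeric(truth))
  expect_error(synthesize_observed_distribution(truth, -1),
               class = "resim_input_error")

  spike <- setNames(c(100, rep(0, 7)), paste0("S", 1:8))
  for (seed in 1:20) {
    obs <- synthesize_observed_distribution(spike, 0.5, seed = seed)
    expect_true(all(obs >= 0))
    expect_equal(sum(obs), 100, tolerance = 1e-9)
  }
})

test_that("synthetic observation noise matches the folded-normal oracle", {
  # truth far from 0 so clamping is negligible; linearized post-
  # renormalization noise: d_i = e_i - (t_i/100) * sum(e), hence
  # sd_i = sd * sqrt((1 - t_i/100)^2 + (t_i/100)^2 (k-1)) and
  # E|d_i| = sd_i * sqrt(2/pi).
  k <- 8
  truth <- setNames(rep(100 / k, k), paste0("S", 1:k))
  sd0 <- 2
  reps <- 10000
  acc <- matrix(0, reps, k)
  for (r in seq_len(reps))
    acc[r, ] <- synthesize_observed_distribution(truth, sd0, seed = r) - truth
  sd_i <- sd0 * sqrt((1 - truth / 100)^2 + (truth / 100)^2 * (k - 1))
  expected <- sd_i * sqrt(2 / pi)
  got <- colMeans(abs(acc))
  # MC standard error ~ 0.011 pp per segment; 0.06 pp allows ~5 SE plus
  # the (small) linearization error
  expect_true(all(abs(got - expected) < 0.06))
})
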