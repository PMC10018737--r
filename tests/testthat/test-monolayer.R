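test_that("ligand counts follow the grafting density", {
  expect_equal(ligand_count(314.159, 0.3), 1047L)
  expect_equal(ligand_count(28.274, 0.3), 94L)
  expect_equal(ligand_count(50, 50), 1L)
  expect_equal(ligand_count(0.01, 10), 1L) # never below one ligand
  expect_error(ligand_count(314, 0.3, n_surface = 100), "1047.*100")
  expect_error(ligand_count(-1, 0.3), "positive")
})

test_that("two sites relax to an antipodal pair", {
  s <- optimize_virtual_sites(2, seed = 11)
  expect_equal(attr(s, "objective"), 2, tolerance = 0.01)
})

test_that("four sites relax to the regular tetrahedron", {
  s <- optimize_virtual_sites(4, seed = 5)
  expect_equal(attr(s, "objective"), 6 * sqrt(8 / 3), tolerance = 0.01)
})

test_that("a single site is a unit vector with zero objective", {
  s <- optimize_virtual_sites(1, seed = 1)
  expect_equal(sum(s^2), 1)
  expect_equal(attr(s, "objective"), 0)
  expect_error(optimize_virtual_sites(0), "positive")
})

test_that("the spherical constraint holds and the objective never degrades", {
  for (seed in 1:4) {
    n <- c(3, 7, 12, 25)[seed]
    s <- optimize_virtual_sites(n, seed = seed, budget = 300L * n)
    expect_true(all(abs(sqrt(rowSums(s^2)) - 1) < 1e-12))
    expect_gte(attr(s, "objective"), attr(s, "objective_initial"))
    # the reported objective is the actual sum of pairwise distances
    expect_equal(attr(s, "objective"), sum(stats::dist(s)), tolerance = 1e-9)
  }
})

test_that("site optimization is reproducible for a fixed seed", {
  a <- optimize_virtual_sites(10, seed = 42, budget = 2000L)
  b <- optimize_virtual_sites(10, seed = 42, budget = 2000L)
  expect_identical(a, b)
  c_ <- optimize_virtual_sites(10, seed = 43, budget = 2000L)
  expect_false(identical(a, c_))
})

test_that("a site aligned with a surface bead claims that bead", {
  core <- small_fcc_core()
  k <- core$surface_index[5]
  site <- matrix(core$positions[k, ] / sqrt(sum(core$positions[k, ]^2)), 1, 3)
  anchors <- map_anchors(site, core)
  expect_equal(anchors$anchor_indices, k)
})

test_that("colliding sites are exchanged for the nearest available bead", {
  core <- small_fcc_core()
  k <- core$surface_index[5]
  dir <- core$positions[k, ] / sqrt(sum(core$positions[k, ]^2))
  sites <- rbind(dir, dir) # both sites want the same bead
  anchors <- map_anchors(sites, core)
  expect_equal(anchors$n_lig, 2L)
  expect_false(anyDuplicated(anchors$anchor_indices) > 0)
  expect_true(k %in% anchors$anchor_indices)
})

test_that("as many sites as surface beads yields a bijection", {
  core <- small_fcc_core(radius = 1.0)
  n_surf <- length(core$surface_index)
  sites <- optimize_virtual_sites(n_surf, seed = 3, budget = 50L * n_surf)
  anchors <- map_anchors(sites, core)
  expect_setequal(anchors$anchor_indices, core$surface_index)
  expect_error(map_anchors(rbind(sites, c(1, 0, 0)), core), "cannot map")
})

test_that("homogeneous morphology labels every anchor alike", {
  core <- small_fcc_core()
  anchors <- map_anchors(optimize_virtual_sites(30, seed = 2, budget = 6000L),
                         core)
  lab <- label_morphology(anchors, morphology_spec("homogeneous"), core)
  expect_true(all(lab$labels == 1L))
})

test_that("random morphology draws an exact, seed-stable partition", {
  core <- small_fcc_core()
  anchors <- map_anchors(optimize_virtual_sites(100, seed = 2,
                                                budget = 10000L), core)
  a <- label_morphology(anchors, morphology_spec("random", ratio = 0.5,
                                                 seed = 9), core)
  expect_equal(sum(a$labels == 1L), 50L)
  b <- label_morphology(anchors, morphology_spec("random", ratio = 0.5,
                                                 seed = 9), core)
  expect_identical(a$labels, b$labels)
  c_ <- label_morphology(anchors, morphology_spec("random", ratio = 0.5,
                                                  seed = 10), core)
  expect_false(identical(a$labels, c_$labels))
  # exact counts for other ratios too
  d <- label_morphology(anchors, morphology_spec("random", ratio = 0.3,
                                                 seed = 1), core)
  expect_equal(sum(d$labels == 1L), 30L)
})

test_that("janus_z splits a symmetric sphere at the z = 0 plane", {
  core <- small_fcc_core()
  anchors <- map_anchors(optimize_virtual_sites(60, seed = 4,
                                                budget = 12000L), core)
  lab <- label_morphology(anchors, morphology_spec("janus_z", ratio = 0.5),
                          core)
  expect_equal(sum(lab$labels == 1L), 30L)
  z <- core$positions[lab$anchor_indices, 3]
  expect_lte(max(z[lab$labels == 1L]), min(z[lab$labels == 2L]) + 1e-9)
})

test_that("stripes alternate labels along the axis from the negative end", {
  core <- small_fcc_core()
  anchors <- map_anchors(optimize_virtual_sites(80, seed = 4,
                                                budget = 8000L), core)
  lab <- label_morphology(anchors,
                          morphology_spec("stripe_z", n_stripes = 4), core)
  z <- core$positions[lab$anchor_indices, 3]
  rng <- range(z)
  band <- pmin(floor((z - rng[1]) / (diff(rng) / 4)), 3)
  expect_equal(lab$labels, as.integer(band %% 2 + 1))
  expect_equal(lab$labels[which.min(z)], 1L)
  expect_error(morphology_spec("stripe_z", n_stripes = 1), "at least 2")
})
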