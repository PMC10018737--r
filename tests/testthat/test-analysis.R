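test_that("the cumulative RDF is the empirical CDF of bead distances", {
  g <- cumulative_rdf(5)
  expect_equal(g$G(4.999), 0)
  expect_equal(g$G(5), 1)
  g2 <- cumulative_rdf(1:100)
  for (r in c(1, 25, 50, 99, 100)) expect_equal(g2$G(r), r / 100)
  expect_error(cumulative_rdf(numeric(0)), "empty")
})

test_that("the cumulative RDF is a valid CDF for arbitrary samples", {
  for (seed in 1:3) {
    d <- with(list(), { set.seed(seed); stats::rlnorm(200) })
    g <- cumulative_rdf(d)
    r <- sort(unique(d))
    vals <- g$G(r)
    expect_true(all(diff(vals) >= 0))
    expect_equal(vals[length(vals)], 1)
    expect_equal(g$G(min(d) - 1), 0)
  }
})

test_that("thickness matches an independent percentile oracle", {
  set.seed(4)
  d <- stats::rgamma(5000, shape = 3, rate = 1.2)
  w <- monolayer_thickness(cumulative_rdf(d))
  # oracle: linear interpolation between order statistics, written out
  s <- sort(d)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  expect_equal(w, interp(0.95) - interp(0.05), tolerance = 1e-12)
})

test_that("degenerate and uniform distance samples behave as expected", {
  expect_warning(w0 <- monolayer_thickness(rep(2.5, 10)), "thickness is 0")
  expect_equal(w0, 0)
  set.seed(8)
  w <- monolayer_thickness(stats::runif(200000, 0, 10))
  expect_equal(w, 9.0, tolerance = 0.01)
})

test_that("thickness is invariant under rigid translation of the model", {
  np <- small_np(n_lig = 12)
  w1 <- monolayer_thickness(cumulative_rdf(np))
  shift <- c(3.2, -1.1, 0.7)
  np2 <- np
  np2$core$positions <- sweep(np2$core$positions, 2, shift, "+")
  np2$ligands <- lapply(np2$ligands, function(l) {
    l$coords <- sweep(l$coords, 2, shift, "+")
    l
  })
  w2 <- monolayer_thickness(cumulative_rdf(np2))
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("radially built monolayers tilt by exactly zero", {
  np <- small_np(n_lig = 16) # collinear ligands along the normals
  ta <- tilt_angles(np)
  expect_lt(ta$mean, 1e-6)
  expect_true(all(ta$per_ligand < 1e-6))
})

test_that("tangent-plane beads tilt by ninety degrees", {
  # hand-built frame: one core bead at origin plus an anchored ligand
  # whose bead lies perpendicular to the outward normal
  frame <- list(
    core_positions = rbind(c(0, 0, 0), c(1, 0, 0)),
    core_masses = c(1e6, 1), # center of mass pinned at the origin
    ligands = list(list(anchor = 2L, coords = rbind(c(1, 0.4, 0))))
  )
  series <- structure(list(frames = list(frame)), class = "frame_series")
  ta <- tilt_angles(series)
  expect_equal(ta$mean, 90, tolerance = 1e-4)
})

test_that("beads coincident with their anchor are skipped and counted", {
  frame <- list(
    core_positions = rbind(c(0, 0, 0), c(1, 0, 0)),
    core_masses = c(1e6, 1),
    ligands = list(list(anchor = 2L,
                        coords = rbind(c(1, 0, 0), c(1.5, 0, 0))))
  )
  series <- structure(list(frames = list(frame)), class = "frame_series")
  ta <- tilt_angles(series)
  expect_equal(ta$n_skipped, 1L)
  expect_equal(ta$mean, 0, tolerance = 1e-8)
})

test_that("radius of gyration reproduces closed-form cases", {
  expect_equal(radius_of_gyration(rbind(c(1, 2, 3))), 0)
  two <- rbind(c(0, 0, 0), c(0, 0, 2))
  expect_equal(radius_of_gyration(two), 1) # d/2 for equal masses
  sh <- build_shell(4, 0.1)
  expect_equal(radius_of_gyration(sh$positions), 4, tolerance = 0.01)
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "positive")
})

test_that("Rg of a solid fcc sphere approaches R sqrt(3/5)", {
  core <- build_core(lattice_spec("fcc", 0.17), shape_spec("sphere", 1.7))
  rg <- radius_of_gyration(core$positions)
  expect_equal(rg, 1.7 * sqrt(3 / 5), tolerance = 0.02)
})

test_that("bootstrap errors are seeded, zero for constants, and CLT-sized", {
  expect_equal(bootstrap_error(rep(3, 500)), 0)
  x <- with(list(), { set.seed(2); stats::rnorm(10000) })
  e1 <- bootstrap_error(x, seed = 5)
  e2 <- bootstrap_error(x, seed = 5)
  expect_identical(e1, e2)
  # 1% resamples of n = 1e4 have size 100: se of the mean ~ 1/sqrt(100)
  expect_equal(e1, 0.1, tolerance = 0.2)
  expect_error(bootstrap_error(numeric(0)), "empty")
})
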