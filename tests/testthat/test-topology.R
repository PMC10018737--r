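test_that("core mass equals density times analytic volume", {
  core <- build_core(lattice_spec("fcc", 0.17), shape_spec("sphere", 1.5))
  core <- assign_core_masses(core, 19.3)
  # oracle by dimensional analysis: g/cm^3 -> amu/nm^3 is N_A * 1e-24 * 1e3
  vol <- 4 / 3 * pi * 1.5^3
  expected <- 19.3 * vol * 6.02214076e23 * 1e-21
  expect_equal(sum(core$masses), expected, tolerance = 1e-9)
  expect_equal(expected, 1.643e5, tolerance = 1e-3) # a ~3 nm gold core
  expect_true(all(abs(core$masses - core$masses[1]) < 1e-12))
})

test_that("a one-bead core carries the whole mass", {
  lat <- lattice_spec("fcc", 0.17)
  blk <- build_lattice_block(lat, c(1.5, 1.5, 1.5))
  core <- sculpt_core(blk, shape_spec("sphere", 0.1), lat)
  core <- assign_core_masses(core, 10)
  expect_length(core$masses, 1L)
  expect_equal(core$masses,
               10 * shape_geometry(core$shape)$volume * 602.214076)
  expect_error(assign_core_masses(core, -1), "positive")
})

test_that("interior lattice beads receive the full coordination of bonds", {
  r <- 0.2
  expected <- c(primitive = 6, bcc = 8, fcc = 12, hcp = 12)
  for (motif in names(expected)) {
    core <- build_core(lattice_spec(motif, r), shape_spec("sphere", 1.6))
    net <- build_elastic_network(core, 32500)
    # every unordered pair appears exactly once
    expect_false(anyDuplicated(net[, c("i", "j")]) > 0)
    expect_true(all(net$i < net$j))
    incid <- tabulate(c(net$i, net$j), nbins = nrow(core$positions))
    interior <- interior_of_sphere(core, 1.6, 3 * r)
    expect_true(all(incid[interior] == expected[[motif]]),
                label = sprintf("%s interior bond count", motif))
    expect_equal(net$length, rep(2 * r, nrow(net)), tolerance = 1e-9)
    expect_true(all(net$k == 32500))
  }
})

test_that("shell beads are braced to six neighbors and their antipode", {
  sh <- build_shell(2.5, 0.17)
  net <- build_elastic_network(sh, 5000)
  pos <- sh$positions
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  bonded <- lapply(seq_len(n), function(i) {
    c(net$j[net$i == i], net$i[net$j == i])
  })
  anti_d <- as.matrix(stats::dist(rbind(pos, -pos)))[1:n, (n + 1):(2 * n)]
  diag(anti_d) <- Inf
  for (i in seq_len(n)) {
    nn6 <- order(d[i, ])[1:6]
    expect_true(all(nn6 %in% bonded[[i]]))
    expect_true(which.min(anti_d[i, ]) %in% bonded[[i]])
  }
  expect_error(build_elastic_network(sh, -1), "positive")
})

test_that("a three-bead ligand yields 3 bonds, 2 angles, 1 dihedral per copy", {
  fx <- write_fixture_itp(3, dihedrals = data.frame(phi0 = 180, k = 2,
                                                    mult = 1))
  params <- parse_itp(fx$path)
  np <- small_np(n_lig = 10, params = params)
  doc <- assign_ligand_topology(np, params, bulk_density = 19.3)
  expect_equal(nrow(doc$bonds), 10 * 3)
  expect_equal(nrow(doc$angles), 10 * 2)
  expect_equal(nrow(doc$dihedrals), 10 * 1)
  expect_equal(unname(doc$n_enumerated),
               unname(doc$n_assigned + doc$n_skipped))
  expect_equal(nrow(doc$report), 0L)
})

test_that("every ligand copy of a homogeneous monolayer gets identical terms", {
  fx <- write_fixture_itp(3)
  params <- parse_itp(fx$path)
  np <- small_np(n_lig = 6, params = params)
  doc <- assign_ligand_topology(np, params, bulk_density = 19.3)
  per_copy <- split(doc$bonds[, c("length", "k")],
                    rep(seq_len(6), each = 3))
  for (k in 2:6) {
    expect_equal(per_copy[[k]], per_copy[[1]], ignore_attr = TRUE)
  }
})

test_that("stacked dihedral entries emit one term per entry", {
  fx <- write_fixture_itp(4, dihedrals = data.frame(phi0 = c(180, 0),
                                                    k = c(1.96, 0.18),
                                                    mult = c(1, 3)))
  params <- parse_itp(fx$path)
  np <- small_np(n_lig = 5, ligand_beads = 4, params = params)
  doc <- assign_ligand_topology(np, params, bulk_density = 19.3)
  # per copy: quadruplets anchor-1-2-3, 1-2-3-4 -> 2 tuples x 2 entries
  expect_equal(nrow(doc$dihedrals), 5 * 2 * 2)
  expect_equal(unname(doc$n_assigned["dihedral"]), 5 * 2)
})

test_that("missing parameters are skipped and itemized, never fatal", {
  np <- small_np(n_lig = 8)
  doc <- assign_ligand_topology(np, cgnano:::empty_bonded_params(),
                                bulk_density = 19.3)
  expect_null(doc$bonds)
  expect_null(doc$angles)
  expect_gt(nrow(doc$elastic), 0)
  expect_equal(sum(doc$n_assigned), 0L)
  expect_equal(nrow(doc$report), sum(doc$n_enumerated))
  expect_equal(unname(doc$n_enumerated),
               unname(doc$n_assigned + doc$n_skipped))
})

test_that("topology indices stay within the bead count and cores are neutral", {
  fx <- write_fixture_itp(3)
  params <- parse_itp(fx$path)
  np <- small_np(n_lig = 10, params = params)
  doc <- assign_ligand_topology(np, params, bulk_density = 19.3)
  n_atoms <- nrow(doc$atoms)
  idx <- c(doc$bonds$i, doc$bonds$j, doc$angles$i, doc$angles$j,
           doc$angles$k, doc$dihedrals$i, doc$dihedrals$j, doc$dihedrals$k,
           doc$dihedrals$l, doc$elastic$i, doc$elastic$j)
  expect_true(all(idx >= 1 & idx <= n_atoms))
  core_rows <- doc$atoms$resname == "CORE"
  expect_true(all(doc$atoms$charge[core_rows] == 0))
  expect_true(all(doc$atoms$mass > 0))
  # ligand masses and charges come straight from the template
  lig_rows <- !core_rows
  expect_true(all(doc$atoms$mass[lig_rows] == 72))
})
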