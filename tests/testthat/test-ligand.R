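test_that("two beads sit at the equilibrium bond length", {
  fx <- write_fixture_itp(2, l0 = 0.35)
  params <- parse_itp(fx$path)
  lig <- build_ligand(fx$template, params)
  expect_equal(sqrt(sum((lig$coords[2, ] - lig$coords[1, ])^2)), 0.35,
               tolerance = 1e-9)
})

test_that("straight equilibrium angles give a collinear chain", {
  fx <- write_fixture_itp(3, theta0 = 180)
  lig <- build_ligand(fx$template, parse_itp(fx$path))
  v1 <- lig$coords[2, ] - lig$coords[1, ]
  v2 <- lig$coords[3, ] - lig$coords[2, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  expect_lt(ang, 1e-6)
})

test_that("without parameters the chain is collinear at the default spacing", {
  fx <- make_ligand_fixture(4)
  lig <- build_ligand(fx$template)
  d <- diff(lig$coords[, 1])
  expect_equal(d, rep(0.35, 3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(lig$coords[, 2], rep(0, 4), ignore_attr = TRUE)
  expect_equal(lig$coords[, 3], rep(0, 4), ignore_attr = TRUE)
})

test_that("built geometry reproduces the equilibrium bonds and angles", {
  fx <- write_fixture_itp(5, l0 = 0.42, theta0 = 130)
  params <- parse_itp(fx$path)
  lig <- build_ligand(fx$template, params)
  for (i in 1:4) {
    expect_equal(sqrt(sum((lig$coords[i + 1, ] - lig$coords[i, ])^2)), 0.42,
                 tolerance = 1e-9)
  }
  for (i in 2:4) {
    a <- lig$coords[i - 1, ] - lig$coords[i, ]
    b <- lig$coords[i + 1, ] - lig$coords[i, ]
    ang <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
    expect_equal(ang, 130, tolerance = 1e-6)
  }
  # trans torsions keep the chain maximally extended: strictly
  # monotone progress along the principal axis
  expect_true(all(diff(lig$coords[, 1]) > 0))
})

test_that("missing bond entries fall back to defaults and are reported", {
  fx <- write_fixture_itp(3, bead_type = "P4")
  params <- parse_itp(fx$path)
  tpl <- ligand_template(c("A", "B", "C"), c("QX", "QX", "QX"), rep(60, 3))
  lig <- build_ligand(tpl, params)
  expect_equal(sqrt(sum((lig$coords[2, ] - lig$coords[1, ])^2)), 0.35,
               tolerance = 1e-9)
  expect_true(any(grepl("no bond parameters", lig$report)))
})

test_that("ligand templates validate connectivity and attachment", {
  expect_error(ligand_template("A", "C1", numeric(0)), "length")
  expect_error(
    ligand_template(c("A", "B", "C"), rep("C1", 3), rep(72, 3),
                    bonds = rbind(c(1, 2))),
    "connected"
  )
  expect_error(ligand_template("A", "C1", -5), "positive")
})

test_that("grafted ligands align PC1 with the anchor normal", {
  np <- small_np(n_lig = 12)
  for (k in seq_along(np$ligands)) {
    lg <- np$ligands[[k]]
    nrm <- np$anchors$normals[k, ]
    centered <- sweep(lg$coords, 2, colMeans(lg$coords), "-")
    pc1 <- svd(centered, nu = 0, nv = 1)$v[, 1]
    ang <- acos(min(1, abs(sum(pc1 * nrm))))
    expect_lt(ang, 1e-6)
  }
})

test_that("exactly 20 clash-relief rotations are evaluated and the best kept", {
  np <- small_np(n_lig = 15)
  for (lg in np$ligands) {
    expect_length(lg$rotation_scores, 20L)
    expect_equal(lg$rotation_scores[lg$chosen], max(lg$rotation_scores))
  }
})

test_that("grafting is a rigid motion: copies are congruent to the template", {
  fx <- write_fixture_itp(5, theta0 = 140)
  params <- parse_itp(fx$path)
  core <- small_fcc_core()
  sites <- optimize_virtual_sites(10, seed = 3, budget = 4000L)
  anchors <- label_morphology(map_anchors(sites, core),
                              morphology_spec("homogeneous"), core)
  lig <- build_ligand(fx$template, params)
  np <- graft_ligands(core, anchors, lig, params = params)
  ref <- as.matrix(stats::dist(lig$coords))
  for (lg in np$ligands) {
    expect_equal(as.matrix(stats::dist(lg$coords)), ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("the attachment bead sits one anchor-bond length along the normal", {
  np <- small_np(n_lig = 8)
  for (k in seq_along(np$ligands)) {
    lg <- np$ligands[[k]]
    anchor_pos <- np$core$positions[lg$anchor, ]
    offset <- lg$coords[1, ] - anchor_pos
    expect_equal(sqrt(sum(offset^2)), np$anchor_bond_lengths[lg$label],
                 tolerance = 1e-9)
    nrm <- np$anchors$normals[k, ]
    expect_equal(sum(offset * nrm), sqrt(sum(offset^2)), tolerance = 1e-9)
  }
})

test_that("mixed monolayers place the ligand matching each anchor label", {
  core <- small_fcc_core()
  sites <- optimize_virtual_sites(20, seed = 5, budget = 4000L)
  anchors <- label_morphology(map_anchors(sites, core),
                              morphology_spec("random", ratio = 0.5, seed = 2),
                              core)
  lig1 <- build_ligand(make_ligand_fixture(2)$template)
  lig5 <- build_ligand(make_ligand_fixture(5)$template)
  np <- graft_ligands(core, anchors, list(lig1, lig5))
  sizes <- vapply(np$ligands, function(l) nrow(l$coords), numeric(1))
  expect_equal(sizes, ifelse(anchors$labels == 1L, 2, 5), ignore_attr = TRUE)
})
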