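# Shared builders for small test systems. Everything is generated in
# code; nothing is read from disk except files the tests write first.

# small fcc sphere with surface info (about 500 beads)
small_fcc_core <- function(radius = 1.5, bead_radius = 0.17) {
  identify_surface(build_core(
    lattice_spec("fcc", bead_radius),
    shape_spec("sphere", radius)
  ))
}

# a fully assembled small particle with collinear 3-bead ligands
small_np <- function(n_lig = 20, ligand_beads = 3, params = NULL,
                     seed = 7, core = small_fcc_core()) {
  fx <- make_ligand_fixture(ligand_beads)
  sites <- optimize_virtual_sites(n_lig, seed = seed, budget = 400L * n_lig)
  anchors <- map_anchors(sites, core)
  anchors <- label_morphology(anchors, morphology_spec("homogeneous"), core)
  lig <- build_ligand(fx$template, params = params)
  graft_ligands(core, anchors, lig, params = params)
}

# brute-force neighbor count within cutoff, independent of the package's
# offset-matching scheme
brute_neighbor_counts <- function(pos, cutoff) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  rowSums(d <= cutoff)
}

# interior beads = beads farther than `shrink` from the boundary of a
# sphere of radius R (for coordination checks)
interior_of_sphere <- function(core, R, shrink) {
  which(sqrt(rowSums(core$positions^2)) < R - shrink)
}

write_fixture_itp <- function(..., dir = tempdir()) {
  path <- tempfile(fileext = ".itp", tmpdir = dir)
  fx <- make_ligand_fixture(..., path = path)
  fx$path <- path
  fx
}
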