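#' Build a complete monolayer-protected nanoparticle model
#'
#' Runs the full construction pipeline: lattice block generation and
#' sculpting (or shell placement), surface detection, ligand-count from
#' the grafting density, anchor selection by constrained distance
#' maximization, morphology labeling, in-site ligand construction,
#' grafting, mass assignment and topology assembly.
#'
#' @param lattice A [lattice_spec()] (ignored for `shape = "shell"`,
#'   where only its `bead_radius` is used).
#' @param shape A [shape_spec()].
#' @param ligands One or two [ligand_template()]s (two for mixed
#'   monolayers).
#' @param grafting_density Surface area per ligand (nm^2).
#' @param morphology A [morphology_spec()].
#' @param params Optional `bonded_params` from [parse_itp()].
#' @param bulk_density Core material bulk density (g cm^-3).
#' @param k_elastic Elastic-network force constant (kJ mol^-1 nm^-2).
#' @param core_type Force-field type of the core beads.
#' @param seed Seed for the virtual-site optimizer.
#' @param budget Optimizer proposal budget (default `2000 * N_lig`).
#' @return A list with the assembled `model` (`np_model`) and its
#'   `topology` (`topology_doc`).
#' @examples
#' \donttest{
#' fx <- make_ligand_fixture(3)
#' np <- build_nanoparticle(
#'   lattice = lattice_spec("fcc", 0.17),
#'   shape = shape_spec("sphere", 1.5),
#'   ligands = fx$template,
#'   grafting_density = 0.6,
#'   morphology = morphology_spec("homogeneous"),
#'   bulk_density = 19.3
#' )
#' np$model
#' }
#' @export
build_nanoparticle <- function(lattice, shape, ligands, grafting_density,
                               morphology = morphology_spec("homogeneous"),
                               params = NULL, bulk_density = 19.3,
                               k_elastic = 32500, core_type = "C1",
                               seed = 1L, budget = NULL) {
  stopifnot(inherits(shape, "shape_spec"))
  if (inherits(ligands, "ligand_template")) ligands <- list(ligands)
  if (shape$shape == "shell") {
    core <- build_shell(shape$dimensions[1], lattice$bead_radius)
  } else {
    core <- identify_surface(build_core(lattice, shape))
  }
  core <- assign_core_masses(core, bulk_density)
  geom <- shape_geometry(shape)
  n_lig <- ligand_count(geom$area, grafting_density,
                        n_surface = length(core$surface_index))
  if (is.null(budget)) budget <- 2000L * n_lig
  sites <- optimize_virtual_sites(n_lig, seed = seed, budget = budget)
  anchors <- map_anchors(sites, core)
  anchors <- label_morphology(anchors, morphology, core)
  built <- lapply(ligands, build_ligand, params = params)
  model <- graft_ligands(core, anchors, built, params = params,
                         core_type = core_type)
  topology <- assign_ligand_topology(
    model, params = if (is.null(params)) empty_bonded_params() else params,
    k_elastic = k_elastic
  )
  list(model = model, topology = topology)
}

# An empty parameter set: every bonded tuple will be skipped and
# itemized, leaving a topology with the elastic network only.
empty_bonded_params <- function() {
  structure(
    list(
      bonds = data.frame(type1 = character(0), type2 = character(0),
                         func = integer(0), length = numeric(0),
                         k = numeric(0)),
      angles = data.frame(type1 = character(0), type2 = character(0),
                          type3 = character(0), func = integer(0),
                          angle = numeric(0), k = numeric(0)),
      dihedrals = data.frame(type1 = character(0), type2 = character(0),
                             type3 = character(0), type4 = character(0),
                             func = integer(0), phi0 = numeric(0),
                             k = numeric(0), mult = integer(0)),
      source = NULL
    ),
    class = "bonded_params"
  )
}

#' Build a nanoparticle from a YAML configuration file
#'
#' Reads a declarative build description and runs
#' [build_nanoparticle()]. Recognized keys: `lattice`, `bead_radius`,
#' `shape`, `dimensions`, `grafting_density`, `morphology` (`kind`,
#' `ratio`, `n_stripes`, `seed`), `ligands` (a list of bead tables with
#' `names`, `types`, `masses`, `charges`), `itp` (path to a bonded
#' parameter file), `bulk_density`, `k_elastic`, `core_type`, `seed`.
#'
#' @param path Path to the YAML file.
#' @return As [build_nanoparticle()].
#' @export
build_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop(sprintf("config key '%s' is required", key))
    cfg[[key]]
  }
  lattice <- lattice_spec(
    if (is.null(cfg$lattice)) "fcc" else cfg$lattice,
    need("bead_radius")
  )
  shape <- shape_spec(need("shape"), unlist(need("dimensions")))
  morph <- cfg$morphology
  morphology <- if (is.null(morph)) morphology_spec("homogeneous") else {
    morphology_spec(
      morph$kind %||% "homogeneous",
      ratio = morph$ratio %||% 0.5,
      n_stripes = morph$n_stripes %||% 4L,
      seed = morph$seed %||% 1L
    )
  }
  ligands <- lapply(need("ligands"), function(lg) {
    ligand_template(
      names = unlist(lg$names), types = unlist(lg$types),
      masses = unlist(lg$masses),
      charges = if (is.null(lg$charges)) NULL else unlist(lg$charges)
    )
  })
  params <- if (!is.null(cfg$itp)) parse_itp(cfg$itp) else NULL
  build_nanoparticle(
    lattice = lattice, shape = shape, ligands = ligands,
    grafting_density = need("grafting_density"),
    morphology = morphology, params = params,
    bulk_density = cfg$bulk_density %||% 19.3,
    k_elastic = cfg$k_elastic %||% 32500,
    core_type = cfg$core_type %||% "C1",
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
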