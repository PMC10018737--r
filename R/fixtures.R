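#' Generate a toy ligand and matching parameter file
#'
#' Produces a linear `n_beads` chain plus the .itp text that
#' parametrizes it, for tests and examples that need a self-consistent
#' ligand without external input. The defaults mirror a coarse alkyl
#' chain under a 4-to-1 mapping (apolar beads, 0.47 nm bonds, straight
#' equilibrium angles), so `n_beads` of 1, 2, 3 and 5 stand for thiols
#' of 4, 8, 13 and 20 carbons whose sulfur is absorbed into the anchor.
#'
#' @param n_beads Number of beads (>= 1).
#' @param bead_type Force-field type string shared by the beads.
#' @param mass Per-bead mass (amu).
#' @param charge Per-bead charge (e).
#' @param l0 Equilibrium bond length (nm).
#' @param theta0 Equilibrium bending angle (degrees).
#' @param k_bond,k_angle Force constants for the emitted entries.
#' @param dihedrals Optional data frame with columns `phi0`, `k`,
#'   `mult`; each row becomes a dihedral entry for the homogeneous
#'   quadruplet, so several rows exercise stacked periodic terms.
#' @param path If non-`NULL`, the .itp text is written here.
#' @return A list with the `ligand_template`, the `itp` text lines and
#'   `path` (or `NULL`).
#' @examples
#' fx <- make_ligand_fixture(3)
#' fx$template
#' @export
make_ligand_fixture <- function(n_beads, bead_type = "C1", mass = 72,
                                charge = 0, l0 = 0.47, theta0 = 180,
                                k_bond = 1250, k_angle = 25,
                                dihedrals = NULL, path = NULL) {
  if (!is.numeric(n_beads) || n_beads < 1) {
    stop("'n_beads' must be a positive integer")
  }
  n_beads <- as.integer(n_beads)
  template <- ligand_template(
    names = sprintf("%s%d", substr(bead_type, 1, 3), seq_len(n_beads)),
    types = rep(bead_type, n_beads),
    masses = rep(mass, n_beads),
    charges = rep(charge, n_beads)
  )
  itp <- c(
    "; toy ligand bonded parameters",
    "[ bondtypes ]",
    "; i  j  func  b0  kb"
  )
  if (n_beads >= 1) {
    # the anchor-attachment bond uses the same homotypic entry
    itp <- c(itp, sprintf("%s  %s  1  %g  %g", bead_type, bead_type,
                          l0, k_bond))
  }
  if (n_beads >= 3) {
    itp <- c(
      itp, "",
      "[ angletypes ]",
      "; i  j  k  func  theta0  k",
      sprintf("%s  %s  %s  2  %g  %g", bead_type, bead_type, bead_type,
              theta0, k_angle)
    )
  }
  if (!is.null(dihedrals)) {
    itp <- c(
      itp, "",
      "[ dihedraltypes ]",
      "; i  j  k  l  func  phi0  k  mult",
      sprintf("%s  %s  %s  %s  1  %g  %g  %d",
              bead_type, bead_type, bead_type, bead_type,
              dihedrals$phi0, dihedrals$k, as.integer(dihedrals$mult))
    )
  }
  if (!is.null(path)) writeLines(itp, path)
  list(template = template, itp = itp, path = path)
}

#' Jitter the monolayer of a model into a synthetic frame series
#'
#' Adds seeded isotropic Gaussian noise to the ligand beads of an
#' assembled model, frame by frame, while keeping the core fixed — the
#' simplest stand-in for the thermal motion of a monolayer over a rigid
#' elastically networked core. With `amplitude = 0` every frame
#' reproduces the input exactly.
#'
#' @param model An `np_model`.
#' @param amplitude Standard deviation of the per-coordinate noise (nm).
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; the series is bit-reproducible for a fixed
#'   seed.
#' @return An object of class `frame_series` consumable by
#'   [tilt_angles()] and friends.
#' @export
make_jittered_series <- function(model, amplitude, n_frames = 10L,
                                 seed = 1L) {
  stopifnot(inherits(model, "np_model"))
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  base <- model_frame(model)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      fr <- base
      fr$ligands <- lapply(fr$ligands, function(l) {
        noise <- matrix(stats::rnorm(length(l$coords), sd = amplitude),
                        nrow = nrow(l$coords))
        l$coords <- l$coords + noise
        l
      })
      fr
    })
  })
  structure(list(frames = frames), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf(
    "<frame_series> %d frame(s), %d core beads, %d ligands\n",
    length(x$frames), nrow(x$frames[[1]]$core_positions),
    length(x$frames[[1]]$ligands)
  ))
  invisible(x)
}
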