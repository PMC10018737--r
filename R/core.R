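new_core_model <- function(positions, bead_radius, lattice, shape,
                           masses = NULL, surface_index = NULL,
                           normals = NULL, notes = character()) {
  structure(
    list(
      positions = positions, bead_radius = bead_radius,
      lattice = lattice, shape = shape, masses = masses,
      surface_index = surface_index, normals = normals, notes = notes
    ),
    class = "core_model"
  )
}

#' @export
print.core_model <- function(x, ...) {
  lat <- if (is.null(x$lattice)) "shell (no lattice)" else x$lattice$motif
  cat(sprintf(
    "<core_model> %s %s, %d beads (radius %.4g nm)%s\n",
    lat, x$shape$shape, nrow(x$positions), x$bead_radius,
    if (!is.null(x$surface_index)) {
      sprintf(", %d surface beads", length(x$surface_index))
    } else ""
  ))
  for (n in x$notes) cat(" note:", n, "\n")
  invisible(x)
}

#' Sculpt a lattice block into a core shape
#'
#' Keeps exactly the beads whose centers pass the analytic inside-test of
#' `shape` (boundary inclusive). The shape is centered at the origin;
#' cylinder, rod and pyramid axes run along Z. Sculpting is deterministic
#' and idempotent: re-sculpting a sculpted core with the same shape
#' returns the identical bead set.
#'
#' @param block Bead position matrix from [build_lattice_block()], or a
#'   `core_model` to re-sculpt.
#' @param shape A [shape_spec()].
#' @param lattice The [lattice_spec()] the block was generated from
#'   (taken from `block` when re-sculpting a `core_model`).
#' @return A `core_model` with the retained bead positions.
#' @examples
#' lat <- lattice_spec("fcc", 0.17)
#' blk <- build_lattice_block(lat, c(4, 4, 4))
#' core <- sculpt_core(blk, shape_spec("sphere", 1.5), lat)
#' @export
sculpt_core <- function(block, shape, lattice = NULL) {
  stopifnot(inherits(shape, "shape_spec"))
  resculpt <- inherits(block, "core_model")
  if (resculpt) {
    if (is.null(lattice)) lattice <- block$lattice
    block <- block$positions
  }
  if (!is.matrix(block) || ncol(block) != 3) {
    stop("'block' must be an n x 3 position matrix or a core_model")
  }
  if (shape$shape == "shell") {
    stop("hollow shells are built directly with build_shell(), not sculpted")
  }
  bbox <- shape_bounding_box(shape)
  span <- apply(block, 2, function(v) diff(range(v)))
  # the outermost lattice points can sit up to one cell short of the box
  # edge, so only reject blocks that are clearly undersized; a re-sculpt
  # of an existing core is exempt (its beads already all lie inside)
  slack <- if (!is.null(lattice)) max(lattice$cell) else 0.05 * max(bbox)
  if (!resculpt && nrow(block) > 1 && any(span < bbox - slack - 1e-9)) {
    stop("the lattice block does not circumscribe the requested shape")
  }
  keep <- shape_inside(shape, block)
  if (!any(keep)) {
    stop("no lattice bead falls inside the requested shape; increase its size")
  }
  pos <- block[keep, , drop = FALSE]
  pos <- pos[order(pos[, 3], pos[, 2], pos[, 1]), , drop = FALSE]
  r <- if (!is.null(lattice)) lattice$bead_radius else NA_real_
  new_core_model(pos, r, lattice, shape)
}

#' Build a sculpted core in one step
#'
#' Convenience wrapper: generates a lattice block with a one-cell margin
#' beyond the shape's bounding box and sculpts it.
#'
#' @inheritParams sculpt_core
#' @param lattice A [lattice_spec()].
#' @return A `core_model`.
#' @examples
#' core <- build_core(lattice_spec("fcc", 0.17), shape_spec("sphere", 1.5))
#' @export
build_core <- function(lattice, shape) {
  stopifnot(inherits(lattice, "lattice_spec"), inherits(shape, "shape_spec"))
  extents <- shape_bounding_box(shape) + 2 * lattice$cell
  block <- build_lattice_block(lattice, extents)
  sculpt_core(block, shape, lattice)
}

#' Build a hollow spherical shell core
#'
#' Places beads quasi-uniformly on a sphere with a deterministic
#' golden-angle (Fibonacci) spiral. No crystal lattice is involved. The
#' bead count comes from an area budget: each bead claims the footprint
#' of a disc of the bead radius, which makes the mean nearest-neighbor
#' spacing approximately two bead radii.
#'
#' The budget uses the golden-angle spiral's own packing efficiency
#' (0.715, measured on the spiral itself) rather than the ideal hexagonal
#' value, because the spiral is quasi- rather than perfectly regular.
#'
#' @param radius Shell radius (nm).
#' @param bead_radius Bead radius (nm), smaller than `radius`.
#' @return A `core_model` whose `lattice` is `NULL`; every bead is a
#'   surface bead with an outward radial normal.
#' @examples
#' sh <- build_shell(3, 0.17)
#' range(sqrt(rowSums(sh$positions^2))) # all beads on the 3 nm sphere
#' @export
build_shell <- function(radius, bead_radius) {
  stopifnot(is.numeric(radius), is.numeric(bead_radius))
  if (radius <= bead_radius) stop("shell radius must exceed the bead radius")
  # area budget: N beads of footprint pi r^2 at the spiral's measured
  # packing efficiency eta cover 4 pi R^2, i.e. N = 4 eta R^2 / r^2
  eta <- 0.715
  n <- round(4 * eta * radius^2 / bead_radius^2)
  if (n < 4) {
    stop(sprintf(
      "shell of radius %g nm holds only %d bead(s) of radius %g nm; at least 4 are required",
      radius, n, bead_radius
    ))
  }
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) # golden angle
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- phi * i
  dirs <- cbind(x = rho * cos(theta), y = rho * sin(theta), z = z)
  core <- new_core_model(radius * dirs, bead_radius, NULL,
                         shape_spec("shell", radius))
  core$surface_index <- seq_len(n)
  core$normals <- dirs
  core
}

#' Identify surface beads and their outward normals
#'
#' A bead is superficial when it has fewer nearest neighbors (beads two
#' bead radii away, within a tolerance of `1e-3 * bead_radius`) than the
#' bulk coordination number of the lattice (6 primitive, 8 bcc, 12 fcc,
#' 12 hcp). The normal stored for each surface bead is the unit vector
#' from the core's center of mass to the bead — exact for spheres and a
#' documented approximation on flat facets of the other convex shapes.
#'
#' @param core A lattice-based `core_model` (shells from [build_shell()]
#'   already carry their surface set and radial normals).
#' @return The `core_model` with `surface_index` and `normals` filled in.
#' @examples
#' core <- identify_surface(build_core(lattice_spec("fcc", 0.17),
#'                                     shape_spec("sphere", 1.2)))
#' length(core$surface_index)
#' @export
identify_surface <- function(core) {
  stopifnot(inherits(core, "core_model"))
  if (is.null(core$lattice)) {
    stop("surface detection by coordination requires a lattice-based core")
  }
  n <- nrow(core$positions)
  if (n == 1) {
    core$surface_index <- 1L
    core$normals <- matrix(c(0, 0, 1), 1, 3,
                           dimnames = list(NULL, c("x", "y", "z")))
    core$notes <- c(core$notes,
                    "single-bead core: surface normal is arbitrary (+Z)")
    return(core)
  }
  counts <- coordination_counts(core)
  surf <- which(counts < core$lattice$coordination)
  com <- colMeans(core$positions)
  vec <- sweep(core$positions[surf, , drop = FALSE], 2, com, "-")
  nrm <- row_norms(vec)
  if (any(nrm == 0)) {
    # a surface bead exactly at the center of mass cannot happen for the
    # supported convex shapes unless the core is degenerate (e.g. planar)
    vec[nrm == 0, ] <- rep(c(0, 0, 1), each = sum(nrm == 0))
    nrm[nrm == 0] <- 1
  }
  core$surface_index <- surf
  core$normals <- vec / nrm
  core
}

# Nearest-neighbor count per bead, by exact offset matching on the lattice:
# each bead's candidate neighbor positions are bead + offset for the known
# nearest-neighbor offset vectors, checked by hashed position lookup.
# O(N x coordination), exact on ideal lattices.
coordination_counts <- function(core) {
  pos <- core$positions
  lat <- core$lattice
  offs <- lattice_neighbor_offsets(lat)
  delta <- lat$cell[1] / 100 # key bin, well under the finest coordinate gap
  key_of <- function(m) {
    paste(round(m[, 1] / delta), round(m[, 2] / delta), round(m[, 3] / delta),
          sep = ",")
  }
  keys <- key_of(pos)
  counts <- integer(nrow(pos))
  for (k in seq_len(nrow(offs))) {
    shifted <- sweep(pos, 2, offs[k, ], "+")
    counts <- counts + !is.na(match(key_of(shifted), keys))
  }
  counts
}

# Unique nearest-neighbor pairs (i < j) of a lattice core, by the same
# offset-matching scheme as coordination_counts().
lattice_bond_pairs <- function(core) {
  pos <- core$positions
  lat <- core$lattice
  offs <- lattice_neighbor_offsets(lat)
  delta <- lat$cell[1] / 100
  key_of <- function(m) {
    paste(round(m[, 1] / delta), round(m[, 2] / delta), round(m[, 3] / delta),
          sep = ",")
  }
  keys <- key_of(pos)
  ii <- list(); jj <- list()
  for (k in seq_len(nrow(offs))) {
    shifted <- sweep(pos, 2, offs[k, ], "+")
    m <- match(key_of(shifted), keys)
    hit <- which(!is.na(m))
    ii[[k]] <- hit
    jj[[k]] <- m[hit]
  }
  i <- unlist(ii, use.names = FALSE)
  j <- unlist(jj, use.names = FALSE)
  keep <- i < j # each unordered pair appears once from each side
  cbind(i = i[keep], j = j[keep])
}
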