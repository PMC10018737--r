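#' Crystal lattice specification
#'
#' Declares the crystal motif and bead radius used to generate core beads.
#' Lattice constants follow the touching-sphere convention: nearest
#' neighbors sit exactly two bead radii apart, so
#' \eqn{a = 2r} (primitive), \eqn{a = 4r/\sqrt{3}} (bcc),
#' \eqn{a = 2\sqrt{2}\,r} (fcc) and \eqn{a = 2r}, \eqn{c = 2r\sqrt{8/3}}
#' (hcp, ideal axial ratio).
#'
#' @param motif One of `"primitive"`, `"bcc"`, `"fcc"`, `"hcp"`.
#' @param bead_radius Bead radius in nm, strictly positive.
#'
#' @return An object of class `lattice_spec` with elements `motif`,
#'   `bead_radius`, the conventional-cell edge lengths `cell` (nm), the
#'   fractional `basis` of the cell and the bulk `coordination` number.
#' @examples
#' lattice_spec("fcc", 0.17)
#' @export
lattice_spec <- function(motif = c("primitive", "bcc", "fcc", "hcp"),
                         bead_radius) {
  motif <- match.arg(motif)
  stopifnot(is.numeric(bead_radius), length(bead_radius) == 1)
  if (!is.finite(bead_radius) || bead_radius <= 0) {
    stop("'bead_radius' must be a positive length in nm")
  }
  r <- bead_radius
  geom <- switch(motif,
    primitive = list(
      cell = c(2 * r, 2 * r, 2 * r),
      basis = rbind(c(0, 0, 0)),
      coordination = 6L
    ),
    bcc = list(
      cell = rep(4 * r / sqrt(3), 3),
      basis = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
      coordination = 8L
    ),
    fcc = list(
      cell = rep(2 * sqrt(2) * r, 3),
      basis = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)),
      coordination = 12L
    ),
    hcp = {
      a <- 2 * r
      c_ <- 2 * r * sqrt(8 / 3)
      # orthorhombic conventional cell (a, sqrt(3) a, c) holding both
      # close-packed layers: A sites at z = 0, B sites at z = c/2
      list(
        cell = c(a, sqrt(3) * a, c_),
        basis = rbind(
          c(0, 0, 0), c(0.5, 0.5, 0),
          c(0.5, 1 / 6, 0.5), c(0, 2 / 3, 0.5)
        ),
        coordination = 12L
      )
    }
  )
  structure(
    list(
      motif = motif, bead_radius = bead_radius,
      cell = geom$cell, basis = geom$basis,
      coordination = geom$coordination
    ),
    class = "lattice_spec"
  )
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "<lattice_spec> %s, bead radius %.4g nm, cell %s nm, coordination %d\n",
    x$motif, x$bead_radius,
    paste(sprintf("%.4g", x$cell), collapse = " x "),
    x$coordination
  ))
  invisible(x)
}

#' Replicate a unit cell into a rectangular block of beads
#'
#' Tiles the conventional cell of `lattice` symmetrically about the origin
#' and keeps every lattice point whose coordinates fall inside the block
#' `[-Lx/2, Lx/2] x [-Ly/2, Ly/2] x [-Lz/2, Lz/2]` (boundary inclusive).
#' The origin is always a lattice point, so a shape centered at the origin
#' always captures the central bead.
#'
#' @param lattice A [lattice_spec()].
#' @param extents Numeric length-3 vector of block edge lengths (nm).
#' @return A numeric matrix with one bead position (nm) per row.
#' @examples
#' blk <- build_lattice_block(lattice_spec("primitive", 0.17), c(1, 1, 1))
#' nrow(blk) # 3^3 grid points fit in a 1 nm cube with a = 0.34 nm
#' @export
build_lattice_block <- function(lattice, extents) {
  stopifnot(inherits(lattice, "lattice_spec"))
  extents <- as.numeric(extents)
  if (length(extents) == 1) extents <- rep(extents, 3)
  if (length(extents) != 3) stop("'extents' must give three edge lengths")
  for (ax in 1:3) {
    if (!is.finite(extents[ax]) || extents[ax] <= 0) {
      stop(sprintf(
        "block extent along %s must be positive (got %g)",
        c("x", "y", "z")[ax], extents[ax]
      ))
    }
  }
  cell <- lattice$cell
  # symmetric index range; +1 cell margin so boundary points are never lost
  nrep <- ceiling(extents / (2 * cell)) + 1L
  grid <- as.matrix(expand.grid(
    x = seq.int(-nrep[1], nrep[1]),
    y = seq.int(-nrep[2], nrep[2]),
    z = seq.int(-nrep[3], nrep[3])
  ))
  origins <- sweep(grid, 2, cell, "*")
  basis_cart <- sweep(lattice$basis, 2, cell, "*")
  pos <- do.call(rbind, lapply(seq_len(nrow(basis_cart)), function(b) {
    sweep(origins, 2, basis_cart[b, ], "+")
  }))
  tol <- 1e-9 + 1e-9 * max(cell)
  half <- extents / 2
  keep <- abs(pos[, 1]) <= half[1] + tol &
    abs(pos[, 2]) <= half[2] + tol &
    abs(pos[, 3]) <= half[3] + tol
  out <- pos[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

# Nearest-neighbor offset vectors of the lattice, computed numerically from
# a reference block (for hcp this is the union over the two sublattices, so
# some offsets are void for a given bead; void offsets simply fail to match).
lattice_neighbor_offsets <- function(lattice) {
  blk <- build_lattice_block(lattice, 4.2 * lattice$cell)
  d_nn <- 2 * lattice$bead_radius
  tol <- 1e-3 * lattice$bead_radius
  # reference beads: the basis sites of the central cell
  refs <- sweep(lattice$basis, 2, lattice$cell, "*")
  offs <- list()
  for (b in seq_len(nrow(refs))) {
    d <- sweep(blk, 2, refs[b, ], "-")
    dist <- row_norms(d)
    offs[[b]] <- d[abs(dist - d_nn) < tol, , drop = FALSE]
  }
  offs <- do.call(rbind, offs)
  unique(round(offs / (tol / 10)) * (tol / 10))
}
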