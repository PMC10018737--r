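#' Target core shape specification
#'
#' Describes the analytic solid a lattice block is sculpted into. All
#' shapes are centered at the origin; cylinder, rod and pyramid axes run
#' along Z. Dimension meaning per shape (all nm):
#' \describe{
#'   \item{sphere, shell}{`radius`}
#'   \item{octahedron}{`edge` (regular octahedron edge length)}
#'   \item{cylinder}{`radius`, `length`}
#'   \item{rod}{`radius`, `length` — a cylinder with hemispherical caps;
#'     `length` is the total tip-to-tip length, so `length >= 2 * radius`}
#'   \item{pyramid}{`base`, `height` (right square pyramid)}
#'   \item{ellipsoid}{three semiaxes `a`, `b`, `c`}
#'   \item{rectangular_prism}{three edge lengths}
#' }
#'
#' @param shape Shape name (see above).
#' @param dimensions Numeric vector of shape dimensions; its length must
#'   match the shape's arity (1, 1, 1, 2, 2, 2, 3, 3 in the order listed).
#' @return An object of class `shape_spec`.
#' @examples
#' shape_spec("sphere", 5)
#' shape_spec("rod", c(1, 6))
#' @export
shape_spec <- function(shape = c("sphere", "shell", "octahedron", "cylinder",
                                 "rod", "pyramid", "ellipsoid",
                                 "rectangular_prism"),
                       dimensions) {
  shape <- match.arg(shape)
  dimensions <- as.numeric(dimensions)
  arity <- c(
    sphere = 1L, shell = 1L, octahedron = 1L, cylinder = 2L,
    rod = 2L, pyramid = 2L, ellipsoid = 3L, rectangular_prism = 3L
  )[[shape]]
  if (length(dimensions) != arity) {
    stop(sprintf(
      "shape '%s' takes %d dimension(s), got %d",
      shape, arity, length(dimensions)
    ))
  }
  if (any(!is.finite(dimensions)) || any(dimensions <= 0)) {
    stop("all shape dimensions must be strictly positive lengths in nm")
  }
  if (shape == "rod" && dimensions[2] < 2 * dimensions[1]) {
    stop("a rod's total length must be at least twice its radius")
  }
  structure(list(shape = shape, dimensions = dimensions),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf(
    "<shape_spec> %s (%s nm)\n", x$shape,
    paste(sprintf("%.4g", x$dimensions), collapse = ", ")
  ))
  invisible(x)
}

# Axis-aligned bounding box edge lengths of the analytic shape.
shape_bounding_box <- function(spec) {
  d <- spec$dimensions
  switch(spec$shape,
    sphere = ,
    shell = rep(2 * d[1], 3),
    octahedron = rep(sqrt(2) * d[1], 3),
    cylinder = ,
    rod = c(2 * d[1], 2 * d[1], d[2]),
    pyramid = c(d[1], d[1], d[2]),
    ellipsoid = 2 * d,
    rectangular_prism = d
  )
}

# Logical inside-test (boundary inclusive, tolerance `tol` nm) for bead
# centers in the analytic shape.
shape_inside <- function(spec, pos, tol = 1e-9) {
  d <- spec$dimensions
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  switch(spec$shape,
    sphere = ,
    shell = x^2 + y^2 + z^2 <= (d[1] + tol)^2,
    octahedron = {
      # regular octahedron, vertices on the axes at distance edge/sqrt(2)
      abs(x) + abs(y) + abs(z) <= d[1] / sqrt(2) + tol
    },
    cylinder = x^2 + y^2 <= (d[1] + tol)^2 & abs(z) <= d[2] / 2 + tol,
    rod = {
      half_cyl <- d[2] / 2 - d[1] # cylindrical section half-length
      in_cyl <- x^2 + y^2 <= (d[1] + tol)^2 & abs(z) <= half_cyl + tol
      zc <- pmax(abs(z) - half_cyl, 0)
      in_cap <- x^2 + y^2 + zc^2 <= (d[1] + tol)^2
      in_cyl | in_cap
    },
    pyramid = {
      # base at z = -height/2, apex at z = +height/2
      frac <- 1 - (z + d[2] / 2) / d[2] # half-width fraction, 1 at base
      abs(z) <= d[2] / 2 + tol &
        abs(x) <= frac * d[1] / 2 + tol &
        abs(y) <= frac * d[1] / 2 + tol
    },
    ellipsoid = {
      (x / (d[1] + tol))^2 + (y / (d[2] + tol))^2 + (z / (d[3] + tol))^2 <= 1
    },
    rectangular_prism = {
      abs(x) <= d[1] / 2 + tol & abs(y) <= d[2] / 2 + tol &
        abs(z) <= d[3] / 2 + tol
    }
  )
}

#' Closed-form surface area and volume of a core shape
#'
#' Returns the analytic surface area (nm^2) and volume (nm^3) of the
#' shape. Both feed downstream steps: the grafting density converts the
#' area into a ligand count, and the bulk density converts the volume
#' into the total core mass. For a hollow shell the enclosed sphere is
#' used, so a shell weighs the same as the solid particle it stands in
#' for. The ellipsoid area uses the Thomsen approximation
#' (p = 1.6075, relative error below 1.1%); all other formulas are exact.
#'
#' @param spec A [shape_spec()].
#' @return A list with elements `area` (nm^2) and `volume` (nm^3).
#' @examples
#' shape_geometry(shape_spec("sphere", 5))$area # pi * 10^2
#' @export
shape_geometry <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  d <- spec$dimensions
  out <- switch(spec$shape,
    sphere = ,
    shell = list(area = 4 * pi * d[1]^2, volume = 4 / 3 * pi * d[1]^3),
    octahedron = list(
      area = 2 * sqrt(3) * d[1]^2,
      volume = sqrt(2) / 3 * d[1]^3
    ),
    cylinder = list(
      area = 2 * pi * d[1]^2 + 2 * pi * d[1] * d[2],
      volume = pi * d[1]^2 * d[2]
    ),
    rod = {
      lc <- d[2] - 2 * d[1] # cylindrical section length
      list(
        area = 2 * pi * d[1] * lc + 4 * pi * d[1]^2,
        volume = pi * d[1]^2 * lc + 4 / 3 * pi * d[1]^3
      )
    },
    pyramid = list(
      area = d[1]^2 + 2 * d[1] * sqrt(d[2]^2 + d[1]^2 / 4),
      volume = d[1]^2 * d[2] / 3
    ),
    ellipsoid = {
      p <- 1.6075
      list(
        area = 4 * pi * ((d[1]^p * d[2]^p + d[1]^p * d[3]^p +
                            d[2]^p * d[3]^p) / 3)^(1 / p),
        volume = 4 / 3 * pi * prod(d)
      )
    },
    rectangular_prism = list(
      area = 2 * (d[1] * d[2] + d[2] * d[3] + d[1] * d[3]),
      volume = prod(d)
    )
  )
  out
}
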