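#' Normalized cumulative radial distribution of the monolayer
#'
#' The cumulative radial distribution
#' \eqn{G_{mono}(r) = N_{mono}^{-1} \sum_i H(r - r_i)} counts the
#' fraction of monolayer beads within distance `r` of the particle's
#' center of mass — the empirical CDF of the bead distances, normalized
#' to 1 at long distances.
#'
#' @param distances Distances (nm) of the monolayer beads from the
#'   center of mass, or an `np_model` (in which case
#'   [monolayer_distances()] supplies them).
#' @param ... Passed on to [monolayer_distances()] for model input.
#' @return An object of class `cumulative_rdf`: a list with the sorted
#'   `distances` and the step function `G` (from [stats::ecdf()]).
#' @examples
#' g <- cumulative_rdf(c(1, 2, 3, 4))
#' g$G(2.5) # 0.5
#' @export
cumulative_rdf <- function(distances, ...) {
  if (inherits(distances, "np_model")) {
    distances <- monolayer_distances(distances, ...)
  }
  distances <- as.numeric(distances)
  if (length(distances) == 0) {
    stop("the monolayer is empty; no distances to accumulate")
  }
  structure(
    list(distances = sort(distances), G = stats::ecdf(distances)),
    class = "cumulative_rdf"
  )
}

#' @export
print.cumulative_rdf <- function(x, ...) {
  cat(sprintf(
    "<cumulative_rdf> %d beads, distances %.3g-%.3g nm\n",
    length(x$distances), min(x$distances), max(x$distances)
  ))
  invisible(x)
}

#' Distances of monolayer beads from the particle center of mass
#'
#' The center of mass is mass-weighted over the core beads only by
#' default (the core dominates the particle's mass); set
#' `include_ligands = TRUE` to weigh ligand beads in as well.
#'
#' @param model An `np_model` whose core carries masses (see
#'   [assign_core_masses()]).
#' @param include_ligands Include ligand beads in the center of mass.
#' @param terminal_only Use only the last bead of each ligand (the
#'   chain tip) instead of all monolayer beads.
#' @return Numeric vector of distances (nm).
#' @export
monolayer_distances <- function(model, include_ligands = FALSE,
                                terminal_only = FALSE) {
  stopifnot(inherits(model, "np_model"))
  if (length(model$ligands) == 0) stop("the model has no grafted ligands")
  lig_pos <- do.call(rbind, lapply(model$ligands, function(l) {
    if (terminal_only) l$coords[nrow(l$coords), , drop = FALSE] else l$coords
  }))
  com <- particle_com(model, include_ligands = include_ligands)
  row_norms(sweep(lig_pos, 2, com, "-"))
}

particle_com <- function(model, include_ligands = FALSE) {
  core <- model$core
  m <- core$masses
  if (is.null(m)) m <- rep(1, nrow(core$positions))
  pos <- core$positions
  if (include_ligands) {
    for (l in model$ligands) {
      tpl <- model$templates[[l$label]]$template
      pos <- rbind(pos, l$coords)
      m <- c(m, tpl$masses)
    }
  }
  colSums(pos * m) / sum(m)
}

#' Monolayer thickness from the cumulative radial distribution
#'
#' The thickness is the width of the radial band holding the monolayer
#' with 90% probability: `r_max - r_min` with
#' \eqn{G_{mono}(r_{min}) = 0.05} and \eqn{G_{mono}(r_{max}) = 0.95}.
#' The two radii are located by linear interpolation between order
#' statistics of the distance sample.
#'
#' @param g A `cumulative_rdf`, or anything [cumulative_rdf()] accepts.
#' @param probs The two limiting probabilities.
#' @return Thickness (nm), always >= 0. A sample with fewer than two
#'   distinct distances yields 0 with a warning.
#' @export
monolayer_thickness <- function(g, probs = c(0.05, 0.95)) {
  if (!inherits(g, "cumulative_rdf")) g <- cumulative_rdf(g)
  d <- g$distances
  if (length(unique(d)) < 2) {
    warning("fewer than two distinct distances; thickness is 0")
    return(0)
  }
  q <- stats::quantile(d, probs = probs, names = FALSE, type = 7)
  unname(q[2] - q[1])
}

#' Ligand tilt angles relative to the local surface normal
#'
#' For every ligand bead, the tilt is the angle between the vector from
#' the ligand's anchor bead to that bead and the outward normal of the
#' core at the anchor. Averaging follows the hierarchy: beads within a
#' ligand, then ligands within the particle, then frames. For
#' trajectory input the anchor normals are recomputed per frame from
#' the instantaneous core center of mass.
#'
#' @param x An `np_model`, or a coordinate frame series from
#'   [make_jittered_series()].
#' @return A list with `mean` (degrees), `per_ligand` (first frame),
#'   `per_frame` (frame means), and `n_skipped` (beads coincident with
#'   their anchor, which carry no direction).
#' @export
tilt_angles <- function(x) {
  frames <- if (inherits(x, "np_model")) list(model_frame(x)) else {
    stopifnot(inherits(x, "frame_series"))
    x$frames
  }
  n_skipped <- 0L
  per_frame <- numeric(length(frames))
  per_ligand_first <- NULL
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    core_com <- colSums(fr$core_positions * fr$core_masses) /
      sum(fr$core_masses)
    lig_means <- vapply(fr$ligands, function(l) {
      anchor_pos <- fr$core_positions[l$anchor, ]
      normal <- anchor_pos - core_com
      nn <- vec_norm(normal)
      if (nn == 0) return(NA_real_)
      normal <- normal / nn
      vecs <- sweep(l$coords, 2, anchor_pos, "-")
      lens <- row_norms(vecs)
      ok <- lens > 1e-12
      n_skipped <<- n_skipped + sum(!ok)
      if (!any(ok)) return(NA_real_)
      cosang <- (vecs[ok, , drop = FALSE] %*% normal) / lens[ok]
      cosang <- pmin(1, pmax(-1, cosang))
      mean(acos(cosang)) * 180 / pi
    }, numeric(1))
    if (f == 1L) per_ligand_first <- lig_means
    per_frame[f] <- mean(lig_means, na.rm = TRUE)
  }
  list(
    mean = mean(per_frame),
    per_ligand = per_ligand_first,
    per_frame = per_frame,
    n_skipped = n_skipped
  )
}

# Collapse an np_model into a single analysis frame.
model_frame <- function(model) {
  masses <- model$core$masses
  if (is.null(masses)) masses <- rep(1, nrow(model$core$positions))
  list(
    core_positions = model$core$positions,
    core_masses = masses,
    ligands = lapply(model$ligands, function(l) {
      list(anchor = l$anchor, coords = l$coords)
    })
  )
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i \|x_i - x_{com}\|^2 / \sum_i m_i}} over
#' all beads of the particle (core and monolayer). Scales linearly with
#' the hydrodynamic radius for globular bodies, which makes it a proxy
#' for sizes measured by light scattering.
#'
#' @param x An `np_model`, or a position matrix.
#' @param masses Bead masses when `x` is a matrix (defaults to equal
#'   masses).
#' @return Radius of gyration (nm).
#' @export
radius_of_gyration <- function(x, masses = NULL) {
  if (inherits(x, "np_model")) {
    pos <- model_positions(x)
    masses <- x$core$masses
    if (is.null(masses)) stop("assign core masses before computing Rg")
    for (l in x$ligands) {
      masses <- c(masses, x$templates[[l$label]]$template$masses)
    }
  } else {
    pos <- x
    if (is.null(masses)) masses <- rep(1, nrow(pos))
  }
  if (sum(masses) <= 0) stop("total mass must be positive")
  com <- colSums(pos * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(pos, 2, com, "-")^2)) / sum(masses))
}

#' Bootstrap standard error of a sample mean
#'
#' Resamples the data with replacement at a fixed fraction of the
#' original size and reports the standard deviation of the resampled
#' means. The defaults (1,000 iterations, 1% sample size) match common
#' practice for error bars on long, autocorrelated simulation series,
#' where small resamples temper the correlation between draws.
#'
#' @param x Numeric sample (at least 100 values so a 1% resample is
#'   non-empty).
#' @param iterations Number of bootstrap draws.
#' @param fraction Resample size as a fraction of `length(x)`.
#' @param seed Integer seed.
#' @return The bootstrap standard error (same units as `x`).
#' @export
bootstrap_error <- function(x, iterations = 1000L, fraction = 0.01,
                            seed = 1L) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("cannot bootstrap an empty sample")
  m <- max(1L, as.integer(round(fraction * length(x))))
  with_seed(seed, {
    means <- vapply(seq_len(iterations), function(i) {
      mean(x[sample.int(length(x), m, replace = TRUE)])
    }, numeric(1))
    stats::sd(means)
  })
}
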