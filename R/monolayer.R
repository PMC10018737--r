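#' Number of ligands from grafting density
#'
#' Converts the core's surface area and a grafting density ("ligand
#' footprint", nm^2 per ligand) into the number of ligands to graft.
#'
#' @param area Core surface area (nm^2).
#' @param grafting_density Surface area per ligand (nm^2).
#' @param n_surface Optional number of available surface beads; when
#'   given, a ligand count exceeding it is an error.
#' @return Integer ligand count, at least 1.
#' @examples
#' ligand_count(4 * pi * 5^2, 0.3) # 10 nm sphere at 0.3 nm^2 per thiol
#' @export
ligand_count <- function(area, grafting_density, n_surface = NULL) {
  stopifnot(is.numeric(area), is.numeric(grafting_density))
  if (area <= 0 || grafting_density <= 0) {
    stop("'area' and 'grafting_density' must be positive")
  }
  n <- max(1L, as.integer(round(area / grafting_density)))
  if (!is.null(n_surface) && n > n_surface) {
    stop(sprintf(
      "grafting density requests %d ligands but the core exposes only %d surface beads",
      n, n_surface
    ))
  }
  n
}

#' Spread points on the unit sphere by constrained distance maximization
#'
#' Places `n` virtual sites uniformly at random on the unit sphere and
#' then maximizes the sum of pairwise Euclidean distances
#' \eqn{D_u = \sum_{i<j} \|x_i - x_j\|} with a Metropolis–Hastings walk
#' constrained to the sphere: each proposal perturbs one site in its
#' tangent plane (Gaussian, `sigma` radians) and renormalizes it to unit
#' length, so the constraint holds exactly after every move. Uphill moves
#' are always accepted; downhill moves are accepted with Boltzmann
#' probability under an effective temperature annealed linearly to zero
#' over the budget. The best configuration seen is returned, so the
#' final objective never falls below the initial one.
#'
#' @param n Number of sites (>= 1).
#' @param seed Integer seed; fixed seeds give reproducible layouts.
#' @param budget Total number of proposals (default `2000 * n`).
#' @param sigma Tangent-step size in radians.
#' @return Matrix of `n` unit row vectors with attributes
#'   `objective_initial` and `objective` (initial and final \eqn{D_u}).
#' @examples
#' s <- optimize_virtual_sites(4, seed = 1)
#' attr(s, "objective") # close to the tetrahedral optimum 6 * sqrt(8/3)
#' @export
optimize_virtual_sites <- function(n, seed = 1L, budget = 2000L * n,
                                   sigma = 0.1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("'n' must be a positive integer number of sites")
  }
  n <- as.integer(n)
  if (n == 1) {
    x <- with_seed(seed, unit_rows(matrix(stats::rnorm(3), 1, 3)))
    colnames(x) <- c("x", "y", "z")
    attr(x, "objective_initial") <- 0
    attr(x, "objective") <- 0
    return(x)
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(3 * n), n, 3)
    x <- unit_rows(x)
    colnames(x) <- c("x", "y", "z")
    # per-site sums of distances to all others; D_u = sum(site_sum) / 2
    dmat <- as.matrix(stats::dist(x))
    site_sum <- unname(colSums(dmat))
    d_u <- sum(site_sum) / 2
    d_init <- d_u
    best <- x
    best_d <- d_u
    t0 <- 0.05 * sqrt(n) # energy scale of a sigma-sized move
    for (it in seq_len(budget)) {
      i <- sample.int(n, 1)
      xi <- x[i, ]
      step <- stats::rnorm(3, sd = sigma)
      step <- step - sum(step * xi) * xi # tangent-plane component
      prop <- xi + step
      prop <- prop / vec_norm(prop)
      d_new <- sqrt(colSums((t(x) - prop)^2))
      d_new[i] <- 0
      delta <- sum(d_new) - site_sum[i]
      temp <- t0 * (1 - it / budget)
      if (delta >= 0 ||
          (temp > 0 && stats::runif(1) < exp(delta / temp))) {
        d_old <- sqrt(colSums((t(x) - xi)^2))
        d_old[i] <- 0
        x[i, ] <- prop
        site_sum <- site_sum - d_old + d_new
        site_sum[i] <- sum(d_new)
        d_u <- d_u + delta
        if (d_u > best_d) {
          best_d <- d_u
          best <- x
        }
      }
    }
    attr(best, "objective_initial") <- d_init
    attr(best, "objective") <- best_d
    best
  })
}

#' Map virtual sites onto anchor beads of the core surface
#'
#' Each optimized virtual site claims the surface bead with the smallest
#' angular distance (arc between the unit direction of the site and the
#' unit direction of the bead as seen from the origin). When two sites
#' claim the same bead, the closer claim keeps it and the other is moved
#' to the nearest surface bead still available, so anchors are unique.
#'
#' @param sites Unit-vector matrix from [optimize_virtual_sites()].
#' @param core A `core_model` with surface information (see
#'   [identify_surface()]).
#' @return An object of class `anchor_set`: a list with `anchor_indices`
#'   (into the core's beads), `normals`, and empty `labels` to be filled
#'   by [label_morphology()].
#' @export
map_anchors <- function(sites, core) {
  stopifnot(inherits(core, "core_model"))
  if (is.null(core$surface_index)) {
    stop("run identify_surface() (or build_shell()) before mapping anchors")
  }
  n_sites <- nrow(sites)
  surf <- core$surface_index
  if (n_sites > length(surf)) {
    stop(sprintf(
      "%d virtual sites cannot map onto %d surface beads",
      n_sites, length(surf)
    ))
  }
  surf_dir <- unit_rows(core$positions[surf, , drop = FALSE])
  # angular distance = acos of the dot product of unit vectors
  cosang <- sites %*% t(surf_dir)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  ang <- acos(cosang) # n_sites x n_surface
  first_choice <- max.col(-ang, ties.method = "first")
  chosen <- rep(NA_integer_, n_sites)
  taken <- logical(length(surf))
  # closer claims win; displaced sites take the nearest free bead
  ord <- order(ang[cbind(seq_len(n_sites), first_choice)])
  for (s in ord) {
    pref <- order(ang[s, ])
    pick <- pref[!taken[pref]][1]
    chosen[s] <- pick
    taken[pick] <- TRUE
  }
  structure(
    list(
      anchor_indices = surf[chosen],
      normals = core$normals[chosen, , drop = FALSE],
      labels = rep(1L, n_sites),
      n_lig = n_sites
    ),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf(
    "<anchor_set> %d anchors (%d ligand-1, %d ligand-2)\n",
    x$n_lig, sum(x$labels == 1L), sum(x$labels == 2L)
  ))
  invisible(x)
}

#' Monolayer morphology specification
#'
#' @param kind One of `"homogeneous"`, `"random"`, `"janus_x"`,
#'   `"janus_y"`, `"janus_z"`, `"stripe_x"`, `"stripe_y"`, `"stripe_z"`.
#' @param ratio Fraction of anchors assigned ligand 1 (the mixing
#'   fraction of a two-component monolayer); used by `random` and the
#'   Janus kinds.
#' @param n_stripes Number of alternating bands (stripe kinds only,
#'   >= 2).
#' @param seed Integer seed for the `random` kind.
#' @return An object of class `morphology_spec`.
#' @examples
#' morphology_spec("random", ratio = 0.5, seed = 7)
#' @export
morphology_spec <- function(kind = c("homogeneous", "random", "janus_x",
                                     "janus_y", "janus_z", "stripe_x",
                                     "stripe_y", "stripe_z"),
                            ratio = 0.5, n_stripes = 4L, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(ratio) || ratio < 0 || ratio > 1) {
    stop("'ratio' must lie in [0, 1]")
  }
  if (startsWith(kind, "stripe") && n_stripes < 2) {
    stop("striped morphologies need at least 2 stripes")
  }
  structure(
    list(kind = kind, ratio = ratio, n_stripes = as.integer(n_stripes),
         seed = as.integer(seed)),
    class = "morphology_spec"
  )
}

#' Assign ligand labels to anchors according to a monolayer morphology
#'
#' Homogeneous monolayers give every anchor label 1. Random morphologies
#' draw exactly `round(ratio * N)` label-1 anchors with a seeded shuffle.
#' Janus morphologies split the anchors by position along the chosen
#' axis, placing the dividing plane at the ratio-quantile of the anchor
#' coordinates so `ratio` controls the relative abundance (label 1 on the
#' negative side). Striped morphologies slice the anchor extent along the
#' axis into `n_stripes` equal-width bands with alternating labels,
#' starting with label 1 at the negative end.
#'
#' @param anchors An `anchor_set` from [map_anchors()].
#' @param spec A [morphology_spec()].
#' @param core The `core_model` the anchors index into (positions are
#'   needed for the position-dependent morphologies).
#' @return The `anchor_set` with `labels` filled (integer 1 or 2).
#' @export
label_morphology <- function(anchors, spec, core) {
  stopifnot(inherits(anchors, "anchor_set"), inherits(spec, "morphology_spec"),
            inherits(core, "core_model"))
  n <- anchors$n_lig
  pos <- core$positions[anchors$anchor_indices, , drop = FALSE]
  axis_of <- function(kind) match(substring(kind, nchar(kind)), c("x", "y", "z"))
  labels <- switch(spec$kind,
    homogeneous = rep(1L, n),
    random = {
      n1 <- round(spec$ratio * n)
      idx <- with_seed(spec$seed, sample.int(n))
      lab <- rep(2L, n)
      lab[idx[seq_len(n1)]] <- 1L
      lab
    },
    janus_x = ,
    janus_y = ,
    janus_z = {
      ax <- axis_of(spec$kind)
      n1 <- round(spec$ratio * n)
      lab <- rep(2L, n)
      # the n1 anchors lowest along the axis sit below the ratio-quantile
      lab[order(pos[, ax])[seq_len(n1)]] <- 1L
      lab
    },
    stripe_x = ,
    stripe_y = ,
    stripe_z = {
      ax <- axis_of(spec$kind)
      rng <- range(pos[, ax])
      width <- diff(rng) / spec$n_stripes
      if (width == 0) {
        rep(1L, n)
      } else {
        band <- pmin(floor((pos[, ax] - rng[1]) / width), spec$n_stripes - 1)
        as.integer(band %% 2 + 1)
      }
    }
  )
  anchors$labels <- labels
  anchors
}
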