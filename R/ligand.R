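#' Ligand template
#'
#' Describes one coating molecule as a list of beads and a bond graph.
#' Bead 1 is the attachment point that binds the anchor bead of the core
#' (the chemistry of the binding group — e.g. the thiol sulfur on gold —
#' is absorbed into the anchor under the coarse mapping).
#'
#' @param names Character bead names.
#' @param types Character force-field bead types (used for parameter
#'   lookups).
#' @param masses Numeric bead masses (amu).
#' @param charges Numeric bead charges (e); defaults to neutral.
#' @param bonds Two-column integer matrix of bonded bead pairs; defaults
#'   to a linear chain. The bond graph must be connected.
#' @return An object of class `ligand_template`.
#' @examples
#' ligand_template(c("C1A", "C1B", "C1C"), rep("C1", 3), rep(57, 3))
#' @export
ligand_template <- function(names, types, masses, charges = NULL,
                            bonds = NULL) {
  n <- length(names)
  if (n < 1) stop("a ligand needs at least one bead")
  stopifnot(length(types) == n, length(masses) == n)
  if (any(masses <= 0)) stop("bead masses must be positive")
  if (is.null(charges)) charges <- rep(0, n)
  stopifnot(length(charges) == n)
  if (is.null(bonds)) {
    bonds <- if (n > 1) cbind(seq_len(n - 1), seq.int(2, n)) else
      matrix(integer(0), 0, 2)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 &&
      (any(bonds < 1) || any(bonds > n) || any(bonds[, 1] == bonds[, 2]))) {
    stop("bond indices must reference distinct beads of the ligand")
  }
  # connectivity check by flood fill from bead 1
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  repeat {
    grow <- seen[bonds[, 1]] | seen[bonds[, 2]]
    nxt <- seen
    nxt[bonds[grow, 1]] <- TRUE
    nxt[bonds[grow, 2]] <- TRUE
    if (identical(nxt, seen)) break
    seen <- nxt
  }
  if (!all(seen)) stop("the ligand bond graph must be connected")
  structure(
    list(names = as.character(names), types = as.character(types),
         masses = as.numeric(masses), charges = as.numeric(charges),
         bonds = bonds, n_beads = n),
    class = "ligand_template"
  )
}

#' @export
print.ligand_template <- function(x, ...) {
  cat(sprintf(
    "<ligand_template> %d beads (%s), total mass %.4g amu, charge %+.3g e\n",
    x$n_beads, paste(x$types, collapse = "-"), sum(x$masses), sum(x$charges)
  ))
  invisible(x)
}

# children of each bead when the bond graph is rooted at bead 1,
# deepest subtree first so the longest chain is laid down first
rooted_children <- function(template) {
  n <- template$n_beads
  adj <- vector("list", n)
  for (b in seq_len(nrow(template$bonds))) {
    i <- template$bonds[b, 1]; j <- template$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, n)
  depth_below <- rep(0L, n)
  order_bfs <- integer(0)
  queue <- 1L
  visited <- rep(FALSE, n); visited[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  for (v in rev(order_bfs)) {
    if (!is.na(parent[v])) {
      depth_below[parent[v]] <- max(depth_below[parent[v]], depth_below[v] + 1L)
    }
  }
  children <- vector("list", n)
  for (v in seq_len(n)) {
    kids <- which(parent == v)
    children[[v]] <- kids[order(-depth_below[kids])]
  }
  list(parent = parent, children = children)
}

#' Build a ligand in an elongated equilibrium conformation
#'
#' Appends beads sequentially from the attachment bead outward. Each new
#' bead is placed at the equilibrium bond length from its parent, forming
#' the equilibrium bending angle at the parent, with a trans (180°)
#' torsion — the conformation that maximizes the molecule's extension
#' along its principal axis (PC1). Without a parameter set the beads are
#' placed collinearly at a default spacing. The result is rotated so PC1
#' lies exactly along +X with the attachment bead at the origin.
#'
#' Branched ligands are laid down depth-first along the longest chain
#' first; additional branches at a bead leave the trans plane in 120°
#' torsion steps.
#'
#' @param template A [ligand_template()].
#' @param params A `bonded_params` set from [parse_itp()], or `NULL` for
#'   a collinear build.
#' @param default_bond Spacing (nm) used when no bond entry is available.
#' @param default_angle Bending angle (degrees) used when no angle entry
#'   is available.
#' @return An object of class `cg_ligand`: the template plus `coords`
#'   (one row per bead, nm) and a character `report` of parameter
#'   lookups that fell back to defaults.
#' @examples
#' lig <- build_ligand(ligand_template("B1", "C1", 57))
#' @export
build_ligand <- function(template, params = NULL, default_bond = 0.35,
                         default_angle = 180) {
  stopifnot(inherits(template, "ligand_template"))
  n <- template$n_beads
  report <- character(0)
  coords <- matrix(0, n, 3, dimnames = list(template$names, c("x", "y", "z")))
  if (n > 1) {
    tree <- rooted_children(template)
    bond_len <- function(p, c_) {
      l <- if (!is.null(params)) {
        lookup_bond(params, template$types[p], template$types[c_])$length
      }
      if (is.null(l)) {
        if (!is.null(params)) {
          report <<- c(report, sprintf(
            "no bond parameters for types %s-%s; default spacing %g nm used",
            template$types[p], template$types[c_], default_bond
          ))
        }
        l <- default_bond
      }
      l
    }
    bend_angle <- function(g, p, c_) {
      th <- if (!is.null(params)) {
        lookup_angle(params, template$types[g], template$types[p],
                     template$types[c_])$angle
      }
      if (is.null(th)) {
        if (!is.null(params)) {
          report <<- c(report, sprintf(
            "no angle parameters for types %s-%s-%s; %g degrees used",
            template$types[g], template$types[p], template$types[c_],
            default_angle
          ))
        }
        th <- default_angle
      }
      th
    }
    placed <- rep(FALSE, n)
    placed[1] <- TRUE
    place <- function(v) {
      n_side <- 0L
      for (w in tree$children[[v]]) {
        g <- tree$parent[v]
        l <- bond_len(v, w)
        if (is.na(g)) {
          # children of the attachment bead start the chain along +X;
          # extra branches at the root fan out at the default angle
          dir <- if (n_side == 0L) c(1, 0, 0) else {
            rotation_about_axis(c(0, 0, 1), n_side * 2 * pi / 3) %*%
              c(-cos(pi / 6), sin(pi / 6), 0)
          }
          coords[w, ] <<- coords[v, ] + l * as.numeric(dir)
        } else {
          th <- bend_angle(g, v, w) * pi / 180
          phi <- pi + n_side * 2 * pi / 3 # trans, then 120 degree steps
          gg <- tree$parent[g]
          coords[w, ] <<- place_internal(
            if (is.na(gg)) NULL else coords[gg, ],
            coords[g, ], coords[v, ], l, th, phi
          )
        }
        n_side <- n_side + 1L
        placed[w] <<- TRUE
        place(w)
      }
    }
    place(1L)
    coords <- orient_along_pc1(coords)
  }
  structure(
    list(template = template, coords = coords, report = report),
    class = "cg_ligand"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension-reference-frame placement: new bead at distance l
# from p, bending angle theta at p (between g-p and p-new), torsion phi
# of the gg-g-p-new quadruplet (phi = pi is trans). With no gg (or a
# collinear gg-g-p backbone) the torsion plane is arbitrary and a stable
# perpendicular is used instead.
place_internal <- function(gg, g, p, l, theta, phi) {
  bc <- p - g
  bc <- bc / vec_norm(bc)
  ab <- if (is.null(gg)) NULL else g - gg
  nvec <- if (is.null(ab)) c(0, 0, 0) else cross3(ab, bc)
  if (vec_norm(nvec) < 1e-10) {
    ref <- if (abs(bc[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    nvec <- cross3(ref, bc)
  }
  nvec <- nvec / vec_norm(nvec)
  m <- cross3(nvec, bc)
  dir <- -cos(theta) * bc + sin(theta) * (cos(phi) * m + sin(phi) * nvec)
  p + l * dir
}

# Rotate coords so PC1 is exactly +X (pointing from the attachment bead
# into the molecule) with bead 1 at the origin.
orient_along_pc1 <- function(coords) {
  coords <- sweep(coords, 2, coords[1, ], "-")
  if (nrow(coords) == 1) return(coords)
  pc1 <- principal_axis(coords)
  rot <- rotation_between(pc1, c(1, 0, 0))
  out <- coords %*% t(rot)
  dimnames(out) <- dimnames(coords)
  out
}

# First principal component of a bead cloud, oriented from the first
# bead toward the cloud's far end.
principal_axis <- function(coords) {
  if (nrow(coords) == 2) {
    v <- coords[2, ] - coords[1, ]
    return(v / vec_norm(v))
  }
  centered <- sweep(coords, 2, colMeans(coords), "-")
  pc1 <- svd(centered, nu = 0, nv = 1)$v[, 1]
  span <- centered %*% pc1
  if (span[which.max(abs(span))] < 0) pc1 <- -pc1
  # orient away from the attachment bead
  if (sum((colMeans(coords) - coords[1, ]) * pc1) < 0) pc1 <- -pc1
  pc1
}

#' Graft built ligands onto the anchors of a core
#'
#' Rigidly places one copy of the appropriate ligand at every anchor.
#' Each copy is rotated (quaternion-equivalent rotation matrix) so its
#' PC1 is parallel to the anchor's outward normal and translated so the
#' attachment bead sits one anchor-bond length outward from the anchor
#' bead. To relieve steric clashes the copy is then spun about its PC1
#' through 20 evenly spaced candidate rotations (18° grid) and the
#' candidate that maximizes the shortest distance to all beads already in
#' the system is kept, which yields the most voluminous, least hindered
#' monolayer the rigid construction allows.
#'
#' @param core A `core_model` with surface information.
#' @param anchors A labeled `anchor_set`.
#' @param ligands A single `cg_ligand`, or a list of them indexed by
#'   label (`ligands[[1]]` for label 1, `ligands[[2]]` for label 2).
#' @param params Optional `bonded_params` used to look up the
#'   anchor-to-attachment bond length.
#' @param core_type Force-field type of the core beads (used for that
#'   lookup).
#' @param default_bond Anchor bond length (nm) when no parameter entry
#'   exists.
#' @return An object of class `np_model`: the core, anchors, per-anchor
#'   ligand copies (`label`, `coords`, `rotation_scores`, `chosen`), the
#'   templates, and a build report.
#' @examples
#' core <- identify_surface(build_core(lattice_spec("fcc", 0.17),
#'                                     shape_spec("sphere", 1)))
#' sites <- optimize_virtual_sites(8, seed = 1)
#' anchors <- map_anchors(sites, core)
#' anchors <- label_morphology(anchors, morphology_spec("homogeneous"), core)
#' lig <- build_ligand(ligand_template(c("A", "B"), c("C1", "C1"), c(57, 57)))
#' np <- graft_ligands(core, anchors, lig)
#' @export
graft_ligands <- function(core, anchors, ligands, params = NULL,
                          core_type = "C1", default_bond = 0.35) {
  stopifnot(inherits(core, "core_model"), inherits(anchors, "anchor_set"))
  if (inherits(ligands, "cg_ligand")) ligands <- list(ligands)
  labels_used <- sort(unique(anchors$labels))
  if (max(labels_used) > length(ligands)) {
    stop(sprintf(
      "anchors carry label %d but only %d built ligand(s) were supplied",
      max(labels_used), length(ligands)
    ))
  }
  report <- character(0)
  # anchor bond length per label
  d0 <- vapply(seq_along(ligands), function(l) {
    ft <- ligands[[l]]$template$types[1]
    len <- if (!is.null(params)) lookup_bond(params, core_type, ft)$length
    if (is.null(len)) {
      if (!is.null(params)) {
        report <<- c(report, sprintf(
          "no anchor bond parameters for types %s-%s; default %g nm used",
          core_type, ft, default_bond
        ))
      }
      len <- default_bond
    }
    len
  }, numeric(1))

  nrot <- 20L
  rot_grid <- 2 * pi * (seq_len(nrot) - 1) / nrot
  system_pos <- core$positions
  placed <- vector("list", anchors$n_lig)
  for (k in seq_len(anchors$n_lig)) {
    lab <- anchors$labels[k]
    lig <- ligands[[lab]]
    nrm <- anchors$normals[k, ]
    if (vec_norm(nrm) == 0) stop("anchor normal has zero length")
    nrm <- nrm / vec_norm(nrm)
    base <- core$positions[anchors$anchor_indices[k], ] + d0[lab] * nrm
    # PC1 of the built ligand is +X by construction
    align <- rotation_between(c(1, 0, 0), nrm)
    aligned <- lig$coords %*% t(align)
    scores <- numeric(nrot)
    best_coords <- NULL
    for (ri in seq_len(nrot)) {
      spin <- rotation_about_axis(nrm, rot_grid[ri])
      cand <- sweep(aligned %*% t(spin), 2, base, "+")
      d2min <- min_cross_dist2(cand, system_pos)
      scores[ri] <- sqrt(d2min)
      if (is.null(best_coords) || scores[ri] > max(scores[seq_len(ri - 1)])) {
        best_coords <- cand
      }
    }
    chosen <- which.max(scores)
    dimnames(best_coords) <- list(lig$template$names, c("x", "y", "z"))
    placed[[k]] <- list(
      label = lab, anchor = anchors$anchor_indices[k], coords = best_coords,
      rotation_scores = scores, chosen = chosen
    )
    system_pos <- rbind(system_pos, best_coords)
  }
  structure(
    list(
      core = core, anchors = anchors, ligands = placed,
      templates = ligands, core_type = core_type,
      anchor_bond_lengths = d0, report = report
    ),
    class = "np_model"
  )
}

# squared minimum distance between two bead sets
min_cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  min(d2)
}

#' @export
print.np_model <- function(x, ...) {
  n_lig_beads <- sum(vapply(x$ligands, function(l) nrow(l$coords), numeric(1)))
  cat(sprintf(
    "<np_model> %d core beads + %d ligands (%d beads) = %d beads\n",
    nrow(x$core$positions), length(x$ligands), n_lig_beads,
    nrow(x$core$positions) + n_lig_beads
  ))
  for (n in x$report) cat(" note:", n, "\n")
  invisible(x)
}

# All bead positions of an assembled model, core first then ligands in
# anchor order (the canonical serialization order).
model_positions <- function(model) {
  do.call(rbind, c(
    list(model$core$positions),
    lapply(model$ligands, function(l) l$coords)
  ))
}
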