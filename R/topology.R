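# 1 g/cm^3 corresponds to this many amu per nm^3 (Avogadro 6.02214076e23)
AMU_PER_GCM3_NM3 <- 602.214076

#' Distribute the real core mass over the core beads
#'
#' A coarse-grained core must weigh the same as the atomically detailed
#' particle it replaces, so the total mass is the bulk density of the
#' material times the analytic volume of the core shape, converted to
#' amu (1 g cm^-3 = 602.214 amu nm^-3), and distributed equally over the
#' beads. For gold, pass 19.3 g cm^-3.
#'
#' @param core A `core_model`.
#' @param bulk_density Bulk mass density of the core material (g cm^-3).
#' @return The `core_model` with equal per-bead `masses` (amu) filled in.
#' @examples
#' core <- build_core(lattice_spec("fcc", 0.17), shape_spec("sphere", 1.5))
#' core <- assign_core_masses(core, 19.3)
#' sum(core$masses) # 19.3 * (4/3) * pi * 1.5^3 * 602.214
#' @export
assign_core_masses <- function(core, bulk_density) {
  stopifnot(inherits(core, "core_model"))
  if (!is.numeric(bulk_density) || bulk_density <= 0) {
    stop("'bulk_density' must be a positive density in g cm^-3")
  }
  n <- nrow(core$positions)
  if (n == 0) stop("the core has no beads to carry mass")
  total <- bulk_density * shape_geometry(core$shape)$volume * AMU_PER_GCM3_NM3
  core$masses <- rep(total / n, n)
  core
}

#' Build the elastic network that keeps a core rigid
#'
#' For lattice cores, a harmonic bond is laid between every pair of
#' nearest neighbors (beads two bead radii apart, so interior beads get
#' 6 / 8 / 12 / 12 bonds on primitive / bcc / fcc / hcp lattices). For
#' hollow shells, every bead is bonded to its six nearest neighbors and
#' to the bead closest to its antipode, which braces the shell across
#' its diameter. Bonds are deduplicated; each carries its current length
#' as the equilibrium length and the force constant `k_b`.
#'
#' @param core A `core_model`.
#' @param k_b Elastic force constant (kJ mol^-1 nm^-2); the default is a
#'   stiffness commonly used to keep metal cores rigid.
#' @return A data frame with columns `i`, `j` (bead indices), `length`
#'   (nm) and `k`.
#' @export
build_elastic_network <- function(core, k_b = 32500) {
  stopifnot(inherits(core, "core_model"))
  if (!is.numeric(k_b) || k_b <= 0) {
    stop("'k_b' must be a positive force constant")
  }
  pos <- core$positions
  if (is.null(core$lattice)) {
    pairs <- shell_network_pairs(pos)
  } else {
    pairs <- lattice_bond_pairs(core)
  }
  len <- row_norms(pos[pairs[, 1], , drop = FALSE] -
                     pos[pairs[, 2], , drop = FALSE])
  data.frame(i = pairs[, 1], j = pairs[, 2], length = len, k = k_b)
}

# Shell network: 6 nearest neighbors per bead plus the bead nearest to
# the exact antipode, as unique unordered pairs.
shell_network_pairs <- function(pos) {
  n <- nrow(pos)
  if (n < 8) stop("a shell needs at least 8 beads for its elastic network")
  d2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * tcrossprod(pos)
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(row) order(row)[1:6]))
  anti2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") + 2 * tcrossprod(pos)
  diag(anti2) <- Inf # a bead is never its own antipodal partner
  anti <- apply(anti2, 1, which.min)
  i <- rep(seq_len(n), each = 6L)
  j <- as.vector(t(nn))
  i <- c(i, seq_len(n))
  j <- c(j, anti)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  unique(cbind(i = i, j = j))
}

#' Assemble the complete topology of a grafted nanoparticle
#'
#' Walks every ligand copy "center out", from the anchor bead of the
#' core to the ligand tip, enumerating the bonded pairs, triplets and
#' quadruplets, and assigns parameters by bead-type lookup in `params`.
#' A quadruplet whose types match several dihedral entries receives one
#' dihedral term per entry. Tuples with no matching entry are skipped
#' and itemized in the report, so
#' `enumerated = assigned + skipped` holds exactly per category. Core
#' beads are neutral and typed `core_type`; ligand beads carry the
#' masses and charges of their templates, written explicitly.
#'
#' @param model An `np_model` from [graft_ligands()].
#' @param params A `bonded_params` set (possibly empty).
#' @param bulk_density Optional bulk density (g cm^-3); required when
#'   the core does not yet carry masses.
#' @param k_elastic Elastic-network force constant (kJ mol^-1 nm^-2).
#' @param interaction_matrix Filename of the nonbonded interaction
#'   matrix referenced (not copied into) the topology.
#' @param nrexcl Number of bonded neighbors excluded from nonbonded
#'   interactions in the molecule definition.
#' @return An object of class `topology_doc` with `atoms` (type, mass,
#'   charge per bead in serialization order), `bonds`, `angles`,
#'   `dihedrals`, `elastic`, the skip `report`, and counters
#'   `n_enumerated` / `n_assigned` / `n_skipped` per term category.
#' @export
assign_ligand_topology <- function(model, params,
                                   bulk_density = NULL,
                                   k_elastic = 32500,
                                   interaction_matrix = "interaction_matrix.itp",
                                   nrexcl = 1L) {
  stopifnot(inherits(model, "np_model"))
  core <- model$core
  if (is.null(core$masses)) {
    if (is.null(bulk_density)) {
      stop("core masses are unset; provide 'bulk_density'")
    }
    core <- assign_core_masses(core, bulk_density)
  }
  n_core <- nrow(core$positions)

  # atoms: core first, then ligand copies in anchor order
  atom_rows <- list(data.frame(
    name = rep("COR", n_core),
    type = rep(model$core_type, n_core),
    mass = core$masses,
    charge = rep(0, n_core),
    resname = rep("CORE", n_core)
  ))
  offset <- n_core
  lig_offsets <- integer(length(model$ligands))
  for (k in seq_along(model$ligands)) {
    tpl <- model$templates[[model$ligands[[k]]$label]]$template
    atom_rows[[k + 1L]] <- data.frame(
      name = tpl$names, type = tpl$types, mass = tpl$masses,
      charge = tpl$charges,
      resname = rep(sprintf("LG%d", model$ligands[[k]]$label), tpl$n_beads)
    )
    lig_offsets[k] <- offset
    offset <- offset + tpl$n_beads
  }
  atoms <- do.call(rbind, atom_rows)
  atoms$index <- seq_len(nrow(atoms))

  bonds <- list(); angles <- list(); dihedrals <- list()
  skipped <- list()
  counts <- c(bond = 0L, angle = 0L, dihedral = 0L)
  assigned <- c(bond = 0L, angle = 0L, dihedral = 0L)

  for (k in seq_along(model$ligands)) {
    lab <- model$ligands[[k]]$label
    tpl <- model$templates[[lab]]$template
    off <- lig_offsets[k]
    anchor_global <- model$ligands[[k]]$anchor
    # graph over local ids: 0 = anchor, 1..n = ligand beads
    edges <- rbind(c(0L, 1L), tpl$bonds)
    types <- c(model$core_type, tpl$types)
    gid <- function(local) ifelse(local == 0L, anchor_global, off + local)
    adj <- vector("list", tpl$n_beads + 1L)
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1] + 1L; b <- edges[e, 2] + 1L
      adj[[a]] <- c(adj[[a]], edges[e, 2])
      adj[[b]] <- c(adj[[b]], edges[e, 1])
    }
    # bonds
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      counts["bond"] <- counts["bond"] + 1L
      hit <- lookup_bond(params, types[a + 1L], types[b + 1L])
      if (is.null(hit)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          term = "bond", types = paste(types[c(a, b) + 1L], collapse = "-")
        )
      } else {
        assigned["bond"] <- assigned["bond"] + 1L
        bonds[[length(bonds) + 1L]] <- data.frame(
          i = gid(a), j = gid(b), func = hit$func,
          length = hit$length, k = hit$k
        )
      }
    }
    # angles: all paths b1 - v - b2 with b1 < b2
    trips <- list()
    for (v in 0:tpl$n_beads) {
      nb <- sort(unique(adj[[v + 1L]]))
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        for (cc in seq_len(ncol(cmb))) {
          trips[[length(trips) + 1L]] <- c(cmb[1, cc], v, cmb[2, cc])
        }
      }
    }
    for (tr in trips) {
      counts["angle"] <- counts["angle"] + 1L
      tt <- types[tr + 1L]
      hit <- lookup_angle(params, tt[1], tt[2], tt[3])
      if (is.null(hit)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          term = "angle", types = paste(tt, collapse = "-")
        )
      } else {
        assigned["angle"] <- assigned["angle"] + 1L
        angles[[length(angles) + 1L]] <- data.frame(
          i = gid(tr[1]), j = gid(tr[2]), k = gid(tr[3]),
          func = hit$func, angle = hit$angle, fc = hit$k
        )
      }
    }
    # dihedrals: all paths a - b - c - d along distinct beads
    quads <- list()
    for (e in seq_len(nrow(edges))) {
      b <- edges[e, 1]; c_ <- edges[e, 2]
      for (a in setdiff(adj[[b + 1L]], c_)) {
        for (d in setdiff(adj[[c_ + 1L]], b)) {
          if (a == d) next
          q <- c(a, b, c_, d)
          # canonical orientation so each path is counted once
          if (q[1] > q[4] || (q[1] == q[4] && q[2] > q[3])) q <- rev(q)
          quads[[length(quads) + 1L]] <- q
        }
      }
    }
    quads <- unique(quads)
    for (q in quads) {
      counts["dihedral"] <- counts["dihedral"] + 1L
      tt <- types[q + 1L]
      hits <- lookup_dihedral(params, tt[1], tt[2], tt[3], tt[4])
      if (nrow(hits) == 0) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          term = "dihedral", types = paste(tt, collapse = "-")
        )
      } else {
        assigned["dihedral"] <- assigned["dihedral"] + 1L
        for (h in seq_len(nrow(hits))) {
          dihedrals[[length(dihedrals) + 1L]] <- data.frame(
            i = gid(q[1]), j = gid(q[2]), k = gid(q[3]), l = gid(q[4]),
            func = hits$func[h], phi0 = hits$phi0[h], fc = hits$k[h],
            mult = hits$mult[h]
          )
        }
      }
    }
  }

  elastic <- build_elastic_network(core, k_elastic)
  model$core <- core
  structure(
    list(
      model = model,
      atoms = atoms,
      bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
      angles = if (length(angles)) do.call(rbind, angles) else NULL,
      dihedrals = if (length(dihedrals)) do.call(rbind, dihedrals) else NULL,
      elastic = elastic,
      interaction_matrix = interaction_matrix,
      nrexcl = as.integer(nrexcl),
      n_enumerated = counts,
      n_assigned = assigned,
      n_skipped = counts - assigned,
      report = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(term = character(0), types = character(0))
    ),
    class = "topology_doc"
  )
}

#' @export
print.topology_doc <- function(x, ...) {
  cat(sprintf(
    "<topology_doc> %d atoms; %d bonds, %d angles, %d dihedrals assigned; %d elastic bonds\n",
    nrow(x$atoms),
    if (is.null(x$bonds)) 0L else nrow(x$bonds),
    if (is.null(x$angles)) 0L else nrow(x$angles),
    if (is.null(x$dihedrals)) 0L else nrow(x$dihedrals),
    nrow(x$elastic)
  ))
  if (nrow(x$report)) {
    cat(sprintf(" %d bonded tuple(s) skipped for missing parameters\n",
                nrow(x$report)))
  }
  invisible(x)
}
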