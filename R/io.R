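# Atom metadata (names, residue ids) in the canonical serialization
# order: core beads first as residue 1, then each ligand copy as its own
# residue in anchor order.
model_atom_table <- function(model) {
  n_core <- nrow(model$core$positions)
  rows <- list(data.frame(
    resno = rep(1L, n_core), resname = rep("CORE", n_core),
    name = rep("COR", n_core)
  ))
  for (k in seq_along(model$ligands)) {
    tpl <- model$templates[[model$ligands[[k]]$label]]$template
    rows[[k + 1L]] <- data.frame(
      resno = rep(k + 1L, tpl$n_beads),
      resname = rep(sprintf("LG%d", model$ligands[[k]]$label), tpl$n_beads),
      name = tpl$names
    )
  }
  out <- do.call(rbind, rows)
  out$index <- seq_len(nrow(out))
  out
}

#' Write model coordinates to a structure file
#'
#' Serializes an assembled nanoparticle (or a bare core) in the
#' canonical bead order — core beads first, then ligands in anchor
#' order, matching the topology files. `.gro` files are written in nm
#' with the fixed Gromacs columns and a cubic box enclosing the model
#' with a 2 nm margin; `.pdb` files are written in Angstrom through
#' bio3d. Atom serials wrap at the field width of each format (100,000
#' for .pdb), which is noted in the return value.
#'
#' @param model An `np_model` or `core_model`.
#' @param file Output path.
#' @param format `"gro"` or `"pdb"` (default: from the file extension).
#' @param title Title line for .gro output.
#' @return Invisibly, a character vector of notes (empty when nothing
#'   noteworthy happened).
#' @export
write_structure <- function(model, file,
                            format = c("auto", "gro", "pdb"),
                            title = "coarse-grained nanoparticle") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", file, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (inherits(model, "core_model")) {
    pos <- model$positions
    atoms <- data.frame(
      resno = 1L, resname = "CORE", name = "COR",
      index = seq_len(nrow(pos))
    )
  } else {
    pos <- model_positions(model)
    atoms <- model_atom_table(model)
  }
  notes <- character(0)
  n <- nrow(pos)
  if (format == "gro") {
    box <- apply(pos, 2, function(v) diff(range(v))) + 4
    lines <- c(
      title,
      sprintf("%5d", n),
      sprintf(
        "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
        atoms$resno %% 100000L, substr(atoms$resname, 1, 5),
        substr(atoms$name, 1, 5), atoms$index %% 100000L,
        pos[, 1], pos[, 2], pos[, 3]
      ),
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
    )
    writeLines(lines, file)
    if (n >= 100000L) {
      notes <- c(notes, "atom numbers wrap at 100,000 in the .gro serial field")
    }
  } else {
    if (n >= 100000L) {
      notes <- c(notes, "atom serials wrap at 100,000 in the .pdb serial field")
    }
    bio3d::write.pdb(
      file = file,
      xyz = as.vector(t(pos)) * 10, # nm -> Angstrom
      eleno = atoms$index %% 100000L,
      elety = atoms$name,
      resno = atoms$resno %% 10000L,
      resid = substr(atoms$resname, 1, 3) # PDB residue names are 3 chars
    )
  }
  invisible(notes)
}

#' Read one or more frames from a .gro file
#'
#' Understands plain single-frame files and multi-frame concatenations
#' (several title/count/atoms/box blocks in one file), as produced by
#' trajectory dumps.
#'
#' @param file Path to the .gro file.
#' @return A list of frames; each frame is a list with `title`, `atoms`
#'   (resno, resname, name) and `positions` (nm).
#' @export
read_gro <- function(file) {
  lines <- readLines(file, warn = FALSE)
  frames <- list()
  at <- 1L
  while (at <= length(lines)) {
    if (trimws(lines[at]) == "") {
      at <- at + 1L
      next
    }
    title <- lines[at]
    n <- as.integer(trimws(lines[at + 1L]))
    if (is.na(n)) stop(sprintf("bad atom count near line %d", at + 1L))
    rows <- lines[at + 1L + seq_len(n)]
    frames[[length(frames) + 1L]] <- list(
      title = title,
      atoms = data.frame(
        resno = as.integer(substr(rows, 1, 5)),
        resname = trimws(substr(rows, 6, 10)),
        name = trimws(substr(rows, 11, 15))
      ),
      positions = cbind(
        x = as.numeric(substr(rows, 21, 28)),
        y = as.numeric(substr(rows, 29, 36)),
        z = as.numeric(substr(rows, 37, 44))
      )
    )
    at <- at + n + 3L # title + count + atoms + box
  }
  frames
}

#' Write Gromacs-dialect topology files
#'
#' Emits the molecule definition (.itp) — atoms with explicit types,
#' masses and charges, ligand bonds / angles / dihedrals, and the core
#' elastic network as harmonic (function type 1) bonds — plus a system
#' topology (.top) whose only reference to nonbonded parameters is a
#' single `#include` line naming the interaction-matrix file. Swapping
#' force fields therefore means editing that one line. A minimal
#' synthetic interaction-matrix stub for the bead types present is
#' written alongside unless the referenced file already exists.
#'
#' @param doc A `topology_doc` from [assign_ligand_topology()].
#' @param dir Output directory (created if missing).
#' @param name Molecule and file base name.
#' @return Invisibly, the paths written.
#' @export
write_topology <- function(doc, dir = ".", name = "NP") {
  stopifnot(inherits(doc, "topology_doc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  itp_path <- file.path(dir, paste0(name, ".itp"))
  top_path <- file.path(dir, paste0(name, ".top"))

  fmt_num <- function(x) formatC(x, format = "g", digits = 8)
  out <- c(
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s  %d", name, doc$nrexcl),
    "",
    "[ atoms ]",
    "; nr  type  resnr  residue  atom  cgnr  charge  mass",
    sprintf(
      "%6d  %-6s %5d  %-6s %-6s %6d  %10.4f  %12.4f",
      doc$atoms$index, doc$atoms$type,
      as.integer(factor(doc$atoms$resname, levels = unique(doc$atoms$resname))),
      doc$atoms$resname, doc$atoms$name, doc$atoms$index,
      doc$atoms$charge, doc$atoms$mass
    )
  )
  bond_lines <- character(0)
  if (!is.null(doc$bonds) && nrow(doc$bonds)) {
    bond_lines <- sprintf(
      "%6d %6d   %d  %s  %s",
      doc$bonds$i, doc$bonds$j, doc$bonds$func,
      fmt_num(doc$bonds$length), fmt_num(doc$bonds$k)
    )
  }
  elastic_lines <- sprintf(
    "%6d %6d   1  %s  %s  ; elastic network",
    doc$elastic$i, doc$elastic$j,
    fmt_num(doc$elastic$length), fmt_num(doc$elastic$k)
  )
  out <- c(
    out, "",
    "[ bonds ]",
    "; i  j  func  b0(nm)  kb(kJ mol-1 nm-2)",
    bond_lines,
    elastic_lines
  )
  if (!is.null(doc$angles) && nrow(doc$angles)) {
    out <- c(
      out, "",
      "[ angles ]",
      "; i  j  k  func  theta0(deg)  k",
      sprintf(
        "%6d %6d %6d   %d  %s  %s",
        doc$angles$i, doc$angles$j, doc$angles$k, doc$angles$func,
        fmt_num(doc$angles$angle), fmt_num(doc$angles$fc)
      )
    )
  }
  if (!is.null(doc$dihedrals) && nrow(doc$dihedrals)) {
    out <- c(
      out, "",
      "[ dihedrals ]",
      "; i  j  k  l  func  phi0(deg)  k  mult",
      sprintf(
        "%6d %6d %6d %6d   %d  %s  %s  %d",
        doc$dihedrals$i, doc$dihedrals$j, doc$dihedrals$k, doc$dihedrals$l,
        doc$dihedrals$func, fmt_num(doc$dihedrals$phi0),
        fmt_num(doc$dihedrals$fc), doc$dihedrals$mult
      )
    )
  }
  writeLines(out, itp_path)

  top <- c(
    sprintf("#include \"%s\"", doc$interaction_matrix),
    sprintf("#include \"%s.itp\"", name),
    "",
    "[ system ]",
    "coarse-grained monolayer-protected nanoparticle",
    "",
    "[ molecules ]",
    sprintf("%s  1", name)
  )
  writeLines(top, top_path)

  matrix_path <- file.path(dir, doc$interaction_matrix)
  if (!file.exists(matrix_path)) {
    write_interaction_matrix_stub(unique(doc$atoms$type), matrix_path)
  }
  invisible(c(itp = itp_path, top = top_path, matrix = matrix_path))
}

# A synthetic stand-in for a real force-field interaction matrix: it
# declares the bead types present with placeholder self-interactions so
# the file set is self-consistent; users substitute their force field's
# matrix by editing the include line in the .top file.
write_interaction_matrix_stub <- function(types, path) {
  lines <- c(
    "; synthetic interaction-matrix stub (placeholder Lennard-Jones terms)",
    "; replace via the #include line in the .top file to use a real force field",
    "[ defaults ]",
    "; nbfunc  comb-rule",
    "  1       1",
    "",
    "[ atomtypes ]",
    "; name  mass  charge  ptype  c6  c12",
    sprintf("%-6s  72.0  0.000  A  0.0  0.0", types),
    "",
    "[ nonbond_params ]",
    "; i  j  func  c6  c12"
  )
  pairs <- expand.grid(i = types, j = types, stringsAsFactors = FALSE)
  pairs <- pairs[as.integer(factor(pairs$i, levels = types)) <=
                   as.integer(factor(pairs$j, levels = types)), ]
  lines <- c(lines, sprintf("%-6s %-6s  1  0.0  0.0", pairs$i, pairs$j))
  writeLines(lines, path)
  invisible(path)
}
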