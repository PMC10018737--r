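#' Parse bonded parameters from a Gromacs-dialect include topology
#'
#' Reads the `[ bondtypes ]` / `[ angletypes ]` / `[ dihedraltypes ]`
#' sections (the plain `[ bonds ]` / `[ angles ]` / `[ dihedrals ]`
#' spellings are accepted too) of an .itp file into a parameter set
#' keyed by bead-type tuples. Entries are
#' `type1 type2 [func] b0 k` for bonds,
#' `type1 type2 type3 [func] theta0 k` for angles and
#' `type1 ... type4 [func] phi0 k mult` for dihedrals, following the
#' Gromacs column order; the integer function-type column is optional.
#' `;` starts a comment. Duplicate entries for the same dihedral
#' quadruplet are all retained, so force fields that stack several
#' periodic terms on one quadruplet work as intended. Unknown sections
#' are skipped with a warning.
#'
#' @param path Path to the .itp file.
#' @return An object of class `bonded_params` with data frames `bonds`
#'   (`type1`, `type2`, `func`, `length`, `k`), `angles` (`...`,
#'   `angle`, `k`) and `dihedrals` (`...`, `phi0`, `k`, `mult`).
#'   Lookups through [lookup_bond()], [lookup_angle()] and
#'   [lookup_dihedral()] are symmetric under tuple reversal.
#' @export
parse_itp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  bonds <- list(); angles <- list(); dihedrals <- list()
  unknown <- character(0)
  for (ln in seq_along(lines)) {
    txt <- sub(";.*$", "", lines[ln])
    txt <- trimws(txt)
    if (txt == "" || startsWith(txt, "#")) next
    if (grepl("^\\[", txt)) {
      section <- tolower(gsub("[][[:space:]]", "", txt))
      next
    }
    fields <- strsplit(txt, "[[:space:]]+")[[1]]
    n_types <- switch(section,
      bondtypes = , bonds = 2L,
      angletypes = , angles = 3L,
      dihedraltypes = , dihedrals = 4L,
      0L
    )
    if (n_types == 0L) {
      if (!is.na(section)) unknown <- union(unknown, section)
      next
    }
    if (length(fields) < n_types + 2) {
      stop(sprintf("line %d of %s: too few fields for a %s entry",
                   ln, path, section))
    }
    types <- fields[seq_len(n_types)]
    nums <- suppressWarnings(as.numeric(fields[-seq_len(n_types)]))
    if (any(is.na(nums))) {
      stop(sprintf("line %d of %s: malformed numeric field '%s'",
                   ln, path,
                   fields[-seq_len(n_types)][which(is.na(nums))[1]]))
    }
    if (n_types == 2L) {
      v <- if (length(nums) >= 3) nums[1:3] else c(1, nums[1:2])
      bonds[[length(bonds) + 1L]] <- data.frame(
        type1 = types[1], type2 = types[2],
        func = as.integer(v[1]), length = v[2], k = v[3]
      )
    } else if (n_types == 3L) {
      v <- if (length(nums) >= 3) nums[1:3] else c(1, nums[1:2])
      angles[[length(angles) + 1L]] <- data.frame(
        type1 = types[1], type2 = types[2], type3 = types[3],
        func = as.integer(v[1]), angle = v[2], k = v[3]
      )
    } else {
      v <- if (length(nums) >= 4) nums[1:4] else c(1, nums[1:3])
      dihedrals[[length(dihedrals) + 1L]] <- data.frame(
        type1 = types[1], type2 = types[2], type3 = types[3],
        type4 = types[4],
        func = as.integer(v[1]), phi0 = v[2], k = v[3],
        mult = as.integer(v[4])
      )
    }
  }
  if (length(unknown)) {
    warning(sprintf("ignored unrecognized section(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      bonds = if (length(bonds)) do.call(rbind, bonds) else
        data.frame(type1 = character(0), type2 = character(0),
                   func = integer(0), length = numeric(0), k = numeric(0)),
      angles = if (length(angles)) do.call(rbind, angles) else
        data.frame(type1 = character(0), type2 = character(0),
                   type3 = character(0), func = integer(0),
                   angle = numeric(0), k = numeric(0)),
      dihedrals = if (length(dihedrals)) do.call(rbind, dihedrals) else
        data.frame(type1 = character(0), type2 = character(0),
                   type3 = character(0), type4 = character(0),
                   func = integer(0), phi0 = numeric(0), k = numeric(0),
                   mult = integer(0)),
      source = path
    ),
    class = "bonded_params"
  )
}

#' @export
print.bonded_params <- function(x, ...) {
  cat(sprintf(
    "<bonded_params> %d bond, %d angle, %d dihedral entries (%s)\n",
    nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
    if (is.null(x$source)) "in memory" else x$source
  ))
  invisible(x)
}

#' Look up bonded parameters by bead-type tuple
#'
#' Lookups are symmetric under reversal of the tuple: the pair (A, B)
#' matches an entry stored as (B, A), the triplet (A, B, C) matches
#' (C, B, A), and likewise for quadruplets. `lookup_dihedral()` returns
#' all matching entries, because one quadruplet may legitimately carry
#' several periodic terms.
#'
#' @param params A `bonded_params` set.
#' @param t1,t2,t3,t4 Bead type strings.
#' @return `lookup_bond()` / `lookup_angle()`: a one-row data frame, or
#'   `NULL` when no entry matches. `lookup_dihedral()`: a data frame of
#'   zero or more matching rows.
#' @export
lookup_bond <- function(params, t1, t2) {
  b <- params$bonds
  hit <- (b$type1 == t1 & b$type2 == t2) | (b$type1 == t2 & b$type2 == t1)
  if (!any(hit)) return(NULL)
  b[which(hit)[1], , drop = FALSE]
}

#' @rdname lookup_bond
#' @export
lookup_angle <- function(params, t1, t2, t3) {
  a <- params$angles
  hit <- (a$type1 == t1 & a$type2 == t2 & a$type3 == t3) |
    (a$type1 == t3 & a$type2 == t2 & a$type3 == t1)
  if (!any(hit)) return(NULL)
  a[which(hit)[1], , drop = FALSE]
}

#' @rdname lookup_bond
#' @export
lookup_dihedral <- function(params, t1, t2, t3, t4) {
  d <- params$dihedrals
  hit <- (d$type1 == t1 & d$type2 == t2 & d$type3 == t3 & d$type4 == t4) |
    (d$type1 == t4 & d$type2 == t3 & d$type3 == t2 & d$type4 == t1)
  d[hit, , drop = FALSE]
}
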