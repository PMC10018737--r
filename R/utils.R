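# Internal geometry and bookkeeping helpers shared across modules.

vec_norm <- function(v) sqrt(sum(v * v))

row_norms <- function(m) sqrt(rowSums(m * m))

#' @keywords internal
unit_rows <- function(m) {
  n <- row_norms(m)
  if (any(n == 0)) stop("cannot normalize a zero-length vector")
  m / n
}

# Rotation matrix taking unit vector `from` onto unit vector `to`
# (Rodrigues formula; the antiparallel case picks a stable perpendicular axis).
rotation_between <- function(from, to) {
  from <- from / vec_norm(from)
  to <- to / vec_norm(to)
  c_ <- sum(from * to)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to `from`
    ref <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- ref - sum(ref * from) * from
    axis <- axis / vec_norm(axis)
    return(2 * tcrossprod(axis) - diag(3))
  }
  v <- c(
    from[2] * to[3] - from[3] * to[2],
    from[3] * to[1] - from[1] * to[3],
    from[1] * to[2] - from[2] * to[1]
  )
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Rotation by `angle` radians about unit `axis` (right-handed).
rotation_about_axis <- function(axis, angle) {
  axis <- axis / vec_norm(axis)
  c_ <- cos(angle)
  s_ <- sin(angle)
  vx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) * c_ + s_ * vx + (1 - c_) * tcrossprod(axis)
}

angle_between <- function(a, b) {
  ca <- sum(a * b) / (vec_norm(a) * vec_norm(b))
  acos(min(1, max(-1, ca)))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# All unordered pairs (i, j), i < j, with |x_i - x_j| <= cutoff.
# Cell-list search: O(N) cells of side `cutoff`, candidate pairs only from
# the 27-cell neighborhood, scanned over a non-redundant half-space of
# offsets so each pair is emitted once.
neighbor_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  lo <- apply(pos, 2, min)
  cell <- floor(sweep(pos, 2, lo) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  members <- split(seq_len(n), key)
  coords <- do.call(rbind, lapply(strsplit(names(members), ","), as.integer))

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- offs[, 1] > 0 |
    (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] >= 0)
  offs <- offs[keep, , drop = FALSE]

  cut2 <- cutoff^2
  out_i <- vector("list", length(members) * nrow(offs))
  out_j <- vector("list", length(members) * nrow(offs))
  slot <- 0L
  for (ci in seq_along(members)) {
    a_idx <- members[[ci]]
    for (oi in seq_len(nrow(offs))) {
      self <- all(offs[oi, ] == 0L)
      if (self) {
        b_idx <- a_idx
      } else {
        k2 <- paste(coords[ci, 1] + offs[oi, 1],
                    coords[ci, 2] + offs[oi, 2],
                    coords[ci, 3] + offs[oi, 3], sep = ",")
        b_idx <- members[[k2]]
        if (is.null(b_idx)) next
      }
      # pairwise squared distances between the two (small) cells
      d2 <- outer(rowSums(pos[a_idx, , drop = FALSE]^2),
                  rowSums(pos[b_idx, , drop = FALSE]^2), "+") -
        2 * pos[a_idx, , drop = FALSE] %*% t(pos[b_idx, , drop = FALSE])
      hit <- which(d2 <= cut2 + 1e-12, arr.ind = TRUE)
      if (self) hit <- hit[a_idx[hit[, 1]] < b_idx[hit[, 2]], , drop = FALSE]
      if (nrow(hit) == 0) next
      slot <- slot + 1L
      out_i[[slot]] <- a_idx[hit[, 1]]
      out_j[[slot]] <- b_idx[hit[, 2]]
    }
  }
  if (slot == 0L) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  i <- unlist(out_i[seq_len(slot)], use.names = FALSE)
  j <- unlist(out_j[seq_len(slot)], use.names = FALSE)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  cbind(i = i, j = j)
}
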