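#' Periodic pair list within a cutoff
#'
#' Enumerates all atom pairs (including pairs of an atom with its own
#' periodic images) whose separation can fall below `cutoff`, by looping
#' over the integer lattice shifts needed to cover the cutoff sphere.
#' The list stores (i, j, shift) with the Cartesian shift of atom j, and
#' is reusable across MD steps as long as no atom has moved more than
#' `skin`/2 since it was built.
#'
#' @param config an [atoms] object.
#' @param cutoff interaction cutoff (Angstrom).
#' @param skin extra margin added to the cutoff when building (Angstrom).
#' @return list with integer vectors `i`, `j`, matrix `shift` (M x 3,
#'   Cartesian), the positions the list was built at, and the build
#'   cutoff.  For gas-phase input all i < j pairs with shift 0.
#' @keywords internal
pair_list <- function(config, cutoff, skin = 0) {
  pos <- config$positions
  n <- nrow(pos)
  rc <- cutoff + skin
  if (!config$pbc) {
    if (n < 2) {
      idx <- integer(0)
      return(list(i = idx, j = idx, shift = matrix(0, 0, 3),
                  built_at = pos, cutoff = rc))
    }
    cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dr <- pos[cmb[, 2], , drop = FALSE] - pos[cmb[, 1], , drop = FALSE]
    keep <- rowSums(dr^2) < rc^2
    return(list(i = cmb[keep, 1], j = cmb[keep, 2],
                shift = matrix(0, sum(keep), 3),
                built_at = pos, cutoff = rc))
  }
  cell <- config$cell
  # number of cells needed along each axis: use perpendicular widths
  recip <- solve(cell)                       # columns are reciprocal vectors
  widths <- 1 / sqrt(colSums(recip^2))       # perpendicular cell widths
  nrep <- ceiling(rc / widths)
  sh <- as.matrix(expand.grid(-nrep[1]:nrep[1], -nrep[2]:nrep[2],
                              -nrep[3]:nrep[3]))
  ii <- integer(0); jj <- integer(0)
  shifts <- matrix(0, 0, 3)
  for (k in seq_len(nrow(sh))) {
    s <- sh[k, ]
    svec <- as.numeric(s %*% cell)
    if (all(s == 0)) {
      if (n < 2) next
      cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      dr <- pos[cmb[, 2], , drop = FALSE] - pos[cmb[, 1], , drop = FALSE]
      keep <- rowSums(dr^2) < rc^2
      ii <- c(ii, cmb[keep, 1]); jj <- c(jj, cmb[keep, 2])
      shifts <- rbind(shifts, matrix(0, sum(keep), 3))
    } else if (s[3] > 0 || (s[3] == 0 && (s[2] > 0 ||
               (s[2] == 0 && s[1] > 0)))) {
      # half the shifts: each (i, j, S) pairs i with image j+S, all i, j
      drx <- outer(pos[, 1], pos[, 1], function(a, b) b - a) + svec[1]
      dry <- outer(pos[, 2], pos[, 2], function(a, b) b - a) + svec[2]
      drz <- outer(pos[, 3], pos[, 3], function(a, b) b - a) + svec[3]
      keep <- which(drx^2 + dry^2 + drz^2 < rc^2, arr.ind = TRUE)
      if (nrow(keep)) {
        ii <- c(ii, keep[, 1]); jj <- c(jj, keep[, 2])
        shifts <- rbind(shifts, matrix(svec, nrow(keep), 3, byrow = TRUE))
      }
    }
  }
  list(i = ii, j = jj, shift = shifts, built_at = pos, cutoff = rc)
}

# displacement vectors r_j + shift - r_i for a pair list at current positions
pair_vectors <- function(pl, pos) {
  pos[pl$j, , drop = FALSE] + pl$shift - pos[pl$i, , drop = FALSE]
}

# does the pair list need rebuilding for these positions?
pair_list_stale <- function(pl, pos, cutoff, skin) {
  if (skin <= 0) return(TRUE)
  max(abs(pos - pl$built_at)) > skin / 2  # conservative per-component bound
}

# accumulate per-pair force contributions (M x 3, force on i; -f on j)
accumulate_pair_forces <- function(n, pl, fpair) {
  f <- matrix(0, n, 3)
  for (d in 1:3) {
    f[, d] <- f[, d] + tabulate_sum(pl$i, fpair[, d], n) -
      tabulate_sum(pl$j, fpair[, d], n)
  }
  f
}

# sum values by integer index (rowsum without dimnames overhead)
tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  if (length(idx)) {
    agg <- rowsum(val, idx)
    out[as.integer(rownames(agg))] <- agg
  }
  out
}
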