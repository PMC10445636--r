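# Neighbor lists under periodic (minimum-image) or open boundaries,
# deterministic species-blocked neighbor ordering, the smooth radial
# envelope, per-atom environment matrices and the local-frame construction.

#' Smooth switching function
#'
#' The radial envelope `s(r)`: `1/r` inside `rs`, a quintic interpolation of
#' `1/r` down to zero on `[rs, rc)` and zero beyond the cutoff.  Value,
#' first and second derivatives are continuous everywhere (including at `rs`
#' and `rc`), which is what makes descriptors built on it twice
#' differentiable and hence gives smooth forces.
#'
#' @param r distances (Angstrom), `r > 0`.
#' @param rs inner radius where the decay starts.
#' @param rc cutoff radius, `0 < rs < rc`.
#' @param deriv 0, 1 or 2 for the value or its derivatives in `r`.
#' @return numeric vector like `r`.
#' @export
switch_fn <- function(r, rs, rc, deriv = 0L) {
  if (!(rs > 0 && rc > rs))
    stop("switch_fn requires 0 < rs < rc", call. = FALSE)
  if (any(r == 0)) stop("switch_fn is singular at r = 0", call. = FALSE)
  if (any(r < 0)) stop("switch_fn requires r >= 0", call. = FALSE)
  d <- rc - rs
  x <- (r - rs) / d
  out <- numeric(length(r))
  lo <- r < rs
  mid <- r >= rs & r < rc
  xm <- x[mid]; rm <- r[mid]
  # P(x) = -6 x^5 + 15 x^4 - 10 x^3 + 1 interpolates 1 -> 0 with flat ends
  P <- function(x) ((-6 * x + 15) * x - 10) * x^3 + 1
  P1 <- function(x) -30 * x^2 * (x - 1)^2
  P2 <- function(x) -60 * x * (2 * x - 1) * (x - 1)
  if (deriv == 0L) {
    out[lo] <- 1 / r[lo]
    out[mid] <- P(xm) / rm
  } else if (deriv == 1L) {
    out[lo] <- -1 / r[lo]^2
    out[mid] <- P1(xm) / d / rm - P(xm) / rm^2
  } else if (deriv == 2L) {
    out[lo] <- 2 / r[lo]^3
    out[mid] <- P2(xm) / d^2 / rm - 2 * P1(xm) / d / rm^2 + 2 * P(xm) / rm^3
  } else stop("deriv must be 0, 1 or 2", call. = FALSE)
  out
}

# bare quintic bracket w(u): 1 for u <= 0, P(u) on (0,1), 0 for u >= 1;
# used by the pairwise-potential interpolation weight
poly_switch <- function(u, deriv = 0L) {
  out <- numeric(length(u))
  mid <- u > 0 & u < 1
  um <- u[mid]
  if (deriv == 0L) {
    out[u <= 0] <- 1
    out[mid] <- ((-6 * um + 15) * um - 10) * um^3 + 1
  } else if (deriv == 1L) {
    out[mid] <- -30 * um^2 * (um - 1)^2
  } else if (deriv == 2L) {
    out[mid] <- -60 * um * (2 * um - 1) * (um - 1)
  } else stop("deriv must be 0, 1 or 2", call. = FALSE)
  out
}

#' Pack a neighbor triple into its 64-bit sort key
#'
#' Species index, distance quantized at 1e-8 Angstrom and atom index are
#' packed into non-overlapping decimal fields of one 64-bit integer,
#' `S = alpha * 1e15 + floor(r * 1e8) * 1e5 + j`, so that sorting by `S`
#' equals the lexicographic sort by `(alpha, floor(r * 1e8), j)`.  Keys are
#' computed in exact 64-bit arithmetic; the numeric return value is exact
#' only below 2^53 (species index <= 8), use `as = "character"` beyond.
#'
#' @param alpha 0-based species indices, `< 9223`.
#' @param r distances in Angstrom, `< 92`.
#' @param j 0-based atom indices, `< 1e5`.
#' @param as `"numeric"` or `"character"`.
#' @return key vector.
#' @export
neighbor_sort_key <- function(alpha, r, j, as = c("numeric", "character")) {
  as <- match.arg(as)
  alpha <- as.integer(alpha); j <- as.integer(j)
  if (as == "numeric") .sort_key_num(alpha, as.numeric(r), j)
  else .sort_key_str(alpha, as.numeric(r), j)
}

# order of neighbor rows by exact 64-bit key comparison
sort_key_order <- function(alpha, r, j)
  .sort_key_order(as.integer(alpha), as.numeric(r), as.integer(j))

cell_heights <- function(cell) {
  v <- abs(det(cell))
  vapply(1:3, function(k) {
    others <- setdiff(1:3, k)
    v / sqrt(sum(pracma_cross(cell[others[1], ], cell[others[2], ])^2))
  }, 0)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Build a neighbor list
#'
#' All ordered pairs closer than `rc`, under minimum-image convention when
#' the frame is periodic.  Within each atom's list, neighbors are grouped by
#' species and sorted inside each species block by quantized distance then
#' index (the 64-bit key ordering).  If an atom has more than `nc` neighbors
#' the nearest `nc` in key order are kept with a warning.
#'
#' @param frame a [dp_frame()].
#' @param rc cutoff radius (Angstrom).  Under periodic boundaries `rc` must
#'   be smaller than half the smallest cell height for the minimum image to
#'   be valid.
#' @param nc expected maximum number of neighbors (padding size), or `NULL`
#'   for no truncation (`nc` is set to the observed maximum).
#' @return an object of class `dp_neighbors`: flat ordered-pair arrays
#'   (`i`, `j`, `rvec = r_j - r_i`, `dist`, `alpha_j`) plus the per-atom row
#'   index list `atom_rows` in sorted order, and `nc`.
#' @export
build_neighbor_list <- function(frame, rc, nc = NULL) {
  n <- frame$n_atoms
  coords <- frame$coords
  if (frame$pbc) {
    h <- frame$cell
    if (rc >= min(cell_heights(h)) / 2)
      stop("minimum-image violation: rc = ", rc,
           " not below half the smallest cell height ",
           format(min(cell_heights(h)) / 2), call. = FALSE)
  }
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  d <- coords[jj, , drop = FALSE] - coords[ii, , drop = FALSE]
  if (frame$pbc) {
    hs <- solve(frame$cell)
    s <- d %*% hs
    d <- (s - round(s)) %*% frame$cell
  }
  dist <- sqrt(.rowSums(d * d, length(ii), 3L))
  keep <- dist < rc
  ii <- ii[keep]; jj <- jj[keep]
  d <- d[keep, , drop = FALSE]; dist <- dist[keep]
  aj <- frame$species[jj]

  atom_rows <- split(seq_along(ii), factor(ii, levels = seq_len(n)))
  trunc_warned <- FALSE
  per_species <- !is.null(nc) && length(nc) > 1L
  for (a in seq_len(n)) {
    rows <- atom_rows[[a]]
    if (length(rows) == 0L) next
    ord <- sort_key_order(aj[rows], dist[rows], jj[rows] - 1L)
    rows <- rows[ord]
    if (!is.null(nc)) {
      # truncate to the padding size, per species block when nc is a
      # vector (the key sort keeps blocks contiguous, nearest first)
      keep <- if (per_species) {
        bl <- aj[rows] + 1L
        stats::ave(seq_along(rows), bl, FUN = seq_along) <= nc[bl]
      } else seq_along(rows) <= nc
      if (!all(keep)) {
        if (!trunc_warned) {
          warning("neighbor list truncated to sel = ",
                  paste(nc, collapse = "/"), " (atom with ",
                  length(rows), " neighbors); increase sel to avoid ",
                  "discarding neighbors", call. = FALSE)
          trunc_warned <- TRUE
        }
        rows <- rows[keep]
      }
    }
    atom_rows[[a]] <- rows
  }
  ordflat <- unlist(atom_rows, use.names = FALSE)
  structure(list(
    n_atoms = n,
    i = ii[ordflat], j = jj[ordflat],
    rvec = d[ordflat, , drop = FALSE],
    dist = dist[ordflat],
    alpha_j = aj[ordflat],
    atom_rows = {
      lens <- vapply(atom_rows, length, 1L)
      split(seq_along(ordflat), rep(seq_len(n), lens))[as.character(seq_len(n))]
    },
    nc = if (is.null(nc)) max(vapply(atom_rows, length, 1L), 0L)
         else sum(nc),
    rc = rc, species = frame$species, pbc = frame$pbc),
    class = "dp_neighbors")
}

#' @export
print.dp_neighbors <- function(x, ...) {
  cat("Neighbor list:", x$n_atoms, "atoms,", length(x$i),
      "ordered pairs, rc =", x$rc, "A, nc =", x$nc, "\n")
  invisible(x)
}

# per-atom row indices (possibly empty) in deterministic order
nl_rows <- function(nl, a) {
  r <- nl$atom_rows[[a]]
  if (is.null(r)) integer(0) else r
}

#' Species-block offsets of one atom's neighbor list
#'
#' Neighbors are stored species-blocked (key order), so each species
#' occupies one contiguous run; returns the start/end positions of every
#' non-empty block within the atom's sorted neighbor rows.
#'
#' @param nl a neighbor list.
#' @param atom 1-based atom index.
#' @return data frame with columns `species` (0-based), `start`, `end`.
#' @export
neighbor_species_blocks <- function(nl, atom) {
  rows <- nl_rows(nl, atom)
  if (length(rows) == 0L)
    return(data.frame(species = integer(0), start = integer(0),
                      end = integer(0)))
  a <- nl$alpha_j[rows]
  r <- rle(a)
  ends <- cumsum(r$lengths)
  data.frame(species = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' Per-atom padded environment matrices
#'
#' The coordinate matrix of each atom: rows `s(r) * (1, x/r, y/r, z/r)`
#' (full mode) or `s(r)` (radial mode) for each real neighbor, zero rows for
#' the padded slots up to `nc`.
#'
#' @param nl a neighbor list.
#' @param rs,rc switching radii.
#' @param mode `"full"` or `"radial"`.
#' @return list with per-atom matrices `R` (`nc x 4` or `nc x 1`), per-atom
#'   switching values `s`, and the padded neighbor index matrix `index`
#'   (`n_atoms x nc`, sentinel -1).
#' @export
env_matrix <- function(nl, rs, rc, mode = c("full", "radial")) {
  mode <- match.arg(mode)
  s_all <- switch_fn(nl$dist, rs, rc)
  w <- if (mode == "full") 4L else 1L
  Rs <- vector("list", nl$n_atoms)
  ss <- vector("list", nl$n_atoms)
  idx <- matrix(-1L, nl$n_atoms, nl$nc)
  for (a in seq_len(nl$n_atoms)) {
    rows <- nl_rows(nl, a)
    R <- matrix(0, nl$nc, w)
    if (length(rows)) {
      s <- s_all[rows]
      if (mode == "full") {
        rhat <- nl$rvec[rows, , drop = FALSE] / nl$dist[rows]
        R[seq_along(rows), ] <- cbind(s, s * rhat)
      } else R[seq_along(rows), 1L] <- s
      idx[a, seq_along(rows)] <- nl$j[rows] - 1L
    }
    Rs[[a]] <- R
    ss[[a]] <- s_all[rows]
  }
  list(R = Rs, s = ss, index = idx, mode = mode, rs = rs, rc = rc, nc = nl$nc)
}

#' Local-frame rotation of an atom
#'
#' The orthonormal frame spanned by the two nearest neighbors (by distance,
#' ties broken by atom index, species ignored): `e1` along the first axis
#' atom, `e2` the Gram-Schmidt complement of the second, `e3 = e1 x e2`.
#' Relative coordinates here follow the `r_i - r_j` convention of the
#' local-frame descriptor.
#'
#' @param nl a neighbor list.
#' @param atom 1-based atom index.
#' @return list with `rotation` (3 x 3, rows `e1`, `e2`, `e3`, det +1),
#'   `axis_atoms` (1-based indices of a(i), b(i)).
#' @export
local_frame <- function(nl, atom) {
  rows <- nl_rows(nl, atom)
  if (length(rows) < 2L)
    stop("local frame requires at least 2 neighbors (atom ", atom, ")",
         call. = FALSE)
  ord <- order(nl$dist[rows], nl$j[rows])
  ra <- -nl$rvec[rows[ord[1L]], ]   # r_i - r_a
  rb <- -nl$rvec[rows[ord[2L]], ]
  e1 <- ra / sqrt(sum(ra^2))
  v <- rb - sum(rb * e1) * e1
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10 * sqrt(sum(rb^2)))
    stop("degenerate local frame: axis atoms are collinear with atom ",
         atom, call. = FALSE)
  e2 <- v / nv
  e3 <- pracma_cross(e1, e2)
  list(rotation = unname(rbind(e1, e2, e3)),
       axis_atoms = c(nl$j[rows[ord[1L]]], nl$j[rows[ord[2L]]]))
}
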