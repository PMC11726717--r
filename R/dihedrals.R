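#' Signed dihedral angle series
#'
#' Computes the IUPAC signed dihedral a-b-c-d (degrees, in `(-180, 180]`)
#' for every frame of a trajectory, or for a single coordinate frame.
#' Positive angles are clockwise when looking from b towards c.
#'
#' @param traj an `allodyn_trajectory`, a frame vector in `xyz` layout, or
#'   a 4 x 3 coordinate matrix (in which case `atom_ids` defaults to 1:4).
#' @param atom_ids four distinct 1-based atom indices (a, b, c, d).
#' @return a `metric_series` with `metric = "dihedral"` (degrees); for a
#'   single frame, a numeric scalar.
#' @export
dihedral_series <- function(traj, atom_ids = NULL) {
  if (is.matrix(traj) && ncol(traj) == 3L) {
    if (is.null(atom_ids)) atom_ids <- 1:4
    traj <- as.numeric(t(traj))
  }
  if (is.numeric(traj)) {
    return(dihedral_one(frame_coords(traj, check_dihedral_ids(atom_ids))))
  }
  stopifnot(inherits(traj, "allodyn_trajectory"))
  ids <- check_dihedral_ids(atom_ids)
  vals <- vapply(seq_len(traj$nframes), function(f) {
    dihedral_one(frame_coords(traj$xyz[f, ], ids))
  }, numeric(1L))
  structure(list(metric = "dihedral", values = vals,
                 selection = paste(ids, collapse = "-"),
                 replica = traj$replica),
            class = "metric_series")
}

check_dihedral_ids <- function(atom_ids) {
  ids <- as.integer(atom_ids)
  if (length(ids) != 4L || anyDuplicated(ids))
    stop("a dihedral needs four distinct atom indices")
  ids
}

dihedral_one <- function(p) {
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14)
    stop("collinear atoms: dihedral is undefined")
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Rotamer-state occupancy of a dihedral series
#'
#' Bins side-chain dihedral angles into the three staggered rotamer
#' states: gauche+ `(0, 120]`, trans `(120, 180] U (-180, -120]` and
#' gauche- `(-120, 0]`. Angles are wrapped into `(-180, 180]` first, so
#' occupancies are invariant to adding multiples of 360 degrees.
#'
#' @param series a `metric_series` of dihedrals, or a numeric vector of
#'   angles in degrees.
#' @param residue optional residue number recorded in the result.
#' @param dihedral_name label, e.g. `"chi1"`.
#' @return a `rotamer_distribution`: list with `occupancy` (named
#'   fractions `gplus`, `trans`, `gminus` summing to 1), `n`, `residue`,
#'   `dihedral`.
#' @export
rotamer_distribution <- function(series, residue = NA_integer_,
                                 dihedral_name = "chi1") {
  x <- if (inherits(series, "metric_series")) series$values else as.numeric(series)
  if (!length(x)) stop("empty dihedral series")
  w <- ((x %% 360) + 360) %% 360
  w[w > 180] <- w[w > 180] - 360              # now in (-180, 180]
  gplus <- mean(w > 0 & w <= 120)
  trans <- mean(w > 120 | w <= -120)
  gminus <- mean(w > -120 & w <= 0)
  structure(list(occupancy = c(gplus = gplus, trans = trans, gminus = gminus),
                 n = length(x), residue = residue, dihedral = dihedral_name),
            class = "rotamer_distribution")
}

#' @export
print.rotamer_distribution <- function(x, ...) {
  cat("<rotamer_distribution> residue ", x$residue, " ", x$dihedral,
      " (n = ", x$n, "): g+ ", sprintf("%.3f", x$occupancy[["gplus"]]),
      ", trans ", sprintf("%.3f", x$occupancy[["trans"]]),
      ", g- ", sprintf("%.3f", x$occupancy[["gminus"]]), "\n", sep = "")
  invisible(x)
}
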