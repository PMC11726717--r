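#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' the selected atoms of a mobile and a reference frame, and applies the
#' transform to the whole mobile frame. The rotation is guaranteed proper
#' (determinant +1): a reflection in the SVD solution is corrected by
#' flipping the smallest singular direction.
#'
#' @param mobile numeric vector, one frame in `xyz` layout (length
#'   `3 * natom`).
#' @param reference numeric vector, same layout and length.
#' @param fit_indices 1-based atom indices (or an `allodyn_selection`)
#'   used for the fit; at least 3 non-collinear atoms.
#' @return list with `xyz` (transformed mobile frame), `rotation` (3x3,
#'   det +1), `translation` (length 3) and `rmsd` (fit-atom RMSD after
#'   superposition, Angstrom).
#' @export
superpose <- function(mobile, reference, fit_indices) {
  idx <- resolve_indices(fit_indices)
  if (length(idx) < 3L) stop("superposition needs at least 3 fit atoms")
  M <- frame_coords(mobile, idx)
  R <- frame_coords(reference, idx)
  cm <- colMeans(M); cr <- colMeans(R)
  Mc <- sweep(M, 2L, cm); Rc <- sweep(R, 2L, cr)
  if (collinear(Mc) || collinear(Rc))
    stop("degenerate (collinear) fit selection: rotation is underdetermined")
  s <- svd(crossprod(Mc, Rc))           # 3x3 covariance M^T R
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)           # maps centred mobile onto centred ref
  all_xyz <- frame_coords(mobile, seq_len(length(mobile) %/% 3L))
  moved <- sweep(all_xyz, 2L, cm) %*% t(rot)
  moved <- sweep(moved, 2L, cr, `+`)
  fit_rmsd <- sqrt(mean(rowSums((Mc %*% t(rot) - Rc)^2)))
  trans <- as.numeric(cr - rot %*% cm)
  list(xyz = as.numeric(t(moved)), rotation = rot, translation = trans,
       rmsd = fit_rmsd)
}

resolve_indices <- function(x) {
  if (inherits(x, "allodyn_selection")) x$indices else as.integer(x)
}

# atoms x 3 coordinate block for the given atom indices
frame_coords <- function(frame, idx) {
  cbind(frame[3L * idx - 2L], frame[3L * idx - 1L], frame[3L * idx])
}

collinear <- function(centred, tol = 1e-8) {
  sv <- svd(centred, nu = 0L, nv = 0L)$d
  sum(sv > tol * max(sv, tol)) < 2L
}
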