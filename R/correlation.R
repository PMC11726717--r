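#' Correlation of motion between residues
#'
#' Computes the normalised covariance of residue displacements over the
#' merged frame pool,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#' {\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}},}
#' where \eqn{\Delta r_i} is the displacement of residue i's C-alpha from
#' its time-mean position. When `fit_sel` is given, frames are first
#' superposed (two-pass, as in [rmsf_profile()]) to remove global
#' rotation/translation. Exact symmetry and a unit diagonal are enforced.
#'
#' @param trajs trajectory or list of replica trajectories (merged).
#' @param ca_sel selection of one atom per residue (typically
#'   `"name CA"`).
#' @param fit_sel superposition atoms, or `NULL` for pre-aligned frames.
#' @return a `corr_matrix`: residue-indexed symmetric matrix with
#'   dimnames set to residue numbers.
#' @export
correlation_matrix <- function(trajs, ca_sel, fit_sel = NULL) {
  m <- merge_replicas(trajs)
  if (nrow(m$xyz) < 2L) stop("correlation needs at least 2 merged frames")
  idx <- resolve_indices(ca_sel)
  if (!length(idx)) stop("empty selection")
  resno <- m$topology$atom$resno[idx]
  if (anyDuplicated(resno))
    stop("ca_sel must select exactly one atom per residue")
  xyz <- m$xyz
  if (!is.null(fit_sel)) {
    ref <- xyz[1L, ]
    pass1 <- t(apply(xyz, 1L, function(fr) superpose(fr, ref, fit_sel)$xyz))
    mu <- colMeans(pass1)
    xyz <- t(apply(xyz, 1L, function(fr) superpose(fr, mu, fit_sel)$xyz))
  }
  n <- length(idx)
  cols <- as.vector(vapply(idx, function(a) (3L * a - 2L):(3L * a),
                           integer(3L)))
  X <- xyz[, cols, drop = FALSE]
  X <- sweep(X, 2L, colMeans(X))
  # inner products of 3-vector displacements: sum over the residue's x,y,z
  G <- crossprod(X) / nrow(X)
  dim(G) <- c(3L, n, 3L, n)
  cov_ij <- apply(G, c(2L, 4L), function(b) sum(diag(b)))
  v <- diag(cov_ij)
  if (any(v <= 0))
    stop("zero-variance residue(s): ",
         paste(resno[v <= 0], collapse = ", "))
  C <- cov_ij / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  dimnames(C) <- list(resno, resno)
  class(C) <- c("corr_matrix", "matrix")
  C
}
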