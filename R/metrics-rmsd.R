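#' Per-frame RMSD of a selection
#'
#' Computes the RMSD of `analysis_sel` against a reference frame for every
#' frame of a trajectory, optionally after rigid-body superposition on
#' `fit_sel` (e.g. receptor C-alphas). With `fit_sel = NULL` no fit is
#' applied, which measures displacement in the laboratory frame.
#'
#' @param traj an `allodyn_trajectory`.
#' @param reference reference frame (`xyz` vector of the trajectory's atom
#'   count); defaults to the first frame.
#' @param analysis_sel atoms measured (`allodyn_selection` or indices).
#' @param fit_sel atoms used for superposition, or `NULL` for none.
#' @return a `metric_series`: list with `metric = "RMSD"`, per-frame
#'   `values` (Angstrom), `selection`, `replica`.
#' @export
rmsd_series <- function(traj, reference = NULL, analysis_sel,
                        fit_sel = NULL) {
  stopifnot(inherits(traj, "allodyn_trajectory"))
  if (is.null(reference)) reference <- traj$xyz[1L, ]
  if (length(reference) != 3L * traj$natom)
    stop("reference frame does not match trajectory atom count")
  a_idx <- resolve_indices(analysis_sel)
  if (!length(a_idx)) stop("empty analysis selection")
  ref_a <- frame_coords(reference, a_idx)
  vals <- vapply(seq_len(traj$nframes), function(f) {
    fr <- traj$xyz[f, ]
    if (!is.null(fit_sel)) fr <- superpose(fr, reference, fit_sel)$xyz
    sqrt(mean(rowSums((frame_coords(fr, a_idx) - ref_a)^2)))
  }, numeric(1L))
  structure(list(metric = "RMSD", values = vals,
                 selection = selection_label(analysis_sel),
                 replica = traj$replica),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat("<metric_series> ", x$metric, " [", x$selection, "], ",
      length(x$values), " frames: ", format_mean_sd(x$values), "\n", sep = "")
  invisible(x)
}

#' Summarise a metric as "mean +/- SD"
#'
#' @param x numeric vector or `metric_series`.
#' @param digits digits after the decimal point.
#' @return character scalar, e.g. `"2.32 ± 0.87"`.
#' @export
format_mean_sd <- function(x, digits = 2L) {
  if (inherits(x, "metric_series")) x <- x$values
  sprintf("%.*f ± %.*f", digits, mean(x), digits, sd(x))
}

#' Per-residue RMSF over merged replicas
#'
#' Root-mean-square fluctuation about the mean structure. When `fit_sel`
#' is given a two-pass scheme is used: frames are first superposed on the
#' reference, the mean structure is computed, frames are re-superposed on
#' that mean and the mean is recomputed before measuring fluctuations.
#' Residue positions are averaged over the selected atoms of the residue
#' (for a C-alpha selection this is the C-alpha itself).
#'
#' @param trajs trajectory or list of replica trajectories.
#' @param selection atoms measured (typically `"name CA"`).
#' @param fit_sel superposition atoms, or `NULL` to measure in the frame
#'   as stored (appropriate for pre-aligned or synthetic ensembles).
#' @return an `rmsf_profile` data frame with columns `resno`, `rmsf` (A).
#' @export
rmsf_profile <- function(trajs, selection, fit_sel = NULL) {
  m <- merge_replicas(trajs)
  if (nrow(m$xyz) < 2L) stop("RMSF needs at least 2 merged frames")
  idx <- resolve_indices(selection)
  if (!length(idx)) stop("empty selection")
  xyz <- m$xyz
  if (!is.null(fit_sel)) {
    ref <- xyz[1L, ]
    pass1 <- t(apply(xyz, 1L, function(fr) superpose(fr, ref, fit_sel)$xyz))
    mu <- colMeans(pass1)
    xyz <- t(apply(xyz, 1L, function(fr) superpose(fr, mu, fit_sel)$xyz))
  }
  mu <- colMeans(xyz)
  resno <- m$topology$atom$resno[idx]
  # squared fluctuation per selected atom, then averaged within residue
  sq <- vapply(idx, function(a) {
    cols <- (3L * a - 2L):(3L * a)
    d <- sweep(xyz[, cols, drop = FALSE], 2L, mu[cols])
    mean(rowSums(d^2))
  }, numeric(1L))
  per_res <- tapply(sq, resno, mean)
  out <- data.frame(resno = as.integer(names(per_res)),
                    rmsf = sqrt(as.numeric(per_res)))
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rmsf_profile", "data.frame")
  attr(out, "selection") <- selection_label(selection)
  attr(out, "nframes") <- nrow(xyz)
  out
}

selection_label <- function(sel) {
  if (inherits(sel, "allodyn_selection")) sel$expression
  else paste0("indices[", length(resolve_indices(sel)), "]")
}
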