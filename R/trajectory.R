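#' Construct a trajectory object
#'
#' A trajectory binds an ordered set of coordinate frames (in Angstrom) to
#' a topology and a replica id. Frames are rows of an `nframes x 3*natom`
#' matrix in bio3d `xyz` layout (x1, y1, z1, x2, ...).
#'
#' @param xyz numeric matrix of frames.
#' @param topology an `allodyn_topology`.
#' @param replica replica identifier (integer or label).
#' @return an `allodyn_trajectory`.
#' @export
trajectory <- function(xyz, topology, replica = 1L) {
  stopifnot(inherits(topology, "allodyn_topology"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * topology$natom)
    stop("frame width (", ncol(xyz), ") does not match topology atom count (",
         topology$natom, ")")
  if (!all(is.finite(xyz))) stop("trajectory contains non-finite coordinates")
  structure(list(xyz = xyz, topology = topology, replica = replica,
                 natom = topology$natom, nframes = nrow(xyz)),
            class = "allodyn_trajectory")
}

#' @export
print.allodyn_trajectory <- function(x, ...) {
  cat("<allodyn_trajectory> replica ", format(x$replica), ": ", x$nframes,
      " frames x ", x$natom, " atoms\n", sep = "")
  invisible(x)
}

#' Read one replica's trajectory from DCD files
#'
#' Frames from multiple files are concatenated in file order into a single
#' replica. Only the CHARMM/NAMD DCD dialect is supported; other trajectory
#' formats fail loudly rather than being guessed at.
#'
#' @param paths character vector of DCD files, in order.
#' @param topology the matching `allodyn_topology`.
#' @param replica replica identifier attached to the result.
#' @return an `allodyn_trajectory`.
#' @export
read_trajectory <- function(paths, topology, replica = 1L) {
  stopifnot(inherits(topology, "allodyn_topology"), length(paths) >= 1L)
  bad_ext <- !grepl("\\.dcd$", paths, ignore.case = TRUE)
  if (any(bad_ext))
    stop("unsupported trajectory format (only DCD is read): ",
         paste(basename(paths[bad_ext]), collapse = ", "))
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    m <- tryCatch(bio3d::read.dcd(p, verbose = FALSE),
                  error = function(e) stop("truncated or unreadable DCD '", p,
                                           "': ", conditionMessage(e)))
    m <- unclass(m)
    if (ncol(m) != 3L * topology$natom)
      stop("DCD '", p, "' has ", ncol(m) / 3, " atoms but topology has ",
           topology$natom)
    m
  })
  trajectory(do.call(rbind, frames), topology, replica)
}

#' Write frames as a CHARMM-dialect DCD file
#'
#' Minimal single-precision DCD writer (no unit cell, no fixed atoms) used
#' by the synthetic generators so that synthetic ensembles flow through the
#' same reader as real trajectories.
#'
#' @param xyz frame matrix (`nframes x 3*natom`, bio3d layout) or an
#'   `allodyn_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(xyz, path) {
  if (inherits(xyz, "allodyn_trajectory")) xyz <- xyz$xyz
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) stop("frame width must be a multiple of 3")
  natom <- ncol(xyz) %/% 3L
  nframes <- nrow(xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header record: "CORD" + 20 control ints (frame count, step info,
  # timestep, unit-cell flag = 0, CHARMM version tag)
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  icntrl <- integer(20L)
  icntrl[1L] <- nframes
  icntrl[2L] <- 1L
  icntrl[3L] <- 1L
  icntrl[4L] <- nframes
  icntrl[20L] <- 24L
  wint(icntrl)
  wint(84L)
  title <- formatC("Synthetic ensemble written by allodyn", width = -80L)
  wint(4L + 80L)
  wint(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wint(4L + 80L)
  wint(4L); wint(natom); wint(4L)
  ix <- seq(1L, 3L * natom, by = 3L)
  for (f in seq_len(nframes)) {
    fr <- xyz[f, ]
    for (off in 0:2) {
      wint(4L * natom)
      writeBin(as.numeric(fr[ix + off]), con, size = 4L, endian = "little")
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Merge replicas into one frame pool
#'
#' Accepts a single trajectory or a list of them and returns the stacked
#' frame matrix together with per-replica frame counts; used by every
#' estimator that works on merged replicas.
#'
#' @param trajs an `allodyn_trajectory` or list of them (same topology).
#' @return list with `xyz` (stacked frames), `nframes` (per replica),
#'   `replica` (ids) and `topology`.
#' @keywords internal
merge_replicas <- function(trajs) {
  if (inherits(trajs, "allodyn_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L,
            all(vapply(trajs, inherits, TRUE, "allodyn_trajectory")))
  natom <- unique(vapply(trajs, `[[`, 0L, "natom"))
  if (length(natom) != 1L) stop("replicas disagree on atom count")
  list(xyz = do.call(rbind, lapply(trajs, `[[`, "xyz")),
       nframes = vapply(trajs, `[[`, 0L, "nframes"),
       replica = lapply(trajs, `[[`, "replica"),
       topology = trajs[[1L]]$topology)
}
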