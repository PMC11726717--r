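#' Specify a harmonic ensemble with prescribed correlation of motion
#'
#' The generator draws i.i.d. frames about a mean structure in which each
#' residue's displacement along every Cartesian axis is
#' \eqn{\sigma_i z_i}, with the residue-level latent vector
#' \eqn{z \sim N(0, R)} sharing one correlation matrix `R` across the
#' three axes. Under this model the correlation of motion
#' \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}}
#' equals `R[i, j]` exactly and the per-residue RMSF equals
#' \eqn{\sqrt{3}\,\sigma_i}, so network-recovery and fluctuation tests have
#' closed-form truth. Frames are independent: time correlation is not
#' modelled.
#'
#' @param n_residues number of residues (one C-alpha node each).
#' @param sigma per-coordinate displacement standard deviation in
#'   Angstrom; length 1 or `n_residues`, all > 0.
#' @param correlation target residue correlation matrix (symmetric, unit
#'   diagonal, entries in `[-1, 1]`, positive semidefinite). Default
#'   identity (independent residues).
#' @param mean_structure C-alpha coordinates in `xyz` layout (length
#'   `3 * n_residues`); default an extended chain with 3.8 A spacing.
#' @param n_frames frames per replica (>= 2).
#' @param n_replicas number of replicas.
#' @param seed integer seed; identical spec + seed give identical frames.
#' @return an object of class `harmonic_spec`.
#' @export
harmonic_ensemble_spec <- function(n_residues, sigma, correlation = NULL,
                                   mean_structure = NULL, n_frames,
                                   n_replicas = 1L, seed = 1L) {
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 1L, n_frames >= 2L, n_replicas >= 1L)
  sigma <- rep_len(as.numeric(sigma), n_residues)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("per-residue sigma must be strictly positive")
  if (is.null(correlation)) correlation <- diag(n_residues)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(dim(correlation), c(n_residues, n_residues))))
    stop("correlation matrix must be ", n_residues, " x ", n_residues)
  if (max(abs(correlation - t(correlation))) > 1e-12)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal")
  if (any(correlation < -1 - 1e-12) || any(correlation > 1 + 1e-12))
    stop("correlation entries must lie in [-1, 1]")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("correlation matrix is not positive semidefinite ",
         "(min eigenvalue ", format(min(ev)), ")")
  if (is.null(mean_structure)) {
    mean_structure <- as.numeric(t(cbind(3.8 * (seq_len(n_residues) - 1), 0, 0)))
  }
  if (length(mean_structure) != 3L * n_residues)
    stop("mean_structure must have length 3 * n_residues")
  structure(list(n_residues = n_residues, sigma = sigma,
                 correlation = correlation, mean_structure = mean_structure,
                 n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas), seed = as.integer(seed)),
            class = "harmonic_spec")
}

#' Build the C-alpha topology of a synthetic ensemble
#'
#' @param n_residues residue count.
#' @param mean_structure coordinates stored on the topology (optional).
#' @return an `allodyn_topology` with one CA atom per residue.
#' @export
calpha_topology <- function(n_residues, mean_structure = NULL) {
  n <- as.integer(n_residues)
  structure(
    list(atom = data.frame(eleno = seq_len(n), elety = "CA",
                           resno = seq_len(n), resid = "ALA", chain = "A",
                           elesy = "C", stringsAsFactors = FALSE),
         bw = NULL, natom = n, xyz = mean_structure),
    class = "allodyn_topology")
}

#' Generate harmonic-ensemble trajectories
#'
#' Draws `n_replicas` trajectories from the model described in
#' [harmonic_ensemble_spec()]. The latent square-root factor comes from the
#' eigendecomposition of the target correlation matrix, so rank-deficient
#' (perfectly correlated) targets are allowed.
#'
#' @param spec a `harmonic_spec`.
#' @return a list of `allodyn_trajectory` objects (one per replica)
#'   sharing a C-alpha topology.
#' @export
gen_harmonic_trajectory <- function(spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  n <- spec$n_residues
  eg <- eigen(spec$correlation, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  L <- eg$vectors %*% diag(sqrt(lam), n)        # z = L %*% iid gives cov R
  top <- calpha_topology(n, spec$mean_structure)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_replicas), function(rep_id) {
    xyz <- matrix(rep(spec$mean_structure, each = spec$n_frames),
                  nrow = spec$n_frames)
    for (axis in 1:3) {
      z <- matrix(rnorm(spec$n_frames * n), spec$n_frames, n) %*% t(L)
      disp <- sweep(z, 2L, spec$sigma, `*`)
      cols <- 3L * seq_len(n) - (3L - axis)
      xyz[, cols] <- xyz[, cols] + disp
    }
    trajectory(xyz, top, replica = rep_id)
  })
}

#' Write a synthetic ensemble to disk as PDB + DCD
#'
#' Emits the mean structure as a PDB topology and one DCD per replica so
#' that synthetic data enter the pipeline through the same readers as real
#' trajectories.
#'
#' @param spec a `harmonic_spec`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return list with `topology` (PDB path) and `trajectories` (DCD paths).
#' @export
write_harmonic_ensemble <- function(spec, dir, prefix = "ensemble") {
  trajs <- gen_harmonic_trajectory(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(prefix, ".pdb"))
  write_topology_pdb(trajs[[1L]]$topology, pdb, xyz = spec$mean_structure)
  dcds <- vapply(seq_along(trajs), function(i) {
    p <- file.path(dir, sprintf("%s_rep%d.dcd", prefix, i))
    write_dcd(trajs[[i]], p)
    p
  }, character(1L))
  list(topology = pdb, trajectories = dcds)
}

#' Four-atom fixture with a prescribed dihedral angle
#'
#' Builds atoms a-b-c-d with 1.5 A bonds and tetrahedral bond angles such
#' that the signed dihedral a-b-c-d equals `angle` exactly (to numerical
#' precision). `angle = 180` is the trans zig-zag, `0` the cis geometry.
#'
#' @param angle target dihedral in degrees, in `(-180, 180]`.
#' @return a 4 x 3 coordinate matrix (rows a, b, c, d).
#' @export
gen_dihedral_fixture <- function(angle) {
  if (!is.finite(angle) || angle <= -180 || angle > 180)
    stop("angle must lie in (-180, 180]")
  phi <- angle * pi / 180
  bond <- 1.5
  beta <- (180 - 109.47) * pi / 180          # supplement of the bond angle
  a <- c(-bond * cos(beta), bond * sin(beta), 0)
  b <- c(0, 0, 0)
  c_ <- c(bond, 0, 0)
  d <- c_ + bond * c(cos(beta), sin(beta) * cos(phi), sin(beta) * sin(phi))
  rbind(a = a, b = b, c = c_, d = d)
}

#' Generate a planted-community dynamical network
#'
#' Stochastic block model with `n_blocks` blocks of `n_per_block` nodes:
#' within-block edges appear with probability `p_in` and carry high
#' correlation of motion, between-block edges appear with probability
#' `p_out` and carry low correlation; weights are `-log|C|`. Block labels
#' are recorded as ground truth for community-recovery tests.
#'
#' @param n_per_block nodes per block (>= 2).
#' @param n_blocks number of blocks (>= 1).
#' @param p_in,p_out edge probabilities, `p_in > p_out`.
#' @param seed integer seed.
#' @param c_in,c_out ranges (length 2) of |C| for within/between edges.
#' @return an `allodyn_network` with a `truth` attribute (block labels).
#' @export
gen_planted_network <- function(n_per_block, n_blocks, p_in, p_out, seed = 1L,
                                c_in = c(0.7, 0.95), c_out = c(0.1, 0.4)) {
  n_per_block <- as.integer(n_per_block); n_blocks <- as.integer(n_blocks)
  if (n_per_block < 2L || n_blocks < 1L)
    stop("degenerate block sizes: need n_per_block >= 2 and n_blocks >= 1")
  if (!(p_in > p_out)) stop("p_in must exceed p_out")
  stopifnot(p_in <= 1, p_out >= 0)
  n <- n_per_block * n_blocks
  block <- rep(seq_len(n_blocks), each = n_per_block)
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[pairs[, 1L]] == block[pairs[, 2L]]
  keep <- stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  ei <- pairs[keep, , drop = FALSE]
  cmag <- ifelse(same[keep],
                 stats::runif(sum(keep), c_in[1L], c_in[2L]),
                 stats::runif(sum(keep), c_out[1L], c_out[2L]))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (nrow(ei)) {
    g <- igraph::add_edges(g, as.vector(t(ei)))
    igraph::E(g)$corr <- cmag
    igraph::E(g)$weight <- -log(cmag)
    igraph::E(g)$persistency <- 100
  }
  net <- new_dynet(g, params = list(log_base = exp(1)),
                   provenance = list(condition = "planted", seed = seed))
  net$truth <- block
  net
}

#' Simulate concentration--response data from the operational model
#'
#' Responses are operational-model-of-allosterism predictions (see
#' [operational_response()]) plus i.i.d. Gaussian noise. Defaults mirror a
#' cAMP-accumulation study design: agonist 1 pM--1 uM in log10 steps,
#' modulator vehicle plus 10 nM--10 uM, 4 replicates, responses on a 0--100
#' normalized scale with noise sd 5.
#'
#' @param pars operational-model parameters from [operational_pars()].
#' @param agonist_conc agonist concentrations (molar, > 0).
#' @param modulator_conc modulator concentrations (molar, 0 = vehicle).
#' @param n_replicates replicate count.
#' @param noise_sd Gaussian noise sd in response units (>= 0).
#' @param seed integer seed.
#' @param agonist label stored in the `agonist` column.
#' @return an `allodyn_dose_response` data frame.
#' @export
gen_dose_response <- function(pars,
                              agonist_conc = 10^seq(-12, -6),
                              modulator_conc = c(0, 1e-8, 1e-7, 1e-6, 1e-5),
                              n_replicates = 4L, noise_sd = 5, seed = 1L,
                              agonist = "agonist") {
  stopifnot(all(agonist_conc > 0), all(modulator_conc >= 0), noise_sd >= 0,
            n_replicates >= 1L)
  grid <- expand.grid(agonist_conc = agonist_conc,
                      modulator_conc = modulator_conc,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- operational_response(grid$agonist_conc, grid$modulator_conc, pars)
  set.seed(seed)
  grid$response <- mu + rnorm(nrow(grid), 0, noise_sd)
  grid$agonist <- agonist
  as_dose_response(grid[c("agonist", "agonist_conc", "modulator_conc",
                          "response", "replicate")])
}

#' Simulate concentration--response data from a unit-slope logistic
#'
#' Single-curve counterpart of [gen_dose_response()] used for
#' potency-recovery studies (e.g. BRET G protein dissociation reads):
#' responses follow the 3-parameter logistic with Hill slope 1 plus
#' Gaussian noise.
#'
#' @param pec50 generating potency (-log10 molar).
#' @param agonist_conc agonist concentrations (molar).
#' @param top,bottom asymptotes (response units).
#' @param n_replicates,noise_sd,seed,agonist as in [gen_dose_response()].
#' @param modulator_conc single modulator concentration tag for the rows
#'   (molar; default 0 = vehicle).
#' @return an `allodyn_dose_response` data frame.
#' @export
gen_logistic_dose_response <- function(pec50, agonist_conc = 10^seq(-12, -6),
                                       top = 100, bottom = 0,
                                       n_replicates = 4L, noise_sd = 5,
                                       seed = 1L, agonist = "agonist",
                                       modulator_conc = 0) {
  stopifnot(all(agonist_conc > 0), noise_sd >= 0, length(modulator_conc) == 1L)
  grid <- expand.grid(agonist_conc = agonist_conc,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- logistic3_response(grid$agonist_conc, pec50, top, bottom)
  set.seed(seed)
  grid$response <- mu + rnorm(nrow(grid), 0, noise_sd)
  grid$agonist <- agonist
  grid$modulator_conc <- modulator_conc
  as_dose_response(grid[c("agonist", "agonist_conc", "modulator_conc",
                          "response", "replicate")])
}
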