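test_that("harmonic generator is seed-deterministic and shape-correct", {
  spec <- harmonic_ensemble_spec(4, 0.5, n_frames = 50, n_replicas = 2,
                                 seed = 11)
  t1 <- gen_harmonic_trajectory(spec)
  t2 <- gen_harmonic_trajectory(spec)
  expect_identical(t1[[1]]$xyz, t2[[1]]$xyz)
  expect_identical(t1[[2]]$xyz, t2[[2]]$xyz)
  expect_false(identical(t1[[1]]$xyz, t1[[2]]$xyz))
  expect_equal(t1[[1]]$nframes, 50L)
  expect_equal(unique(vapply(t1, `[[`, 0L, "natom")), 4L)
  spec2 <- harmonic_ensemble_spec(4, 0.5, n_frames = 50, n_replicas = 1,
                                  seed = 12)
  expect_false(identical(gen_harmonic_trajectory(spec2)[[1]]$xyz,
                         t1[[1]]$xyz))
})

test_that("harmonic spec rejects invalid inputs", {
  expect_error(harmonic_ensemble_spec(3, 0, n_frames = 10), "positive")
  expect_error(harmonic_ensemble_spec(3, -1, n_frames = 10), "positive")
  bad <- diag(3); bad[1, 2] <- 0.5            # asymmetric
  expect_error(harmonic_ensemble_spec(3, 1, bad, n_frames = 10), "symmetric")
  nonpsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(harmonic_ensemble_spec(3, 1, nonpsd, n_frames = 10),
               "positive semidefinite")
  baddiag <- diag(3) * 1.1
  expect_error(harmonic_ensemble_spec(3, 1, baddiag, n_frames = 10),
               "unit diagonal")
})

test_that("independent-residue ensemble has near-zero cross correlations", {
  spec <- harmonic_ensemble_spec(6, 0.5, n_frames = 1e4, seed = 21)
  tr <- gen_harmonic_trajectory(spec)[[1]]
  C <- correlation_matrix(tr, select_atoms(tr$topology, "name CA"))
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("dihedral fixtures reproduce the requested angle", {
  expect_equal(dihedral_series(gen_dihedral_fixture(180)), 180,
               tolerance = 1e-9)
  expect_equal(dihedral_series(gen_dihedral_fixture(0)), 0,
               tolerance = 1e-9)
  for (a in c(60, -60, 135.5, -179.9, 1e-3))
    expect_equal(dihedral_series(gen_dihedral_fixture(a)), a,
                 tolerance = 1e-6)
  expect_error(gen_dihedral_fixture(-180), "-180, 180")
  expect_error(gen_dihedral_fixture(200), "-180, 180")
})

test_that("planted networks respect block structure parameters", {
  expect_error(gen_planted_network(1, 3, 0.9, 0.1), "degenerate")
  expect_error(gen_planted_network(5, 3, 0.1, 0.5), "exceed")
  net <- gen_planted_network(6, 3, 1, 0, seed = 4)
  expect_equal(igraph::count_components(net$graph), 3)
  expect_true(all(igraph::E(net$graph)$weight > 0))
  expect_equal(net$truth, rep(1:3, each = 6))
  # determinism
  net2 <- gen_planted_network(6, 3, 1, 0, seed = 4)
  expect_identical(network_edges(net), network_edges(net2))
})

test_that("dose-response generator sits on the model surface at zero noise", {
  pars <- operational_pars(Em = 100, tauA = 2, tauB = 0.3, pKA = 7,
                           pKB = 7.5, logab = 1.2)
  d <- gen_dose_response(pars, n_replicates = 2, noise_sd = 0, seed = 5)
  expect_equal(d$response,
               operational_response(d$agonist_conc, d$modulator_conc, pars))
  # seeded determinism with noise
  d1 <- gen_dose_response(pars, noise_sd = 4, seed = 9)
  d2 <- gen_dose_response(pars, noise_sd = 4, seed = 9)
  expect_identical(d1$response, d2$response)
})

test_that("null cooperativity with silent modulator collapses onto vehicle", {
  pars <- operational_pars(Em = 100, tauA = 3, tauB = 1e-8, pKA = 7.2,
                           pKB = 7, logab = 0)
  d <- gen_dose_response(pars, n_replicates = 1, noise_sd = 0, seed = 1)
  veh <- d[d$modulator_conc == 0, ]
  for (b in setdiff(unique(d$modulator_conc), 0)) {
    cur <- d[d$modulator_conc == b, ]
    expect_equal(cur$response[order(cur$agonist_conc)],
                 veh$response[order(veh$agonist_conc)], tolerance = 1e-6)
  }
})

test_that("ensembles round-trip to disk through PDB + DCD", {
  spec <- harmonic_ensemble_spec(5, 0.4, n_frames = 12, n_replicas = 2,
                                 seed = 3)
  dir <- tempfile(); files <- write_harmonic_ensemble(spec, dir)
  top <- read_topology(files$topology)
  expect_equal(top$natom, 5L)
  trs <- gen_harmonic_trajectory(spec)
  for (i in 1:2) {
    rt <- read_trajectory(files$trajectories[i], top, replica = i)
    expect_equal(rt$nframes, 12L)
    expect_lt(max(abs(rt$xyz - trs[[i]]$xyz)), 1e-3)
  }
})
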