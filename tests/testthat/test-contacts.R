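test_that("contact persistency counts frames with the closed 4.5 A gate", {
  # residues at x = 0, 3, 10: pair (1,2) at 3 A always; (1,3) never
  tr <- static_chain_traj(c(0, 3, 10), n_frames = 4)
  tab <- contact_persistency(tr, 1:3, 1:3, allow_overlap = TRUE)
  expect_equal(tab$persistency[tab$resno_a == 1 & tab$resno_b == 2], 100)
  expect_equal(tab$persistency[tab$resno_a == 1 & tab$resno_b == 3], 0)
  expect_true(tab$consecutive[tab$resno_a == 1 & tab$resno_b == 2])
  # boundary: exactly the cutoff counts as contact in every frame
  trb <- static_chain_traj(c(0, 4.5), n_frames = 3)
  tb <- contact_persistency(trb, 1L, 2L)
  expect_equal(tb$persistency, 100)
})

test_that("partial contacts give fractional persistency (2 of 3 frames)", {
  top <- calpha_topology(2)
  near <- as.numeric(t(cbind(c(0, 3), 0, 0)))
  far <- as.numeric(t(cbind(c(0, 30), 0, 0)))
  tr <- trajectory(rbind(near, near, far), top)
  tab <- contact_persistency(tr, 1L, 2L)
  expect_equal(tab$persistency, 200 / 3, tolerance = 1e-9)
})

test_that("merged persistency is the frame-weighted mean over replicas", {
  top <- calpha_topology(2)
  near <- as.numeric(t(cbind(c(0, 3), 0, 0)))
  far <- as.numeric(t(cbind(c(0, 30), 0, 0)))
  r1 <- trajectory(rbind(near, near, near, far), top, replica = 1)  # 75%
  r2 <- trajectory(rbind(near, far), top, replica = 2)              # 50%
  tab <- contact_persistency(list(r1, r2), 1L, 2L)
  expect_equal(tab$rep_1, 75)
  expect_equal(tab$rep_2, 50)
  expect_equal(tab$persistency, (3 + 1) / 6 * 100)
  expect_equal(tab$persistency,
               sum(c(75, 50) * c(4, 2)) / 6)       # frame-weighted mean
  # invariance under frame reordering and replica relabelling
  r1s <- trajectory(rbind(far, near, near, near), top, replica = 1)
  tab2 <- contact_persistency(list(r2, r1s), 1L, 2L)
  expect_equal(sort(unlist(tab2[, c("rep_1", "rep_2")])),
               sort(unlist(tab[, c("rep_1", "rep_2")])),
               ignore_attr = TRUE)
  expect_equal(tab2$persistency, tab$persistency)
})

test_that("overlapping selections need explicit intra mode", {
  tr <- static_chain_traj(c(0, 3, 6))
  expect_error(contact_persistency(tr, 1:3, 1:3), "allow_overlap")
})

test_that("hydrogen bonds apply distance and angle gates", {
  # donor at origin, H on the D-A axis (linear, 180 deg), acceptor at 2.8 A
  top <- calpha_topology(3)
  top$atom$elety <- c("N", "H", "O")
  top$atom$elesy <- c("N", "H", "O")
  linear <- as.numeric(t(rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))))
  bent <- as.numeric(t(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.6, 0))))
  bonds <- data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L)
  tr_lin <- trajectory(rbind(linear, linear), top)
  expect_equal(hbond_persistency(tr_lin, bonds)$persistency, 100)
  # 90 degree D-H-A angle fails a 120 degree cutoff despite the distance
  tr_bent <- trajectory(rbind(bent, bent), top)
  expect_equal(hbond_persistency(tr_bent, bonds)$persistency, 0)
  expect_equal(hbond_persistency(tr_bent, bonds,
                                 geometric_only = TRUE)$persistency, 100)
  # toggled geometry in half the frames
  tr_half <- trajectory(rbind(linear, bent), top)
  expect_equal(hbond_persistency(tr_half, bonds)$persistency, 50)
  bonds_na <- data.frame(donor = 1L, hydrogen = NA, acceptor = 3L)
  expect_error(hbond_persistency(tr_half, bonds_na), "geometric_only")
})

test_that("contact differences propagate replica spread", {
  a <- manual_contact_table(1, 5, 100)
  expect_equal(contact_difference(a, a)$delta, 0)
  b <- manual_contact_table(1, 5, 25)
  expect_equal(contact_difference(a, b)$delta, 75)
  a3 <- manual_contact_table(1, 5, 40, reps = matrix(c(20, 40, 60), 1))
  b3 <- manual_contact_table(1, 5, 20, reps = matrix(c(10, 20, 30), 1))
  d <- contact_difference(a3, b3)
  expect_equal(d$delta, 20)
  expect_equal(d$sd, 10)                    # sd of (10, 20, 30)
  # mismatched replica counts fall back to pooled variance
  b2 <- manual_contact_table(1, 5, 20, reps = matrix(c(10, 30), 1))
  d2 <- contact_difference(a3, b2)
  expect_equal(d2$sd, sqrt(var(c(20, 40, 60)) + var(c(10, 30))))
  far <- manual_contact_table(90, 95, 10)
  expect_error(contact_difference(a, far), "disjoint")
})
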